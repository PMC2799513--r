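test_that("maxmean matches hand values and the direct formula", {
  z <- c(a = 1, b = -2, c = 3)
  expect_equal(maxmean(c("a", "b", "c"), z), 4 / 3, tolerance = 1e-12)
  expect_equal(maxmean(c("a", "b"), c(a = -1, b = -1)), -1.0)
  expect_equal(maxmean(c("a", "b"), c(a = 0, b = 0)), 0)
  expect_error(maxmean("zz", z), "data error")
  set.seed(41)
  for (i in 1:1000) {
    m <- sample(2:30, 1)
    zz <- stats::setNames(stats::rnorm(m), paste0("g", seq_len(m)))
    expect_equal(maxmean(names(zz), zz), oracle_maxmean(zz),
                 tolerance = 1e-12)
  }
  # positive homogeneity
  zz <- stats::setNames(stats::rnorm(20), paste0("g", 1:20))
  for (cc in c(0.5, 2, 10))
    expect_equal(maxmean(names(zz), cc * zz),
                 cc * maxmean(names(zz), zz), tolerance = 1e-12)
})

test_that("hypergeometric upper tail equals enumeration over the full grid", {
  for (N in c(1, 5, 12, 20, 25)) {
    for (K in 0:N) {
      for (n in c(0, 1, floor(N / 2), N)) {
        for (k in 0:(min(K, n) + 1)) {
          expect_equal(hypergeom_tail(N, K, n, k),
                       oracle_hyper_tail(N, K, n, k), tolerance = 1e-12)
        }
      }
    }
  }
  expect_equal(hypergeom_tail(20, 5, 5, 0), 1.0)
  expect_equal(hypergeom_tail(20, 5, 5, 2),
               1 - (choose(15, 5) + 5 * choose(15, 4)) / choose(20, 5),
               tolerance = 1e-12)
  expect_equal(hypergeom_tail(20, 5, 5, 6), 0.0)
  expect_error(hypergeom_tail(10, 12, 5, 1), "data error")
  # log-space evaluation stays finite where naive products overflow
  expect_gt(hypergeom_tail(10000, 500, 400, 10), 0)
})

test_that("consensus membership cutoff is the ceiling of the fraction", {
  sets23 <- lapply(1:23, function(i) sprintf("s%d_g%d", i, 1:3))
  names(sets23) <- paste0("S", 1:23)
  cs <- consensus_signature(sets23, 0.25)
  expect_equal(cs$min_count, 6L)
  for (n_sets in c(1, 4, 8, 23, 40)) {
    for (f in c(0.1, 0.25, 0.5, 1)) {
      sets <- lapply(seq_len(n_sets), function(i) "g1")
      names(sets) <- paste0("S", seq_len(n_sets))
      expect_equal(consensus_signature(sets, f)$min_count,
                   as.integer(ceiling(f * n_sets - 1e-9)))
    }
  }
  # a single set at fraction 0.25 keeps all its genes
  one <- consensus_signature(list(A = c("x", "y")), 0.25)
  expect_equal(one$min_count, 1L)
  expect_setequal(one$members$gene_id, c("x", "y"))
  # counting rule: gene in 2 of 4 sets at fraction 0.5 is in, 1 of 4 is out
  sets4 <- list(A = c("in2", "only1"), B = "in2", C = "other", D = "other2")
  cs4 <- consensus_signature(sets4, 0.5)
  expect_true("in2" %in% cs4$members$gene_id)
  expect_false("only1" %in% cs4$members$gene_id)
  expect_error(consensus_signature(sets4, 0), "configuration error")
  expect_error(consensus_signature(sets4, 1.1), "configuration error")
})

test_that("membership counts from planted catalogs drive consensus", {
  uni <- sprintf("g%03d", 1:200)
  cat1 <- simulate_gene_sets(23, 15, planted = c(g001 = 6, g002 = 5),
                             universe = uni, seed = 42)
  cs <- consensus_signature(cat1, 0.25)
  expect_true("g001" %in% cs$members$gene_id)
  expect_false("g002" %in% cs$members$gene_id)
})

test_that("directional overlap keeps only direction-matched genes", {
  a <- data.frame(gene_id = c("g1", "g2", "g3"),
                  direction = c("up", "down", "up"))
  b <- data.frame(gene_id = c("g2", "g3"), direction = c("down", "down"))
  expect_equal(directional_overlap(a, b)$gene_id, "g2")
  disjoint <- data.frame(gene_id = "g9", direction = "up")
  expect_equal(nrow(directional_overlap(a, disjoint)), 0)
  flip <- data.frame(gene_id = "g1", direction = "down")
  expect_equal(nrow(directional_overlap(a, flip)), 0)
  ov <- overlap_test(a, b, n_universe = 100)
  expect_equal(ov$k_observed, 1)
  expect_equal(ov$p_hypergeom, hypergeom_tail(100, 3, 2, 1),
               tolerance = 1e-12)
})

test_that("Fisher enrichment agrees with fisher.test's right tail", {
  uni <- paste0("g", 1:20)
  hits <- paste0("g", 1:5)
  set <- paste0("g", c(1:4, 6))  # a=4, b=1, c=1, d=14
  fe <- fisher_enrichment(hits, set, uni)
  expect_equal(fe$p, hypergeom_tail(20, 5, 5, 4), tolerance = 1e-12)
  expect_equal(fe$p, 76 / choose(20, 5), tolerance = 1e-12)
  ref <- stats::fisher.test(fe$table, alternative = "greater")
  expect_equal(fe$p, ref$p.value, tolerance = 1e-9)
  expect_equal(fisher_enrichment(uni, uni, uni)$p, 1)
  expect_equal(fisher_enrichment(paste0("g", 1:5), paste0("g", 6:10),
                                 uni)$p, 1, tolerance = 1e-12)
  expect_error(fisher_enrichment("x", "y", character(0)), "data error")
})

test_that("GSA flags planted sets and stays calibrated under the null", {
  set.seed(43)
  genes <- sprintf("g%04d", 1:800)
  mat <- matrix(stats::rnorm(800 * 16, 0, 0.5), 800,
                dimnames = list(genes, paste0("s", 1:16)))
  labels <- factor(rep(c("control", "case"), each = 8),
                   levels = c("control", "case"))
  cat1 <- simulate_gene_sets(40, 15, universe = genes, seed = 44)
  # plant a uniform shift into one set's genes
  mat2 <- mat
  idx <- cat1$sets[["SET_007"]]
  mat2[idx, labels == "case"] <- mat2[idx, labels == "case"] + 0.8
  res <- gsa(cat1, mat2, labels, n_perm = 100, seed = 45,
             n_random_sets = 300)
  expect_equal(res$name[1], "SET_007")
  expect_true(res$significant[res$name == "SET_007"])
  # duplicated sets score identically
  cat2 <- gene_set_catalog(list(A = idx, B = idx), genes)
  res2 <- gsa(cat2, mat2, labels, n_perm = 60, seed = 46,
              n_random_sets = 200)
  expect_equal(res2$score[1], res2$score[2])
  expect_equal(res2$z[1], res2$z[2])
  expect_warning(gsa(cat2, mat2, labels, n_perm = 30, seed = 1,
                     n_random_sets = 50), "unstable")
})
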