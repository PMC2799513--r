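test_that("noise-free, signal-free expression cohorts are identically zero", {
  cfg <- expression_sim_config(3, 3, 20, n_de_genes = 0, noise_sd = 0,
                               seed = 1)
  sim <- simulate_expression(cfg)
  expect_equal(dim(sim$matrix), c(20, 6))
  expect_true(all(sim$matrix == 0))
  expect_equal(levels(sim$labels), c("control", "case"))
})

test_that("identical seeds give bitwise-identical cohorts", {
  cfg <- expression_sim_config(5, 5, 100, n_de_genes = 10,
                               de_log2_shift = 1.5, noise_sd = 0.4,
                               patterns = list(pattern_spec(10, "cov1")),
                               seed = 7)
  a <- simulate_expression(cfg)
  b <- simulate_expression(cfg)
  expect_identical(a$matrix, b$matrix)
  expect_identical(a$truth, b$truth)
  q <- qpcr_sim_config(seed = 7, n_cases = 6, n_controls = 4)
  expect_identical(simulate_qpcr(q)$table, simulate_qpcr(q)$table)
  expect_identical(simulate_clinical(20, seed = 7),
                   simulate_clinical(20, seed = 7))
})

test_that("planted DE genes carry the configured mean shift", {
  cfg <- expression_sim_config(10, 10, 1000, n_de_genes = 50,
                               de_log2_shift = 2, noise_sd = 0.5, seed = 42)
  sim <- simulate_expression(cfg)
  truth <- sim$truth$de_genes
  expect_equal(nrow(truth), 50)
  is_case <- sim$labels == "case"
  diffs <- rowMeans(sim$matrix[truth$gene_id, is_case]) -
    rowMeans(sim$matrix[truth$gene_id, !is_case])
  signed <- diffs * ifelse(truth$direction == "up", 1, -1)
  expect_lt(abs(mean(signed) - 2), 0.1)
  # directions split half/half
  expect_equal(sum(truth$direction == "up"), 25)
})

test_that("configs with more planted than total genes are rejected", {
  expect_error(expression_sim_config(3, 3, 10, n_de_genes = 11),
               "configuration error")
  expect_error(
    expression_sim_config(3, 3, 10, n_de_genes = 5,
                          patterns = list(pattern_spec(6, "c"))),
    "configuration error")
  expect_error(expression_sim_config(3, 3, 10, noise_sd = -1),
               "configuration error")
})

test_that("noise-free QPCR signals follow the Poisson zero class exactly", {
  amp <- default_amplicons()
  cfg0 <- qpcr_sim_config(
    lesions_per_10kb_cases = c(mitochondrial = 0, nuclear = 0),
    copy_number_cv = 0, measurement_cv = 0, lesion_cv = 0,
    n_cases = 3, n_controls = 2, seed = 1)
  expect_true(all(simulate_qpcr(cfg0)$table$signal == 1))

  cfg <- qpcr_sim_config(
    lesions_per_10kb_cases = c(mitochondrial = 0.78, nuclear = 0),
    copy_number_cv = 0, measurement_cv = 0, lesion_cv = 0,
    n_cases = 2, n_controls = 2, seed = 1)
  tab <- simulate_qpcr(cfg)$table
  long <- tab[tab$target == "mt_long", ]
  ratio <- long$signal[long$group == "case"][1] /
    long$signal[long$group == "control"][1]
  expect_equal(ratio, exp(-0.78 * 8.9 / 10), tolerance = 1e-12)

  amp10 <- amplicon_table(data.frame(name = "t", genome = "nuclear",
                                     length_kb = 10, role = "damage_target"))
  cfg10 <- qpcr_sim_config(amplicons = amp10,
                           lesions_per_10kb_cases = c(nuclear = 1),
                           lesions_per_10kb_controls = c(nuclear = 0),
                           copy_number_cv = 0, measurement_cv = 0,
                           lesion_cv = 0, n_cases = 1, n_controls = 1,
                           seed = 1)
  tab10 <- simulate_qpcr(cfg10)$table
  expect_equal(tab10$signal[tab10$group == "case"] /
                 tab10$signal[tab10$group == "control"],
               exp(-1), tolerance = 1e-12)
  expect_error(qpcr_sim_config(lesions_per_10kb_cases = c(nuclear = -1)),
               "configuration error")
  expect_error(qpcr_sim_config(lesions_per_10kb_cases = c(plastid = 1)),
               "configuration error")
})

test_that("explicit Poisson lesion placement agrees with the zero class", {
  # Monte-Carlo cross-check of the closed form exp(-lambda): place a
  # Poisson number of lesions on each template and count clean amplicons.
  set.seed(99)
  for (lambda in c(0.3, 0.69, 1.2)) {
    n <- 1e5
    zero_frac <- mean(stats::rpois(n, lambda) == 0)
    se <- sqrt(exp(-lambda) * (1 - exp(-lambda)) / n)
    expect_lt(abs(zero_frac - exp(-lambda)), 3 * se)
  }
})

test_that("planted gene-set memberships are honoured exactly", {
  uni <- sprintf("g%03d", 1:100)
  cat1 <- simulate_gene_sets(23, 10, planted = c(g001 = 6, g002 = 5),
                             universe = uni, seed = 3)
  counts <- table(unlist(cat1$sets))
  expect_equal(unname(counts["g001"]), 6L)
  expect_equal(unname(counts["g002"]), 5L)

  cat2 <- simulate_gene_sets(1, 5, planted = c(g007 = 1),
                             universe = uni, seed = 4)
  expect_true("g007" %in% cat2$sets[[1]])

  cat3 <- simulate_gene_sets(4, 10, universe = uni, seed = 5)
  expect_equal(length(unlist(cat3$sets)), 40L)
  expect_error(simulate_gene_sets(2, 200, universe = uni, seed = 1),
               "configuration error")
  expect_error(simulate_gene_sets(2, 5, planted = c(g001 = 3),
                                  universe = uni, seed = 1),
               "configuration error")
})

test_that("clinical covariates hit their planted correlation targets", {
  # exact line when r2 = 1
  cl1 <- simulate_clinical(30, onset_r2 = 1, seed = 2)
  fit <- stats::lm(age_of_onset ~ ddct, data = cl1$clinical)
  expect_equal(unname(suppressWarnings(summary(fit))$r.squared), 1,
               tolerance = 1e-12)
  # near-zero correlation when r2 = 0
  cl0 <- simulate_clinical(500, onset_r2 = 0, seed = 3)
  r2 <- stats::cor(cl0$clinical$ddct, cl0$clinical$age_of_onset)^2
  expect_lt(r2, 0.05)
  # bimodal ddct reproduces the planted high/low counts at the -2.5 split
  cl <- simulate_clinical(27, ddct_modes = list(c(0, 0.3, 0.22),
                                                c(-3.5, 0.6, 0.78)),
                          seed = 11)
  n_high <- sum(cl$clinical$ddct > -2.5)
  expect_true(abs(n_high - 6) <= 1)
  expect_error(simulate_clinical(10, onset_r2 = 1.2), "configuration error")
  expect_error(
    simulate_clinical(10, ddct_modes = list(c(0, 1, 0.4), c(1, 1, 0.4))),
    "configuration error")
})

test_that("planted truth ids always exist in the generated cohort", {
  for (seed in 1:5) {
    cfg <- expression_sim_config(
      6, 6, 200, n_de_genes = 20, noise_sd = 0.3,
      patterns = list(pattern_spec(15, "cov1"), pattern_spec(15, "cov2")),
      seed = seed)
    sim <- simulate_expression(cfg)
    expect_true(all(sim$truth$de_genes$gene_id %in% rownames(sim$matrix)))
    expect_true(all(unlist(sim$truth$pattern_memberships) %in%
                      rownames(sim$matrix)))
    expect_equal(rownames(sim$truth$covariate_values), colnames(sim$matrix))
  }
})
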