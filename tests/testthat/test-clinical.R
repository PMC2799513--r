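test_that("relative expression follows the ddCt orientation and fold rule", {
  ctrl <- c(5, 6, 7)
  re <- relative_expression(c(6, 8.5, 5), ctrl,
                            sample_id = c("p1", "p2", "p3"))
  expect_equal(re$ddct, c(0, -2.5, 1))
  expect_equal(re$fold, 2^re$ddct, tolerance = 1e-12)
  expect_equal(re$fold[2], 0.17678, tolerance = 1e-4)
  expect_equal(re$fold[3], 2)
  expect_error(relative_expression(1, numeric(0)), "data error")
  # round trip ddct -> fold -> ddct
  x <- seq(-5, 3, by = 0.25)
  expect_equal(log2(2^x), x, tolerance = 1e-9)
})

test_that("expresser stratification splits at -2.5 with boundary low", {
  expect_equal(stratify_expressers(c(0, -3.1, -2.5, -2.4)),
               c("high", "low", "low", "high"))
  expect_error(stratify_expressers(c(1, Inf)), "data error")
  # the planted bimodal cohort reproduces its 6/21 split with noise-free modes
  cl <- simulate_clinical(27, ddct_modes = list(c(0, 0, 0.22),
                                                c(-3.5, 0, 0.78)),
                          seed = 8)
  lab <- stratify_expressers(cl$clinical$ddct)
  expect_equal(sum(lab == "high"), 6)
  expect_equal(sum(lab == "low"), 21)
  expect_equal(unname(table(cl$truth$component)[1]), 6L)
})

test_that("univariate fits reproduce hand OLS and calibrated nulls", {
  exact <- suppressWarnings(univariate_fit(1:10, 2 * (1:10)))
  expect_equal(exact$slope, 2, tolerance = 1e-12)
  expect_equal(exact$r_squared, 1, tolerance = 1e-12)
  hand <- univariate_fit(c(0, 1, 2), c(0, 2, 2))
  expect_equal(hand$slope, 1, tolerance = 1e-12)
  expect_equal(hand$intercept, 1 / 3, tolerance = 1e-12)
  expect_equal(hand$r_squared, 0.75, tolerance = 1e-12)
  expect_error(univariate_fit(rep(1, 5), 1:5), "data error")
  expect_error(univariate_fit(1:2, 1:2), "data error")
  # r^2 equals squared Pearson correlation
  set.seed(81)
  for (i in 1:5) {
    x <- stats::rnorm(30); y <- stats::rnorm(30)
    expect_equal(univariate_fit(x, y)$r_squared, stats::cor(x, y)^2,
                 tolerance = 1e-12)
  }
  # null calibration: p uniform under shuffling
  set.seed(82)
  x <- stats::rnorm(100)
  y <- stats::rnorm(100)
  ps <- replicate(200, univariate_fit(sample(x), y)$p)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("BH q-values match step-up hand enumeration", {
  expect_equal(qvalues(0.05), 0.05)
  expect_equal(qvalues(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(qvalues(rep(1, 4)), rep(1, 4))
  # hand enumeration for n <= 5: q_i = min over j >= i of p_(j) * n / j
  set.seed(83)
  for (i in 1:10) {
    n <- sample(1:5, 1)
    p <- stats::runif(n)
    ord <- order(p)
    q_hand <- numeric(n)
    for (j in seq_len(n))
      q_hand[ord[j]] <- min(p[ord][j:n] * n / (j:n))
    q_hand <- pmin(q_hand, 1)
    expect_equal(qvalues(p), q_hand, tolerance = 1e-12)
    expect_true(all(qvalues(p) >= p - 1e-15))
    # permutation invariance
    perm <- sample(n)
    expect_equal(qvalues(p[perm]), qvalues(p)[perm], tolerance = 1e-12)
  }
  expect_error(qvalues(c(0.5, 1.2)), "data error")
})

test_that("supervised correlation recovers planted blocks and stays null", {
  # null: ~1% of genes pass at p <= 0.01
  set.seed(84)
  genes <- sprintf("g%04d", 1:1000)
  mat <- matrix(stats::rnorm(1000 * 28), 1000,
                dimnames = list(genes, paste0("s", 1:28)))
  covariate <- stats::rnorm(28)
  sc <- supervised_correlation(mat, covariate, 0.01)
  expect_lt(abs(nrow(sc$passers) - 10), 3 * sqrt(1000 * 0.01 * 0.99) + 1)
  # planted correlated block at |r| ~ 0.6, n = 28
  blk <- 1:144
  signs <- rep(c(1, -1), length.out = 144)
  r_target <- 0.6
  mat2 <- mat
  mat2[blk, ] <- t(sapply(signs, function(sg)
    sg * (r_target * scale(covariate)[, 1] +
            sqrt(1 - r_target^2) * stats::rnorm(28))))
  sc2 <- supervised_correlation(mat2, covariate, 0.01)
  recovered <- sum(genes[blk] %in% sc2$passers$gene_id)
  expect_gte(recovered, 120)
  signs_found <- sc2$passers$sign[match(genes[blk], sc2$passers$gene_id)]
  agree <- signs_found == ifelse(signs > 0, "positive", "negative")
  expect_gte(mean(agree, na.rm = TRUE), 0.95)
  # zero-variance rows are skipped, constant covariate rejected
  mat3 <- rbind(flat = rep(1, 28), mat[1:5, ])
  expect_message(sc3 <- supervised_correlation(mat3, covariate), "skipping")
  expect_false("flat" %in% sc3$results$gene_id)
  expect_error(supervised_correlation(mat, rep(1, 28)), "constant")
})

test_that("median-age dichotomization behaves across regimes", {
  set.seed(85)
  ages <- c(21, 25, 28, 30, 33, 35, 41, 44, 50, 52, 55, 60, 61, 63, 70)
  # values equal to age separate almost perfectly
  strong <- dichotomized_age_test(ages, ages)
  expect_lt(strong$p, 0.001)
  # independence: close to nominal false-positive rate
  ps <- replicate(100, dichotomized_age_test(stats::rnorm(15), ages)$p)
  expect_gte(mean(ps > 0.05), 0.9)
  # equal values in both strata
  flat <- dichotomized_age_test(rep(3, 4), c(1, 2, 10, 11))
  expect_equal(flat$t, 0)
  expect_equal(flat$p, 1)
  # samples at the median fall into the lower stratum
  strata <- dichotomize_age(c(1, 2, 2, 5))
  expect_equal(as.character(strata), c("lower", "lower", "lower", "upper"))
  expect_error(dichotomized_age_test(1:3, 1:2), "data error")
})

test_that("planted onset correlation strength is recovered on average", {
  r2s <- sapply(1:10, function(seed) {
    cl <- simulate_clinical(27, onset_r2 = 0.305, seed = seed)
    univariate_fit(cl$clinical$ddct, cl$clinical$age_of_onset)$r_squared
  })
  expect_lt(abs(mean(r2s) - 0.305), 0.15)
})
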