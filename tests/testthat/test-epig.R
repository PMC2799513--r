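planted_cohort <- function(seed, n_patterns = 3, members = 50,
                           within_r = 0.9, shift = 2) {
  pats <- lapply(seq_len(n_patterns), function(i)
    pattern_spec(members, paste0("cov", i),
                 within_pattern_corr_target = within_r))
  cfg <- expression_sim_config(14, 14, 1000, noise_sd = 0.3,
                               patterns = pats,
                               covariate_group_shift = shift, seed = seed)
  simulate_expression(cfg)
}

test_that("local cluster sizes count correlated neighbours", {
  ident <- matrix(rep(sin(1:12), 5), nrow = 5, byrow = TRUE,
                  dimnames = list(paste0("g", 1:5), NULL))
  expect_true(all(local_cluster_sizes(ident, 0.9) == 4))
  two <- rbind(sinus = sin(seq(0, 2 * pi, length.out = 12)),
               linear = seq(-1, 1, length.out = 12))
  expect_true(all(local_cluster_sizes(two, 0.5) == 0))
  # planted 50-member cluster at within-correlation ~0.9
  sim <- planted_cohort(51, n_patterns = 1)
  sizes <- local_cluster_sizes(sim$matrix, 0.7)
  members <- sim$truth$pattern_memberships$pattern_1
  expect_true(all(sizes[members] >= 45))
  # zero-variance profile contributes no links
  flat <- rbind(a = rep(1, 8), b = stats::rnorm(8), c = stats::rnorm(8))
  expect_message(sz <- local_cluster_sizes(flat, 0.5), "zero-variance")
  expect_equal(unname(sz["a"]), 0L)
})

test_that("SNR follows the group-mean over pooled-within definition", {
  labels <- factor(c("a", "a", "b", "b"))
  expect_equal(snr(c(0, 1, 2, 3), labels), 2.0, tolerance = 1e-12)
  expect_equal(snr(c(1, 2, 1, 2), labels), 0)
  expect_warning(s <- snr(c(0, 0, 1, 1), labels), "infinite")
  expect_true(is.infinite(s))
  expect_message(s1 <- snr(c(1, 2, 3, 4), factor(rep("a", 4))),
                 "mean")
  expect_equal(s1, abs(mean(1:4)) / stats::sd(1:4))
})

test_that("planted patterns are recovered exactly and noise yields none", {
  for (seed in c(61, 62, 63)) {
    sim <- planted_cohort(seed)
    pat <- extract_patterns(sim$matrix, epig_params(), sim$labels)
    expect_equal(nrow(pat$profiles), 3)
    expect_true(all(pat$info$local_cluster_size >= 10))
    expect_true(all(pat$info$snr >= 1.0))
    a <- assign_genes(sim$matrix, pat, 0.64)
    expect_gte(planted_assignment_accuracy(a, sim$truth$pattern_memberships),
               0.95)
  }
  # pure noise: nothing clusters
  cfg <- expression_sim_config(14, 14, 1000, noise_sd = 0.3, seed = 64)
  noise <- simulate_expression(cfg)
  expect_message(
    p0 <- extract_patterns(noise$matrix, epig_params(), noise$labels),
    "no patterns")
  expect_equal(nrow(p0$profiles), 0)
})

test_that("duplicated pattern blocks are pruned to a single pattern", {
  sim <- planted_cohort(65)
  # append exact copies of the first pattern's genes under new ids
  members <- sim$truth$pattern_memberships$pattern_1
  dup <- sim$matrix[members, , drop = FALSE]
  rownames(dup) <- paste0("dup_", seq_len(nrow(dup)))
  pat <- extract_patterns(rbind(sim$matrix, dup), epig_params(),
                          sim$labels)
  expect_equal(nrow(pat$profiles), 3)
})

test_that("mutually uncorrelated patterns separate without a group offset", {
  sim <- planted_cohort(66, shift = 0)
  params <- epig_params(snr_t = 0, magnitude_t = 0.5)
  pat <- extract_patterns(sim$matrix, params, sim$labels)
  expect_equal(nrow(pat$profiles), 3)
  a <- assign_genes(sim$matrix, pat, 0.64)
  expect_gte(planted_assignment_accuracy(a, sim$truth$pattern_memberships),
             0.95)
})

test_that("assignment thresholds and ties behave as documented", {
  sim <- planted_cohort(67)
  pat <- extract_patterns(sim$matrix, epig_params(), sim$labels)
  # a gene equal to a representative correlates at 1
  probe <- matrix(pat$profiles[1, ], nrow = 1,
                  dimnames = list("probe", colnames(sim$matrix)))
  a1 <- assign_genes(probe, pat, 0.64)
  expect_equal(a1$pattern_id, rownames(pat$profiles)[1])
  expect_equal(a1$r, 1, tolerance = 1e-12)
  # an uncorrelated gene is an orphan
  set.seed(1)
  orphan <- matrix(stats::rnorm(ncol(sim$matrix)), nrow = 1,
                   dimnames = list("noise", colnames(sim$matrix)))
  expect_equal(assign_genes(orphan, pat, 0.64)$pattern_id, "orphan")
  # raising r_assign never decreases the orphan count
  counts <- sapply(c(0.3, 0.5, 0.7, 0.9), function(r)
    sum(assign_genes(sim$matrix, pat, r)$pattern_id == "orphan"))
  expect_true(all(diff(counts) >= 0))
})

test_that("rescaling all profiles leaves clustering and assignment alone", {
  sim <- planted_cohort(68)
  params <- epig_params(magnitude_t = 0)  # magnitude is scale-dependent
  p1 <- extract_patterns(sim$matrix, params, sim$labels)
  p2 <- extract_patterns(3.7 * sim$matrix, params, sim$labels)
  expect_equal(nrow(p1$profiles), nrow(p2$profiles))
  expect_equal(p1$profiles, p2$profiles, tolerance = 1e-9)
  a1 <- assign_genes(sim$matrix, p1, 0.64)
  a2 <- assign_genes(3.7 * sim$matrix, p2, 0.64)
  expect_equal(a1$pattern_id, a2$pattern_id)
  expect_equal(local_cluster_sizes(sim$matrix, 0.7),
               local_cluster_sizes(3.7 * sim$matrix, 0.7))
})

test_that("pattern-covariate correlation has calibrated p-values", {
  sim <- planted_cohort(69, n_patterns = 1)
  pat <- extract_patterns(sim$matrix, epig_params(), sim$labels)
  cov1 <- sim$truth$covariate_values$cov1
  r1 <- correlate_pattern_covariate(pat$profiles[1, ], cov1)
  expect_gt(abs(r1$r), 0.9)
  expect_lt(r1$p, 1e-6)
  # exact linear profile
  lin <- correlate_pattern_covariate(2 * cov1 + 1, cov1)
  expect_equal(abs(lin$r), 1, tolerance = 1e-12)
  expect_equal(lin$p, 0)
  # shuffled covariate: mostly non-significant
  set.seed(70)
  ps <- replicate(100, {
    correlate_pattern_covariate(pat$profiles[1, ], sample(cov1))$p
  })
  expect_gte(mean(ps > 0.05), 0.9)
  expect_error(correlate_pattern_covariate(pat$profiles[1, ],
                                           rep(1, ncol(sim$matrix))),
               "constant")
})
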