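# Independent oracles used by the tests. These deliberately use plain loops
# and direct formulas, not the package's code paths.

# Exhaustive SAM FDR oracle for tiny matrices: enumerates every distinct
# assignment of columns to group 1, computes d by the textbook formulas,
# and applies the documented thresholding rule.
oracle_sam_fdr <- function(mat, n1, s0, deltas) {
  n <- ncol(mat)
  splits <- utils::combn(n, n1)
  d_of <- function(idx1) {
    idx2 <- setdiff(seq_len(n), idx1)
    apply(mat, 1, function(x) {
      x1 <- x[idx1]; x2 <- x[idx2]
      ss <- sum((x1 - mean(x1))^2) + sum((x2 - mean(x2))^2)
      s <- sqrt((1 / length(x1) + 1 / length(x2)) * ss /
                  (length(x1) + length(x2) - 2))
      if (s + s0 > 0) (mean(x2) - mean(x1)) / (s + s0) else 0
    })
  }
  perm_d <- sapply(seq_len(ncol(splits)), function(j) d_of(splits[, j]))
  if (is.null(dim(perm_d))) perm_d <- matrix(perm_d, nrow = nrow(mat))
  dbar <- rowMeans(apply(perm_d, 2, sort))
  d_obs <- d_of(seq_len(n1))
  ds <- sort(d_obs)
  diffs <- ds - dbar
  out <- NULL
  for (delta in sort(unique(deltas))) {
    up <- diffs >= delta
    dn <- if (delta == 0) diffs < 0 else diffs <= -delta
    n_called <- sum(up) + sum(dn)
    cutup <- if (any(up)) min(ds[up]) else Inf
    cutlow <- if (any(dn)) max(ds[dn]) else -Inf
    false_b <- numeric(ncol(perm_d))
    for (b in seq_len(ncol(perm_d)))
      false_b[b] <- sum(perm_d[, b] >= cutup) + sum(perm_d[, b] <= cutlow)
    out <- rbind(out, data.frame(
      delta = delta, n_called = n_called,
      mean_false = mean(false_b),
      median_false = stats::median(false_b),
      fdr = if (n_called > 0) mean(false_b) / n_called else 0))
  }
  out
}

# Hypergeometric upper tail by direct choose() arithmetic
oracle_hyper_tail <- function(N, K, n, k) {
  if (k <= 0) return(1)
  hi <- min(K, n)
  if (k > hi) return(0)
  tot <- 0
  for (i in k:hi) {
    if (n - i > N - K) next
    tot <- tot + choose(K, i) * choose(N - K, n - i)
  }
  tot / choose(N, n)
}

# maxmean by explicit accumulation loops
oracle_maxmean <- function(z) {
  sp <- 0; sn <- 0
  for (v in z) {
    if (v > 0) sp <- sp + v else sn <- sn - v
  }
  sp <- sp / length(z); sn <- sn / length(z)
  if (sp >= sn) sp else -sn
}

# Match extracted patterns to planted memberships; returns the worst
# per-pattern fraction assigned to that pattern's majority label, with
# distinct majority labels required for full credit.
planted_assignment_accuracy <- function(assignment, memberships) {
  majors <- character(0)
  accs <- numeric(0)
  for (nm in names(memberships)) {
    sub <- assignment$pattern_id[assignment$gene_id %in% memberships[[nm]]]
    tb <- table(sub)
    majors[nm] <- names(tb)[which.max(tb)]
    accs[nm] <- max(tb) / length(memberships[[nm]])
  }
  if (anyDuplicated(majors[majors != "orphan"]) ||
      any(majors == "orphan")) return(0)
  min(accs)
}
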