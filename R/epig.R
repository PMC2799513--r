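#' EPIG filtering parameters
#'
#' Defaults are package defaults for log2-ratio blood expression data, not
#' values taken from any particular study.
#'
#' @param r_t Pairwise Pearson correlation threshold defining a profile's
#'   local cluster, in (0, 1).
#' @param m_t Minimum local cluster size for a pattern candidate.
#' @param snr_t Minimum signal-to-noise ratio of a representative profile.
#' @param magnitude_t Minimum magnitude (max |log2 ratio|) of a
#'   representative profile.
#' @param r_assign Gene-to-pattern assignment threshold R in (0, 1); genes
#'   whose best correlation is below it are orphans.
#' @export
epig_params <- function(r_t = 0.7, m_t = 10, snr_t = 1.0,
                        magnitude_t = 0.5, r_assign = 0.64) {
  if (r_t <= 0 || r_t >= 1 || r_assign <= 0 || r_assign >= 1)
    stop("configuration error: correlation thresholds must be in (0, 1)",
         call. = FALSE)
  if (m_t < 1 || snr_t < 0 || magnitude_t < 0)
    stop("configuration error: m_t >= 1 and snr_t, magnitude_t >= 0 required",
         call. = FALSE)
  list(r_t = r_t, m_t = as.integer(m_t), snr_t = snr_t,
       magnitude_t = magnitude_t, r_assign = r_assign)
}

# correlation matrix with zero-variance rows mapped to NA (no links)
profile_cor <- function(mat) {
  suppressWarnings(stats::cor(t(mat)))
}

#' Local cluster sizes of all profiles
#'
#' For each gene profile, the number of other profiles whose Pearson
#' correlation with it exceeds `r_t`. Zero-variance profiles have undefined
#' correlations and get size 0 (with a message).
#'
#' @param mat Genes x samples matrix.
#' @param r_t Correlation threshold.
#' @return Named integer vector of cluster sizes.
#' @export
local_cluster_sizes <- function(mat, r_t) {
  if (nrow(mat) < 2)
    stop("data error: at least 2 profiles required", call. = FALSE)
  C <- profile_cor(mat)
  if (anyNA(C))
    message("zero-variance profiles present; their cluster size is 0")
  diag(C) <- NA
  sizes <- rowSums(C > r_t, na.rm = TRUE)
  stats::setNames(as.integer(sizes), rownames(mat))
}

#' Signal-to-noise ratio of a profile across sample groups
#'
#' Defined here as the standard deviation of the group means divided by the
#' pooled within-group standard deviation. With a single group (or groups
#' too small), falls back to |mean| / sd of the profile with a message.
#' A zero pooled within-group SD yields Inf with a warning.
#'
#' @param profile Per-sample numeric vector.
#' @param labels Group labels (length = length(profile)).
#' @return Non-negative SNR (possibly Inf).
#' @export
snr <- function(profile, labels) {
  labels <- factor(labels)
  ok <- table(labels) >= 2
  if (nlevels(labels) < 2 || sum(ok) < 2) {
    message("fewer than two groups with >= 2 samples; using |mean|/sd")
    return(abs(mean(profile)) / stats::sd(profile))
  }
  gm <- tapply(profile, labels, mean)
  gv <- tapply(profile, labels, stats::var)
  gn <- tapply(profile, labels, length)
  pooled <- sqrt(sum(gv * (gn - 1)) / (sum(gn) - nlevels(labels)))
  if (pooled == 0) {
    warning("zero within-group variance; SNR is infinite")
    return(Inf)
  }
  stats::sd(gm) / pooled
}

#' Extract co-expression patterns by iterative filtering
#'
#' All profiles start as pattern candidates. Candidates whose local cluster
#' size (number of profiles correlated above `r_t`) is below `m_t` are
#' dropped. Among remaining candidates correlated above `r_t` with each
#' other, the one with the smaller local cluster is dropped (candidates are
#' processed in decreasing cluster-size order, ties by gene id, so the
#' largest cluster always survives). Each survivor's representative profile
#' is the centroid of its local cluster; representatives with SNR below
#' `snr_t` or magnitude (max |value|) below `magnitude_t` are dropped, and
#' the remaining representatives - standardized to mean 0, SD 1 across
#' samples - are the extracted patterns.
#'
#' @param mat Genes x samples matrix.
#' @param params [epig_params()].
#' @param labels Group labels for the SNR filter.
#' @return Object of class `epig_patterns`: list with `profiles`
#'   (patterns x samples matrix of standardized representatives), `info`
#'   (data frame: id, seed_gene, local_cluster_size, snr, magnitude), and
#'   `members` (list of local-cluster gene ids per pattern).
#' @export
extract_patterns <- function(mat, params = epig_params(), labels) {
  if (nrow(mat) < params$m_t)
    stop("data error: fewer profiles than m_t", call. = FALSE)
  C <- profile_cor(mat)
  diag(C) <- NA
  sizes <- rowSums(C > params$r_t, na.rm = TRUE)
  cand <- which(sizes >= params$m_t)

  # pairwise pruning in decreasing cluster-size order, ties by gene id
  ord <- cand[order(-sizes[cand], rownames(mat)[cand])]
  alive <- rep(TRUE, length(ord))
  for (i in seq_along(ord)) {
    if (!alive[i]) next
    if (i < length(ord)) {
      later <- ord[seq.int(i + 1, length(ord))]
      drop <- C[ord[i], later] > params$r_t
      drop[is.na(drop)] <- FALSE
      alive[seq.int(i + 1, length(ord))][drop] <- FALSE
    }
  }
  survivors <- ord[alive]

  profiles <- list(); info <- list(); members <- list()
  for (g in survivors) {
    cluster <- c(g, which(C[g, ] > params$r_t))
    centroid <- colMeans(mat[cluster, , drop = FALSE])
    s <- snr(centroid, labels)
    mag <- max(abs(centroid))
    if (s < params$snr_t || mag < params$magnitude_t) next
    k <- length(profiles) + 1
    rep_profile <- (centroid - mean(centroid)) / stats::sd(centroid)
    profiles[[k]] <- rep_profile
    members[[k]] <- rownames(mat)[sort(unique(cluster))]
    info[[k]] <- data.frame(id = sprintf("P%d", k),
                            seed_gene = rownames(mat)[g],
                            local_cluster_size = length(unique(cluster)),
                            snr = s, magnitude = mag,
                            stringsAsFactors = FALSE)
  }
  if (length(profiles) == 0) {
    message("no patterns survive filtering")
    return(structure(list(profiles = matrix(0, 0, ncol(mat),
                                            dimnames = list(NULL,
                                                            colnames(mat))),
                          info = data.frame(), members = list()),
                     class = "epig_patterns"))
  }
  prof <- do.call(rbind, profiles)
  info <- do.call(rbind, info)
  dimnames(prof) <- list(info$id, colnames(mat))
  names(members) <- info$id
  structure(list(profiles = prof, info = info, members = members),
            class = "epig_patterns")
}

#' Assign genes to extracted patterns
#'
#' Each gene goes to the pattern whose representative profile it correlates
#' with most strongly (Pearson); ties are broken by the lowest pattern id.
#' Genes whose best correlation is below `r_assign` are orphans.
#'
#' @param mat Genes x samples matrix.
#' @param patterns An `epig_patterns` object with >= 1 pattern.
#' @param r_assign Assignment threshold in (0, 1).
#' @return Data frame (gene_id, pattern_id, r); orphans have pattern_id
#'   "orphan".
#' @export
assign_genes <- function(mat, patterns, r_assign = 0.64) {
  stopifnot(inherits(patterns, "epig_patterns"))
  if (nrow(patterns$profiles) == 0)
    stop("data error: no patterns to assign to", call. = FALSE)
  R <- suppressWarnings(stats::cor(t(mat), t(patterns$profiles)))
  R[is.na(R)] <- -Inf
  best <- max.col(R, ties.method = "first")
  r_best <- R[cbind(seq_len(nrow(R)), best)]
  pid <- rownames(patterns$profiles)[best]
  pid[r_best < r_assign] <- "orphan"
  data.frame(gene_id = rownames(mat), pattern_id = pid,
             r = ifelse(is.finite(r_best), r_best, NA_real_),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Correlate a pattern profile with a clinical covariate
#'
#' Pearson correlation with a two-sided p-value from the t-distribution on
#' n - 2 degrees of freedom.
#'
#' @param profile Per-sample numeric vector (representative profile or a
#'   member gene's profile).
#' @param covariate Per-sample covariate values (no missing values).
#' @return List with `r`, `p`, `n`.
#' @export
correlate_pattern_covariate <- function(profile, covariate) {
  if (length(profile) != length(covariate))
    stop("data error: covariate must cover all samples", call. = FALSE)
  if (anyNA(covariate) || anyNA(profile))
    stop("data error: missing values in profile or covariate", call. = FALSE)
  if (stats::sd(covariate) == 0)
    stop("data error: constant covariate", call. = FALSE)
  n <- length(profile)
  r <- stats::cor(profile, covariate)
  p <- if (abs(r) >= 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(r = r, p = p, n = n)
}
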