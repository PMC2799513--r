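#' Normalize the long mitochondrial amplicon to mitochondrial copy number
#'
#' Long-amplicon signal divided by the short-fragment signal of the same
#' sample. The short fragment is too small to carry lesions at realistic
#' densities, so it tracks template copy number only.
#'
#' @param long_signal,short_signal Strictly positive amplification signals.
#' @param sample_id Optional identifier used in error messages.
#' @return `long_signal / short_signal`.
#' @export
normalize_mito <- function(long_signal, short_signal, sample_id = NULL) {
  bad <- !is.finite(long_signal) | !is.finite(short_signal) |
    long_signal <= 0 | short_signal <= 0
  if (any(bad))
    stop("data error: non-positive amplification signal",
         if (!is.null(sample_id))
           paste0(" for sample ", paste(sample_id[bad], collapse = ", ")),
         call. = FALSE)
  long_signal / short_signal
}

#' Control-group reference amplification
#'
#' Arithmetic mean of the control samples' (normalized) amplification.
#' A control group evaluated against its own mean has mean relative
#' amplification 1 and hence mean lesion excess ~0 by construction.
#'
#' @param control_values Positive amplification values of controls.
#' @export
control_reference <- function(control_values) {
  control_values <- control_values[!is.na(control_values)]
  if (length(control_values) == 0)
    stop("data error: empty control group", call. = FALSE)
  mean(control_values)
}

#' Relative amplification ratio versus the control reference
#'
#' @param sample_value Positive (normalized) amplification of a sample;
#'   vectorized.
#' @param reference Control reference, see [control_reference()].
#' @return `sample_value / reference`.
#' @export
relative_amplification <- function(sample_value, reference) {
  if (!is.finite(reference) || reference <= 0)
    stop("data error: control reference must be positive", call. = FALSE)
  if (any(!is.finite(sample_value) | sample_value <= 0))
    stop("data error: non-positive sample amplification", call. = FALSE)
  sample_value / reference
}

#' Lesion frequency per amplicon from the Poisson zero class
#'
#' Under random lesion placement, a template amplifies only if it carries
#' zero polymerase-blocking lesions, an event of probability `exp(-lambda)`.
#' Inverting, `lambda = -ln(ratio)`. Negative values (a sample amplifying
#' better than the control mean) are legitimate and returned as-is; clamping
#' them would bias group means upward.
#'
#' @param ratio Positive relative amplification ratio; vectorized.
#' @return Average lesions per amplicon.
#' @export
lesion_frequency <- function(ratio) {
  if (any(!is.finite(ratio) | ratio <= 0))
    stop("data error: relative amplification ratio must be > 0",
         call. = FALSE)
  -log(ratio)
}

#' Rescale lesions per amplicon to lesions per 10 kb
#'
#' @param lambda Lesions per amplicon.
#' @param length_kb Amplicon length in kb (> 0).
#' @export
per_10kb <- function(lambda, length_kb) {
  if (any(!is.finite(length_kb) | length_kb <= 0))
    stop("configuration error: amplicon length must be > 0", call. = FALSE)
  lambda / length_kb * 10
}

#' Estimate per-sample lesion densities from an amplification table
#'
#' For each genome with a damage-target amplicon: signals are normalized by
#' the genome's copy-number reference amplicon where one exists (the
#' mitochondrial short fragment; the nuclear target is used unnormalized,
#' nuclear copy number being assumed constant across blood samples), the
#' control reference is the arithmetic mean of control normalized signals,
#' and lesion frequencies follow the Poisson zero-class inversion.
#'
#' @param table Amplification table: data frame with columns sample_id,
#'   group (case/control), target, signal.
#' @param amplicons Amplicon panel, default [default_amplicons()].
#' @return Data frame with columns sample_id, group, genome,
#'   relative_amplification, lambda_per_amplicon, lesions_per_10kb.
#' @export
estimate_lesions <- function(table, amplicons = default_amplicons()) {
  amplicons <- amplicon_table(amplicons)
  req <- c("sample_id", "group", "target", "signal")
  if (!all(req %in% names(table)))
    stop("data error: amplification table needs columns ",
         paste(req, collapse = ", "), call. = FALSE)
  if (anyDuplicated(table[c("sample_id", "target")]))
    stop("data error: duplicated (sample_id, target) pair", call. = FALSE)
  if (any(!is.finite(table$signal) | table$signal <= 0))
    stop("data error: non-positive signal for sample ",
         paste(unique(table$sample_id[!is.finite(table$signal) |
                                        table$signal <= 0]),
               collapse = ", "), call. = FALSE)
  if (!all(table$group %in% c("case", "control")))
    stop("data error: group must be case or control", call. = FALSE)

  out <- list()
  for (g in unique(amplicons$genome)) {
    tgt <- amplicons[amplicons$genome == g &
                       amplicons$role == "damage_target", ]
    if (nrow(tgt) == 0) next
    ref_amp <- amplicons[amplicons$genome == g &
                           amplicons$role == "copy_number_reference", ]
    long <- table[table$target == tgt$name, ]
    if (nrow(long) == 0)
      stop("data error: no signals for amplicon ", tgt$name, call. = FALSE)
    norm <- long$signal
    if (nrow(ref_amp) == 1) {
      short <- table[table$target == ref_amp$name, ]
      m <- match(long$sample_id, short$sample_id)
      if (anyNA(m))
        stop("data error: missing ", ref_amp$name, " signal for sample ",
             paste(long$sample_id[is.na(m)], collapse = ", "), call. = FALSE)
      norm <- normalize_mito(long$signal, short$signal[m], long$sample_id)
    }
    ref <- control_reference(norm[long$group == "control"])
    ratio <- relative_amplification(norm, ref)
    lambda <- lesion_frequency(ratio)
    out[[g]] <- data.frame(sample_id = long$sample_id, group = long$group,
                           genome = g, relative_amplification = ratio,
                           lambda_per_amplicon = lambda,
                           lesions_per_10kb = per_10kb(lambda, tgt$length_kb),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Mann-Whitney U comparison of case vs control damage
#'
#' Exact p-value when the combined sample size is at most 12 and the data
#' are tie-free; otherwise the normal approximation with tie correction and
#' continuity correction. U is the number of (case, control) pairs with the
#' case value larger.
#'
#' @param case_values,control_values Numeric vectors (each non-empty).
#' @return List with `U` and two-sided `p`.
#' @export
compare_damage <- function(case_values, control_values) {
  case_values <- case_values[!is.na(case_values)]
  control_values <- control_values[!is.na(control_values)]
  if (length(case_values) == 0 || length(control_values) == 0)
    stop("data error: empty group in damage comparison", call. = FALSE)
  ties <- anyDuplicated(c(case_values, control_values)) > 0
  exact <- !ties && (length(case_values) + length(control_values)) <= 12
  ht <- suppressWarnings(
    stats::wilcox.test(case_values, control_values, exact = exact,
                       correct = TRUE))
  list(U = unname(ht$statistic), p = ht$p.value)
}

#' Spearman rank correlation with small-sample exact p
#'
#' Rho uses average ranks for ties. The p-value is computed by exhaustive
#' enumeration over all rank permutations when n <= 7 and the data are
#' tie-free, and from the t-approximation on n - 2 df otherwise.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return List with `rho` and two-sided `p`.
#' @export
correlate_damage <- function(x, y) {
  if (length(x) != length(y))
    stop("data error: length mismatch in correlation", call. = FALSE)
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3)
    stop("data error: need at least 3 paired values", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("data error: rank correlation undefined for constant input",
         call. = FALSE)
  rho <- stats::cor(x, y, method = "spearman")
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  if (!ties && n <= 7) {
    perms <- all_permutations(n)
    rx <- rank(x)
    ry <- rank(y)
    null_rho <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(null_rho) >= abs(rho) - 1e-12)
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
  }
  list(rho = rho, p = p)
}

# all permutations of 1..n as a matrix (n! rows); used for exact enumeration
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out[[i]] <- cbind(i, matrix(rest[sub], nrow(sub)))
  }
  do.call(rbind, out)
}

#' Classify damage as high or low
#'
#' Samples with more than `threshold` lesions/10 kb are "high damage";
#' values at or below the threshold (including the boundary) are "low".
#'
#' @param lesions_per_10kb Numeric vector.
#' @param threshold Classification boundary, default 0.85 lesions/10 kb.
#' @return Character vector of "high"/"low".
#' @export
classify_damage <- function(lesions_per_10kb, threshold = 0.85) {
  if (any(!is.finite(lesions_per_10kb)))
    stop("data error: non-finite lesion density", call. = FALSE)
  ifelse(lesions_per_10kb > threshold, "high", "low")
}

#' Group-level damage statistics
#'
#' Per genome: case-group mean excess lesions/10 kb (minus the control mean,
#' which is ~0 by construction of the reference), its SEM, and the
#' Mann-Whitney case-vs-control comparison. Across genomes: Spearman
#' correlation of case samples' mitochondrial vs nuclear lesion densities.
#'
#' @param lesions Output of [estimate_lesions()].
#' @return List with `per_genome` (data frame) and `mito_nuclear`
#'   (list rho, p; NULL when fewer than two genomes are present).
#' @export
damage_group_stats <- function(lesions) {
  genomes <- unique(lesions$genome)
  per <- lapply(genomes, function(g) {
    d <- lesions[lesions$genome == g, ]
    cs <- d$lesions_per_10kb[d$group == "case"]
    ct <- d$lesions_per_10kb[d$group == "control"]
    mw <- compare_damage(cs, ct)
    data.frame(genome = g,
               mean_excess_per_10kb = mean(cs) - mean(ct),
               sem = stats::sd(cs) / sqrt(length(cs)),
               U = mw$U, p_mannwhitney = mw$p, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  mito_nuclear <- NULL
  if (all(c("mitochondrial", "nuclear") %in% genomes)) {
    mt <- lesions[lesions$genome == "mitochondrial" &
                    lesions$group == "case", ]
    nu <- lesions[lesions$genome == "nuclear" & lesions$group == "case", ]
    m <- match(mt$sample_id, nu$sample_id)
    mito_nuclear <- correlate_damage(mt$lesions_per_10kb,
                                     nu$lesions_per_10kb[m])
  }
  list(per_genome = per, mito_nuclear = mito_nuclear)
}
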