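#' Relative expression from delta-Ct values
#'
#' ddCt is oriented so that lower expression (a later threshold cycle,
#' i.e. larger delta-Ct) gives a negative value:
#' `ddct = mean(control delta-Ct) - sample delta-Ct`, and the fold change is
#' `2^ddct`.
#'
#' @param sample_dct Per-sample delta-Ct values (frataxin Ct minus
#'   reference-gene Ct).
#' @param control_dct Control-group delta-Ct values (>= 1).
#' @param sample_id Optional ids for the output.
#' @return Data frame (sample_id, ddct, fold).
#' @export
relative_expression <- function(sample_dct, control_dct, sample_id = NULL) {
  control_dct <- control_dct[!is.na(control_dct)]
  if (length(control_dct) == 0)
    stop("data error: empty control group for relative expression",
         call. = FALSE)
  ddct <- mean(control_dct) - sample_dct
  if (is.null(sample_id)) sample_id <- as.character(seq_along(sample_dct))
  data.frame(sample_id = sample_id, ddct = ddct, fold = 2^ddct,
             stringsAsFactors = FALSE)
}

#' Stratify patients into high/low expressers
#'
#' ddCt above the threshold (default -2.5, separating the two modes of the
#' frataxin expression distribution) means "high" expresser; values at or
#' below the threshold are "low".
#'
#' @param ddct Numeric vector of ddCt values.
#' @param threshold Stratification boundary.
#' @return Character vector "high"/"low".
#' @export
stratify_expressers <- function(ddct, threshold = -2.5) {
  if (any(!is.finite(ddct)))
    stop("data error: non-finite ddct", call. = FALSE)
  ifelse(ddct > threshold, "high", "low")
}

#' Univariate linear fit of y on x
#'
#' Ordinary least squares with pairwise deletion of missing values;
#' r-squared is the squared Pearson correlation and the two-sided p tests
#' slope = 0 on n - 2 df.
#'
#' @param x,y Numeric vectors of equal length.
#' @return List (slope, intercept, r_squared, p, n).
#' @export
univariate_fit <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3)
    stop("data error: need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0)
    stop("data error: constant predictor", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  co <- stats::coef(sm)
  list(slope = unname(co["x", "Estimate"]),
       intercept = unname(co["(Intercept)", "Estimate"]),
       r_squared = sm$r.squared,
       p = unname(co["x", "Pr(>|t|)"]),
       n = n)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up adjusted p-values; monotone in p-rank and never smaller than the
#' raw p.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @export
qvalues <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("data error: p-values must be in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Supervised per-gene correlation with a covariate
#'
#' Pearson r and two-sided t-test p-value (n - 2 df) per gene; genes at or
#' below the p threshold are returned as passers with the sign of their
#' correlation. Zero-variance gene rows are skipped with a message.
#'
#' @param mat Genes x samples matrix.
#' @param covariate Per-sample covariate (no missing values).
#' @param p_threshold Passer threshold on p (default 0.01).
#' @return List with `results` (gene_id, r, p for every testable gene) and
#'   `passers` (subset with p <= threshold, plus a sign column).
#' @export
supervised_correlation <- function(mat, covariate, p_threshold = 0.01) {
  if (length(covariate) != ncol(mat) || anyNA(covariate))
    stop("data error: covariate must be complete for all samples",
         call. = FALSE)
  if (stats::sd(covariate) == 0)
    stop("data error: constant covariate", call. = FALSE)
  v <- apply(mat, 1, stats::sd)
  if (any(v == 0))
    message("skipping ", sum(v == 0), " zero-variance gene rows")
  keep <- v > 0
  n <- ncol(mat)
  r <- as.numeric(stats::cor(t(mat[keep, , drop = FALSE]), covariate))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- ifelse(abs(r) >= 1, 0, 2 * stats::pt(-abs(tstat), df = n - 2))
  results <- data.frame(gene_id = rownames(mat)[keep], r = r, p = p,
                        stringsAsFactors = FALSE, row.names = NULL)
  passers <- results[results$p <= p_threshold, ]
  passers$sign <- ifelse(passers$r > 0, "positive", "negative")
  rownames(passers) <- NULL
  list(results = results, passers = passers)
}

#' Dichotomize samples at the median age
#'
#' Samples at or below the median go to the lower stratum.
#'
#' @param ages Numeric vector of ages.
#' @return Factor with levels "lower"/"upper".
#' @export
dichotomize_age <- function(ages) {
  m <- stats::median(ages)
  factor(ifelse(ages <= m, "lower", "upper"), levels = c("lower", "upper"))
}

#' Association of a variable with dichotomized age
#'
#' Splits the samples at the median age (values at the median fall in the
#' lower stratum) and applies an equal-variance two-sample t-test. For
#' expression matrices use the SAM route ([permutation_fdr()]) on the
#' strata from [dichotomize_age()] instead; this function is for scalar
#' variables such as per-sample DNA damage.
#'
#' @param values Numeric vector (one value per sample).
#' @param ages Ages in years.
#' @return List (t, p, n_lower, n_upper).
#' @export
dichotomized_age_test <- function(values, ages) {
  if (length(values) != length(ages))
    stop("data error: values and ages must have equal length", call. = FALSE)
  strata <- dichotomize_age(ages)
  if (any(table(strata) == 0))
    stop("data error: all samples fall in one age stratum", call. = FALSE)
  lo <- values[strata == "lower"]
  up <- values[strata == "upper"]
  if (stats::sd(c(lo, up)) == 0)
    return(list(t = 0, p = 1, n_lower = length(lo), n_upper = length(up)))
  if (stats::sd(lo) == 0 && stats::sd(up) == 0)
    return(list(t = sign(mean(lo) - mean(up)) * Inf, p = 0,
                n_lower = length(lo), n_upper = length(up)))
  ht <- stats::t.test(lo, up, var.equal = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       n_lower = length(lo), n_upper = length(up))
}
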