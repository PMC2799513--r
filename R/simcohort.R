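#' Configuration for the synthetic expression cohort
#'
#' Describes a two-group (case vs control) cohort of log-ratio expression
#' profiles with planted differentially expressed genes and planted
#' covariate-driven co-expression patterns. Expression values emulate
#' two-colour log2 ratios against a universal reference, so the null level
#' is 0 and group differences live on the log2 scale.
#'
#' @param n_cases,n_controls Number of case / control samples (> 0).
#' @param n_genes Total number of genes (> 0).
#' @param n_de_genes Number of planted differentially expressed genes;
#'   half are shifted up in cases, half down (extra odd gene goes up).
#' @param de_log2_shift Planted case-minus-control mean difference for DE
#'   genes, in log2 units.
#' @param noise_sd Additive Gaussian noise standard deviation (log2 units)
#'   for background and DE genes.
#' @param patterns List of [pattern_spec()] objects describing planted
#'   co-expression patterns.
#' @param covariate_group_shift Mean offset (in within-group SD units) added
#'   to pattern covariates in cases. Disease-severity covariates track the
#'   case/control split in real cohorts; the offset gives planted patterns a
#'   genuine group signal-to-noise ratio. Set to 0 for group-independent
#'   covariates.
#' @param seed Integer seed; identical seed and config give bitwise-identical
#'   output.
#' @return A validated list of class `expression_sim_config`.
#' @export
expression_sim_config <- function(n_cases, n_controls, n_genes,
                                  n_de_genes = 0, de_log2_shift = 1,
                                  noise_sd = 0.3, patterns = list(),
                                  covariate_group_shift = 2, seed = 1L) {
  stopifnot(is.numeric(n_cases), is.numeric(n_controls), is.numeric(n_genes))
  if (n_cases < 1 || n_controls < 1 || n_genes < 1)
    stop("configuration error: all counts must be > 0", call. = FALSE)
  if (n_de_genes < 0)
    stop("configuration error: n_de_genes must be >= 0", call. = FALSE)
  if (noise_sd < 0)
    stop("configuration error: noise_sd must be >= 0", call. = FALSE)
  n_pattern_genes <- sum(vapply(patterns, function(p) p$n_member_genes, 0))
  if (n_de_genes + n_pattern_genes > n_genes)
    stop("configuration error: more DE/pattern genes than n_genes",
         call. = FALSE)
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 n_genes = as.integer(n_genes),
                 n_de_genes = as.integer(n_de_genes),
                 de_log2_shift = de_log2_shift, noise_sd = noise_sd,
                 patterns = patterns,
                 covariate_group_shift = covariate_group_shift,
                 seed = as.integer(seed)),
            class = "expression_sim_config")
}

#' Specification of one planted co-expression pattern
#'
#' @param n_member_genes Number of member genes (>= 2).
#' @param covariate_name Name of the driving covariate; covariates are drawn
#'   N(0, 1) within group (cases offset by `covariate_group_shift` of the
#'   cohort config). Patterns sharing a covariate name share its values.
#' @param loading Log2 expression change per covariate unit.
#' @param within_pattern_corr_target Target pairwise Pearson correlation
#'   between member genes, in (0, 1]; sets the member-gene noise variance.
#' @export
pattern_spec <- function(n_member_genes, covariate_name, loading = 1,
                         within_pattern_corr_target = 0.9) {
  if (n_member_genes < 2)
    stop("configuration error: n_member_genes must be >= 2", call. = FALSE)
  if (within_pattern_corr_target <= 0 || within_pattern_corr_target > 1)
    stop("configuration error: within_pattern_corr_target must be in (0,1]",
         call. = FALSE)
  list(n_member_genes = as.integer(n_member_genes),
       covariate_name = covariate_name, loading = loading,
       within_pattern_corr_target = within_pattern_corr_target)
}

#' Simulate a two-group expression cohort with planted truth
#'
#' Background genes are pure noise around 0. Planted DE genes receive a
#' case-vs-control mean shift of `de_log2_shift` (half up, half down).
#' Pattern member genes are `loading * covariate + noise`, with the noise
#' variance chosen so pairwise member correlation matches
#' `within_pattern_corr_target` in expectation.
#'
#' @param config An [expression_sim_config()].
#' @return List with components `matrix` (genes x samples, log2 ratios),
#'   `labels` (factor, levels control/case), and `truth` (planted DE gene
#'   directions, pattern memberships, covariate values).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "expression_sim_config"))
  set.seed(config$seed)
  n <- config$n_cases + config$n_controls
  samples <- c(sprintf("case_%02d", seq_len(config$n_cases)),
               sprintf("ctrl_%02d", seq_len(config$n_controls)))
  labels <- factor(rep(c("case", "control"),
                       c(config$n_cases, config$n_controls)),
                   levels = c("control", "case"))
  genes <- sprintf("g%05d", seq_len(config$n_genes))

  mat <- matrix(if (config$noise_sd > 0)
                  stats::rnorm(config$n_genes * n, 0, config$noise_sd)
                else 0,
                nrow = config$n_genes, ncol = n,
                dimnames = list(genes, samples))
  is_case <- labels == "case"

  # planted DE genes occupy the first block, patterns the next; background rest
  de_ids <- character(0); de_dir <- character(0)
  if (config$n_de_genes > 0) {
    de_idx <- seq_len(config$n_de_genes)
    n_up <- ceiling(config$n_de_genes / 2)
    dir_sign <- rep(c(1, -1), c(n_up, config$n_de_genes - n_up))
    mat[de_idx, is_case] <- mat[de_idx, is_case] +
      dir_sign * config$de_log2_shift
    de_ids <- genes[de_idx]
    de_dir <- ifelse(dir_sign > 0, "up", "down")
  }

  # Pattern covariates: unit-variance noise within each group, cases offset
  # by covariate_group_shift. The within-group components are exactly
  # centered, scaled and mutually orthogonalized per group, so planted
  # group SNR and cross-covariate correlations are stable by construction
  # rather than subject to sampling noise.
  cov_names <- unique(vapply(config$patterns,
                             function(p) p$covariate_name, ""))
  covariates <- matrix(0, nrow = n, ncol = length(cov_names),
                       dimnames = list(samples, cov_names))
  for (j in seq_along(cov_names)) {
    z <- stats::rnorm(n)
    for (grp_idx in list(which(is_case), which(!is_case))) {
      zg <- z[grp_idx]
      if (j > 1 && length(grp_idx) > j + 1) {
        prev <- covariates[grp_idx, seq_len(j - 1), drop = FALSE]
        zg <- stats::lm.fit(cbind(1, prev), zg)$residuals
      }
      zg <- zg - mean(zg)
      if (stats::sd(zg) > 0) zg <- zg / stats::sd(zg)
      z[grp_idx] <- zg
    }
    covariates[, j] <- z + config$covariate_group_shift * as.numeric(is_case)
  }

  memberships <- list()
  next_gene <- config$n_de_genes + 1L
  for (i in seq_along(config$patterns)) {
    p <- config$patterns[[i]]
    idx <- seq.int(next_gene, next_gene + p$n_member_genes - 1L)
    next_gene <- next_gene + p$n_member_genes
    cv <- covariates[, p$covariate_name]
    r <- p$within_pattern_corr_target
    # within-group covariate variance is 1; member noise sd from corr target
    noise_var <- p$loading^2 * (1 - r) / r
    noise <- if (noise_var > 0)
      matrix(stats::rnorm(p$n_member_genes * n, 0, sqrt(noise_var)),
             nrow = p$n_member_genes)
    else 0
    mat[idx, ] <- matrix(p$loading * cv, nrow = p$n_member_genes,
                         ncol = n, byrow = TRUE) + noise
    memberships[[paste0("pattern_", i)]] <- genes[idx]
  }

  truth <- list(
    de_genes = data.frame(gene_id = de_ids, direction = de_dir,
                          stringsAsFactors = FALSE),
    de_log2_shift = config$de_log2_shift,
    pattern_memberships = memberships,
    covariate_values = as.data.frame(covariates))
  list(matrix = mat, labels = labels, truth = truth)
}

#' Default long-amplicon QPCR panel
#'
#' The standard panel: an 8.9 kb mitochondrial damage target, a 12.2 kb
#' nuclear damage target, and a ~0.2 kb mitochondrial fragment that is short
#' enough to be essentially lesion-free and serves as the mitochondrial
#' copy-number reference.
#'
#' @return Data frame with columns name, genome, length_kb, role.
#' @export
default_amplicons <- function() {
  amplicon_table(data.frame(
    name = c("mt_long", "nuc_long", "mt_short"),
    genome = c("mitochondrial", "nuclear", "mitochondrial"),
    length_kb = c(8.9, 12.2, 0.2),
    role = c("damage_target", "damage_target", "copy_number_reference"),
    stringsAsFactors = FALSE))
}

#' Validate an amplicon specification table
#'
#' @param amplicons Data frame with columns name, genome, length_kb, role.
#' @return The validated data frame.
#' @export
amplicon_table <- function(amplicons) {
  req <- c("name", "genome", "length_kb", "role")
  if (!all(req %in% names(amplicons)))
    stop("configuration error: amplicon table needs columns ",
         paste(req, collapse = ", "), call. = FALSE)
  if (any(amplicons$length_kb <= 0))
    stop("configuration error: amplicon length_kb must be > 0", call. = FALSE)
  if (!all(amplicons$genome %in% c("mitochondrial", "nuclear")))
    stop("configuration error: genome must be mitochondrial or nuclear",
         call. = FALSE)
  if (!all(amplicons$role %in% c("damage_target", "copy_number_reference")))
    stop("configuration error: unknown amplicon role", call. = FALSE)
  nref <- table(amplicons$genome[amplicons$role == "copy_number_reference"])
  if (any(nref > 1))
    stop("configuration error: at most one copy_number_reference per genome",
         call. = FALSE)
  if (anyDuplicated(amplicons$name))
    stop("configuration error: duplicate amplicon names", call. = FALSE)
  amplicons
}

#' Configuration for the synthetic QPCR damage assay
#'
#' Signals follow the Poisson zero-class model: only lesion-free templates
#' amplify, so the expected signal for an amplicon of length L kb carrying
#' lesion density rho (lesions/10 kb) is `exp(-rho * L / 10)`. On top of
#' this sit a per-sample, per-genome copy-number factor (shared by all
#' amplicons of that genome, which is what short-fragment normalization
#' removes) and independent multiplicative measurement noise, both mean-1
#' lognormal.
#'
#' Case samples additionally receive per-sample lesion-rate multipliers
#' (mean-1 lognormal, CV `lesion_cv`) correlated across genomes on the log
#' scale with correlation `lesion_corr`, emulating the strong mito-nuclear
#' damage correlation seen in patient blood.
#'
#' @param amplicons Amplicon panel, see [default_amplicons()].
#' @param lesions_per_10kb_cases,lesions_per_10kb_controls Named vectors
#'   (genome -> lesion density, lesions/10 kb, >= 0).
#' @param copy_number_cv,measurement_cv Coefficients of variation (>= 0) of
#'   the lognormal copy-number and measurement factors.
#' @param lesion_cv CV of the per-sample lesion-rate multiplier (cases and
#'   controls alike; a zero planted rate is unaffected).
#' @param lesion_corr Log-scale correlation of the lesion multipliers across
#'   genomes within a sample, in [-1, 1].
#' @param n_cases,n_controls Group sizes.
#' @param seed Integer seed.
#' @export
qpcr_sim_config <- function(amplicons = default_amplicons(),
                            lesions_per_10kb_cases =
                              c(mitochondrial = 0.81, nuclear = 0.53),
                            lesions_per_10kb_controls =
                              c(mitochondrial = 0, nuclear = 0),
                            copy_number_cv = 0.05, measurement_cv = 0.05,
                            lesion_cv = 0.3, lesion_corr = 0.7,
                            n_cases = 47L, n_controls = 15L, seed = 1L) {
  amplicons <- amplicon_table(amplicons)
  if (any(lesions_per_10kb_cases < 0) || any(lesions_per_10kb_controls < 0))
    stop("configuration error: lesion rates must be >= 0", call. = FALSE)
  if (copy_number_cv < 0 || measurement_cv < 0 || lesion_cv < 0)
    stop("configuration error: CVs must be >= 0", call. = FALSE)
  if (abs(lesion_corr) > 1)
    stop("configuration error: lesion_corr must be in [-1, 1]", call. = FALSE)
  targets <- amplicons$genome[amplicons$role == "damage_target"]
  for (g in union(names(lesions_per_10kb_cases),
                  names(lesions_per_10kb_controls)))
    if (!g %in% targets)
      stop("configuration error: no damage_target amplicon for genome ", g,
           call. = FALSE)
  structure(list(amplicons = amplicons,
                 lesions_per_10kb_cases = lesions_per_10kb_cases,
                 lesions_per_10kb_controls = lesions_per_10kb_controls,
                 copy_number_cv = copy_number_cv,
                 measurement_cv = measurement_cv,
                 lesion_cv = lesion_cv, lesion_corr = lesion_corr,
                 n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 seed = as.integer(seed)),
            class = "qpcr_sim_config")
}

# mean-1 lognormal draws at coefficient of variation cv
rlnorm_mean1 <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

#' Simulate a QPCR amplification table with planted lesion densities
#'
#' @param config A [qpcr_sim_config()].
#' @return List with `table` (data frame: sample_id, group, target, signal)
#'   and `truth` (planted lesion densities per group and genome, and the
#'   per-sample realized densities).
#' @export
simulate_qpcr <- function(config) {
  stopifnot(inherits(config, "qpcr_sim_config"))
  set.seed(config$seed)
  amp <- config$amplicons
  genomes <- unique(amp$genome)
  n <- config$n_cases + config$n_controls
  samples <- c(sprintf("case_%02d", seq_len(config$n_cases)),
               sprintf("ctrl_%02d", seq_len(config$n_controls)))
  group <- rep(c("case", "control"), c(config$n_cases, config$n_controls))

  # per-sample per-genome lesion multipliers, correlated across genomes
  s <- sqrt(log(1 + config$lesion_cv^2))
  if (s > 0) {
    z_shared <- stats::rnorm(n)
    lr <- config$lesion_corr
    mult <- sapply(genomes, function(g) {
      z <- sign(lr) * sqrt(abs(lr)) * z_shared +
        sqrt(1 - abs(lr)) * stats::rnorm(n)
      exp(s * z - s^2 / 2)
    })
  } else {
    mult <- matrix(1, n, length(genomes))
  }
  if (is.null(dim(mult))) mult <- matrix(mult, nrow = n)
  colnames(mult) <- genomes

  # per-sample per-genome copy factors
  copy <- sapply(genomes, function(g) rlnorm_mean1(n, config$copy_number_cv))
  if (is.null(dim(copy))) copy <- matrix(copy, nrow = n)
  colnames(copy) <- genomes

  base_rate <- function(g, grp)
    ifelse(grp == "case",
           get0_named(config$lesions_per_10kb_cases, g),
           get0_named(config$lesions_per_10kb_controls, g))

  rows <- list()
  realized <- matrix(0, n, length(genomes), dimnames = list(samples, genomes))
  for (g in genomes)
    realized[, g] <- vapply(seq_len(n), function(i)
      base_rate(g, group[i]) * mult[i, g], 0)
  for (j in seq_len(nrow(amp))) {
    g <- amp$genome[j]
    lambda <- realized[, g] * amp$length_kb[j] / 10
    signal <- copy[, g] * exp(-lambda) *
      rlnorm_mean1(n, config$measurement_cv)
    rows[[j]] <- data.frame(sample_id = samples, group = group,
                            target = amp$name[j], signal = signal,
                            stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(table = tab,
       truth = list(true_lesions_per_10kb = list(
                      case = config$lesions_per_10kb_cases,
                      control = config$lesions_per_10kb_controls),
                    realized_lesions_per_10kb = realized,
                    group = stats::setNames(group, samples)))
}

get0_named <- function(v, name) {
  if (name %in% names(v)) unname(v[name]) else 0
}

#' Simulate a gene-set catalog with planted memberships
#'
#' Emulates an experiment-derived gene-set collection. Each planted gene is
#' placed in exactly its requested number of sets (chosen uniformly);
#' remaining slots are filled uniformly at random from the universe.
#'
#' @param n_sets Number of sets.
#' @param set_sizes Integer vector of set sizes, recycled to `n_sets`.
#' @param planted Named integer vector: gene id -> number of sets it must
#'   appear in (each <= n_sets).
#' @param universe Character vector of gene ids.
#' @param seed Integer seed.
#' @return A `gene_set_catalog`: list with `sets` (named list of character
#'   vectors) and `universe`.
#' @export
simulate_gene_sets <- function(n_sets, set_sizes, planted = integer(0),
                               universe, seed = 1L) {
  set.seed(seed)
  sizes <- rep_len(as.integer(set_sizes), n_sets)
  if (any(sizes > length(universe)))
    stop("configuration error: set size exceeds universe", call. = FALSE)
  if (length(planted) && any(planted > n_sets))
    stop("configuration error: planted membership count exceeds n_sets",
         call. = FALSE)
  if (length(planted) && !all(names(planted) %in% universe))
    stop("configuration error: planted genes must be in the universe",
         call. = FALSE)
  sets <- replicate(n_sets, character(0), simplify = FALSE)
  names(sets) <- sprintf("SET_%03d", seq_len(n_sets))
  for (g in names(planted)) {
    pick <- sample.int(n_sets, planted[[g]])
    for (k in pick) sets[[k]] <- c(sets[[k]], g)
  }
  for (k in seq_len(n_sets)) {
    if (length(sets[[k]]) > sizes[k])
      stop("configuration error: planted genes exceed set size for set ", k,
           call. = FALSE)
    # planted genes are excluded from the fill pool so their membership
    # counts stay exact
    pool <- setdiff(universe, c(names(planted), sets[[k]]))
    extra <- sizes[k] - length(sets[[k]])
    if (extra > length(pool))
      stop("configuration error: universe too small to fill set ", k,
           call. = FALSE)
    sets[[k]] <- c(sets[[k]], sample(pool, extra))
  }
  gene_set_catalog(sets, universe)
}

#' Construct a gene-set catalog
#'
#' @param sets Named list of character vectors (unique set names).
#' @param universe Character vector of gene ids; sets are restricted to it.
#' @export
gene_set_catalog <- function(sets, universe) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("configuration error: set names must be unique and non-empty",
         call. = FALSE)
  sets <- lapply(sets, function(g) unique(as.character(g)))
  structure(list(sets = sets, universe = as.character(universe)),
            class = "gene_set_catalog")
}

#' Simulate a clinical table with bimodal frataxin ddCt and covariates
#'
#' Frataxin ddCt values (relative to the control mean; negative = lower
#' expression) are drawn from a two-component Gaussian mixture whose
#' component counts are fixed deterministically at `round(weight * n)`
#' (largest-remainder), so a noise-free configuration reproduces its planted
#' high/low split exactly. Covariates (age of onset, ICARS, short GAA
#' repeats) are linear-Gaussian in ddCt with the squared correlation hitting
#' its target in expectation: onset increases with ddCt (more frataxin,
#' later onset), ICARS and GAA repeat length decrease.
#'
#' @param n Number of patients.
#' @param ddct_modes List of two numeric triples `c(mean, sd, weight)`;
#'   weights must sum to 1.
#' @param onset_r2,icars_r2,gaa_r2 Target squared Pearson correlations with
#'   ddCt, each in [0, 1].
#' @param seed Integer seed.
#' @return List with `clinical` (data frame: sample_id, group, ddct, fold,
#'   age_of_onset, icars, gaa_short) and `truth` (component labels, targets).
#' @export
simulate_clinical <- function(n, ddct_modes = list(c(0, 0.3, 0.22),
                                                   c(-3.5, 0.6, 0.78)),
                              onset_r2 = 0.305, icars_r2 = 0.3,
                              gaa_r2 = 0.344, seed = 1L) {
  stopifnot(length(ddct_modes) == 2)
  w <- vapply(ddct_modes, `[`, 0, 3)
  if (abs(sum(w) - 1) > 1e-8)
    stop("configuration error: mixture weights must sum to 1", call. = FALSE)
  for (r2 in c(onset_r2, icars_r2, gaa_r2))
    if (r2 < 0 || r2 > 1)
      stop("configuration error: target r2 must be in [0, 1]", call. = FALSE)
  set.seed(seed)
  n1 <- round(w[1] * n)
  comp <- sample(rep(c(1L, 2L), c(n1, n - n1)))
  mu <- vapply(ddct_modes, `[`, 0, 1)
  sdv <- vapply(ddct_modes, `[`, 0, 2)
  ddct <- stats::rnorm(n, mu[comp], sdv[comp])

  # population mean/sd of the mixture, for standardization
  m_pop <- sum(w * mu)
  v_pop <- sum(w * (sdv^2 + mu^2)) - m_pop^2
  zd <- (ddct - m_pop) / sqrt(v_pop)
  gen_cov <- function(r2, sign, mean, sd) {
    eps <- if (r2 < 1) stats::rnorm(n) else 0
    mean + sd * (sign * sqrt(r2) * zd + sqrt(1 - r2) * eps)
  }
  onset <- gen_cov(onset_r2, +1, mean = 10, sd = 4)
  icars <- gen_cov(icars_r2, -1, mean = 35, sd = 15)
  gaa <- round(gen_cov(gaa_r2, -1, mean = 650, sd = 230))
  gaa <- pmax(gaa, 0L)

  clinical <- data.frame(
    sample_id = sprintf("case_%02d", seq_len(n)), group = "case",
    ddct = ddct, fold = 2^ddct, age_of_onset = onset, icars = icars,
    gaa_short = gaa, stringsAsFactors = FALSE)
  list(clinical = clinical,
       truth = list(component = comp,
                    targets = c(onset_r2 = onset_r2, icars_r2 = icars_r2,
                                gaa_r2 = gaa_r2),
                    modes = ddct_modes))
}
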