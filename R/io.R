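#' Read a genes-by-samples expression matrix from TSV
#'
#' Expected layout: a header row of sample ids, then one row per gene with
#' the gene id in the first column. Ragged rows, duplicated gene ids and
#' non-numeric cells are rejected with line-numbered errors; empty cells and
#' "NA" become missing values (their count is attached as attribute
#' `n_missing`).
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_expression_matrix <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2)
    stop("parse error: expression matrix needs a header and at least one row",
         call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  n_col <- length(header)
  samples <- header[-1]
  rows <- fields[-1]
  genes <- character(length(rows))
  mat <- matrix(NA_real_, nrow = length(rows), ncol = n_col - 1)
  n_missing <- 0L
  for (i in seq_along(rows)) {
    f <- rows[[i]]
    if (length(f) != n_col)
      stop("parse error: line ", i + 1, ": expected ", n_col,
           " fields, found ", length(f), call. = FALSE)
    genes[i] <- f[1]
    cells <- f[-1]
    missing <- cells == "" | cells == "NA"
    vals <- suppressWarnings(as.numeric(cells))
    bad <- is.na(vals) & !missing
    if (any(bad))
      stop("parse error: line ", i + 1, ": non-numeric value '",
           cells[which(bad)[1]], "'", call. = FALSE)
    n_missing <- n_missing + sum(missing)
    mat[i, ] <- vals
  }
  dup <- genes[duplicated(genes)]
  if (length(dup))
    stop("parse error: duplicated gene id ", dup[1], call. = FALSE)
  dimnames(mat) <- list(genes, samples)
  attr(mat, "n_missing") <- n_missing
  mat
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_matrix()]; numbers are written at full
#' precision so write-then-read round trips are exact.
#'
#' @param mat Numeric matrix with dimnames.
#' @param path Output path.
#' @export
write_expression_matrix <- function(mat, path) {
  header <- paste(c("gene_id", colnames(mat)), collapse = "\t")
  body <- vapply(seq_len(nrow(mat)), function(i)
    paste(c(rownames(mat)[i],
            format(mat[i, ], digits = 17, trim = TRUE, scientific = FALSE)),
          collapse = "\t"), "")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Tab-separated lines: set name, description, then one or more gene ids.
#' Lines with fewer than three fields are parse errors; duplicate genes
#' within a set are de-duplicated with a warning; empty sets are rejected.
#'
#' @param path Path to the GMT file.
#' @param universe Optional universe; defaults to the union of all genes.
#' @return A `gene_set_catalog`.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list(); descs <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("parse error: line ", i,
           ": GMT lines need name, description and at least one gene",
           call. = FALSE)
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0)
      stop("parse error: line ", i, ": empty gene set ", f[1], call. = FALSE)
    if (anyDuplicated(genes)) {
      warning("line ", i, ": duplicate genes in set ", f[1],
              " de-duplicated")
      genes <- unique(genes)
    }
    sets[[f[1]]] <- genes
    descs[f[1]] <- f[2]
  }
  cat_universe <- if (is.null(universe)) unique(unlist(sets)) else universe
  out <- gene_set_catalog(sets, cat_universe)
  attr(out, "descriptions") <- descs
  out
}

#' Write a gene-set catalog as GMT
#'
#' @param catalog A `gene_set_catalog`.
#' @param path Output path.
#' @param descriptions Optional named character vector of set descriptions
#'   (defaults to "na").
#' @export
write_gmt <- function(catalog, path, descriptions = NULL) {
  stopifnot(inherits(catalog, "gene_set_catalog"))
  if (is.null(descriptions))
    descriptions <- attr(catalog, "descriptions")
  lines <- vapply(names(catalog$sets), function(nm) {
    desc <- if (!is.null(descriptions) && nm %in% names(descriptions))
      descriptions[[nm]] else "na"
    paste(c(nm, desc, catalog$sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a sample-metadata TSV
#'
#' First column sample_id, remaining columns covariates; a `group` column,
#' when present, must contain only case/control.
#'
#' @param path Path to the TSV file.
#' @return Data frame.
#' @export
read_metadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sample_id" %in% names(md))
    stop("parse error: metadata needs a sample_id column", call. = FALSE)
  if (anyDuplicated(md$sample_id))
    stop("parse error: duplicated sample_id in metadata", call. = FALSE)
  if ("group" %in% names(md) && !all(md$group %in% c("case", "control")))
    stop("parse error: group must be case or control", call. = FALSE)
  md
}

#' Read a QPCR amplification table from CSV
#'
#' Columns: sample_id, group, target, signal.
#'
#' @param path Path to the CSV file.
#' @return Data frame validated for [estimate_lesions()].
#' @export
read_qpcr_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "group", "target", "signal")
  if (!all(req %in% names(tab)))
    stop("parse error: QPCR table needs columns ",
         paste(req, collapse = ", "), call. = FALSE)
  if (!is.numeric(tab$signal))
    stop("parse error: non-numeric signal column", call. = FALSE)
  tab
}

#' Pipeline configuration
#'
#' Bundles the synthetic-cohort settings, analysis thresholds and the
#' mandatory seed for a full run. Thresholds are validated up front so a bad
#' configuration fails before any stage runs.
#'
#' @param expression An [expression_sim_config()].
#' @param qpcr A [qpcr_sim_config()].
#' @param clinical_n Number of patients in the synthetic clinical table.
#' @param n_sets,set_sizes Gene-set catalog shape for the GSA stage.
#' @param fdr_threshold_percent SAM FDR calling threshold (percent, >= 0).
#' @param gsa_p GSA set-significance threshold in (0, 1).
#' @param consensus_fraction Consensus membership fraction in (0, 1].
#' @param damage_threshold High/low damage boundary (lesions/10 kb).
#' @param stratify_threshold ddCt stratification boundary.
#' @param epig [epig_params()].
#' @param n_perm Permutations for SAM and GSA.
#' @param seed Integer seed (mandatory).
#' @export
pipeline_config <- function(expression, qpcr, clinical_n = 27L,
                            n_sets = 23L, set_sizes = 40L,
                            fdr_threshold_percent = 1, gsa_p = 0.01,
                            consensus_fraction = 0.25,
                            damage_threshold = 0.85,
                            stratify_threshold = -2.5,
                            epig = epig_params(), n_perm = 100L, seed) {
  if (missing(seed))
    stop("configuration error: seed is mandatory", call. = FALSE)
  stopifnot(inherits(expression, "expression_sim_config"),
            inherits(qpcr, "qpcr_sim_config"))
  if (fdr_threshold_percent < 0)
    stop("configuration error: fdr_threshold_percent must be >= 0",
         call. = FALSE)
  if (gsa_p <= 0 || gsa_p >= 1)
    stop("configuration error: gsa_p must be in (0, 1)", call. = FALSE)
  if (consensus_fraction <= 0 || consensus_fraction > 1)
    stop("configuration error: consensus_fraction must be in (0, 1]",
         call. = FALSE)
  if (n_perm < 1)
    stop("configuration error: n_perm must be >= 1", call. = FALSE)
  structure(list(expression = expression, qpcr = qpcr,
                 clinical_n = as.integer(clinical_n),
                 n_sets = as.integer(n_sets),
                 set_sizes = as.integer(set_sizes),
                 fdr_threshold_percent = fdr_threshold_percent,
                 gsa_p = gsa_p, consensus_fraction = consensus_fraction,
                 damage_threshold = damage_threshold,
                 stratify_threshold = stratify_threshold, epig = epig,
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "pipeline_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  dput(unclass_recursive(config), file = tmp)
  unname(tools::md5sum(tmp))
}

unclass_recursive <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, unclass_recursive) else x
}

new_runlog <- function() {
  env <- new.env()
  env$entries <- data.frame(time = character(0), level = character(0),
                            stage = character(0), message = character(0),
                            stringsAsFactors = FALSE)
  env
}

log_entry <- function(log, stage, message, level = "INFO") {
  log$entries <- rbind(log$entries, data.frame(
    time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), level = level,
    stage = stage, message = message, stringsAsFactors = FALSE))
  invisible(log)
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Stages, in dependency order: cohort simulation (expression, QPCR,
#' gene sets, clinical) - DNA damage estimation - SAM differential
#' expression - GSA - consensus signature - validation-cohort overlap -
#' EPIG pattern extraction - clinical correlations. Every stage writes its
#' artifacts under `out_dir`; a manifest records the configuration hash and
#' seed so reruns are reproducible and restartable from disk. Rerunning
#' with an identical configuration reproduces all stochastic outputs
#' exactly.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results and the run
#'   log.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- new_runlog()
  hash <- config_hash(config)
  p <- function(...) file.path(out_dir, paste0(...))

  log_entry(log, "simulate", "start")
  expr_cfg <- config$expression
  expr_cfg$seed <- config$seed
  expr <- simulate_expression(expr_cfg)
  qpcr_cfg <- config$qpcr
  qpcr_cfg$seed <- config$seed + 1L
  qpcr <- simulate_qpcr(qpcr_cfg)
  clin <- simulate_clinical(config$clinical_n, seed = config$seed + 2L)
  catalog <- simulate_gene_sets(
    config$n_sets, config$set_sizes,
    planted = stats::setNames(
      rep(config$n_sets, min(5L, nrow(expr$truth$de_genes))),
      utils::head(expr$truth$de_genes$gene_id, 5L)),
    universe = rownames(expr$matrix), seed = config$seed + 3L)
  write_expression_matrix(expr$matrix, p("expression.tsv"))
  utils::write.csv(qpcr$table, p("qpcr.csv"), row.names = FALSE)
  utils::write.table(clin$clinical, p("clinical.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  write_gmt(catalog, p("gene_sets.gmt"))
  jsonlite::write_json(expr$truth[c("de_genes", "pattern_memberships")],
                       p("truth.json"), auto_unbox = TRUE, digits = NA)
  log_entry(log, "simulate", sprintf("end: %d genes x %d samples",
                                     nrow(expr$matrix), ncol(expr$matrix)))

  log_entry(log, "damage", "start")
  lesions <- estimate_lesions(qpcr$table, config$qpcr$amplicons)
  lesions$classification <- classify_damage(lesions$lesions_per_10kb,
                                            config$damage_threshold)
  stats_dmg <- damage_group_stats(lesions)
  utils::write.table(lesions, p("lesions.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(stats_dmg, p("damage_stats.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  log_entry(log, "damage", sprintf("end: %d lesion records", nrow(lesions)))

  log_entry(log, "de", "start")
  fdr <- permutation_fdr(expr$matrix, expr$labels, n_perm = config$n_perm,
                         seed = config$seed + 4L)
  de <- call_genes(fdr, config$fdr_threshold_percent)
  utils::write.table(fdr$table, p("fdr_table.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(de, p("de_genes.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  log_entry(log, "de", sprintf("end: %d genes called", nrow(de)))

  log_entry(log, "gsa", "start")
  gsa_res <- gsa(catalog, expr$matrix, expr$labels, n_perm = config$n_perm,
                 seed = config$seed + 5L, p_significant = config$gsa_p)
  utils::write.table(gsa_res, p("gsa.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  log_entry(log, "gsa",
            sprintf("end: %d/%d sets significant",
                    sum(gsa_res$significant), nrow(gsa_res)))

  log_entry(log, "consensus", "start")
  sig_sets <- catalog$sets[gsa_res$name[gsa_res$significant]]
  consensus <- if (length(sig_sets) > 0)
    consensus_signature(sig_sets, config$consensus_fraction)
  else consensus_signature(catalog$sets, config$consensus_fraction)
  utils::write.table(consensus$members, p("consensus.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  log_entry(log, "consensus",
            sprintf("end: %d genes at count >= %d",
                    nrow(consensus$members), consensus$min_count))

  log_entry(log, "overlap", "start")
  val_cfg <- expr_cfg
  val_cfg$seed <- config$seed + 6L
  val <- simulate_expression(val_cfg)
  fdr_val <- permutation_fdr(val$matrix, val$labels, n_perm = config$n_perm,
                             seed = config$seed + 7L)
  de_val <- call_genes(fdr_val, config$fdr_threshold_percent)
  ov <- overlap_test(de, de_val,
                     n_universe = length(intersect(rownames(expr$matrix),
                                                   rownames(val$matrix))))
  jsonlite::write_json(ov[c("n_universe", "size_a", "size_b", "k_observed",
                            "p_hypergeom")],
                       p("overlap.json"), auto_unbox = TRUE, digits = NA)
  log_entry(log, "overlap",
            sprintf("end: %d direction-matched genes, p = %.3g",
                    ov$k_observed, ov$p_hypergeom))

  log_entry(log, "epig", "start")
  patterns <- extract_patterns(expr$matrix, config$epig, expr$labels)
  if (nrow(patterns$profiles) > 0) {
    assignment <- assign_genes(expr$matrix, patterns,
                               config$epig$r_assign)
    utils::write.table(assignment, p("epig_assignment.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    write_expression_matrix(patterns$profiles, p("epig_patterns.tsv"))
  } else assignment <- NULL
  log_entry(log, "epig",
            sprintf("end: %d patterns", nrow(patterns$profiles)))

  log_entry(log, "clinical", "start")
  strata <- stratify_expressers(clin$clinical$ddct,
                                config$stratify_threshold)
  onset_fit <- univariate_fit(clin$clinical$ddct,
                              clin$clinical$age_of_onset)
  clin_out <- list(n_high = sum(strata == "high"),
                   n_low = sum(strata == "low"),
                   onset_fit = onset_fit)
  jsonlite::write_json(clin_out, p("clinical_fits.json"),
                       auto_unbox = TRUE, digits = NA)
  log_entry(log, "clinical", "end")

  manifest <- list(config_hash = hash, seed = config$seed,
                   outputs = list.files(out_dir))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE)
  utils::write.table(log$entries, p("run_log.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(list(expression = expr, qpcr = qpcr, clinical = clin,
                 lesions = lesions, damage_stats = stats_dmg, fdr = fdr,
                 de = de, gsa = gsa_res, consensus = consensus,
                 overlap = ov, patterns = patterns,
                 assignment = assignment, clinical_fits = clin_out,
                 log = log$entries, config_hash = hash))
}
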