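#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study cohort with known planted truth.
#
# The cohort mirrors the blood study's design: a two-group expression
# cohort (cases vs controls, log2 ratios vs a universal reference) with
# planted differentially expressed genes and covariate-driven co-expression
# patterns; a long-amplicon QPCR table with planted mitochondrial (0.81)
# and nuclear (0.53) excess lesions per 10 kb at 47 cases vs 15 controls;
# a gene-set catalog; and a clinical table with bimodal frataxin ddCt.

suppressPackageStartupMessages(library(lesionsig))
seed <- 1L
out <- file.path("results", "cohort")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

# with shift 1.5 and noise 0.7 the DE block's within-group pairwise
# correlation is ~0.53: the block is co-expressed (EPIG picks parts of it
# up alongside the planted covariate patterns, as pattern extraction did on
# the real cohorts) without dominating the pattern stage
expr_cfg <- expression_sim_config(
  n_cases = 14, n_controls = 14, n_genes = 2000,
  n_de_genes = 100, de_log2_shift = 1.5, noise_sd = 0.7,
  patterns = list(pattern_spec(50, "frataxin_ddct"),
                  pattern_spec(50, "icars"),
                  pattern_spec(50, "age_of_diagnosis")),
  seed = seed)
expr <- simulate_expression(expr_cfg)
write_expression_matrix(expr$matrix, file.path(out, "expression.tsv"))
meta <- data.frame(sample_id = colnames(expr$matrix),
                   group = as.character(expr$labels),
                   expr$truth$covariate_values)
write.table(meta, file.path(out, "metadata.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

qpcr_cfg <- qpcr_sim_config(seed = seed + 1L)  # 47 v 15, 0.81 / 0.53
qpcr <- simulate_qpcr(qpcr_cfg)
write.csv(qpcr$table, file.path(out, "qpcr.csv"), row.names = FALSE)

catalog <- simulate_gene_sets(
  23, 40,
  planted = setNames(rep(6L, 10), head(expr$truth$de_genes$gene_id, 10)),
  universe = rownames(expr$matrix), seed = seed + 2L)
write_gmt(catalog, file.path(out, "gene_sets.gmt"))

clin <- simulate_clinical(27, seed = seed + 3L)
write.table(clin$clinical, file.path(out, "clinical.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

jsonlite::write_json(
  list(de_genes = expr$truth$de_genes,
       pattern_memberships = expr$truth$pattern_memberships,
       true_lesions_per_10kb = qpcr$truth$true_lesions_per_10kb,
       clinical_targets = as.list(clin$truth$targets)),
  file.path(out, "planted_truth.json"), auto_unbox = TRUE, digits = NA)

cat("Simulated cohort written to", out, "\n")
cat(sprintf(" expression: %d genes x %d samples (%d planted DE, 3 patterns)\n",
            nrow(expr$matrix), ncol(expr$matrix), nrow(expr$truth$de_genes)))
cat(sprintf(" qpcr: %d signals over %d samples\n", nrow(qpcr$table),
            length(unique(qpcr$table$sample_id))))
cat(sprintf(" clinical: %d patients, %d high-frataxin by planted mode\n",
            nrow(clin$clinical), sum(clin$truth$component == 1)))
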