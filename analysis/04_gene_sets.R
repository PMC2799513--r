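#!/usr/bin/env Rscript
# Stage 4: gene-set analysis (GSA maxmean with restandardization), the 25%
# consensus signature over significant sets, and a direction-matched
# hypergeometric overlap against a validation cohort's SAM gene list.

suppressPackageStartupMessages(library(lesionsig))
cohort <- file.path("results", "cohort")
out <- file.path("results", "genesets")
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 1L

mat <- read_expression_matrix(file.path(cohort, "expression.tsv"))
meta <- read_metadata(file.path(cohort, "metadata.tsv"))
labels <- meta$group[match(colnames(mat), meta$sample_id)]
catalog <- read_gmt(file.path(cohort, "gene_sets.gmt"))

res <- gsa(catalog, mat, labels, n_perm = 200, seed = seed,
           p_significant = 0.01)
write.table(res, file.path(out, "gsa_results.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
cat(sprintf("GSA: %d of %d sets significant at p < 0.01\n",
            sum(res$significant), nrow(res)))
print(head(res[, c("name", "score", "p", "fdr")], 5), row.names = FALSE)

sig <- catalog$sets[res$name[res$significant]]
use <- if (length(sig) > 0) sig else catalog$sets
cons <- consensus_signature(use, min_fraction = 0.25)
write.table(cons$members, file.path(out, "consensus_signature.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
cat(sprintf("Consensus: genes in >= %d of %d sets (25%%): %d members\n",
            cons$min_count, cons$n_sets, nrow(cons$members)))

# validation cohort: an independent replicate of the same design
de_main <- read.delim(file.path("results", "diffexpr", "de_genes.tsv"))
val_cfg <- expression_sim_config(
  n_cases = 14, n_controls = 14, n_genes = 2000,
  n_de_genes = 100, de_log2_shift = 1.5, noise_sd = 0.7, seed = seed + 100L)
val <- simulate_expression(val_cfg)
fdr_val <- permutation_fdr(val$matrix, val$labels, n_perm = 200,
                           seed = seed + 101L)
de_val <- call_genes(fdr_val, 1)
ov <- overlap_test(de_main, de_val,
                   n_universe = length(intersect(rownames(val$matrix),
                                                 rownames(mat))))
jsonlite::write_json(ov[c("n_universe", "size_a", "size_b", "k_observed",
                          "p_hypergeom")],
                     file.path(out, "overlap.json"),
                     auto_unbox = TRUE, digits = NA)
cat(sprintf(
  "Overlap: %d direction-matched genes of %d vs %d (N = %d), p = %.3g\n",
  ov$k_observed, ov$size_a, ov$size_b, ov$n_universe, ov$p_hypergeom))
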