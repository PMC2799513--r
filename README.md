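# lesionsig

Blood is an accessible tissue in which to look for systemic signatures of
a mitochondrial disease. `lesionsig` implements, as a tested R package
plus a numbered analysis workflow, the computational chain of a
blood-based Friedreich's ataxia study:

1. **DNA damage from long-amplicon QPCR.** Only lesion-free templates
   amplify, so the amplifiable fraction is the Poisson zero class
   `exp(-lambda)` and the excess lesion frequency of a sample relative to
   undamaged controls is `lambda = -ln(A_sample / A_control)`, scaled to
   lesions per 10 kb. The panel is an 8.9 kb mitochondrial and a 12.2 kb
   nuclear target plus a ~0.2 kb mitochondrial fragment used as the
   copy-number reference. Group statistics: Mann-Whitney U, Spearman rank
   correlation, high/low classification at 0.85 lesions/10 kb.
2. **SAM differential expression.** Two-class unpaired moderated
   d-statistic `d = (m2 - m1) / (s + s0)` with the fudge factor `s0`
   chosen by the CV-minimization recipe, permutation-based FDR over the
   quantile-quantile thresholding rule, and direction-signed gene calling.
3. **Gene-set analysis.** The signed maxmean statistic with
   restandardization against row-randomized sets and a sample-permutation
   null; consensus signatures (genes in at least 25% of significant
   sets); direction-matched cross-cohort overlap with a log-space
   hypergeometric tail; right-tailed Fisher enrichment.
4. **EPIG co-expression patterns.** Iterative filtering by local cluster
   size, pairwise correlation, SNR and magnitude; standardized centroid
   representatives; gene-to-pattern assignment with orphans; correlation
   of patterns with clinical covariates.
5. **Clinical associations.** ddCt relative quantification
   (`fold = 2^ddct`), high/low-expresser stratification at -2.5,
   univariate linear models, BH q-values, supervised per-gene correlation,
   and median-age dichotomization tests.

Patient data of this kind are not redistributable, so the package ships a
synthetic-cohort generator (`simulate_expression`, `simulate_qpcr`,
`simulate_gene_sets`, `simulate_clinical`) with known planted truth;
every stage is validated against it. The methods vignette
(`vignettes/genotoxic-blood-pipeline.Rmd`) documents the models, the
parameter choices, and what the synthetic validation does and does not
establish.

## Worked example

Simulate a study-sized QPCR cohort (47 cases vs 15 controls, planted
excess of 0.81 mitochondrial and 0.53 nuclear lesions/10 kb, 5%
measurement CVs) and estimate the damage:

```r
library(lesionsig)
cfg <- qpcr_sim_config(seed = 1)          # study-sized defaults
lesions <- estimate_lesions(simulate_qpcr(cfg)$table)
st <- damage_group_stats(lesions)
st$per_genome
#>          genome mean_excess_per_10kb        sem   U p_mannwhitney
#> 1 mitochondrial            0.7702236 0.03318638 705  7.213924e-09
#> 2       nuclear            0.5195045 0.02276161 705  7.213924e-09
st$mito_nuclear$rho
#> [1] 0.4441489
```

The estimated group-mean excesses recover the planted 0.81 and 0.53
lesions/10 kb within sampling error; the Mann-Whitney p-values show the
case/control separation, and the positive Spearman rho reflects the
planted co-variation of mitochondrial and nuclear damage across patients.
The closed-form inversion itself:

```r
per_10kb(lesion_frequency(0.5), 8.9)   # ratio 0.5 on the 8.9 kb amplicon
#> [1] 0.7788171
```

## The analysis workflow

The `analysis/` scripts run the full chain on a synthetic cohort, each
stage writing its tables under `results/` and printing what it found:

```sh
Rscript analysis/01_simulate_cohort.R     # cohort + planted truth
Rscript analysis/02_dna_damage.R          # lesion estimates + group stats
Rscript analysis/03_differential_expression.R
Rscript analysis/04_gene_sets.R           # GSA, consensus, overlap
Rscript analysis/05_patterns.R            # EPIG + covariate correlations
Rscript analysis/06_clinical.R            # stratification, fits, q-values
```

Stage 2, for example, prints:

```
 mitochondrial: 0.813 excess lesions/10 kb (SEM 0.045), Mann-Whitney p = 7.2e-09
 nuclear: 0.551 excess lesions/10 kb (SEM 0.031), Mann-Whitney p = 7.2e-09
 mito vs nuclear damage (cases): Spearman rho = 0.659, p = 4.7e-07
```

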