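---
title: "Quantifying DNA damage and genotoxic expression signatures in blood"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying DNA damage and genotoxic expression signatures in blood}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lesionsig)
```

`lesionsig` implements the computational chain of a blood-based study of
Friedreich's ataxia: Poisson-model quantification of mitochondrial and
nuclear DNA damage from long-amplicon QPCR, permutation-based differential
expression (SAM), gene-set scoring (GSA maxmean), consensus
genotoxic-signature construction, co-expression pattern extraction (EPIG),
and clinical-covariate association. Because patient data of this kind are
not freely redistributable, the package ships a synthetic-cohort generator
with known planted truth; every stage is exercised and validated against
that truth.

This vignette explains the models, the tunable parameters, the numerical
choices, and what the synthetic validation does and does not establish
about real data.

## The Poisson zero-class damage model

Long-range quantitative PCR quantifies polymerase-blocking lesions
(strand breaks, abasic sites, oxidized bases). A template molecule
amplifies only if the polymerase traverses the whole amplicon, i.e. if the
template carries zero lesions. Under random lesion placement the lesion
count on an amplicon is Poisson with mean $\lambda$, so the amplifiable
fraction is the zero class $e^{-\lambda}$. Comparing a sample's
amplification $A_s$ to the mean amplification of undamaged controls
$A_c$ gives

$$\hat\lambda = -\ln(A_s / A_c),$$

the *excess* lesions per amplicon relative to the control group. Scaling
by amplicon length expresses this per 10 kb. The panel is an 8.9 kb
mitochondrial target, a 12.2 kb nuclear target, and a ~0.2 kb
mitochondrial fragment that is short enough to be essentially lesion-free
and therefore tracks mitochondrial copy number; the long mitochondrial
signal is divided by it before any ratio is formed.

Numerical and definitional choices:

* **Control reference.** The per-sample ratio uses the *arithmetic mean* of
  the control samples' normalized signals. With this choice the control
  group's expected excess is zero by construction, which the tests verify
  both exactly (noise-free) and in expectation (multiplicative noise).
* **Nuclear normalization.** Only the mitochondrial genome has a
  copy-number reference amplicon; the nuclear target is used unnormalized,
  on the assumption that nuclear copy number is constant across blood DNA
  samples. Per-sample nuclear copy variation therefore flows into the
  nuclear lesion estimate; the generator deliberately includes it so the
  tests measure the consequence.
* **Negative estimates are kept.** A sample that amplifies better than the
  control mean gets a negative $\hat\lambda$. Clamping at zero would bias
  group means upward.
* **Classification boundary.** Samples above 0.85 lesions/10 kb are "high
  damage"; a value exactly at the threshold is classified "low" (the
  boundary is not defined by the source convention, so we fixed it).
* **Group statistics.** Case/control comparison uses the Mann-Whitney U
  test: exact when the combined sample size is at most 12 and tie-free,
  otherwise the normal approximation with tie and continuity corrections
  (`stats::wilcox.test` provides both regimes). The mitochondrial-nuclear
  damage association uses Spearman's rank correlation with an
  exact-enumeration p-value for $n \le 7$ and the t-approximation
  otherwise.

## SAM differential expression

The two-class unpaired SAM statistic for gene $i$ is

$$d_i = \frac{\bar x_{i,2} - \bar x_{i,1}}{s_i + s_0},$$

with $s_i$ the pooled two-sample standard error and $s_0$ a shared fudge
factor that damps low-variance genes. $s_0$ is selected from the
percentiles (0, 5, ..., 100) of the $s_i$ distribution by minimizing the
coefficient of variation of the windowed median absolute deviations of
$d$, the standard stabilization recipe.

Significance calling orders the observed $d$ values against the expected
order statistics $\bar d_{(i)}$ (the mean of the sorted permuted
statistics). For a threshold $\Delta$, genes with
$|d_{(i)} - \bar d_{(i)}| \ge \Delta$ are called; the implied cutoffs
(smallest called $d$ on the positive side, largest on the negative side)
are applied to every permutation, and the false discovery rate is the
summarized permutation false count divided by the number called. All
distinct label assignments are used when there are few enough, otherwise a
seeded uniform sample.

**Why the FDR uses the mean false count.** The false count over
permutations can be summarized by its mean or its median; both are
tabulated, and a flag selects which one drives the FDR (default: mean, the
original SAM formulation). The median interacts badly with the "smallest
$\Delta$ achieving the target FDR" calling rule: on pure-null data the most
extreme observed gene exceeds the *median* permutation maximum with
probability about one half, so the median-based FDR collapses to zero at
the largest thresholds on roughly half of null datasets and spuriously
calls the top gene (and occasionally several). The mean false count only
vanishes when no permutation anywhere reaches the observed cutoff, which
restores the expected null behaviour (the validation suite checks that
pure-null cohorts call at most a stray gene or two over 20 seeds). No
$\pi_0$ correction is applied.

## Gene-set analysis and the consensus signature

Per-gene scores feeding GSA are the SAM $d$ statistics. The set statistic
is the signed *maxmean*: with scores $z$ restricted to the set,
$s^+ = \operatorname{mean}(\max(z, 0))$,
$s^- = \operatorname{mean}(\max(-z, 0))$, and the statistic is $s^+$ if
$s^+ \ge s^-$, else $-s^-$. Observed scores are *restandardized* by the
mean and SD of maxmean over random gene sets of the same size drawn from
all scored genes; the identical construction under each sample-label
permutation yields the two-sided p-value (with the +1 correction, so the
smallest attainable p is $1/(B+1)$ for $B$ permutations). The set-level
FDR is the permutation ratio: the average permutation count of sets
scoring beyond $|z_k|$ over the observed count. Sets with $p < 0.01$ are
flagged significant. Defaults: 200 permutations, 1000 random sets per
size (tests use fewer where the calibration they probe does not need
them).

The consensus signature across significant sets collects genes present in
at least a fraction $f$ (default 25%) of the sets; the membership cutoff
is the smallest integer at or above $f \times n_{\text{sets}}$, so 25% of
23 sets requires membership in at least 6. Cross-cohort agreement is
measured by the direction-matched intersection of two signed gene lists
and an upper-tail hypergeometric p-value with the two list sizes as
margins; the universe defaults to the genes present in both analyses. The
hypergeometric tail is summed in log space, and the enrichment of a gene
list in a set (right-tailed Fisher's exact test) reuses it; the odds ratio
gets a 0.5 continuity correction only when a table cell is zero.

## EPIG pattern extraction

All gene profiles start as pattern candidates. A candidate's *local
cluster* is the set of profiles whose Pearson correlation with it exceeds
$R_t$; candidates with local cluster size below $M_t$ are dropped; among
candidates correlated above $R_t$ with each other the one with the
smaller local cluster is dropped (processing in decreasing cluster-size
order, ties by gene id, so the larger cluster always survives). Each
survivor's *representative profile* is the centroid of its local cluster;
representatives failing the signal-to-noise or magnitude filters are
dropped, and the remainder — standardized to mean 0, SD 1 across samples —
are the patterns. Genes are then assigned to the pattern they correlate
with most strongly, or flagged *orphans* below the assignment threshold
$R$.

Definitions this package had to fix because the procedure's published
description leaves them open: the representative profile is the
standardized centroid; correlations are Pearson on the log-ratio
profiles; the SNR of a profile is the standard deviation of its
case/control group means over the pooled within-group SD (with a
$|\text{mean}|/\text{SD}$ fallback when only one group is usable);
magnitude is the maximum absolute value of the unstandardized centroid.
Defaults ($R_t = 0.7$, $M_t = 10$, $\text{SNR}_t = 1.0$,
$\text{magnitude}_t = 0.5$, $R = 0.64$) are package defaults for
log2-ratio blood data, not values inherited from any study. Zero-variance
profiles have undefined correlations and are treated as unlinked.
Multiplying all profiles by a positive constant changes nothing except
through the magnitude filter.

## Clinical associations

Frataxin expression is quantified by the threshold-cycle method: a
sample's ddCt is the control-group mean delta-Ct minus the sample's
delta-Ct, so *negative ddCt means lower expression* and the fold change is
$2^{\text{ddct}}$ (the source material never states the sign convention;
this orientation puts the low-expresser mode below the -2.5 stratification
threshold, matching the distribution it was chosen from). Values exactly
at -2.5 stratify as low expressers. Gene- and damage-level associations
with clinical covariates use ordinary least squares with the two-sided
slope test on $n - 2$ df; multiple testing uses Benjamini-Hochberg
step-up q-values (the transparent default; the original analysis does not
name its method, so a switch is reserved). Supervised per-gene correlation
against a covariate reports Pearson r with the t-based p-value and the
passers at $p \le 0.01$ with their signs. Age effects are tested after
dichotomizing at the median age, samples at the median going to the lower
stratum, with an equal-variance t-test for scalar variables; expression
matrices go through the SAM route on the same strata instead.

## The synthetic-cohort generator

The generator is first-class, tested code; its defaults are the study
conditions the pipeline is validated under.

* **Expression.** Genes-by-samples log2 ratios versus a universal
  reference (a single matrix; no dye-swap modelling). Background noise is
  additive Gaussian. Planted DE genes get a case-minus-control mean shift
  (half up, half down). Pattern member genes are
  $\text{loading} \times \text{covariate} + \text{noise}$, the noise
  variance set from the target within-pattern correlation.
* **Pattern covariates.** Drawn with unit variance within each group and a
  case-mean offset (default 2 within-group SDs). The offset reflects that
  disease-severity covariates track the case/control split in real
  cohorts, and it gives planted patterns a genuine group SNR — without it
  no planted pattern could pass the default SNR filter. The within-group
  components are exactly centered, scaled and mutually orthogonalized per
  group, so planted SNRs and cross-pattern correlations are stable by
  construction instead of fluctuating with the seed.
* **QPCR.** Signals follow
  $\text{copy factor} \times e^{-\lambda} \times \text{noise factor}$,
  with mean-1 lognormal copy-number factors shared by all amplicons of a
  genome within a sample (so short-fragment normalization has something
  real to remove) and independent mean-1 lognormal measurement noise. The
  short amplicon obeys the same lesion model; its $\lambda$ is small only
  because it is short, which makes the assay's slight underestimation of
  the mitochondrial rate (the short fragment is not perfectly lesion-free)
  part of the simulation rather than an idealization. Case samples get
  per-sample lesion-rate multipliers (mean-1 lognormal, CV 0.3) correlated
  across genomes on the log scale (correlation 0.7): real patients differ
  in damage burden and their mitochondrial and nuclear burdens co-vary
  strongly; without this between-sample heterogeneity the mito-nuclear
  damage correlation the pipeline measures would have nothing to detect.
  The measurement CVs default to 5%; the assay's true noise is not
  published, so these are stated working values.
* **Gene sets.** Planted genes appear in exactly their requested number of
  sets; remaining slots are filled uniformly from the universe excluding
  planted genes (so planted membership counts stay exact).
* **Clinical.** Frataxin ddCt comes from a two-component Gaussian mixture
  whose component counts are fixed at round(weight x n) rather than drawn
  binomially, so a noise-free configuration reproduces its planted
  high/low split exactly. Covariates are linear-Gaussian in ddCt with the
  squared correlation hitting its target in expectation (exact sample r²
  is not forced): age of onset increases with ddCt, ICARS and short-GAA
  repeat length decrease. GAA repeats are rounded to integers and floored
  at zero, which makes a planted $r^2 = 1$ exact only before rounding.

**What passing tests show — and do not.** The synthetic cohorts have
Gaussian noise, exchangeable samples, and no batch structure, probe-level
artifacts, dye bias, missing values, or confounding between group and
covariates beyond what is planted. Validation against them establishes
that the estimators are implemented correctly, are calibrated under their
own model, and recover planted signal at the study's sample sizes — not
that real blood cohorts satisfy the model. In particular the real assay's
noise level is unknown, and real expression data would add normalization
and annotation issues that are out of scope here.

## Problem sizes used in validation

The validation suite runs the damage chain at the study's 47 vs 15 design
(1000 null replicates for calibration), differential expression at
1000 genes with 10 vs 10 samples and 100-200 permutations, GSA at 200
sets of 15 genes with 200 permutations and 500 random sets per size, EPIG
at 1000 genes with 14 vs 14 samples over 10 seeds, and the clinical chain
at n = 27. These sizes were chosen so each statistical property is
measured with useful precision while the whole suite stays quick to run.

## Known limitations

* The nuclear lesion estimate absorbs nuclear copy-number variation by
  design; a nuclear copy-number reference amplicon would remove it.
* The SAM route offers only the two-class unpaired mode.
* GSA p-values are permutation-granular: with 200 permutations the
  smallest attainable p is about 0.005.
* The consensus-signature and overlap stages take gene identifiers as
  opaque strings; cross-platform identifier mapping is the caller's
  concern.
* The GEO series backing the original expression analysis can be analyzed
  with this package after external download and conversion to the TSV
  format, but no downloader is bundled and no result in this package
  depends on it.
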