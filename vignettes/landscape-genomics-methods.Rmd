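---
title: "Methods: selection scans and polygenic scores for structured populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: selection scans and polygenic scores for structured populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaptscan)
```

## The analysis problem

`adaptscan` implements a complete landscape-genomics workflow for detecting
local adaptation from SNP genotypes of a small number of strongly
differentiated populations — the situation typical of range-wide sampling in
low-dispersal amphibians, where a handful of collection sites (often four to
eight) each contribute ~20 individuals, reduced-representation sequencing
leaves ~20% of genotypes uncalled, and a large fraction of SNPs is invariant
within any single site. The workflow runs from genotype filtering through
per-locus selection scans, consensus candidate sets, and
missingness-normalized additive polygenic scores tested against random-subset
null distributions.

The package deliberately replaces MCMC-based tools with deterministic,
closed-form analogs of the same statistics (labeled `xtx-lite` / `bf-lite`),
so that every stage is seedable, fast, and testable against analytic
expectations. No numeric equivalence with the original tools is claimed;
the statistical roles are the same.

## Data model

Genotypes live in a `genotype_matrix`: a samples-by-loci matrix of
alternate-allele dosages in {0, 1, 2}, `NA` for uncalled genotypes, with
per-sample population labels and a locus table (chromosome, 1-based position,
REF/ALT). Allele-count statistics (F-statistics, allele frequencies,
diversity, polygenic scores) only ever consume called integer dosages;
population-mean imputation (`impute_by_population()`, fractional expected
dosages `2 p_hat`) marks the matrix `imputed`, and only PCA-style operations
accept it. This split prevents imputed values from ever leaking into
allele-count estimators.

Site-level environments are an `env_table`: one row per site with decimal
coordinates and any number of site-constant variables. The bundled
`barbouri_sites()` table carries the four *Ambystoma barbouri* study sites
(range core plus northern, southern, western edges) with the six retained
environmental factors.

## Filtering and summary statistics

`iterative_filter()` applies an alternating schedule of SNP and individual
missingness filters; a SNP is dropped when its missingness exceeds the
threshold in *any one* population, which protects against markers that are
informative in some sites and absent in others. The default schedule (SNP
0.5 → 0.3 → 0.25 interleaved with individual 0.7 → 0.5) is progressively
stricter; the exact published schedules of comparable studies live in
supplements and vary, so the schedule is fully user-configurable and the
default is documented, not claimed to match any particular study.

Weir–Cockerham F\_ST is the multi-locus ratio-of-averages estimator over the
per-locus variance components a, b, c, restricted to loci polymorphic in the
pooled pair; F\_IS uses per-locus observed heterozygosity against
sample-corrected gene diversity, again as a ratio of averages. Confidence
intervals bootstrap across loci with the bias-corrected percentile method
(BC, not BCa): the reference implementations name a "bias-corrected"
bootstrap without further detail, and BC is the simplest member of that
family. Negative F\_ST estimates are reported as-is alongside a zero-clamped
column, keeping transparency while supporting the
`F_ST / (1 - F_ST)` linearization.

Nucleotide diversity uses the unbiased `2 p q n/(n-1)` form with `n` the
number of called allele copies, which equals the average pairwise difference
among the sampled alleles.

Genetic structure is summarized by genotype PCA (SVD on the centered,
optionally scaled dosage matrix) and successive K-means with the BIC
`n log(WSS/n) + K log(n)`. One practical subtlety: with only a few retained
PCs the BIC gain from splitting isotropic noise exceeds the `log(n)` penalty
and K is overestimated; clustering therefore operates on a deep PC basis
(the pipeline uses up to 40 components), where noise dimensions dilute the
within-cluster sum-of-squares gain and the criterion recovers the planted K
reliably.

Geographic distance is the haversine great-circle distance on a sphere of
radius 6371 km — with the bundled site table this reproduces the published
mean pairwise separation (190.6 km) and the north–south distance (268 km) to
better than 0.5%, which is why the haversine was chosen over an ellipsoidal
geodesic. Environmental distance standardizes the variables, rotates by PCA
and takes Euclidean distance on all components; the rotation is documented
as a no-op for the distance (orthogonal invariance) and is kept for parity
with the field's habit of working in environmental PC space.

## Selection scans

Four per-locus scans are provided. All report a tidy `scan_result` tibble
with a `significant` flag tied to the stated threshold, and all thresholds
follow the conventions of the tools they parallel: Bonferroni `0.01/L` for
the individual-based scans, BH FDR `q < 0.05` for FLK, an empirical
pseudo-observed-dataset (POD) quantile for XtX, and joint empirical
quantiles (BF top 5% AND |rho| top 1%) for the frequency-level association
scan.

**PCA-regression outliers** (`pcadapt_scan()`). Each scaled locus is
regressed on K principal components; the K-vector of z-scores is summarized
by a Mahalanobis distance. Two numerical choices differ from the reference
implementation and are deliberate: the distance is centered at zero (the
theoretical null center of z-scores) rather than at a robust location
estimate, and the scatter is estimated by deterministic iterative trimming
(best 75% of loci, with the standard normal-consistency factor) rather than
by the randomized fast-MCD algorithm. Both choices make the scan exactly
equivariant to locus order and to allele recoding, properties the package
tests. The genomic inflation factor `median(D)/median(chi2_K)` rescales the
distances before chi-square p-values.

**FLK** (`flk_scan()`). The population kinship matrix comes from pairwise
Reynolds coancestry distances (ratio of sums across loci), scaled so that
two independently drifted populations with frequency variances `F_i pi q`
have expected distance `F_i + F_j`, a neighbor-joining tree, midpoint
rooting, and shared branch lengths. The per-locus statistic is the quadratic
form of frequency deviations from the kinship-weighted ancestral-frequency
estimate, referred to chi-square with `n_pops - 1` degrees of freedom. Because
the kinship is estimated from the same (finite-sample) frequencies, binomial
sampling noise is absorbed into the kinship scale; the null distribution
matches its chi-square reference well when per-population samples are
moderate (the tests use 40 diploids per population).

**Covariance model and XtX** (`estimate_pop_covariance()`, `xtx_scan()`,
`pod_calibrate()`). The among-population covariance Omega of the Gaussian
drift model is estimated by a method of moments. A genuine identifiability
limit shapes the estimator: the per-locus ancestral frequency is estimated
by the across-population mean, and centering on an estimated mean
annihilates the all-ones component of Omega — the moment matrix only
determines `A Omega A` with `A = I - 11'/r`. The estimator returns the unique
completion minimizing the off-diagonal sum of squares, which reconstructs
any diagonal (independent-drift) Omega exactly and attributes unresolvable
shared drift to the diagonal. Linear shrinkage toward the diagonal (default
intensity 0.05, automatically increased if needed) guarantees positive
definiteness. The estimated Omega is the *total* covariance of observed
frequencies, including binomial sampling noise; the XtX statistic and its
POD calibration use the same quantity, so the calibration is internally
consistent. A second consequence of estimated centering: the neutral
expectation of XtX is `n_pops - 1`, not `n_pops` — the centering consumes one
degree of freedom — and the package's tests assert the mean against a
Monte-Carlo evaluation of exactly this quantity.

The POD draws ancestral frequencies from Uniform(0.05, 0.95) (the original
tool's prior is internal to its MCMC; this range is a stated substitute, not
a claim of equivalence), simulates population frequencies from the clipped
Gaussian drift model, resamples observed allele-count denominators with
replacement from the data, and returns the `1 - q` quantile (default top
0.01%). With the historical choice `L_pod = L` a 0.01% quantile rests on a
single order statistic; the default is therefore
`L_pod = max(L, 1e5)`, with the smaller choice available.

**Latent-factor association** (`lfmm_scan()`). For each variable, K latent
factors are estimated from the SVD of genotype residuals after a
ridge-regularized projection on the environmental design; each locus is then
regressed jointly on the variable and the factors, and z-scores are
recalibrated by the genomic inflation factor. With a site-constant
environment and K factors estimated after removing the environmental
direction, drift *along* the environmental axis cannot be absorbed by the
factors; its variance loads on the environmental coefficient and is removed
only by the global GIF rescaling. The practical consequence, documented
rather than hidden: under strong drift (`F n_per_site >> 1`) the raw GIF is
well above 1 and the scan leans entirely on the empirical recalibration,
while in the weak-structure regime (`F n_per_site << 1`, no imputation) the
model is well specified and the GIF sits near 1. The package's calibration
tests therefore run at `F = 0.002` with 25 diploids per site (GIF in
[0.8, 1.2], Bonferroni null rate ≤ 0.1%, power ≥ 80% on planted effects of
1.5 logit units per environmental SD across 8 sites); behaviour at
study-strength drift is exercised separately without a GIF-band assertion.
Population-mean imputation itself adds site-level covariance (imputed
entries equal site means), a second reason the calibration suite uses
complete matrices.

**Frequency-level association** (`env_assoc_scan()`). The standardized
frequency deviations are whitened by the Cholesky inverse of the estimated
Omega; a Zellner g-prior Bayes factor (unit information, `g = n_pops`)
compares the whitened regression on the standardized variable against the
intercept-only null, and Spearman's |rho| between whitened frequencies and
the raw site values adds a robust, threshold-gated second criterion.
Monomorphic loci are retained with the null-favoring BF `(1+g)^(-1/2)` and
rho 0, so the empirical quantile thresholds always see the full locus set.

## Consensus, polygenic scores, null models

`overlap_permutation()` evaluates whether tests agree more than chance:
observed statistics are the proportion of the significant-locus union found
by at least two tests and, per test pair, the Jaccard shared proportion
(the raw intersection count is also reported — its permutation null mean is
the hypergeometric `s1 s2 / L`, which the tests verify). Null sets are
redrawn uniformly without replacement at the observed sizes;
one-sided p-values use the `(1 + #{null >= obs}) / (reps + 1)` convention.

`gea_consensus_sets()` builds one candidate set per environmental variable:
loci flagged by at least one association test for that variable and by at
least one *other* test (of any kind). `orient_alleles()` determines, per
candidate locus, the allele whose frequency rises with the variable (sign of
the Pearson correlation across sites; zero-correlation loci are excluded);
`additive_scores()` then sums oriented dosages into a raw score and divides
by twice the number of non-missing candidate loci — the percent score is the
fraction of the maximum score attainable given the individual's missing
data. Recoding REF/ALT at every locus maps each percent score p to exactly
1 − p under a fixed orientation, and re-deriving the orientation restores
the original scores; both identities are tested.

`fit_score_glmm()` models raw successes out of `2 n_nonmissing` trials with
a binomial-logit GLMM: a site-level fixed predictor (standardized
internally, coefficient reported on the original scale) and a random site
intercept. Estimation is penalized-likelihood (Laplace, lme4); the original
study used weakly-informative Bayesian priors whose settings are not
published, so no numeric equivalence is claimed and the backend is recorded
in the fit object. Intervals are Wald with a t critical value at
`n_sites - 2` degrees of freedom — a site-level predictor carries site-level,
not individual-level, information, and the normal critical value undercovers
noticeably at 8 sites. With four or five sites the fixed effect and the
random intercept are weakly identified (a warning is issued); the package's
parameter-recovery and coverage tests use 8 sites.

`random_subset_null()` re-runs orientation, scoring and the same GLMM on
random locus subsets of the observed candidate-set size, giving the
empirical one-sided p-value for the observed coefficient. Random subsets are
drawn from the full locus universe (including candidate loci), matching the
natural reading of the published procedure.

## Annotation

`nearest_gene()` reproduces BEDTools `closest -d` semantics, verified
against bedtools on worked examples: distance 0 inside a gene, gap + 1
otherwise (bookended intervals report 1), sign positive when the gene lies
downstream of the SNP. Equidistant genes are all reported with a tie flag —
the underlying tool's tie behaviour is configuration-dependent, so
surfacing ties is the conservative choice. SNPs on chromosomes without gene
models are returned unannotated rather than dropped.
`fisher_enrichment()` is a generic two-sided Fisher-exact term enrichment
with BH FDR, taking the user's gene-to-term map; no external annotation
service is contacted.

## The synthetic-data generator

`simulate_dataset()` generates the statistical structure the analysis
assumes: ancestral frequencies Uniform(0.05, 0.95); per-population
frequencies from a Balding–Nichols Beta distribution (scalar drift F) or
from `Normal(pi, pi(1-pi) Omega)` clipped to [0, 1] (matrix Omega — clipping
produces the point masses at 0/1 that generate realistic within-population
invariant fractions); planted adaptive loci as shifts of `b` logit units per
standardized-environment SD; Binomial(2, p) genotypes; MCAR missingness.
Defaults mirror the study conditions the package targets: 4 populations ×
20 diploids, 2000 loci, F = 0.3 (pairwise Weir–Cockerham F\_ST ≈ 0.3, inside
the 0.2–0.5 range of strongly structured amphibian sites), 19% missingness,
50 adaptive loci of effect 1.5.

What the generator does *not* emulate — and what passing tests therefore do
not demonstrate about real data: linkage between loci (all loci independent;
no LD, no haplotype structure), non-random missingness (real RAD dropout
correlates with divergence at restriction sites), genotyping error and
depth-dependent allele-balance artifacts, paralog collapse, and continuous
admixture between sites. Recovery rates on planted loci are accordingly
optimistic relative to field data at equal effect size.

Test and validation problem sizes (2000-locus scans, 5-seed calibration
suites, 20-seed GLMM recovery, permutation and subset-null replicates of
39–4000 in tests versus package defaults of 1000–10,000) were chosen so the
complete suite runs in minutes on one CPU; the package defaults keep the
published replicate counts.

## Worked example

```{r example, eval = FALSE}
sim <- simulate_dataset(sim_config(seed = 1))
g   <- iterative_filter(sim$genotypes)
fr  <- population_allele_freqs(g)

pairwise_wc_fst(g, n_boot = 200)

gi  <- impute_by_population(g, global_fallback = TRUE)
pc  <- pcadapt_scan(gi, K = 3)
cov <- estimate_pop_covariance(fr)
thr <- pod_calibrate(cov, fr$n_alleles, seed = 2)
xt  <- xtx_scan(fr, cov, pod_threshold = as.numeric(thr))
lf  <- lfmm_scan(gi, sim$env, K = 4)
bf  <- env_assoc_scan(fr, cov, sim$env)
fl  <- flk_scan(fr)

sets <- significance_sets(
  list(pcadapt = pc, flk = fl, xtx = xt, lfmm = lf, bf = bf),
  universe = g$loci$locus, gea_tests = c("lfmm", "bf")
)
overlap_permutation(sets, reps = 10000, seed = 3)
cons <- gea_consensus_sets(sets)

ori <- orient_alleles(fr, sim$env, "temp", cons$temp)
sc  <- additive_scores(g, ori)
fit <- fit_score_glmm(sc, sim$env, "temp")
random_subset_null(g, fr, sim$env, "temp",
  n_loci = length(cons$temp), reps = 1000, seed = 4,
  observed_beta = fit$beta
)
```

## Known limitations

- With four sites, any site-level association test is weakly identified;
  the GLMM warns, and per-locus GEA power under strong drift is low. The
  consensus-set and polygenic-score machinery exists precisely because
  per-locus evidence is weak in this regime.
- The covariance estimator cannot recover shared drift components that are
  uniform across all populations (they are attributed to the diagonal); XtX
  and the Bayes-factor scan are internally consistent because estimation and
  calibration share the same convention.
- The latent-factor scan's GIF correction is a global rescaling; under
  strong, heavy-tailed drift (Balding–Nichols F around 0.3) the far tail of
  the PCA-regression scan is mildly anticonservative, which is why its
  calibration is validated at moderate drift.
- Bootstrap intervals use the BC, not BCa, correction; acceleration is
  unidentified without a stated jackknife convention in the references.
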