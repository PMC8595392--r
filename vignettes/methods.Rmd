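---
title: "Models and methods: low-coverage genomic selection with lcgblup"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: low-coverage genomic selection with lcgblup}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`lcgblup` implements a complete evaluation pipeline for genomic selection
based on low-coverage whole-genome sequencing (lcWGS): a generative model of
a structured diploid population with shallow sequencing reads, reference-free
genotype imputation through a founder-haplotype hidden Markov model,
imputation scoring, genomic relationship matrices, single- and two-trait
GBLUP fitted by AI-REML, and k-fold cross-validation of prediction accuracy
and dispersion bias. This vignette documents the models, the tunable
parameters, the numerical choices, and what the synthetic data do and do not
establish about real data.

# The population generator

## Founder-mosaic model

Every simulated chromosome is a mosaic of `K` founder haplotypes. A
haplotype starts from a uniformly drawn founder and, between adjacent sites,
re-draws its founder with probability `switch_rate` (uniform destination, so
the probability of an effective change is `switch_rate * (K-1)/K`). Founder
alleles are Bernoulli draws at per-site target frequencies (uniform on
`[0.05, 0.5]` by default), optionally copying the previous site's allele
with probability `ld_copy` (default 0.3) to give the founders themselves
some along-genome autocorrelation. Genotypes are the sums of the two
haplotype alleles and are exactly reconstructible from the stored mosaic
paths, which is what makes the generator usable as ground truth for the
imputation model: the data are generated by precisely the process class the
HMM assumes.

`switch_rate` controls the information content of the data and deserves
explanation. The default is 0.002 per interval over the default 200 sites,
i.e. well under one switch per chromosome per window. Real lcWGS panels in
livestock carry millions of segregating sites, so a 200-site desk-scale
window corresponds to a short physical region in which founder segments
essentially always span the window; equivalently, each founder segment
receives on the order of several hundred reads at 1x coverage. A much
higher switch rate (say 0.02 over 200 sites) would model a population whose
founder segments carry only ~50 reads each — an information regime far
below what dense real data provide, and one in which no method, including
an oracle given the true founder haplotypes, can impute accurately. We
verified this with the Bayes-optimal bound: handing the true founder panel
and switch rate to the forward-backward smoother yields dosage r-squared of
about 0.84, 0.96 and 0.98 at switch rates 0.02, 0.005 and 0.002 under the
default configuration. The default therefore emulates the segment-level
read support of dense data rather than literally scaling the switch process.

## Traits

Phenotypes follow the standard animal-model decomposition
`y = fixed effects + u + e`. Causal sites (`n_qtl`) are sampled from the
segregating sites, effects are drawn normal, and the resulting genetic
scores are *calibrated in sample*: each trait's breeding values are
standardized and rescaled so their sample variance equals the target
`sigma_a^2` exactly, and for two traits the second score is built as
`r * z1 + sqrt(1 - r^2) * z2_orth` from the standardized first score and an
orthogonalized second score, so the realized genetic correlation equals the
target exactly. The point of exact calibration is sharpness of
parameter-recovery tests at desk scale: REML estimates can be compared
against known realized values instead of against targets blurred by
finite-QTL sampling noise. Residuals are drawn from the target residual
(co)variance; fixed effects (sex, year-season, and an age covariate for the
second trait) default to contrasts of about half a residual standard
deviation — large enough that a failure to correct for them is visible in
cross-validation tests.

Exact calibration has one statistical side effect worth knowing when using
the generator for estimator-calibration studies. REML estimates the
*G-scale* of the breeding values, whereas the calibration pins their
*sample variance*; the two functionals coincide only when the relationship
matrix has high effective rank. In a strongly structured population (few
founders, strong LD) a Gaussian draw concentrates on the top eigenvectors
of `G`, the pinned sample variance is dominated by those components, and
the rescaling injects their fluctuation into every other component —
inflating the replicate-to-replicate scatter of genetic-variance estimates
roughly twofold relative to the reported standard errors (which we verified
match the observed information). Parameter-recovery studies should
therefore use a well-mixed population (large `K`, high `switch_rate`),
where the effective rank is high and 2-SE coverage is nominal; the
package's own recovery tests do exactly that.

## Reads

Read counts are per-site, per-individual Poisson with mean `mean_depth`;
each read reports the alternate allele with probability
`g/2 (1-e) + (1-g/2) e` for genotype `g` and base error `e`. Depth has no
along-genome autocorrelation, which is exactly the assumption that makes
binomial thinning (`downsample_reads`) the correct model of re-sampling
reads to a lower target depth. There is no read-level sequence simulation,
no mapping error, and no site-discovery step: the simulator emits a known
site list.

# Imputation

## Read likelihoods and the LD-free baseline

`genotype_likelihoods` computes binomial likelihoods `P(reads | g)` with
per-read alternate probabilities `e`, `1/2`, `1-e` for `g = 0, 1, 2`. The
allele counted throughout is the VCF alternate allele, not the minor
allele, so dosages remain consistently coded when frequencies cross 0.5.
`baseline_dosages` is the single-site reference method: per site, an EM
iteration alternates Hardy-Weinberg genotype priors at the current
frequency with posterior averaging of dosages (convergence 1e-6 on the
frequency, at most 100 iterations). It uses no linkage information, so the
margin of the HMM over this baseline isolates the value of modelling
haplotype structure.

## The founder-haplotype HMM

The hidden state of an individual at a site is the ordered founder pair
`(k1, k2)`; transitions factorize over the two haplotypes, each switching
with fixed probability `rho` (uniform destination). Founder `k` carries the
alternate allele at site `j` with probability `pi[k, j]`; the emission is
the read likelihood marginalized over the pair of founder alleles. `pi` is
estimated by EM; `rho` is a fixed user parameter (there is no genetic map
for synthetic data, and freezing `rho` stabilizes EM at desk scale). All
chain passes rescale per site and accumulate logs, so stretches of zero
coverage cannot underflow; the recursions are vectorized across individuals
with the `K^2 x K^2` pair transition applied as a single matrix product.

Initialization matters more than iteration count. The EM surface has a
symmetric saddle at which every founder equals the population frequency;
starts near it (the baseline frequency plus small jitter) differentiate
founders extremely slowly and can stall hundreds of log-likelihood units
below the optimum. The default start therefore runs a seeded k-means on the
baseline dosage matrix and uses the cluster centers divided by two as
founder rows: at strong LD individuals cluster by founder pair, so the
centers straddle the founder space and EM converges quickly. The jittered
start remains available (`init = "jitter"`) and is used automatically when
there are too few individuals to cluster; `n_restarts` runs independently
seeded fits and keeps the best final log-likelihood. Posterior genotype
probabilities combine the state posteriors with the per-state genotype
distribution conditioned on the site's reads; hard calls break argmax ties
toward the smaller genotype.

# Imputation metrics

Genotypic concordance is the proportion of hard calls equal to truth.
Dosage r-squared is computed *per site* across individuals and then
averaged unweighted over sites; sites monomorphic in either vector are
excluded from r-squared (Pearson is undefined) but kept in concordance.
Per-site aggregation is the only choice under which accuracy can be
resolved within minor-allele-frequency bins, which is how the MAF
stratification reports it: 15 bins with edges at 0.001, 0.002, 0.005,
0.01, 0.02, 0.05 and then steps of 0.05 up to 0.5, half-open on the left
(a MAF of exactly 0.01 falls in the (0.005, 0.01] bin). MAF is
`min(p, 1-p)` of the truth alternate frequency, snapped to 10 decimals so
that `1 - 0.7` lands on the 0.3 edge rather than a floating-point hair
above it.

# Relationship matrices

Site QC keeps sites with MAF >= 0.01 (inclusive) and a Hardy-Weinberg
1-df chi-square p-value strictly above 1e-6. The chi-square test was chosen
over an exact test because it is closed-form and hand-checkable; at desk
sample sizes the difference only matters in bins the MAF filter removes
anyway. LD pruning is windowed and greedy (window 50 sites, step 5): while
any within-window pair exceeds the r-squared ceiling, the lower-MAF member
of the currently worst pair is removed (ties: larger index), which makes
the result deterministic given input order.

The genotype-based matrix is VanRaden's first form,
`G(g) = W W' / sum_j 2 p_j (1-p_j)` with `w_ij = m_ij - 2 p_j`; `p_j` is
the alternate-allele frequency even above 0.5 (centering makes `G`
invariant to per-site allele flips; only the denominator is affected, and
only marginally). The dosage-based matrix `G(d) = D D' / s_d` centers each
dosage column and divides by the sum of population (denominator-n) column
variances, which forces `trace(G(d)) = n` exactly — a convenient contract
that the tests assert. The pedigree matrix uses the tabular method after a
topological sort; cycles are an error. Matrices that are numerically
non-positive-definite (near-duplicate individuals) can be stabilized by a
logged 1e-6 diagonal jitter before REML.

# GBLUP and AI-REML

The mixed model is `y = Xb + Zu + e` with `u ~ N(0, G sigma_a^2)` for one
trait and `[u1; u2] ~ N(0, G (x) M)`, `[e1; e2] ~ N(0, I (x) R)` for two,
where `M` and `R` are the 2x2 genetic and residual (co)variance matrices.
Fixed-effect design matrices are built per trait from formulas; year-season
enters as a crossed factor with the reference level dropped, and age as a
centered covariate. A rank-deficient design is an error that names the
confounded columns rather than a silent drop.

REML maximization uses average-information updates: the AI matrix
`0.5 y' P V_i P V_j P y` approximates the expected Hessian and doubles as
the asymptotic covariance of the estimates at convergence (reported
standard errors are square roots of its inverse's diagonal). A proposed AI
step is accepted only if it stays in the parameter space (variances floored
at 1e-8 of the phenotypic variance, covariances bounded by their
Cauchy-Schwarz limits) and does not decrease the restricted likelihood;
otherwise the step is halved up to 30 times, and failing that an exact
EM-REML update is taken (for the complete-record engine the textbook
`M - M S_M M / n` form; for the general engine a damped gradient step).
Accepted iterations therefore never decrease the likelihood. Convergence is
declared when the likelihood improves by less than `tol` (default 1e-8).
Initialization is half the phenotypic variance for each variance component
and half the Cauchy-Schwarz bound, signed by the sample trait correlation,
for covariances.

Two computational engines produce identical results (tested to 1e-6) but
scale differently. When every phenotyped individual has a record on every
modelled trait, rotating by the eigenvectors of `G` block-diagonalizes the
covariance into n independent `t x t` blocks `lam_i M + R`, making every
REML quantity O(n) per iteration after one decomposition; `grm_eigen`
precomputes the decomposition for reuse across many fits of the same
matrix. Arbitrary missing-record patterns fall back to a dense-V engine,
quadratic in the record count, in which the residual structure is
per-record within a trait and couples the two traits only through records
of the same individual — precisely what joint masking in cross-validation
requires. Parameters whose covariance structure vanishes from the data
(e.g. a trait with no records) are frozen rather than estimated, so a
two-trait fit with the second trait absent reproduces the single-trait fit
exactly.

Breeding values are predicted at the estimates as
`u_hat = Cov(u, y) V^{-1} (y - X b_hat)` over all individuals in `G`,
including unphenotyped ones; `predict(fit, masked_ids = ...)` re-solves
with the masked individuals' records removed while keeping them in `G`.

# Cross-validation

`make_folds` partitions the phenotyped individuals uniformly at random into
folds whose sizes differ by at most one. Corrected phenotypes are the
observed values minus the fixed-effect solutions of the same mixed model
fitted with the pedigree relationship matrix in place of `G` (identity for
simulated populations, which are founder mosaics without a pedigree);
random effects are not subtracted. For each fold the validation
individuals' phenotypes are withheld — both traits jointly in the two-trait
model — their GEBVs predicted, and the fold scored by the Pearson
correlation of corrected phenotypes with GEBVs (accuracy) and the
least-squares slope of corrected phenotypes on GEBVs, reported as bias
`1 - slope`. The slope direction follows the model-based definition of
dispersion bias (corrected phenotype regressed on GEBV); the reversed
regression is a distinct quantity and is not computed. Variance components
are estimated once on the full data and reused across folds — the standard
workflow, 12 times cheaper — with `reestimate = TRUE` available to re-fit
per training fold; fold means and empirical standard errors
(SD across folds / sqrt(n_folds)) are reported, with pooled-validation
metrics available by flag.

# Problem sizes and runtime choices

The package's own test and acceptance runs use: the reference imputation
operating point at 400 individuals, 200 sites, K = 8, 1x depth over 3-5
seeds (~1 minute per seed, dominated by EM); two-trait REML recovery at
n = 2000 over 20 phenotype replicates sharing one relationship matrix and
its eigendecomposition; G-matrix contracts at 500 x 2000; and
cross-validation comparisons at n = 600 with 12 folds over 5 seeds. These
sizes keep each property readable in minutes on one core while staying in
the asymptotic regime the properties describe.

# What passing tests do and do not show

The generator is model-matched: the HMM fits data produced by its own model
class. Passing the imputation bounds therefore demonstrates the
correctness and efficiency of the inference machinery — not that real
livestock or human lcWGS data would reach the same numbers, since real
data add site-discovery error, mapping artifacts, depth autocorrelation,
population structure beyond K founders, and reference-panel-free estimation
of a genuinely unknown K. Likewise the CV comparisons establish the
qualitative directions (two-trait GBLUP helps the lower-heritability trait
under strong genetic correlation; accuracy rises with heritability and
depth), not the absolute accuracies of any particular real population.

# Known limitations

- `rho` is fixed, not estimated, and shared across intervals; there is no
  genetic map, no per-interval recombination, and no estimation of K.
- The two-trait REML engine supports at most two traits; no dominance or
  epistatic components; no single-step blending of pedigree and genomic
  information.
- The pedigree module implements the plain tabular method without inbred
  founders or metafounders.
- VCF output is written directly (GT/DS/GP with fixed precision); only
  biallelic SNPs are supported end to end.
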