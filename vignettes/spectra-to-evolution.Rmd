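---
title: "From leaf spectra to evolutionary inference: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From leaf spectra to evolutionary inference: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectevol)
```

This vignette documents the statistical models behind each stage of the
package, the tunable parameters that matter, the numerical choices made where
conventions diverge, and what the synthetic-data generators do and do not
emulate. It states no empirical result beyond what the test suite and
`scripts/acceptance.R` themselves compute.

## Spectral preprocessing

**Splice correction.** Field spectroradiometers stitch separate detectors at
roughly 990 and 1900 nm, leaving small multiplicative steps. `splice_correct()`
rescales each downstream segment so that its first band matches the linear
extrapolation of the last two upstream bands. We chose extrapolation-ratio
matching over matching the neighbouring band values directly because the
latter would force a locally flat spectrum at the joint; extrapolation
preserves the local slope and inverts an injected multiplicative step exactly
whenever the spectrum is locally linear at the joint, which reflectance
spectra are at 3 nm resolution.

**Resampling.** Linear interpolation onto an arithmetic grid (default 3 nm)
covering the input range. Nothing fancier is warranted: the downstream
wavelet transform is itself a smoother.

**Continuous wavelet transform.** Each spectrum is convolved with a
Mexican-hat (second derivative of Gaussian) kernel at dyadic scales
$2^2, 2^4, 2^6$ bands; the three coefficient layers are summed bandwise. Two
conventions had to be fixed where common practice varies:

- *Normalization*: each discrete kernel is forced to exact zero mean and unit
  L2 norm, so coefficient magnitudes are comparable across scales before
  summation. (With L1 normalization the coarse scale would dominate the sum.)
- *Edges*: reflect padding, which avoids the spurious edge extrema produced
  by zero padding on spectra whose baseline is far from zero. Bands below
  400 nm and above 2450 nm are trimmed after the transform — trimming last
  means the retained bands are computed from the full support rather than
  from an already-truncated signal, which is the conservative ordering when
  the discarded bands are noise-dominated rather than invalid.

The transform is linear and annihilates constants, and a Gaussian absorption
dip produces a summed-coefficient extremum at its centre; all three
properties are asserted to 1e-9 in the tests.

**Regions and indices.** VIS = [400, 700), NIR = [700, 1200),
SWIR = [1200, 2500] nm, a partition of the grid. Vegetation indices
(CI = R750/R710, NDWI, ARI) use nearest-band lookup with a tolerance of half
a grid step, because a resampled grid need not contain, say, 835 nm exactly.

## PLSR, PLS-DA and VIP

`fit_plsr()` implements NIPALS partial least squares: sequential latent
components maximizing covariance between the deflated band matrix and the
target. Bands are centred but, by default, not scaled to unit variance —
wavelet coefficients share units across bands, and variance scaling would
inflate noise-dominated bands; `scale = TRUE` is available for heterogeneous
predictors. With as many components as the rank of a tall predictor matrix,
PLSR reproduces ordinary least squares, which the tests use as an oracle.

`select_ncomp()` uses k-fold cross-validated RMSEP with the one-standard-error
rule: the smallest component count whose mean RMSEP lies within one SE of the
global minimum. The rule collapses to a single component for pure-noise
targets, providing a guard against overfitting that a bare minimum-RMSEP rule
lacks.

VIP scores follow
$\mathrm{VIP}_j = \sqrt{p \sum_a \mathrm{SSY}_a w_{ja}^2 / \sum_a \mathrm{SSY}_a}$
with unit-norm component weights, so $\sum_j \mathrm{VIP}_j^2 = p$ exactly.
Band selection uses the conventional two-tier rule: VIP > 0.8, extended by
bands with VIP ≥ 0.4 once any band passes the strict tier.

`fit_plsda()` one-hot encodes classes and, per iteration (default 50),
resamples every class with replacement down to the minimum class size. We
interpreted "bootstrap to control sample size" as per-class balanced
resampling because it simultaneously equalizes class priors and propagates
sampling variability into the aggregated confusion matrix, matching
caret-style resampling workflows. Classes below 20 samples trigger a warning
rather than an error. Argmax ties break to the lowest class index — a
documented, deterministic choice. Confusion matrices have predicted classes
as rows and observed classes as columns; column percentages therefore give
per-class recall on the diagonal.

## Weir–Cockerham F_ST and AMOVA

`wc_theta()` computes the 1984 variance-components estimator, summed over
alleles and loci before taking the ratio (a "ratio of sums", not a mean of
ratios). Missing genotypes are handled by per-locus complete case within the
compared groups. Negative estimates are reported as computed — truncation
would bias bootstrap distributions. Confidence intervals resample loci with
replacement (percentile method), which treats loci as the exchangeable unit —
the standard choice for a genome-wide parameter estimated from a handful of
microsatellites.

`amova()` decomposes allele-indicator variance across four nested levels with
individuals contributing two gene copies. Because every individual carries
exactly two copies, the copy-level coefficients are exact; the
population- and species-level coefficients use the standard unbalanced-design
sums-of-squares formulas per locus (each locus may have its own missingness
pattern), and components are summed across loci. Components are truncated at
zero for the percentage decomposition only. Permutation tests shuffle the
exchangeable unit for each level: populations among species, individuals
among populations within species, and gene copies among individuals within
populations. The package default is 999 permutations; the test suite and
acceptance script use 49–99 because the AMOVA permutation loop is the most
expensive operation in the package and the tests only require the P-values
to be well-defined, not maximally resolved.

## P_ST–F_ST

The phenotypic analogue of Q_ST is
$P_{ST} = \frac{(c/h^2)\,\sigma^2_B}{(c/h^2)\,\sigma^2_B + 2\sigma^2_W}$,
where $c/h^2$ — the proportion of between-group variance that is
additive-genetic, scaled by heritability — is never estimated, only swept.
Variance components come from the one-way random-effects method of moments
with the standard unbalanced coefficient $n_0$; negative between-group
estimates are truncated at zero for the statistic but retained in
diagnostics.

Choices made where the convention is unsettled:

- *Ratio grid*: 40 log-spaced points on [0.05, 2], always containing the
  reporting anchors 0.25, 0.5, 0.75. The anchors are where decisions are
  reported; the grid exists to locate the critical ratio.
- *Bootstrap unit*: individuals within groups, because the compared groups
  (species, genetic clusters) are fixed entities, not samples from a
  population of groups. Percentile intervals are used throughout; a normal
  approximation would misbehave near the [0, 1] boundary where P_ST lives.
- *Decision rule*: a pair/trait is flagged at a given $c/h^2$ when the lower
  95% P_ST limit exceeds the upper 95% F_ST limit; the critical ratio is the
  smallest grid value at which this holds. Flagging at 0.25 is therefore the
  most conservative claim, and the decision flags are monotone in the anchor
  by construction.

## IBD vs IBE variance partitioning

Redundancy analysis and its partial form are delegated to vegan; the package
contributes the partitioning contract: with environmental block $E$ and
spatial block $G$,
$a = R^2_{adj}(E{+}G) - R^2_{adj}(G)$ (isolation-by-environment),
$c = R^2_{adj}(E{+}G) - R^2_{adj}(E)$ (isolation-by-distance),
$b$ the joint remainder, and the Ezekiel adjustment throughout. Negative
adjusted fractions can and do occur; they are reported as-is and flagged,
not clipped, because clipping would destroy the closure identity
$a + b + c + \text{unexplained} = 1$ that the tests assert to 1e-6.
Significance of $a$ and $c$ uses residual permutation under the reduced
model (vegan's `anova.cca`), whose null P-values the acceptance suite checks
for uniformity.

Spatial predictors default to centred longitude and latitude plus their
squares and interaction (five columns) — enough to absorb smooth large-scale
gradients without the model-selection machinery of Moran eigenvector maps,
which would be the natural extension for fine-scale spatial structure.
Predictor screening offers both iterative VIF filtering (default threshold 5,
dropping the worst offender each round, ties to the earliest column) and
greedy |r| ≤ 0.60 correlation filtering, which is order-dependent by
construction and documented as such. Genetic predictor blocks pass through
the same interface; the partitioning is label-agnostic.

## Phylogenetic signal and PGLS

Blomberg's K is computed in closed form from the Brownian covariance matrix
(shared branch lengths): the ratio of the ordinary to the
covariance-weighted mean squared error around the phylogenetically weighted
mean, scaled by its Brownian expectation. K is scale- and location-invariant.
Two nulls are provided: tip-swap permutations (default 999 plus the observed,
matching the usual permutation P-value construction) and Brownian simulations
(default 1000) rescaled to the observed tip variance so the envelope is
scale-free. The white-noise P-value tests whether any signal is present; the
Brownian envelope tests whether the observed K is *less* structured than
Brownian expectation. The spectrum-wide profile applies this per band to
population means and annotates each band with its region; either
wavelet-coefficient or resampled-reflectance bands may be profiled — both are
supported and the choice is the caller's, since band-level signal can differ
between the two representations.

PGLS solves generalized least squares with the Brownian covariance directly
(no Pagel's λ optimization — the strict-Brownian model keeps the estimator
closed-form and matches the K machinery's assumptions). On a star phylogeny
the covariance is proportional to the identity and PGLS reduces exactly to
OLS, which the tests assert to 1e-9. An optional measurement-error extension
(inflating the covariance diagonal with squared within-tip standard errors)
was considered and deliberately left out of the default path: population
means enter with very unequal per-tip sample sizes, and silently mixing
sampling error into the evolutionary covariance changes the estimand; the
per-tip standard errors are retained by `population_means()` so callers can
weight explicitly.

## The synthetic-data generators

The generators exist so that every estimator has a recovery test with known
truth and no downloads. Their defaults describe a small multi-species
sampling design: 4 groups × 30 diploids, 20 microsatellite-like loci with 8
alleles, an among-population F_ST target of 0.15, two archetype traits with
group-specific means, Gaussian absorption features on a sigmoidal reflectance
baseline with noise SD 0.003 reflectance units, and IBE/IBD environment
shares of 0.4/0.1.

- *Genotypes* use the Balding–Nichols construction (population frequencies
  Dirichlet-distributed around ancestral frequencies with concentration
  $(1-F)/F$) because it gives an analytic differentiation target; a
  coalescent simulator would add realism the estimators never see.
- *Spectra* are a smooth baseline minus one Gaussian dip per (trait, feature)
  pair, depth proportional to the trait value, clipped to (0.001, 0.999).
  This makes PLSR recoverability and VIP localization analytically
  predictable. It deliberately does **not** emulate radiative-transfer
  optics, scattering, or water-band saturation: passing recovery tests shows
  the estimators work, not that real dried-leaf spectra carry the traits.
- *Environments* are a weighted sum of a population-level niche effect, a
  latitudinal gradient, and noise, with the niche effect decorrelated from
  both coordinate axes at the group level so the IBE and IBD shares are
  separately identifiable; the realized shares and the underlying components
  are emitted as ground truth.
- *Phylogenies* are unit-rate Yule trees; Brownian traits accumulate
  independent Gaussian increments along edges, so tip covariance equals the
  shared-branch-length matrix by construction.

A single seed fans out into named per-generator substreams in a documented
order (`seed_streams()`), so adding a generator never perturbs the draws of
existing ones, and identical configurations are bit-reproducible.

## Problem sizes and runtime

The test-suite and acceptance-script problem sizes are the package's chosen
desk-scale study conditions: 50 replicate genotype datasets per F_ST target
(4 populations × 30 diploids × 20 loci), 100 datasets for CI coverage and for
each P_ST decision rate, n = 200 spectra for PLSR recovery, n = 300 for the
IBE/IBD recovery, 500 Brownian simulations on a 50-tip tree for the K
calibration, and 200 simulations for PGLS slope recovery. Bootstrap and
permutation counts in tests (100–500) are smaller than the package defaults
(999–1000), which only widens Monte-Carlo error on the checked rates.

## Known limitations

- The splice correction assumes a multiplicative detector mismatch; additive
  offsets would need a different model.
- AMOVA's exact invariance to duplicating individuals holds only
  asymptotically, because the mean squares carry finite-sample degrees-of-
  freedom corrections.
- PLS-DA class scores are not calibrated probabilities; the argmax rule is a
  classifier, not a posterior.
- The P_ST machinery never separates $c$ from $h^2$; conclusions are
  conditional on the swept ratio, which is the honest limit of the method.
- Clustering itself (admixture inference, spatially explicit clustering) is
  out of scope: the package consumes Q-matrices and log-likelihood tables
  produced by external tools.
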