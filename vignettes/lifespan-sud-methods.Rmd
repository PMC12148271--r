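---
title: "Methods: lifespan normative modeling of brain-volume differences in substance use disorder"
author: "lifespanSUD maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lifespan normative modeling of SUD brain-volume differences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lifespanSUD)
```

# The scientific problem

Substance use disorder (SUD) is associated with regional grey-matter-volume
(GMV) differences whose sign and size change over the lifespan: some
addiction-circuit regions differ most in adolescence and converge by the
mid-20s, some show a transient mid-life divergence, and some diverge
progressively after ~45y. Detecting these patterns across pooled population
cohorts requires (i) harmonizing scans across scanners and studies,
(ii) converting raw volumes into age- and sex-specific centiles under a
normative model of healthy development, (iii) comparing group trajectories
on a fine age grid with multiplicity control, and (iv) relating the
resulting differential maps to behavior, cognitive-term atlases and
genetics. `lifespanSUD` implements this pipeline end to end, together with
a synthetic multi-cohort generator whose ground truth makes every stage
testable without access to protected cohort data.

# The normative model

Regional volumes are strictly positive and right-skewed, so healthy-control
volumes are modeled with a generalized gamma distribution in the
location-scale-shape convention: with location $\mu > 0$ (mm^3), relative
dispersion $\sigma > 0$ and power shape $\nu$, define
$\theta = 1/(\sigma^2\nu^2)$ and $z = (y/\mu)^\nu$; then $\theta z$ is
Gamma($\theta$) distributed (upper tail for $\nu < 0$). Two identities pin
the convention down: $\sigma = 1, \nu = 1$ gives the exponential with mean
$\mu$, and $\nu \to 0$ gives the lognormal with median $\mu$. Numerically
the lognormal form is used when $|\nu| < 10^{-4}$; for larger $\theta$ the
gamma form is stable. `ggQuantile()` inverts `ggCdf()` exactly through the
gamma quantile function. (The Prentice parameterization used by survival
packages maps onto this one through $Q = \sigma\nu$.)

Covariates enter through

$$\log \mu = \mathrm{FP}_{m}(a)\,\beta + \beta_s\,\mathrm{sex}
  + \beta_h\,\mathrm{hand}\;[+\,\text{study offsets}],\qquad
  \log \sigma = \mathrm{FP}_{s}(a)\,\gamma,$$

with $\nu$ constant. $\mathrm{FP}_d(a)$ is a degree-$d$ fractional
polynomial of $x = a/10$ with powers from
$\{-2, -1, -0.5, 0, 0.5, 1, 2, 3\}$ in the Royston–Altman convention
(power 0 is $\log x$; a repeated power multiplies by $\log x$). The shape
is modeled as constant because the mean and dispersion carry the age
structure; an age-varying shape is very weakly identified at realistic
dispersions (about 10–12% of the median) and adds nothing to centile
calibration. The dispersion basis is searched independently of the
location basis; nothing forces the two trends to share knots or powers,
and coupling them would only constrain the search.

## Model selection

Candidate models differ in location degree (1–3), dispersion degree (1–3)
and study-offset inclusion; the model minimizing
$\mathrm{BIC} = -2\ell + k\log n$ under the full generalized-gamma
likelihood is returned, and the complete candidate log is stored in the
fitted object so `BIC(selected) <= BIC(candidate)` is assertable.

Power multisets are pre-screened per degree by least squares on the log
volumes (for $\mu$) and on log absolute residuals (for $\sigma$). At
realistic noise, competing power sets of the same degree fit almost
identically (differences of a fraction of a percent of the residual sum of
squares), so the degree comparison carries the top three screened power
sets per degree rather than a single noisy pick; a full generalized-gamma
maximization over all 164 power multisets per degree would cost three
orders of magnitude more for no inferential gain. The search is staged —
dispersion degree and offset inclusion are fixed first with the location
basis held at its best max-degree pick, then the location degree is
compared — and the optimizer is BFGS on the unconstrained parameterization
(coefficients free, $\log\sigma$-coefficients and $\nu$ free), relative
tolerance $10^{-9}$, with up to two jittered restarts on non-convergence.

"Study-specific random effects" are implemented as per-study fixed offsets
on $\log\mu$ that enter the BIC penalty. A true mixed generalized-gamma
model would be substantially heavier; with a handful of studies, fixed
offsets estimate the same quantities and preserve the BIC-based inclusion
decision. This is a documented simplification, not an equivalence claim.

## Scanner harmonization and centiles

Scanner batches are adjusted with empirical-Bayes ComBat (`sva::ComBat`)
before normative fitting, protecting biological covariates through the
model matrix. ComBat's shrinkage is not an exact projection, so
re-applying it moves values by a small fraction (~0.1–1%) of the batch
effect removed; the test suite asserts this honest form of idempotence.
A batch with zero residual variance triggers mean-only adjustment.

Training sets are healthy-control and cross-sectional; multi-visit
participants contribute one visit sampled with probability proportional to
the reciprocal frequency of the visit's age bin (1y bins), which flattens
the pooled age distribution. Centiles are
$F_{GG}(y;\hat\mu,\hat\sigma,\hat\nu)$ clipped to
$[10^{-7}, 1-10^{-7}]$ before the probit transform so z-equivalents stay
finite; scores outside the training age span are returned but flagged
`extrapolated`.

# Trajectory divergence

Group comparisons operate on covariate-adjusted volumes (sex, handedness,
study regressed out pooled across groups, residuals plus grand mean), not
on centiles — centiles feed the behavior and genetics arms. Each group's
trajectory is a least-squares natural cubic regression spline; "K = 3" is
read as three interior knots placed at the 25/50/75% age quantiles of the
group (equally spaced quantiles generalize to other K), with boundary
knots at the observed age range. Pointwise standard errors come from the
coefficient covariance, $se(a) = \sqrt{x(a)^\top V x(a)}$.

Both trajectories are evaluated on the 8.00–70.00y grid in steps of 0.05y
(1241 points); $z(a) = (m_{SUD} - m_{HC})/\sqrt{se_{SUD}^2 + se_{HC}^2}$
with a two-sided normal p-value. Benjamini–Hochberg FDR is applied across
the grid points within each ROI — the grid points of one region are the
multiplicity family — and significant age windows are maximal runs of
$q < 0.05$, reported at grid resolution without interpolation. Grid points
where either trajectory extrapolates beyond its group's observed ages are
excluded from window calling. Substance-specific reruns
(alcohol/tobacco/marijuana/drug) go through the identical code path via a
`subgroup` filter on the group label.

The continuous significance curve is a cubic smoothing spline through the
signed $-\log_{10} q(a)\,\mathrm{sign}(z(a))$ values, with level crossings
at $-\log_{10} 0.05$ reported as window edges; this is an interpretive
summary, and window calling never depends on it.

Validation machinery: per-participant longitudinal change rates
(first-to-last volume difference per year, optionally as percent of
baseline) regressed on group, baseline age and sex; inverse-variance
pooling $\hat\beta = \sum w_i\beta_i/\sum w_i$, $w_i = se_i^{-2}$;
Spearman correlation of discovery and validation z-curves over their
overlapping age span (fewer than three overlapping grid points is reported
as missing, and full-range comparison is deliberately not attempted);
hierarchical clustering of ROI centile patterns with correlation distance
and average linkage.

# Behavior

Instrument scores are compared by covariate-adjusted linear models, with
Cohen's d defined as the adjusted group difference over the residual SD
(adjusted models are used uniformly; the raw two-sample form is the
special case with no covariates). Severe class imbalance is handled by
subsampling controls 1:1 with cases `R` times (default 1000) and reporting
the median effect; with an already balanced design and R = 1 this
reproduces the plain estimate exactly.

Common rule-breaking and impulsivity factors are extracted per study block
by principal-axis factoring of the instrument correlation matrix, the
eigenvalue-above-1 retention rule (with a machine-precision guard so an
exactly spherical correlation matrix retains nothing), varimax rotation,
and regression-method scores standardized to unit variance. The sign
convention fixes the maximum-loading instrument positive, and factors are
labeled by the construct of their maximum-loading instrument.
Brain–behavior associations are Pearson correlations between factor scores
and ROI centiles, optionally partial with respect to the other factor,
with BH-FDR across ROIs; adolescent-study effects are pooled by Fisher-z
inverse-variance meta-analysis with weights $n - 3$.

# Atlas association

Cognitive-term maps (terms x parcels) are factor-analyzed on the term
correlation matrix over parcels with varimax rotation; factors explaining
more than 1% of total variance are retained. Per factor, terms are kept
only when their absolute loading exceeds 0.2 AND reaches the factor-wise
median absolute loading; absolute rather than signed loadings are used for
the percentile filter because the filter targets strength of association,
not direction. A factor whose retained-term mask empties is dropped with a
warning. Factor-level brain maps are regression scores computed from the
retained loadings (ridge-stabilized when the correlation matrix is
singular).

Associations between factor maps and the age-resolved differential
z-maps (0.5y steps, 125 ages) use univariate $R^2$ with a spin-permutation
null: uniform random 3D rotations (orthogonalized Gaussian triples,
determinant +1) rotate the parcel centroids on the unit sphere, each
parcel takes the factor value of its nearest original centroid (duplicates
allowed — the spun map is a draw with replacement from the original value
multiset), and the one-sided p-value uses the +1 correction,
$p = (1 + \#\{R^2_{null} \ge R^2_{obs}\})/(1 + n_{spin})$. One set of spins
is shared across ages within a factor so the profile has a common spatial
null, and BH-FDR is applied across ages within factor (the age grid of one
factor is the natural family for the profile; the per-region family used
for trajectory testing does not apply to a map-level statistic). Parcels
without spherical coordinates would require a value-permutation null;
the synthetic atlas always has coordinates, so this path is not exercised
here. Bespoke autocorrelation-preserving surrogate nulls for
non-spherical data are out of scope.

# Genetics

Quality control drops samples with >10% missing dosages, then variants
with call rate <95%, MAF <1%, or 1-df Hardy-Weinberg chi-square p below
1e-10 on genotype counts. Longitudinal labels collapse to a binary
phenotype by strict majority: case iff SUD at more than half of the
visits (so a 1-of-2 participant is a control; "more than the average"
readings that include ties were considered and rejected for determinacy).

Association is a covariate-adjusted Wald test: logistic regression per
variant for the binary phenotype, and a vectorized linear regression
(covariates residualized once via QR) for continuous phenotypes.
Saddlepoint-corrected mixed-model machinery is intentionally not
reproduced; at synthetic scale with moderate case fractions the Wald
logistic test is calibrated, and the case-imbalance caveat applies to
rare-case designs only.

The wGMV brain score is $\sum_r w_r c_r$ over ROI centiles. The default
weights are the ROI-level SUD-HC differential z-statistics evaluated at a
reference age (`wgmvWeights()`); a GWAS-z weighting can be passed to
`computeWgmv()` directly instead. Both readings exist in the literature
this package models; the regional-differential reading is the default
because the score is then interpretable as a brain-pattern propensity
independent of the GWAS it feeds.

LD pruning is greedy windowed pairwise pruning (window 50kb, step 5
variants, r^2 threshold 0.1): within each window the worst pair above
threshold loses its lower-MAF member (tie: later position), and a final
exhaustive sweep guarantees no retained within-window pair violates the
threshold. The tie-breaks are fixed purely for determinism. Polygenic
scores align the effect allele against the variant map, flip swapped
alleles, drop unresolvable ones with a count, and mean-impute missing
dosages; genetic correlation is the standardized slope of the target on
the standardized PGS with covariates, reported with incremental $R^2$ and
an explicit `uncorrected = TRUE` flag (no measurement-error correction is
applied).

The conditional FDR is the pointwise empirical estimator
$\widehat{\mathrm{cFDR}}(p_1|p_2) = p_1\,\#\{P_2 \le p_2\}/\#\{P_1 \le
p_1, P_2 \le p_2\}$ evaluated at each variant's own pair and capped at 1;
no kernel smoothing or binning is applied, so the estimator is exactly
reproducible by direct counting (the test suite asserts equality against
an independent brute-force implementation). The conjunctional FDR is the
elementwise maximum of the two conditional directions, and significant
variants are clumped by distance into loci led by the smallest conjFDR.

# The synthetic generator

`simConfig()` bundles the generative truth; `generateCohort()` draws:

* **Cohorts.** Four studies with realistic age windows (9–11, 14–23,
  22–37, 45–70y), per-study scanner pools, configurable sizes.
* **Volumes.** 24 addiction-circuit ROIs (12 bilateral structures) from
  the generalized gamma with
  $\log\mu = \log m_0 + 0.12x - 0.022x^2$ ($x = a/10$; peak ~27y, ~30%
  decline to 70y), $\sigma$ declining mildly with age from 0.12,
  $\nu = 0.6$, a +8% male effect, small per-study offsets (SD 0.02 log
  units), and per-scanner multiplicative shift/scale batch effects
  (SD 0.03/0.05 on the log scale).
* **SUD offsets.** Each ROI belongs to one temporal class, offset in
  units of $\sigma(a)$: early $= A_e e^{-(a-8)/6}$ (gone by ~25y), mid
  $= A_m e^{-(a-45)^2/128}$ (bump at 45y), late $= A_l (a-45)_+/25$.
  Defaults $A_e = -0.35$, $A_m = +0.30$, $A_l = -0.45$ are plausible-size
  placeholders exposed in the configuration — the literature quantifies
  directions and timing, not amplitudes — and the mid-life sign is
  positive to emulate the salience-network enlargement pattern.
* **Labels.** SUD liability = 0.6 x genetic burden + 0.8 x latent
  impulsivity + an age-prevalence offset peaking at 25y, plus standard
  logistic noise; the label is liability > 0, which yields a prevalence
  rising to ~25% at the peak. `truePrevalence()` integrates the implied
  marginal curve for calibration tests. Substance sublabels are sampled
  for subgroup reruns.
* **Genotypes.** Two latent Gaussian AR(1) "haplotypes" per block
  (default 8 variants, rho 0.6) thresholded at each variant's MAF give
  Hardy-Weinberg dosages with tunable LD; blocks sit >50kb apart so the
  pruning window never straddles blocks. Eight SUD-causal and eight
  brain-causal variants (four shared) drive the standardized burden and a
  brain shift of 0.6 sigma per SD applied to all ROI log-volumes. The
  shared-locus effect sizes are configured so the cross-module chain has
  detectable signal, which is the generator's stated purpose.
* **Behavior.** Three rule-breaking and three impulsivity instruments per
  study block load 0.75 on their factor (0.1 cross), with an extra +0.4
  rule-breaking shift in SUD.
* **Atlas.** Fibonacci-lattice centroids on the unit sphere; spatial
  factor patterns are geodesic-Gaussian-smoothed noise, orthogonalized
  across factors (so recovery is identified up to rotation); term maps
  are loadings times patterns plus smoothed residual noise.
* **Follow-up.** Revisits scale the baseline volume by the true age trend
  times an extra configured decline for SUD (default -0.5%/yr) times
  lognormal noise, giving strongly correlated within-person measurements
  by construction.

Everything is bit-for-bit reproducible under the configuration seed, and
all latent truth is recorded in a manifest (flat TSV plus JSON sidecar).

What the generator does **not** emulate: realistic inter-ROI covariance
beyond the shared genetic shift, item-level questionnaire structure,
genotype imputation artifacts, population stratification, ascertainment
and attrition, or image-level artifacts. Passing tests therefore
demonstrate statistical correctness of the pipeline under its stated
generative model, not robustness to everything real cohort data contains.

# Problem sizes used by the tests and the acceptance script

The suite works at sizes where the targeted properties are measurable with
comfortable margins: normative recovery uses 20 replicates of n = 2000
healthy controls on one ROI (single cohort, batch effects off — the
recovery question is about the distributional model, harmonization is
tested separately); null divergence calibration uses 100 replicates at
n = 1000 per group and power uses 20 replicates at n = 3000 per group with
a rectangular 0.5 SD deficit at 40–50y; spin calibration uses 200
independent map pairs at 24 parcels and 1000 fresh spins each; the
genetics chain uses 20 replicates of n = 2500 participants x 400 variants,
and null GWAS calibration 5000 independent variants at n = 2000. These
are the package's chosen study conditions and are fixed in the test code.

# Known limitations

* Study effects are fixed offsets, not random effects; with many studies
  the BIC comparison would favor a genuine mixed model.
* The FP power screen is least-squares based; in principle a power set
  optimal under the generalized-gamma likelihood but not top-three under
  least squares could be missed.
* Natural-spline trajectories smear sharp temporal effects: a rectangular
  offset produces significance windows wider than the injected span
  (localized, but typically covering 2–4x the true window).
* The empirical pointwise cFDR is conservative at small variant counts
  and is not smoothed; a lookup-table estimator would pool information
  across variants.
* The spin null assumes complete spherical coordinates; subcortical
  parcels without coordinates would need a different surrogate null.
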