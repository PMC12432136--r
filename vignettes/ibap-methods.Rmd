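---
title: "Methods: normative deviation scoring and IBAP analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: normative deviation scoring and IBAP analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its statistical machinery:
the models, their assumptions, the tunable parameters, what the synthetic
generator does and does not emulate, and the numerical decisions taken
where the design was genuinely open.

## 1. The normative chart

Brain-chart frameworks model a morphometric measure as an age- and
sex-conditional distribution in a reference population and read off each
individual's percentile. Full lifespan charts use generalized-gamma GAMLSS
models over enormous reference samples; at desk scale the package uses a
deliberately simpler distributional family with the same downstream
contract (a CDF evaluation):

* sinh–arcsinh (SHASH): `X = mu(t) + sigma(t) * sinh(asinh(Z) + nu)`,
  `Z ~ N(0, 1)`. It is a genuine location–scale–skew family — `nu = 0`
  recovers the Gaussian, positive `nu` skews right — with closed-form CDF
  and quantile function, which is all that deviation scoring consumes.
* `t` is standardised `log(days since conception)`. One continuous axis
  serves both the neonatal regime (postmenstrual weeks, `days = 7·weeks`)
  and later life (`days = 280 + 365.25·years`, assuming a 40-week term
  gestation), avoiding unit clashes near birth.
* Per region and sex: `mu(t)` quadratic, `log sigma(t)` linear, `nu`
  constant. Fitting is numerical maximum likelihood (BFGS, three jittered
  restarts, OLS-based initialisation), on term-born subjects only.
  A region that fails to converge in either sex stratum is excluded: its
  scores are missing downstream and no subject can be extranormal there —
  the same contract as a missing published chart (the entorhinal
  surface-area situation).

**Predictive calibration.** The plug-in ML chart understates the spread of
a *new* observation: `sigma`-hat carries an `O(p/n)` downward df bias and
parameter uncertainty in `mu` and `nu` is not propagated. On held-out data
this deflates tail coverage by about one percentage point at
`n = 250`/stratum, which matters when the quantity of interest is the 5th/
95th-percentile exceedance. The fitted scale is therefore inflated by
`sqrt((n/(n - p)) · (1 + p_loc/n))` — the direct analogue of using
`s·sqrt(1 + h)` with `t`-quantiles for Gaussian prediction intervals. The
correction is derived, not tuned; the held-out calibration test measures
its effect.

**Study offsets.** A new study's location shift is the median term-born
residual on the measurement scale, pooled over regions — the robust
analogue of a random intercept of study. Preterm subjects never enter the
estimate, so the deviations of interest cannot be absorbed into the site
term. No scale offset is estimated (an intercept-only random effect); the
offset is exactly equivariant under constant shifts of a study's values.

**Scores and labels.** The deviation score is the model CDF value of the
offset-corrected observation — a percentile in (0, 1). (The plausible
alternative, an empirical percentile against the normative band, is not
implemented.) Thresholds are strict: `score < 0.05` infranormal,
`score > 0.95` supranormal, a score exactly at a threshold is normal —
"below"/"above" read strictly for determinism.

**Out-of-support ages** are tolerated up to 2% of the support width by
linear extension of the `mu` and `log sigma` curves at the boundary;
beyond that, scoring errors out naming the subject, rather than silently
extrapolating a polynomial.

## 2. Heterogeneity and consistency statistics

* **Group-average dysmaturation**: per region, OLS
  `value ~ group + age + sex`, BH-FDR across the 34 regions at 0.05. This
  is the classical average-difference analysis the individual-level
  machinery is contrasted against.
* **Overlap**: percentage of a group's subjects extranormal in a region
  (per direction). Subjects with a missing score in a region leave both
  numerator and denominator; regions with no scored subject drop out.
* **Similarity**: binarised profiles (extranormal = 1) cross-correlated
  with Spearman correlation; with midrank ties on binary data this equals
  the phi coefficient, and the tests verify equality with Pearson on the
  0/1 values. Profiles with zero variance (no extranormal region) have
  undefined correlations: they are excluded from per-subject means and
  reported, a choice the underlying publications leave open.
* **Extent consistency**: Spearman correlation of the extranormal count
  with gestational age, two-sided p via the t approximation, percentile
  bootstrap CI over subject resampling (B = 10,000, seeded), BH-FDR across
  whatever directions/strata were tested in one call (the per-analysis
  adjustment family).
* **Location consistency**: subject–region pairs extranormal at at least
  one of two timepoints; the persistence fraction is the share maintained
  in the same direction (an infra→supra flip is *not* maintained — "a
  similar deviation in that same region" implies direction). Per-region
  ICC(3,1) — two-way mixed, single measurement, consistency:
  `(MS_R − MS_E)/(MS_R + (k−1)·MS_E)`, `k = 2`, computed from the ANOVA
  decomposition and checked against an independent `aov()` oracle. The
  default uses all subjects with both timepoints; the extranormal-selected
  subset and a binary-agreement variant are exposed but non-default.
  Regions need at least 5 complete subjects to report.

## 3. Cell-type maps and spatial nulls

Marker-gene aggregation starts from a gene × region matrix (the donor-level
microarray preprocessing that produces such a matrix — probe aggregation,
intensity filtering, distance thresholds, donor normalisation — is out of
scope). Genes are normalised across regions with the scaled robust sigmoid
`1/(1 + exp(−(x − median)/(IQR/1.35)))` then min–max rescaled to [0, 1];
1.35 is the normal-consistent IQR→SD factor. A cell-type map is the
unweighted mean of its marker genes' normalised vectors; whether to rescale
*after* aggregation is unstated in the source methods, so rescaling happens
per gene only.

Spin tests preserve spatial autocorrelation while breaking alignment: all
parcel centroids are rotated by one Haar-uniform rotation (QR of a Gaussian
3×3, determinant corrected to +1) and mapped back to parcels. The package
solves a minimum-total-chord-distance one-to-one assignment (an O(n³)
Hungarian solver, tested against brute-force enumeration), so every spun
map is a true permutation and rank correlations stay well-defined;
nearest-centroid-with-replacement is available for parity with common
toolchains but is not a permutation. Bilateral maps are spun on
single-hemisphere centroids (the hemisphere-averaged value sits at one
centroid); the default synthetic geometry is a seeded Fibonacci lattice on
a hemisphere, and real centroid tables can be supplied as CSV. The p-value
is two-sided with +1 smoothing, `(1 + #{|rho_null| ≥ |rho_obs|})/(1 + N)`,
so it can never be 0; one shared schedule serves all subjects and cell
types in an analysis, keeping subject results comparable. Subject-level
correlations use continuous deviation scores, not binary labels.

## 4. Plasticity and outcomes

PC1 of the column-centred (unscaled — scores already share the (0, 1)
scale) subjects × regions score matrix summarises global deviation; the
loading sign is fixed so the mean loading is positive, making results
backend-independent. Environment/behaviour associations are Spearman
correlations with bootstrap CIs and per-call BH-FDR. The moderation model
is OLS `PC1 ~ GA + SES + GA:SES` with raw (uncentred) predictors, SES on
the ordinal code low = 1, middle = 2, high = 3, a one-sided interaction
test (directional hypothesis), conditional GA effects
`beta_GA + code·beta_int` at the three observed levels, and a seeded
percentile bootstrap (B = 5,000) for the interaction. Because the
published analysis reports conditional effects without stating its numeric
coding, only sign-and-ordering statements are coding-invariant: with this
coding, "the GA effect weakens as SES improves" is a *negative* fitted
interaction, and the conditional effects order low > middle > high.

## 5. The synthetic world

The generator emulates the statistical structure the analyses assume, with
every parameter recorded for recovery testing:

* **Charts**: analytic SHASH charts per region/sex; adult cortical
  thickness levels 2.2–3.1 mm, `sigma` ≈ 0.10–0.14 mm, mild log-age
  thinning, small per-region skew; per-study additive offsets (mm).
* **Latent percentiles**: each subject × region observation has a latent
  standard-normal score composed of a stable per-subject *global factor*
  (variance share 0.15) and a regional component with within-subject
  correlation 0.9 across timepoints. Marginals stay exactly N(0, 1), so
  term scores are uniform and ~90% of scores sit inside (0.05, 0.95) when
  injection is disabled. The global factor models the strong shared
  component of real morphometric deviations and is what makes PC1 a
  global axis with one-signed loadings; 0.15 balances that against the
  moderation model's residual noise. The 0.9 within-subject stability
  mirrors the high longitudinal reliabilities reported for surface area.
* **Injection**: each preterm subject receives
  `K ~ Poisson(lambda0 + lambda1·max(0, 40 − GA))` target regions
  (defaults 0.5 + 0.8/week — roughly 8.5 expected extranormal regions at
  28–30 weeks, a handful near term), sampled without replacement with
  probability softmax(`tau`·map), `tau = 5`. The placement map is a
  GA-interpolated mixture of the latent cell-type maps:
  oligodendrocyte-weighted near term, sliding toward OPC / astrocyte /
  endothelial maps with every week of prematurity — the cell classes
  vulnerable to perinatal injury. Target CDF values are drawn uniformly
  from (0.95, 1) or (0, 0.05) via the chart's own quantile function, so
  injected regions are truly extranormal under the generating model;
  the direction mix is a parameter (default 0.8 supranormal, the
  neonatal-like thickness excess) because the source literature does not
  pin the joint direction distribution. At timepoint 2 each target is
  retained with probability `persistence_prob` (default 0.8, in the range
  of the published persistence fractions).
* **Cell maps and expression**: 8 latent maps are Gaussian-process draws
  on the unit sphere (Gaussian kernel on chord distance, length-scale 0.6
  — needed for spin tests to be non-trivial), orthogonalised across types
  (linear combinations of GP draws remain spatially smooth) so each
  type's alignment signal is identifiable rather than confounded by
  chance correlations between maps. Marker genes are latent map + iid
  noise.
* **Environment and cognition**: SES multinomial (0.3/0.4/0.3); the
  global deviation shift `delta = a·ses + b·ses·(40 − GA)` in
  within-region SD units, defaults `a = 0.03`, `b = 0.05`. The scale of
  `b` was set by a design-stage power analysis: percentile saturation
  means a much larger `b` *reverses* the fitted interaction (the
  low-GA/high-SES corner saturates near score 1), while a much smaller
  one is unidentifiable at n = 150; 0.05 also reproduces the
  published-scale spread of conditional effects. PIRI (0 good – 8 poor)
  is binomial with worse expectation at lower SES; cognition is
  `100 + 3·z(mean deviation score) + N(0, 10)`.

**What a green test does not establish.** The generator draws independent
subjects from the stated model: no scanner batch structure beyond an
additive site shift, no QC-driven missingness, no measurement error
distinct from the chart's `sigma`, no nonlinear lifespan trajectories
(ages sit in one adult window), no direction shifts across development,
and regional injection is conditionally independent given the placement
map. Recovery of a parameter here demonstrates the estimator and pipeline
are correct — not that real cohorts satisfy the model.

## 6. Numerical choices and degenerate inputs

* Scores are clamped to `[1e-12, 1 − 1e-12]`; CDF∘quantile round-trips to
  1e-8 across the fitted range.
* Ties: Spearman uses midranks everywhere; boundary scores (exactly 0.05
  or 0.95) are normal; p-values for Spearman use the t approximation
  (tie-safe, matching `cor.test(exact = FALSE)`).
* Degenerate inputs error loudly: empty sex strata, singular age designs,
  studies without term members, constant maps in spin tests, rank-0
  deviation matrices, single SES levels. Zero-variance similarity rows
  and empty GA bins are excluded with messages/warnings instead, since
  they occur in legitimate data.
* Seeds: every stochastic routine takes or derives an explicit seed;
  `run_pipeline` derives per-stage seeds from one master seed and records
  them with per-file checksums in the manifest, so a rerun is bit-exact.
* Persistence under the *fitted* chart is attenuated a few percent because
  tail draws near the 0.95 boundary can be relabelled by chart estimation
  error (the predictive inflation shifts the fitted 95th percentile
  slightly outward); the recovery test therefore scores the cohort under
  the generating chart, where the binomial oracle is exact, and leaves
  chart fidelity to the dedicated calibration criterion.

## 7. Known limitations

* The SHASH family has a fixed tail weight (no kurtosis parameter); heavy-
  tailed measures would need the four-parameter extension.
* The study offset is location-only; multiplicative scanner effects are
  assumed removed upstream (inputs are taken as harmonised).
* Only two-timepoint longitudinal designs; no growth-curve modelling of
  deviation trajectories, no within-subject chart terms.
* The spin test assumes parcel centroids summarise parcel geometry;
  vertex-level spinning and variogram-matching nulls are not implemented.
* Cell-type maps inherit every caveat of marker-set aggregation: marker
  expression is an indirect abundance proxy and the eight classes are a
  simplification of cortical cell diversity.
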