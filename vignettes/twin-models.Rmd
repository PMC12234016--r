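---
title: "Longitudinal twin models of stability and change: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal twin models of stability and change: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinstab)
```

## The classical twin design

A phenotype measured in monozygotic (MZ) and dizygotic (DZ) twin pairs can be
decomposed into additive genetic (A), dominance genetic (D), shared
environmental (C) and non-shared environmental (E) variance. Identification
comes from the kinship coefficients: the latent components correlate across
co-twins at 1 (MZ) versus 0.5 (DZ) for A, 1 versus 0.25 for D, 1 versus 1
for C, and 0 for E. C and D cannot be estimated jointly from twins reared
together, so the admissible families are ACE, ADE, AE, CE and E.

For a vector of phenotypes $y$ per twin (waves of a repeated measure, or
several traits), each component contributes a covariance matrix
$\Sigma_X = X X'$ built from a path matrix $X$. The model-implied twin-pair
covariance is

$$\Sigma_{zyg} = \begin{pmatrix} \Sigma_A+\Sigma_C+\Sigma_D+\Sigma_E &
k_A\Sigma_A + k_C\Sigma_C + k_D\Sigma_D \\ \cdot & \text{(sym.)}
\end{pmatrix},$$

with the kinship weights $k$ above. Means are constrained equal across twins
and zygosity groups in all biometric fits (free-means saturated models are
available as a diagnostic baseline).

Four structures for the path matrices are provided:

* **Univariate** (`build_univariate`): scalar paths per component; reported
  quantities are the standardized shares $a^2, c^2/d^2, e^2$.
* **Cholesky decomposition** (`build_cholesky`): lower-triangular $X$ per
  component across $W$ waves. Factor $k$ loads on waves $k..W$; off-diagonal
  paths quantify continuity (how much earlier genetic/environmental
  influences persist), diagonal paths quantify innovation.
* **Common pathway model** (`build_common_pathway`): all waves load on one
  latent stability factor, $y_w = \lambda_w L + s_w$. The latent variance is
  fixed to 1 and decomposed into component shares summing to one (the
  "latent heritability" is the latent A share); wave-specific residuals get
  their own A/E (or A/C/E, A/D/E) paths. The communality
  $\lambda_w^2/\mathrm{var}(y_w)$ is the share of wave-$w$ variance
  explained by the stable factor. Identification through the unit latent
  variance (rather than fixing one loading) was chosen because the
  quantities of interest are the latent component percentages themselves.
* **Correlated factors** (`build_correlated_factors`): each variable keeps
  its own component variances while component correlation matrices carry
  the etiological overlap; their entries are the genetic (rG) and
  environmental (rE) correlations.

## The FIML engine

All models share one two-group structured-covariance maximum-likelihood
core. Missing data are handled by full-information maximum likelihood: each
pair contributes minus twice the log multivariate-normal density of its
observed subvector. Pairs are grouped by missingness pattern, and each
pattern enters through its sufficient statistics (count, sum vector, raw
cross-product), so the cost of one likelihood evaluation is independent of
the number of pairs. With complete data this reduces exactly to the
sufficient-statistic form of the complete-data likelihood (verified to
1e-8 in the test suite).

Numerical choices, made once and stated here because the field's customary
tools leave them implicit:

* **Paths, not variances, are the free parameters.** Squaring inside the
  builders keeps every component covariance positive semi-definite without
  constrained optimization. Path signs are not identified; all reported
  quantities are squares or correlations.
* **Correlation matrices via spherical angles.** Correlation blocks (rG/rE,
  CFA factor correlations) are parameterized by angles of a unit-row
  triangular factor, guaranteeing unit diagonal and positive
  semi-definiteness throughout optimization; angle bounds keep correlations
  in (-1, 1).
* **Latent splits via angles** in $(0, \pi/2)$, so latent component shares
  are positive and sum to exactly 1.
* **Optimization**: `nlminb` quasi-Newton from 5 jittered starts by default
  (recovery suites use 1-2 starts with moment-based starting values, which
  the multimodality checks showed to be sufficient at those sample sizes);
  best -2LL wins, ties within 1e-6 to the first start. Starting values are
  data-driven: pooled means and within-twin covariances split by plausible
  component fractions.
* **Non-positive-definite proposals** return a large penalty (1e10) instead
  of an error, keeping the optimizer inside the feasible region.
* **Standard errors** come from the numerical Hessian of -2LL
  (covariance $2H^{-1}$); confidence intervals for derived quantities
  (shares, correlations, communalities) use the delta method by default,
  with profile-likelihood intervals available (`profile_ci`) since the two
  can differ near boundaries.
* **df and AIC**: df = observed data cells minus free parameters;
  AIC = -2LL + 2k. Model choice is by AIC with ties broken toward fewer
  parameters; chi-square LRTs are reported for declared nestings. When a
  variance component's truth is on the boundary (e.g. c2 = 0), the naive
  chi-square reference is conservative and AIC over-selects the richer
  family in roughly 8% of replicates per competing family; this behaviour
  is documented rather than corrected, and the selection-consistency
  property test reflects it (see Limitations).

## The synthetic-data generator

`simulate_twins` draws each component's factor scores with the exact
kinship correlation (co-twins share $\sqrt{k}$ of a common standard-normal
draw) and maps them through the same loading matrices the likelihood uses,
so the empirical cross-twin covariances converge to the model-implied ones
by construction — the simulator and the expected-covariance algebra share
one code path, and their agreement is checked at n = 50,000 pairs to 0.02.

The default truths (`default_sim_params`) encode the study conditions the
recovery suites target: a six-wave generalized-anxiety sum score in
2,200 MZ and 4,200 DZ young-adult pairs, with

* univariate additive share 0.39 (the lower end of the plausible 0.39-0.46
  single-wave band);
* a Cholesky truth whose first genetic factor explains 39% of wave-1
  variance and persists at 36% later, with a small (5%) genetic innovation
  at wave 2, a persistent 7-9% first environmental factor and otherwise
  time-specific E — genetic continuity, environmental change;
* a common-pathway truth with latent additive share 0.60 and communalities
  0.51-0.76 (largest at wave 2); residual wave variance is split 20/80
  between specific A and specific E, so single-wave heritabilities land
  near 0.40-0.50 and specific-E shares near 0.19-0.39;
* a bivariate correlated-factor truth with additive shares 0.43/0.33,
  rG = 0.90 and rE = 0.62 — strong genetic, moderate environmental overlap
  between the two symptom dimensions;
* a two-wave phenotypic-stability truth with implied cross-wave r = 0.76.

Skewness of raw sum scores is emulated by squaring shifted normals
(`params$skew_shift`), so the pipeline's square-root transform maps scores
back to approximate normality; this is a stand-in for the right-skew of
real symptom scores, not a claim about any cohort's distribution.
Missingness is MCAR at a per-cell rate, with pairs retained whenever at
least one twin has at least one observed wave; MAR mechanisms are out of
scope because FIML correctness under ignorable missingness is what the
suites exercise. Item-level data come from a two-factor model (six strong
items, three strong items, one weak item, factor correlation 0.6)
discretized to a right-skewed 0-4 Likert scale by fixed thresholds.

What the generator does **not** emulate: assortative mating, violations of
the equal-environments assumption, sex-limitation or age moderation,
MAR/MNAR missingness, and floor effects of true ordinal scales beyond the
threshold discretization. Passing recovery suites therefore demonstrates
correctness of the estimators under the stated model, not robustness to
those violations.

## The phenotypic stage

Descriptive statistics deliberately use simpler estimators than the model
stage: Pearson correlations on pairwise-complete observations with Fisher-z
intervals (FIML is reserved for model fitting). Longitudinal correlations
default to one randomly selected twin per pair — mirroring how the
factor-analysis stage removes relatedness — with a both-twins mode
available, since either convention is defensible for descriptive tables.
Cross-twin correlations use double entry (each pair in both orderings) so
they are invariant to twin labelling. No residualization for sex or age is
performed.

The EFA stage uses minimum-residual extraction (uniquenesses optimized,
loadings from the reduced correlation matrix's leading eigenvectors) with
oblique promax rotation; the factor count comes from parallel analysis
against mean eigenvalues of simulated independent data, corroborated by the
residual fit of each candidate count. Items are assigned to a factor when
they load above 0.3 and strictly higher than on any other factor; ties stay
unassigned. Pearson (not polychoric) correlations are used on the 0-4
items, consistent with treating sum scores as continuous elsewhere. The CFA
is fitted by the same FIML engine (factor variances fixed to 1, oblique
correlations free) with CFI/TLI/RMSEA/SRMR computed against the saturated
and independence baselines.

## Problem sizes

The recovery suites run 20 replicates per quantity at the study-scale
sample sizes above (50 replicates for the selection-consistency check,
which is cheap), with complete data in the study-scale runs; FIML under
missingness is exercised separately at smaller scale where the
missingness-pattern bookkeeping, not the sample size, dominates cost.
These sizes give Monte-Carlo standard errors of the reported means well
under one percentage point for the share-type quantities.

## Known limitations

* Ordinal liability-threshold models are not implemented; Likert items are
  treated as continuous, which attenuates correlations relative to the
  latent scale (visible in the item simulator's checks).
* AIC selection at boundary truths retains the richer family in roughly
  15% of AE-truth replicates (about 8% each for ACE and ADE); this matches
  the half-mixture distribution of the boundary likelihood-ratio statistic
  and is inherent to uncorrected AIC comparison, not an implementation
  artifact.
* Delta-method intervals can be poor for shares near 0 or 1; use
  `profile_ci` there.
* The correlated-factor model is implemented for a general number of
  variables, but the high-dimensional (all waves x dimensions) joint fit is
  slow; pairwise bivariate fits are the intended workhorse.
* No sex-limitation, age-moderation or definition-variable support.
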