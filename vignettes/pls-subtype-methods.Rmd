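---
title: "Multiclass intrinsic-subtype prediction by PLS regression: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiclass intrinsic-subtype prediction by PLS regression: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plsSubtype)
```

## The problem

Breast cancers fall into five "intrinsic" molecular subtypes — Basal-like,
HER2-enriched, Luminal-A, Luminal-B and Normal breast-like — defined by the
expression of the PAM50 signature genes.  The standard way to assign a new
tumour to a subtype is nearest-centroid single sample prediction (SSP): the
sample's expression profile is correlated against each subtype's mean profile
(centroid), and the best-correlated subtype wins.  SSP produces a hard label
but no statement of confidence.

`plsSubtype` implements an alternative: one binary classifier per subtype,
each built from partial least squares (PLS) latent factors and logistic
regression, combined into a single multiclass call with a reject option.
Each classifier reports a cross-validated predicted probability, so a call
carries its own confidence, ambiguous calls (two classifiers firing at once)
are visible, and samples that match no subtype are explicitly Unclassified
rather than force-assigned.  The package also ships the SSP comparator and
weighted-kappa agreement machinery used to compare the two approaches, and a
synthetic-cohort generator so the entire pipeline is testable without any
external microarray download.

## The PLS-regression classifier

### Latent gene components

For one subtype, let $X_0$ be the $n \times p$ matrix of centred and scaled
expression values of the classifier's gene panel (samples in rows) and $Y_0$
the centred/scaled binary membership indicator.  The number of predictors
exceeds what ordinary logistic regression can handle comfortably when genes
are strongly collinear, so the predictor space is first compressed into a
few orthogonal latent factors ("gene components") that maximize covariance
with the response.

Components are extracted by NIPALS with deflation.  For a single response
the inner iteration collapses to a closed form, per component $a$:

$$w_a = \frac{X'y}{\lVert X'y \rVert}, \qquad
  t_a = X w_a, \qquad
  p_a = \frac{X' t_a}{t_a' t_a}, \qquad
  c_a = \frac{y' t_a}{t_a' t_a},$$

after which $X \leftarrow X - t_a p_a'$ and $y \leftarrow y - t_a c_a$.
Weight vectors are normalized to unit length; successive score vectors are
orthogonal by construction.  Because signs of the weight vectors are
mathematically arbitrary, each $w_a$ is flipped so that its
largest-magnitude entry is positive — a convention, fixed here once, that
makes fits reproducible across runs and platforms.  New samples are
projected through the rotation $R = W (P'W)^{-1}$, which corrects the
weights for deflation so that projecting the training matrix reproduces the
training scores exactly.

Variance-explained fractions per component are computed from the deflation
sums of squares: component $a$ removes
$(t_a't_a)(p_a'p_a)$ from the predictor sum of squares and
$(t_a't_a)c_a^2$ from the response sum of squares.

### Choosing the number of components

The component count $k$ is selected by split-sample cross-validation.
Observations are assigned to folds systematically by input order
(observation $i$ to fold $(i-1) \bmod F + 1$, default $F = 7$, the
convention of the statistical software family in which this model-selection
recipe is standard).  For each fold, the PLS model is refit on the
remainder — without re-centring, since the data were centred once globally
— and held-out responses are predicted; $\mathrm{PRESS}(k)$ is the summed
squared cross-validated residual.

Rather than taking the $k$ with minimal PRESS outright, the final choice is
the *fewest* components whose residuals are statistically indistinguishable
from the minimal-PRESS candidate under van der Voet's randomization test:
with paired residuals $r_{i,k}$ and $r_{i,\mathrm{ref}}$ the statistic is
$C = \sum_i (r_{i,k}^2 - r_{i,\mathrm{ref}}^2)$, and its null distribution
is generated by independently negating each paired difference.  All $2^n$
sign patterns are enumerated when $n \le 20$; beyond that, Monte Carlo with
a caller-supplied seed (default 2000 draws, with add-one smoothing).  The
default significance level is $\alpha = 0.10$, a deliberately conservative
screen that accepts a smaller model only when the evidence against it is
weak; both $\alpha$ and the fold count are configurable.

### Logistic regression on the scores

With $k$ fixed, the subtype-membership probability is the binary logistic
model on the component scores:

$$\Pr(\text{subtype}) =
  \bigl(1 + e^{-(\beta_0 + \beta_1 x_1 + \cdots + \beta_k x_k)}\bigr)^{-1},$$

fit by iteratively reweighted least squares (`stats::glm`).  Because PLS
scores separate well-structured training data very effectively, perfect
separation is common rather than exotic; in that case the package refits
with a ridge-stabilised IRLS (penalty $10^{-6}$ on the coefficients),
keeping coefficients finite while leaving the decision boundary essentially
unchanged.  The fallback is reported via a message and recorded on the
model object.

Classifier performance is evaluated honestly by leave-one-out
cross-validation: for each sample, gene centring/scaling, the PLS fit and
the logistic fit are all recomputed on the other $n-1$ samples — so no
information from the held-out sample leaks through the standardization —
and the held-out probability is recorded.  The component count is *not*
re-selected per fold: $k$ is part of the model specification being
evaluated.  Reported metrics are accuracy, sensitivity and specificity at
the call threshold, the midrank (Mann–Whitney) AUC, and Nagelkerke's pseudo
$R^2$ (the "adjusted R-square" of the report tables; the literature this
family of reports descends from does not pin down a definition, and
Nagelkerke's is the conventional choice for logistic models).

### Assembling the five binary calls

Each of the five subtype classifiers produces a cross-validated
probability.  The multiclass call is then:

* **standard mode** — the sample is assigned to the subtype with the
  highest probability *provided* that probability exceeds 0.5 (strict
  inequality); if two or more classifiers exceed 0.5 the call is made but
  flagged **ambiguous**; if none does, the sample is **Unclassified**.
* **forced mode** — the argmax subtype is always called as long as the top
  probability exceeds 0.1; this mirrors the permissiveness of centroid SSP
  and nearly eliminates rejections.

The 0.5 threshold encodes an uninformative prior — an unprejudiced belief
in each binary classifier — and is deliberately stricter than SSP's
correlation floor of 0.1.  Exact probability ties are resolved by canonical
subtype order and flagged ambiguous; they cannot occur with
continuous-valued data but are pinned down so the behaviour is total.

## The SSP comparator

Centroids are per-gene arithmetic means over the training samples of each
subtype.  A sample is correlated with each centroid by Spearman's rank
correlation (midrank ties) and assigned to the argmax, unless all five
correlations fall below 0.1, in which case it is Unclassified (assignment
requires $\max \rho \ge 0.1$; the rejection region is the open interval
below it).  Rank correlation makes the assignment invariant to any strictly
increasing transform of the sample's values, which is what makes
single-sample prediction usable across platforms and normalizations.  By
default all genes present in the centroid table participate.

## Agreement: weighted Cohen's kappa

Two call sets over the same samples are cross-tabulated over the canonical
category order (Basal-like, HER2-enriched, Luminal-A, Luminal-B, Normal
breast-like, with Unclassified last when retained).  Weighted kappa with
linear (Cicchetti–Allison) weights $w_{ij} = 1 - |i-j|/(R-1)$ is

$$\kappa_w = \frac{P_{o,w} - P_{e,w}}{1 - P_{e,w}},$$

with $P_{o,w}$ the weighted observed agreement and $P_{e,w}$ its expected
value under independent marginals.  The standard error is the
Fleiss–Cohen–Everitt large-sample formula and the 95% CI is
$\kappa \pm 1.96\,\mathrm{SE}$ truncated to $[-1, 1]$.  The linear scheme
and the printed category order are the package defaults because together
they reproduce the published agreement values on the packaged tables
(quadratic weights do not); both remain configurable.  Note that with an
ordered weight scheme the *position* of the Unclassified category matters —
it sits last, so rejecting a Luminal-B sample is a milder disagreement than
rejecting a Basal-like one.  That asymmetry is inherited from the published
table layout, not a modelling claim.

## Missing values and probeset collapse

Upstream of everything, two preprocessing utilities:

* `collapse_by_iqr()` resolves multiple probesets per gene by keeping the
  one with the largest inter-quartile range across arrays — the most
  variable measurement is the most informative one.  Quantiles use linear
  interpolation (`stats::quantile` type 7, the common default; Tukey hinges
  can differ by at most one sample and no convention is canonical here).
  Ties keep the first probeset in input order with a warning.
* `impute_em()` fills missing entries by expectation-maximization:
  initialize each gene's missing cells at the gene's observed mean, then
  alternate between fitting a low-rank latent-factor model to the completed
  matrix and replacing the missing cells with the model reconstruction,
  until the largest change drops below `tol` ($10^{-6}$ by default, at most
  100 iterations).  Observed cells are never altered.  When binary labels
  are available at imputation time the reconstruction model is a PLS fit
  with that response; otherwise a principal-component reconstruction.  The
  choice of which gene set to impute on (a classifier's 10-gene panel or
  the full signature) is left to the caller, as either is defensible.

Gene standardization uses the $n-1$ standard deviation; zero-variance genes
are centred only and flagged rather than producing NaNs.

## The synthetic-cohort generator

`generate_cohort()` draws cohorts with exactly the structure the classifier
assumes: gene $g$ in sample $s$ equals a subtype-specific mean shift plus
independent Gaussian noise.  The shift is `effect_size` when $g$ belongs to
the sample's own subtype panel, an optional cross-effect when it belongs to
another panel, and zero for background genes.  Defaults are 40 samples per
subtype, an effect size of 2 noise standard deviations and unit noise —
a separation at which subtype recovery is achievable but not trivial, which
is what makes it a useful operating point for validating the pipeline.
Cohorts are bitwise reproducible from their mandatory seed.

What the generator deliberately does **not** emulate: probe-level artefacts
and normalization residue, correlated noise between co-regulated genes,
batch effects between studies, unbalanced subtype prevalences, and label
noise in the training annotations.  Passing the simulation-based tests
therefore demonstrates that the machinery is implemented correctly and
recovers structure it was designed for; it does not by itself establish
performance on real arrays, which is why the published confusion tables are
also packaged and reproduced.

Test and validation problem sizes used by the package's own suite — chosen
to exercise each property at the smallest scale where it is meaningful:
cohorts of 40 samples per subtype (10 seeds) for parameter recovery, 60
null samples per replicate (100 replicates) for the chance-level AUC check,
and 20-observation instances for the PLS-against-oracle algebra checks.

## Numerical choices and degenerate inputs

* NIPALS is exact (single pass) for a single response; no inner iteration
  tolerance is consequential.  A residual cross-covariance below $10^{-12}$
  in norm stops extraction with a "no predictive structure" error.
* Probabilities returned by `predict_probability()` are clamped to the open
  unit interval, so downstream log-likelihoods are finite.
* `van_der_voet_test()` returns $p = 1$ when all paired differences vanish;
  enumeration is used through $n = 20$ (an incremental sum construction, no
  $2^n \times n$ matrix) and Monte Carlo beyond.
* Confusion tables with degenerate marginals ($P_{e,w} = 1$) make kappa
  undefined and raise an error rather than returning 0/0.
* Constant sample vectors in SSP yield undefined correlations: the sample
  is Unclassified with a warning.

## Known limitations

* The PLS machinery is single-response (PLS1) by design; modelling all five
  subtypes in one multi-response fit is out of scope because the dummy
  responses' mutual exclusivity cannot be encoded in that framework.
* Published PAM50 centroid values are not redistributed; `build_centroids()`
  constructs centroids from any labelled training cohort, and the SSP path
  is validated on synthetic data.
* Kappa confidence intervals use the large-sample SE; no bootstrap and no
  multi-rater generalization.
* The reference weight vectors shipped with the gene panels are stored
  verbatim from the published report, including one (Luminal-B) whose
  squared norm is visibly not 1; they are provenance metadata for
  inspection and spot-checking, not parameters the classifier loads.
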