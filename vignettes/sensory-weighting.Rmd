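---
title: "Consumer-weighted sensory scales: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consumer-weighted sensory scales: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lagerscale)
```

## The problem

Professional beer-evaluation scorecards weight sensory attributes by expert
judgement. When the goal is predicting *consumer* acceptance, those weights
can misrank products: attributes experts discriminate finely (foam fineness,
hop character) may barely move ordinary buyers, while holistic mouthfeel
does. `lagerscale` estimates attribute importance directly from consumer
questionnaire data and turns the estimates into a compact, integer-weighted
scorecard whose rankings can be validated against consumer hedonic
preferences.

The data model is a two-level **attribute hierarchy**: primary sensory
dimensions (appearance, aroma, taste, drinking sensation in the default
pale-lager configuration) each containing sub-attributes. Respondents rate
the purchase-decision importance of every sub-attribute on a 1–5 Likert
scale and are grouped into drinking-frequency cohorts (low = 1–3, mid =
4–8, high = 9+ occasions/month), because attribute priorities shift
systematically with product experience.

## The weighting model

For each cohort and each hierarchy level the package computes three layers:

**Subjective (AHP) weights.** Attribute means $m_i$ are min–max normalized
and mapped linearly onto Saaty's 1–9 intensity scale,
$v_i = 1 + 8\,(m_i - m_{\min})/(m_{\max} - m_{\min})$, and the pairwise
comparison matrix is built as the ratio matrix $a_{ij} = v_i / v_j$. Ratio
matrices are perfectly consistent (consistency ratio 0 by construction), so
the principal-eigenvector priorities reduce to $w_i = v_i / \sum_j v_j$.
This makes the "pairwise judgements" fully ratings-driven: no expert panel
fills in a matrix, and the usual CR < 0.1 admissibility question does not
arise (the `consistency_ratio()` facility still guards user-supplied
matrices). When all means are equal the map is degenerate; every attribute
is sent to the scale midpoint 5, which yields uniform weights, with a
warning.

**Objective (entropy) weights.** The entropy weight method scores each
attribute by the dispersion of its ratings: with column distributions
$p_{ij} = x_{ij}/\sum_i x_{ij}$, entropy
$e_j = -\frac{1}{\ln n}\sum_i p_{ij}\ln p_{ij}$ (taking $0\ln 0 = 0$) and
divergence $d_j = 1 - e_j$, the weights are $w_j = d_j / \sum_k d_k$. A
constant column has $e = 1$ and weight 0; if every column is constant the
method is uninformative and the package falls back to uniform weights with
a warning. Entropy is computed on individual respondents' raw 1–5 ratings
(already positive, so no shift is applied); the $\ln n$ normalization makes
the logarithm base irrelevant.

**Composite weights.** The two layers are fused as the convex combination
$w = \alpha\, w_{\mathrm{AHP}} + (1-\alpha)\, w_{\mathrm{EWM}}$ with
$\alpha = 0.7$ by default — a fixed subjective:objective ratio of 7:3 of
the kind typically settled by Delphi consultation. $\alpha$ is a plain
config field; sensitivity to it is easy to explore.

**Comprehensive weights.** Cohorts are blended with population coefficients
$C_i = f_i N_i / \sum_k f_k N_k$, where $N_i$ is the cohort size and $f_i$
a representative monthly drinking frequency (defaults 2, 6, 14): a
consumption-weighted, not head-count, view of the market. The market-wide
weight of attribute $a$ is $W_a = \sum_k C_k W_{k,a}$, renormalized only if
floating-point drift exceeds $10^{-9}$.

*Which layer is aggregated?* Written down naively, one would aggregate the
composite layer. The package's default (`aggregate_layer = "ahp"`)
aggregates the per-cohort subjective layer instead, which keeps the
comprehensive weights interpretable as stated importance and matches the
published dimension-level aggregation arithmetic this pipeline was designed
to reproduce; `aggregate_layer = "composite"` exposes the formula-as-written
alternative, and the run log records the choice prominently. Mixing layers
across cohorts is refused rather than silently accepted.

## Scale construction (three-step standardization)

`build_scale()` converts comprehensive weights into a scorecard:

1. **Merge** perceptually similar attributes (default: hop + floral,
   fruit + fermentation, aftertaste + persistence) by *summing* their
   weights. Merging happens before top-k selection — a merged pair can earn
   a top-3 rank that neither source would alone, which is the behavioural
   point of merging. Weight mass is conserved exactly.
2. **Exclude** attributes that are perceptible but unreliable in consumer
   ratings (default: alcohol warmth) and whole dimensions configured out of
   the scorecard (default: appearance, whose visual cues the bundled weight
   table carries only at dimension level). Exclusion does not renormalize —
   normalization is owned by the next step.
3. **Standardize**: keep the top `k = 3` attributes per retained dimension,
   normalize them locally to sum to 1, multiply by the dimension's
   comprehensive weight, normalize globally to 100%, and finally convert to
   integer percentages by largest-remainder apportionment (floor, then
   distribute the shortfall to the largest fractional remainders; remainder
   ties go to the larger fraction, then lexicographically).

Ties at rank `k` are broken by the larger pre-merge source weight backing
each candidate, then lexicographically — deterministic and stable under
attribute reordering. Ratings-derived weights almost never tie; the rule
exists so that printed, rounded tables behave predictably.

Weight-sum tolerances are deliberately two-tiered: internally computed
vectors must be normalized to $10^{-9}$, while *inputs* may drift by up to
$5\times10^{-3}$ in fraction units (and $10^{-3}$ in `integerize()`),
because tables republished at two-decimal percent precision do not sum to
exactly 100.

## Validation against consumer rankings

A tasting session pairs a professional panel (default 10 assessors), who
score each sample on each scale attribute (1 = extremely weak … 9 =
extremely strong), with a consumer panel (default 30), who give 9-point
hedonic liking scores. The sample composite under a scale is the mean over
assessors of per-assessor weighted averages $\sum_a w_a s_a$ (by linearity
this equals weighting the mean attribute scores; the per-assessor form
keeps assessor-level diagnostics possible). Samples are ranked descending
(rank 1 = best, average ranks on ties) and concordance between professional
and consumer rankings is measured with Kendall's $\tau_b$ and Spearman's
$\rho$ (tie-averaged ranks), both delegated to `stats::cor()`. With the
usual four-sample tasting, $n = 4$ makes significance tests meaningless, so
only the coefficients are reported. An existing holistic scorecard enters
the comparison as a single `"overall"` score per assessor per sample.

## The synthetic generator

`simulate_survey()` emulates the study conditions the estimator is designed
for: 1837 respondents by default, allocated to cohorts by largest remainder
on shares 38.54% / 42.49% / 18.97% (the residual share is assigned to the
high-frequency cohort), with each (cohort, attribute) cell drawing Likert
ratings from a latent normal rounded to the nearest integer and clamped to
[1, 5]. Default targets — means in [3.6, 4.0], SDs in [1.0, 1.25] — sit in
the mid-to-upper range with the dispersion typical of consumer importance
surveys. `likert_moments()` gives the exact post-discretization mean and SD
implied by any $(\mu, \sigma)$, which is what the recovery tests compare
against. A single seed determines everything.

What the generator does **not** emulate: inter-attribute correlation
(attributes are independent given their marginals), single-factor structure
within dimensions, demographic–preference dependence, response styles
(straight-lining, acquiescence), or missingness. Consequences worth
knowing: on synthetic data Cronbach's $\alpha$ hovers near 0 and KMO near
0.5 — the reliability module is therefore tested for formula correctness
and invariances, not for hitting real-survey values — and passing recovery
tests show the estimator recovers *planted marginal structure*, not that it
is robust to correlated response behaviour. `simulate_tasting()` similarly
plants true attribute intensities and hedonic means, adds independent
normal noise, and discretizes onto [1, 9]; with noise SD 0 it reproduces
the planted values exactly, which anchors the scoring tests.

## Numerical and design choices

* Pearson correlations feed KMO and Bartlett's sphericity even though
  Likert items are ordinal: those diagnostics are defined on
  product-moment correlation matrices and their conventional cutoffs assume
  them. Polychoric alternatives are out of scope.
* Complete-case analysis everywhere in reliability; pairwise deletion in
  `attribute_means()`; an attribute with fewer than two ratings in a cohort
  aborts with a named error rather than imputing.
* The principal eigenvalue in `consistency_ratio()` comes from `eigen()`;
  the Saaty random-index table covers $n \le 10$.
* `cohort_coefficients()` treats cohort sizes as data. When only shares are
  known, largest-remainder allocation of the total yields sizes whose
  coefficients match published four-decimal coefficients to within
  $10^{-3}$ — the level of agreement one can expect without the exact
  per-cohort counts.
* Reports render percentages at two decimals; all internal arithmetic is
  double precision.

## Problem sizes in the test suite

Property-style tests run the full estimator on synthetic surveys of
$n = 1800$ (100 seeds) for ordering recovery, $n \approx 1000$–2000 for
moment recovery, and 100-seed Monte-Carlo checks for tasting-session
ranking recovery — sizes chosen to keep Monte-Carlo error well below the
planted effect gaps (0.15 scale points between adjacent dimension means)
while the whole suite stays comfortably fast on a laptop.

## Known limitations

* The ratio-matrix AHP construction cannot represent intransitive or
  inconsistent expert judgement — by design, but it means
  expert-elicited matrices are only supported through
  `consistency_ratio()`, not as the primary weighting path.
* Entropy weights on near-constant columns are sensitive to a handful of
  outlying respondents (a column with one divergent rating gets all the
  dispersion credit within that column's divergence).
* Frequency factors $f_i$ are external constants; the package does not
  estimate them from consumption data.
* Rank concordance on four samples takes only seven distinct $\tau$ values;
  interpret magnitudes, not decimals.
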