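---
title: "Screening biomarker candidates with the Measure of Relevance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening biomarker candidates with the Measure of Relevance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup, message = FALSE}
library(morscreen)
library(dplyr)
```

## The problem

Basic-research studies in biology and medicine routinely measure hundreds
to many thousands of candidate variables — gene expressions, SNP allele
indicators, EEG-derived sleep parameters — on a handful of subjects per
group, and then ask which of these variables distinguish the two groups.
Testing every variable runs into the classic multiple-testing dilemma:
controlling the family-wise type I error over thousands of tests makes the
per-test level so strict that real effects in small samples cannot reach
it, while testing without correction floods the result list with false
positives. morscreen implements an alternative *screening* viewpoint: do
not test at all, but rank every feature by a distribution-free relevance
score and cut the ranked list with an explicit selection rule. The output
is a set of biomarker *candidates* for focused follow-up, not a set of
significant findings.

## The score

For each feature, the values of all `N = n1 + n2` samples are pooled,
ranked (midranks for ties, per-feature complete cases), and mapped to the
unit interval by

$$U = \frac{R - 0.5}{N},$$

so that every feature — metric, ordinal or binary 0/1 — lives on the same
scale, outliers are neutralized, and any strictly monotone transformation
of a feature leaves everything that follows unchanged. Three quantities are
computed from the transformed values:

* **B**, the *biological difference*: the difference of the two group
  means of `U`. It is confined to `[-0.5, 0.5]`, hitting the bounds exactly
  when the groups separate completely.
* **S**, the *dispersion*: the pooled standard deviation of `U`
  (independent design) or the standard deviation of the paired `U`
  differences (dependent design). The per-group variances enter as
  empirical `1/n` variances, pooled with `n - 1` weights; `S` is
  deliberately not an unbiased estimator of the population value — it is a
  normalizer, not an estimand.
* **O**, the *overlap factor*: a two-proportion z-like statistic. For
  independent groups it compares the fractions of each group lying
  strictly above the pooled `γ`-quantile (default `γ = 0.5`, the pooled
  median); on untied data the pooled exceedance fraction equals `1 - γ` up
  to the `1/N` rank grid. For matched pairs it is the sign balance of the
  non-tied pair differences, ties discarded.

The Measure of Relevance combines them as

$$\mathrm{MoR} = c \cdot B \cdot |O| \, / \, S,$$

with a common weighting factor `c = 1` by default. `|MoR| = c|O||B|/S`
drives all ranking and selection; the sign is carried by `B` so that it
reads directly as the direction of the group difference. (Writing the
product as `O·B/S` is equivalent whenever the two factors agree in sign,
which they do except for noise-level features; tying the sign to `B` keeps
the direction readable in every case.) Sorting features by decreasing
`|MoR|` yields the *information chain*; selection criteria decide how far
down the chain features still count as relevant.

Degenerate features — empty groups, fewer than two usable values, zero
rank dispersion — are flagged and scored 0 rather than dropped, so the
chain always has one row per scorable feature. Nominal features with more
than two categories have no defensible one-dimensional coding and are
excluded from scoring with a warning.

### Raw mode for very small samples

With tiny samples and many continuous features, rank-based `B` values are
heavily tied: over all group assignments of fixed sizes, untied data admit
exactly `n1·n2 + 1` distinct `B` values, so at `n1 = n2 = 5` the whole
study shares 26 possible values and the chain loses resolution. `mode =
"raw"` computes `B` and `S` from the original values instead, accepting
outlier risk in exchange for resolution; `O` is transformation-invariant
and is always computed on ranks. In raw mode a feature that is constant
within both groups but differs between them has `S = 0` with `B ≠ 0`; it
is flagged and scored with a large sentinel (`±1e6`) rather than silently
infinite.

### Choice of the U formula

Any order-preserving map of ranks into `(0,1)` would do. `U = (R - 0.5)/N`
was chosen because it centres every untied full rank set at exactly 0.5
and makes the pooled median of the transformed values equal 0.5, so the
default overlap split is symmetric. The common alternative `R/(N + 1)` has
the same invariance properties and is available via `u_method = "ratio"`;
all shipped defaults and calibration results use the midpoint form.

## Selection criteria

Four families are provided, with the composite `screen_features()`
encoding the recommended order: first an *objective* decision whether the
chain contains anything at all, then an optional *subjective* pruning.

* **Sample-related cut-off** (`select_sample_cutoff()`): select
  `|MoR| ≥ w·z0/√(n1+n2)` with per-feature sample sizes. For large
  samples `O` behaves like a Z statistic, and `z0 = 3.28` is the sum of
  the two one-sided 5% normal quantiles (2 × 1.645); the threshold
  therefore marks scores outside the central null mass and shrinks like
  `1/√N`, so growing studies admit smaller standardized effects. The
  weight `w` (default 1) lets the analyst brake the rule; values up to ~4
  are sensible for very small samples where only large effects are
  credible. The flip side, visible in the calibration runs below, is that
  specificity *decreases* with `N` at fixed `w`: among thousands of null
  features, ever more exceed a shrinking threshold by chance.
* **Entropy stopping rule** (`select_entropy()`): weight the first `k`
  chain entries by their `|MoR|` share and track the Shannon entropy
  `H_k`; stop when the adjusted change drops below `δ` (default 0.01).
  The default adjustment is the relative change `(H_{k+1} - H_k)/H_k`;
  the plain increment is available as `change = "absolute"` and is the
  variant that stops immediately on a chain dominated by a single large
  score, so both are exposed. Recommended for very small samples, where
  the cut-off threshold would be so large that granular rank statistics
  straddle it.
* **Permutation criterion** (`select_permutation()`): re-score under `K`
  random regroupings (label permutations preserving `n1`/`n2`, or
  within-pair flips), select features whose observed `|MoR|` ranks among
  the top `⌈αK⌉` permuted values. Distinct regroupings are enumerated
  exhaustively when `K` covers them (`choose(N, n1)` or `2^n`). Valid for
  moderate samples but computationally the heaviest; restricting it to
  the head of the chain (`top_m`) is supported.
* **Subjective cut-offs**: the smallest prefix holding a fraction `d` of
  the total `|MoR|` information (`select_fraction()`), or a fixed
  proportion `⌈ε·p⌉` of all features (`select_top_proportion()`).

No criterion attaches a p-value to the score itself: the point of the
method is to avoid feature-wise inference and its multiplicity corrections
altogether. The package deliberately offers no automatic choice among the
criteria; which one is "optimal" is an open question, and the qualitative
guidance above (entropy for very small, permutation for moderate, cut-off
for large samples) is a recommendation, not a constraint.

## What the simulation generator emulates

`simulate_features()` reproduces the study designs used to calibrate the
procedure: `p = 1000` features, the first 10 carrying a standardized group
difference (*normalized biological difference*, NBD) and the rest none,
at the conventional class values NBD = 2 (very informative), 1
(semi-informative) and 0 (non-informative). All features within a dataset
share one marginal family — normal, equal-width uniform, rescaled bimodal
normal mixture (mode offset 2 before rescaling), or Bernoulli with success
probabilities `0.5 ± NBD/4` — standardized to unit variance so the
location offset *is* the NBD. Matched designs draw pairs with within-pair
correlation `ρ = 0.5` through a shared normal component (latent-threshold
construction for Bernoulli) and place the shift on the pair-difference
scale, `NBD·√(2(1-ρ))`, so the standardized paired effect equals the
nominal NBD; matched designs with uniform or bimodal marginals are not
provided, matching the scope of the calibration grids.
`dichotomize_at_median()` converts any table to pooled-median 0/1 splits,
the construction used to compare score distributions across data types.

What the generator does *not* emulate — and what passing calibration
checks therefore cannot certify — includes correlated features
(co-expression blocks, LD structure), heteroscedastic groups, mixed
feature scales within one dataset, missingness mechanisms, and batch
effects. Real screens should treat the simulation results as evidence
about the procedure's operating characteristics under clean conditions,
not as a power guarantee.

## Calibration results at desk scale

`run_study()` re-runs the objectivity/reliability/validity grids at 100
runs per condition by default (reducible for quick checks). The headline
behaviour, reproduced by `scripts/acceptance.R` and the package tests at
20–100 runs:

* With NBD = 2 the cut-off screen attains sensitivity ≈ 1.00 across
  designs (independent 12/10 and 15/15, matched 11 pairs) and
  distributions (normal, uniform), matching unadjusted per-feature t
  tests, while Bonferroni-adjusted t tests lose sensitivity at small `n`.
* Specificity of the screen at 12/10 is ≈ 0.81 with the default
  constants — below the ≈ 0.95 of unadjusted t tests, and falling further
  as `N` grows (the `1/√N` threshold at work).
* One deliberate red flag: the claim that the 10 strong features occupy
  the top 10 chain positions in ≥ 99% of runs at NBD = 2, n = 15/15 is
  not attainable — measured ≈ 25%, and ≈ 50% even for an oracle pooled-t
  ranking — because the maximum of 990 null scores overlaps the minimum
  of 10 informative ones at these sizes. The corresponding test is left
  failing by design; complete top-of-chain isolation at `p = 1000` would
  require NBD ≈ 3 or more.

The random-forest comparator (`baseline_forest()`) is qualitative only:
importance thresholds have no canonical value, so it is excluded from
numeric calibration.

## Numerical conventions and edge cases

* Ties receive midranks everywhere; the quantile in the overlap factor is
  the type-1 (left-continuous inverse) empirical quantile, and exceedance
  is strict (`>`), which is what makes the pooled exceedance identity
  `p̄ = 1 - γ` exact up to the rank grid.
* Missing values are handled feature-wise (complete cases; complete pairs
  in the dependent design, re-ranked within the usable sample), so `n1`,
  `n2` and the cut-off threshold are per-feature quantities.
* Chain ties in `|MoR|` are broken by input order (stable sort), making
  reports reproducible byte for byte.
* All randomness (simulation, permutation, bootstrap) is funnelled
  through explicit integer seeds.
* Bootstrap intervals (`bootstrap_mor()`) are percentile intervals from
  resampling samples within groups — pairs jointly under matching — with
  no bias correction; they describe sampling variability of the score,
  not a test.
* `pairwise_mor()` extends screening to factors with more than two levels
  by running all level pairs and reporting the union of the per-pair
  selections as the overall candidate set. Interactions between factors
  and between features are out of scope.

## Problem sizes used in the shipped checks

The package's own test suite runs the table-cell reproductions at 20 runs
per condition, the monotonicity grid at 40 runs with 300 features, and the
top-of-chain study at 100 runs with the full 1000 features; the
acceptance script defaults to 100 runs per condition. These sizes keep a
full check under a couple of minutes on one core while leaving the
Monte-Carlo error of every asserted mean well inside its tolerance; all
of them scale up by a flag (`runs`) without further changes.
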