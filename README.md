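# morscreen

Distribution-free screening of biomarker candidates in two-sample studies
with the **Measure of Relevance (MoR)**.

## What problem this solves, and for whom

High-dimensional basic-research studies — gene expression, SNP panels,
sleep-EEG parameter sets — measure hundreds to thousands of candidate
variables on small samples and ask which variables distinguish two groups
(cases vs controls, before vs after treatment). Feature-wise hypothesis
testing forces a choice between harsh multiplicity corrections (which
small samples cannot survive) and inflated false-positive lists. morscreen
takes the exploratory route instead: every feature gets a nonparametric
relevance score, features are sorted into an *information chain* by score
magnitude, and an explicit selection rule decides how far down the chain
features still count as candidates. No per-feature p-values, hence no
significance-level corrections, for any number of features.

It is aimed at analysts screening metric, ordinal and/or binary features,
in independent or matched (paired) two-group designs, who want a ranked
shortlist for focused follow-up.

## The score

Per feature, pooled midranks are mapped to the unit interval,
`U = (R − 0.5)/N`, and three factors are computed:

- `B = mean(U₁) − mean(U₂)` — the biological difference, in `[-0.5, 0.5]`;
- `S` — pooled dispersion of `U` (independent) or the SD of paired `U`
  differences (dependent);
- `O` — a two-proportion z-like overlap factor: how the groups split
  around the pooled median (independent), or the sign balance of non-tied
  pair differences (dependent).

These combine into

```
MoR = c · B · |O| / S        (c = 1 by default)
```

so `|MoR|` grows with separation, location difference and homogeneity,
and `sign(MoR)` gives the direction of the difference. Selection criteria
on the chain include an objective sample-related cut-off
`|MoR| ≥ w·3.28/√(n1+n2)`, an entropy-based stopping rule, a permutation
null criterion, and fraction / top-proportion cut-offs. See the methods
vignette (`vignettes/mor-screening.Rmd`) for the full account.

## Worked example

Simulate a screen of 1000 features (10 truly informative at a
standardized shift of 2 SD) on 15 + 15 samples, score, select, and attach
bootstrap intervals:

```r
library(morscreen)

sim <- simulate_features(p = 1000, n_informative = 10, nbd = 2,
                         n1 = 15, n2 = 15, seed = 42)
chain <- mor(sim)
print(chain, n = 5)
#> <mor_result> information chain of 1000 features (independent design, rank mode, gamma = 0.5, c = 1)
#> # A tibble: 1,000 × 9
#>   feature chain_rank    n1    n2     B     S     O   mor degenerate
#>   <chr>        <int> <dbl> <dbl> <dbl> <dbl> <dbl> <dbl> <lgl>
#> 1 f0010            1    15    15 0.447 0.183  4.75 11.6  FALSE
#> 2 f0006            2    15    15 0.464 0.171  4.02 10.9  FALSE
#> 3 f0007            3    15    15 0.46  0.174  4.02 10.6  FALSE
#> 4 f0004            4    15    15 0.42  0.198  4.02  8.53 FALSE
#> 5 f0005            5    15    15 0.447 0.183  3.29  8.04 FALSE
```

The top of the chain is dominated by the shifted features: `B` near its
bound 0.5, overlap factor `O` around 4 (nearly separated groups), hence
`|MoR| ≈ 8–12`, far above typical null scores. Screening with the
objective cut-off and evaluating against the known truth:

```r
sel <- screen_features(chain)
glance(sel)
#> # A tibble: 1 × 5
#>   criterion n_features n_selected threshold status
#> 1 screen          1000        193     0.599 ok

evaluate_selection(sel, informative_features(sim))
#> # A tibble: 1 × 6
#>      tp    fp    fn    tn sensitivity specificity
#> 1    10   183     0   807           1       0.815
```

All 10 informative features are recovered (sensitivity 1.00); the price
of the shrinking `1/√N` threshold is a false-positive rate around 19%
among the 990 nulls — the documented trade-off of the objective cut-off,
which a subjective refinement (`screen_features(..., refine =
"top_proportion", epsilon = 0.01)`) or a stricter weight `w` can tighten.

```r
bootstrap_mor(sim, features = selected_features(sel)[1:3],
              times = 500, seed = 1)
#> # A tibble: 3 × 6
#>   feature estimate lower upper times level
#> 1 f0010       11.6  3.69  19.3   500  0.95
#> 2 f0006       10.9  5.01  19.2   500  0.95
#> 3 f0007       10.6  4.78  19.2   500  0.95
```

Real tables enter through `read_feature_matrix()` (CSV/TSV, samples as
rows, one group column, optional pair column) or any data frame piped
into `mor(data, group, pair)`. Factors with more than two levels go
through `pairwise_mor()`. A thin command-line wrapper
(`inst/cli/mor.R score|simulate|bootstrap`) drives the same functions
headless from a JSON config.

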