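# ribmetric

Welfare-based quality evaluation of agricultural index-insurance
contracts.

## The problem

Index insurance pays out on an observable proxy — typically a satellite
vegetation or rainfall anomaly — instead of verified individual losses.
Such contracts inevitably make errors: they miss real losses (false
negatives) and pay when nothing was lost (false positives).  The remote
sensing literature usually scores candidate indices with generic
goodness-of-fit statistics (R², RMSE), but those statistics weight all
errors equally, while the *insurance* value of an index depends almost
entirely on whether it pays in the bad states of the world, when money is
worth the most to the insured.

`ribmetric` is for analysts designing or auditing index-insurance
programs (livestock or crop) who want to rank candidate indices and loss
models by what they are worth *as insurance*, not merely by predictive
skill.

## The metric

A household with insured herd value normalized to 1 faces seasonal
mortality `M`.  A contract with deductible (trigger) `t` pays
`I(M̂) = max(0, M̂ − t)` on predicted mortality `M̂`, and costs the
actuarially fair price — the long-run mean payout — loaded by a markup
`m`: `p = AFP · (1 + m)`.  Wealth next season is `1 − M` uninsured and
`1 − M + I − p` insured.  Preferences are constant relative risk
aversion, `U(k) = k^(1−ρ)/(1−ρ)` (default `ρ = 2`).

With expected utilities `EU^N` (no insurance), `EU^J` (the candidate
index contract) and `EU^P` (the *perfect* contract, which pays on
observed mortality), convert to certainty equivalents
`CE = [(1−ρ)·EU]^{1/(1−ρ)}` and define the certainty-equivalent
insurance benefits `ÎB^J = CE^J − CE^N` and `ÎB^P = CE^P − CE^N`.  The
**relative insurance benefit** is

    RIB^J = ÎB^J / ÎB^P        (defined when ÎB^P > 0)

RIB = 1 means the index contract is as valuable as perfect insurance;
0 means it is worthless; negative means the insured would be better off
uninsured.  A first-order decomposition
`IB ≈ Σ_j Δ(M_j) · λ(k_j) · π_j` — the wealth transfer in each state,
times the shadow value of money `λ(k) = k^(−ρ)` when it occurs, times the
state probability — shows *why* a contract scores as it does, and every
season is classified as a true negative, false positive, or a small /
intermediate / severe false negative by payout shortfall.

Loss models mapping standardized index anomalies (z-scores) to mortality:
ordinary least squares (`lm`), OLS restricted to `z < 0` (`lm0`) or
`z < −0.5` (`lm5`), segmented regression with an estimated breakpoint
(`sm`), and conditional quantile regression (`qr`, default τ = 0.77).

## Worked example

The package ships a seeded generator that emulates the structure of a
sub-location × season livestock mortality survey panel (15 locations,
8 years, 2 seasons; mean mortality ≈ 13%; mortality declining in the
forage index below a breakpoint near z = −1):

```r
library(ribmetric)

d   <- simulate_seasons(scenario_config(seed = 42))
d   <- zscore_index(d, "ndvi")                 # per-location z-scores
fit <- loss_model(mortality ~ z_ndvi, d, kind = "sm")
fit
#> Mortality loss model [sm: segmented]
#>    intercept        slope slope_change
#>      -0.0839      -0.2080       0.2044
#> breakpoint psi: -0.9451
#> n = 240  SSE = 1.246

evaluate_contract(d, model = fit, terms = contract_terms(), rho = 2)
#> Index-insurance contract evaluation (rho = 2, n = 240)
#>   CE no insurance:       860.85
#>   CE index contract:     863.43   (IBhat_J +2.58)
#>   CE perfect:            867.04   (IBhat_P +6.19)
#>   premium (index):         4.77   AFP 3.82
#>   RIB: 0.4174
#>   payout classes:  TN=213  FP=10  FN_small=7  FN_intermediate=10  FN_severe=0
```

The fitted breakpoint sits near the true hinge (−1); the index contract
delivers 42% of the certainty-equivalent benefit a perfect contract
would.  Comparing model kinds on the same data:

```r
rib_sweep(d, indices = "ndvi", kinds = c("lm", "lm0", "lm5", "sm"))
#>   index kind r_squared     RIB premium
#> 1  ndvi   sm     0.336 0.41742  4.7688
#> 2  ndvi  lm5    -0.623 0.39040  3.9785
#> 3  ndvi  lm0    -0.199 0.25475  1.4858
#> 4  ndvi   lm     0.147 0.00602  0.0137

kfold_cv(d, index = "ndvi", kind = "sm", k = 5, seed = 42)
#> 5-fold cross-validation (seed 42, pricing per_fold)
#>   R-squared: 0.287 out-of-fold vs 0.336 in-sample
#>   RIB:       0.168 out-of-fold vs 0.417 in-sample
```

Note the signature finding this package exists to expose: the welfare
ranking (`sm` ≻ `lm5` ≻ `lm0` ≻ `lm`) does not follow the R² ranking —
the plain linear model has a better R² than both restricted models yet
is nearly worthless as insurance, because its payouts miss the severe
loss seasons.  `simulate_matched_indices()` sharpens this into a
controlled experiment: two indices with matched R² whose errors sit in
bad versus good seasons, with very different RIB.

A thin command-line wrapper over the same functions is installed at
`inst/cli/ribmetric.R` (subcommands `simulate`, `pipeline`, `sweep`,
`cv`, `rho-sweep`).

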