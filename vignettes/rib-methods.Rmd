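---
title: "Valuing index-insurance contracts: models, pricing, and the RIB"
author: "ribmetric"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Valuing index-insurance contracts: models, pricing, and the RIB}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribmetric)
```

## The economic model

A pastoralist household holds productive wealth in livestock, measured in
Tropical Livestock Units (1 TLU = 1 cow = 0.7 camels = 10 goats or
sheep; `tlu_from_herd()` applies the camel factor as the exact
reciprocal of 0.7).  Seasonal mortality $M \in [0,1]$ reduces wealth to
$k^N = k_1(1 - M)$; herd growth is deliberately ignored — the object of
interest is the loss process, not herd dynamics.

An indemnity contract with trigger $t$ pays $\max(0, \hat M - t)$ per
insured TLU on a mortality estimate $\hat M$.  The *perfect* contract
uses observed mortality ($\hat M = M$); an *index* contract uses a model
prediction from a remote-sensing anomaly.  Pricing is actuarial: the
fair price is the mean backcast payout over the pricing sample (or a
probability-weighted mean over a discrete outcome distribution), and the
market premium loads it proportionally, $p = \mathrm{AFP}(1 + m)$.  The
premium is charged every season, payout seasons included.

Preferences are constant relative risk aversion (CRRA),
$U(k) = k^{1-\rho}/(1-\rho)$ for $\rho \neq 1$ and $\log k$ at
$\rho = 1$.  CRRA is homothetic, so all wealth accounting is done
internally in fractions of the insured value and currency is applied as
a final scale; certainty equivalents scale linearly and the RIB is
exactly unit-free (this is asserted as a test rather than assumed).
Expected utility over the observed location-seasons uses equal weights
by default — every location-season is one draw from the risk
distribution — and accepts an explicit weight vector where sub-locations
should count differently.

The quality metric compares certainty-equivalent benefits:
$\widehat{IB}^J = CE^J - CE^N$, $\widehat{IB}^P = CE^P - CE^N$, and
$RIB^J = \widehat{IB}^J / \widehat{IB}^P$.  The ratio is only meaningful
when perfect insurance itself is beneficial; `rib()` raises an error
when $\widehat{IB}^P \le 0$, while the `evaluate_contract()` report
records `NA` so that sweeps over unfavourable parameter regions (e.g.
risk neutrality with a positive markup, where any contract is a pure
cost) degrade gracefully instead of aborting.

The first-order decomposition implemented by `decompose_ib()` writes
$IB \approx \sum_j \Delta_j \,\lambda(k_j)\, \pi_j$ with
$\Delta_j = I_j - p$ the wealth transfer and $\lambda(k) = k^{-\rho}$
the shadow value of money.  $\lambda$ is evaluated at the *uninsured*
wealth $k^N(M_j)$ — the state the household is in absent the transfer —
which is the natural expansion point for a first-order approximation
around the no-insurance wealth path; a flag (`lambda_at = "insured"`)
exposes the alternative.  The approximation error is reported; it
shrinks quadratically as payouts and premium are scaled toward zero,
and the tests assert both the 5% relative accuracy at a 0.01 scale and
the super-linear shrinkage under halving.

## Loss models

Five model kinds map a standardized index anomaly $z$ to mortality:

| kind | definition | tunables |
|------|------------|----------|
| `lm`  | OLS on all data | — |
| `lm0` | OLS on $z < 0$ | cutoff preset |
| `lm5` | OLS on $z < -0.5$ | cutoff preset |
| `sm`  | $M = \beta_0 + \beta_1 z + \beta_2 (z-\psi)\,1[z>\psi]$ | breakpoint $\psi$ estimated |
| `qr`  | linear conditional quantile | $\tau$, default 0.77 |

**Breakpoint estimation (`sm`).**  For fixed $\psi$ the model is exact
OLS on $\{1, z, (z-\psi)^+\}$, so the SSE profile over $\psi$ can be
evaluated directly.  The fit profiles all admissible observed $z$ values
(at least `min_seg = 3` observations on each side, the minimum that
identifies two slopes), then refines continuously by `optimize()`
between the best candidate's neighbours; ties break toward the smaller
$\psi$.  This is deterministic and checkable against an exhaustive grid
oracle, which the test suite does on 50 seeded panels; iterative
segmented-regression algorithms converge to the same optimum when they
converge, but offer no such guarantee.

**Quantile fit (`qr`).**  The pinball objective
$\sum_i \rho_\tau(M_i - \beta_0 - \beta_1 z_i)$ is minimized by
iteratively reweighted least squares with a smoothing parameter shrunk
to $10^{-6}$, followed by a vertex polish: the optimum of this
piecewise-linear program interpolates two observations, so the fit
enumerates lines through pairs of the observations nearest the smoothed
solution and keeps the best objective.  The polish is what lets the
tests demand agreement with an exhaustive vertex-search oracle to
$10^{-8}$; smoothing alone gets close but cannot certify the vertex.
At the optimum the residual-balance condition holds: the fraction of
observations below the fitted line is within $2/n$ of $\tau$.

**Prediction and clipping.**  Predictions are clipped to $[0,1]$ at
prediction time, never during fitting.  The cutoff-restricted models
extrapolate their fitted line over the whole $z$ range; payouts are
insensitive to this choice because extrapolated predictions above the
cutoff sit below any realistic trigger.  `goodness_of_fit()` evaluates
clipped predictions on the full evaluation set by default so all kinds
are compared on a common footing — note that this full-sample convention
can drive the restricted models' R² negative on data whose mortality is
flat above the breakpoint, precisely because they are never asked to fit
that region; `subset_only = TRUE` gives the within-sample alternative.

## Index preparation

Raw seasonal aggregates (mean NDVI or rainfall per location-season) are
standardized per location: $z_{ls} = (x_{ls} - \mu_l)/\sigma_l$ with the
sample (n−1) standard deviation — conventional for anomaly indices and
the less biased choice at the short per-location series lengths
involved.  Both seasons are pooled when computing $\mu_l, \sigma_l$,
matching a climatology indexed by location only; `by_season = TRUE`
stratifies by season-of-year, since seasonal means can differ
systematically.  The standardization window is whatever the input table
spans, and is recorded in the `"standardization"` attribute.  Log
transformation (for right-skewed series) happens before standardization
and rejects non-positive values loudly, because NDVI can be negative
over non-vegetated surfaces and silently dropping such records would
bias the climatology.

## The synthetic generator

`simulate_seasons()` emulates the *structure* the analysis assumes: a
panel of 15 sub-locations × 8 years × 2 herding seasons (240 records); a
latent standard-normal forage anomaly per location-season; mean
mortality piecewise-linear in the anomaly — base 0.10, rising 0.25 per
z unit of deficit below a breakpoint at $z^\ast = -1$, flat above it;
additive noise (sd 0.05, optionally concentrated in bad or good
states); and rare forage-independent shocks (probability 0.03, magnitude
0.2–0.4) standing in for disease outbreaks, which occur even when forage
conditions are good.  These defaults give overall mean mortality near
13% and a perfect-contract fair price of roughly 2% of insured value per
season at the 0.23 trigger.  Mortality is capped at 0.95: total herd
loss is not observed in survey panels of this kind and would create
zero-wealth states outside the CRRA domain.  The raw index is
constructed per location as $\mu_l + \sigma_l z$ with location-specific
level and spread, so the standardization step does real work.

The noise model is additive on the mortality scale with truncation into
$[0, 0.95]$ — a simple bounded stand-in chosen for transparency, not a
claim about the error structure of household surveys (a beta model would
be the natural refinement).  The generator also does not emulate sensor
noise, cloud contamination, spatial autocorrelation between
sub-locations, or household-level heterogeneity; passing tests therefore
demonstrate correctness of the estimators and welfare accounting under
the assumed data-generating structure, not performance on real survey
data.

`simulate_matched_indices()` builds the controlled contrast between
predictive skill and insurance value: two indices with (root-finding)
matched segmented-model R², one whose measurement errors sit in the
high-mortality quartile (upward index shifts — undetected droughts,
severe false negatives), one whose errors sit in the low-mortality
quartile (downward shifts bounded at $z = -2$ — spurious drought
readings, overpayments).  Both error fields reuse the same half-normal
draws so error mass is reallocated rather than redrawn.
`outcome_distribution()` provides a stylized 25-state discrete mortality
distribution (0 to 0.65, exponentially decaying probabilities, decay
0.14) whose perfect contract prices near $20 per $1000 insured.

## Contract evaluation, sweeps and cross-validation

`evaluate_contract()` runs predict → indemnify → price → wealth → EU →
CE → IB → RIB → classification in one pass and returns the per-season
records.  Payout errors are classified by shortfall
$s = (I^P - I^J) / (\text{insured value})$: true negative (nothing due,
nothing paid), false positive ($s < 0$), and false negatives split at
10% and 30% of insured value.  The insured-value denominator makes the
severity thresholds comparable across seasons regardless of how much was
owed; both the thresholds and the denominator are configurable
(`denominator = "perfect_payout"` measures shortfall relative to what
was owed instead).

Default contract parameters: trigger 0.23 (mortality fraction), markup
0.25, one insured TLU worth $1000, $\rho = 2$ — a moderately risk-averse
smallholder, with a 0–3 sweep (`rho_sweep()`) covering the range of
field-experimental estimates; $\rho = 1$ uses the log branch, and the
sweep is continuous through it.

The wealth guard defaults to a hard error on non-positive wealth (CRRA
is undefined there, and silently flooring would overstate benefits); an
explicit `wealth_floor` (e.g. 1% of initial wealth) is available and is
the user's documented deviation, not the package's.

`rib_sweep()` fits every (index, kind) combination and reports R², RMSE,
RIB, pricing, and class counts, recording per-row failures rather than
aborting — a sweep over many candidates should survive one degenerate
column.  `kfold_cv()` partitions individual location-season records into
seeded folds (`block_by = "location"` gives the spatially blocked
alternative), pools out-of-fold predictions so each record is predicted
exactly once, and computes R² and RIB once on the pooled series.  Each
record's index premium is re-priced from its fold's training payouts by
default — out-of-fold pricing is the honest analogue of out-of-fold
prediction — with `pricing = "pooled"` as the single-pass alternative;
the perfect contract is always priced on the full sample, since it does
not depend on the fitted model.  Leave-one-out (`k = n`) is supported.

## Numerical choices and degenerate inputs

* Segmented ties break toward the smallest breakpoint; the continuous
  refinement uses `optimize()` at tolerance $10^{-10}$ and only replaces
  the grid optimum when it strictly improves the SSE.
* The IRLS smoothing floor is $10^{-6}$ with a $10^{-11}$ step
  criterion; the vertex polish searches pairs among the 40 observations
  with the smallest smoothed residuals.
* Constant predictors, all-constant mortality (zero SST), empty payout
  lists, weights not summing to 1, non-positive wealth, and
  $\widehat{IB}^P \le 0$ all fail loudly with the offending record named
  where applicable.
* Equality comparisons on money are exact where the arithmetic is exact
  (the perfect-contract RIB is identically 1 because both numerators are
  the same floating-point numbers), and tolerance-based elsewhere.

## Problem sizes

The test suite exercises panels of 240–360 location-seasons, 50-seed
oracle comparisons for the segmented fit, 20-seed batteries for the
matched-pair contrast and cross-validation optimism, and exhaustive
oracles at $n \le 50$ for the quantile fit — sizes chosen to mirror the
survey-panel scale the generator emulates while keeping the full suite
in the tens of seconds.

## Known limitations

* The welfare engine is strictly expected-utility/CRRA; probability
  weighting (rank-dependent or prospect-theoretic) evaluation is out of
  scope by design, as a normative quality standard should not embed
  misperceived probabilities.
* Pricing is pooled across locations; location-differentiated premiums,
  reinsurance layering and intertemporal adverse-selection adjustments
  are not modelled.
* The input table is taken as already aggregated to location-season
  level; survey weighting upstream of that aggregation is the user's
  responsibility.
* The crop variant implements the yield-shortfall indemnity and reuses
  the same welfare machinery, but ships without a crop-specific
  synthetic generator.
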