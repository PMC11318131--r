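---
title: "Cheap-but-noisy outcome measures: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cheap-but-noisy outcome measures: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noisymeasures)
```

## The problem

A large simple trial measures a continuous outcome on thousands of
participants. With a fixed follow-up budget there is a trade-off: an
expensive, high-resolution gold-standard assessment on fewer participants, or
a cheap short questionnaire — which categorises the outcome coarsely and
correlates imperfectly with the gold standard — on many more. This package
quantifies both sides of that trade: how much variance the cheap measure
adds, and how much money it saves, including the follow-up gain from lower
participant burden.

## Variance from outcome categorisation

We model the gold standard as an integer scale `lo..hi` (default 0–99). A
measure with `M` ordered categories assigns every participant the midpoint
value of their category, so the measurement adds

$$\sigma_c^2 \;=\; \sum_{m=1}^{M} \sum_{k \in m} p(k)\,(k - \bar y_m)^2 ,$$

the expected squared distance between the true value and the assigned
midpoint. `M = 1` is the *variance of non-measurement* (everyone at the scale
midpoint); `M = hi - lo + 1` is perfect measurement with
$\sigma_c^2 = 0$. The percentage reduction relative to non-measurement can be
negative: a dichotomy applied to a distribution tightly concentrated on the
cut places everyone ~25 scale units from the truth, far worse than simply
assigning the overall midpoint.

### Scale conventions

`make_scale(M, lo, hi)` divides the continuous range `[lo, hi]` into `M`
equal parts; an integer falling exactly on an interior cut belongs to the
category above. Midpoints follow a mixed convention chosen to match the
reference variance tables this package reproduces:

* when **every** interior cut is representable at the scale's half-unit
  resolution (M = 1, 2, 3 on 0–99), the midpoint is half-way from the
  category's first integer to the next cut, the last category ending at
  `hi`. The dichotomy thus reads "0 to 49.5" and "50 to 99", midpoints 24.75
  and 74.5 — the asymmetric convention of the underlying methodology — and
  thirds read "0 to 33", "33 to 66", "66 to 99", midpoints 16.5, 49.5, 82.5;
* otherwise the midpoint of the category's integer range is used, so
  equal-block scales (5 or 10 categories on 0–99) get the ordinary midpoints
  9.5, 29.5, … and 4.5, 14.5, ….

Under this convention the uniform-outcome column of the reference table is
exact: 833.25, 208.28 (75.0%), 92.73 (88.8%), 33.25 (96.0%), 8.25 (99.0%), 0.
`midpoint = "mean"` switches to exact within-category integer means (the
least-squares midpoints), under which the dichotomy gives 208.25 instead —
useful for sensitivity analysis of the convention itself.

```{r}
u <- uniform_distribution()
vapply(c(1, 2, 3, 5, 10, 100),
       function(M) categorisation_variance(u, make_scale(M))$sigma_c_sq,
       numeric(1))
```

*Known limitation*: the reference table's 8- and 15-category uniform cells
(13.06, 5.46) are not reproduced by any near-equal partition under either
midpoint convention (near-equal blocks give 13.00 and 3.68); the original
boundary tables for those scales were evidently unequal in a way that is not
documented in the material available to us. No package result depends on
those two cells, and the monotone decrease of $\sigma_c^2$ in `M` holds
throughout.

### Outcome distributions and discretisation

Two outcome families are built in: the discrete uniform, and the
*constrained discrete normal* — a normal with mean `mu` (default 49.5) and SD
`sigma`, truncated to `[lo, hi]` and discretised so that integer `k` owns the
truncated mass of `[k - 0.5, k + 0.5]` clipped to the range (the edge
integers own half-width bins), renormalised. The clipping convention was
selected because it reproduces every reference non-measurement variance to
within 0.03% — at SD 5 the value is Sheppard's $\sigma^2 + 1/12 = 25.08$, at
SD 25 heavy truncation gives 479.08 — whereas binning over the wider range
`[lo - 0.5, hi + 0.5]` misses the SD-25 value by ~1%.
`method = "simulate"` (draw, keep in-range, round, tabulate) is the
Monte-Carlo version of the same construction, provided for sensitivity
checks.

## Sample size, effective variance and the decision rule

The two-arm normal-approximation sample size is
$n = F(\sigma_1^2 + \sigma_2^2)/d^2$ per arm with
$F = (z_{1-\alpha/2} + z_{1-\beta})^2$; no t-correction is applied, matching
the large-trial setting (`required_n()` returns the real value; `ceil` is an
option so the analytic rule below stays exact).

A cheap measure inflates the variance entering that formula in two ways.
Categorisation adds $\sigma_c^2$. Imperfect concurrent validity `r` is
modelled, by default, through the classical error model
$\hat y = y + e$: the error variance that makes
$\mathrm{cor}(\hat y, y) = r$ is $\sigma^2(1 - r^2)/r^2$, so

$$\sigma^2_{\text{eff}} = \sigma^2 + \sigma_c^2 + \sigma^2\frac{1 - r^2}{r^2}.$$

An alternative `mode = "attenuation"` treats low validity as shrinking the
detectable effect ($d \to r d$), equivalent to
$(\sigma^2 + \sigma_c^2)/r^2$; the two coincide when $\sigma_c^2 = 0$. The
choice is exposed because validation studies report `r` without fixing the
error mechanism; the default is the standard classical-error reading.

Since total measurement cost is $2 n c$ per measure and $n$ is proportional
to effective variance, the cheap measure is more cost-effective **iff**

$$\frac{\sigma^2_{\text{eff,cheap}}}{\sigma^2_{\text{eff,gold}}}
  \;<\; \frac{c_{\text{gold}}}{c_{\text{cheap}}},$$

i.e. the relative variance increase is smaller than the relative cost
increase. `decide_measure()` computes both sides and the total costs; ties
resolve to the gold standard, which carries less information-bias risk. With
unrounded sample sizes the inequality agrees with direct total-cost
comparison *exactly* — the test suite checks 1,000 random scenarios.

## Participant burden and response

Randomised questionnaire-length trials (each randomising participants to a
longer or shorter questionnaire) provide a log odds ratio of response
$y_i = \log \mathrm{OR}_i$ with sampling variance $v_i$ equal to the sum of
reciprocal cell counts (+0.5 to all four cells of any trial containing a
zero — the standard continuity correction; the source data convention is not
recorded). `fit_burden_meta()` fits

$$y_i = a + b \log \mathrm{RQ}_i + u_i + e_i, \qquad u_i \sim N(0, \tau^2),$$

by inverse-variance weighting with an additive random effect,
$w_i = 1/(v_i + \tau^2)$, $\tau^2$ estimated by REML. The fitting engine is
`metafor::rma()`, the standard random-effects meta-regression implementation;
the suite cross-checks it against the noiseless and equal-weight limits
rather than against itself. The "percentage of heterogeneity explained" is
reported as the proportional reduction in $\tau^2$ against the
intercept-only model — one of several pseudo-$R^2$ conventions, flagged as
such. An optional quadratic term in $\log \mathrm{RQ}$ can be fitted for
curvature checks; it is reported, never auto-selected.

On the natural scale the fitted model is a power law
$\mathrm{OR} = \mathrm{RQ}^{b}$. At the canonical estimate $b = -0.594$,
doubling a questionnaire's length multiplies response odds by
$2^{-0.594} \approx 0.663$ — about a one-third drop in response, hence
roughly $1/0.663 \approx 1.51$ times as many people approached for the same
number of observations.

### The synthetic trial generator

`synth_burden_trials()` generates length trials on this model: log length
ratios uniform on `log(1.25)`–`log(4)`, a short-arm response probability of
0.7, 200 participants per arm, and $\tau = 0.25$ — a few dozen modest postal
trials with length ratios up to fourfold, matching the character of the
published trial pool. It emulates *only* the length–response mechanism:
real trial sets also vary in topic, mode of administration, incentives and
population, sources of heterogeneity that here are all absorbed into the
single additive $u_i$. Parameter-recovery results on these data therefore
show the estimator is correct under its own model, not that the power law is
true of any particular literature. The suite checks (500 replicates, 40
trials each) that the mean fitted slope is within ±0.03 of truth and the 95%
CI covers it 90–98% of the time.

## The cost-ratio simulation

`run_cost_simulation()` sweeps population SD 0.5–25 (step 0.5; 0 is excluded
as degenerate) for cheap scales with 3, 5, 8, 10, 15 categories against a
100-level gold standard, under the reference scenario: α = 0.05, power 0.9,
d = 0.1, cheap validity r = 0.7, unit costs 50 and 5. Everything is analytic
— no sampling — so runs are byte-identical.

Choices the methodology leaves open, and what this package does:

* **Length proxy.** Burden is measured in items: a cheap measure with `M`
  categories counts as `M` items, the gold standard as its 100 levels. The
  proxy is configurable (`gold_levels`), since a gold standard's "length" is
  inherently somewhat arbitrary.
* **Response anchoring.** The shortest instrument in the scenario is
  anchored at `baseline_response_p = 0.97` — simple instruments in large
  simple trials achieve near-complete follow-up — and every other
  instrument's response is scaled by $\mathrm{RQ}^{-0.594}$ relative to it.
* **Rate vs odds scale.** The power law was *estimated* on the odds scale,
  but its operational summary — "double the burden, lose a third of
  responses, approach 50% more people" — is a statement about response
  rates, and the corresponding recruitment-inflation curve is
  $\mathrm{RQ}^{0.594}$ on the rate scale. The simulator therefore applies
  the multiplier to the response rate by default
  (`response_scale = "rate"`). This matters: near a baseline of 0.97 an
  odds multiplier barely moves the probability, and the non-response penalty
  would then never reverse the ordering of scale lengths. The odds-scale
  bridge (`apply_to_rate()`) is available via `response_scale = "odds"`.
* **Costing lost participants.** By default every recruited participant is
  billed at the full unit cost whether or not they respond
  (`lost_cost_equals_followed = TRUE`); recruitment is inflated by the
  reciprocal response probability. Sample sizes and recruitment are kept
  real-valued so the curves are smooth and the cost identity
  `total = 2 × recruited × unit_cost` holds exactly.

The qualitative surface this produces: without the non-response penalty,
cheap measures beat the gold standard once the population SD exceeds a small
threshold (around 1 for scales with a central category; nearer 3 for even
scales, whose two middle categories straddle a concentrated outcome), and
finer scales dominate coarser ones. With the penalty on, the ordering
reverses — the shortest scale wins everywhere on the default grid, and the
gold standard (100 items ⇒ response ≈ 0.12 from a 0.97 anchor) is beaten by
a wide margin.

```{r, fig.width = 7, fig.height = 4.5}
curves <- run_cost_simulation(simulation_config(include_nonresponse = TRUE))
plot_cost_curves(curves)
```

## Numerical and testing notes

* Cut points are snapped to the half-integer grid within 1e−9 to keep
  floating-point division from perturbing category assignment.
* PMFs are validated to sum to 1 within 1e−12 after renormalisation.
* Analytic $\sigma_c^2$ values are cross-checked against a Monte-Carlo
  oracle (10⁶ draws, 3-standard-error band); `required_n()` against a
  binary search over simulated z-test power; the meta-regression against
  ordinary least squares in the negligible-sampling-variance limit.
* Problem sizes in the test suite — 10⁶-draw oracles, 500 meta-regression
  replicates of 40 trials, the full 250-cell simulation grid — run in well
  under a minute in total.

## Limitations

Only non-differential (classical) measurement error is modelled; calibration
error, differential error and multidimensional outcomes are out of scope, as
are unequal randomisation, non-continuous endpoints and formal
health-economic modelling. The decision rule compares *measurement* costs
only. The 8- and 15-category reference cells, and the exact provenance of
the original trial-level burden dataset, are unresolved as described above;
reproducing the canonical −0.594 slope exactly requires that original trial
table, which is not redistributed here.
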