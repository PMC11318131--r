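# noisymeasures

Large simple trials enrol thousands of participants, so the cost of measuring
the outcome on each of them dominates the follow-up budget. A detailed
"gold-standard" assessment (a clinician visit, a long validated instrument)
may cost ten times as much per participant as a short questionnaire — but the
short questionnaire is noisier: it categorises a continuous outcome into a
handful of levels and it correlates imperfectly with the gold standard.
`noisymeasures` provides the quantitative machinery for deciding when the
cheap-but-noisy option is the better buy.

## What it computes

**Variance from outcome categorisation.** For an outcome `y` on an integer
scale (by default 0–99) measured by assigning each participant the midpoint
`ȳ_m` of their outcome category,

    σ_c² = Σ_m Σ_{k ∈ m} p(k) (k − ȳ_m)²

is the variance added by categorisation. With a single category (no
measurement at all, everyone at the scale midpoint) this is the *variance of
non-measurement*; a scale with only 5 categories already removes 96% of it
for a uniformly distributed outcome.

**The cost-effectiveness rule.** With a two-arm sample size
`n = F(σ₁² + σ₂²)/d²`, `F = (z₁₋α/₂ + z₁₋β)²`, total measurement cost is
proportional to (effective variance) × (unit cost). The cheap measure
therefore wins exactly when its relative increase in effective variance —
population variance plus categorisation variance plus the classical-error
variance `σ²(1−r²)/r²` implied by its concurrent validity `r` — is smaller
than the gold standard's relative increase in unit cost.

**The participant-burden power law.** A random-effects log–log
meta-regression of the odds ratio of responding on the questionnaire length
ratio gives `OR = RQ^slope`. At the canonical slope −0.594, doubling the
length multiplies response odds by 2^−0.594 ≈ 0.663 — roughly a one-third
drop in response, i.e. about 50% more people must be approached for the same
number of observations.

**The cost-ratio simulation.** Puts the three pieces together: cheap:gold
total-cost ratios over a grid of population SDs for scales with 3, 5, 8, 10
and 15 categories, with and without the non-response penalty.

## Worked example

```r
library(noisymeasures)

# A 5-category scale keeps 96% of the information in a uniform 0-99 outcome
categorisation_variance(uniform_distribution(), make_scale(5))
#> Variance from categorisation (5 categories, uniform)
#>   sigma_c^2          = 33.25
#>   non-measurement    = 833.25
#>   reduction          = 96.0%

# Should a trial detecting d = 0.1 on a normal outcome (SD 10) pay 50/unit
# for the gold standard, or 5/unit for a 5-category questionnaire (r = 0.7)?
dist  <- constrained_normal_distribution(10)
sc2   <- categorisation_variance(dist, make_scale(5))$sigma_c_sq  # 32.96
des   <- trial_design(alpha = 0.05, power = 0.9, d = 0.1, sd1 = 10)
decide_measure(des, gold = measure_spec(50),
               cheap = measure_spec(5, validity_r = 0.7,
                                    sigma_c_sq = sc2, length_items = 5))
#> Cost-effectiveness decision
#>   n per arm        gold: 210148.5   cheap: 498141.2
#>   total cost       gold: 21014846   cheap: 4981412
#>   variance ratio (cheap:gold): 2.370425
#>   unit-cost ratio (gold:cheap): 10
#>   cheap measure is more cost-effective
```

The cheap questionnaire needs 2.37× the sample size but costs 10× less per
participant, so the trial is powered for about a quarter of the money.

```r
# Recover the burden power law from synthetic questionnaire-length trials
fit <- fit_burden_meta(synth_burden_trials(40, seed = 7))
fit
#> Random-effects log-log meta-regression (k = 40 trials)
#>   slope     -0.5184 (SE 0.1424, 95% CI -0.7975 to -0.2393)
#>   intercept 0.0090 (SE 0.1253)
#>   tau^2     0.0643 (intercept-only: 0.0990); heterogeneity explained: 35.0%

# Full simulation surface (Fig-2-style curves)
curves <- run_cost_simulation(simulation_config(include_nonresponse = TRUE))
plot_cost_curves(curves)
```

A command-line front end with `table1`, `decide`, `metareg`, `synth-trials`
and `simulate` subcommands is installed at
`system.file("cli", "noisy-measures", package = "noisymeasures")`.

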