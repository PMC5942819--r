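# selfexcite

Detecting contagion in discrete-day event series with unbinned likelihood
methods.

Many event phenomena in the life and social sciences — disease clusters,
violent incidents, behavioral cascades — are suspected of being
*self-exciting*: each event temporarily raises the probability of another
one in the following days. Analysts often probe such data with coarsely
binned summaries (how many inter-event gaps fall within two weeks? do the
mean and variance match a uniform-in-time null?). Those summaries discard
nearly all information about the *shape* of the inter-event distribution,
and two models with visibly different shapes can agree on every one of
them. `selfexcite` implements both approaches side by side so the
difference in statistical power can be measured, not argued.

## The model

Events are recorded at day resolution. An event on day `t_i` raises the
expected count on a later day `t_j` by the exponential kernel integrated
over that day,

    P(t_j | t_i, T_excite) = exp(-(t_j - t_i - 1)/T_excite)
                           - exp(-(t_j - t_i)/T_excite),

which sums to 1 over all later days. The conditional intensity on day `t_n`
is

    N_exp(t_n) = N_0(t_n) + N_secondary * sum_{t_i < t_n} P(t_n | t_i, T_excite),

where `N_0(t)` is a baseline rate (constant, or a running mean of the data,
optionally weighted by day of week) and `N_secondary` is the branching
ratio: the mean number of secondary events incited per event. The
parameters are estimated by minimizing the unbinned Poisson negative
log-likelihood

    -log L = sum_i [ N_exp(t_i) - N_i_obs * log N_exp(t_i) ]

over every day of the span — zero-count days included — subject to the
constraint that the total expected equals the total observed (a Negative
Binomial likelihood is available for over-dispersed data). The no-contagion
null (`N_exp = N_0`) is nested, so the Wilks likelihood ratio test (df 2)
and AIC compare the hypotheses; profile likelihood gives confidence
intervals.

The package also ships forward Monte Carlo simulators for both hypotheses,
the coarse binned/moment tests (two-bin cutoff fraction Z test, one-sample
t test of the gap mean, chi-square test of the gap variance), and a power
harness that runs all of them on simulated data.

## Worked example

Simulate eight years of contagious events (expected 232 events,
`N_secondary = 0.28`, `T_excite = 13` days), then fit both models:

```r
library(selfexcite)

cfg <- sim_config()              # 2922 days, 232 events, (0.28, 13)
es  <- simulate_contagion(cfg, seed = 42)
dc  <- to_daily_counts(es)

alt  <- fit_contagion(dc)
null <- fit_null(dc)
alt
#> fit_result (contagion model, poisson likelihood)
#>   n_secondary = 0.3224, t_excite = 8.140 days
#>   -logL = 831.1646  (2 free parameters, converged)
lrt(null, alt)
#> likelihood ratio test: stat = 22.3700 (df 2), p = 1.388e-05
#>   -logL null 842.3496 vs alt 831.1646;  AIC null 1684.70 vs alt 1666.33
profile_ci(dc, baseline_spec("constant"), alt, "n_secondary")
#> $lower [1] 0.157  $upper [1] 0.507  ...
```

The fitted branching ratio (0.32, 95% CI [0.16, 0.51]) covers the planted
0.28, and the likelihood ratio test rejects the no-contagion null
decisively. The coarse summaries on the same realization cannot: the
two-bin 14-day fraction and the gap mean are statistically consistent with
the uniform null, which is precisely the power gap the package quantifies
(`power_study()` puts the unbinned LRT's power near 0.8 at this effect
size, against about 0.1 for the two-bin test).

A shell entry point is installed as `exec/selfexcite` with `simulate`,
`fit`, `power`, and `gapstats` subcommands, e.g.

```sh
selfexcite simulate --model null --events 232 --span-days 2922 \
    --reps 1000 --seed 1 --out ensemble.json
selfexcite fit --input events.csv --out fit.json
```

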