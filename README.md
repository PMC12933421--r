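# evactwin

Agent-based digital-twin simulation of theory-driven crisis messaging for
hurricane evacuation, with the accompanying statistical analysis layer.

Crisis communicators need to know which message framing — a fear appeal, an
efficacy cue, a social-norm cue, or a combination — best moves people to
evacuate, but field experiments during hurricanes are slow, confounded and
ethically constrained. `evactwin` provides a controlled in-silico testbed:
a zoned synthetic population whose agents carry belief constructs from the
Extended Parallel Process Model (EPPM) and the Theory of Planned Behavior
(TPB), a deterministic Message Assessment Framework (MAF) that maps each of
sixteen catalogued messages onto belief activations, and a transparent
evacuation decision rule. It is aimed at crisis-communication researchers
and emergency-management analysts who want to pre-test message framings
before field deployment.

## The model

Each agent holds five beliefs on [0, 1] — severity, susceptibility,
self-efficacy, response efficacy, subjective norm — initialized from its
demographic and geospatial profile with seeded Beta noise. A message adds
its framing's construct deltas (fear → threat components, efficacy →
efficacy components, norm → subjective norm), after which the agent
computes

    P(evacuate) = σ(α·T + β·E + γ·N − δ·C − c₀)

with T, E the means of their two parent beliefs, N the subjective norm and
C a weighted constraint score (mobility, vehicle access, finances, pets,
caregiving). An EPPM appraisal gate intervenes first: high threat with low
efficacy sends the agent into *fear control* (no action regardless of
propensity); otherwise the agent is in *danger control* and evacuates when
the propensity reaches the threshold τ. The decision step is deterministic;
all variability comes from agent heterogeneity and replication redraws.

The experiment protocol runs 16 message conditions × 222 agents (one
condition with 220) × 10 replications with per-replication seeds derived by
a stable hash, memory reset between conditions, and replication-averaged
integer counts — 3,550 aggregated agent-observations per experiment.

The statistics layer reproduces the analysis of such experiments:
Pearson chi-square with adjusted standardized residuals, pooled compliance
rates by framing, grouped logistic regression odds ratios against control
(with the saturated-model cross-product identity asserted), and noncentral
chi-square power computation. See the methods vignette
(`vignettes/evactwin-methods.Rmd`) for the full model account, the
calibration of the shipped decision weights, and known limitations.

## Worked example

Analyze the bundled reference counts of the sixteen-condition experiment:

```r
library(evactwin)
tab <- reference_counts()

chi <- chi_square_test(tab)
sprintf("chi2 = %.1f, df = %d, p = %.2g", chi$statistic, chi$df, chi$p_value)
#> "chi2 = 323.2, df = 15, p = 8.1e-60"

framing_rates(tab)
#>              framing n_agents evacuated rate_pct
#> 1            control      222         2    0.901
#> 2               fear      666         6    0.901
#> 3           efficacy      666         8    1.201
#> 4               norm      666         6    0.901
#> 5      fear_efficacy      666        82   12.312
#> 6 fear_efficacy_norm      664       102   15.361

fit <- fit_grouped_logistic(tab)
fit$estimates[, 1:5]
#>              framing odds_ratio ci_low ci_high  p_value
#> 1               fear       1.00  0.200    4.99 1.00e+00
#> 2           efficacy       1.34  0.282    6.35 7.14e-01
#> 3               norm       1.00  0.200    4.99 1.00e+00
#> 4      fear_efficacy      15.45  3.766   63.34 1.44e-04
#> 5 fear_efficacy_norm      19.96  4.884   81.62 3.08e-05
```

Evacuation compliance differs strongly across conditions (the chi-square is
far beyond its df = 15 reference), and the odds of evacuating under a
combined fear+efficacy message are about 15 times the control odds
(baseline odds `fit$baseline_odds` = 0.0091), while single-cue framings are
indistinguishable from control.

Run the full simulated experiment under the shipped calibration and analyze
it the same way:

```r
res <- run_experiment(default_design(master_seed = 42))
framing_rates(build_table(res))
#>              framing n_agents evacuated rate_pct
#> 1            control      222         2    0.901
#> 2               fear      666         9    1.351
#> 3           efficacy      666         9    1.351
#> 4      fear_efficacy      666        90   13.514
#> 5               norm      666         8    1.201
#> 6 fear_efficacy_norm      664        87   13.102
```

The simulator reproduces the qualitative pattern: single-cue framings stay
at control level while combined framings evacuate more than ten times as
many agents. The a-priori power computation behind the per-condition size:

```r
required_sample_size(w = 0.3, alpha = 0.05, power = 0.95, df = 5)
#> [1] 220
```

A shell front end wraps the same functions:

```sh
Rscript inst/scripts/evactwin simulate --out runs/demo --seed 42
Rscript inst/scripts/evactwin analyze --counts runs/demo/counts.csv --out runs/demo
```

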