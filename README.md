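# matchrisk

Recurrent-event injury-risk modelling for match-exposure cohorts in
professional team sport.

Sports medicine teams record match involvements (minutes played), weekly
group training hours, and time-loss injuries for every player across
seasons. matchrisk turns those four tables into an injury-risk analysis
that respects the structure of such data: injuries recur within players,
players cluster within teams, and a player is only at risk while actually
exposed. It is aimed at sports epidemiologists and team analysts who want
to quantify how accumulated (12-month) and recent (1-month) match workloads
drive current injury risk.

## The model

Each player contributes gap intervals (entry → injury, return → next
injury, …, → exit) on a survival axis of **cumulative exposure hours**
(match minutes/60 + pro-rated team training hours). The hazard for player
*j* of team *i* is

    lambda_ij(t) = lambda_0(t) * exp( x_ij(t)' beta + u_i + v_ij ),
    u_i ~ N(0, sigma2_team),  v_ij ~ N(0, sigma2_player)

a proportional-hazards model with nested log-normal frailties, fitted by
penalized partial likelihood (Newton–Raphson over fixed effects and frailty
modes) inside a derivative-free search over the log variance components
that maximises a Laplace-approximate integrated likelihood. Time-varying
workload covariates enter in counting-process form (weekly segments with
delayed entry on the gap axis). Continuous covariates are standardized to
2-SD units so hazard ratios are comparable across predictors; effects are
classified by magnitude-based inference against smallest-worthwhile-effect
thresholds (HR 0.90 benefit / 1.11 harm); and Cox, shared-frailty and
nested-frailty fits are compared by boundary-aware likelihood-ratio tests,
AIC and BIC. A calibrated multi-team cohort simulator generates realistic
synthetic data for validation, so the entire pipeline runs without access
to proprietary club records.

## Worked example

```r
library(matchrisk)

# a synthetic 4-team cohort over two seasons (defaults emulate elite rugby)
cohort <- simulate_cohort(sim_config(n_teams = 4, players_per_team = 12,
                                     n_seasons = 2), seed = 3)
cohort
#> <cohort_bundle>
#>   players :    48 rows (48 players, 4 teams)
#>   matches :  1835 involvements
#>   training:   304 team-weeks
#>   injuries:   105 time-loss spells

# weekly counting-process risk segments with rolling workload covariates
iv <- build_intervals(cohort)
#> build_intervals: excluded 207 record(s) (14 event(s)) with zero 12-month
#> match exposure
iv <- standardize_2sd(iv, c("age_years", "one_month_fge"))
scale_report(iv)$two_sd          # original units spanned by one model unit
#> [1] 7.72 2.28

# nested frailty fit, hazard ratios per 2 SD
fit <- fit_frailty(iv, ~ age_years + position + twelve_month_matches +
                     one_month_fge, random = "team_player")
glance(fit)[c("logLik", "AIC", "sigma2_team", "sigma2_player", "n_events")]
#>   logLik   AIC sigma2_team sigma2_player n_events
#> 1 -376.6 765.1      0.1035       0.07997       91

hr_per_2sd(fit, "one_month_fge")
#>            term    hr ci_low ci_high   beta    se
#> 1 one_month_fge 0.765    0.5    1.17 -0.268 0.258

# magnitude-based inference for the acute-load term
mbi_from_fit(fit, "one_month_fge")[c("hr", "beneficial", "trivial",
                                     "harmful", "inference")]
#>      hr beneficial trivial harmful inference
#> 1 0.765         73      19       8   unclear
```

With only ~90 events in this toy four-team cohort the acute-load hazard
ratio is estimated as 0.77 per 2 SD (≈ 2.3 FGE) with a 90% interval of
0.50–1.17 spanning both thresholds: a 73% chance the effect is beneficial
but an 8% chance it is harmful — an *unclear* call at this sample size, as
it should be (the default generator's true acute effect, HR 1.14 per
2 SD, needs far more events to pin down; the package's validation suite
recovers it over 50 replicates of a 12-team, three-season cohort). The
full pipeline (exposures → intervals → fits → comparison table → MBI
table → hazard-ratio curve, plus a JSON run manifest) is available as one
call:

```r
run_pipeline(list(cohort = list(sim = list(), seed = 1)), "results/")
```

and as a thin command-line wrapper in `inst/cli/matchrisk.R`.

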