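# epvsim

Monte-Carlo evaluation of binary logistic regression at low events per
variable (EPV), for biostatisticians studying small-sample behaviour of the
logistic model and for methodologists auditing how simulation studies
detect and handle *separation*.

## What it does

The number of events per estimated coefficient, EPV, is a widely used
sample-size heuristic for logistic regression. Simulation studies of this
heuristic estimate, per scenario, the accuracy of a primary log-odds-ratio
estimate: bias `mean(b̂₁) − β₁`, relative bias, coverage and mean width of
the 90% interval, and MSE `bias² + SD(b̂₁)²`. At low EPV two phenomena mix:
finite-sample bias of maximum likelihood (systematic over-estimation away
from zero), and separation — covariates perfectly classifying events from
non-events, so no finite MLE exists and the software's output is an
artifact of its iteration rules. `epvsim` provides all the pieces:

- **Data generation** (`true_model()`, `calibrate_intercept()`,
  `sample_quota()`): logistic outcomes over normal, equicorrelated-normal
  or Bernoulli covariates, quota-sampled so every dataset has exactly the
  prescribed size `N` and event count (EPV is controlled exactly);
- **Estimators** (`fit_ml()`, `fit_firth()`, `wald_ci()`, `profile_ci()`):
  maximum likelihood with the exact IWLS semantics of `glm` (starting
  values, relative-deviance rule `|Δdev|/(|dev|+0.1) < tol`, SEs from the
  final IWLS solve) under presets `default` (1e-8, 25), `typeI` (1e-6,
  25), `typeII` (1e-10, 25), `typeIII` (1e-10, 50); and Firth's penalized
  likelihood `l*(β) = l(β) + ½·log|I(β)|` (Jeffreys prior) via modified-
  score scoring with step-halving, finite even on separated data, with
  profile penalized-likelihood intervals solving
  `2·(l*(β̂) − l*prof(β₁)) = χ²₁,₀.₉₀`;
- **Separation diagnostics** (`detect_tracing()`, `detect_threshold()`,
  `detect_nonconvergence()`, `detect_exact()`, `detect_separation()`):
  the re-estimation tracing detector (30 iteration-capped refits, flag
  when any parameter's first-iteration-scaled SE path has variance > 20),
  the `|β̂ⱼ| > log 50` rule, likelihood non-convergence, and an exact
  linear-programming classifier of complete/quasi-complete separation;
- **Studies** (`build_grid()`, `run_scenario()`, `run_study()`,
  `iib_table()`, `band_summary()`, `plot_study()`): the factorial designs
  Ia–Id, IIa, IIb (465 scenarios), handling policies `remove`,
  `keep_naive` and `replace_max` for flagged datasets, tidy summary
  tibbles, EPV-banded tables and ggplot summaries.

Everything is tibble-in/tibble-out and pipe-friendly; fitted objects have
`tidy()` and `glance()` methods.

## Worked example

One severely under-sized design: 4 events and 4 non-events, true odds
ratio 4, one standard-normal covariate.

```r
library(epvsim)

m <- true_model(log(4), prevalence = 0.5)
d <- sample_quota(m, n_total = 8, n_events = 4, seed = 7)

detect_separation(d)
#> # A tibble: 1 × 5
#>   tracing threshold nonconvergence exact scaled_variances
#> 1 FALSE   FALSE     FALSE          none  <dbl [2]>

fit_firth(d)
#> <epv_fit> FIRTH fit, 8 obs, converged in 8 iteration(s)
#>           (Intercept)     x1
#> estimate      -0.2901 0.8223
#> std.error      0.8522 0.5800

profile_ci(fit_firth(d), "x1")
#> # A tibble: 1 × 6
#>   term  estimate  lower upper level kind
#> 1 x1       0.822 0.0794  1.94   0.9 profile
```

This draw happens to overlap (`exact = none`), so all detectors agree and
the Firth estimate 0.82 shrinks the diverging-prone ML fit towards zero;
the profile interval (0.08, 1.94) excludes zero but is far from covering
the truth log 4 ≈ 1.39 tightly — exactly the imprecision low EPV buys.

Scaling up to the full single-cell study (500 replicates here):

```r
s <- build_grid("IIb")  # EPV 4, beta1 = log 4, N = 8
run_scenario(s, n_reps = 500, master_seed = 1, firth_ci = FALSE)$summaries
#>   estimator       detector policy pct_removed    bias    mse rate_tracing
#> 1        ml nonconvergence remove         8.2  9.3354 743.33        0.202
#> 2        ml        tracing remove        20.2  0.6826   5.38        0.202
#> 3        ml      threshold remove        30.6  0.0129   1.19        0.202
#> 4     firth           <NA>    all         0.0 -0.1072   1.01        0.202
```

One replicate in five is separated (`rate_tracing` 0.202 — at this design
the true separation probability is 18.9%, so the tracing flag is nearly
exact); which datasets a policy removes changes the apparent ML bias by
orders of magnitude (9.34 naive-converged vs 0.68 tracing-removed vs 0.01
threshold-removed), while Firth's correction analyses every dataset with
near-zero bias and the smallest MSE. That contrast — the handling of
separated datasets dominating the headline numbers — is the package's
reason to exist.

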