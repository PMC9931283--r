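# walkmort

Mortality-risk modelling from walking-intensity accelerometry.

Supervised walk tests (gait speed over six minutes) are strong predictors of
all-cause mortality but need an in-person visit. `walkmort` implements the
passive alternative for week-long wrist accelerometer cohorts: find the
moments when a person walks steadily for at least six minutes during daily
living, measure how *intensely* they walk, and feed that into censored
survival models.

The pipeline:

1. **Signal I/O** — 100 Hz tri-axial recordings in g (CSV or a binary
   container), segmented into non-overlapping 30-second epochs (3000 samples)
   each carrying a `walking`/`other` activity label.
2. **Steady-walking detection** — maximal runs of ≥ 12 consecutive walking
   epochs (6 minutes); participants are excluded for insufficient wear, then
   for having no qualifying session.
3. **Feature extraction** — a 76-dimensional time-domain feature vector per
   epoch (ENMO variants, deviation and shape statistics, quantiles, crossing
   rates, activity counts, cross-axis dependence, orientation angles; see
   `feature_registry()`), averaged over included epochs per participant.
4. **Survival modelling** — Cox proportional hazards with an elastic-net
   penalty (α ∈ {0, 0.5, 1}, automatic λ grid), maximizing
   `Σ_events [x'β − log Σ_{at risk} exp(x'β)] − λ(α‖β‖₁ + (1−α)/2 ‖β‖₂²)`,
   evaluated by Harrell's C-index under outcome-stratified 10-fold
   cross-validation at 1–5-year truncated horizons; greedy stepwise
   minimal-model selection, marginal feature ranking, feature-hierarchy
   clustering with lasso flags, Schoenfeld proportional-hazards diagnostics,
   98%-percentile survival curves by sex × feature tertile × age, and
   per-site concordance.
5. **Synthetic cohort generator** — labeled recordings, covariates and
   outcomes from a known ground-truth hazard on age, sex and true walking
   intensity (~2% five-year events), so every stage is testable without
   access-restricted data.

## Worked example

```r
library(walkmort)

cfg <- sim_config(n_participants = 2000, seed = 1)
cohort <- simulate_cohort(cfg, seed = 1)
cohort
#> <walk_cohort> 1774 included of 2000 participants; 32 events (1.8%)
#> exclusions: ok 1774, insufficient_wear 0, insufficient_walking 226

p <- cohort$participants
fit <- fit_penalized_cox(p, c("age", "sex", "ENMOtrunc"), lambda = 0)
coef(fit)
#>        age        sex  ENMOtrunc
#>  0.0691...  0.6...   -17.5...    # signs: older/male = higher risk,
                                   # more intense walking = lower risk

cv_demo <- cross_validate(p, c("age", "sex"), seed = 2)
cv_both <- cross_validate(p, c("age", "sex", "ENMOtrunc"), seed = 2)
c(demo = cv_demo$mean_cindex, demo_enmo = cv_both$mean_cindex)
#>      demo demo_enmo
#> 0.756     0.833      # adding walking intensity raises CV concordance
```

Numbers above are from the synthetic generator (exact values vary with seed
and R version only through the stated RNG); the coefficient on `ENMOtrunc` is
negative — higher walking intensity, lower hazard — and adding it to
demographics improves cross-validated discrimination. The whole pipeline with
reports (C-index matrix by feature set × horizon, stepwise trace, marginal
ranking, PH tests, independence curves, per-site table) runs via

```r
run_pipeline(load_run_config("config.yaml"), out_dir = "out")
```

or the CLI in `inst/cli/walkmort`
(`walkmort report --config config.yaml --out out`).

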