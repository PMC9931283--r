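---
title: "Modelling mortality risk from walking-intensity accelerometry"
author: "walkmort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling mortality risk from walking-intensity accelerometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(walkmort)
```

## The problem

Gait speed measured in a supervised walk test is one of the best-validated
functional predictors of all-cause mortality in older adults, but it requires
an in-person assessment. Week-long wrist accelerometry offers a passive
alternative: if a person walks steadily for at least six minutes at some point
during daily living, the *intensity* of that walking — how hard the
acceleration signal moves — can stand in for gait speed. walkmort implements
that idea end to end: it detects steady-walking sessions in labeled 100 Hz
tri-axial recordings, summarizes each 30-second epoch by a 76-dimensional
time-domain feature vector, aggregates features per participant, and relates
them to time-to-death with penalized Cox proportional-hazards models evaluated
by stratified cross-validated concordance.

Because national accelerometer cohorts are access-restricted, the package
ships a synthetic cohort generator with a known ground-truth hazard. Every
stage of the pipeline is therefore testable without any data download, and
parameter-recovery experiments can quantify what the pipeline does and does
not detect.

## The measurement chain

A recording is a fixed-rate stream of tri-axial acceleration in g. It is cut
into non-overlapping 30-second epochs (3000 samples at 100 Hz; a trailing
partial window is dropped, never padded), each carrying one activity label
(`walking` / `other`); the labels are trusted input, produced upstream by an
activity classifier that is out of scope here.

*Steady walking* is a maximal run of at least 12 consecutive walking epochs —
six minutes, the daily-living analogue of the Six Minute Walk Test. A single
non-walking epoch breaks a run; we take "consecutive" literally because the
alternative (gap tolerance) is unstated in the source design and strictness is
the conservative reading. All epochs of a qualifying run are included, so a
20-epoch run contributes all 20 epochs. Participants are excluded first for
insufficient wear (default: fewer than 8640 labeled epochs, i.e. 72 hours —
the usual QC convention for week-long wrist protocols; the threshold is a
`session_criteria()` argument), then for having no qualifying session.

Per epoch, `extract_epoch_features()` computes 76 features in two groups of
38 (see `feature_registry()`): ENMO variants (mean positive / absolute
deviation of the magnitude from 1 g), means, standard deviations, RMS,
deviation statistics (MAD/MPD), shape (excess kurtosis, skewness), quantiles,
ranges, total activity counts, mean- and min/max-referenced crossing rates,
cross-axis covariances/correlations, lag-1 autocorrelations, and orientation
angles of the gravity vector. Numerical conventions that matter:

* `Sd` uses the sample (n−1) denominator; `MPD` and covariances use the
  population (n) denominator — these are signal-power quantities, and this
  choice also keeps `Sd` and `MPD` distinct.
* Quantiles interpolate linearly between order statistics.
* `autocorr` is the Pearson correlation between the series and its one-sample
  shift; correlations of constant series are defined as 0, as are `kurt`,
  `skew` and `coefvariation` of a constant signal (and `coefvariation` of a
  zero-mean series).
* Crossing counts are strict: a sample exactly on the threshold level
  registers no crossing. Each series is referenced to its own epoch mean.
* Angles are in degrees; the "yaw" formula mirrors pitch/roll by symmetry in
  z — true yaw is unobservable from a static accelerometer, so this is a
  convention, not physics.

The participant-level feature vector is the element-wise mean over all
included epochs. The epoch-to-participant reduction is not pinned down in the
source design; the mean is the simplest choice consistent with treating every
steady-walking epoch as an equally informative draw of the person's walking
intensity.

## The survival model

For participant $i$ with predictor vector $x_i$, the Cox model takes the
hazard as $h_i(t) = h_0(t)\exp(x_i^\top\beta)$. The elastic-net penalized fit
maximizes

$$\sum_{i:\,\delta_i=1}\Big[x_i^\top\beta-\log\!\!\sum_{j:\,T_j\ge T_i}\!\!\exp(x_j^\top\beta)\Big]
-\lambda\Big(\alpha\lVert\beta\rVert_1+\tfrac{1-\alpha}{2}\lVert\beta\rVert_2^2\Big),$$

with Breslow handling of tied event times (ties are rare in continuous
synthetic times) and predictors standardized internally; coefficients are
reported on both scales. Mixing parameters default to
$\alpha \in \{0, 0.5, 1\}$ and the $\lambda$ grid is 100 log-spaced values
from $\lambda_{\max}$ (all penalized coefficients zero; for ridge a finite
ceiling substitutes, since $\lambda_{\max}$ is infinite at $\alpha = 0$) down
to $10^{-3}\lambda_{\max}$. All coefficients are penalized uniformly — no
exemption for demographics — because no exemption rule is stated in the
source design; the unpenalized route (`lambda = 0`) is the ordinary partial
likelihood maximizer.

Discrimination is Harrell's concordance: among comparable pairs (an event
before another subject's event or censoring time, plus tied-time pairs with
exactly one event), the fraction where the shorter-lived subject has the
higher risk score, ties in score counting one half. Evaluation uses
outcome-stratified 10-fold cross-validation — events are ~2% of subjects, so
unstratified folds would frequently hold almost no events — with per-class
fold sizes differing by at most one. Follow-up horizons of 1–5 years are
imposed by administrative truncation *before* splitting: an event after the
horizon is recoded as censored at the horizon. For a penalized run, the
$(\alpha, \lambda)$ pair with the best mean CV concordance is selected and
refit on the full table.

Minimal ("Min-Model") selection is greedy forward stepwise scored by CV
concordance (never the in-sample fit), stopping when the best increment falls
below a threshold (0.01 or 0.001 in the study design). Marginal ranking
evaluates each feature alone. The feature hierarchy clusters features by
average-linkage agglomeration on $1-|\rho|$ and flags the nonzero
coefficients of the CV-selected lasso.

Proportional hazards are checked with scaled Schoenfeld residuals
(Grambsch–Therneau scaling by the average per-event information): for each
predictor, a t-test on the Pearson correlation between the scaled residuals
and event time, with a default significance threshold of 0.001 — at national
cohort scale almost any violation is "significant", so the threshold is
deliberately strict and the residual series is returned for plotting.

The demographic-independence display reports, within sex-by-feature-tertile
strata and 5-year age bins, the first time the Kaplan–Meier estimate falls to
0.98 (the "98% percentile survival time" — the natural level for a cohort
with ~2% events), linearly interpolated between the surrounding event times;
strata that never reach the level report the horizon with a censored flag.
Per-site evaluation scores a single full-cohort model within each site by
default, with a per-site refit protocol available behind a flag, since either
reading of "computed independently per center" is defensible.

## The synthetic cohort generator

The generator emulates the study conditions: week-long recordings at 100 Hz
(20160 possible epochs), ages 45–79 uniform, 22 sites, an approximately 2%
five-year event proportion, and a ground-truth hazard on age, sex and true
walking intensity. Unstated quantities were fixed once at values a
practitioner would call realistic:

* **Walking bouts.** Per week: a Poisson(15) number of short bouts (1–11
  epochs, mean 3) and, with probability 0.9, $1+\mathrm{Pois}(1.2)$ steady
  bouts of $12+\mathrm{Geom}$ (mean 15.5, capped at 40) epochs. This gives
  ~90% of participants at least one qualifying session — so both inclusion
  branches are exercised — with a right tail in which roughly a tenth of the
  cohort accumulates half an hour or more of steady walking per week.
* **Intensity model.** True mean walking-epoch ENMOtrunc (g):
  $0.22 - 0.0025\,(\text{age}-62) + 0.01\,\text{sex} + N(0, 0.05^2)$, floored
  at 0.02. Typical walking ENMO values in wrist actigraphy sit in the
  0.1–0.4 g range, declining mildly with age.
* **Signal model.** During walking epochs the magnitude is
  $1 + \pi\,I\,\sin(2\pi f t + \phi) + N(0, 0.03^2)$ with step frequency
  $f \sim U(1.5, 2.2)$ Hz, so the expected epoch ENMOtrunc equals the true
  intensity $I$ (the positive part of a sinusoid of amplitude $A$ averages
  $A/\pi$). Axes decompose the magnitude along a gravity direction that
  drifts as a slow random walk on the unit sphere, with extra directional
  wobble while walking so per-axis and orientation features are
  non-degenerate. Non-walking epochs are low-amplitude noise about 1 g.
* **Hazard.** $\beta_{\text{age}} = 0.09$/yr (mortality roughly doubles per
  8 years in this age band), $\beta_{\text{sex}} = 0.8$ (male excess), and
  $\beta_{\text{ENMO}} = -16$/g. The intensity coefficient is calibrated so
  that the intensity effect on the linear-predictor scale,
  $|\beta|\cdot\mathrm{sd}(I) \approx 0.9$, matches the age effect
  ($0.09 \times \mathrm{sd(age)} \approx 0.9$), mirroring the study's
  marginal-ranking structure in which the top intensity feature discriminates
  nearly as well as age alone.
* **Censoring.** 5% uniform dropout on $(0, 5]$ years, the remainder
  administratively censored at 5 years. The baseline hazard is calibrated by
  root-finding so the expected event proportion over the realized linear
  predictors equals the 2% target.
* **PH violation hook.** `tv_gamma` adds a linearly time-growing log hazard
  ratio on sex (event times by inversion of the cumulative hazard), giving
  the Schoenfeld test a built-in alternative to reject.

**Two fidelities.** The raw-signal chain at cohort scale is enormous (one
week at 100 Hz is 60 million samples per participant), so
`simulate_cohort()` offers `fidelity = "signal"` — full synthesis and feature
extraction of every included epoch, used at small n to validate the
measurement chain — and `fidelity = "summary"`, which draws walking-epoch
ENMOtrunc values directly from the intensity model (plus the deterministic
sinusoid relations for companion amplitude features and independent noise
features) and is the surface for cohort-scale modelling experiments. A test
pins the two together: the signal path reproduces the configured intensity to
within a few percent across a grid.

What the generator does **not** emulate: biomechanical gait (the signal is a
noisy sinusoid, not strides), device non-wear and calibration artifacts,
label errors from the activity classifier, correlated categorical health
covariates (they are independent draws, so categorical feature sets carry no
real signal here), and any real geographic heterogeneity (sites are
homogeneous unless a frailty SD is set). Passing tests therefore demonstrate
that the machinery is correct and that known effects are recovered under
clean conditions — not that the headline discrimination of any real cohort
would be reproduced. The headline concordance numbers of the motivating study
(around 0.72–0.76) come from access-restricted data at a hundred-fold larger
scale and are deliberately not targets of this package's tests.

## Problem sizes and numerical choices

Cohort experiments default to n = 2000 with ~2% events over 5 years (about
35–40 events): large enough for stable sign recovery of all three ground-truth
coefficients and for the intensity feature to beat demographics in CV
concordance across seeds, small enough that the full experiment battery runs
on a laptop in minutes. Per-fold concordance with ~4 test-set events is noisy;
null checks therefore average over replicate cohorts. The independence-curve
check uses n = 8000 so each sex-by-tertile-by-age-bin stratum holds enough
events for a meaningful crossing time. Type-I error of the PH test is checked
at level 0.05 over a few hundred small replicates (at 0.001 a far larger
simulation would be needed to pin the rate; the check at 0.001 is an upper
bound), and power at n = 2000 against the built-in time-varying effect.

Degenerate inputs follow explicit conventions rather than NaN: constant
series yield zero dispersion/shape/correlation features; a zero epoch-mean
vector zeroes the gravity angles with a warning; fewer events than folds, no
comparable pairs, and label-count mismatches are hard errors. Every
stochastic operation takes an explicit seed (package default 45178) and all
generation is a pure function of (config, seed).

## Known limitations

* The exact closed forms of a few features (MPD, MMCR, TAC, the
  autocorrelation lag, the yaw convention) follow standard actigraphy usage
  plus the one-line published glosses; a differently-conventioned upstream
  implementation would differ by fixed rescalings.
* The mean-crossing-rate upper bound is one crossing per adjacent sample pair
  (≈100/s at 100 Hz), which is what the tests assert.
* Summary-fidelity cohorts carry only the intensity-linked features and noise
  columns; experiments about the other 70 features require the signal path.
* The stepwise and marginal procedures inherit the variance of CV
  concordance at ~2% events; at these sizes they are demonstrations of the
  machinery, not stable feature rankings.
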