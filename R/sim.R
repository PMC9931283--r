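#' @title Synthetic cohort generation
#' @description
#' The generator emulates the statistical structure of a national wrist-sensor
#' sub-study: week-long labeled tri-axial recordings with steady-walking bouts
#' of varying run length and intensity, a participant table with demographics
#' and categorical health features, and survival outcomes driven by a known
#' ground-truth Cox hazard on age, sex and true walking intensity. Every
#' generation function is a pure function of its `(sim_config, seed)` inputs.
#' @name synthetic_cohort
NULL

#' Simulate participant profiles
#'
#' Demographics (age uniform over the configured range; sex balanced; race
#' with a 94% majority class, encoded 0), site assignment (multinomial over
#' `site_count` sites), true walking intensity from the intensity model, and
#' the categorical health features: 7 advanced disease conditions (ADC) and
#' 10 modifiable risk factors (MRF), encoded 1 = bad health / 0 = good health
#' (ordinal fields keep ordered integer codes).
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (default `config$seed`).
#' @return Data frame with one row per participant.
#' @export
simulate_profiles <- function(config, seed = config$seed) {
  n <- config$n_participants
  im <- config$intensity_model
  with_seed(seed, {
    age <- stats::runif(n, config$age_range[1], config$age_range[2])
    sex <- stats::rbinom(n, 1, 0.5)
    race <- stats::rbinom(n, 1, 0.06)
    site <- sample.int(config$site_count, n, replace = TRUE)
    ti <- pmax(im$floor,
               im$intercept + im$age_slope * (age - 62) +
                 im$sex_effect * sex + stats::rnorm(n, 0, im$sd))
    adc <- data.frame(
      CVD = stats::rbinom(n, 1, 0.08),
      Pulmonary = stats::rbinom(n, 1, 0.04),
      Cancer = stats::rbinom(n, 1, 0.06),
      Diabetes = stats::rbinom(n, 1, 0.05),
      Operation = stats::rbinom(n, 1, 0.15),
      HospitalAdmissions = stats::rbinom(n, 1, 0.10),
      Falls = stats::rbinom(n, 1, 0.08)
    )
    mrf <- data.frame(
      Hypertension = stats::rbinom(n, 1, 0.25),
      Cholesterol = stats::rbinom(n, 1, 0.20),
      Obesity = stats::rbinom(n, 1, 0.22),
      Medications = stats::rbinom(n, 1, 0.12),
      Alcohol = sample(0:5, n, replace = TRUE),
      Smoking = stats::rbinom(n, 1, 0.10),
      Stress = stats::rbinom(n, 1, 0.15),
      Health = sample(0:3, n, replace = TRUE,
                      prob = c(0.25, 0.45, 0.22, 0.08)),
      Education = stats::rbinom(n, 1, 0.3),
      Income = sample(0:4, n, replace = TRUE)
    )
    cbind(
      data.frame(id = sprintf("P%05d", seq_len(n)), age = age, sex = sex,
                 race = race, site = site, true_intensity = ti,
                 stringsAsFactors = FALSE),
      adc, mrf
    )
  })
}

#' Names of the categorical feature groups
#'
#' @return Named list of column-name vectors: `demo` (3), `adc` (7),
#'   `mrf` (10).
#' @export
covariate_groups <- function() {
  list(demo = c("age", "sex", "race"),
       adc = c("CVD", "Pulmonary", "Cancer", "Diabetes", "Operation",
               "HospitalAdmissions", "Falls"),
       mrf = c("Hypertension", "Cholesterol", "Obesity", "Medications",
               "Alcohol", "Smoking", "Stress", "Health", "Education",
               "Income"))
}

# draw one participant's walking-bout run lengths (epochs)
draw_bout_lengths <- function(bd) {
  n_short <- stats::rpois(1, bd$n_short_mean)
  short <- pmin(1L + stats::rpois(n_short, bd$short_mean - 1), 11L)
  n_long <- if (stats::runif(1) < bd$p_any_long) {
    1L + stats::rpois(1, bd$n_long_extra_mean)
  } else {
    0L
  }
  long <- if (n_long > 0) {
    pmin(12L + stats::rgeom(n_long, 1 / (bd$long_mean_extra + 1)), bd$long_cap)
  } else {
    integer()
  }
  as.integer(sample(c(short, long)))
}

#' Simulate an epoch label sequence
#'
#' Draws walking bouts (run lengths from the configured mixture) and separates
#' them with non-walking gaps of at least one epoch, so every bout is a
#' maximal run. The sequence has one label per complete epoch of the
#' configured recording length.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return Character vector over `{"walking", "other"}`.
#' @export
simulate_labels <- function(config, seed = config$seed) {
  n_ep <- n_epochs_per_recording(config)
  with_seed(seed, {
    lens <- draw_bout_lengths(config$bout_dist)
    # drop bouts that cannot fit with 1-epoch separating gaps
    while (length(lens) && sum(lens) + length(lens) + 1L > n_ep) {
      lens <- lens[-length(lens)]
    }
    labels <- rep("other", n_ep)
    if (length(lens)) {
      k <- length(lens)
      spare <- n_ep - sum(lens) - (k + 1L)
      # distribute spare non-walking epochs over the k+1 gaps
      extra <- if (spare > 0) {
        tabulate(sample.int(k + 1L, spare, replace = TRUE), nbins = k + 1L)
      } else {
        integer(k + 1L)
      }
      gaps <- 1L + extra
      pos <- 1L
      for (j in seq_len(k)) {
        pos <- pos + gaps[j]
        labels[pos:(pos + lens[j] - 1L)] <- "walking"
        pos <- pos + lens[j]
      }
    }
    labels
  })
}

#' Simulate a raw tri-axial recording
#'
#' Builds the 100 Hz signal for one participant. The magnitude is 1 g plus,
#' during walking epochs, a quasi-periodic component at a step frequency
#' drawn from `step_freq_range` whose amplitude is `pi * true_intensity` (so
#' the expected walking-epoch ENMOtrunc equals `true_intensity`), plus
#' Gaussian noise. Axes decompose the magnitude along a randomly oriented
#' gravity direction that drifts as a slow random walk on the unit sphere,
#' with extra directional wobble during walking.
#'
#' @param profile One-row data frame (or list) with at least `age`, `sex` and
#'   `true_intensity > 0` (0 allowed for a stationary-device reference).
#' @param config A [sim_config()].
#' @param labels Optional label sequence (defaults to [simulate_labels()]
#'   with the same seed).
#' @param seed Integer seed.
#' @return List with `recording` (a `raw_recording`) and `labels`.
#' @export
simulate_recording <- function(profile, config, labels = NULL,
                               seed = config$seed) {
  if (is.null(profile$true_intensity) || profile$true_intensity < 0) {
    stop("profile must carry true_intensity >= 0")
  }
  if (is.null(labels)) labels <- simulate_labels(config, seed = seed)
  rate <- config$sampling_rate_hz
  per <- as.integer(rate * 30)
  n <- length(labels) * per
  amp <- pi * profile$true_intensity
  with_seed(seed + 1L, {
    # magnitude series
    tt <- (seq_len(per) - 1L) / rate
    mag <- rep(1, n)
    walk_idx <- which(labels == "walking")
    for (i in walk_idx) {
      f <- stats::runif(1, config$step_freq_range[1], config$step_freq_range[2])
      phi <- stats::runif(1, 0, 2 * pi)
      rows <- ((i - 1L) * per + 1L):(i * per)
      mag[rows] <- 1 + amp * sin(2 * pi * f * tt + phi) +
        if (config$walk_noise_sd > 0) {
          stats::rnorm(per, 0, config$walk_noise_sd)
        } else 0
    }
    rest_rows <- which(rep(labels, each = per) == "other")
    if (length(rest_rows) && config$rest_noise_sd > 0) {
      mag[rest_rows] <- mag[rest_rows] +
        stats::rnorm(length(rest_rows), 0, config$rest_noise_sd)
    }
    # slowly drifting gravity direction (random walk on the sphere)
    g0 <- stats::rnorm(3)
    g0 <- g0 / sqrt(sum(g0^2))
    drift <- matrix(stats::rnorm(n * 3, 0, 2e-4), ncol = 3)
    dir_raw <- sweep(apply(drift, 2, cumsum), 2, g0, "+")
    # directional wobble during walking (gait sway)
    if (length(walk_idx)) {
      wrows <- which(rep(labels, each = per) == "walking")
      dir_raw[wrows, ] <- dir_raw[wrows, ] +
        matrix(stats::rnorm(length(wrows) * 3, 0, 0.05), ncol = 3)
    }
    norms <- sqrt(rowSums(dir_raw^2))
    norms[norms == 0] <- 1
    samples <- dir_raw / norms * mag
    list(recording = new_raw_recording(samples, rate), labels = labels)
  })
}

# expected event proportion under rate lambda, admin horizon Y, uniform
# dropout fraction d on (0, Y]
expected_event_prop <- function(lambda, horizon, dropout_frac) {
  if (horizon <= 0) return(rep(0, length(lambda)))
  p_admin <- 1 - exp(-lambda * horizon)
  p_drop <- 1 - p_admin / (lambda * horizon)
  mean((1 - dropout_frac) * p_admin + dropout_frac * p_drop)
}

#' Simulate survival outcomes with known ground truth
#'
#' Event times are exponential with rate `h0 * exp(lp)` where the linear
#' predictor is `beta_age * (age - 62) + beta_sex * sex +
#' beta_enmo * (true_intensity - intensity intercept)` (plus optional site
#' frailty). When `event_rate_target` is set and no time-varying effect is
#' active, `h0` is calibrated so the expected event proportion over the
#' realized linear predictors equals the target. Censoring is the minimum of
#' uniform dropout (fraction `dropout_frac` on `(0, horizon]`) and
#' administrative censoring at the horizon.
#'
#' With `tv_gamma != 0` the sex covariate gets a linearly time-growing log
#' hazard ratio `beta_sex + tv_gamma * t` (for proportional-hazards
#' diagnostics); event times then come from inverting the cumulative hazard,
#' and `baseline_hazard` is used as-is.
#'
#' @param profiles Data frame from [simulate_profiles()] (needs `age`, `sex`,
#'   `true_intensity`, and `site` if site frailty is active).
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return Data frame with `id`, `time` (observed years, > 0 unless the
#'   horizon is 0), `event` (0/1), `true_event_time`, `censor_time`,
#'   `linear_predictor` and `baseline_hazard_used`.
#' @export
simulate_survival <- function(profiles, config, seed = config$seed) {
  hc <- config$hazard_coefs
  if (!all(vapply(hc, is.finite, TRUE))) stop("hazard_coefs must be finite")
  n <- nrow(profiles)
  horizon <- config$admin_censor_years
  lp <- hc$beta_age * (profiles$age - 62) + hc$beta_sex * profiles$sex +
    hc$beta_enmo * (profiles$true_intensity - config$intensity_model$intercept)
  with_seed(seed + 2L, {
    if (config$site_frailty_sd > 0) {
      fr <- stats::rnorm(config$site_count, 0, config$site_frailty_sd)
      lp <- lp + fr[profiles$site]
    }
    h0 <- config$baseline_hazard
    if (!is.null(config$event_rate_target) && config$tv_gamma == 0 &&
        horizon > 0) {
      f <- function(log_h0) {
        expected_event_prop(exp(log_h0 + lp), horizon, config$dropout_frac) -
          config$event_rate_target
      }
      h0 <- exp(stats::uniroot(f, c(log(1e-8), log(10)))$root)
    }
    e_std <- stats::rexp(n)
    g <- config$tv_gamma * profiles$sex
    rate <- h0 * exp(lp)
    true_t <- ifelse(g == 0, e_std / rate, log1p(g * e_std / rate) / g)
    cens <- ifelse(stats::runif(n) < config$dropout_frac & horizon > 0,
                   stats::runif(n, 0, horizon), horizon)
    time <- pmin(true_t, cens)
    event <- as.integer(true_t <= cens & horizon > 0)
    data.frame(id = profiles$id, time = time, event = event,
               true_event_time = true_t, censor_time = cens,
               linear_predictor = lp, baseline_hazard_used = h0,
               stringsAsFactors = FALSE)
  })
}

# summary-fidelity participant sensor features: epoch-level walking ENMOtrunc
# draws around the true intensity, with the deterministic sinusoid relations
# for the companion amplitude features and independent noise features
summary_sensor_features <- function(profiles, n_epochs, config, n_noise = 5) {
  n <- nrow(profiles)
  enmo <- vapply(seq_len(n), function(i) {
    mean(pmax(0, stats::rnorm(n_epochs[i], profiles$true_intensity[i],
                              config$epoch_feature_sd)))
  }, 0)
  rel <- function(x, fac, sd) pmax(0, x * fac + stats::rnorm(n, 0, sd))
  out <- data.frame(
    ENMOtrunc = enmo,
    ENMOabs = rel(enmo, 2, 0.005),
    MPD = rel(enmo, pi / sqrt(2), 0.005),
    MAD = rel(enmo, 2, 0.005),
    Mean = 1 + rel(enmo, 0.1, 0.002),
    Sd = rel(enmo, pi / sqrt(2), 0.005)
  )
  for (k in seq_len(n_noise)) {
    out[[paste0("noise", k)]] <- stats::rnorm(n)
  }
  out
}

#' Simulate a full synthetic cohort
#'
#' Runs the whole generative chain: profiles, per-participant label
#' sequences, steady-walking detection and inclusion, survival outcomes, and
#' participant-level sensor features, at one of two fidelities:
#'
#' * `"summary"` (default): walking-epoch ENMOtrunc values are drawn directly
#'   from the intensity model (no raw signal synthesis), companion amplitude
#'   features follow their sinusoid-model relations, and independent noise
#'   features are appended. Suitable for cohort-scale modelling experiments.
#' * `"signal"`: every included epoch is synthesized at the full sampling
#'   rate and run through [extract_epoch_features()]; the participant feature
#'   vector is the epoch mean over all 76 registry features. Exercises the
#'   complete measurement chain; intended for small `n` and short recordings.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param fidelity `"summary"` or `"signal"`.
#' @return A `walk_cohort`: list with `participants` (included participants:
#'   demographics, categorical features, sensor features, `time`, `event`,
#'   `site`), `ground_truth` (all participants: true intensities, linear
#'   predictors, true event/censor times, inclusion status and reason),
#'   `inclusion` (tally per reason), `sensor_cols`, and `config`.
#' @export
simulate_cohort <- function(config = sim_config(), seed = config$seed,
                            fidelity = c("summary", "signal")) {
  fidelity <- match.arg(fidelity)
  profiles <- simulate_profiles(config, seed = seed)
  n <- nrow(profiles)
  crit <- session_criteria(
    min_wear_epochs = min(8640, n_epochs_per_recording(config))
  )
  seeds <- with_seed(seed, sample.int(2^30, n + 1L))
  sets <- lapply(seq_len(n), function(i) {
    session_set(simulate_labels(config, seed = seeds[i]), crit)
  })
  names(sets) <- profiles$id
  incl <- apply_inclusion(sets)
  surv <- simulate_survival(profiles, config, seed = seed)

  n_inc_epochs <- vapply(sets, function(s) length(s$included_epochs), 0L)
  inc_idx <- which(profiles$id %in% incl$included_ids)

  if (fidelity == "summary") {
    sens <- with_seed(seeds[n + 1L], {
      summary_sensor_features(profiles[inc_idx, , drop = FALSE],
                              n_inc_epochs[inc_idx], config)
    })
  } else {
    reg <- feature_registry()
    sens <- do.call(rbind, lapply(inc_idx, function(i) {
      sim <- simulate_recording(profiles[i, , drop = FALSE], config,
                                seed = seeds[i])
      eps <- segment_epochs(sim$recording, sim$labels)
      keep <- sets[[i]]$included_epochs
      fm <- do.call(rbind, lapply(eps[keep], function(e) {
        extract_epoch_features(e, registry = reg)
      }))
      t(aggregate_participant(fm))
    }))
    sens <- as.data.frame(sens)
  }

  participants <- cbind(
    profiles[inc_idx, setdiff(names(profiles), "true_intensity"),
             drop = FALSE],
    sens,
    surv[inc_idx, c("time", "event")]
  )
  rownames(participants) <- NULL
  ground_truth <- cbind(
    profiles[, c("id", "age", "sex", "race", "site", "true_intensity")],
    surv[, c("time", "event", "true_event_time", "censor_time",
             "linear_predictor")],
    included = profiles$id %in% incl$included_ids,
    reason = incl$table$exclusion_reason,
    steady_epochs = unname(n_inc_epochs)
  )
  structure(
    list(participants = participants, ground_truth = ground_truth,
         inclusion = incl$tally, sensor_cols = names(sens), config = config),
    class = "walk_cohort"
  )
}

#' @export
print.walk_cohort <- function(x, ...) {
  cat(sprintf(
    "<walk_cohort> %d included of %d participants; %d events (%.1f%%)\n",
    nrow(x$participants), nrow(x$ground_truth), sum(x$participants$event),
    100 * mean(x$participants$event)))
  cat("exclusions:",
      paste(names(x$inclusion), x$inclusion, collapse = ", "), "\n")
  invisible(x)
}
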