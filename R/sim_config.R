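#' Simulation configuration for the synthetic cohort generator
#'
#' Bundles every constant of the emulated study design: week-long wrist
#' recordings at 100 Hz, ages 45-79, an approximately 2% five-year event rate,
#' and 22 recruitment sites. All generation is a pure function of
#' `(sim_config, seed)`.
#'
#' @param n_participants Cohort size.
#' @param sampling_rate_hz Sampling rate in Hz (default 100).
#' @param recording_days Recording length in days (default 7; fractional
#'   values are allowed for short test recordings).
#' @param age_range Two-element vector of recruitment ages in years
#'   (default 45-79, uniform).
#' @param bout_dist Walking-bout run-length distribution, a list with
#'   `n_short_mean` (Poisson mean of short bouts per week), `short_mean`
#'   (mean short-bout length, epochs, capped at 11), `p_any_long`
#'   (probability a participant has any steady bout of >= 12 epochs; default
#'   0.9 so both inclusion branches are exercised), `n_long_extra_mean`
#'   (Poisson mean of additional long bouts) and `long_mean_extra` (mean
#'   epochs beyond 12, capped at `long_cap`).
#' @param intensity_model Coefficients linking demographics to the true mean
#'   walking intensity (expected walking-epoch ENMOtrunc, g):
#'   `intercept + age_slope * (age - 62) + sex_effect * sex` plus normal
#'   between-participant noise `sd`, floored at `floor`.
#' @param hazard_coefs True log-hazard coefficients:
#'   `beta_age` (per year, age centered at 62), `beta_sex` (male vs female)
#'   and `beta_enmo` (per g of true walking intensity, centered at the
#'   intensity-model intercept; negative = more intense walking, lower risk).
#' @param baseline_hazard Baseline event rate (events/year) used when
#'   `event_rate_target` is `NULL` or when a time-varying effect is active.
#' @param admin_censor_years Administrative censoring horizon (default 5).
#' @param event_rate_target Target overall event proportion by the horizon
#'   (default 0.02). When set (and `tv_gamma == 0`), the baseline hazard is
#'   calibrated so the expected event proportion over the realized linear
#'   predictors equals the target.
#' @param dropout_frac Fraction of participants censored uniformly on
#'   `(0, admin_censor_years]` instead of administratively (default 0.05).
#' @param site_count Number of assessment sites (default 22).
#' @param site_frailty_sd Standard deviation of a per-site log-normal frailty
#'   on the hazard (default 0 = homogeneous sites).
#' @param tv_gamma Time-varying effect strength on the sex covariate: the
#'   log hazard ratio for sex grows linearly as `beta_sex + tv_gamma * t`.
#'   Default 0 (proportional hazards hold exactly).
#' @param step_freq_range Walking step (cycle) frequency range in Hz.
#' @param walk_noise_sd Magnitude noise during walking epochs (g).
#' @param rest_noise_sd Magnitude noise during non-walking epochs (g).
#' @param epoch_feature_sd Epoch-to-epoch standard deviation of walking-epoch
#'   ENMOtrunc around the participant's true intensity, used by the
#'   summary-fidelity cohort path (g).
#' @param seed Default seed used when a generation function is called without
#'   one.
#' @return A `sim_config` object (validated list).
#' @export
sim_config <- function(n_participants = 500,
                       sampling_rate_hz = 100,
                       recording_days = 7,
                       age_range = c(45, 79),
                       bout_dist = list(n_short_mean = 15, short_mean = 3,
                                        p_any_long = 0.9,
                                        n_long_extra_mean = 1.2,
                                        long_mean_extra = 3.5, long_cap = 40),
                       intensity_model = list(intercept = 0.22,
                                              age_slope = -0.0025,
                                              sex_effect = 0.01,
                                              sd = 0.05, floor = 0.02),
                       hazard_coefs = list(beta_age = 0.09, beta_sex = 0.8,
                                           beta_enmo = -16),
                       baseline_hazard = 0.004,
                       admin_censor_years = 5,
                       event_rate_target = 0.02,
                       dropout_frac = 0.05,
                       site_count = 22,
                       site_frailty_sd = 0,
                       tv_gamma = 0,
                       step_freq_range = c(1.5, 2.2),
                       walk_noise_sd = 0.03,
                       rest_noise_sd = 0.01,
                       epoch_feature_sd = 0.02,
                       seed = default_seed()) {
  check_scalar(n_participants, "n_participants", lower = 1)
  check_scalar(sampling_rate_hz, "sampling_rate_hz", lower = 0,
               strict_lower = TRUE)
  check_scalar(recording_days, "recording_days", lower = 0,
               strict_lower = TRUE)
  check_scalar(baseline_hazard, "baseline_hazard", lower = 0,
               strict_lower = TRUE)
  check_scalar(admin_censor_years, "admin_censor_years", lower = 0)
  check_scalar(dropout_frac, "dropout_frac", lower = 0, upper = 1)
  check_scalar(site_count, "site_count", lower = 1)
  if (!is.null(event_rate_target)) {
    check_scalar(event_rate_target, "event_rate_target", lower = 0, upper = 1)
  }
  stopifnot(length(age_range) == 2L, age_range[1] <= age_range[2],
            length(step_freq_range) == 2L,
            all(vapply(hazard_coefs, is.finite, TRUE)))
  structure(
    list(n_participants = as.integer(n_participants),
         sampling_rate_hz = sampling_rate_hz,
         recording_days = recording_days,
         age_range = age_range,
         bout_dist = bout_dist,
         intensity_model = intensity_model,
         hazard_coefs = hazard_coefs,
         baseline_hazard = baseline_hazard,
         admin_censor_years = admin_censor_years,
         event_rate_target = event_rate_target,
         dropout_frac = dropout_frac,
         site_count = as.integer(site_count),
         site_frailty_sd = site_frailty_sd,
         tv_gamma = tv_gamma,
         step_freq_range = step_freq_range,
         walk_noise_sd = walk_noise_sd,
         rest_noise_sd = rest_noise_sd,
         epoch_feature_sd = epoch_feature_sd,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Number of complete epochs in a configured recording
#'
#' @param config A [sim_config()].
#' @param epoch_s Epoch length in seconds (default 30).
#' @return Integer epoch count (`floor(recording seconds / epoch_s)`);
#'   20160 for the default 7-day recording.
#' @export
n_epochs_per_recording <- function(config, epoch_s = 30) {
  as.integer(floor(config$recording_days * 86400 / epoch_s))
}
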