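test_that("a 7-day recording has 20160 possible epochs", {
  cfg <- sim_config()
  expect_equal(n_epochs_per_recording(cfg), 20160L)
  expect_length(simulate_labels(cfg, seed = 1), 20160L)
  # and a 30-s epoch at 100 Hz holds 3000 tri-axial samples
  prof <- list(age = 60, sex = 0, true_intensity = 0.2)
  short <- sim_config(recording_days = 60 / 86400)
  sim <- simulate_recording(prof, short, seed = 1)
  expect_equal(nrow(sim$recording$samples), 2L * 3000L)
})

test_that("generation is a pure function of (config, seed)", {
  cfg <- sim_config(recording_days = 300 / 86400)
  prof <- list(age = 55, sex = 1, true_intensity = 0.25)
  a <- simulate_recording(prof, cfg, seed = 7)
  b <- simulate_recording(prof, cfg, seed = 7)
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(a$labels, b$labels)
  c <- simulate_recording(prof, cfg, seed = 8)
  expect_false(identical(a$recording$samples, c$recording$samples))
  # full cohort determinism
  cfg2 <- sim_config(n_participants = 60)
  co1 <- simulate_cohort(cfg2, seed = 3)
  co2 <- simulate_cohort(cfg2, seed = 3)
  expect_identical(co1$participants, co2$participants)
  expect_identical(co1$ground_truth, co2$ground_truth)
})

test_that("a stationary noiseless device sits at exactly 1 g", {
  cfg <- sim_config(recording_days = 60 / 86400, walk_noise_sd = 0,
                    rest_noise_sd = 0)
  prof <- list(age = 60, sex = 0, true_intensity = 0)
  sim <- simulate_recording(prof, cfg, seed = 5)
  r <- sqrt(rowSums(sim$recording$samples^2))
  expect_lt(max(abs(r - 1)), 1e-12)
  eps <- segment_epochs(sim$recording, sim$labels)
  expect_lt(enmo_features(eps[[1]])[["ENMOtrunc"]], 1e-13)
})

test_that("with all hazard betas zero the event proportion follows the exponential CDF", {
  cfg <- sim_config(n_participants = 10000,
                    hazard_coefs = list(beta_age = 0, beta_sex = 0,
                                        beta_enmo = 0),
                    baseline_hazard = 0.05, event_rate_target = NULL,
                    dropout_frac = 0)
  pr <- simulate_profiles(cfg, seed = 21)
  sv <- simulate_survival(pr, cfg, seed = 21)
  expected <- 1 - exp(-0.05 * 5)
  expect_lt(abs(mean(sv$event) - expected),
            3 * sqrt(expected * (1 - expected) / 10000))
})

test_that("negative intensity effect makes intense walkers die less often", {
  cfg <- sim_config(n_participants = 5000, baseline_hazard = 0.05,
                    event_rate_target = NULL, dropout_frac = 0)
  pr <- simulate_profiles(cfg, seed = 31)
  pr$age <- 60; pr$sex <- 0  # fix demographics, vary only intensity
  sv <- simulate_survival(pr, cfg, seed = 31)
  rho <- cor(pr$true_intensity, sv$event, method = "spearman")
  expect_lt(rho, -0.05)
})

test_that("a zero administrative horizon censors everyone at time zero", {
  cfg <- sim_config(n_participants = 50, admin_censor_years = 0,
                    event_rate_target = NULL)
  pr <- simulate_profiles(cfg, seed = 2)
  sv <- simulate_survival(pr, cfg, seed = 2)
  expect_true(all(sv$event == 0))
  expect_true(all(sv$time == 0))
})

test_that("the default configuration hits the ~2% five-year event rate", {
  rates <- vapply(1:10, function(s) {
    cfg <- sim_config(n_participants = 5000, seed = s)
    pr <- simulate_profiles(cfg, seed = s)
    mean(simulate_survival(pr, cfg, seed = s)$event)
  }, 0)
  expect_lt(abs(mean(rates) - 0.02), 0.005)
})

test_that("walking-epoch ENMOtrunc rises with true intensity and exceeds rest", {
  cfg <- sim_config(recording_days = 600 / 86400)
  labels <- rep(c("walking", "other"), each = 10)
  mean_enmo <- function(intensity, lab_value) {
    prof <- list(age = 60, sex = 0, true_intensity = intensity)
    sim <- simulate_recording(prof, cfg, labels = labels, seed = 17)
    eps <- segment_epochs(sim$recording, labels)
    vals <- vapply(eps, function(e) enmo_features(e)[["ENMOtrunc"]], 0)
    mean(vals[labels == lab_value])
  }
  grid <- c(0.05, 0.12, 0.2, 0.3)
  walk <- vapply(grid, mean_enmo, 0, lab_value = "walking")
  expect_true(all(diff(walk) > 0))
  # the signal chain reproduces the configured intensity closely
  expect_true(all(abs(walk - grid) / grid < 0.15))
  # non-walking epochs are much quieter than walking epochs
  rest <- mean_enmo(0.2, "other")
  expect_lt(rest, walk[3] / 4)
})

test_that("bout mixture exercises both inclusion branches", {
  cfg <- sim_config()
  has_steady <- vapply(1:200, function(s) {
    runs <- find_walking_runs(simulate_labels(cfg, seed = s))
    nrow(runs) > 0 && max(runs$length) >= 12
  }, FALSE)
  # ~90% of participants should have at least one steady session
  expect_gt(mean(has_steady), 0.8)
  expect_lt(mean(has_steady), 0.97)
})
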