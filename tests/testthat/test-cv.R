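test_that("stratified folds split each outcome class to within one subject", {
  ev <- rep(c(1, 0), c(20, 80))
  f <- stratified_folds(ev, k = 10, seed = 1)
  expect_equal(unname(table(f[ev == 1])), rep(2L, 10), ignore_attr = TRUE)
  expect_equal(unname(table(f[ev == 0])), rep(8L, 10), ignore_attr = TRUE)
  # remainder rule
  ev2 <- rep(c(1, 0), c(21, 80))
  f2 <- stratified_folds(ev2, k = 10, seed = 1)
  expect_true(all(table(f2[ev2 == 1]) %in% 2:3))
  # partition: every subject in exactly one fold
  set.seed(44)
  for (k in 1:10) {
    ev3 <- rbinom(150, 1, 0.3)
    if (sum(ev3) < 10 || sum(1 - ev3) < 10) next
    f3 <- stratified_folds(ev3, k = 10, seed = k)
    expect_length(f3, 150L)
    expect_true(all(f3 %in% 1:10))
    cls <- table(f3[ev3 == 1])
    expect_lte(max(cls) - min(cls), 1L)
  }
  expect_error(stratified_folds(rep(c(1, 0), c(5, 95)), k = 10, seed = 1),
               "fewer events")
})

test_that("folds and CV results are deterministic given the seed", {
  f1 <- stratified_folds(rep(c(1, 0), c(30, 170)), seed = 9)
  f2 <- stratified_folds(rep(c(1, 0), c(30, 170)), seed = 9)
  expect_identical(f1, f2)
  expect_false(identical(f1, stratified_folds(rep(c(1, 0), c(30, 170)),
                                              seed = 10)))
  cfg <- sim_config(n_participants = 800)
  co <- simulate_cohort(cfg, seed = 5)
  a <- cross_validate(co$participants, c("age", "sex"), seed = 2)
  b <- cross_validate(co$participants, c("age", "sex"), seed = 2)
  expect_identical(a$fold_cindex, b$fold_cindex)
  expect_identical(a$mean_cindex, b$mean_cindex)
})

test_that("a pure-noise predictor cross-validates near chance", {
  # single-seed CV concordance is noisy with ~35 events, so the null check
  # averages over replicate cohorts
  cs <- vapply(1:5, function(s) {
    cfg <- sim_config(n_participants = 2000, seed = 100 + s)
    co <- simulate_cohort(cfg, seed = 100 + s)
    cross_validate(co$participants, "noise1", seed = s)$mean_cindex
  }, 0)
  expect_lt(abs(mean(cs) - 0.5), 0.05)
})

test_that("adding an informative intensity feature improves CV concordance", {
  wins <- vapply(1:10, function(s) {
    cfg <- sim_config(n_participants = 2000, seed = s)
    co <- simulate_cohort(cfg, seed = s)
    p <- co$participants
    demo <- cross_validate(p, c("age", "sex"), seed = s)$mean_cindex
    both <- cross_validate(p, c("age", "sex", "ENMOtrunc"),
                           seed = s)$mean_cindex
    both > demo
  }, FALSE)
  expect_gte(sum(wins), 9L)
})

test_that("penalized CV selects a grid point and refits on the full table", {
  cfg <- sim_config(n_participants = 1200)
  co <- simulate_cohort(cfg, seed = 13)
  cv <- cross_validate(co$participants,
                       c("age", "sex", "ENMOtrunc", "noise1", "noise2"),
                       penalty = penalty_spec(alpha = c(0.5, 1)),
                       seed = 13)
  expect_true(cv$alpha %in% c(0.5, 1))
  expect_true(cv$lambda %in% cv$cv_path$lambda)
  expect_s3_class(cv$fit, "pencox")
  expect_length(cv$fold_cindex, 10L)
  expect_equal(cv$mean_cindex, mean(cv$fold_cindex))
})

test_that("the feature-set by horizon matrix has the requested shape", {
  cfg <- sim_config(n_participants = 1500)
  co <- simulate_cohort(cfg, seed = 19)
  tab <- evaluate_feature_sets(co$participants,
                               list(demo = c("age", "sex"),
                                    enmo = "ENMOtrunc"),
                               horizons = c(3, 5), k = 5, seed = 19)
  expect_equal(dim(tab), c(2L, 3L))
  expect_equal(names(tab), c("feature_set", "Y3", "Y5"))
  expect_true(all(tab$Y5 > 0 & tab$Y5 < 1, na.rm = TRUE))
})
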