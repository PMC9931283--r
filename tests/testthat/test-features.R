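test_that("registry holds exactly 76 unique names split 38/38", {
  reg <- feature_registry()
  expect_equal(nrow(reg), 76L)
  expect_equal(anyDuplicated(reg$name), 0L)
  expect_equal(unname(table(reg$group)["biobank_time_domain"]), 38L,
               ignore_attr = TRUE)
  expect_equal(unname(table(reg$group)["derived"]), 38L, ignore_attr = TRUE)
  expect_true(all(reg$axis %in%
                    c("magnitude", "x", "y", "z", "cross-axis", "orientation")))
  # the names used in the paper-style header are present verbatim
  expect_true(all(c("ENMOtrunc", "ENMOabs", "xSd", "yMMCR", "25thp",
                    "pitchg", "avgyaw", "Covxy", "corryz") %in% reg$name))
})

test_that("ENMO features follow their closed forms on constant epochs", {
  expect_equal(enmo_features(const_epoch(0, 0, 1)),
               c(ENMOtrunc = 0, ENMOabs = 0))
  expect_equal(enmo_features(const_epoch(0, 0, 2)),
               c(ENMOtrunc = 1, ENMOabs = 1))
  expect_equal(enmo_features(const_epoch(0, 0, 0.5)),
               c(ENMOtrunc = 0, ENMOabs = 0.5))
})

test_that("moment features on constant and symmetric signals", {
  m <- moment_features(const_epoch(0, 0, 1))
  expect_equal(m[["Mean"]], 1)
  expect_equal(m[["RMS"]], 1)
  expect_equal(m[["Sd"]], 0)
  expect_equal(m[["MAD"]], 0)
  expect_equal(m[["zRange"]], 0)
  expect_equal(m[["kurt"]], 0)       # constant-signal convention
  expect_equal(m[["coefvariation"]], 0)
  # symmetric sinusoid: skewness vanishes
  ms <- moment_features(sine_epoch())
  expect_lt(abs(ms[["skew"]]), 1e-3)
})

test_that("a 2 Hz magnitude sinusoid crosses its mean 4 times per second", {
  cf <- crossing_features(sine_epoch(a = 0.1, f = 2))
  expect_equal(cf[["MCR"]], 4.0)
  cz <- crossing_features(const_epoch(0, 0, 1))
  expect_equal(cz[["MCR"]], 0)
  expect_equal(cz[["MMCR"]], 0)
  expect_equal(cz[["TAC"]], 0)
})

test_that("dependence features hit their degenerate closed forms", {
  set.seed(7)
  v <- rnorm(3000)
  ep <- cbind(v, v, rnorm(3000))
  d <- dependence_features(ep)
  expect_equal(d[["corrxy"]], 1)
  # strictly alternating series about its mean has lag-1 autocorrelation -1
  alt <- rep(c(0.8, 1.2), length.out = 3000)
  ep2 <- cbind(alt, rep(1, 3000), rep(1, 3000))
  d2 <- dependence_features(ep2)
  expect_equal(d2[["xautocorr"]], -1)
  # constant series convention
  expect_equal(d2[["yautocorr"]], 0)
  expect_equal(d2[["corrxy"]], 0)
})

test_that("orientation features match axis-aligned gravity closed forms", {
  o <- orientation_features(const_epoch(0, 0, 1))
  expect_equal(o[["pitchg"]], 0)
  expect_equal(o[["rollg"]], 0)
  expect_equal(o[["yawg"]], 90)
  expect_equal(o[["sdpitch"]], 0)
  o2 <- orientation_features(const_epoch(1, 0, 0))
  expect_equal(o2[["pitchg"]], 90)
  expect_warning(orientation_features(const_epoch(0, 0, 0)),
                 "zero epoch-mean")
})

test_that("every feature matches the direct-definition oracle on random epochs", {
  reg <- feature_registry()
  set.seed(42)
  worst <- 0
  for (k in 1:100) {
    ep <- random_epoch(sd = runif(1, 0.05, 0.5))
    got <- extract_epoch_features(ep, registry = reg)
    want <- oracle_features(ep)[reg$name]
    rel <- abs(got - want) / pmax(abs(want), 1e-8)
    worst <- max(worst, max(rel))
  }
  expect_lt(worst, 1e-10)
})

test_that("order and bound invariants hold on random epochs", {
  set.seed(11)
  for (k in 1:25) {
    fv <- extract_epoch_features(random_epoch(sd = runif(1, 0.01, 0.6)))
    expect_true(fv[["Min"]] <= fv[["25thp"]])
    expect_true(fv[["25thp"]] <= fv[["Median"]])
    expect_true(fv[["Median"]] <= fv[["75thp"]])
    expect_true(fv[["75thp"]] <= fv[["Max"]])
    expect_true(fv[["ENMOabs"]] >= fv[["ENMOtrunc"]])
    expect_true(fv[["ENMOtrunc"]] >= 0)
    expect_true(fv[["RMS"]] >= abs(fv[["Mean"]]) - 1e-12)
    expect_true(all(abs(fv[c("corrxy", "corrxz", "corryz")]) <= 1 + 1e-12))
    # at most one crossing per adjacent sample pair: (n-1)/30 per second
    expect_true(fv[["MCR"]] >= 0 && fv[["MCR"]] <= 2999 / 30)
  }
})

test_that("extract_epoch_features is deterministic, complete and finite", {
  ep <- random_epoch()
  a <- extract_epoch_features(ep)
  b <- extract_epoch_features(ep)
  expect_identical(a, b)
  expect_length(a, 76L)
  expect_true(all(is.finite(a)))
})

test_that("participant aggregation is the epoch mean and is order-invariant", {
  fm <- rbind(c(ENMOtrunc = 0.1, Mean = 1), c(ENMOtrunc = 0.3, Mean = 1.2))
  ag <- aggregate_participant(fm)
  expect_equal(unname(ag["ENMOtrunc"]), 0.2)
  expect_equal(attr(ag, "n_epochs"), 2L)
  # idempotence on identical epochs
  one <- extract_epoch_features(random_epoch())
  same <- aggregate_participant(rbind(one, one, one))
  expect_equal(unname(same), unname(one), ignore_attr = TRUE)
  # permutation symmetry
  set.seed(5)
  fm2 <- matrix(rnorm(5 * 76), 5, 76,
                dimnames = list(NULL, feature_registry()$name))
  expect_equal(aggregate_participant(fm2),
               aggregate_participant(fm2[sample(5), ]))
  expect_error(aggregate_participant(fm2[0, ]), "excluded")
})
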