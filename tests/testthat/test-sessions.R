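lab <- function(...) {
  spec <- list(...)
  unlist(lapply(spec, function(s) rep(s[[1]], s[[2]])))
}

test_that("maximal walking runs are recovered with correct starts and lengths", {
  labels <- lab(list("walking", 4), list("other", 1), list("walking", 12),
                list("other", 1), list("walking", 20))
  runs <- find_walking_runs(labels)
  expect_equal(runs$length, c(4L, 12L, 20L))
  expect_equal(runs$start, c(1L, 6L, 19L))
  expect_equal(nrow(find_walking_runs(rep("other", 50))), 0L)
  expect_equal(nrow(find_walking_runs(character())), 0L)
})

test_that("run detection matches a brute-force scan on random label sequences", {
  set.seed(99)
  for (k in 1:20) {
    labels <- sample(c("walking", "other"), 500, replace = TRUE,
                     prob = c(0.4, 0.6))
    expect_equal(find_walking_runs(labels), brute_runs(labels))
  }
})

test_that("session selection keeps whole runs of >= 12 epochs", {
  labels <- lab(list("walking", 4), list("other", 1), list("walking", 12),
                list("other", 1), list("walking", 20))
  sel <- select_steady_sessions(find_walking_runs(labels))
  expect_equal(nrow(sel$sessions), 2L)
  expect_equal(sum(sel$sessions$length), 32L)
  expect_length(sel$included_epochs, 32L)
  # all epochs of a kept run are included, including beyond the 12th
  expect_true(all(19:38 %in% sel$included_epochs))
  # boundary: 11 is excluded, 12 qualifies (exactly 6 minutes)
  s11 <- session_set(lab(list("walking", 11), list("other", 1)),
                     session_criteria(min_wear_epochs = 0))
  expect_false(s11$included)
  expect_equal(s11$reason, "insufficient_walking")
  s12 <- session_set(lab(list("walking", 12), list("other", 1)),
                     session_criteria(min_wear_epochs = 0))
  expect_true(s12$included)
  expect_length(s12$included_epochs, 12L)
  expect_equal(length(s12$included_epochs) * 0.5, 6)  # minutes
})

test_that("included epochs never carry a non-walking label", {
  set.seed(4)
  n_with_sessions <- 0
  for (k in 1:10) {
    labels <- sample(c("walking", "other"), 300, replace = TRUE,
                     prob = c(0.8, 0.2))
    ss <- session_set(labels, session_criteria(min_wear_epochs = 0))
    if (length(ss$included_epochs)) {
      n_with_sessions <- n_with_sessions + 1
      expect_true(all(labels[ss$included_epochs] == "walking"))
      expect_gte(length(ss$included_epochs), 12L)
    }
  }
  expect_gt(n_with_sessions, 0)
})

test_that("inclusion applies wear-time before walking sufficiency", {
  crit <- session_criteria(min_wear_epochs = 100)
  # long walking runs but too few labeled epochs: wear exclusion wins
  short <- session_set(rep("walking", 50), crit)
  expect_equal(short$reason, "insufficient_wear")
  long_enough <- session_set(lab(list("walking", 50), list("other", 60)), crit)
  expect_equal(long_enough$reason, "ok")
})

test_that("cohort inclusion tallies exclusions by reason", {
  crit <- session_criteria(min_wear_epochs = 0)
  sets <- c(
    lapply(1:93, function(i) {
      session_set(lab(list("other", 5), list("walking", 12 + i %% 9),
                      list("other", 5)), crit)
    }),
    lapply(1:7, function(i) {
      session_set(lab(list("walking", 11), list("other", 10)), crit)
    })
  )
  names(sets) <- sprintf("P%03d", 1:100)
  incl <- apply_inclusion(sets)
  expect_length(incl$included_ids, 93L)
  expect_equal(unname(incl$tally["insufficient_walking"]), 7L)
  expect_equal(nrow(incl$table), 100L)
})

test_that("lowering the run threshold never excludes a previously included participant", {
  set.seed(12)
  for (k in 1:10) {
    labels <- sample(c("walking", "other"), 400, replace = TRUE,
                     prob = c(0.55, 0.45))
    inc <- vapply(c(16, 12, 8, 4, 1), function(thr) {
      session_set(labels, session_criteria(min_run_epochs = thr,
                                           min_wear_epochs = 0))$included
    }, FALSE)
    # once included at a high threshold, included at every lower one
    expect_true(all(diff(cumsum(inc) > 0) >= 0) || all(!inc))
    if (any(inc)) expect_true(all(inc[which(inc)[1]:length(inc)]))
  }
})

test_that("walking distribution totals are epochs * half a minute", {
  crit <- session_criteria(min_wear_epochs = 0)
  sets <- list(
    a = session_set(lab(list("walking", 12), list("other", 3)), crit),
    b = session_set(lab(list("walking", 12), list("other", 2),
                        list("walking", 20), list("other", 1)), crit),
    c = session_set(lab(list("walking", 5), list("other", 10)), crit)
  )
  wd <- walking_distribution(sets)
  expect_equal(unname(wd$minutes["a"]), 6)
  expect_equal(unname(wd$minutes["b"]), 16)
  expect_false("c" %in% names(wd$minutes))  # excluded participants excluded
  expect_true(all(wd$minutes >= 6))
  expect_equal(sum(wd$histogram$count), 2L)
})
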