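#' @title Steady-walking session detection and participant inclusion
#' @description
#' A steady-walking session is a maximal run of consecutive walking-labeled
#' epochs at least `min_run_epochs` long (default 12 epochs = 6 minutes, the
#' daily-living analogue of the Six Minute Walk Test). A single non-walking
#' epoch breaks a run: "consecutive" is taken literally, with no gap
#' tolerance. Participants are excluded first for insufficient device wear
#' (too few labeled epochs), then for the absence of any qualifying session.
#' @name walk_sessions
NULL

#' Session criteria
#'
#' @param min_run_epochs Minimum consecutive walking epochs per qualifying
#'   session (default 12).
#' @param epoch_s Epoch length in seconds (default 30).
#' @param min_wear_epochs Minimum labeled epochs for sufficient device wear.
#'   The default, 8640 epochs (72 hours), follows the usual accelerometry
#'   quality-control convention for week-long wear.
#' @return A `session_criteria` list.
#' @export
session_criteria <- function(min_run_epochs = 12, epoch_s = 30,
                             min_wear_epochs = 8640) {
  check_scalar(min_run_epochs, "min_run_epochs", lower = 1)
  check_scalar(epoch_s, "epoch_s", lower = 0, strict_lower = TRUE)
  check_scalar(min_wear_epochs, "min_wear_epochs", lower = 0)
  structure(list(min_run_epochs = as.integer(min_run_epochs),
                 epoch_s = epoch_s,
                 min_wear_epochs = as.integer(min_wear_epochs)),
            class = "session_criteria")
}

#' Find maximal runs of consecutive walking epochs
#'
#' Run-length scan over the label sequence; every maximal run of consecutive
#' `"walking"` labels is returned, with no length filtering.
#'
#' @param epoch_labels Character vector over `{"walking", "other"}`.
#' @return Data frame with columns `start` (1-based epoch index) and `length`,
#'   one row per maximal walking run; zero rows if none.
#' @examples
#' find_walking_runs(rep(c("walking", "other"), times = c(4, 2)))
#' @export
find_walking_runs <- function(epoch_labels) {
  epoch_labels <- as.character(epoch_labels)
  if (length(epoch_labels) == 0L) {
    return(data.frame(start = integer(), length = integer()))
  }
  rl <- rle(epoch_labels == "walking")
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  keep <- rl$values
  data.frame(start = as.integer(starts[keep]),
             length = as.integer(rl$lengths[keep]))
}

#' Select qualifying steady-walking sessions
#'
#' Keeps every run at least `min_run_epochs` long. All epochs of a kept run
#' are included: a 20-epoch run contributes all 20 epochs, not just 12.
#'
#' @param runs Data frame from [find_walking_runs()].
#' @param criteria A [session_criteria()].
#' @return List with `sessions` (the qualifying subset of `runs`) and
#'   `included_epochs` (sorted integer vector of included epoch indices).
#' @export
select_steady_sessions <- function(runs, criteria = session_criteria()) {
  keep <- runs$length >= criteria$min_run_epochs
  sessions <- runs[keep, , drop = FALSE]
  included <- integer()
  if (nrow(sessions)) {
    included <- sort(unlist(
      mapply(function(s, l) s:(s + l - 1L), sessions$start, sessions$length,
             SIMPLIFY = FALSE)
    ))
  }
  list(sessions = sessions, included_epochs = as.integer(included))
}

#' Per-participant session set with inclusion status
#'
#' Applies wear-time and steady-walking rules to one participant's label
#' sequence. Wear time is evaluated first: a participant with fewer labeled
#' epochs than `min_wear_epochs` is excluded for insufficient wear even if
#' they have long walking runs.
#'
#' @param epoch_labels Character label vector for the participant.
#' @param criteria A [session_criteria()].
#' @return A `session_set`: list with `runs`, `sessions`, `included_epochs`,
#'   `n_labeled_epochs`, `included` (logical) and `reason` (one of `"ok"`,
#'   `"insufficient_wear"`, `"insufficient_walking"`).
#' @export
session_set <- function(epoch_labels, criteria = session_criteria()) {
  runs <- find_walking_runs(epoch_labels)
  sel <- select_steady_sessions(runs, criteria)
  n_lab <- length(epoch_labels)
  if (n_lab < criteria$min_wear_epochs) {
    reason <- "insufficient_wear"
  } else if (nrow(sel$sessions) == 0L) {
    reason <- "insufficient_walking"
  } else {
    reason <- "ok"
  }
  structure(list(runs = runs, sessions = sel$sessions,
                 included_epochs = if (reason == "ok") sel$included_epochs else integer(),
                 n_labeled_epochs = n_lab,
                 included = reason == "ok", reason = reason),
            class = "session_set")
}

#' Apply inclusion/exclusion rules across a cohort
#'
#' @param cohort_sessions Named list of `session_set` objects, one per
#'   participant.
#' @return List with `included_ids`, `table` (per-participant CSV-ready data
#'   frame: `participant_id`, `n_sessions`, `total_epochs`, `included_flag`,
#'   `exclusion_reason`) and `tally` (named counts per reason, including
#'   `"ok"`).
#' @export
apply_inclusion <- function(cohort_sessions) {
  ids <- names(cohort_sessions)
  if (is.null(ids)) ids <- as.character(seq_along(cohort_sessions))
  tab <- data.frame(
    participant_id = ids,
    n_sessions = vapply(cohort_sessions, function(s) nrow(s$sessions), 0L),
    total_epochs = vapply(cohort_sessions,
                          function(s) length(s$included_epochs), 0L),
    included_flag = vapply(cohort_sessions, function(s) s$included, FALSE),
    exclusion_reason = vapply(cohort_sessions, function(s) s$reason, ""),
    stringsAsFactors = FALSE
  )
  reasons <- c("ok", "insufficient_wear", "insufficient_walking")
  tally <- vapply(reasons,
                  function(r) sum(tab$exclusion_reason == r), 0L)
  list(included_ids = ids[tab$included_flag], table = tab, tally = tally)
}

#' Distribution of total steady-walking time per included participant
#'
#' Each included epoch contributes 30 seconds, so per-participant total
#' steady-walking minutes = included epochs * 0.5.
#'
#' @param cohort_sessions Named list of `session_set` objects.
#' @param breaks Histogram bin boundaries in minutes (passed to
#'   [graphics::hist] semantics via [base::cut]); default 6-minute-wide bins.
#' @return List with `minutes` (named per-participant totals, included
#'   participants only) and `histogram` (data frame `bin`, `count`).
#' @export
walking_distribution <- function(cohort_sessions, breaks = NULL) {
  inc <- Filter(function(s) s$included, cohort_sessions)
  minutes <- vapply(inc, function(s) length(s$included_epochs) * 0.5, 0)
  if (is.null(breaks)) {
    top <- max(c(minutes, 6)) + 6
    breaks <- seq(0, ceiling(top / 6) * 6, by = 6)
  }
  cuts <- cut(minutes, breaks = breaks, include.lowest = TRUE, right = FALSE)
  hist_df <- as.data.frame(table(cuts), stringsAsFactors = FALSE)
  names(hist_df) <- c("bin", "count")
  list(minutes = minutes, histogram = hist_df)
}
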