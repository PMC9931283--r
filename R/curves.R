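#' Percentile survival time against age, stratified by sex and feature level
#'
#' Demographic-independence curves: participants are split by sex and by
#' tertile of a sensor feature (tertiles over the whole table), then within
#' age bins the product-limit (Kaplan-Meier) survival estimate is computed and
#' the reported value is the first time at which the survival function falls
#' to the given level (default 0.98, matching an approximately 2% event
#' cohort), linearly interpolated between the surrounding event times. Strata
#' whose survival never reaches the level report the follow-up horizon with a
#' censored flag; empty strata are flagged gaps.
#'
#' @param table Cohort table with `time`, `event`, `sex`, `age` and the
#'   feature column.
#' @param feature Name of the sensor feature column (e.g. `"ENMOtrunc"`).
#' @param percentile Survival level to cross (default 0.98; 1.0 gives the
#'   time of the first event).
#' @param age_bin Age bin width in years (default 5).
#' @param horizon_years Reported value for strata that never cross (default:
#'   the maximum observed time).
#' @return Data frame: `sex`, `tertile` (1 = lowest feature third), `age_bin`
#'   (left edge), `n`, `events`, `t_cross`, `censored` (TRUE when the level
#'   was never reached), `empty` (no subjects in stratum).
#' @export
percentile_survival_curves <- function(table, feature, percentile = 0.98,
                                       age_bin = 5,
                                       horizon_years = max(table$time)) {
  check_scalar(percentile, "percentile", lower = 0, upper = 1)
  if (!feature %in% names(table)) stop("feature not in table: ", feature)
  q <- stats::quantile(table[[feature]], c(1 / 3, 2 / 3), type = 7)
  tert <- 1L + (table[[feature]] > q[1]) + (table[[feature]] > q[2])
  lo <- floor(min(table$age) / age_bin) * age_bin
  hi <- ceiling((max(table$age) + 1e-9) / age_bin) * age_bin
  edges <- seq(lo, hi, by = age_bin)
  bin <- edges[findInterval(table$age, edges, rightmost.closed = TRUE)]

  out <- list()
  for (s in sort(unique(table$sex))) {
    for (g in 1:3) {
      for (b in edges[-length(edges)]) {
        rows <- table$sex == s & tert == g & bin == b
        n <- sum(rows)
        if (n == 0) {
          out[[length(out) + 1L]] <- data.frame(
            sex = s, tertile = g, age_bin = b, n = 0L, events = 0L,
            t_cross = NA_real_, censored = NA, empty = TRUE)
          next
        }
        km <- survival::survfit(
          survival::Surv(time, event) ~ 1,
          data = table[rows, c("time", "event")])
        cross <- km_crossing_time(km, percentile, horizon_years)
        out[[length(out) + 1L]] <- data.frame(
          sex = s, tertile = g, age_bin = b, n = n,
          events = sum(table$event[rows]),
          t_cross = cross$t, censored = cross$censored, empty = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

# first time the KM curve falls to `level`, linearly interpolated between the
# last time above the level and the first time at or below it
km_crossing_time <- function(km, level, horizon) {
  tt <- km$time
  ss <- km$surv
  idx <- which(ss <= level)
  if (!length(idx)) return(list(t = horizon, censored = TRUE))
  i <- idx[1]
  s_prev <- if (i == 1) 1 else ss[i - 1]
  t_prev <- if (i == 1) 0 else tt[i - 1]
  if (s_prev <= level || s_prev == ss[i]) {
    return(list(t = tt[i], censored = FALSE))
  }
  frac <- (s_prev - level) / (s_prev - ss[i])
  list(t = t_prev + frac * (tt[i] - t_prev), censored = FALSE)
}

#' Concordance evaluated within groups
#'
#' Scores risk within each group (e.g. assessment site) separately, either
#' from one model fitted on the full cohort (`protocol = "global"`) or from
#' per-group refits (`protocol = "refit"`). Groups without events or with
#' fewer comparable pairs than `min_pairs` are flagged and excluded from the
#' C-index column.
#'
#' @param table Cohort table.
#' @param predictors Predictor columns.
#' @param group Name of the grouping column (e.g. `"site"`).
#' @param protocol `"global"` (default) or `"refit"`.
#' @param min_pairs Minimum comparable pairs for a reported value (default 1).
#' @return Data frame: `group`, `n`, `events`, `cindex` (NA when flagged),
#'   `flagged`.
#' @export
grouped_cindex <- function(table, predictors, group = "site",
                           protocol = c("global", "refit"), min_pairs = 1) {
  protocol <- match.arg(protocol)
  if (!group %in% names(table)) stop("group column not in table: ", group)
  if (protocol == "global") {
    fit <- fit_penalized_cox(table, predictors, lambda = 0)
  }
  out <- list()
  for (g in sort(unique(table[[group]]))) {
    sub <- table[table[[group]] == g, , drop = FALSE]
    ev <- sum(sub$event)
    ci <- NA_real_
    flagged <- TRUE
    if (ev >= 1) {
      lp <- tryCatch({
        if (protocol == "refit") {
          f <- fit_penalized_cox(sub, predictors, lambda = 0)
          predict.pencox(f, sub)
        } else {
          predict.pencox(fit, sub)
        }
      }, error = function(e) NULL)
      if (!is.null(lp)) {
        np <- comparable_pairs(sub$time, sub$event)
        if (np >= min_pairs) {
          ci <- concordance_index(sub$time, sub$event, lp)
          flagged <- FALSE
        }
      }
    }
    out[[length(out) + 1L]] <- data.frame(
      group = g, n = nrow(sub), events = ev, cindex = ci, flagged = flagged)
  }
  do.call(rbind, out)
}

comparable_pairs <- function(times, events) {
  ev <- which(events == 1)
  sum(vapply(ev, function(i) {
    later <- times > times[i] | (times == times[i] & events == 0)
    later[i] <- FALSE
    sum(later)
  }, 0))
}
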