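#' Harrell concordance index
#'
#' Fraction of comparable subject pairs whose risk-score ordering matches
#' their observed survival ordering, correcting for censoring. A pair (i, j)
#' is comparable when `T_i < T_j` and subject i had the event, or when
#' `T_i == T_j` and exactly one of the two had the event (the event subject is
#' then the shorter-lived one). A comparable pair is concordant when the
#' shorter-lived subject has the strictly higher risk score; tied scores count
#' one half.
#'
#' @param times Observed times.
#' @param events Event indicators (0/1).
#' @param risk Risk scores (higher = shorter predicted survival).
#' @return Concordant share of comparable pairs, in `[0, 1]`.
#' @examples
#' concordance_index(c(1, 2, 3), c(1, 1, 1), c(3, 2, 1)) # 1
#' @export
concordance_index <- function(times, events, risk) {
  n <- length(times)
  stopifnot(length(events) == n, length(risk) == n)
  if (any(!is.finite(times)) || any(!is.finite(risk))) {
    stop("times and risk scores must be finite")
  }
  ev <- which(events == 1)
  conc <- 0
  comp <- 0
  for (i in ev) {
    # later deaths/censorings, plus same-time censored subjects
    later <- times > times[i] | (times == times[i] & events == 0)
    later[i] <- FALSE
    m <- sum(later)
    if (m == 0) next
    comp <- comp + m
    conc <- conc + sum(risk[i] > risk[later]) + 0.5 * sum(risk[i] == risk[later])
  }
  # tied event times with exactly one event are covered above; pairs of two
  # events at the same time are not comparable
  if (comp == 0) stop("no comparable pairs")
  conc / comp
}
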