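# Schoenfeld residuals and the proportional-hazards correlation test.
#
# At each event time t_i the residual is x_i minus the risk-weighted mean of
# x over the risk set {j : T_j >= t_i} (Breslow handling of ties: tied events
# share the same risk set). Scaled residuals follow Grambsch & Therneau:
# s*_i = beta + d * Ibar^{-1} r_i, with d the event count and Ibar the average
# per-event information. Under proportional hazards the scaled residuals are
# uncorrelated with time.

schoenfeld_residuals <- function(fit) {
  stopifnot(inherits(fit, "pencox"), fit$engine == "coxph")
  cph <- fit$fit
  y <- cph$y
  x <- cph$x
  beta <- stats::coef(cph)
  times <- y[, "time"]
  status <- y[, "status"]
  ev_idx <- which(status == 1)
  if (length(ev_idx) < 3) stop("need at least 3 events")
  ord <- ev_idx[order(times[ev_idx])]
  eta <- drop(x %*% beta)
  w_all <- exp(eta)
  p <- ncol(x)
  d <- length(ord)
  resid <- matrix(NA_real_, nrow = d, ncol = p,
                  dimnames = list(NULL, colnames(x)))
  vsum <- matrix(0, p, p)
  for (k in seq_len(d)) {
    i <- ord[k]
    at_risk <- times >= times[i]
    w <- w_all[at_risk]
    xr <- x[at_risk, , drop = FALSE]
    xbar <- colSums(xr * w) / sum(w)
    resid[k, ] <- x[i, ] - xbar
    xc <- sweep(xr, 2, xbar)
    vsum <- vsum + crossprod(xc * w, xc) / sum(w)
  }
  vbar <- vsum / d
  vinv <- tryCatch(solve(vbar), error = function(e) MASS_ginv(vbar))
  scaled <- sweep(d * resid %*% vinv, 2, beta, "+")
  colnames(scaled) <- colnames(x)
  list(resid = resid, scaled = scaled, times = times[ord], beta = beta)
}

# minimal Moore-Penrose fallback for a singular average information matrix
MASS_ginv <- function(m, tol = 1e-10) {
  s <- svd(m)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Proportional-hazards test from Schoenfeld residuals
#'
#' Refits (or reuses) an unpenalized Cox model on the given predictors,
#' computes scaled Schoenfeld residuals at the event times, and tests each
#' predictor for correlation between its scaled residuals and event time
#' (t-test on the Pearson correlation with `d - 2` degrees of freedom). A
#' predictor passes the PH check when its p-value is at or above the
#' significance threshold (default 0.001).
#'
#' @param fit A `pencox` fit with `engine == "coxph"`, or `NULL` to refit
#'   from `table` and `predictors`.
#' @param table Cohort table (required when `fit` is `NULL`).
#' @param predictors Predictor columns for the refit.
#' @param threshold Significance threshold for the pass flag (default 0.001).
#' @return List with `table` (data frame `predictor`, `rho`, `statistic`,
#'   `p_value`, `pass`), `residuals` (scaled residual matrix) and `times`
#'   (event times).
#' @export
schoenfeld_test <- function(fit = NULL, table = NULL, predictors = NULL,
                            threshold = 0.001) {
  if (is.null(fit)) {
    if (is.null(table) || is.null(predictors)) {
      stop("provide either a fit or (table, predictors)")
    }
    fit <- fit_penalized_cox(table, predictors, lambda = 0)
  }
  sr <- schoenfeld_residuals(fit)
  d <- length(sr$times)
  tt <- sr$times
  res <- do.call(rbind, lapply(colnames(sr$scaled), function(nm) {
    s <- sr$scaled[, nm]
    rho <- if (stats::sd(s) == 0 || stats::sd(tt) == 0) 0 else stats::cor(s, tt)
    stat <- rho * sqrt((d - 2) / max(1 - rho^2, 1e-12))
    p <- 2 * stats::pt(-abs(stat), df = d - 2)
    data.frame(predictor = nm, rho = rho, statistic = stat, p_value = p,
               pass = p >= threshold, stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  list(table = res, residuals = sr$scaled, times = sr$times)
}
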