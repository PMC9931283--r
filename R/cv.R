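#' Outcome-stratified k-fold assignment
#'
#' Because events are rare (about 2% of the cohort), folds are stratified by
#' outcome: within each class (dead / alive-or-censored at the horizon) the
#' subjects are shuffled and dealt round-robin, so per-class fold sizes differ
#' by at most one and every fold holds about 1/k of the events.
#'
#' @param events Event indicator vector (0/1) after any follow-up truncation.
#' @param k Number of folds (default 10).
#' @param seed Integer seed; the assignment is deterministic given the seed.
#' @return Integer vector of fold labels in `1:k`.
#' @export
stratified_folds <- function(events, k = 10, seed = default_seed()) {
  n <- length(events)
  n_ev <- sum(events == 1)
  if (n_ev < k) stop("fewer events than folds")
  if (n - n_ev < k) stop("fewer non-events than folds")
  folds <- integer(n)
  with_seed(seed, {
    for (cls in c(1, 0)) {
      idx <- sample(which(events == cls))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

cindex_of_fit <- function(fit, test, lambda = NULL) {
  lp <- predict.pencox(fit, test, type = "lp", lambda = lambda)
  if (is.matrix(lp)) {
    apply(lp, 2, function(s) concordance_index(test$time, test$event, s))
  } else {
    concordance_index(test$time, test$event, lp)
  }
}

#' Stratified cross-validated concordance of a Cox model
#'
#' Applies the follow-up horizon, builds outcome-stratified folds, fits on
#' each 9/10 and scores the held-out 1/10 by Harrell's C-index. With a
#' `penalty_spec`, a shared lambda grid (computed once on the full truncated
#' table) is evaluated per fold for every alpha, and the `(alpha, lambda)`
#' pair with the best mean CV C-index is selected and refit on the full
#' table.
#'
#' @param table Cohort table with `time`, `event` and predictor columns.
#' @param predictors Character vector of predictor columns.
#' @param penalty A [penalty_spec()], or `NULL` for an unpenalized fit.
#' @param horizon_years Maximum follow-up horizon (default `Inf` = none).
#' @param k Number of folds (default 10).
#' @param seed Integer seed (folds and fits are deterministic given it).
#' @return A `pencox_cv` object: list with `fold_cindex`, `mean_cindex`,
#'   `folds`, `horizon_years`, `predictors`, and for penalized runs `alpha`,
#'   `lambda`, `cv_path` (mean C per alpha x lambda) and `fit` (the full-data
#'   refit at the selected pair).
#' @export
cross_validate <- function(table, predictors, penalty = NULL,
                           horizon_years = Inf, k = 10,
                           seed = default_seed()) {
  if (is.finite(horizon_years)) {
    table <- truncate_followup(table, horizon_years)
  }
  folds <- stratified_folds(table$event, k = k, seed = seed)

  if (is.null(penalty)) {
    fold_c <- vapply(seq_len(k), function(j) {
      fit <- fit_penalized_cox(table[folds != j, , drop = FALSE],
                               predictors, lambda = 0)
      cindex_of_fit(fit, table[folds == j, , drop = FALSE])
    }, 0)
    res <- list(fold_cindex = fold_c, mean_cindex = mean(fold_c),
                folds = folds, horizon_years = horizon_years,
                predictors = predictors, alpha = NA_real_, lambda = 0)
  } else {
    # shared grid from the full table so fold paths are comparable
    grids <- lapply(penalty$alpha, function(a) {
      if (!is.null(penalty$lambda)) return(penalty$lambda)
      full <- fit_penalized_cox(table, predictors, alpha = a, lambda = NULL,
                                nlambda = penalty$nlambda,
                                lambda_min_ratio = penalty$lambda_min_ratio)
      full$lambda
    })
    cv_path <- list()
    best <- list(c = -Inf)
    for (ai in seq_along(penalty$alpha)) {
      a <- penalty$alpha[ai]
      lam <- grids[[ai]]
      cmat <- matrix(NA_real_, nrow = k, ncol = length(lam))
      for (j in seq_len(k)) {
        fit <- fit_penalized_cox(table[folds != j, , drop = FALSE],
                                 predictors, alpha = a, lambda = lam)
        # glmnet may truncate the path; score the lambdas it kept
        kept <- match(fit$lambda, lam)
        cs <- cindex_of_fit(fit, table[folds == j, , drop = FALSE])
        cmat[j, kept] <- cs
      }
      cmean <- colMeans(cmat)
      cv_path[[as.character(a)]] <-
        data.frame(alpha = a, lambda = lam, mean_cindex = cmean)
      ok <- which(!is.na(cmean))
      if (length(ok)) {
        jbest <- ok[which.max(cmean[ok])]
        if (cmean[jbest] > best$c) {
          best <- list(c = cmean[jbest], alpha = a, lambda = lam[jbest],
                       fold_c = cmat[, jbest])
        }
      }
    }
    refit <- fit_penalized_cox(table, predictors, alpha = best$alpha,
                               lambda = c(best$lambda * 2, best$lambda))
    res <- list(fold_cindex = best$fold_c, mean_cindex = best$c,
                folds = folds, horizon_years = horizon_years,
                predictors = predictors, alpha = best$alpha,
                lambda = best$lambda,
                cv_path = do.call(rbind, cv_path), fit = refit)
  }
  class(res) <- "pencox_cv"
  res
}

#' @export
print.pencox_cv <- function(x, ...) {
  cat(sprintf(
    "<pencox_cv> %d-fold CV C-index = %.4f (horizon %s y, %d predictors)\n",
    length(x$fold_cindex), x$mean_cindex,
    format(x$horizon_years), length(x$predictors)))
  if (!is.na(x$alpha)) {
    cat(sprintf("selected alpha = %g, lambda = %g\n", x$alpha, x$lambda))
  }
  invisible(x)
}

#' Cross-validated C-index matrix of feature sets by horizon
#'
#' Evaluates each named feature set at each maximum follow-up horizon,
#' producing the feature-set-by-risk-year concordance matrix.
#'
#' @param table Cohort table.
#' @param feature_sets Named list of predictor-name vectors.
#' @param horizons Numeric vector of horizons in years (default 1:5).
#' @param penalty Optional [penalty_spec()] (default `NULL`: unpenalized).
#' @param k,seed Cross-validation controls.
#' @return Data frame: one row per feature set, one column per horizon.
#' @export
max_model_table <- function(table, feature_sets, horizons = 1:5,
                            penalty = NULL, k = 10, seed = default_seed()) {
  out <- matrix(NA_real_, nrow = length(feature_sets),
                ncol = length(horizons),
                dimnames = list(names(feature_sets),
                                paste0("Y", horizons)))
  for (i in seq_along(feature_sets)) {
    for (j in seq_along(horizons)) {
      cv <- cross_validate(table, feature_sets[[i]], penalty = penalty,
                           horizon_years = horizons[j], k = k, seed = seed)
      out[i, j] <- cv$mean_cindex
    }
  }
  data.frame(feature_set = names(feature_sets), out,
             check.names = FALSE, row.names = NULL)
}
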