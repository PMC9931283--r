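#' Elastic-net penalty specification
#'
#' @param alpha Mixing parameters to consider (default `c(0, 0.5, 1)`:
#'   ridge, balanced elastic net, lasso).
#' @param lambda Optional decreasing grid of penalty strengths. When `NULL`,
#'   a 100-value log-spaced grid from `lambda_max` (the smallest strength at
#'   which all penalized coefficients are zero; for ridge a finite ceiling is
#'   substituted) down to `lambda_min_ratio * lambda_max` is used.
#' @param nlambda,lambda_min_ratio Grid size and lower endpoint ratio for the
#'   automatic grid.
#' @return A `penalty_spec` list.
#' @export
penalty_spec <- function(alpha = c(0, 0.5, 1), lambda = NULL,
                         nlambda = 100, lambda_min_ratio = 1e-3) {
  stopifnot(all(alpha >= 0 & alpha <= 1))
  if (!is.null(lambda)) {
    stopifnot(all(lambda >= 0))
    lambda <- sort(lambda, decreasing = TRUE)
  }
  structure(list(alpha = alpha, lambda = lambda, nlambda = nlambda,
                 lambda_min_ratio = lambda_min_ratio),
            class = "penalty_spec")
}

#' Fit a (penalized) Cox proportional hazards model
#'
#' The package's core fit. With `lambda = 0` this is the ordinary Cox partial
#' likelihood maximizer (Breslow tie handling) via [survival::coxph()]; with
#' `lambda > 0` the elastic-net penalized partial likelihood is maximized via
#' glmnet, with predictors standardized internally and coefficients returned
#' on both the original and the standardized scale.
#'
#' @param formula Model formula with a [survival::Surv] response, e.g.
#'   `Surv(time, event) ~ age + sex + ENMOtrunc`.
#' @param data Data frame.
#' @param alpha Single elastic-net mixing parameter in `[0, 1]`.
#' @param lambda Penalty strength: a scalar (0 for unpenalized) or a
#'   decreasing grid, in which case the whole regularization path is kept.
#' @param nlambda,lambda_min_ratio Automatic-grid controls used when
#'   `lambda = NULL`.
#' @return A `pencox` object: list with `coefficients` (original scale;
#'   matrix with one column per lambda for a path), `coefficients_std`
#'   (standardized scale), `alpha`, `lambda`, `center`/`scale`
#'   (standardization parameters), `converged`, `n`, `n_events`, `engine`
#'   (`"coxph"` or `"glmnet"`) and the underlying fit.
#' @examples
#' d <- data.frame(time = c(1, 2, 3, 4, 5, 6),
#'                 event = c(1, 1, 0, 1, 0, 1),
#'                 x = c(1, 1, 0, 0, 1, 0))
#' fit <- pencox(survival::Surv(time, event) ~ x, d, lambda = 0)
#' coef(fit)
#' @export
pencox <- function(formula, data, alpha = 0.5, lambda = 0,
                   nlambda = 100, lambda_min_ratio = 1e-3) {
  stopifnot(length(alpha) == 1L, alpha >= 0, alpha <= 1)
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (!inherits(y, "Surv")) stop("formula response must be a survival::Surv")
  x <- stats::model.matrix(formula, mf)
  x <- x[, colnames(x) != "(Intercept)", drop = FALSE]
  n_events <- sum(y[, "status"])
  if (n_events < 2) stop("need at least 2 events to fit")

  ctr <- colMeans(x)
  scl <- apply(x, 2, function(v) sqrt(mean((v - mean(v))^2)))
  scl[scl == 0] <- 1

  if (!is.null(lambda) && length(lambda) == 1L && lambda == 0) {
    conv <- TRUE
    # monotone-likelihood warnings (rare events, near-separated binary
    # covariates) are recorded on the convergence flag, not re-emitted
    fit <- withCallingHandlers(
      survival::coxph(formula, data = data, ties = "breslow",
                      x = TRUE, y = TRUE),
      warning = function(w) {
        if (grepl("converge|infinite|singular", conditionMessage(w))) {
          conv <<- FALSE
          invokeRestart("muffleWarning")
        }
      })
    beta <- stats::coef(fit)
    if (any(!is.finite(beta))) conv <- FALSE
    out <- list(coefficients = beta, coefficients_std = beta * scl,
                alpha = alpha, lambda = 0, center = ctr, scale = scl,
                converged = conv, n = nrow(x), n_events = n_events,
                engine = "coxph", fit = fit, formula = formula,
                predictors = colnames(x))
  } else {
    sy <- survival::Surv(y[, "time"], y[, "status"])
    args <- list(x = x, y = sy, family = "cox", alpha = alpha,
                 standardize = TRUE)
    if (is.null(lambda)) {
      args$nlambda <- nlambda
      args$lambda.min.ratio <- lambda_min_ratio
    } else {
      args$lambda <- sort(lambda, decreasing = TRUE)
    }
    fit <- do.call(glmnet::glmnet, args)
    beta <- as.matrix(fit$beta)
    if (ncol(beta) == 1L) beta <- beta[, 1]
    out <- list(coefficients = beta, coefficients_std = beta * scl,
                alpha = alpha, lambda = fit$lambda, center = ctr, scale = scl,
                converged = fit$jerr == 0, n = nrow(x), n_events = n_events,
                engine = "glmnet", fit = fit, formula = formula,
                predictors = colnames(x))
  }
  if (!out$converged && out$engine == "glmnet") {
    warning("pencox fit did not converge")
  }
  class(out) <- "pencox"
  out
}

#' Fit a penalized Cox model on a cohort table by predictor names
#'
#' Thin interface over [pencox()] taking the modelling table and a character
#' vector of predictor columns (a named feature set).
#'
#' @param table Cohort table with `time` and `event` columns.
#' @param predictors Character vector of predictor column names.
#' @param alpha Elastic-net mixing parameter.
#' @param lambda Penalty strength or grid (see [pencox()]).
#' @param ... Passed to [pencox()].
#' @return A `pencox` object.
#' @export
fit_penalized_cox <- function(table, predictors, alpha = 0.5, lambda = 0,
                              ...) {
  f <- stats::as.formula(paste(
    "survival::Surv(time, event) ~",
    paste(sprintf("`%s`", predictors), collapse = " + ")
  ))
  pencox(f, table, alpha = alpha, lambda = lambda, ...)
}

#' @export
print.pencox <- function(x, ...) {
  cat(sprintf("<pencox> %s fit, alpha = %g, n = %d, events = %d\n",
              x$engine, x$alpha, x$n, x$n_events))
  if (is.matrix(x$coefficients)) {
    cat(sprintf("regularization path over %d lambda values [%g, %g]\n",
                length(x$lambda), min(x$lambda), max(x$lambda)))
  } else {
    print(x$coefficients)
  }
  invisible(x)
}

#' @export
coef.pencox <- function(object, lambda = NULL, ...) {
  b <- object$coefficients
  if (!is.matrix(b)) return(b)
  if (is.null(lambda)) return(b)
  j <- which.min(abs(object$lambda - lambda))
  b[, j]
}

#' @export
summary.pencox <- function(object, ...) {
  if (object$engine == "coxph") {
    s <- summary(object$fit)
    out <- list(coefficients = s$coefficients, n = object$n,
                n_events = object$n_events, engine = "coxph")
  } else {
    out <- list(coefficients = object$coefficients, lambda = object$lambda,
                alpha = object$alpha, n = object$n,
                n_events = object$n_events, engine = "glmnet")
  }
  class(out) <- "summary.pencox"
  out
}

#' @export
print.summary.pencox <- function(x, ...) {
  cat(sprintf("Penalized Cox model (%s), n = %d, events = %d\n",
              x$engine, x$n, x$n_events))
  print(x$coefficients)
  invisible(x)
}

#' Predict linear predictors or relative risks
#'
#' @param object A `pencox` fit.
#' @param newdata Data frame of predictors.
#' @param type `"lp"` (linear predictor `x'beta`) or `"risk"` (`exp(lp)`).
#' @param lambda For path fits, the lambda at which to predict (nearest grid
#'   value is used).
#' @param ... Unused.
#' @return Numeric vector (or matrix over the path when `lambda` is `NULL`
#'   for a path fit).
#' @export
predict.pencox <- function(object, newdata, type = c("lp", "risk"),
                           lambda = NULL, ...) {
  type <- match.arg(type)
  f <- stats::as.formula(paste(
    "~", paste(sprintf("`%s`", object$predictors), collapse = " + ")
  ))
  x <- stats::model.matrix(f, newdata)
  x <- x[, colnames(x) != "(Intercept)", drop = FALSE]
  b <- coef(object, lambda = lambda)
  lp <- if (is.matrix(b)) x %*% b else drop(x %*% b)
  if (type == "risk") exp(lp) else lp
}

#' Schoenfeld residuals of an unpenalized `pencox` fit
#'
#' @param object A `pencox` fit with `engine == "coxph"`.
#' @param type `"schoenfeld"` (raw) or `"scaled"` (Grambsch-Therneau scaled).
#' @param ... Unused.
#' @return Matrix of residuals, one row per event time (`"times"` attribute).
#' @export
residuals.pencox <- function(object, type = c("schoenfeld", "scaled"), ...) {
  type <- match.arg(type)
  if (object$engine != "coxph") {
    stop("Schoenfeld residuals require an unpenalized (lambda = 0) fit")
  }
  sr <- schoenfeld_residuals(object)
  if (type == "schoenfeld") {
    structure(sr$resid, times = sr$times)
  } else {
    structure(sr$scaled, times = sr$times)
  }
}
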