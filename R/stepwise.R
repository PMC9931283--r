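#' Greedy forward stepwise selection by CV concordance
#'
#' Starting from `base` (possibly empty), each step adds the candidate that
#' increases the mean cross-validated C-index the most; selection stops when
#' the best achievable increment falls below `threshold`. The score of an
#' empty base set is 0.5 (no discrimination). Scoring uses k-fold stratified
#' CV concordance, not the in-sample fit.
#'
#' @param table Cohort table.
#' @param candidates Character vector of candidate predictor columns.
#' @param base Character vector of always-included predictors (default none).
#' @param threshold Minimum C-index increment to accept a step (the study's
#'   thresholds are 0.01 and 0.001).
#' @param horizon_years Follow-up horizon (default `Inf`).
#' @param k,seed Cross-validation controls.
#' @return List with `selected` (ordered accepted predictors, excluding the
#'   base), `trace` (data frame `step`, `name`, `cindex`, `increment`; the
#'   cumulative C-index trace) and `base`.
#' @export
stepwise_select <- function(table, candidates, base = character(),
                            threshold = 0.01, horizon_years = Inf,
                            k = 10, seed = default_seed()) {
  check_scalar(threshold, "threshold", lower = 0, strict_lower = TRUE)
  if (length(candidates) < 1) stop("need at least one candidate")
  score <- function(preds) {
    if (length(preds) == 0) return(0.5)
    cross_validate(table, preds, horizon_years = horizon_years,
                   k = k, seed = seed)$mean_cindex
  }
  current <- base
  current_c <- score(current)
  remaining <- setdiff(candidates, base)
  trace <- data.frame(step = integer(), name = character(),
                      cindex = numeric(), increment = numeric(),
                      stringsAsFactors = FALSE)
  step <- 0L
  while (length(remaining)) {
    cs <- vapply(remaining, function(p) score(c(current, p)), 0)
    ibest <- which.max(cs)
    inc <- cs[ibest] - current_c
    if (inc < threshold) break
    step <- step + 1L
    current <- c(current, remaining[ibest])
    current_c <- cs[ibest]
    trace <- rbind(trace, data.frame(
      step = step, name = remaining[ibest], cindex = current_c,
      increment = inc, stringsAsFactors = FALSE))
    remaining <- remaining[-ibest]
  }
  list(selected = setdiff(current, base), trace = trace, base = base)
}

#' Marginal single-predictor concordance ranking
#'
#' Cross-validated C-index of each candidate alone, ranked in descending
#' order — the per-feature marginal performance table.
#'
#' @inheritParams stepwise_select
#' @return Data frame `rank`, `name`, `cindex`, sorted by descending
#'   `cindex`.
#' @export
marginal_feature_ranking <- function(table, candidates, horizon_years = Inf,
                                     k = 10, seed = default_seed()) {
  cs <- vapply(candidates, function(p) {
    cross_validate(table, p, horizon_years = horizon_years,
                   k = k, seed = seed)$mean_cindex
  }, 0)
  ord <- order(cs, decreasing = TRUE)
  data.frame(rank = seq_along(candidates), name = candidates[ord],
             cindex = unname(cs[ord]), stringsAsFactors = FALSE)
}

#' Hierarchical clustering of sensor features with lasso selection flags
#'
#' Agglomerates features with average linkage on the dissimilarity
#' `1 - |Pearson correlation|` computed across rows of the feature table.
#' When survival columns are available, a CV-selected lasso fit flags the
#' features with nonzero coefficients at the optimal lambda.
#'
#' @param table Data frame with the feature columns (epoch- or
#'   participant-level) and optionally `time`/`event` for the lasso flags.
#' @param features Character vector of feature column names (>= 2).
#' @param horizon_years,k,seed Passed to the lasso [cross_validate()] run.
#' @param flag_selected Compute lasso selection flags (requires
#'   `time`/`event`; default `TRUE` when present).
#' @return List with `tree` (an [stats::hclust] object), `selected`
#'   (character vector of flagged features, possibly empty) and `dissimilarity`.
#' @export
feature_hierarchy <- function(table, features,
                              horizon_years = Inf, k = 10,
                              seed = default_seed(),
                              flag_selected = all(c("time", "event") %in%
                                                    names(table))) {
  if (length(features) < 2) stop("need at least 2 features")
  cm <- suppressWarnings(stats::cor(as.matrix(table[, features])))
  cm[!is.finite(cm)] <- 0
  diag(cm) <- 1
  d <- stats::as.dist(1 - abs(cm))
  tree <- stats::hclust(d, method = "average")
  selected <- character()
  if (flag_selected) {
    cv <- cross_validate(table, features,
                         penalty = penalty_spec(alpha = 1),
                         horizon_years = horizon_years, k = k, seed = seed)
    b <- coef(cv$fit, lambda = cv$lambda)
    selected <- names(b)[b != 0]
    # strip model.matrix backtick artifacts
    selected <- gsub("`", "", selected)
  }
  list(tree = tree, selected = selected, dissimilarity = d)
}
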