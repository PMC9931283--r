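#' Assemble the modelling table
#'
#' Inner join of participant-level sensor aggregates, the covariate table and
#' survival outcomes on `id`. Only participants present in all three inputs
#' enter; rows with any missing covariate are dropped (complete-case) and the
#' drop count recorded. Column group membership (demo / adc / mrf /
#' continuous) is attached as the `"groups"` attribute so model feature sets
#' are selectable by name.
#'
#' @param sensor Data frame with `id` plus sensor feature columns.
#' @param covariates Data frame with `id`, demographics and categorical
#'   features.
#' @param outcomes Data frame with `id`, `time`, `event`.
#' @return Data frame with attributes `groups` (named list of column names)
#'   and `n_dropped_incomplete`. A warning is issued when the id sets are
#'   disjoint.
#' @export
assemble_table <- function(sensor, covariates, outcomes) {
  for (nm in list(sensor, covariates, outcomes)) {
    if (anyDuplicated(nm$id)) stop("duplicate participant ids in input")
  }
  tab <- merge(merge(covariates, sensor, by = "id"), outcomes, by = "id")
  if (nrow(tab) == 0L) warning("no overlapping participant ids; empty table")
  complete <- stats::complete.cases(tab)
  dropped <- sum(!complete)
  tab <- tab[complete, , drop = FALSE]
  rownames(tab) <- NULL
  grp <- covariate_groups()
  attr(tab, "groups") <- list(
    demo = intersect(grp$demo, names(tab)),
    adc = intersect(grp$adc, names(tab)),
    mrf = intersect(grp$mrf, names(tab)),
    continuous = setdiff(names(sensor), "id")
  )
  attr(tab, "n_dropped_incomplete") <- dropped
  tab
}

#' Truncate follow-up at a horizon
#'
#' Administrative truncation at `horizon_years`: any event after the horizon
#' is ignored, with observation censored at the horizon. Idempotent, and the
#' post-truncation event count is nondecreasing in the horizon.
#'
#' @param table Data frame with `time` and `event` columns (years, 0/1).
#' @param horizon_years Maximum follow-up in years (> 0; `Inf` leaves the
#'   table unchanged).
#' @return The table with truncated `time` and `event`.
#' @examples
#' truncate_followup(data.frame(time = c(3.2, 0.5), event = c(1, 1)), 1)
#' @export
truncate_followup <- function(table, horizon_years) {
  if (!is.numeric(horizon_years) || length(horizon_years) != 1L ||
      is.na(horizon_years) || horizon_years <= 0) {
    stop("`horizon_years` must be a single positive number")
  }
  if (!is.finite(horizon_years)) return(table)
  over <- table$time > horizon_years
  table$event[over] <- 0L
  table$time[over] <- horizon_years
  table
}
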