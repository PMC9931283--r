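#' Registry of the 76 per-epoch sensor features
#'
#' Returns the ordered catalogue of the time-domain features computed for each
#' 30-second epoch. The registry is split into two groups of 38: the
#' `biobank_time_domain` group mirrors the feature set produced by the UK
#' Biobank accelerometer software (ENMOtrunc, magnitude and per-axis means and
#' standard deviations, deviation and shape statistics of the magnitude,
#' magnitude quantiles, per-axis ranges, cross-axis covariances and
#' correlations, and device-orientation angles), and the `derived` group holds
#' the additional features computed on top of it (ENMOabs, per-axis quantile /
#' autocorrelation / dispersion variants, and RMS / TAC / MCR / MMCR for the
#' magnitude and each axis).
#'
#' Feature names are the column headers used verbatim in all feature tables
#' (`ENMOtrunc`, `xSd`, `yMMCR`, ...). Axis-specific variants carry an `x`,
#' `y` or `z` prefix; unprefixed amplitude/shape names refer to the vector
#' magnitude.
#'
#' @return A data frame with columns `name`, `group`
#'   (`biobank_time_domain` or `derived`) and `axis` (`magnitude`, `x`, `y`,
#'   `z`, `cross-axis` or `orientation`), with exactly 76 rows.
#' @examples
#' reg <- feature_registry()
#' nrow(reg)            # 76
#' table(reg$group)     # 38 / 38
#' @export
feature_registry <- function() {
  rows <- list()
  add <- function(name, group, axis) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, group = group, axis = axis, stringsAsFactors = FALSE
    )
  }
  axes <- c("x", "y", "z")

  ## --- biobank_time_domain (38) ---
  add("ENMOtrunc", "biobank_time_domain", "magnitude")
  add("Mean", "biobank_time_domain", "magnitude")
  for (a in axes) add(paste0(a, "Mean"), "biobank_time_domain", a)
  add("Sd", "biobank_time_domain", "magnitude")
  for (a in axes) add(paste0(a, "Sd"), "biobank_time_domain", a)
  for (f in c("MAD", "MPD", "kurt", "skew")) {
    add(f, "biobank_time_domain", "magnitude")
  }
  for (f in c("Min", "Max", "25thp", "Median", "75thp",
              "autocorr", "coefvariation")) {
    add(f, "biobank_time_domain", "magnitude")
  }
  for (a in axes) add(paste0(a, "Range"), "biobank_time_domain", a)
  for (p in c("xy", "xz", "yz")) {
    add(paste0("Cov", p), "biobank_time_domain", "cross-axis")
  }
  for (p in c("xy", "xz", "yz")) {
    add(paste0("corr", p), "biobank_time_domain", "cross-axis")
  }
  for (ang in c("pitch", "roll", "yaw")) {
    add(paste0(ang, "g"), "biobank_time_domain", "orientation")
  }
  for (ang in c("pitch", "roll", "yaw")) {
    add(paste0("sd", ang), "biobank_time_domain", "orientation")
  }
  for (ang in c("pitch", "roll", "yaw")) {
    add(paste0("avg", ang), "biobank_time_domain", "orientation")
  }

  ## --- derived (38) ---
  add("ENMOabs", "derived", "magnitude")
  for (f in c("Min", "Max", "25thp", "Median", "75thp",
              "autocorr", "coefvariation")) {
    for (a in axes) add(paste0(a, f), "derived", a)
  }
  for (f in c("RMS", "TAC", "MCR", "MMCR")) {
    add(f, "derived", "magnitude")
    for (a in axes) add(paste0(a, f), "derived", a)
  }

  out <- do.call(rbind, rows)
  stopifnot(nrow(out) == 76L, !anyDuplicated(out$name))
  out
}
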