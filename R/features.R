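#' @title Per-epoch sensor features
#' @description
#' The feature extractor operates on one epoch: a block of `rate * 30`
#' tri-axial acceleration samples in g (3000 samples at 100 Hz). Per-sample
#' magnitude is `r_i = sqrt(x_i^2 + y_i^2 + z_i^2)`. The functions below
#' compute named groups of the 76-feature registry;
#' [extract_epoch_features()] composes them in registry order.
#'
#' Conventions (applied uniformly):
#' * `Sd` is the sample standard deviation (n-1 denominator); `MPD` and the
#'   cross-axis covariances use the population (n) denominator.
#' * Quantiles use linear interpolation between order statistics
#'   (`stats::quantile` type 7).
#' * `kurt` is excess kurtosis (0 for a normal sample), `skew` the moment
#'   skewness, both without bias correction; a constant series yields 0.
#' * `autocorr` is the lag-1-sample Pearson correlation between the series and
#'   its one-sample shift; correlations of a constant series are 0.
#' * `coefvariation` is `Sd / Mean`, defined as 0 when the series is constant
#'   or its mean is exactly 0.
#' * Crossing counts are strict: a sample exactly on the threshold level
#'   registers no crossing.
#' * Orientation angles are reported in degrees.
#' @name epoch_features
NULL

# Accepts an epoch object from segment_epochs() or a plain n x 3 matrix.
# Returns list(samples, rate, duration_s).
epoch_input <- function(epoch, sampling_rate_hz = 100) {
  if (is.list(epoch) && !is.null(epoch$samples)) {
    samples <- epoch$samples
    rate <- if (!is.null(epoch$sampling_rate_hz)) epoch$sampling_rate_hz else sampling_rate_hz
  } else {
    samples <- epoch
    rate <- sampling_rate_hz
  }
  samples <- as.matrix(samples)
  if (ncol(samples) != 3L) stop("epoch samples must have 3 columns (x, y, z)")
  if (!all(is.finite(samples))) stop("epoch samples must be finite")
  list(samples = samples, rate = rate, duration_s = nrow(samples) / rate)
}

mag_of <- function(samples) sqrt(rowSums(samples^2))

# strict crossing count of `s` through level `L`: pairs with opposite sign,
# samples exactly on the level break the pair (no crossing through equality)
count_crossings <- function(s, level) {
  d <- s - level
  sum(d[-length(d)] * d[-1L] < 0)
}

safe_cor <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  stats::cor(a, b)
}

lag1_autocorr <- function(s) {
  n <- length(s)
  safe_cor(s[-n], s[-1L])
}

#' ENMO features of an epoch
#'
#' Euclidean Norm Minus One of the per-sample magnitude, averaged over the
#' epoch: the truncated variant zeroes negative deviations from 1 g, the
#' absolute variant takes their magnitude.
#'
#' @param epoch Epoch from [segment_epochs()] or an `n x 3` matrix in g.
#' @param sampling_rate_hz Sampling rate, used when `epoch` is a bare matrix.
#' @return Named vector `c(ENMOtrunc, ENMOabs)` in g.
#' @examples
#' enmo_features(matrix(rep(c(0, 0, 2), each = 3000), ncol = 3))
#' @export
enmo_features <- function(epoch, sampling_rate_hz = 100) {
  e <- epoch_input(epoch, sampling_rate_hz)
  r <- mag_of(e$samples)
  c(ENMOtrunc = mean(pmax(r - 1, 0)), ENMOabs = mean(abs(r - 1)))
}

#' Moment, quantile and deviation features of an epoch
#'
#' Location, scale, shape and order statistics of the magnitude series and the
#' three axis series: Mean, Sd (sample), RMS, MAD (mean absolute deviation
#' about the epoch mean), MPD (root mean square deviation, population
#' denominator), excess kurtosis and skewness of the magnitude, coefficient of
#' variation, Min/Max and the 25th/50th/75th percentiles, and per-axis ranges.
#'
#' @inheritParams enmo_features
#' @return Named numeric vector.
#' @export
moment_features <- function(epoch, sampling_rate_hz = 100) {
  e <- epoch_input(epoch, sampling_rate_hz)
  s <- e$samples
  r <- mag_of(s)
  series <- list(mag = r, x = s[, 1], y = s[, 2], z = s[, 3])

  out <- c()
  for (nm in names(series)) {
    v <- series[[nm]]
    pre <- if (nm == "mag") "" else nm
    m <- mean(v)
    sdv <- stats::sd(v)
    q <- unname(stats::quantile(v, c(0.25, 0.5, 0.75), type = 7))
    vals <- c(Mean = m, Sd = sdv, RMS = sqrt(mean(v^2)),
              Min = min(v), Max = max(v),
              "25thp" = q[1], Median = q[2], "75thp" = q[3],
              coefvariation = if (sdv == 0 || m == 0) 0 else sdv / m)
    names(vals) <- paste0(pre, names(vals))
    out <- c(out, vals)
  }
  # magnitude-only deviation and shape statistics
  dev <- r - mean(r)
  m2 <- mean(dev^2)
  out <- c(out,
           MAD = mean(abs(dev)),
           MPD = sqrt(m2),
           kurt = if (m2 == 0) 0 else mean(dev^4) / m2^2 - 3,
           skew = if (m2 == 0) 0 else mean(dev^3) / m2^1.5)
  # per-axis ranges
  for (a in c("x", "y", "z")) {
    v <- series[[a]]
    out[paste0(a, "Range")] <- max(v) - min(v)
  }
  out
}

#' Crossing-rate and activity-count features of an epoch
#'
#' MCR is the rate (crossings per second) at which a series crosses its own
#' epoch mean; MMCR averages the crossing rates through the mid-levels
#' `(mean + max) / 2` and `(mean + min) / 2`. TAC (total activity count) sums
#' the positive part of `r - 1` for the magnitude and the absolute deviation
#' from the axis mean per axis. Each axis variant uses the axis series and its
#' own mean.
#'
#' @inheritParams enmo_features
#' @return Named numeric vector (`MCR`, `xMCR`, ..., `MMCR`, ..., `TAC`, ...).
#' @export
crossing_features <- function(epoch, sampling_rate_hz = 100) {
  e <- epoch_input(epoch, sampling_rate_hz)
  s <- e$samples
  r <- mag_of(s)
  dur <- e$duration_s
  series <- list(mag = r, x = s[, 1], y = s[, 2], z = s[, 3])

  out <- c()
  for (nm in names(series)) {
    v <- series[[nm]]
    pre <- if (nm == "mag") "" else nm
    m <- mean(v)
    out[paste0(pre, "MCR")] <- count_crossings(v, m) / dur
    out[paste0(pre, "MMCR")] <-
      0.5 * (count_crossings(v, (m + max(v)) / 2) +
             count_crossings(v, (m + min(v)) / 2)) / dur
    out[paste0(pre, "TAC")] <-
      if (nm == "mag") sum(pmax(v - 1, 0)) else sum(abs(v - m))
  }
  out
}

#' Cross-axis and serial dependence features of an epoch
#'
#' Population covariances and Pearson correlations between axis pairs, and the
#' lag-1-sample autocorrelation of the magnitude and each axis series.
#'
#' @inheritParams enmo_features
#' @return Named numeric vector.
#' @export
dependence_features <- function(epoch, sampling_rate_hz = 100) {
  e <- epoch_input(epoch, sampling_rate_hz)
  s <- e$samples
  r <- mag_of(s)
  pairs <- list(xy = c(1L, 2L), xz = c(1L, 3L), yz = c(2L, 3L))
  out <- c()
  for (p in names(pairs)) {
    i <- pairs[[p]]
    a <- s[, i[1]]; b <- s[, i[2]]
    out[paste0("Cov", p)] <- mean((a - mean(a)) * (b - mean(b)))
    out[paste0("corr", p)] <- safe_cor(a, b)
  }
  out["autocorr"] <- lag1_autocorr(r)
  for (a in c("x", "y", "z")) {
    out[paste0(a, "autocorr")] <-
      lag1_autocorr(s[, match(a, c("x", "y", "z"))])
  }
  out
}

#' Orientation-angle features of an epoch
#'
#' Per-sample rotation angles in degrees, `pitch = atan2(x, sqrt(y^2 + z^2))`,
#' `roll = atan2(y, sqrt(x^2 + z^2))`, `yaw = atan2(z, sqrt(x^2 + y^2))` (the
#' yaw formula is a z-axis symmetry convention: yaw proper is not observable
#' from a static accelerometer). `avg*` / `sd*` are the mean and sample
#' standard deviation of the per-sample angles; the `*g` variants evaluate the
#' same formulas on the epoch-mean acceleration vector (the gravity estimate).
#' A zero epoch-mean vector yields 0 for the gravity variants, with a warning.
#'
#' @inheritParams enmo_features
#' @return Named numeric vector of 9 angles/statistics in degrees.
#' @export
orientation_features <- function(epoch, sampling_rate_hz = 100) {
  e <- epoch_input(epoch, sampling_rate_hz)
  s <- e$samples
  deg <- 180 / pi
  ang <- function(a, b, c) atan2(a, sqrt(b^2 + c^2)) * deg
  pitch <- ang(s[, 1], s[, 2], s[, 3])
  roll  <- ang(s[, 2], s[, 1], s[, 3])
  yaw   <- ang(s[, 3], s[, 1], s[, 2])
  mu <- unname(colMeans(s))
  if (all(mu == 0)) {
    warning("zero epoch-mean vector; gravity-orientation angles set to 0")
    g <- c(pitchg = 0, rollg = 0, yawg = 0)
  } else {
    g <- c(pitchg = ang(mu[1], mu[2], mu[3]),
           rollg  = ang(mu[2], mu[1], mu[3]),
           yawg   = ang(mu[3], mu[1], mu[2]))
  }
  c(g,
    sdpitch = stats::sd(pitch), sdroll = stats::sd(roll),
    sdyaw = stats::sd(yaw),
    avgpitch = mean(pitch), avgroll = mean(roll), avgyaw = mean(yaw))
}

#' Extract the full 76-feature vector of an epoch
#'
#' Composes [enmo_features()], [moment_features()], [crossing_features()],
#' [dependence_features()] and [orientation_features()] and returns the
#' features in registry order.
#'
#' @inheritParams enmo_features
#' @param registry Feature registry, from [feature_registry()].
#' @return Named numeric vector of length 76 in registry order; never `NaN`.
#' @examples
#' ep <- matrix(rnorm(3000 * 3, c(0, 0, 1), 0.05), ncol = 3, byrow = TRUE)
#' fv <- extract_epoch_features(ep)
#' length(fv)
#' @export
extract_epoch_features <- function(epoch, registry = feature_registry(),
                                   sampling_rate_hz = 100) {
  vals <- c(enmo_features(epoch, sampling_rate_hz),
            moment_features(epoch, sampling_rate_hz),
            crossing_features(epoch, sampling_rate_hz),
            dependence_features(epoch, sampling_rate_hz),
            orientation_features(epoch, sampling_rate_hz))
  missing <- setdiff(registry$name, names(vals))
  if (length(missing)) {
    stop("internal: features missing from extractor: ",
         paste(missing, collapse = ", "))
  }
  out <- vals[registry$name]
  if (any(!is.finite(out))) {
    stop("internal: non-finite feature value for ",
         paste(registry$name[!is.finite(out)], collapse = ", "))
  }
  out
}

#' Aggregate epoch feature vectors to a participant feature vector
#'
#' Element-wise arithmetic mean across all of a participant's included epochs
#' (epochs belonging to qualifying steady-walking sessions). The number of
#' epochs aggregated is recorded in the `n_epochs` attribute.
#'
#' @param feature_matrix Numeric matrix, one row per included epoch, columns
#'   in registry order (e.g. rows from [extract_epoch_features()]).
#' @return Named numeric vector (participant-level feature vector).
#' @export
aggregate_participant <- function(feature_matrix) {
  feature_matrix <- rbind(feature_matrix)
  if (nrow(feature_matrix) == 0L) {
    stop("no epochs to aggregate; participant should have been excluded")
  }
  out <- colMeans(feature_matrix)
  attr(out, "n_epochs") <- nrow(feature_matrix)
  out
}
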