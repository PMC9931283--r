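# Independent direct-definition oracles. These deliberately re-derive every
# quantity from its textbook formula (manual quantiles, explicit crossing
# scans, all-pairs concordance) so they share no code path with the package.

oracle_quantile7 <- function(v, p) {
  v <- sort(v)
  h <- (length(v) - 1) * p + 1
  lo <- floor(h)
  if (lo == length(v)) return(v[lo])
  v[lo] + (h - lo) * (v[lo + 1] - v[lo])
}

oracle_pearson <- function(a, b) {
  da <- a - sum(a) / length(a)
  db <- b - sum(b) / length(b)
  den <- sqrt(sum(da^2) * sum(db^2))
  if (den == 0) 0 else sum(da * db) / den
}

oracle_crossings <- function(s, level) {
  k <- 0L
  for (i in seq_len(length(s) - 1L)) {
    if ((s[i] - level) * (s[i + 1] - level) < 0) k <- k + 1L
  }
  k
}

oracle_series_stats <- function(v, prefix, dur) {
  n <- length(v)
  m <- sum(v) / n
  sdv <- sqrt(sum((v - m)^2) / (n - 1))
  out <- c(
    Mean = m, Sd = sdv, RMS = sqrt(sum(v^2) / n),
    Min = min(v), Max = max(v),
    "25thp" = oracle_quantile7(v, 0.25),
    Median = oracle_quantile7(v, 0.5),
    "75thp" = oracle_quantile7(v, 0.75),
    coefvariation = if (sdv == 0 || m == 0) 0 else sdv / m,
    MCR = oracle_crossings(v, m) / dur,
    MMCR = 0.5 * (oracle_crossings(v, (m + max(v)) / 2) +
                    oracle_crossings(v, (m + min(v)) / 2)) / dur,
    autocorr = oracle_pearson(v[-n], v[-1])
  )
  names(out) <- paste0(prefix, names(out))
  out
}

# all 76 registry features from first principles
oracle_features <- function(s, rate = 100) {
  n <- nrow(s)
  dur <- n / rate
  x <- s[, 1]; y <- s[, 2]; z <- s[, 3]
  r <- sqrt(x^2 + y^2 + z^2)
  rbar <- sum(r) / n
  dev <- r - rbar
  m2 <- sum(dev^2) / n

  out <- c(
    ENMOtrunc = sum(ifelse(r > 1, r - 1, 0)) / n,
    ENMOabs = sum(abs(r - 1)) / n,
    MAD = sum(abs(dev)) / n,
    MPD = sqrt(m2),
    kurt = if (m2 == 0) 0 else (sum(dev^4) / n) / m2^2 - 3,
    skew = if (m2 == 0) 0 else (sum(dev^3) / n) / m2^1.5,
    oracle_series_stats(r, "", dur),
    oracle_series_stats(x, "x", dur),
    oracle_series_stats(y, "y", dur),
    oracle_series_stats(z, "z", dur),
    xRange = max(x) - min(x), yRange = max(y) - min(y),
    zRange = max(z) - min(z),
    Covxy = sum((x - mean(x)) * (y - mean(y))) / n,
    Covxz = sum((x - mean(x)) * (z - mean(z))) / n,
    Covyz = sum((y - mean(y)) * (z - mean(z))) / n,
    corrxy = oracle_pearson(x, y),
    corrxz = oracle_pearson(x, z),
    corryz = oracle_pearson(y, z),
    TAC = sum(ifelse(r > 1, r - 1, 0)),
    xTAC = sum(abs(x - mean(x))), yTAC = sum(abs(y - mean(y))),
    zTAC = sum(abs(z - mean(z)))
  )
  deg <- 180 / pi
  pitch <- atan2(x, sqrt(y^2 + z^2)) * deg
  roll <- atan2(y, sqrt(x^2 + z^2)) * deg
  yaw <- atan2(z, sqrt(x^2 + y^2)) * deg
  mx <- mean(x); my <- mean(y); mz <- mean(z)
  sdev <- function(v) sqrt(sum((v - mean(v))^2) / (length(v) - 1))
  out <- c(out,
    pitchg = atan2(mx, sqrt(my^2 + mz^2)) * deg,
    rollg = atan2(my, sqrt(mx^2 + mz^2)) * deg,
    yawg = atan2(mz, sqrt(mx^2 + my^2)) * deg,
    sdpitch = sdev(pitch), sdroll = sdev(roll), sdyaw = sdev(yaw),
    avgpitch = mean(pitch), avgroll = mean(roll), avgyaw = mean(yaw))
  out
}

# all-pairs Harrell concordance by enumeration
brute_cindex <- function(times, events, risk) {
  conc <- 0; comp <- 0
  n <- length(times)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      comparable <-
        (times[i] < times[j] && events[i] == 1) ||
        (times[i] == times[j] && events[i] == 1 && events[j] == 0)
      if (!comparable) next
      comp <- comp + 1
      if (risk[i] > risk[j]) conc <- conc + 1
      else if (risk[i] == risk[j]) conc <- conc + 0.5
    }
  }
  if (comp == 0) stop("no comparable pairs")
  conc / comp
}

# maximal walking runs by index-by-index scan
brute_runs <- function(labels) {
  starts <- integer(); lens <- integer()
  i <- 1L; n <- length(labels)
  while (i <= n) {
    if (labels[i] == "walking") {
      j <- i
      while (j < n && labels[j + 1L] == "walking") j <- j + 1L
      starts <- c(starts, i); lens <- c(lens, j - i + 1L)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  data.frame(start = starts, length = lens)
}

# Breslow log partial likelihood for a single covariate (1-D grid oracle)
breslow_loglik_1d <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    rs <- time >= time[i]
    ll <- ll + x[i] * beta - log(sum(exp(x[rs] * beta)))
  }
  ll
}
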