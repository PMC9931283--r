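#' @title Raw-recording I/O and epoch segmentation
#' @description
#' A raw recording is a fixed-rate stream of tri-axial acceleration samples in
#' g. Two on-disk formats are supported: plain CSV with a mandatory
#' `t,x,y,z` header (readable anywhere, used for small files and tests) and a
#' chunk-free columnar binary container with an embedded header (rate, start
#' time, sample count) for week-long files. The original device (CWA) format
#' is out of scope; Biobank-style calibration is assumed upstream.
#' @name signal_io
NULL

BIN_MAGIC <- "WMRB"

new_raw_recording <- function(samples, sampling_rate_hz, start_time = 0) {
  samples <- as.matrix(samples)
  colnames(samples) <- c("x", "y", "z")
  structure(
    list(samples = samples, sampling_rate_hz = sampling_rate_hz,
         start_time = start_time),
    class = "raw_recording"
  )
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %d samples at %g Hz (%.1f s)\n",
              nrow(x$samples), x$sampling_rate_hz,
              nrow(x$samples) / x$sampling_rate_hz))
  invisible(x)
}

#' Read a raw accelerometer recording
#'
#' @param path File path.
#' @param format `"csv"` (columns `t,x,y,z`, header mandatory, comma
#'   separated, `.` decimal) or `"bin"` (the package's columnar binary
#'   container).
#' @param sampling_rate_hz Declared sampling rate for CSV input (the binary
#'   header carries its own). The CSV time column is validated for strict
#'   monotonicity but the declared rate is authoritative.
#' @param unit `"g"` (default) or `"ms2"`; `ms2` input is converted to g by
#'   dividing by 9.81 at read time.
#' @return A `raw_recording`: list with `samples` (n x 3 matrix in g),
#'   `sampling_rate_hz`, `start_time`.
#' @export
read_recording <- function(path, format = c("csv", "bin"),
                           sampling_rate_hz = 100, unit = c("g", "ms2")) {
  format <- match.arg(format)
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "csv") {
    df <- utils::read.csv(path, header = TRUE)
    if (nrow(df) == 0L) stop("empty recording file: ", path)
    if (!identical(names(df)[1:4], c("t", "x", "y", "z"))) {
      stop("CSV recording must have header t,x,y,z; got: ",
           paste(names(df), collapse = ","))
    }
    for (cn in c("t", "x", "y", "z")) {
      bad <- which(!is.finite(df[[cn]]))
      if (length(bad)) {
        stop(sprintf("non-finite or non-numeric value in column '%s' at row %d",
                     cn, bad[1]))
      }
    }
    dt <- diff(df$t)
    if (any(dt <= 0)) {
      stop("non-monotone timestamps at row ", which(dt <= 0)[1] + 1L)
    }
    samples <- as.matrix(df[, c("x", "y", "z")])
    start_time <- df$t[1]
    rate <- sampling_rate_hz
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    magic <- readChar(con, 4L, useBytes = TRUE)
    if (!identical(magic, BIN_MAGIC)) stop("not a recording container: ", path)
    rate <- readBin(con, "double", 1L)
    start_time <- readBin(con, "double", 1L)
    n <- readBin(con, "integer", 1L)
    if (!length(n) || n <= 0) stop("empty recording file: ", path)
    vals <- readBin(con, "double", n * 3L)
    if (length(vals) != n * 3L) stop("truncated recording container: ", path)
    samples <- matrix(vals, ncol = 3L)
    if (!all(is.finite(samples))) stop("non-finite sample in container: ", path)
  }
  if (unit == "ms2") samples <- samples / 9.81
  new_raw_recording(samples, rate, start_time)
}

#' Write a raw recording
#'
#' @param recording A `raw_recording`.
#' @param path Output path.
#' @param format `"csv"` or `"bin"`; the binary container round-trips samples
#'   at full double precision.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path, format = c("csv", "bin")) {
  format <- match.arg(format)
  s <- recording$samples
  if (format == "csv") {
    t <- recording$start_time +
      (seq_len(nrow(s)) - 1L) / recording$sampling_rate_hz
    df <- data.frame(t = t, x = s[, 1], y = s[, 2], z = s[, 3])
    utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, row.names = FALSE, quote = FALSE)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(BIN_MAGIC, con, eos = NULL)
    writeBin(as.double(recording$sampling_rate_hz), con)
    writeBin(as.double(recording$start_time), con)
    writeBin(as.integer(nrow(s)), con)
    writeBin(as.double(s), con)
  }
  invisible(path)
}

#' Segment a recording into labeled 30-second epochs
#'
#' Splits the sample stream into contiguous, non-overlapping windows of
#' `epoch_s` seconds (3000 samples at 100 Hz). A trailing partial window is
#' dropped, never padded. One activity label per complete epoch is required.
#'
#' @param recording A `raw_recording`.
#' @param labels Character vector over `{"walking", "other"}` with one entry
#'   per complete epoch.
#' @param epoch_s Epoch length in seconds (default 30).
#' @return List of epochs; each epoch is a list with `index` (1-based),
#'   `samples` (`rate * epoch_s` x 3 matrix), `label`, `sampling_rate_hz` and
#'   `duration_s`.
#' @examples
#' rec <- walkmort:::new_raw_recording(matrix(rnorm(9000 * 3), ncol = 3), 100)
#' length(segment_epochs(rec, labels = c("walking", "other", "walking")))
#' @export
segment_epochs <- function(recording, labels, epoch_s = 30) {
  check_scalar(epoch_s, "epoch_s", lower = 0, strict_lower = TRUE)
  rate <- recording$sampling_rate_hz
  per <- rate * epoch_s
  if (per != round(per)) stop("epoch_s * sampling_rate_hz must be integral")
  per <- as.integer(per)
  n_epochs <- nrow(recording$samples) %/% per
  labels <- as.character(labels)
  if (length(labels) != n_epochs) {
    stop(sprintf("label count (%d) does not match complete epoch count (%d)",
                 length(labels), n_epochs))
  }
  if (n_epochs && !all(labels %in% c("walking", "other"))) {
    stop("labels must be 'walking' or 'other'")
  }
  lapply(seq_len(n_epochs), function(i) {
    rows <- ((i - 1L) * per + 1L):(i * per)
    list(index = i, samples = recording$samples[rows, , drop = FALSE],
         label = labels[i], sampling_rate_hz = rate, duration_s = epoch_s)
  })
}

#' Read / write an epoch label file
#'
#' CSV with columns `epoch_index,label`, one row per epoch in index order.
#'
#' @param path File path.
#' @return `read_labels`: character vector of labels in epoch order.
#' @export
read_labels <- function(path) {
  df <- utils::read.csv(path, header = TRUE)
  if (!all(c("epoch_index", "label") %in% names(df))) {
    stop("labels file must have columns epoch_index,label")
  }
  df <- df[order(df$epoch_index), ]
  as.character(df$label)
}

#' @rdname read_labels
#' @param labels Character vector of epoch labels.
#' @export
write_labels <- function(labels, path) {
  utils::write.csv(
    data.frame(epoch_index = seq_along(labels), label = labels),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
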