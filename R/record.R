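#' Multichannel in-ear pressure record
#'
#' Container for uniformly sampled, clock-aligned traces: left and right in-ear
#' infrasonic channels plus an optional simultaneous reference ECG. All
#' channels share one sample clock (the acquisition hardware samples them
#' simultaneously), so a single `sampling_rate` and `start_time` apply.
#'
#' @param channels Named list of equal-length numeric vectors. Recognised
#'   names: `ih_left`, `ih_right`, `ecg`; at least one channel is required.
#' @param sampling_rate Sampling rate in Hz (default 1000).
#' @param start_time Time of the first sample in ms (default 0).
#' @return An object of class `"multi_channel_record"`.
#' @export
multi_channel_record <- function(channels, sampling_rate = 1000,
                                 start_time = 0) {
  if (!is.list(channels) || length(channels) == 0L ||
      is.null(names(channels)) || any(!nzchar(names(channels)))) {
    stop("'channels' must be a non-empty named list of numeric vectors",
         call. = FALSE)
  }
  lens <- vapply(channels, length, integer(1))
  if (length(unique(lens)) != 1L) {
    stop("all channels must have equal length (shared clock)", call. = FALSE)
  }
  if (!all(vapply(channels, is.numeric, logical(1)))) {
    stop("all channels must be numeric", call. = FALSE)
  }
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    stop("'sampling_rate' must be positive (Hz)", call. = FALSE)
  }
  structure(
    list(
      channels = lapply(channels, as.numeric),
      sampling_rate = sampling_rate,
      start_time = start_time
    ),
    class = "multi_channel_record"
  )
}

#' @export
print.multi_channel_record <- function(x, ...) {
  n <- record_length(x)
  cat(sprintf(
    "Multichannel record: %d samples @ %g Hz (%.1f s), channels: %s\n",
    n, x$sampling_rate, n / x$sampling_rate,
    paste(names(x$channels), collapse = ", ")
  ))
  invisible(x)
}

#' Number of samples per channel of a record
#' @param record A [multi_channel_record()].
#' @return Integer sample count.
#' @export
record_length <- function(record) {
  stopifnot(inherits(record, "multi_channel_record"))
  length(record$channels[[1]])
}

#' Sample timestamps of a record
#' @param record A [multi_channel_record()].
#' @return Numeric vector of sample times in ms.
#' @export
record_times <- function(record) {
  stopifnot(inherits(record, "multi_channel_record"))
  record$start_time +
    (seq_len(record_length(record)) - 1) * 1000 / record$sampling_rate
}

#' Series of detected (or ground-truth) heartbeats
#'
#' Holds strictly increasing beat times and the derived interbeat intervals
#' (IBIs, successive differences).
#'
#' @param peak_times Beat times in ms, strictly increasing.
#' @param source_channel Where the beats came from: `"left"`, `"right"`,
#'   `"merged"`, `"ecg"` or `"truth"`.
#' @return An object of class `"beat_series"` with fields `peak_times`,
#'   `ibis` (ms, length `length(peak_times) - 1`) and `source_channel`.
#' @export
beat_series <- function(peak_times, source_channel = "merged") {
  peak_times <- as.numeric(peak_times)
  if (length(peak_times) >= 2L && any(diff(peak_times) <= 0)) {
    stop("'peak_times' must be strictly increasing", call. = FALSE)
  }
  structure(
    list(
      peak_times = peak_times,
      ibis = if (length(peak_times) >= 2L) diff(peak_times) else numeric(0),
      source_channel = source_channel
    ),
    class = "beat_series"
  )
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf(
    "Beat series (%s): %d beats, %d IBIs%s\n",
    x$source_channel, length(x$peak_times), length(x$ibis),
    if (length(x$ibis)) {
      sprintf(", mean IBI %.1f ms (HR %.1f bpm)",
              mean(x$ibis), 60000 / mean(x$ibis))
    } else ""
  ))
  invisible(x)
}

#' Write a record to the delimited-text dialect
#'
#' One row per sample with header `t_ms,ih_left,ih_right,ecg`; absent channels
#' are omitted from the header. Time is written in ms.
#'
#' @param record A [multi_channel_record()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path) {
  stopifnot(inherits(record, "multi_channel_record"))
  df <- data.frame(t_ms = record_times(record))
  for (nm in intersect(c("ih_left", "ih_right", "ecg"), names(record$channels))) {
    df[[nm]] <- record$channels[[nm]]
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a record from the delimited-text dialect
#'
#' Expects a comma-separated file with header containing `t_ms` plus any of
#' `ih_left`, `ih_right`, `ecg`; the time column must increase uniformly (the
#' sampling rate is inferred from it). Malformed rows and non-monotone time
#' are reported with the offending row number.
#'
#' @param path CSV path written by [write_record()] (or equivalent).
#' @return A [multi_channel_record()].
#' @export
read_record <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  if (!"t_ms" %in% header) {
    stop("missing header: expected a 't_ms' column in ", path, call. = FALSE)
  }
  df <- tryCatch(
    utils::read.csv(path, colClasses = "numeric"),
    warning = function(w) stop("malformed record file ", path, ": ",
                               conditionMessage(w), call. = FALSE),
    error = function(e) stop("malformed record file ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  bad <- which(!stats::complete.cases(df))
  if (length(bad)) {
    stop(sprintf("malformed row %d in %s", bad[1] + 1L, path), call. = FALSE)
  }
  dt <- diff(df$t_ms)
  if (any(dt <= 0)) {
    stop(sprintf("non-monotone time column at row %d in %s",
                 which(dt <= 0)[1] + 2L, path), call. = FALSE)
  }
  if (max(abs(dt - dt[1])) > 1e-6 * dt[1]) {
    stop("non-uniform sampling in ", path, call. = FALSE)
  }
  chans <- intersect(c("ih_left", "ih_right", "ecg"), names(df))
  if (!length(chans)) {
    stop("no signal channels found in ", path, call. = FALSE)
  }
  multi_channel_record(
    channels = as.list(df[chans]),
    sampling_rate = 1000 / dt[1],
    start_time = df$t_ms[1]
  )
}

#' Write a beat series as CSV
#'
#' Columns `peak_time_ms` and `ibi_ms` (first row's IBI is `NA`).
#' @param beats A [beat_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_beats <- function(beats, path) {
  stopifnot(inherits(beats, "beat_series"))
  df <- data.frame(
    peak_time_ms = beats$peak_times,
    ibi_ms = c(NA_real_, beats$ibis)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a beat series written by [write_beats()]
#' @param path CSV path.
#' @param source_channel Label for the returned series.
#' @return A [beat_series()].
#' @export
read_beats <- function(path, source_channel = "merged") {
  df <- utils::read.csv(path)
  beat_series(df$peak_time_ms, source_channel = source_channel)
}
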