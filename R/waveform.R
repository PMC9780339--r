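#' Stack beat-aligned waveform segments
#'
#' Extracts a window around each anchor time (by default 250 ms before to
#' 650 ms after the ECG R-peak), resamples it on a 1 ms grid and z-score
#' normalizes each beat (mean 0, SD 1), so that beats of different amplitude
#' are comparable. Anchors without full support inside the trace are skipped
#' and counted.
#'
#' @param trace Numeric trace.
#' @param anchors Anchor times in ms (ECG R-peaks, or a [beat_series()]).
#' @param pre,post Window extent before/after the anchor, ms.
#' @param sampling_rate Sampling rate of `trace` in Hz.
#' @param start_time Time of the first sample of `trace`, ms.
#' @param normalize Z-score each beat (default `TRUE`).
#' @return An object of class `"beat_stack"`: `beats` (matrix, one row per
#'   beat, one column per ms), `time_ms` (relative to the anchor),
#'   `mean_trace`, `sd_trace` (0 for a single beat, by convention) and
#'   `n_skipped`.
#' @export
stack_beats <- function(trace, anchors, pre = 250, post = 650,
                        sampling_rate = 1000, start_time = 0,
                        normalize = TRUE) {
  if (inherits(anchors, "beat_series")) anchors <- anchors$peak_times
  n <- length(trace)
  tmax <- start_time + (n - 1) * 1000 / sampling_rate
  rel <- seq(-pre, post, by = 1)
  sample_t <- start_time + (seq_len(n) - 1) * 1000 / sampling_rate
  rows <- list()
  skipped <- 0L
  for (a in anchors) {
    if (a - pre < start_time || a + post > tmax) { skipped <- skipped + 1L; next }
    y <- stats::approx(sample_t, trace, xout = a + rel)$y
    if (normalize) {
      s <- stats::sd(y)
      y <- if (s < 1e-12) y - mean(y) else (y - mean(y)) / s
    }
    rows[[length(rows) + 1L]] <- y
  }
  if (!length(rows)) stop("no anchor has full support inside the trace",
                          call. = FALSE)
  beats <- do.call(rbind, rows)
  structure(
    list(
      beats = beats,
      time_ms = rel,
      mean_trace = colMeans(beats),
      sd_trace = if (nrow(beats) > 1) apply(beats, 2, stats::sd)
                 else rep(0, ncol(beats)),
      n_skipped = skipped
    ),
    class = "beat_stack"
  )
}

#' @export
print.beat_stack <- function(x, ...) {
  cat(sprintf(
    "Beat stack: %d beats x %d samples ([%d, %d] ms around the anchor), %d skipped\n",
    nrow(x$beats), ncol(x$beats), min(x$time_ms), max(x$time_ms), x$n_skipped
  ))
  invisible(x)
}

#' Lagged Pearson cross-correlation of two waveforms
#'
#' For each lag `tau` (in samples, 0..`max_lag` ms at 1 kHz), computes the
#' Pearson correlation between `x[i]` and `y[i + tau]` over the valid overlap
#' (no zero padding, which would bias the coefficient toward zero). Both
#' waveforms must be non-constant.
#'
#' @param x,y Equal-length numeric waveforms on a 1 ms grid.
#' @param max_lag Largest lag in ms (default 500).
#' @return Numeric vector `r` of length `max_lag + 1`, with attribute
#'   `"lag_ms"` = `0:max_lag`.
#' @export
cross_correlation <- function(x, y, max_lag = 500) {
  if (length(x) != length(y)) stop("waveforms must have equal length",
                                   call. = FALSE)
  if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12) {
    stop("constant waveform: correlation undefined", call. = FALSE)
  }
  n <- length(x)
  max_lag <- min(max_lag, n - 3L)
  r <- vapply(0:max_lag, function(tau) {
    xs <- x[1:(n - tau)]
    ys <- y[(1 + tau):n]
    if (stats::sd(xs) < 1e-12 || stats::sd(ys) < 1e-12) return(NA_real_)
    sum((xs - mean(xs)) * (ys - mean(ys))) /
      sqrt(sum((xs - mean(xs))^2) * sum((ys - mean(ys))^2))
  }, numeric(1))
  attr(r, "lag_ms") <- 0:max_lag
  r
}

#' Waveform fidelity of a beat stack
#'
#' Fidelity is the median over waveform pairs of the maximum lagged Pearson
#' cross-correlation, with lags searched between 0 and 500 ms. In
#' `"successive"` mode the pairs are consecutive beats of one stack — high
#' values mean the pulse shape repeats faithfully from beat to beat. In
#' `"left_vs_right"` mode each pair is the left- and right-channel waveform
#' of the same heartbeat (pass the second channel's stack as `stack2`).
#'
#' @param stack A [stack_beats()] result.
#' @param stack2 Second-channel stack for `"left_vs_right"` mode.
#' @param mode `"successive"` or `"left_vs_right"`.
#' @param max_lag Largest lag searched, ms.
#' @return An object of class `"fidelity_result"` with `fidelity` (the
#'   median), `pair_max` and `lag_at_max` (per pair, ms).
#' @export
fidelity <- function(stack, stack2 = NULL,
                     mode = c("successive", "left_vs_right"), max_lag = 500) {
  mode <- match.arg(mode)
  stopifnot(inherits(stack, "beat_stack"))
  if (mode == "successive") {
    nb <- nrow(stack$beats)
    if (nb < 2L) stop("successive fidelity needs at least 2 beats",
                      call. = FALSE)
    pairs <- lapply(seq_len(nb - 1L),
                    function(i) list(x = stack$beats[i, ],
                                     y = stack$beats[i + 1L, ], id = i))
  } else {
    stopifnot(inherits(stack2, "beat_stack"))
    nb <- min(nrow(stack$beats), nrow(stack2$beats))
    if (nb < 1L) stop("no paired beats", call. = FALSE)
    pairs <- lapply(seq_len(nb),
                    function(i) list(x = stack$beats[i, ],
                                     y = stack2$beats[i, ], id = i))
  }
  pair_max <- numeric(length(pairs))
  lag_at_max <- numeric(length(pairs))
  for (k in seq_along(pairs)) {
    p <- pairs[[k]]
    if (stats::sd(p$x) < 1e-12 || stats::sd(p$y) < 1e-12) {
      stop("constant waveform in pair ", p$id, ": correlation undefined",
           call. = FALSE)
    }
    r <- cross_correlation(p$x, p$y, max_lag)
    i <- which.max(r)
    pair_max[k] <- r[i]
    lag_at_max[k] <- attr(r, "lag_ms")[i]
  }
  structure(
    list(fidelity = stats::median(pair_max), pair_max = pair_max,
         lag_at_max = lag_at_max, mode = mode, n_pairs = length(pairs)),
    class = "fidelity_result"
  )
}

#' @export
print.fidelity_result <- function(x, ...) {
  cat(sprintf(
    "Waveform fidelity (%s): F = %.4f over %d pairs (pair range %.4f-%.4f)\n",
    x$mode, x$fidelity, x$n_pairs, min(x$pair_max), max(x$pair_max)
  ))
  invisible(x)
}

#' Delay of the in-ear pulse relative to the ECG R-peak
#'
#' For each R-peak, the pulse peak is the maximum of the in-ear trace between
#' that beat and the next, and the pulse onset is the first crossing of a
#' configurable fraction (default 10%) of the peak amplitude above the local
#' baseline (the pre-peak minimum), located with sub-sample interpolation.
#' Returns the mean onset and peak delays across beats.
#'
#' @param ih_trace Calibrated in-ear trace.
#' @param ecg_beats A [beat_series()] of R-peak times (ms).
#' @param sampling_rate Sampling rate in Hz.
#' @param start_time Time of the first sample, ms.
#' @param onset_frac Onset threshold as a fraction of peak amplitude above
#'   baseline.
#' @return A list with `onset_delay`, `peak_delay` (means, ms), `per_beat`
#'   (data frame) and `n_skipped`.
#' @export
ih_delay <- function(ih_trace, ecg_beats, sampling_rate = 1000,
                     start_time = 0, onset_frac = 0.1) {
  stopifnot(inherits(ecg_beats, "beat_series"))
  tms <- start_time + (seq_along(ih_trace) - 1) * 1000 / sampling_rate
  bt <- ecg_beats$peak_times
  res <- list()
  skipped <- 0L
  for (i in seq_len(length(bt) - 1L)) {
    a <- bt[i]; b <- bt[i + 1L]
    idx <- which(tms > a & tms < b)
    if (length(idx) < 5L) { skipped <- skipped + 1L; next }
    seg <- ih_trace[idx]
    pk <- which.max(seg)
    baseline <- min(seg[1:pk])
    amp <- seg[pk] - baseline
    if (amp < 1e-12) { skipped <- skipped + 1L; next }
    thr <- baseline + onset_frac * amp
    above <- which(seg[1:pk] >= thr)
    if (!length(above)) { skipped <- skipped + 1L; next }
    j <- above[1]
    onset_t <- if (j == 1L) tms[idx[1]] else {
      # linear interpolation of the crossing between samples j-1 and j
      t0 <- tms[idx[j - 1]]; t1 <- tms[idx[j]]
      y0 <- seg[j - 1]; y1 <- seg[j]
      t0 + (thr - y0) / (y1 - y0) * (t1 - t0)
    }
    res[[length(res) + 1L]] <- c(onset = onset_t - a, peak = tms[idx[pk]] - a)
  }
  if (!length(res)) stop("no usable pulse found after any R-peak",
                         call. = FALSE)
  per_beat <- as.data.frame(do.call(rbind, res))
  list(
    onset_delay = mean(per_beat$onset),
    peak_delay = mean(per_beat$peak),
    per_beat = per_beat,
    n_skipped = skipped
  )
}
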