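#' Calibrate a record: remove DC and audible-band content
#'
#' Level-2 processing. Each in-ear channel is mean-centred and low-pass
#' filtered with a zero-phase (forward-backward) Butterworth filter so that
#' audible-band content — music played through the earbud speaker above all —
#' is removed while the infrasonic cardiac band is preserved and peak timing
#' is not shifted. The ECG channel, if present, is only mean-centred.
#'
#' @param record A [multi_channel_record()].
#' @param cutoff Low-pass cutoff in Hz (default 20, the top of the infrasonic
#'   band).
#' @param order Butterworth order (default 4); applied forward and backward,
#'   so the effective attenuation is doubled.
#' @return A calibrated [multi_channel_record()].
#' @export
calibrate <- function(record, cutoff = 20, order = 4) {
  stopifnot(inherits(record, "multi_channel_record"))
  fs <- record$sampling_rate
  n <- record_length(record)
  min_n <- ceiling(fs / 2)  # filter warm-up
  if (n < min_n) {
    stop("record too short to calibrate: need at least ",
         sprintf("%.2f s", min_n / fs), " of data", call. = FALSE)
  }
  if (cutoff <= 0 || cutoff >= fs / 2) {
    stop("'cutoff' must lie in (0, sampling_rate/2)", call. = FALSE)
  }
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  chans <- record$channels
  for (nm in intersect(c("ih_left", "ih_right"), names(chans))) {
    x <- chans[[nm]] - mean(chans[[nm]])
    chans[[nm]] <- as.numeric(signal::filtfilt(bf, x))
  }
  if ("ecg" %in% names(chans)) {
    chans$ecg <- chans$ecg - mean(chans$ecg)
  }
  multi_channel_record(chans, fs, record$start_time)
}

#' Time-domain features of a one-second signal window
#'
#' Level-3 feature extraction: 24 named time-domain statistics summarising
#' signal strength, distribution shape and morphology, used by the quality
#' classifier to separate clean cardiac windows from motion-artifact windows.
#' Constant windows are handled by convention (shape and correlation features
#' set to 0).
#'
#' @param x Numeric window (fully populated).
#' @param sampling_rate Sampling rate in Hz.
#' @return A named numeric vector of length 24.
#' @export
window_features <- function(x, sampling_rate = 1000) {
  if (anyNA(x) || !length(x)) stop("window must be fully populated", call. = FALSE)
  v <- stats::var(x)
  s <- sqrt(v)
  rms <- sqrt(mean(x^2))
  q <- stats::quantile(x, c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE)
  xc <- x - mean(x)
  constant <- s < 1e-12
  zcr <- if (constant) 0 else mean(diff(sign(xc + 1e-300)) != 0)
  skw <- if (constant) 0 else e1071::skewness(x)
  krt <- if (constant) 0 else e1071::kurtosis(x)
  acf_l <- if (constant) c(0, 0, 0) else {
    a <- stats::acf(x, lag.max = 5, plot = FALSE, demean = TRUE)$acf
    c(a[2], a[3], a[6])
  }
  # dominant peak of the rectified, demeaned signal
  r <- abs(xc)
  pk_i <- which.max(r)
  pk_h <- r[pk_i]
  pk_w <- if (pk_h < 1e-12) 0 else {
    above <- r >= pk_h / 2
    run <- rle(above)
    ends <- cumsum(run$lengths)
    starts <- ends - run$lengths + 1L
    j <- which(run$values & starts <= pk_i & ends >= pk_i)
    (run$lengths[j][1]) * 1000 / sampling_rate
  }
  dif <- diff(x)
  n_peaks <- if (length(x) < 3) 0 else {
    thr <- mean(r) + stats::sd(r)
    sum(dif[-length(dif)] > 0 & dif[-1] <= 0 & r[2:(length(x) - 1)] > thr,
        na.rm = TRUE)
  }
  c(
    mean = mean(x), variance = v, sd = s, rms = rms,
    min = min(x), max = max(x), range = max(x) - min(x),
    q05 = q[1], q25 = q[2], q50 = q[3], q75 = q[4], q95 = q[5],
    iqr = q[4] - q[2], mad = stats::mad(x),
    skewness = skw, kurtosis = krt,
    zero_cross_rate = zcr,
    crest_factor = if (rms < 1e-12) 0 else max(abs(x)) / rms,
    line_length = mean(abs(dif)),
    peak_height = pk_h, peak_width_ms = pk_w, peak_count = n_peaks,
    acf_lag1 = acf_l[1], acf_lag2 = acf_l[2]
  )
}

#' Build a labelled window corpus from the simulator
#'
#' Generates sinus-rhythm records, injects motion bursts into half of the
#' timeline, cuts the calibrated traces into one-second windows and labels
#' each window good (clean cardiac signal) or bad (motion) from the
#' ground-truth artifact mask. Used to train and evaluate the quality
#' classifier.
#'
#' @param n_windows Approximate number of windows to produce.
#' @param seed Integer seed.
#' @param window_length Window length in seconds.
#' @return A list with `features` (matrix, one row per window) and `labels`
#'   (factor `good`/`bad`).
#' @export
quality_corpus <- function(n_windows = 2000, seed = 1L, window_length = 1) {
  set.seed(as.integer(seed))
  win_ms <- window_length * 1000
  feats <- list()
  labs <- character(0)
  rec_dur <- 40
  k <- 0L
  while (length(labs) < n_windows) {
    k <- k + 1L
    spec <- rhythm_spec("sr_regular", duration = rec_dur,
                        mean_hr = stats::runif(1, 55, 95),
                        hrv_sd = stats::runif(1, 10, 40),
                        seed = seed + 17L * k)
    sim <- gen_ibi(spec)
    rec <- render_record(sim, waveform_model(noise_sd = 0.02),
                         seed = seed + 17L * k + 1L)
    dur_ms <- rec_dur * 1000
    # motion over alternating stretches, jittered, covering ~half the record
    starts <- seq(2000, dur_ms - 5200, by = 7000) +
      stats::runif(length(seq(2000, dur_ms - 5200, by = 7000)), 0, 1500)
    bursts <- data.frame(start_ms = starts, end_ms = starts + 3500)
    inj <- inject_artifacts(rec, motion_bursts = bursts,
                            seed = seed + 17L * k + 2L)
    cal <- calibrate(inj$record)
    x <- cal$channels$ih_left
    n_win <- floor(length(x) / (win_ms * cal$sampling_rate / 1000))
    wlen <- win_ms * cal$sampling_rate / 1000
    for (w in seq_len(n_win)) {
      idx <- ((w - 1) * wlen + 1):(w * wlen)
      frac_bad <- mean(inj$artifact_mask[idx])
      if (frac_bad > 0.1 && frac_bad < 0.9) next  # ambiguous boundary window
      feats[[length(feats) + 1L]] <- window_features(x[idx], cal$sampling_rate)
      labs <- c(labs, if (frac_bad >= 0.9) "bad" else "good")
    }
  }
  list(features = do.call(rbind, feats), labels = factor(labs, c("good", "bad")))
}

#' Train the window quality classifier
#'
#' Level-3 quality assessment: a single-hidden-layer perceptron (feed-forward
#' neural network) mapping the 24 window features to the probability that a
#' window contains a clean cardiac signal. Training standardizes the
#' features, balances the classes by case weights and holds out a fraction
#' for evaluation.
#'
#' @param features Numeric matrix, one row per window (from
#'   [window_features()] / [quality_corpus()]).
#' @param labels Factor with levels `good`, `bad`.
#' @param seed Integer seed (weights initialisation and the held-out split).
#' @param hidden Hidden-layer size.
#' @param holdout Fraction held out for the reported accuracy.
#' @return An object of class `"quality_model"`; its `holdout_accuracy` field
#'   reports the held-out evaluation.
#' @export
train_quality_classifier <- function(features, labels, seed = 1L,
                                     hidden = 8, holdout = 0.2) {
  labels <- factor(labels, c("good", "bad"))
  if (nlevels(droplevels(labels)) < 2L) {
    stop("training set must contain both good and bad windows", call. = FALSE)
  }
  stopifnot(nrow(features) == length(labels))
  set.seed(as.integer(seed))
  n <- nrow(features)
  test_i <- sample(n, round(holdout * n))
  train_i <- setdiff(seq_len(n), test_i)
  ctr <- colMeans(features[train_i, , drop = FALSE])
  scl <- apply(features[train_i, , drop = FALSE], 2, stats::sd)
  scl[scl < 1e-12] <- 1
  z <- scale(features, ctr, scl)
  w <- stats::ave(rep(1, length(train_i)), labels[train_i],
                  FUN = function(g) length(train_i) / (2 * length(g)))
  fit <- nnet::nnet(
    x = z[train_i, , drop = FALSE],
    y = as.numeric(labels[train_i] == "good"),
    weights = w, size = hidden, decay = 1e-3, maxit = 500,
    entropy = TRUE, trace = FALSE
  )
  pred_test <- as.numeric(stats::predict(fit, z[test_i, , drop = FALSE]))
  acc <- mean((pred_test >= 0.5) == (labels[test_i] == "good"))
  structure(
    list(net = fit, center = ctr, scale = scl,
         feature_names = colnames(features),
         threshold = 0.5, holdout_accuracy = acc, seed = as.integer(seed)),
    class = "quality_model"
  )
}

#' @export
print.quality_model <- function(x, ...) {
  cat(sprintf(
    "Window quality classifier: %d features, hidden size %d, held-out accuracy %.3f\n",
    length(x$feature_names), x$net$n[2], x$holdout_accuracy
  ))
  invisible(x)
}

#' Score the windows of one channel for signal quality
#'
#' Splits a trace into non-overlapping windows, extracts features and applies
#' a trained [train_quality_classifier()] model. The label is `good` when the
#' probability of clean cardiac signal reaches the model threshold.
#'
#' @param model A `"quality_model"`.
#' @param trace Numeric calibrated trace.
#' @param sampling_rate Sampling rate in Hz.
#' @param window_length Window length in seconds (default 1).
#' @param start_time Time of the first sample, ms.
#' @return A data frame of class `"quality_mask"` with columns
#'   `window_start_ms`, `score` and `good`.
#' @export
classify_quality <- function(model, trace, sampling_rate = 1000,
                             window_length = 1, start_time = 0) {
  stopifnot(inherits(model, "quality_model"))
  wlen <- round(window_length * sampling_rate)
  n_win <- floor(length(trace) / wlen)
  if (n_win == 0L) stop("trace shorter than one window", call. = FALSE)
  feats <- t(vapply(
    seq_len(n_win),
    function(w) window_features(trace[((w - 1) * wlen + 1):(w * wlen)],
                                sampling_rate),
    numeric(length(model$feature_names))
  ))
  z <- scale(feats, model$center, model$scale)
  score <- as.numeric(stats::predict(model$net, z))
  out <- data.frame(
    window_start_ms = start_time + (seq_len(n_win) - 1) * window_length * 1000,
    score = score,
    good = score >= model$threshold
  )
  class(out) <- c("quality_mask", "data.frame")
  attr(out, "window_length") <- window_length
  out
}

# Rolling quantile of |x| evaluated on a coarse grid and interpolated,
# so the adaptive threshold tracks slow amplitude changes cheaply.
.rolling_quantile <- function(x, fs, horizon_s, q, hop_s = 0.25) {
  n <- length(x)
  half <- round(horizon_s * fs / 2)
  hop <- max(1L, round(hop_s * fs))
  centers <- unique(c(seq(1L, n, by = hop), n))
  vals <- vapply(centers, function(i) {
    stats::quantile(x[max(1L, i - half):min(n, i + half)], q, names = FALSE)
  }, numeric(1))
  stats::approx(centers, vals, xout = seq_len(n), rule = 2)$y
}

#' Detect heartbeats with an adaptive amplitude threshold
#'
#' Level-4 event extraction. The detection threshold is a centred moving
#' quantile of the rectified trace (default: the 0.999 quantile — effectively
#' the rolling pulse amplitude — over a 3 s horizon) scaled by a factor
#' (default 0.5), so it adapts to slow amplitude drift and is independent of
#' the pulse duty cycle, which varies with heart rate. Local maxima above the
#' threshold are accepted greedily by amplitude subject to a refractory
#' period (default 250 ms, well below any physiological IBI), which keeps
#' only the larger of two nearby candidates.
#'
#' @param trace Calibrated numeric trace (bad-quality regions should be
#'   excluded via `quality_mask`).
#' @param sampling_rate Sampling rate in Hz.
#' @param horizon Rolling-quantile horizon in seconds.
#' @param quantile Quantile of the rectified signal used as the base
#'   statistic.
#' @param scale Multiplier applied to the rolling quantile.
#' @param refractory Refractory period in ms.
#' @param quality_mask Optional [classify_quality()] mask; candidate peaks in
#'   bad windows are discarded.
#' @param start_time Time of the first sample, ms.
#' @param source_channel Label for the returned series.
#' @return A [beat_series()]; empty when no sample exceeds the threshold.
#' @export
detect_peaks <- function(trace, sampling_rate = 1000,
                         horizon = 3, quantile = 0.999, scale = 0.5,
                         refractory = 250, quality_mask = NULL,
                         start_time = 0, source_channel = "left") {
  n <- length(trace)
  if (n == 0L) return(beat_series(numeric(0), source_channel))
  thr <- scale * .rolling_quantile(abs(trace), sampling_rate, horizon, quantile)
  i <- 2:(n - 1)
  cand <- i[trace[i] > trace[i - 1] & trace[i] >= trace[i + 1] &
              trace[i] > thr[i]]
  if (!length(cand)) return(beat_series(numeric(0), source_channel))
  cand_t <- start_time + (cand - 1) * 1000 / sampling_rate
  if (!is.null(quality_mask)) {
    wlen_ms <- attr(quality_mask, "window_length") * 1000
    wi <- findInterval(cand_t, quality_mask$window_start_ms)
    ok <- wi >= 1 & wi <= nrow(quality_mask)
    ok[ok] <- quality_mask$good[wi[ok]]
    cand <- cand[ok]; cand_t <- cand_t[ok]
    if (!length(cand)) return(beat_series(numeric(0), source_channel))
  }
  # greedy by amplitude under the refractory constraint
  ord <- order(trace[cand], decreasing = TRUE)
  accepted <- numeric(0)
  for (j in ord) {
    if (!length(accepted) || all(abs(cand_t[j] - accepted) >= refractory)) {
      accepted <- c(accepted, cand_t[j])
    }
  }
  beat_series(sort(accepted), source_channel)
}

#' Merge left and right beat series, favouring the better channel
#'
#' Level-5 fusion: within each quality window the beats of the channel with
#' the higher quality score are adopted (windows where both channels are bad
#' contribute no beats and are flagged as gaps). Across window boundaries,
#' beats closer than the refractory period are de-duplicated keeping the beat
#' from the higher-scoring channel.
#'
#' @param left,right [beat_series()] from the two channels of one record.
#' @param left_mask,right_mask Their [classify_quality()] masks (same window
#'   grid).
#' @param refractory De-duplication distance in ms.
#' @return A merged [beat_series()]; attribute `"gap_windows"` lists the
#'   start times (ms) of windows where both channels were bad.
#' @export
merge_channels <- function(left, right, left_mask, right_mask,
                           refractory = 250) {
  stopifnot(inherits(left, "beat_series"), inherits(right, "beat_series"),
            nrow(left_mask) == nrow(right_mask))
  if (any(left_mask$window_start_ms != right_mask$window_start_ms)) {
    stop("quality masks must share one window grid", call. = FALSE)
  }
  wlen_ms <- attr(left_mask, "window_length") * 1000
  starts <- left_mask$window_start_ms
  take <- list()
  score_of <- numeric(0)
  gaps <- numeric(0)
  for (w in seq_along(starts)) {
    lo <- starts[w]; hi <- lo + wlen_ms
    l_ok <- left_mask$good[w]; r_ok <- right_mask$good[w]
    if (!l_ok && !r_ok) { gaps <- c(gaps, lo); next }
    use_left <- if (l_ok && r_ok) left_mask$score[w] >= right_mask$score[w] else l_ok
    src <- if (use_left) left else right
    sc <- if (use_left) left_mask$score[w] else right_mask$score[w]
    ts <- src$peak_times[src$peak_times >= lo & src$peak_times < hi]
    if (length(ts)) {
      take[[length(take) + 1L]] <- ts
      score_of <- c(score_of, rep(sc, length(ts)))
    }
  }
  ts <- unlist(take)
  if (is.null(ts)) ts <- numeric(0)
  ord <- order(ts)
  ts <- ts[ord]; score_of <- score_of[ord]
  # boundary de-duplication: keep the higher-quality beat
  keep <- rep(TRUE, length(ts))
  i <- 1L
  while (i < length(ts)) {
    if (keep[i] && ts[i + 1] - ts[i] < refractory) {
      if (score_of[i + 1] > score_of[i]) keep[i] <- FALSE else keep[i + 1] <- FALSE
      i <- i + if (keep[i]) 2L else 1L
    } else i <- i + 1L
  }
  out <- beat_series(ts[keep], "merged")
  attr(out, "gap_windows") <- gaps
  out
}

#' Windowed vital signs from a beat series
#'
#' Level-5 output: heart rate and heart-rate variability per non-overlapping,
#' left-aligned, half-open window `[start, start + window_length)`. HR is
#' `60000 / mean(IBI)` in bpm; HRV is the SDNN (SD of the window's IBIs) by
#' default, with RMSSD available. An IBI belongs to the window containing its
#' midpoint; windows with fewer than two IBIs yield no estimate.
#'
#' @param beats A [beat_series()].
#' @param window_length Window length in seconds (20 s for steady reporting,
#'   5 s for maneuver tracking).
#' @param hrv_metric `"sdnn"` (default) or `"rmssd"`.
#' @return A data frame of class `"vitals_series"` with columns
#'   `window_start_ms`, `hr_bpm`, `hrv_ms`, `n`.
#' @export
compute_vitals <- function(beats, window_length = 20, hrv_metric = c("sdnn", "rmssd")) {
  stopifnot(inherits(beats, "beat_series"))
  hrv_metric <- match.arg(hrv_metric)
  if (window_length <= 0) stop("'window_length' must be positive", call. = FALSE)
  out <- data.frame(window_start_ms = numeric(0), hr_bpm = numeric(0),
                    hrv_ms = numeric(0), n = integer(0))
  if (length(beats$ibis) >= 2L) {
    mid <- (beats$peak_times[-1] + beats$peak_times[-length(beats$peak_times)]) / 2
    win <- floor(mid / (window_length * 1000))
    for (w in sort(unique(win))) {
      ib <- beats$ibis[win == w]
      if (length(ib) < 2L) next
      hrv <- if (hrv_metric == "sdnn") stats::sd(ib)
             else sqrt(mean(diff(ib)^2))
      out <- rbind(out, data.frame(
        window_start_ms = w * window_length * 1000,
        hr_bpm = 60000 / mean(ib), hrv_ms = hrv, n = length(ib)
      ))
    }
  }
  class(out) <- c("vitals_series", "data.frame")
  attr(out, "window_length") <- window_length
  out
}

#' Respiratory rate from the tachogram power spectral density
#'
#' Respiratory sinus arrhythmia modulates the IBI sequence at the breathing
#' frequency; for periodic breathing the rate is recovered as the dominant
#' frequency of the tachogram power spectral density within the respiratory
#' band (0.05–0.5 Hz, i.e. 3–30 breaths/min). The irregularly sampled
#' tachogram is interpolated onto a uniform 4 Hz grid and the spectrum is
#' computed with zero padding for fine frequency resolution. When no spectral
#' peak stands above the noise floor the result is indeterminate (`NA`), not
#' an error.
#'
#' @param x A [beat_series()] (the tachogram is taken from its IBIs) or a
#'   numeric low-frequency trace.
#' @param sampling_rate Sampling rate in Hz when `x` is a trace.
#' @param band Respiratory search band in Hz.
#' @param min_peak_ratio Dominant peak must exceed this multiple of the
#'   median in-band power to count as determinate.
#' @return Breaths per minute, or `NA_real_` when indeterminate.
#' @export
respiratory_rate <- function(x, sampling_rate = NULL, band = c(0.05, 0.5),
                             min_peak_ratio = 5) {
  grid_fs <- 4
  if (inherits(x, "beat_series")) {
    if (length(x$ibis) < 4L) return(NA_real_)
    span_s <- diff(range(x$peak_times)) / 1000
    if (span_s < 60) {
      stop("need at least 60 s of beats for respiratory-rate estimation",
           call. = FALSE)
    }
    tt <- x$peak_times[-1] / 1000
    grid <- seq(min(tt), max(tt), by = 1 / grid_fs)
    y <- stats::approx(tt, x$ibis, xout = grid, rule = 2)$y
  } else {
    if (is.null(sampling_rate)) {
      stop("'sampling_rate' is required for a raw trace", call. = FALSE)
    }
    if (length(x) / sampling_rate < 60) {
      stop("need at least 60 s of signal for respiratory-rate estimation",
           call. = FALSE)
    }
    dec <- max(1L, round(sampling_rate / grid_fs))
    nblk <- floor(length(x) / dec)
    y <- colMeans(matrix(x[seq_len(nblk * dec)], nrow = dec))
  }
  y <- y - mean(y)
  if (stats::sd(y) < 1e-9) return(NA_real_)
  nfft <- 2^ceiling(log2(length(y) * 8))
  spec <- Mod(stats::fft(c(y, rep(0, nfft - length(y)))))^2
  freq <- (seq_len(nfft) - 1) * grid_fs / nfft
  in_band <- freq >= band[1] & freq <= band[2]
  p <- spec[in_band]; f <- freq[in_band]
  if (!length(p) || max(p) < min_peak_ratio * stats::median(p)) return(NA_real_)
  60 * f[which.max(p)]
}
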