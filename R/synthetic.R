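#' Specification of a simulated cardiac rhythm
#'
#' Defines the ground-truth interbeat-interval (IBI) process for the
#' simulator. Four rhythm kinds are supported:
#'
#' * `"sr_regular"` — sinus rhythm with low, unstructured variability:
#'   IBIs are the mean IBI plus zero-mean Gaussian noise of SD `hrv_sd`.
#' * `"sr_resonant"` — sinus rhythm under paced (resonant) breathing:
#'   respiratory sinus arrhythmia modulates the IBI sinusoidally at the
#'   breathing frequency `1 / (rsa_inhale + rsa_exhale)` with peak-to-peak
#'   swing `rsa_ibi_swing` (default 300 ms, the swing paced breathing
#'   produces at the studied inhale:exhale ratios).
#' * `"valsalva"` — a four-phase deterministic trend (baseline, strain with a
#'   monotone IBI drop of more than 300 ms, a ~400 ms rebound overshoot at
#'   release, recovery) plus sinus-rhythm noise.
#' * `"af"` — atrial fibrillation: irregularly irregular IBIs drawn from a
#'   wide, weakly serially correlated distribution clipped to `af_ibi_range`
#'   (default 400–1600 ms, the span AF tachograms cover).
#'
#' @param kind One of `"sr_regular"`, `"sr_resonant"`, `"valsalva"`, `"af"`.
#' @param duration Record duration in seconds.
#' @param mean_hr Target mean heart rate in bpm (20–250).
#' @param hrv_sd SD of the unstructured IBI noise in ms.
#' @param rsa_inhale,rsa_exhale Inhale and exhale durations in seconds
#'   (resonant breathing; ratios 4:4, 4:6, 5:7 reproduce the studied paces).
#' @param rsa_ibi_swing Peak-to-peak IBI swing of the respiratory modulation,
#'   ms.
#' @param af_ibi_range Length-2 range (ms) the AF IBIs are clipped to; must
#'   lie within (200, 3000).
#' @param valsalva_drop IBI drop during strain, ms (> 300).
#' @param valsalva_rebound Rebound amplitude from the strain minimum at
#'   release, ms (~400).
#' @param seed Integer seed; the generator is fully reproducible.
#' @return An object of class `"rhythm_spec"`.
#' @export
rhythm_spec <- function(kind = c("sr_regular", "sr_resonant", "valsalva", "af"),
                        duration = 60,
                        mean_hr = 70,
                        hrv_sd = switch(match.arg(kind),
                                        sr_regular = 20, sr_resonant = 10,
                                        valsalva = 15, af = NA_real_),
                        rsa_inhale = 4,
                        rsa_exhale = 4,
                        rsa_ibi_swing = 300,
                        af_ibi_range = c(400, 1600),
                        valsalva_drop = 350,
                        valsalva_rebound = 400,
                        seed = 1L) {
  kind <- match.arg(kind)
  if (!is.numeric(duration) || duration <= 0) {
    stop("'duration' must be positive (s)", call. = FALSE)
  }
  if (mean_hr < 20 || mean_hr > 250) {
    stop("'mean_hr' must be in [20, 250] bpm", call. = FALSE)
  }
  if (kind != "af" && (!is.finite(hrv_sd) || hrv_sd < 0)) {
    stop("'hrv_sd' must be a non-negative number (ms)", call. = FALSE)
  }
  if (rsa_ibi_swing < 0) stop("'rsa_ibi_swing' must be >= 0", call. = FALSE)
  if (length(af_ibi_range) != 2L || af_ibi_range[1] >= af_ibi_range[2] ||
      af_ibi_range[1] <= 200 || af_ibi_range[2] >= 3000) {
    stop("'af_ibi_range' must be (low, high) within (200, 3000) ms",
         call. = FALSE)
  }
  base_ibi <- 60000 / mean_hr
  if (kind == "sr_resonant" && base_ibi - rsa_ibi_swing / 2 <= 0) {
    stop("'rsa_ibi_swing' too large: would produce non-positive IBIs",
         call. = FALSE)
  }
  if (kind == "valsalva" && base_ibi - valsalva_drop <= 0) {
    stop("'valsalva_drop' too large: would produce non-positive IBIs",
         call. = FALSE)
  }
  structure(
    list(
      kind = kind, duration = duration, mean_hr = mean_hr, hrv_sd = hrv_sd,
      rsa_inhale = rsa_inhale, rsa_exhale = rsa_exhale,
      rsa_ibi_swing = rsa_ibi_swing, af_ibi_range = af_ibi_range,
      valsalva_drop = valsalva_drop, valsalva_rebound = valsalva_rebound,
      seed = as.integer(seed)
    ),
    class = "rhythm_spec"
  )
}

# First beat is placed late enough that a full stacking window
# ([-250, +650] ms) fits around every beat.
.first_beat_offset <- 400

#' Generate a ground-truth beat sequence from a rhythm specification
#'
#' Draws IBIs according to the rhythm law in `spec` until the record duration
#' is filled, and returns the implied strictly increasing beat times together
#' with the rhythm label and (for paced breathing) the true respiratory rate.
#'
#' @param spec A [rhythm_spec()].
#' @return An object of class `"ground_truth"`: `beat_times` (ms), `ibis`
#'   (ms), `respiratory_rate` (breaths/min, `NA` when breathing is not
#'   paced), `rhythm_label` (`"SR"` or `"AF"`) and the generating `spec`.
#' @export
gen_ibi <- function(spec) {
  stopifnot(inherits(spec, "rhythm_spec"))
  set.seed(spec$seed)
  dur_ms <- spec$duration * 1000
  base <- 60000 / spec$mean_hr
  # generous upper bound on the number of beats
  n_max <- if (spec$kind == "af") {
    ceiling(dur_ms / spec$af_ibi_range[1]) + 8L
  } else {
    ceiling(dur_ms / max(200, base - 6 * max(0, spec$hrv_sd, na.rm = TRUE))) + 8L
  }

  beat_times <- numeric(0)
  t <- .first_beat_offset
  resp_rate <- NA_real_

  if (spec$kind == "sr_regular") {
    ibis <- base + stats::rnorm(n_max, 0, spec$hrv_sd)
  } else if (spec$kind == "sr_resonant") {
    f_breath <- 1 / (spec$rsa_inhale + spec$rsa_exhale)  # Hz
    resp_rate <- 60 * f_breath
    ibis <- numeric(0)
    tt <- t
    while (tt <= dur_ms && length(ibis) < n_max) {
      ibi <- base + (spec$rsa_ibi_swing / 2) * sin(2 * pi * f_breath * tt / 1000) +
        stats::rnorm(1, 0, spec$hrv_sd)
      ibis <- c(ibis, ibi)
      tt <- tt + ibi
    }
  } else if (spec$kind == "valsalva") {
    # four-phase deterministic trend sampled at each beat time
    ph <- c(baseline = 0.25, strain = 0.25, release = 0.1, recovery = 0.4) * dur_ms
    trend <- function(tt) {
      t1 <- ph[1]; t2 <- t1 + ph[2]; t3 <- t2 + ph[3]
      if (tt < t1) return(base)
      if (tt < t2) return(base - spec$valsalva_drop * (tt - t1) / ph[2])
      low <- base - spec$valsalva_drop
      if (tt < t3) return(low + spec$valsalva_rebound * (tt - t2) / ph[3])
      peak <- low + spec$valsalva_rebound
      peak + (base - peak) * min(1, (tt - t3) / ph[4])
    }
    ibis <- numeric(0)
    tt <- t
    while (tt <= dur_ms && length(ibis) < n_max) {
      ibi <- trend(tt) + stats::rnorm(1, 0, spec$hrv_sd)
      ibis <- c(ibis, ibi)
      tt <- tt + ibi
    }
  } else { # af
    lo <- spec$af_ibi_range[1]; hi <- spec$af_ibi_range[2]
    mu <- min(max(base, lo + 0.2 * (hi - lo)), hi - 0.2 * (hi - lo))
    sd_af <- (hi - lo) / 4
    phi <- 0.1  # weak serial correlation
    z <- stats::rnorm(n_max)
    for (i in 2:n_max) z[i] <- phi * z[i - 1] + sqrt(1 - phi^2) * z[i]
    ibis <- pmin(pmax(mu + sd_af * z, lo), hi)
  }

  if (any(ibis <= 0)) {
    stop("rhythm parameters produced non-positive IBIs; reduce 'hrv_sd' or ",
         "the modulation amplitude", call. = FALSE)
  }
  beat_times <- t + cumsum(c(0, ibis))
  keep <- beat_times <= dur_ms - 700  # leave room for the post-beat window
  beat_times <- beat_times[keep]
  if (length(beat_times) < 2L) {
    stop("duration too short for the requested rhythm", call. = FALSE)
  }
  structure(
    list(
      beat_times = beat_times,
      ibis = diff(beat_times),
      respiratory_rate = resp_rate,
      rhythm_label = if (spec$kind == "af") "AF" else "SR",
      spec = spec
    ),
    class = "ground_truth"
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "Ground truth (%s, %s): %d beats, mean IBI %.0f ms, HR %.1f bpm\n",
    x$rhythm_label, x$spec$kind, length(x$beat_times), mean(x$ibis),
    60000 / mean(x$ibis)
  ))
  invisible(x)
}

#' Waveform model for rendering in-ear and ECG traces
#'
#' Parameterizes the beat-to-waveform rendering. Each in-ear (IH) pulse is a
#' smooth unimodal asymmetric pulse (gamma envelope: fast rise, slow decay)
#' whose 10%-amplitude onset lags the ECG R-peak by `ih_onset_delay`
#' and whose maximum lags it by `ih_peak_delay` — the delays in-ear pressure
#' pulses show relative to ventricular depolarization. The ECG channel is a
#' narrow R-wave template centred on each beat. The two IH channels differ by
#' a per-channel gain, smoothing width and fall-width scale, emulating the
#' left/right difference in ear-canal frequency response.
#'
#' @param ih_onset_delay Onset delay in ms (default 84).
#' @param ih_peak_delay Peak delay in ms (default 158); must exceed
#'   `ih_onset_delay`.
#' @param ih_pulse_width Decay support in ms: the pulse is smoothly tapered
#'   to zero this long after its peak (default 280).
#' @param channel_response Named list (`left`, `right`), each with `gain`,
#'   `smooth_ms` (moving-average width) and `fall_scale` (multiplier on the
#'   falling-edge width).
#' @param ecg_width SD of the Gaussian R-wave template, ms.
#' @param noise_sd SD of additive white measurement noise on every channel,
#'   as a fraction of the cardiac pulse amplitude (0 = noiseless).
#' @param sampling_rate Sampling rate in Hz (default 1000).
#' @return An object of class `"waveform_model"`.
#' @export
waveform_model <- function(ih_onset_delay = 84,
                           ih_peak_delay = 158,
                           ih_pulse_width = 280,
                           channel_response = list(
                             left = list(gain = 1, smooth_ms = 0, fall_scale = 1),
                             right = list(gain = 0.9, smooth_ms = 21, fall_scale = 1.5)
                           ),
                           ecg_width = 5,
                           noise_sd = 0,
                           sampling_rate = 1000) {
  if (!(ih_onset_delay > 0 && ih_onset_delay < ih_peak_delay)) {
    stop("need 0 < ih_onset_delay < ih_peak_delay", call. = FALSE)
  }
  if (ih_pulse_width <= 60) {
    stop("'ih_pulse_width' must exceed the 60 ms taper", call. = FALSE)
  }
  if (sampling_rate <= 0) stop("'sampling_rate' must be positive", call. = FALSE)
  structure(
    list(
      ih_onset_delay = ih_onset_delay, ih_peak_delay = ih_peak_delay,
      ih_pulse_width = ih_pulse_width, channel_response = channel_response,
      ecg_width = ecg_width, noise_sd = noise_sd,
      sampling_rate = sampling_rate
    ),
    class = "waveform_model"
  )
}

# Fraction of the rise time at which a gamma-envelope pulse of shape k
# crosses 10% of its peak amplitude.
.gamma_r10 <- function(k) {
  stats::uniroot(function(r) r^k * exp(k * (1 - r)) - 0.1,
                 c(1e-6, 1 - 1e-6), tol = 1e-10)$root
}

# Asymmetric smooth pulse (gamma envelope, shape k = 4) evaluated at times tt
# (ms) relative to the beat anchor. The start is placed so that the
# 10%-amplitude crossing of the rising limb sits exactly at `onset` and the
# maximum exactly at `peak`; the decay beyond the peak is stretched by
# `fall_scale` (per-channel response) and smoothly tapered to zero `width`
# ms after the peak. The envelope is C2-smooth, so a 20 Hz low-pass leaves
# its peak and onset timing unchanged.
.ih_pulse <- function(tt, onset, peak, width, fall_scale = 1, k = 4) {
  r10 <- .gamma_r10(k)
  ks <- (peak - onset) / (1 - r10)   # start-to-peak time
  t0 <- peak - ks
  u <- pmax(tt - t0, 0)
  u <- ifelse(u > ks, ks + (u - ks) / fall_scale, u)
  y <- (u / ks)^k * exp(k * (1 - u / ks))
  # cosine taper over the last 60 ms of the truncated support
  rel <- tt - peak
  taper_w <- 60
  tp <- rep(1, length(tt))
  ramp <- rel > width - taper_w & rel <= width
  tp[ramp] <- 0.5 * (1 + cos(pi * (rel[ramp] - (width - taper_w)) / taper_w))
  tp[rel > width] <- 0
  y * tp
}

.smooth_ma <- function(x, width_samples) {
  if (width_samples <= 1) return(x)
  w <- as.integer(width_samples)
  if (w %% 2 == 0) w <- w + 1L
  k <- rep(1 / w, w)
  as.numeric(stats::filter(c(rep(x[1], w), x, rep(x[length(x)], w)),
                           k, sides = 2))[(w + 1):(w + length(x))]
}

#' Render a ground-truth beat sequence into a multichannel record
#'
#' Produces the ECG reference channel (R-wave template at each beat time) and
#' the two in-ear channels (delayed smooth pressure pulses, per-channel
#' response applied), all on one shared clock.
#'
#' @param truth A [gen_ibi()] result.
#' @param model A [waveform_model()].
#' @param seed Seed for the measurement noise; defaults to the rhythm seed
#'   so that a simulation is reproducible end to end.
#' @return A [multi_channel_record()] with channels `ih_left`, `ih_right`,
#'   `ecg`.
#' @export
render_record <- function(truth, model = waveform_model(), seed = NULL) {
  stopifnot(inherits(truth, "ground_truth"), inherits(model, "waveform_model"))
  if (length(truth$ibis) &&
      model$ih_peak_delay >= min(truth$ibis)) {
    stop("overlapping pulses: 'ih_peak_delay' (", model$ih_peak_delay,
         " ms) must be below the minimum IBI (", round(min(truth$ibis)),
         " ms)", call. = FALSE)
  }
  fs <- model$sampling_rate
  dur_ms <- truth$spec$duration * 1000
  n <- floor(dur_ms * fs / 1000)
  tms <- (seq_len(n) - 1) * 1000 / fs

  ecg <- numeric(n)
  r10 <- .gamma_r10(4)
  w_rise <- (model$ih_peak_delay - model$ih_onset_delay) / (1 - r10)
  for (b in truth$beat_times) {
    idx <- which(tms >= b - 5 * model$ecg_width & tms <= b + 5 * model$ecg_width)
    ecg[idx] <- ecg[idx] + exp(-(tms[idx] - b)^2 / (2 * model$ecg_width^2))
  }

  render_channel <- function(cr) {
    y <- numeric(n)
    for (b in truth$beat_times) {
      lo <- b + model$ih_peak_delay - w_rise
      hi <- b + model$ih_peak_delay + model$ih_pulse_width
      idx <- which(tms >= lo & tms <= hi)
      y[idx] <- y[idx] + .ih_pulse(tms[idx] - b, model$ih_onset_delay,
                                   model$ih_peak_delay, model$ih_pulse_width,
                                   cr$fall_scale)
    }
    y <- .smooth_ma(y, cr$smooth_ms * fs / 1000)
    cr$gain * y
  }
  left <- render_channel(model$channel_response$left)
  right <- render_channel(model$channel_response$right)

  if (model$noise_sd > 0) {
    set.seed(if (is.null(seed)) truth$spec$seed + 1000L else as.integer(seed))
    left <- left + stats::rnorm(n, 0, model$noise_sd)
    right <- right + stats::rnorm(n, 0, model$noise_sd)
    ecg <- ecg + stats::rnorm(n, 0, model$noise_sd / 5)
  }
  multi_channel_record(
    channels = list(ih_left = left, ih_right = right, ecg = ecg),
    sampling_rate = fs
  )
}

#' Inject motion and music artifacts into a record
#'
#' Motion bursts are high-amplitude broadband noise (default 5x the cardiac
#' pulse amplitude) added to both in-ear channels over the scheduled
#' intervals — the signature of head movements or steps. Music is additive
#' band-limited audible content (sinusoids at `music_freqs`, all >= 20 Hz),
#' which the calibration low-pass is expected to remove.
#'
#' @param record A [multi_channel_record()].
#' @param motion_bursts `NULL` or a data frame with `start_ms`, `end_ms`.
#' @param music `NULL` or a data frame with `start_ms`, `end_ms`.
#' @param motion_gain Motion amplitude as a multiple of the cardiac pulse
#'   amplitude (default 5).
#' @param music_gain Music amplitude as a multiple of the cardiac pulse
#'   amplitude (default 2).
#' @param music_freqs Frequencies (Hz) of the music partials; all must be
#'   >= 20 Hz.
#' @param seed Seed for the broadband bursts.
#' @return A list with `record` (the corrupted record) and `artifact_mask`
#'   (logical, one entry per sample; `TRUE` where an artifact is present).
#' @export
inject_artifacts <- function(record, motion_bursts = NULL, music = NULL,
                             motion_gain = 5, music_gain = 2,
                             music_freqs = c(55, 110, 220), seed = 1L) {
  stopifnot(inherits(record, "multi_channel_record"))
  if (any(music_freqs < 20)) {
    stop("'music_freqs' must all be >= 20 Hz (audible band)", call. = FALSE)
  }
  n <- record_length(record)
  tms <- record_times(record)
  mask <- rep(FALSE, n)
  chans <- record$channels
  ih_names <- intersect(c("ih_left", "ih_right"), names(chans))
  ref_amp <- max(abs(unlist(chans[ih_names])), 1e-12)
  set.seed(as.integer(seed))

  windows <- function(sched) {
    if (is.null(sched) || nrow(sched) == 0L) return(list())
    if (any(sched$start_ms < tms[1]) || any(sched$end_ms > tms[n])) {
      stop("artifact schedule extends beyond the record", call. = FALSE)
    }
    lapply(seq_len(nrow(sched)), function(i) {
      which(tms >= sched$start_ms[i] & tms <= sched$end_ms[i])
    })
  }

  for (idx in windows(motion_bursts)) {
    for (nm in ih_names) {
      chans[[nm]][idx] <- chans[[nm]][idx] +
        stats::rnorm(length(idx), 0, motion_gain * ref_amp)
    }
    mask[idx] <- TRUE
  }
  for (idx in windows(music)) {
    tone <- rowSums(vapply(
      music_freqs,
      function(f) sin(2 * pi * f * tms[idx] / 1000),
      numeric(length(idx))
    )) * music_gain * ref_amp / length(music_freqs)
    for (nm in ih_names) chans[[nm]][idx] <- chans[[nm]][idx] + tone
    mask[idx] <- TRUE
  }
  list(
    record = multi_channel_record(chans, record$sampling_rate,
                                  record$start_time),
    artifact_mask = mask
  )
}

#' Simulate a complete labelled recording
#'
#' Convenience wrapper: generate ground-truth beats, render the waveforms and
#' optionally write the record CSV plus a JSON truth sidecar (beat times,
#' rhythm label, respiratory rate, artifact mask intervals).
#'
#' @param spec A [rhythm_spec()].
#' @param model A [waveform_model()].
#' @param motion_bursts,music Optional artifact schedules
#'   (see [inject_artifacts()]).
#' @param out_prefix If non-`NULL`, write `<prefix>.csv` and
#'   `<prefix>_truth.json`.
#' @return A list with `record`, `truth` and `artifact_mask`.
#' @export
simulate_record <- function(spec, model = waveform_model(),
                            motion_bursts = NULL, music = NULL,
                            out_prefix = NULL) {
  truth <- gen_ibi(spec)
  record <- render_record(truth, model)
  mask <- rep(FALSE, record_length(record))
  if (!is.null(motion_bursts) || !is.null(music)) {
    inj <- inject_artifacts(record, motion_bursts, music, seed = spec$seed + 2L)
    record <- inj$record
    mask <- inj$artifact_mask
  }
  if (!is.null(out_prefix)) {
    write_record(record, paste0(out_prefix, ".csv"))
    write_truth(truth, mask, paste0(out_prefix, "_truth.json"))
  }
  list(record = record, truth = truth, artifact_mask = mask)
}

#' Write the ground-truth sidecar JSON for a simulated record
#' @param truth A `"ground_truth"` object.
#' @param artifact_mask Logical per-sample mask (or `NULL`).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, artifact_mask = NULL, path) {
  runs <- list()
  if (!is.null(artifact_mask) && any(artifact_mask)) {
    r <- rle(artifact_mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    on <- which(r$values)
    runs <- lapply(on, function(i) c(start_ms = starts[i] - 1,
                                     end_ms = ends[i] - 1))
  }
  jsonlite::write_json(
    list(
      beat_times_ms = truth$beat_times,
      rhythm_label = truth$rhythm_label,
      respiratory_rate = truth$respiratory_rate,
      artifact_intervals_ms = runs
    ),
    path, auto_unbox = TRUE, digits = NA, null = "null", na = "null"
  )
  invisible(path)
}
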