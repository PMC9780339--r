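# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

# Quality classifier trained on a moderate simulator corpus; reused by the
# pipeline, merge and acceptance tests.
fixture_quality_model <- function() {
  if (is.null(.fixture_env$qm)) {
    corp <- quality_corpus(n_windows = 800, seed = 101)
    .fixture_env$qm <- train_quality_classifier(corp$features, corp$labels,
                                                seed = 101)
  }
  .fixture_env$qm
}

# Clean 60 s sinus-rhythm simulation at 60 bpm, calibrated, with ECG beats.
fixture_clean_sr <- function() {
  if (is.null(.fixture_env$sr)) {
    spec <- rhythm_spec("sr_regular", duration = 60, mean_hr = 60,
                        hrv_sd = 0, seed = 3)
    truth <- gen_ibi(spec)
    rec <- calibrate(render_record(truth, waveform_model(noise_sd = 0)))
    ecg <- detect_peaks(rec$channels$ecg, rec$sampling_rate,
                        source_channel = "ecg")
    .fixture_env$sr <- list(truth = truth, record = rec, ecg = ecg)
  }
  .fixture_env$sr
}

# A lone rendered pulse peaking at `peak_ms`, for constructed-signal tests.
single_pulse_trace <- function(n_ms, peak_ms, onset_delay = 84,
                               peak_delay = 158) {
  tt <- seq_len(n_ms) - 1
  earbeat:::.ih_pulse(tt, peak_ms - peak_delay + onset_delay, peak_ms, 280)
}
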