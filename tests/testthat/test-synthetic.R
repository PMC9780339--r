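test_that("degenerate sinus rhythm yields exactly constant IBIs", {
  truth <- gen_ibi(rhythm_spec("sr_regular", duration = 30, mean_hr = 60,
                               hrv_sd = 0, seed = 1))
  expect_true(all(abs(truth$ibis - 1000) < 1e-9))
  expect_equal(truth$rhythm_label, "SR")
  expect_equal(truth$ibis, diff(truth$beat_times))
})

test_that("resonant breathing produces the configured IBI swing at the breathing frequency", {
  spec <- rhythm_spec("sr_resonant", duration = 120, mean_hr = 70,
                      hrv_sd = 0, rsa_inhale = 4, rsa_exhale = 4,
                      rsa_ibi_swing = 300, seed = 7)
  truth <- gen_ibi(spec)
  expect_equal(max(truth$ibis) - min(truth$ibis), 300, tolerance = 0.05)
  expect_equal(truth$respiratory_rate, 7.5)  # 8 s breathing period
  # dominant tachogram frequency = 1/8 Hz
  rr <- respiratory_rate(beat_series(truth$beat_times, "truth"))
  expect_equal(rr / 60, 1 / 8, tolerance = 0.05)
})

test_that("AF IBIs stay in range and are more dispersed and less serial than sinus rhythm", {
  af <- gen_ibi(rhythm_spec("af", duration = 300, seed = 11))
  expect_true(all(af$ibis >= 400 & af$ibis <= 1600))
  expect_equal(af$rhythm_label, "AF")
  sr <- gen_ibi(rhythm_spec("sr_regular", duration = 300, mean_hr = 70,
                            seed = 11))
  cv <- function(x) sd(x) / mean(x)
  expect_gt(cv(af$ibis), 2 * cv(sr$ibis))
  pnn50 <- function(x) mean(abs(diff(x)) > 50)
  expect_gt(pnn50(af$ibis), pnn50(sr$ibis))
  # irregularity: AF lag-1 autocorrelation below the periodic RSA rhythm's
  res <- gen_ibi(rhythm_spec("sr_resonant", duration = 300, mean_hr = 70,
                             seed = 11))
  expect_gte(length(af$ibis), 200)
  acf1 <- function(x) acf(x, lag.max = 1, plot = FALSE)$acf[2]
  expect_lt(acf1(af$ibis), acf1(res$ibis))
})

test_that("the Valsalva trend drops, rebounds and recovers", {
  truth <- gen_ibi(rhythm_spec("valsalva", duration = 80, mean_hr = 70,
                               hrv_sd = 0, seed = 2))
  base <- 60000 / 70
  expect_gt(max(truth$ibis[1:10]) - min(truth$ibis), 300)  # strain drop
  # rebound overshoot above the strain minimum by ~400 ms
  expect_equal(max(truth$ibis) - min(truth$ibis), 400, tolerance = 0.15)
  # recovery: final IBIs back near baseline
  tail_ibis <- tail(truth$ibis, 5)
  expect_true(all(abs(tail_ibis - base) < 50))
})

test_that("generated mean heart rate matches the specification", {
  for (hr in c(55, 70, 90)) {
    truth <- gen_ibi(rhythm_spec("sr_regular", duration = 90, mean_hr = hr,
                                 hrv_sd = 25, seed = hr))
    expect_equal(60000 / mean(truth$ibis), hr, tolerance = 2 / hr)
  }
})

test_that("equal seeds reproduce bit-identical simulations", {
  spec <- rhythm_spec("af", duration = 40, seed = 99)
  s1 <- simulate_record(spec, waveform_model(noise_sd = 0.02))
  s2 <- simulate_record(spec, waveform_model(noise_sd = 0.02))
  expect_identical(s1$truth$beat_times, s2$truth$beat_times)
  expect_identical(s1$record$channels$ih_left, s2$record$channels$ih_left)
})

test_that("rhythm specifications validate their parameters", {
  expect_error(rhythm_spec("sr_regular", duration = -5), "duration")
  expect_error(rhythm_spec("sr_regular", mean_hr = 300), "mean_hr")
  expect_error(rhythm_spec("af", af_ibi_range = c(1600, 400)), "af_ibi_range")
  expect_error(rhythm_spec("sr_resonant", mean_hr = 150, rsa_ibi_swing = 900),
               "non-positive")
})

test_that("the renderer places the pulse peak at the configured delay", {
  truth <- gen_ibi(rhythm_spec("sr_regular", duration = 5, mean_hr = 60,
                               hrv_sd = 0, seed = 1))
  rec <- render_record(truth, waveform_model(noise_sd = 0))
  b <- truth$beat_times[1]
  tms <- record_times(rec)
  idx <- which(tms > b & tms < b + 600)
  peak_t <- tms[idx][which.max(rec$channels$ih_left[idx])]
  expect_lt(abs(peak_t - (b + 158)), 1.01)
})

test_that("identical channel responses render identical channels", {
  truth <- gen_ibi(rhythm_spec("sr_regular", duration = 10, mean_hr = 65,
                               hrv_sd = 10, seed = 4))
  cr <- list(gain = 1, smooth_ms = 0, fall_scale = 1)
  rec <- render_record(truth, waveform_model(
    channel_response = list(left = cr, right = cr), noise_sd = 0
  ))
  expect_identical(rec$channels$ih_left, rec$channels$ih_right)
})

test_that("per-channel beat fidelity is near one while the channels differ", {
  fx <- fixture_clean_sr()
  stL <- stack_beats(fx$record$channels$ih_left, fx$ecg)
  stR <- stack_beats(fx$record$channels$ih_right, fx$ecg)
  expect_gte(fidelity(stL)$fidelity, 0.99)
  expect_gte(fidelity(stR)$fidelity, 0.99)
  flr <- fidelity(stL, stR, mode = "left_vs_right")$fidelity
  expect_lt(flr, 1)
  expect_gt(flr, 0.88)
})

test_that("rendering refuses pulses that would overlap the next beat", {
  truth <- gen_ibi(rhythm_spec("sr_regular", duration = 20, mean_hr = 240,
                               hrv_sd = 0, seed = 1))  # 250 ms IBIs
  expect_error(
    render_record(truth, waveform_model(ih_onset_delay = 150,
                                        ih_peak_delay = 300)),
    "overlap"
  )
})

test_that("motion bursts raise masked-sample RMS at least fivefold", {
  truth <- gen_ibi(rhythm_spec("sr_regular", duration = 20, mean_hr = 60,
                               hrv_sd = 0, seed = 6))
  rec <- render_record(truth, waveform_model(noise_sd = 0))
  inj <- inject_artifacts(rec, motion_bursts = data.frame(start_ms = 5000,
                                                          end_ms = 7000),
                          seed = 13)
  clean_rms <- sqrt(mean(rec$channels$ih_left[!inj$artifact_mask]^2))
  burst_rms <- sqrt(mean(inj$record$channels$ih_left[inj$artifact_mask]^2))
  expect_gte(burst_rms, 5 * clean_rms)
  # empty schedules leave the record untouched
  inj0 <- inject_artifacts(rec, seed = 13)
  expect_identical(inj0$record$channels$ih_left, rec$channels$ih_left)
  expect_false(any(inj0$artifact_mask))
})

test_that("calibration removes nearly all injected music power", {
  truth <- gen_ibi(rhythm_spec("sr_regular", duration = 20, mean_hr = 60,
                               hrv_sd = 0, seed = 6))
  rec <- render_record(truth, waveform_model(noise_sd = 0))
  inj <- inject_artifacts(rec, music = data.frame(start_ms = 2000,
                                                  end_ms = 18000),
                          seed = 14)
  cal_clean <- calibrate(rec)
  cal_music <- calibrate(inj$record)
  injected <- mean((inj$record$channels$ih_left - rec$channels$ih_left)^2)
  residual <- mean((cal_music$channels$ih_left - cal_clean$channels$ih_left)^2)
  expect_lt(residual, 0.05 * injected)
})
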