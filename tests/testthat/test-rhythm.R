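test_that("outlier rejection applies the pair and range rules exactly", {
  # pair differing by 120 ms rejected; by 5 ms kept
  out <- reject_outlier_ibis(c(1000, 1000), c(1120, 1005))
  expect_equal(out$kept, c(FALSE, TRUE))
  # 250 ms is below the physiological range
  out2 <- reject_outlier_ibis(c(250, 1000))
  expect_equal(out2$kept, c(FALSE, TRUE))
  expect_equal(unname(out2$log["out_of_range"]), 1L)
  # boundary behaviour: |diff| < 100 is strict, range is inclusive
  expect_false(reject_outlier_ibis(1000, 1100)$kept)
  expect_true(reject_outlier_ibis(300, 310)$kept)
  expect_true(reject_outlier_ibis(2500, 2450)$kept)
})

test_that("outlier rejection is order-independent", {
  set.seed(17)
  x <- runif(50, 200, 2700)
  y <- x + rnorm(50, 0, 80)
  base <- reject_outlier_ibis(x, y)$kept
  perm <- sample(50)
  expect_equal(reject_outlier_ibis(x[perm], y[perm])$kept, base[perm])
})

test_that("tachogram segmentation enforces the window and minimum-IBI rules", {
  # 45 s of beats: one full 30 s window, trailing 15 s discarded
  b45 <- beat_series(seq(400, 44400, by = 1000))
  segs <- segment_tachogram(b45, "SR", duration = 45)
  expect_length(segs, 1L)
  # a 30-s window holding only 9 IBIs is dropped
  sparse <- beat_series(seq(0, 29700, length.out = 10))
  expect_length(segment_tachogram(sparse, "SR", duration = 30), 0L)
  # 60 s at 60 bpm: two segments of ~29 IBIs
  truth <- gen_ibi(rhythm_spec("sr_regular", duration = 60, mean_hr = 60,
                               hrv_sd = 5, seed = 21))
  segs2 <- segment_tachogram(beat_series(truth$beat_times), "SR",
                             duration = 60)
  expect_length(segs2, 2L)
  expect_true(all(vapply(segs2, function(s) length(s$ibis), numeric(1))
                  %in% 28:30))
})

test_that("the 17 tachogram features follow their definitions", {
  f <- tachogram_features(c(800, 860, 865, 990))
  expect_equal(f[["pnn50"]], 2 / 3)  # diffs 60, 5, 125
  expect_length(f, 17L)
  # constant IBIs: dispersion features vanish
  fc <- tachogram_features(rep(900, 20))
  expect_equal(fc[["pnn50"]], 0)
  expect_equal(fc[["sd1"]], 0)
  expect_equal(fc[["rmssd"]], 0)
  expect_equal(fc[["sdnn"]], 0)
  # Poincare identities against direct formulas
  set.seed(3)
  x <- 1000 + cumsum(rnorm(40, 0, 30))
  fx <- tachogram_features(x)
  n <- length(x)
  expect_equal(fx[["sd1"]], sd(diff(x) / sqrt(2)))
  expect_equal(fx[["sd2"]], sd((x[-1] + x[-n]) / sqrt(2)))
  expect_equal(fx[["poincare_dispersion"]], fx[["sd1"]] * fx[["sd2"]])
  expect_equal(fx[["rmssd"]], sqrt(mean(diff(x)^2)))
  expect_true(all(fx[c("sd1", "sd2", "sdnn", "rmssd", "shannon_entropy",
                       "sample_entropy", "spectral_entropy")] >= 0))
  expect_true(fx[["pnn50"]] >= 0 && fx[["pnn50"]] <= 1)
  expect_error(tachogram_features(c(800, 810)), "at least 3")
})

test_that("feature extraction ignores segment start time", {
  truth <- gen_ibi(rhythm_spec("af", duration = 120, seed = 5))
  s1 <- segment_tachogram(beat_series(truth$beat_times), "AF")
  expect_gte(length(s1), 2L)
  shifted <- s1[[2]]
  shifted$start <- shifted$start + 123456
  expect_identical(tachogram_features(shifted), tachogram_features(s1[[2]]))
})

test_that("Wilson intervals match the closed form and its boundary behaviour", {
  expect_equal(unname(wilson_interval(0, 10)["low"]), 0)
  expect_equal(unname(wilson_interval(10, 10)["high"]), 1)
  # closed-form evaluation, cross-checked against the score interval of
  # stats::prop.test(correct = FALSE)
  ci <- wilson_interval(453, 458)
  ref <- stats::prop.test(453, 458, correct = FALSE)$conf.int
  expect_equal(unname(ci), as.numeric(ref), tolerance = 1e-9)
  expect_true(ci["low"] <= 453 / 458 && 453 / 458 <= ci["high"])
  expect_error(wilson_interval(1, 0), "positive")
  expect_error(wilson_interval(11, 10), "successes")
})

test_that("evaluation reproduces the published confusion-matrix arithmetic", {
  # ECG counts: actual SR predicted 606 SR / 0 AF; actual AF 5 SR / 453 AF
  pred_ecg <- c(rep("SR", 606), rep("SR", 5), rep("AF", 453))
  truth_ecg <- c(rep("SR", 606), rep("AF", 458))
  rep_ecg <- evaluate_rhythm(pred_ecg, truth_ecg)
  expect_equal(round(rep_ecg$sensitivity, 2), 0.99)
  expect_equal(rep_ecg$specificity, 1.00)
  # acoustic counts: actual SR 601/5; actual AF 4/454
  pred_ih <- c(rep("SR", 601), rep("AF", 5), rep("SR", 4), rep("AF", 454))
  truth_ih <- c(rep("SR", 606), rep("AF", 458))
  rep_ih <- evaluate_rhythm(pred_ih, truth_ih)
  expect_equal(round(rep_ih$accuracy, 2), 0.99)
  expect_equal(round(rep_ih$sensitivity, 2), 0.99)
  expect_equal(round(rep_ih$specificity, 2), 0.99)
  expect_equal(sum(rep_ih$confusion), 1064)
  expect_equal(unname(rowSums(rep_ih$confusion)), c(606, 458))
  # identity case
  rep_id <- evaluate_rhythm(truth_ih, truth_ih)
  expect_equal(rep_id$accuracy, 1.0)
  expect_equal(unname(diag(rep_id$confusion)), c(606, 458))
  # intervals contain the point estimates
  expect_true(rep_ih$recall_ci$AF["low"] <= rep_ih$sensitivity)
  expect_true(rep_ih$recall_ci$AF["high"] >= rep_ih$sensitivity)
})

test_that("the rhythm classifier separates synthetic AF from SR", {
  segs <- synthetic_segment_corpus(n_sr = 600, n_af = 150, seed = 7)
  model <- train_rhythm_model(segs, seed = 7)
  expect_gte(model$test_report$sensitivity, 0.95)
  expect_gte(model$test_report$specificity, 0.95)
  # determinism: same corpus + seed gives identical predictions
  model2 <- train_rhythm_model(segs, seed = 7)
  p1 <- classify_rhythm(model, segs)
  p2 <- classify_rhythm(model2, segs)
  expect_identical(p1, p2)
})

test_that("a linearly separable toy feature set is classified perfectly", {
  set.seed(23)
  make_seg <- function(label, base) {
    # widely separated dispersion regimes
    ibis <- if (label == "AF") runif(40, 450, 1550) else base + rnorm(40, 0, 10)
    structure(list(start = 0, duration = 30, ibis = ibis,
                   rhythm_label = label, source = "ECG"),
              class = "tachogram_segment")
  }
  segs <- c(lapply(1:60, function(i) make_seg("SR", 900)),
            lapply(1:60, function(i) make_seg("AF", 900)))
  model <- train_rhythm_model(segs, seed = 23,
                              grid = data.frame(mtry = 4, min_node_size = 1))
  expect_equal(model$test_report$accuracy, 1.0)
})

test_that("models trained on ECG-grade tachograms transfer to acoustic-grade ones", {
  segs_ecg <- synthetic_segment_corpus(n_sr = 600, n_af = 150, seed = 31,
                                       ibi_jitter_sd = 0)
  segs_ih <- synthetic_segment_corpus(n_sr = 600, n_af = 150, seed = 31,
                                      ibi_jitter_sd = 21)
  model <- train_rhythm_model(segs_ecg, seed = 31)
  truth <- vapply(segs_ih, function(s) s$rhythm_label, character(1))
  rep_ih <- evaluate_rhythm(classify_rhythm(model, segs_ih), truth)
  expect_gte(rep_ih$sensitivity, model$test_report$sensitivity - 0.02)
  expect_gte(rep_ih$specificity, model$test_report$specificity - 0.02)
})

test_that("beat pairing aligns acoustic and reference series", {
  ecg <- beat_series(seq(500, 30500, by = 1000), "ecg")
  ih <- beat_series(seq(500, 30500, by = 1000) + 158, "merged")
  pr <- pair_ibis(ih, ecg)
  expect_equal(length(pr$ibis), length(ecg$peak_times) - 1L)
  expect_equal(pr$ibis, pr$ibis_ref)
})
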