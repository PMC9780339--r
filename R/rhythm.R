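#' Reject implausible interbeat intervals
#'
#' Filtering applied before rhythm classification. In paired mode (an
#' acoustic IBI matched with its simultaneous ECG IBI) a pair is kept only if
#' the two measurements agree to within `max_pair_diff` (default 100 ms,
#' which for the observed difference distribution corresponds to about four
#' standard deviations from the mean) and both lie within the physiological
#' `range` (default 300–2500 ms). In single-source mode only the range rule
#' applies. Filtering is per-pair, so permuting the input permutes the output
#' identically.
#'
#' @param ibis IBIs in ms (the series under test, e.g. acoustic).
#' @param ibis_ref Optional paired reference IBIs (e.g. ECG), same length.
#' @param max_pair_diff Pair-agreement threshold, ms.
#' @param range Length-2 inclusive physiological range, ms.
#' @return A list with `ibis` (kept values), `ibis_ref` (kept reference
#'   values or `NULL`), `kept` (logical) and `log` (named rejection counts).
#' @export
reject_outlier_ibis <- function(ibis, ibis_ref = NULL, max_pair_diff = 100,
                                range = c(300, 2500)) {
  in_range <- ibis >= range[1] & ibis <= range[2]
  if (is.null(ibis_ref)) {
    kept <- in_range
    log <- c(out_of_range = sum(!in_range), pair_mismatch = 0L)
    return(list(ibis = ibis[kept], ibis_ref = NULL, kept = kept, log = log))
  }
  if (length(ibis_ref) != length(ibis)) {
    stop("'ibis' and 'ibis_ref' must be aligned (equal length)", call. = FALSE)
  }
  ref_in_range <- ibis_ref >= range[1] & ibis_ref <= range[2]
  agree <- abs(ibis - ibis_ref) < max_pair_diff
  kept <- in_range & ref_in_range & agree
  log <- c(out_of_range = sum(!(in_range & ref_in_range)),
           pair_mismatch = sum(in_range & ref_in_range & !agree))
  list(ibis = ibis[kept], ibis_ref = ibis_ref[kept], kept = kept, log = log)
}

#' Pair acoustic and ECG beats by nearest peak time
#'
#' Matches each acoustic beat to the nearest ECG beat within `max_diff`
#' (default 300 ms, comfortably above the mechanical pulse delay); unmatched
#' beats on either side are dropped. Consecutive matched beats yield aligned
#' IBI pairs for [reject_outlier_ibis()].
#'
#' @param beats A [beat_series()] (acoustic).
#' @param beats_ref A [beat_series()] (ECG).
#' @param max_diff Maximum peak-time difference for a match, ms.
#' @return A list with aligned `ibis` and `ibis_ref` (ms).
#' @export
pair_ibis <- function(beats, beats_ref, max_diff = 300) {
  stopifnot(inherits(beats, "beat_series"), inherits(beats_ref, "beat_series"))
  tx <- beats$peak_times; ty <- beats_ref$peak_times
  if (length(tx) < 2L || length(ty) < 2L) {
    return(list(ibis = numeric(0), ibis_ref = numeric(0)))
  }
  j <- findInterval(tx, ty)
  near <- ifelse(j == 0L, 1L,
                 ifelse(j >= length(ty), length(ty),
                        ifelse(tx - ty[j] <= ty[j + 1L] - tx, j, j + 1L)))
  ok <- abs(tx - ty[near]) <= max_diff & !duplicated(near)
  xi <- which(ok); yi <- near[ok]
  consec <- which(diff(xi) == 1L & diff(yi) == 1L)
  list(
    ibis = tx[xi[consec + 1L]] - tx[xi[consec]],
    ibis_ref = ty[yi[consec + 1L]] - ty[yi[consec]]
  )
}

#' Cut a beat series into fixed-length tachogram segments
#'
#' Consecutive non-overlapping windows of `segment_length` seconds from time
#' zero; a trailing partial window is discarded, and a segment is retained
#' only if it contains at least `min_ibis` IBIs (an IBI belongs to the
#' segment containing its midpoint). The rhythm label is inherited from the
#' record.
#'
#' @param beats A [beat_series()] (already filtered).
#' @param rhythm_label `"SR"`, `"AF"` or `"unknown"`.
#' @param duration Record duration in seconds; defaults to the last beat time
#'   rounded up to the next second.
#' @param segment_length Segment length in seconds (default 30).
#' @param min_ibis Minimum IBI count for retention (default 10).
#' @param source Provenance tag (`"ECG"` or `"IH"`).
#' @return A list of `"tachogram_segment"` objects, each with `start` (ms),
#'   `duration` (s), `ibis` (ms) and `rhythm_label`.
#' @export
segment_tachogram <- function(beats, rhythm_label = "unknown", duration = NULL,
                              segment_length = 30, min_ibis = 10,
                              source = "IH") {
  stopifnot(inherits(beats, "beat_series"))
  if (is.null(duration)) {
    duration <- ceiling(max(beats$peak_times, 0) / 1000)
  }
  n_seg <- floor(duration / segment_length)
  if (n_seg < 1L || length(beats$ibis) < 1L) return(list())
  mid <- (beats$peak_times[-1] + beats$peak_times[-length(beats$peak_times)]) / 2
  out <- list()
  for (k in seq_len(n_seg)) {
    lo <- (k - 1) * segment_length * 1000
    hi <- k * segment_length * 1000
    ib <- beats$ibis[mid >= lo & mid < hi]
    if (length(ib) < min_ibis) next
    out[[length(out) + 1L]] <- structure(
      list(start = lo, duration = segment_length, ibis = ib,
           rhythm_label = rhythm_label, source = source),
      class = "tachogram_segment"
    )
  }
  out
}

#' @export
print.tachogram_segment <- function(x, ...) {
  cat(sprintf(
    "Tachogram segment (%s, %s): start %.0f ms, %d IBIs, mean %.0f ms\n",
    x$rhythm_label, x$source, x$start, length(x$ibis), mean(x$ibis)
  ))
  invisible(x)
}

# interpolated-tachogram power spectrum used by the frequency features
.tachogram_psd <- function(ibis, grid_fs = 2) {
  tt <- cumsum(ibis) / 1000
  grid <- seq(tt[1], tt[length(tt)], by = 1 / grid_fs)
  y <- stats::approx(tt, ibis, xout = grid, rule = 2)$y
  y <- y - mean(y)
  nfft <- max(64L, 2^ceiling(log2(length(y) * 4)))
  p <- Mod(stats::fft(c(y, rep(0, nfft - length(y)))))^2
  f <- (seq_len(nfft) - 1) * grid_fs / nfft
  keep <- f > 0 & f <= grid_fs / 2
  list(freq = f[keep], power = p[keep])
}

# sample entropy, m = 2, tolerance r (ms); small-n tachogram version
.sample_entropy <- function(x, m = 2L, r = 0.2 * stats::sd(x)) {
  n <- length(x)
  if (n < m + 2L || r < 1e-12) return(0)
  count_m <- function(mm) {
    templ <- stats::embed(x, mm)          # rows are length-mm templates
    nt <- nrow(templ)
    cnt <- 0L
    for (i in seq_len(nt - 1L)) {
      d <- abs(templ[(i + 1L):nt, , drop = FALSE] -
                 matrix(templ[i, ], nt - i, mm, byrow = TRUE))
      cnt <- cnt + sum(apply(d, 1, max) <= r)
    }
    cnt
  }
  b <- count_m(m)
  a <- count_m(m + 1L)
  if (a == 0L || b == 0L) return(0)
  -log(a / b)
}

#' The 17 tachogram features used for rhythm classification
#'
#' Computes, from a segment's IBIs, seventeen features tracing the
#' dispersion, the degree of randomness and the frequency content of the
#' tachogram — the signatures that separate the irregularly irregular IBIs
#' of atrial fibrillation from sinus rhythm:
#'
#' dispersion — `pnn50` (fraction of successive IBI differences > 50 ms),
#' `sd1` and `sd2` (Poincaré short- and long-term dispersion: SDs of the
#' rotated successive-pair coordinates \eqn{(IBI_{i+1} \mp IBI_i)/\sqrt 2}),
#' `poincare_dispersion` (the SD1*SD2 ellipse-area proxy), `sdnn`, `rmssd`,
#' `cv`, `median_ibi`, `iqr`, `mad`, `range`;
#' randomness — `acf_lag1`, `turning_point_ratio`, `shannon_entropy` (of the
#' IBI histogram on fixed 50 ms bins over 300–2500 ms), `sample_entropy`
#' (m = 2, r = 0.2 SDNN);
#' frequency — `lf_power_norm` (0.04–0.15 Hz fraction of total 0.003–0.4 Hz
#' tachogram power), `spectral_entropy` (of the normalized tachogram PSD).
#'
#' @param segment A `"tachogram_segment"`, or a bare numeric IBI vector (ms).
#' @return Named numeric vector of length 17.
#' @export
tachogram_features <- function(segment) {
  ibis <- if (inherits(segment, "tachogram_segment")) segment$ibis
          else as.numeric(segment)
  n <- length(ibis)
  if (n < 3L) stop("need at least 3 IBIs (2 successive pairs) for features",
                   call. = FALSE)
  d <- diff(ibis)
  sdnn <- stats::sd(ibis)
  sd1 <- stats::sd(d / sqrt(2))
  sd2 <- stats::sd((ibis[-1] + ibis[-n]) / sqrt(2))
  tpr <- if (n < 3L) 0 else {
    mid <- ibis[2:(n - 1)]
    mean((mid > ibis[1:(n - 2)] & mid > ibis[3:n]) |
           (mid < ibis[1:(n - 2)] & mid < ibis[3:n]))
  }
  breaks <- seq(300, 2500, by = 50)
  h <- graphics::hist(pmin(pmax(ibis, 300), 2500), breaks = breaks,
                      plot = FALSE)$counts
  p <- h[h > 0] / sum(h)
  shannon <- -sum(p * log(p))
  acf1 <- if (sdnn < 1e-12) 0 else
    stats::acf(ibis, lag.max = 1, plot = FALSE)$acf[2]
  psd <- .tachogram_psd(ibis)
  tot_band <- psd$freq >= 0.003 & psd$freq <= 0.4
  lf_band <- psd$freq >= 0.04 & psd$freq <= 0.15
  tot_p <- sum(psd$power[tot_band])
  lf_norm <- if (tot_p < 1e-12) 0 else sum(psd$power[lf_band]) / tot_p
  ps <- psd$power[tot_band]
  spec_ent <- if (tot_p < 1e-12) 0 else {
    q <- ps[ps > 0] / tot_p
    -sum(q * log(q))
  }
  c(
    pnn50 = mean(abs(d) > 50),
    sd1 = sd1,
    sd2 = sd2,
    poincare_dispersion = sd1 * sd2,
    sdnn = sdnn,
    rmssd = sqrt(mean(d^2)),
    cv = sdnn / mean(ibis),
    median_ibi = stats::median(ibis),
    iqr = stats::IQR(ibis),
    mad = stats::mad(ibis),
    range = max(ibis) - min(ibis),
    acf_lag1 = acf1,
    turning_point_ratio = tpr,
    shannon_entropy = shannon,
    sample_entropy = .sample_entropy(ibis, 2L, 0.2 * sdnn),
    lf_power_norm = lf_norm,
    spectral_entropy = spec_ent
  )
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param successes Number of successes (0..n).
#' @param n Number of trials (> 0).
#' @param confidence Confidence level (default 0.95).
#' @return Named numeric `c(low, high)`, bounded to \[0, 1\] and containing
#'   the point estimate `successes / n`.
#' @export
wilson_interval <- function(successes, n, confidence = 0.95) {
  if (n <= 0) stop("'n' must be positive", call. = FALSE)
  if (successes < 0 || successes > n) {
    stop("'successes' must lie in [0, n]", call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  p <- successes / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z / denom * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  c(low = max(0, center - half), high = min(1, center + half))
}

.segment_matrix <- function(segments) {
  X <- t(vapply(segments, tachogram_features, numeric(17)))
  y <- factor(vapply(segments, function(s) s$rhythm_label, character(1)),
              levels = c("SR", "AF"))
  list(X = X, y = y)
}

#' Train the AF/SR random-forest classifier
#'
#' Training protocol: a stratified 80–20 train–test split; five-fold
#' cross-validated grid search over forest hyperparameters on the training
#' portion, selecting the configuration that maximizes precision for the AF
#' class; refit of the winning configuration on the full training set; and an
#' internal test evaluation reported with Wilson 95% intervals.
#'
#' @param segments List of labelled `"tachogram_segment"`s (both classes
#'   required).
#' @param seed Integer seed controlling the split, the folds and the forests.
#' @param grid Data frame of candidate hyperparameters with columns `mtry`
#'   and `min_node_size`.
#' @param num_trees Trees per forest.
#' @param test_fraction Held-out fraction (default 0.2).
#' @return An object of class `"rhythm_model"` with the fitted forest, the
#'   frozen feature order, the tuning table and the internal `test_report`.
#' @export
train_rhythm_model <- function(segments, seed = 1L,
                               grid = expand.grid(mtry = c(2L, 4L, 6L),
                                                  min_node_size = c(1L, 5L)),
                               num_trees = 300L, test_fraction = 0.2) {
  dat <- .segment_matrix(segments)
  if (any(table(dat$y) == 0L)) {
    stop("training corpus must contain both SR and AF segments", call. = FALSE)
  }
  set.seed(as.integer(seed))
  n <- length(dat$y)
  test_i <- unlist(lapply(levels(dat$y), function(l) {
    i <- which(dat$y == l)
    sample(i, round(test_fraction * length(i)))
  }))
  train_i <- setdiff(seq_len(n), test_i)
  ytr <- dat$y[train_i]
  folds <- unlist(lapply(levels(ytr), function(l) {
    i <- which(ytr == l)
    stats::setNames(sample(rep_len(1:5, length(i))), i)
  }))
  folds <- folds[order(as.integer(names(folds)))]

  df_tr <- data.frame(dat$X[train_i, , drop = FALSE], label = ytr)
  cv_precision <- vapply(seq_len(nrow(grid)), function(g) {
    prec <- vapply(1:5, function(f) {
      fit <- ranger::ranger(
        label ~ ., data = df_tr[folds != f, ],
        num.trees = num_trees, mtry = grid$mtry[g],
        min.node.size = grid$min_node_size[g],
        seed = seed + g, num.threads = 1
      )
      pred <- stats::predict(fit, df_tr[folds == f, ])$predictions
      truth <- ytr[folds == f]
      tp <- sum(pred == "AF" & truth == "AF")
      fp <- sum(pred == "AF" & truth == "SR")
      if (tp + fp == 0L) 0 else tp / (tp + fp)
    }, numeric(1))
    mean(prec)
  }, numeric(1))
  best <- which.max(cv_precision)
  forest <- ranger::ranger(
    label ~ ., data = df_tr,
    num.trees = num_trees, mtry = grid$mtry[best],
    min.node.size = grid$min_node_size[best],
    seed = seed, num.threads = 1
  )
  df_te <- data.frame(dat$X[test_i, , drop = FALSE], label = dat$y[test_i])
  pred_te <- stats::predict(forest, df_te)$predictions
  report <- evaluate_rhythm(pred_te, dat$y[test_i])
  structure(
    list(
      forest = forest,
      feature_names = colnames(dat$X),
      best_params = cbind(grid[best, , drop = FALSE],
                          cv_af_precision = cv_precision[best]),
      tuning = cbind(grid, cv_af_precision = cv_precision),
      test_report = report,
      seed = as.integer(seed)
    ),
    class = "rhythm_model"
  )
}

#' @export
print.rhythm_model <- function(x, ...) {
  cat(sprintf(
    "AF/SR random forest: %d trees, mtry %d, min node %d (CV AF precision %.3f)\n",
    x$forest$num.trees, x$best_params$mtry, x$best_params$min_node_size,
    x$best_params$cv_af_precision
  ))
  cat(sprintf("Internal test: sensitivity %.3f, specificity %.3f\n",
              x$test_report$sensitivity, x$test_report$specificity))
  invisible(x)
}

#' Classify tachogram segments as SR or AF
#'
#' @param model A [train_rhythm_model()] result.
#' @param segments List of `"tachogram_segment"`s, or a feature matrix whose
#'   columns match the model's feature manifest.
#' @return Factor of predicted labels (`SR`/`AF`).
#' @export
classify_rhythm <- function(model, segments) {
  stopifnot(inherits(model, "rhythm_model"))
  X <- if (is.matrix(segments)) segments else .segment_matrix(segments)$X
  missing <- setdiff(model$feature_names, colnames(X))
  if (length(missing)) {
    stop("missing features: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  X <- X[, model$feature_names, drop = FALSE]
  stats::predict(model$forest, data.frame(X))$predictions
}

#' Evaluate SR/AF predictions against truth
#'
#' @param pred,truth Factors (or characters) with values `SR`/`AF`.
#' @param confidence Level of the Wilson intervals on the recalls.
#' @return An object of class `"evaluation_report"`: 2x2 `confusion` (rows
#'   actual, columns predicted), `accuracy`, per-class `precision` and
#'   `recall`, `sensitivity` (= AF recall), `specificity` (= SR recall) and
#'   Wilson 95% intervals for the recalls.
#' @export
evaluate_rhythm <- function(pred, truth, confidence = 0.95) {
  pred <- factor(pred, c("SR", "AF"))
  truth <- factor(truth, c("SR", "AF"))
  stopifnot(length(pred) == length(truth))
  cm <- table(actual = truth, predicted = pred)
  acc <- sum(diag(cm)) / sum(cm)
  precision <- vapply(c("SR", "AF"), function(l) {
    tp <- cm[l, l]; denom <- sum(cm[, l])
    if (denom == 0) NA_real_ else tp / denom
  }, numeric(1))
  recall <- vapply(c("SR", "AF"), function(l) cm[l, l] / sum(cm[l, ]),
                   numeric(1))
  structure(
    list(
      confusion = cm, accuracy = acc,
      precision = precision, recall = recall,
      sensitivity = recall[["AF"]], specificity = recall[["SR"]],
      recall_ci = list(
        SR = wilson_interval(cm["SR", "SR"], sum(cm["SR", ]), confidence),
        AF = wilson_interval(cm["AF", "AF"], sum(cm["AF", ]), confidence)
      )
    ),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Confusion matrix (rows = actual):\n")
  print(x$confusion)
  cat(sprintf(
    "Accuracy %.3f | Sensitivity (AF) %.3f [%.3f, %.3f] | Specificity (SR) %.3f [%.3f, %.3f]\n",
    x$accuracy, x$sensitivity, x$recall_ci$AF["low"], x$recall_ci$AF["high"],
    x$specificity, x$recall_ci$SR["low"], x$recall_ci$SR["high"]
  ))
  invisible(x)
}

#' Generate a labelled synthetic tachogram-segment corpus
#'
#' Draws 30-s segments from the sinus-rhythm generators (a mix of regular
#' and paced-breathing rhythms across a realistic heart-rate range) and from
#' the AF generator, for training and benchmarking the rhythm classifier
#' without any external data.
#'
#' @param n_sr,n_af Number of SR and AF segments.
#' @param seed Integer seed.
#' @param ibi_jitter_sd SD (ms) of zero-mean Gaussian timing noise added to
#'   each IBI, emulating acoustic (rather than ECG) beat timing; 0 for
#'   ECG-grade segments.
#' @return A list of `"tachogram_segment"`s.
#' @export
synthetic_segment_corpus <- function(n_sr = 2000, n_af = 500, seed = 1L,
                                     ibi_jitter_sd = 0) {
  set.seed(as.integer(seed))
  make <- function(kind, label, k) {
    hr <- stats::runif(1, 50, 100)
    spec <- if (kind == "af") {
      rhythm_spec("af", duration = 40, mean_hr = hr, seed = seed + 7L * k)
    } else if (kind == "sr_resonant") {
      rhythm_spec("sr_resonant", duration = 40, mean_hr = hr,
                  hrv_sd = stats::runif(1, 5, 25),
                  rsa_inhale = sample(3:6, 1), rsa_exhale = sample(3:7, 1),
                  rsa_ibi_swing = stats::runif(1, 150, 300),
                  seed = seed + 7L * k)
    } else {
      rhythm_spec("sr_regular", duration = 40, mean_hr = hr,
                  hrv_sd = stats::runif(1, 10, 50), seed = seed + 7L * k)
    }
    truth <- gen_ibi(spec)
    ibis <- truth$ibis
    if (ibi_jitter_sd > 0) {
      bt <- truth$beat_times + stats::rnorm(length(truth$beat_times),
                                            0, ibi_jitter_sd)
      ibis <- diff(sort(bt))
    }
    # first 30 s worth of IBIs
    cum <- cumsum(ibis)
    ib <- ibis[cum <= 30000]
    if (length(ib) < 10L) return(NULL)
    structure(
      list(start = 0, duration = 30, ibis = ib, rhythm_label = label,
           source = if (ibi_jitter_sd > 0) "IH" else "ECG"),
      class = "tachogram_segment"
    )
  }
  segs <- list()
  k <- 0L
  while (sum(vapply(segs, function(s) s$rhythm_label == "SR", logical(1))) < n_sr) {
    k <- k + 1L
    kind <- if (k %% 3 == 0) "sr_resonant" else "sr_regular"
    s <- make(kind, "SR", k)
    if (!is.null(s)) segs[[length(segs) + 1L]] <- s
  }
  while (length(segs) < n_sr + n_af) {
    k <- k + 1L
    s <- make("af", "AF", k)
    if (!is.null(s)) segs[[length(segs) + 1L]] <- s
  }
  segs
}
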