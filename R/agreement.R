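#' Windowed heart-rate pairs from two beat series
#'
#' Builds paired HR measurements for method comparison: over each common
#' non-overlapping window (default 20 s) containing at least two IBIs from
#' each source, HR is `60000 / mean(IBI)` in bpm. The reference (ECG) series
#' is `x`, the series under test (acoustic) is `y`.
#'
#' @param beats_x,beats_y [beat_series()] objects on one time axis.
#' @param window Window length in seconds.
#' @param condition_label Optional label attached to every pair (e.g.
#'   `"regular"`, `"regular+music"`, `"resonant"`).
#' @return A data frame of class `"paired_measurements"` with columns
#'   `window_start_ms`, `x`, `y`, `condition`; zero rows when there is no
#'   common window.
#' @export
hr_pairs <- function(beats_x, beats_y, window = 20,
                     condition_label = "all") {
  stopifnot(inherits(beats_x, "beat_series"), inherits(beats_y, "beat_series"))
  vx <- compute_vitals(beats_x, window)
  vy <- compute_vitals(beats_y, window)
  common <- intersect(vx$window_start_ms, vy$window_start_ms)
  out <- data.frame(
    window_start_ms = common,
    x = vx$hr_bpm[match(common, vx$window_start_ms)],
    y = vy$hr_bpm[match(common, vy$window_start_ms)],
    condition = rep(condition_label, length(common))
  )
  class(out) <- c("paired_measurements", "data.frame")
  out
}

#' Pearson correlation of paired measurements
#'
#' @param x,y Equal-length numeric vectors, or a `"paired_measurements"`
#'   data frame as `x`.
#' @return The sample Pearson correlation coefficient.
#' @export
pearson_r <- function(x, y = NULL) {
  if (is.data.frame(x)) { y <- x$y; x <- x$x }
  if (length(x) != length(y) || length(x) < 2L) {
    stop("need at least 2 pairs", call. = FALSE)
  }
  if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12) {
    stop("constant series: correlation undefined", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Bland-Altman agreement between a test and a reference method
#'
#' Computes the mean difference `d = mean(y - x)` (test minus reference), the
#' sample SD of the differences `sigma` (n - 1 denominator) and the 95%
#' limits of agreement `d +/- 1.96 sigma`.
#'
#' @param x Reference values (ECG-derived), or a `"paired_measurements"`
#'   data frame.
#' @param y Test values (acoustic-derived).
#' @return An object of class `"agreement_result"` with fields `n`, `r`,
#'   `d`, `sigma` and `loa` (lower, upper).
#' @export
bland_altman <- function(x, y = NULL) {
  if (is.data.frame(x)) { y <- x$y; x <- x$x }
  if (length(x) != length(y) || length(x) < 2L) {
    stop("need at least 2 pairs", call. = FALSE)
  }
  d <- y - x
  m <- mean(d)
  s <- stats::sd(d)
  r <- if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12) NA_real_
       else stats::cor(x, y)
  structure(
    list(n = length(d), r = r, d = m, sigma = s,
         loa = c(lower = m - 1.96 * s, upper = m + 1.96 * s)),
    class = "agreement_result"
  )
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf(
    "Agreement: n = %d, r = %s, d = %.3g +/- %.3g, LoA [%.3g, %.3g]\n",
    x$n, if (is.na(x$r)) "NA" else sprintf("%.3f", x$r), x$d, x$sigma,
    x$loa["lower"], x$loa["upper"]
  ))
  invisible(x)
}

#' One-way analysis of variance across condition groups
#'
#' Standard one-way ANOVA decomposition (fit with [stats::aov()]), returning
#' the between/within/total sums of squares, degrees of freedom, variances,
#' the F statistic and its p value.
#'
#' @param groups A named or unnamed list of numeric vectors, one per group.
#' @return An object of class `"anova_result"`.
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need at least 2 groups", call. = FALSE)
  }
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(values) <= length(groups)) {
    stop("total n must exceed the number of groups", call. = FALSE)
  }
  fit <- stats::aov(values ~ g)
  tab <- summary(fit)[[1]]
  ss_b <- tab["g", "Sum Sq"]
  ss_w <- tab["Residuals", "Sum Sq"]
  df_b <- tab["g", "Df"]
  df_w <- tab["Residuals", "Df"]
  structure(
    list(
      ss_between = ss_b, ss_within = ss_w, ss_total = ss_b + ss_w,
      df_between = df_b, df_within = df_w,
      var_between = ss_b / df_b, var_within = ss_w / df_w,
      F = (ss_b / df_b) / (ss_w / df_w),
      p = stats::pf((ss_b / df_b) / (ss_w / df_w), df_b, df_w,
                    lower.tail = FALSE)
    ),
    class = "anova_result"
  )
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf(
    "One-way ANOVA: SS between %.4g (df %d), within %.4g (df %d), F = %.3f, p = %.3g\n",
    x$ss_between, x$df_between, x$ss_within, x$df_within, x$F, x$p
  ))
  invisible(x)
}

#' F statistic and p value from published sums of squares
#'
#' Recomputes a one-way ANOVA F from the tabulated sum-of-squares
#' decomposition, `F = (ss_between / df_between) / (ss_within / df_within)`,
#' with the p value from the F distribution.
#'
#' @param ss_between,df_between Between-group sum of squares and d.o.f.
#' @param ss_within,df_within Within-group sum of squares and d.o.f.
#' @return A list with `F` and `p`.
#' @export
anova_f_from_sums <- function(ss_between, df_between, ss_within, df_within) {
  if (df_between <= 0 || df_within <= 0) {
    stop("degrees of freedom must be positive", call. = FALSE)
  }
  F <- (ss_between / df_between) / (ss_within / df_within)
  list(F = F, p = stats::pf(F, df_between, df_within, lower.tail = FALSE))
}

#' Two-sided paired t test
#'
#' Wraps [stats::t.test()] with explicit degenerate-case conventions:
#' all-zero differences give `t = 0, p = 1`; zero-variance differences with a
#' nonzero mean give an infinite `t`, reported as `p = 0` with
#' `degenerate = TRUE`.
#'
#' @param x,y Equal-length numeric vectors (n >= 2).
#' @return A list with `t`, `p`, `df` and `degenerate`.
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L) {
    stop("need equal-length vectors with n >= 2", call. = FALSE)
  }
  d <- y - x
  if (stats::sd(d) < 1e-12) {
    if (abs(mean(d)) < 1e-12) {
      return(list(t = 0, p = 1, df = length(d) - 1L, degenerate = TRUE))
    }
    return(list(t = sign(mean(d)) * Inf, p = 0, df = length(d) - 1L,
                degenerate = TRUE))
  }
  tt <- stats::t.test(y, x, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), degenerate = FALSE)
}

#' Minimum sample size for a Bland-Altman agreement study
#'
#' Plans the number of paired measurements needed so that, with power
#' `1 - beta` at two-sided level `alpha`, the confidence bounds on the 95%
#' limits of agreement stay within the maximum allowable difference `delta`.
#' The implemented variant takes the variance of an estimated limit of
#' agreement as \deqn{Var(LoA) = \sigma^2 (1/n + z_{1-\alpha/2}^2 / (2(n-1)))}
#' and returns the smallest n with
#' \deqn{(\delta - |d| - 1.96\sigma) / \sqrt{Var(LoA)} \ge z_{1-\alpha/2} + z_{1-\beta}.}
#' The variant name and inputs are attached to the result, since published
#' formulations of this calculation differ in detail.
#'
#' @param expected_d Expected mean of differences (same units as `sigma`).
#' @param expected_sd Expected SD of differences.
#' @param max_allowed_diff Maximum allowable difference `delta`; must exceed
#'   `|expected_d| + 1.96 * expected_sd`.
#' @param alpha Type-I error (two-sided).
#' @param beta Type-II error.
#' @return Integer minimum sample size, with attributes `formula` and
#'   `inputs`.
#' @export
bland_altman_sample_size <- function(expected_d = 1, expected_sd = 25,
                                     max_allowed_diff = 55,
                                     alpha = 0.05, beta = 0.1) {
  if (alpha <= 0 || alpha >= 1 || beta <= 0 || beta >= 1) {
    stop("'alpha' and 'beta' must lie in (0, 1)", call. = FALSE)
  }
  margin <- max_allowed_diff - abs(expected_d) - 1.96 * expected_sd
  if (margin <= 0) {
    stop("agreement limit exceeds allowable difference: need ",
         "max_allowed_diff > |expected_d| + 1.96 * expected_sd", call. = FALSE)
  }
  z_a <- stats::qnorm(1 - alpha / 2)
  z_b <- stats::qnorm(1 - beta)
  se_loa <- function(n) expected_sd * sqrt(1 / n + z_a^2 / (2 * (n - 1)))
  n <- 3
  while (margin / se_loa(n) < z_a + z_b) n <- n + 1
  structure(
    n,
    formula = "loa_ci_within_delta: Var(LoA) = sigma^2 (1/n + z^2/(2(n-1)))",
    inputs = c(expected_d = expected_d, expected_sd = expected_sd,
               max_allowed_diff = max_allowed_diff, alpha = alpha, beta = beta)
  )
}
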