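test_that("windowed HR pairs follow the direct arithmetic", {
  x <- beat_series(seq(0, 60000, by = 1000))
  p <- hr_pairs(x, x, window = 20)
  expect_equal(nrow(p), 3L)
  expect_true(all(p$x == 60 & p$y == 60))
  # +10 ms on every IBI at a 1000 ms base shifts each window HR by ~0.59 bpm
  y <- beat_series(cumsum(c(0, rep(1010, 60))))
  p2 <- hr_pairs(x, y, window = 20)
  expect_gt(nrow(p2), 0)
  expect_equal(p2$x - p2$y, rep(60 - 60000 / 1010, nrow(p2)),
               tolerance = 1e-9)
  # empty second series: no common windows
  p3 <- hr_pairs(x, beat_series(numeric(0)))
  expect_equal(nrow(p3), 0L)
})

test_that("Pearson correlation and Bland-Altman follow their definitions", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_r(x, 2 * x + 3), 1)
  expect_error(pearson_r(x, rep(1, 5)), "constant")
  ba <- bland_altman(c(1000, 900), c(990, 910))
  expect_equal(ba$d, 0)
  expect_equal(ba$sigma, sqrt(200))
  expect_equal(unname(ba$loa),
               c(-1.96 * sqrt(200), 1.96 * sqrt(200)))
  ba0 <- bland_altman(x, x)
  expect_equal(ba0$d, 0)
  expect_equal(ba0$sigma, 0)
  expect_equal(unname(ba0$loa), c(0, 0))
})

test_that("agreement statistics have the right symmetries", {
  set.seed(19)
  x <- rnorm(100, 1000, 50)
  y <- x + rnorm(100, 0, 20)
  expect_equal(pearson_r(x, y), pearson_r(y, x))
  bxy <- bland_altman(x, y)
  byx <- bland_altman(y, x)
  expect_equal(bxy$d, -byx$d)
  expect_equal(bxy$sigma, byx$sigma)
})

test_that("published ANOVA tables are reproduced from their sums of squares", {
  # HR row: between 1.70 (df 2), within 203.05 (df 195)
  hr <- anova_f_from_sums(1.70, 2, 203.05, 195)
  expect_equal(round(hr$F, 2), 0.82)
  expect_equal(round(hr$p, 2), 0.44)
  # IBI row: between taken as total - within
  ibi <- anova_f_from_sums(1670952.2 - 1669325.1, 2, 1669325.1, 3741)
  expect_equal(round(ibi$F, 2), 1.82)
  expect_equal(round(ibi$p, 2), 0.16)
})

test_that("one-way ANOVA decomposes variance exactly", {
  g <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(5, 6, 9))
  res <- one_way_anova(g)
  expect_equal(res$ss_total, res$ss_between + res$ss_within)
  # against stats::aov directly
  df <- data.frame(v = unlist(g), g = rep(names(g), lengths(g)))
  ref <- summary(stats::aov(v ~ g, df))[[1]]
  expect_equal(res$F, ref["g", "F value"])
  expect_equal(res$p, ref["g", "Pr(>F)"])
  # identical groups: no between-group variance
  same <- one_way_anova(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$ss_between, 0)
  expect_equal(same$F, 0)
  expect_error(one_way_anova(list(c(1, 2))), "2 groups")
})

test_that("ANOVA sum-of-squares conservation holds on random inputs", {
  set.seed(29)
  for (i in 1:20) {
    g <- lapply(seq_len(sample(2:5, 1)),
                function(j) rnorm(sample(3:40, 1), rnorm(1, 0, 50), runif(1, 1, 30)))
    res <- one_way_anova(g)
    expect_equal(res$ss_total, res$ss_between + res$ss_within,
                 tolerance = 1e-9)
  }
})

test_that("the paired t test handles degenerate differences by convention", {
  x <- c(1, 2, 3, 4)
  expect_equal(paired_t_test(x, x + c(1, -1, 1, -1))$t, 0)
  expect_equal(paired_t_test(x, x + c(1, -1, 1, -1))$p, 1)
  same <- paired_t_test(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  shifted <- paired_t_test(x, x + 2)
  expect_true(is.infinite(shifted$t))
  expect_equal(shifted$p, 0)
  expect_true(shifted$degenerate)
  # ordinary case agrees with stats::t.test
  set.seed(31)
  a <- rnorm(30); b <- a + rnorm(30, 0.1, 0.5)
  ours <- paired_t_test(a, b)
  ref <- stats::t.test(b, a, paired = TRUE)
  expect_equal(ours$t, unname(ref$statistic))
  expect_equal(ours$p, ref$p.value)
})

test_that("simulated acoustic-vs-reference jitter is not flagged as bias", {
  set.seed(37)
  reject <- vapply(1:200, function(i) {
    x <- rnorm(80, 1000, 40)
    y <- x + rnorm(80, 0, 5)
    paired_t_test(x, y)$p < 0.05
  }, logical(1))
  expect_lte(mean(reject), 0.12)
})

test_that("sample-size planning is monotone, scale-invariant and matches a power oracle", {
  n0 <- bland_altman_sample_size(1, 25, 55, 0.05, 0.1)
  expect_lt(bland_altman_sample_size(1, 25, 70, 0.05, 0.1), n0)
  expect_equal(as.integer(bland_altman_sample_size(2, 50, 110, 0.05, 0.1)),
               as.integer(n0))
  expect_error(bland_altman_sample_size(1, 25, 45), "allowable")
  # Monte-Carlo power at the returned n should be near the requested 0.90
  set.seed(41)
  z <- qnorm(0.975)
  ok <- vapply(1:1500, function(i) {
    d <- rnorm(n0, 1, 25)
    m <- mean(d); s <- sd(d)
    se <- s * sqrt(1 / n0 + z^2 / (2 * (n0 - 1)))
    (m + 1.96 * s + z * se < 55) && (m - 1.96 * s - z * se > -55)
  }, logical(1))
  expect_gt(mean(ok), 0.85)
  expect_lt(mean(ok), 0.95)
})

test_that("limits of agreement cover 95% of normal differences", {
  set.seed(43)
  x <- rnorm(10000, 1000, 30)
  y <- x + rnorm(10000, 0.5, 20)
  ba <- bland_altman(x, y)
  d <- y - x
  coverage <- mean(d >= ba$loa["lower"] & d <= ba$loa["upper"])
  expect_equal(coverage, 0.95, tolerance = 0.01 / 0.95)
})
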