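test_that("median filter matches a sort-and-pick oracle with shrunken edges", {
  br <- function(v) data.frame(breath_time_s = seq_along(v), vo2_mlmin = v)
  x <- c(500, 510, 2000, 505, 515)
  got <- median_filter_breaths(br(x), 5)$vo2_mlmin
  expect_equal(got[3], 510)
  # brute-force oracle: symmetric shrunken centred windows
  oracle <- function(x, w) {
    h <- (w - 1) %/% 2; n <- length(x)
    sapply(seq_len(n), function(i) {
      hh <- min(h, i - 1, n - i)
      median(sort(x[(i - hh):(i + hh)]))
    })
  }
  set.seed(7)
  for (rep in 1:20) {
    x <- rlnorm(sample(5:40, 1), log(1000), 0.3)
    w <- sample(c(3, 5, 7), 1)
    expect_equal(median_filter_breaths(br(x), w)$vo2_mlmin, oracle(x, w))
  }
  # constant series unchanged; single outlier removed
  expect_equal(median_filter_breaths(br(rep(7, 9)), 5)$vo2_mlmin, rep(7, 9))
  y <- c(500, 505, 510, 5000, 515, 520, 525)
  f <- median_filter_breaths(br(y), 5)$vo2_mlmin
  expect_true(all(f >= 500 & f <= 525))
  # idempotent on monotone data
  z <- sort(rlnorm(20, log(1000), 0.2))
  once <- median_filter_breaths(br(z), 5)$vo2_mlmin
  twice <- median_filter_breaths(br(once), 5)$vo2_mlmin
  expect_equal(once, twice)
  # preconditions
  expect_error(median_filter_breaths(br(y), 4), "odd")
  expect_equal(nrow(median_filter_breaths(br(numeric(0)), 5)), 0)
})

test_that("1 Hz interpolation is exactly piecewise linear with clamped ends", {
  expect_equal(interpolate_1hz(c(0, 2), c(400, 600), 1), 500)
  expect_equal(interpolate_1hz(c(0, 2, 5), c(1, 2, 8), c(0, 2, 5)), c(1, 2, 8))
  set.seed(11)
  bt <- cumsum(runif(30, 1, 4)); bv <- rnorm(30, 1000, 100)
  grid <- seq(ceiling(min(bt)), floor(max(bt)))
  oracle <- sapply(grid, function(g) {
    i <- findInterval(g, bt)
    bv[i] + (bv[i + 1] - bv[i]) * (g - bt[i]) / (bt[i + 1] - bt[i])
  })
  expect_equal(interpolate_1hz(bt, bv, grid), oracle, tolerance = 1e-12)
  # clamping outside the span
  expect_equal(interpolate_1hz(c(10, 20), c(5, 9), c(0, 30)), c(5, 9))
  expect_error(interpolate_1hz(c(3, 1, 2), 1:3, 2), "increasing")
  expect_error(interpolate_1hz(5, 1, 2), "at least 2")
})

test_that("cross-correlation alignment recovers known shifts", {
  set.seed(3)
  base <- 70 + 30 * sin(seq(0, 20, length.out = 600)) + rnorm(600, 0, 1)
  expect_equal(align_by_crosscorr(base, base, 20), 0L)
  shifted <- c(rep(base[1], 7), base[1:(600 - 7)])
  expect_equal(align_by_crosscorr(base, shifted, 20), 7L)
  # noisy shifted copy, verified against an exhaustive lag scan
  noisy <- c(rep(base[1], 12), base[1:(600 - 12)]) + rnorm(600, 0, 3)
  got <- align_by_crosscorr(base, noisy, 30)
  # positive lag: the second series is delayed
  scan <- sapply(-30:30, function(l) {
    if (l >= 0) cor(base[1:(600 - l)], noisy[(1 + l):600])
    else cor(base[(1 - l):600], noisy[1:(600 + l)])
  })
  expect_equal(got, (-30:30)[which.max(scan)])
  expect_equal(got, 12L)
  expect_error(align_by_crosscorr(rep(1, 100), base[1:100], 10), "constant")
})

test_that("ventilation calibration equals closed-form least squares", {
  x <- c(10, 20, 30, 40, 50)
  cal <- calibrate_ve(x, 2 * x + 5)
  expect_equal(cal$slope, 2)
  expect_equal(cal$intercept, 5)
  expect_equal(cal$ve, 2 * x + 5)
  ident <- calibrate_ve(x, x)
  expect_equal(ident$slope, 1)
  expect_equal(ident$intercept, 0, tolerance = 1e-12)
  # noisy case against the normal equations
  set.seed(21)
  xs <- rnorm(1000, 40, 10); ys <- 1.7 * xs - 3 + rnorm(1000, 0, 2)
  cal <- calibrate_ve(xs, ys)
  sxx <- sum((xs - mean(xs))^2)
  slope_o <- sum((xs - mean(xs)) * (ys - mean(ys))) / sxx
  expect_equal(cal$slope, slope_o, tolerance = 1e-10)
  expect_equal(cal$intercept, mean(ys) - slope_o * mean(xs), tolerance = 1e-10)
  expect_error(calibrate_ve(rep(2, 10), rnorm(10)), "constant")
})

test_that("heart-rate reserve follows its defining formula", {
  expect_equal(compute_hrr(60, 60, 190), 0)
  expect_equal(compute_hrr(190, 60, 190), 1)
  expect_equal(compute_hrr(125, 60, 190), 0.5)
  expect_equal(compute_hrr(c(50, 200), 60, 190),
               c((50 - 60) / 130, (200 - 60) / 130))  # no clipping
  expect_error(compute_hrr(100, 190, 60), "exceed")
})

test_that("feature scaling is train-only, invertible, and leak-free", {
  s1 <- toy_session(150, 1); s2 <- toy_session(150, 2)
  sc <- fit_scaler(list(s1, s2))
  sc_df <- apply_scaler(sc, s1)
  pooled <- rbind(apply_scaler(sc, s1), apply_scaler(sc, s2))
  for (f in c("ve_lmin", "bf_brpm", "hr_bpm", "hrr_frac", "vo2_mlmin")) {
    expect_lt(abs(mean(pooled[[f]])), 1e-9)
    expect_equal(sd(pooled[[f]]), 1, tolerance = 1e-9)
  }
  expect_gte(min(pooled$wr_w), 0)
  expect_lte(max(pooled$wr_w), 1)
  # round trip on the target
  z <- sc_df$vo2_mlmin
  expect_equal(unscale_vo2(sc, z), s1$vo2_mlmin, tolerance = 1e-10)
  # statistics do not move when a test session appears
  s3 <- toy_session(150, 3)
  expect_identical(sc$stats, fit_scaler(list(s1, s2))$stats)
  out <- apply_scaler(sc, s3)  # may exceed [0,1]; must not error
  expect_equal(nrow(out), 150)
})

test_that("window extraction is causal with N = L - T + 1", {
  s <- toy_session(60, 5)
  sc <- fit_scaler(s)
  w <- extract_windows(apply_scaler(sc, s), 10)
  expect_equal(dim(w$x), c(51, 10, 5))
  expect_equal(w$target_time, 10:60)
  # protocol-scale count: 1110 s session with a 218 s receptive field
  long <- toy_session(1110, 6)
  wl <- extract_windows(apply_scaler(fit_scaler(long), long), 218)
  expect_equal(dim(wl$x)[1], 893)
  # T = 1 keeps every second
  w1 <- extract_windows(apply_scaler(sc, s), 1)
  expect_equal(dim(w1$x)[1], 60)
  # causality: window i row j equals session feature at time i + j - 1,
  # so the last row is exactly the target time and nothing beyond
  sdf <- apply_scaler(sc, s)
  for (i in c(1, 25, 51))
    expect_equal(w$x[i, 10, ], unname(unlist(
      sdf[i + 9, c("wr_w", "ve_lmin", "bf_brpm", "hr_bpm", "hrr_frac")])))
  expect_warning(ws <- extract_windows(apply_scaler(sc, s[1:5, ]), 10),
                 "shorter")
  expect_equal(dim(ws$x)[1], 0)
})
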