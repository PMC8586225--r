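test_that("repeated-measures limits of agreement match a by-hand ANOVA", {
  # balanced design: 2 subjects x 3 points, fully hand-computable
  pred <- c(105, 110, 115, 208, 204, 212)
  true <- c(100, 100, 100, 200, 200, 200)
  subj <- rep(c("a", "b"), each = 3)
  d <- pred - true
  rep_means <- tapply(d, subj, mean)
  msb <- 3 * sum((rep_means - mean(d))^2) / (2 - 1)
  msw <- sum((d - rep_means[subj])^2) / (6 - 2)
  n0 <- (6 - (9 + 9) / 6) / (2 - 1)
  sd_o <- sqrt(max(0, (msb - msw) / n0) + msw)
  r <- bland_altman_rm(pred, true, subj)
  expect_equal(r$bias, mean(d), tolerance = 1e-10)
  expect_equal(r$sd_used, sd_o, tolerance = 1e-10)
  expect_equal(r$loa_low, mean(d) - 1.96 * sd_o, tolerance = 1e-10)
  expect_equal(r$loa_high, mean(d) + 1.96 * sd_o, tolerance = 1e-10)
  # cross-check the variance components against aov()
  a <- anova(lm(d ~ subj))
  expect_equal(msb, a$`Mean Sq`[1], tolerance = 1e-10)
  expect_equal(msw, a$`Mean Sq`[2], tolerance = 1e-10)
})

test_that("repeated-measures SD is at least the within-subject SD", {
  set.seed(5)
  subj <- rep(letters[1:6], times = c(10, 12, 8, 15, 10, 9))
  true <- rnorm(length(subj), 2000, 300)
  offs <- rnorm(6, 0, 80)[match(subj, letters[1:6])]
  pred <- true + offs + rnorm(length(subj), 0, 40)
  r <- bland_altman_rm(pred, true, subj)
  d <- pred - true
  msw <- sum((d - tapply(d, subj, mean)[subj])^2) /
    (length(d) - 6)
  expect_gte(r$sd_used + 1e-12, sqrt(msw))
  expect_equal(r$n_subjects, 6)
})

test_that("degenerate agreement cases reduce correctly", {
  # identical differences: zero-width limits
  r <- bland_altman_rm(c(10, 10, 10, 10) + 1:4, 1:4, c("a", "a", "b", "b"))
  expect_equal(r$bias, 10)
  expect_equal(r$sd_used, 0)
  expect_equal(r$loa_low, r$loa_high)
  # no between-subject component: equals the standard method
  set.seed(6)
  p <- rnorm(40, 1000, 50); t <- p - rnorm(40, 5, 10)
  same <- bland_altman_rm(p, t, rep("a", 40), method = "standard")
  expect_equal(same$sd_used, sd(p - t))
  # one point per subject: repeated-measures equals standard
  r1 <- suppressWarnings(bland_altman_rm(p[1:8], t[1:8], letters[1:8]))
  expect_equal(r1$sd_used, sd(p[1:8] - t[1:8]), tolerance = 1e-10)
  # single subject falls back with a warning
  expect_warning(bland_altman_rm(p, t, rep("a", 40)), "standard")
})

test_that("proportional bias slope matches a direct regression", {
  set.seed(8)
  true <- rnorm(100, 2000, 400)
  pred <- true + 0.1 * true + rnorm(100, 0, 20)
  r <- bland_altman_rm(pred, true, rep(c("a", "b"), 50))
  fit <- lm(I(pred - true) ~ I((pred + true) / 2))
  expect_equal(r$proportional_slope, unname(coef(fit)[2]), tolerance = 1e-10)
  expect_true(r$proportional_ci[1] < r$proportional_slope)
  expect_true(r$proportional_ci[2] > r$proportional_slope)
})

test_that("per-protocol error summaries report mean and SD of signed error", {
  pred <- c(100, 110, 205, 195)
  true <- c(100, 100, 200, 200)
  lab <- c("L-M", "L-M", "VT-H", "VT-H")
  es <- error_summary(pred, true, lab)
  expect_equal(es$mean_error[es$protocol == "L-M"], 5)
  expect_equal(es$mean_error[es$protocol == "combined"], 2.5)
  zero <- error_summary(true, true, lab)
  expect_true(all(zero$mean_error == 0) && all(zero$sd_error == 0))
  off <- error_summary(true + 50, true, lab)
  expect_true(all(off$mean_error == 50) && all(off$sd_error == 0))
  set.seed(9)
  e <- rnorm(1e4, 0, 100)
  es2 <- error_summary(2000 + e, rep(2000, 1e4), rep("MAX", 1e4))
  expect_lt(abs(es2$mean_error[1]), 3)
  expect_true(es2$sd_error[1] > 97 && es2$sd_error[1] < 103)
  expect_error(error_summary(1, 1, "warmup"), "unknown")
})

test_that("VO2peak agreement compares 20 s moving-average peaks", {
  set.seed(10)
  true <- lapply(1:5, function(i)
    simulate_channel(wr_profile(protocol_ramp(peak_wr = 200 + 10 * i)),
                     25, 25, 600, 10))
  pred <- lapply(true, function(v) v + rnorm(length(v), 30, 20))
  r <- vo2peak_agreement(pred, true)
  direct <- mapply(function(p, t) vo2peak_20s(p) - vo2peak_20s(t),
                   pred, true)
  expect_equal(r$bias, mean(direct), tolerance = 1e-10)
  expect_equal(r$method, "standard")
  ident <- vo2peak_agreement(true, true)
  expect_equal(ident$bias, 0)
  off <- vo2peak_agreement(lapply(true, `+`, 100), true)
  expect_equal(off$bias, 100, tolerance = 1e-10)
  expect_error(vo2peak_agreement(list(), list()), "no ramp")
})

test_that("MET conversion and intensity cut-points follow the guidelines", {
  expect_equal(vo2_to_mets(3.5 * 70, 70), 1)
  expect_equal(vo2_to_mets(2940, 70), 12)
  expect_equal(as.character(classify_mets(c(1, 2.99, 3, 5.99, 6, 9))),
               c("light", "light", "moderate", "moderate",
                 "vigorous", "vigorous"))
  expect_error(vo2_to_mets(1000, 0), "positive")
})

test_that("confusion matrix conserves seconds and scores accuracies", {
  truec <- rep(c("light", "moderate", "vigorous"), times = c(10, 20, 30))
  predc <- truec
  predc[1:2] <- "moderate"    # 2 light misclassified
  r <- confusion_and_accuracy(truec, predc)
  expect_equal(r$total_seconds, 60)
  expect_equal(sum(r$confusion), 60)
  expect_equal(unname(rowSums(r$confusion)), c(10, 20, 30))
  expect_equal(r$overall_accuracy, 100 * 58 / 60)
  expect_equal(unname(r$class_accuracy["light"]), 80)
  perfect <- confusion_and_accuracy(truec, truec)
  expect_equal(perfect$overall_accuracy, 100)
  expect_error(confusion_and_accuracy(truec, predc[-1]), "equal length")
  expect_error(confusion_and_accuracy(c("light", "extreme"),
                                      c("light", "light")), "classes")
})
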