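test_that("shift register produces maximal-length sequences", {
  u <- prbs_sequence(4, c(4, 3), rep(1, 4))
  expect_length(u, 15)
  expect_setequal(unique(u), c(0, 1))
  # balance property of any m-sequence
  expect_equal(abs(sum(u == 1) - sum(u == 0)), 1)

  # 3-stage register checked against an exhaustive state walk
  lfsr_walk <- function(n, taps, state) {
    out <- integer(0)
    repeat {
      out <- c(out, state[n])
      state <- c(sum(state[taps]) %% 2L, state[-n])
      if (all(state == 1L)) break
    }
    out
  }
  expect_equal(prbs_sequence(3, c(3, 2), rep(1, 3)),
               lfsr_walk(3L, c(3L, 2L), rep(1L, 3)))
  expect_length(prbs_sequence(3, c(3, 2)), 7)
})

test_that("degenerate registers are rejected", {
  expect_error(prbs_sequence(4, c(4, 3), rep(0, 4)), "nonzero")
  # x^4 + x^2 + 1 is not primitive: period 6, not 15
  expect_error(prbs_sequence(4, c(4, 2), rep(1, 4)), "period")
})

test_that("balance holds for every maximal 4-stage tap set and seed", {
  for (taps in list(c(4, 3), c(4, 1))) {
    for (s in 1:15) {
      seed_bits <- as.integer(intToBits(s)[1:4])
      u <- prbs_sequence(4, taps, seed_bits)
      expect_equal(abs(sum(u == 1) - sum(u == 0)), 1)
    }
  }
})

test_that("PRBS work-rate profile has the protocol timing", {
  u <- prbs_sequence()
  wr <- wr_profile(protocol_prbs(25, 100), u)
  expect_length(wr, 1110)  # 210 s warm-up + 2 x 450 s
  expect_setequal(unique(wr), c(25, 100))
  # warm-up equals the final 210 s of one period
  one <- rep(ifelse(u == 1, 100, 25), each = 30)
  expect_equal(wr[1:210], one[241:450])
  expect_equal(wr[211:660], one)
  # zero repetitions leaves only the warm-up
  expect_length(wr_profile(protocol_prbs(25, 100, n_repetitions = 0), u), 210)
})

test_that("ramp profile follows the linear closed form", {
  wr <- wr_profile(protocol_ramp(25, 240, 25, 250))
  expect_equal(wr[1:240], rep(25, 240))
  expect_equal(wr[300], 50)          # 25 + 25 * 60/60
  expect_equal(max(wr), 250)
  expect_equal(wr[270], 25 + 25 * 30 / 60)
})

test_that("first-order channel matches the closed-form exponential", {
  # constant input from steady state stays constant
  expect_equal(simulate_channel(rep(50, 100), 30, 30, 600, 10),
               rep(1100, 100))
  # step of amplitude A: ~63.2% covered after one time constant
  wr <- c(0, rep(100, 120))
  v <- simulate_channel(wr, 30, 30, 600, 10)
  expect_equal((v[31] - 600) / 1000, 1 - exp(-1), tolerance = 1e-9)
  # bounded by the steady-state envelope
  expect_true(all(v >= 600 - 1e-9 & v <= 1600 + 1e-9))
})

test_that("equal on/off time constants give a linear (superposable) system", {
  set.seed(4)
  w1 <- rep(sample(0:100, 10), each = 30)
  w2 <- rep(sample(0:100, 10), each = 30)
  r <- function(w) simulate_channel(w, 25, 25, 0, 10)
  # response to sum of inputs = sum of responses (baseline counted once)
  expect_equal(r(w1 + w2), r(w1) + r(w2), tolerance = 1e-6)
})

test_that("asymmetric kinetics recover more slowly than they rise", {
  wr <- c(rep(100, 200), rep(0, 200))
  v <- simulate_channel(wr, 20, 40, 600, 10)
  on_cov <- (v[20] - 600) / 1000        # coverage after tau_on at onset
  off_cov <- (1600 - v[220]) / 1000     # coverage after tau_on in recovery
  expect_gt(on_cov, off_cov)
})

test_that("breath sampling respects frequency, noise, and seeding", {
  tt <- 1:60
  b <- sample_breaths(tt, rep(1000, 60), rep(20, 60), rep(20, 60),
                      physio_params(vo2_cv = 0, ve_cv = 0, bf_sd = 0,
                                    outlier_breath_prob = 0), seed = 1)
  expect_true(abs(nrow(b) - 20) <= 1)   # 20 breaths/min over 1 min
  expect_true(all(b$vo2_mlmin == 1000)) # noiseless identity
  # outlier count reproduces under the same seed
  p <- physio_params(outlier_breath_prob = 0.05)
  long <- rep(1000, 3000)
  b1 <- sample_breaths(1:3000, long, rep(30, 3000), rep(20, 3000), p, seed = 9)
  b2 <- sample_breaths(1:3000, long, rep(30, 3000), rep(20, 3000), p, seed = 9)
  expect_identical(b1, b2)
  n_out <- sum(b1$vo2_mlmin > 1500 | b1$vo2_mlmin < 600)
  expect_gt(n_out, 0)
  expect_lt(n_out, 0.15 * nrow(b1))
  # empty input
  e <- sample_breaths(numeric(0), numeric(0), numeric(0), numeric(0), p)
  expect_equal(nrow(e), 0)
})

test_that("sessions satisfy the channel invariants", {
  s <- simulate_session(physio_params(), protocol_prbs(25, 100), seed = 3)
  expect_equal(nrow(s), 1110)
  expect_equal(diff(s$time_s), rep(1, 1109))
  expect_true(all(s$vo2_mlmin > 0))
  expect_true(all(s$hrr_frac > -0.2 & s$hrr_frac < 1.1))
  expect_setequal(unique(s$wr_w), c(25, 100))
})

test_that("cohort generation is reproducible and complete", {
  c1 <- make_cohort(2, seed = 5, prbs_repetitions = 1)
  c2 <- make_cohort(2, seed = 5, prbs_repetitions = 1)
  expect_identical(c1$sessions, c2$sessions)
  expect_length(c1$sessions, 8)  # 4 protocols per participant
  expect_setequal(unique(c1$manifest$protocol), c("MAX", "L-M", "L-H", "VT-H"))
  # derived work rates are ordered
  expect_true(all(c1$participants$wr_90vt < c1$participants$wr_vt))
  expect_true(all(c1$participants$wr_vt < c1$participants$wr_d50))
  c3 <- make_cohort(2, seed = 6, prbs_repetitions = 1)
  expect_false(identical(c1$sessions, c3$sessions))
})
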