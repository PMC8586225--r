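# Small deterministic fixtures used across tests.

# a minimal synthetic session data.frame without the full simulator
toy_session <- function(L = 200, seed = 1, delay = 2, label = "L-M") {
  set.seed(seed)
  wr <- rep(sample(c(25, 100), ceiling(L / 20), replace = TRUE), each = 20)[1:L]
  wr_del <- c(rep(wr[1], delay), wr[1:(L - delay)])
  vo2 <- 600 + 10 * wr_del
  hr <- 60 + 0.5 * wr_del
  df <- data.frame(
    time_s = 1:L, wr_w = wr, hr_bpm = hr,
    hrr_frac = (hr - 60) / 130,
    bf_brpm = 14 + 0.1 * wr_del,
    ve_lmin = 9 + 0.2 * wr_del,
    vo2_mlmin = vo2, vo2_truth_mlmin = vo2)
  attr(df, "participant_id") <- paste0("T", seed)
  attr(df, "protocol") <- list(kind = "prbs", label = label)
  attr(df, "mass") <- 70
  class(df) <- c("vo2_session", "data.frame")
  df
}

tiny_cfg <- function(...) tcn_config(5, 4, 2, 3, dropout = 0, ...)
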