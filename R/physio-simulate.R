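#' Physiological parameters for the cardiorespiratory simulator
#'
#' One participant's parameter set: steady-state gains and first-order
#' on/off time constants for VO2, heart rate, minute ventilation, and
#' breathing frequency, plus breath-by-breath measurement-noise settings.
#' The VO2 steady state is linear in work rate
#' (\code{vo2_baseline + vo2_gain * wr}); HR, ventilation, and breathing
#' frequency are driven by the metabolic demand, rising linearly with the
#' fraction of the VO2 reserve it engages (HR from \code{hr_rest} to
#' \code{hr_max}, ventilation from \code{ve_rest} to \code{ve_peak}, and
#' so on), since ventilation follows metabolic gas flux and HR tracks
#' %VO2 reserve rather than external work.  Each channel relaxes toward
#' its target with \code{tau_*_on} when the target lies above the current
#' value and \code{tau_*_off} otherwise (asymmetric on/off kinetics, with
#' recovery slower than onset for HR and ventilation).
#'
#' @param vo2_baseline resting/unloaded VO2 (ml/min).
#' @param vo2_gain VO2 per watt (ml/min/W); ~10 in cycling.
#' @param vo2peak peak VO2 (ml/min); sets the peak work rate
#'   \code{(vo2peak - vo2_baseline)/vo2_gain}.
#' @param tau_vo2_on,tau_vo2_off VO2 time constants (s), typically 20-30 s.
#' @param tau_hr_on,tau_hr_off,tau_ve_on,tau_ve_off,tau_bf_on,tau_bf_off
#'   time constants (s) for HR, ventilation, breathing frequency; off
#'   (recovery) values default to 1.3x the on values.
#' @param hr_rest,hr_max resting and maximal heart rate (bpm).
#' @param bf_rest,bf_peak breathing frequency at rest and peak (breaths/min).
#' @param ve_rest,ve_peak minute ventilation at rest and peak (L/min).
#' @param mass body mass (kg), used for ml/min/kg and MET conversions.
#' @param delay pure transport delay (s) before a work-rate change reaches
#'   the channels (cardiodynamic phase; default 0).
#' @param vo2_cv,ve_cv per-breath multiplicative noise coefficients of
#'   variation for VO2 and ventilation.
#' @param bf_sd,hr_sd additive noise SD for breathing frequency
#'   (breaths/min, per breath) and heart rate (bpm, per second).
#' @param outlier_breath_prob probability that a breath is replaced by a
#'   spurious outlier (value multiplied by a factor >= 2 or <= 0.5).
#' @return object of class \code{physio_params}.
#' @export
physio_params <- function(vo2_baseline = 600, vo2_gain = 10, vo2peak = 2940,
                          tau_vo2_on = 25, tau_vo2_off = 25,
                          tau_hr_on = 38, tau_hr_off = 1.3 * tau_hr_on,
                          tau_ve_on = 45, tau_ve_off = 1.3 * tau_ve_on,
                          tau_bf_on = 32, tau_bf_off = 1.3 * tau_bf_on,
                          hr_rest = 62, hr_max = 190,
                          bf_rest = 14, bf_peak = 45,
                          ve_rest = 9, ve_peak = 73,
                          mass = 70, delay = 0,
                          vo2_cv = 0.04, ve_cv = 0.05,
                          bf_sd = 1.0, hr_sd = 1.0,
                          outlier_breath_prob = 0.02) {
  p <- as.list(environment())
  taus <- p[grep("^tau_", names(p))]
  if (any(unlist(taus) <= 0)) stop("all time constants must be positive")
  if (p$tau_hr_off < p$tau_hr_on || p$tau_ve_off < p$tau_ve_on)
    stop("HR and VE recovery (off) time constants must not be faster than onset")
  if (p$hr_rest >= p$hr_max) stop("hr_rest must be below hr_max")
  if (p$vo2peak <= p$vo2_baseline) stop("vo2peak must exceed vo2_baseline")
  if (p$outlier_breath_prob < 0 || p$outlier_breath_prob > 1)
    stop("outlier_breath_prob must be a probability")
  p$wr_peak <- (p$vo2peak - p$vo2_baseline) / p$vo2_gain
  structure(p, class = "physio_params")
}

#' First-order response of a channel to a work-rate profile
#'
#' Integrates mono-exponential kinetics at 1 Hz: the channel relaxes toward
#' the steady state \code{baseline + gain * wr(t - delay)} using
#' \code{tau_on} when the target is above the current value and
#' \code{tau_off} otherwise.  The update over one second uses the exact
#' exponential step \code{v + (1 - exp(-1/tau)) * (target - v)}, so a step
#' input reproduces the closed-form exponential response sample-for-sample.
#' The series starts at the steady state of the first work-rate value.
#'
#' @param wr work-rate profile (W) at 1 Hz.
#' @param tau_on,tau_off time constants (s), both positive.
#' @param baseline channel value at 0 W.
#' @param gain channel units per watt.
#' @param delay pure delay (s) before work-rate changes take effect.
#' @return noise-free channel series, same length as \code{wr}.
#' @export
simulate_channel <- function(wr, tau_on, tau_off, baseline, gain, delay = 0) {
  n <- length(wr)
  d <- as.integer(round(delay))
  wr_eff <- if (d > 0) c(rep(wr[1], d), wr[1:(n - d)]) else wr
  first_order_response(baseline + gain * wr_eff, tau_on, tau_off)
}

# integrate dv/dt = (target - v)/tau at 1 Hz with the exact exponential step
first_order_response <- function(target, tau_on, tau_off) {
  if (tau_on <= 0 || tau_off <= 0) stop("time constants must be positive")
  a_on <- 1 - exp(-1 / tau_on)
  a_off <- 1 - exp(-1 / tau_off)
  v <- numeric(length(target))
  v[1] <- target[1]
  for (t in seq_along(target)[-1]) {
    a <- if (target[t] > v[t - 1]) a_on else a_off
    v[t] <- v[t - 1] + a * (target[t] - v[t - 1])
  }
  v
}

#' Breath-by-breath sampling of latent gas-exchange channels
#'
#' Emulates a metabolic cart: breath times follow the instantaneous
#' breathing frequency (inter-breath interval 60/bf), each breath carries
#' the latent VO2 and ventilation at that moment plus heteroscedastic
#' (multiplicative) noise, and with probability \code{outlier_breath_prob}
#' a breath's VO2 is replaced by a spurious outlier (x2-3 or x0.2-0.5),
#' which the 5-breath median filter is designed to remove.
#'
#' @param time 1 Hz time stamps (s).
#' @param vo2,ve,bf latent channel series aligned with \code{time}.
#' @param params a \code{\link{physio_params}} (noise fields used).
#' @param seed RNG seed; sampling is deterministic given the seed.
#' @return data.frame with columns \code{breath_time_s}, \code{vo2_mlmin},
#'   \code{ve_lmin}, \code{bf_brpm}.
#' @export
sample_breaths <- function(time, vo2, ve, bf, params = physio_params(),
                           seed = NULL) {
  stopifnot(length(time) == length(vo2), length(vo2) == length(ve),
            length(ve) == length(bf))
  if (length(time) == 0)
    return(data.frame(breath_time_s = numeric(0), vo2_mlmin = numeric(0),
                      ve_lmin = numeric(0), bf_brpm = numeric(0)))
  if (any(bf <= 0)) stop("breathing frequency must be positive everywhere")
  with_seed(seed, {
    at <- function(series, t) stats::approx(time, series, t, rule = 2)$y
    t_end <- max(time)
    bt <- numeric(0)
    t <- time[1]
    while (t <= t_end) {
      bt <- c(bt, t)
      t <- t + 60 / at(bf, t)
    }
    n <- length(bt)
    v <- at(vo2, bt) * (1 + params$vo2_cv * stats::rnorm(n))
    out <- stats::runif(n) < params$outlier_breath_prob
    if (any(out)) {
      k <- sum(out)
      up <- stats::runif(k) < 0.5
      fac <- ifelse(up, stats::runif(k, 2, 3), stats::runif(k, 0.2, 0.5))
      v[out] <- v[out] * fac
    }
    data.frame(
      breath_time_s = bt,
      vo2_mlmin = v,
      ve_lmin = at(ve, bt) * (1 + params$ve_cv * stats::rnorm(n)),
      bf_brpm = pmax(4, at(bf, bt) + params$bf_sd * stats::rnorm(n)))
  })
}

#' Simulate one exercise session
#'
#' Renders the protocol's work-rate profile, integrates the latent VO2, HR,
#' ventilation, and breathing-frequency responses, samples noisy
#' breath-by-breath records, and rebuilds the measured 1 Hz channels the
#' way the acquisition pipeline would: VO2 through a 5-breath median filter
#' then linear 1 Hz interpolation, ventilation and breathing frequency by
#' interpolation, HR at 1 Hz with additive sensor noise, and heart-rate
#' reserve from the participant's resting and maximal HR.
#'
#' @param params a \code{\link{physio_params}}.
#' @param protocol a \code{\link{protocol_prbs}} or \code{\link{protocol_ramp}}.
#' @param seed RNG seed for the measurement noise.
#' @param participant_id participant label stored with the session.
#' @param units PRBS binary sequence (ignored for ramp protocols).
#' @return a \code{vo2_session}: data.frame with columns \code{time_s},
#'   \code{wr_w}, \code{hr_bpm}, \code{hrr_frac}, \code{bf_brpm},
#'   \code{ve_lmin}, \code{vo2_mlmin}, \code{vo2_truth_mlmin}, carrying the
#'   protocol, participant id, mass, and HR limits as attributes.
#' @export
simulate_session <- function(params = physio_params(),
                             protocol = protocol_prbs(),
                             seed = NULL, participant_id = "P1",
                             units = prbs_sequence()) {
  wr <- wr_profile(protocol, units)
  n <- length(wr)
  time <- seq_len(n)
  d <- as.integer(round(params$delay))
  wr_eff <- if (d > 0) c(rep(wr[1], d), wr[1:(n - d)]) else wr
  # metabolic demand: VO2 steady state for the current work rate
  vo2_ss <- params$vo2_baseline + params$vo2_gain * wr_eff
  # fraction of the VO2 reserve demanded; HR, ventilation, and breathing
  # frequency are driven by metabolic demand (not external work directly),
  # each with its own on/off kinetics -- HR tracks %VO2 reserve and
  # ventilation rises with metabolic gas flux
  frac <- (vo2_ss - params$vo2_baseline) /
    (params$vo2peak - params$vo2_baseline)
  lat_vo2 <- first_order_response(vo2_ss, params$tau_vo2_on,
                                  params$tau_vo2_off)
  lat_hr <- first_order_response(
    params$hr_rest + (params$hr_max - params$hr_rest) * frac,
    params$tau_hr_on, params$tau_hr_off)
  lat_bf <- first_order_response(
    params$bf_rest + (params$bf_peak - params$bf_rest) * frac,
    params$tau_bf_on, params$tau_bf_off)
  lat_ve <- first_order_response(
    params$ve_rest + (params$ve_peak - params$ve_rest) * frac,
    params$tau_ve_on, params$tau_ve_off)
  with_seed(seed, {
    breaths <- sample_breaths(time, lat_vo2, lat_ve, lat_bf, params)
    filt <- median_filter_breaths(breaths, width = 5)
    vo2_meas <- interpolate_1hz(filt$breath_time_s, filt$vo2_mlmin, time)
    ve_meas <- interpolate_1hz(breaths$breath_time_s, breaths$ve_lmin, time)
    bf_meas <- interpolate_1hz(breaths$breath_time_s, breaths$bf_brpm, time)
    hr_meas <- lat_hr + params$hr_sd * stats::rnorm(n)
    sess <- data.frame(
      time_s = time, wr_w = wr, hr_bpm = hr_meas,
      hrr_frac = compute_hrr(hr_meas, params$hr_rest, params$hr_max),
      bf_brpm = bf_meas, ve_lmin = ve_meas,
      vo2_mlmin = pmax(vo2_meas, 1), vo2_truth_mlmin = lat_vo2)
    attr(sess, "participant_id") <- participant_id
    attr(sess, "protocol") <- protocol
    attr(sess, "mass") <- params$mass
    attr(sess, "hr_rest") <- params$hr_rest
    attr(sess, "hr_max") <- params$hr_max
    class(sess) <- c("vo2_session", "data.frame")
    sess
  })
}

# draw one participant's physiology from the population distributions
draw_participant <- function(population = list()) {
  pop <- utils::modifyList(list(
    mass_mean = 70, mass_sd = 11,
    vo2peak_kg_mean = 42, vo2peak_kg_sd = 6,
    vo2_baseline_mean = 600, vo2_baseline_sd = 50,
    vo2_gain_mean = 10, vo2_gain_sd = 0.7,
    tau_vo2_range = c(20, 30),
    tau_hr_range = c(30, 45),
    tau_ve_range = c(35, 55),
    tau_bf_range = c(25, 40),
    off_tau_factor = 1.3,
    hr_rest_mean = 62, hr_rest_sd = 6,
    hr_max_mean = 190, hr_max_sd = 8,
    bf_rest_mean = 14, bf_rest_sd = 2,
    bf_peak_mean = 45, bf_peak_sd = 5,
    ve_rest_mean = 9, ve_rest_sd = 1.5,
    ve_equiv_mean = 0.0275, ve_equiv_sd = 0.0018,
    vo2_cv = 0.04, ve_cv = 0.05, bf_sd = 1, hr_sd = 1,
    outlier_breath_prob = 0.02), population)
  clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  mass <- clip(stats::rnorm(1, pop$mass_mean, pop$mass_sd), 45, 110)
  vo2peak_kg <- clip(stats::rnorm(1, pop$vo2peak_kg_mean, pop$vo2peak_kg_sd),
                     30, 60)
  vo2_baseline <- clip(stats::rnorm(1, pop$vo2_baseline_mean,
                                    pop$vo2_baseline_sd), 400, 800)
  ve_rest <- clip(stats::rnorm(1, pop$ve_rest_mean, pop$ve_rest_sd), 5, 14)
  # ventilation scales with absolute metabolic rate: peak VE follows the
  # participant's VO2 reserve through the ventilatory equivalent for O2
  ve_equiv <- clip(stats::rnorm(1, pop$ve_equiv_mean, pop$ve_equiv_sd),
                   0.020, 0.036)
  ve_peak <- ve_rest + ve_equiv * (vo2peak_kg * mass - vo2_baseline)
  tau_vo2 <- stats::runif(1, pop$tau_vo2_range[1], pop$tau_vo2_range[2])
  tau_hr <- stats::runif(1, pop$tau_hr_range[1], pop$tau_hr_range[2])
  tau_ve <- stats::runif(1, pop$tau_ve_range[1], pop$tau_ve_range[2])
  tau_bf <- stats::runif(1, pop$tau_bf_range[1], pop$tau_bf_range[2])
  physio_params(
    vo2_baseline = vo2_baseline,
    vo2_gain = clip(stats::rnorm(1, pop$vo2_gain_mean, pop$vo2_gain_sd),
                    8, 12),
    vo2peak = vo2peak_kg * mass,
    tau_vo2_on = tau_vo2, tau_vo2_off = tau_vo2,
    tau_hr_on = tau_hr, tau_hr_off = pop$off_tau_factor * tau_hr,
    tau_ve_on = tau_ve, tau_ve_off = pop$off_tau_factor * tau_ve,
    tau_bf_on = tau_bf, tau_bf_off = pop$off_tau_factor * tau_bf,
    hr_rest = clip(stats::rnorm(1, pop$hr_rest_mean, pop$hr_rest_sd), 45, 80),
    hr_max = clip(stats::rnorm(1, pop$hr_max_mean, pop$hr_max_sd), 170, 210),
    bf_rest = clip(stats::rnorm(1, pop$bf_rest_mean, pop$bf_rest_sd), 8, 20),
    bf_peak = clip(stats::rnorm(1, pop$bf_peak_mean, pop$bf_peak_sd), 35, 60),
    ve_rest = ve_rest,
    ve_peak = ve_peak,
    mass = mass,
    vo2_cv = pop$vo2_cv, ve_cv = pop$ve_cv, bf_sd = pop$bf_sd,
    hr_sd = pop$hr_sd, outlier_breath_prob = pop$outlier_breath_prob)
}

#' Simulate a cohort of participants
#'
#' Draws per-participant physiology from population distributions, runs a
#' ramp-incremental test, derives the participant-specific protocol work
#' rates from the ramp (VO2peak, mean response time, synthetic ventilatory
#' threshold), and simulates the three pseudorandom binary sequence
#' sessions: low-to-moderate "L-M" (25 W vs 90% VT), low-to-high "L-H"
#' (25 W vs delta-50%), and "VT-H" (VT vs delta-50%), alongside the ramp
#' ("MAX").  Everything is reproducible given \code{seed}.
#'
#' @param n_participants number of participants (>= 1).
#' @param seed RNG seed controlling parameter draws and measurement noise.
#' @param population named list overriding population-distribution settings
#'   (see \code{vo2tcn:::draw_participant} for the fields).
#' @param prbs_repetitions,prbs_warmup PRBS session length controls
#'   (defaults: 2 repetitions after a 210 s warm-up -> 1110 s sessions).
#' @param vt_frac synthetic ventilatory threshold as a fraction of VO2peak.
#' @return object of class \code{vo2_cohort}: list with \code{sessions} (a
#'   list of \code{vo2_session}), \code{participants} (data.frame of drawn
#'   parameters), and \code{manifest} (data.frame: participant, protocol).
#' @examples
#' coh <- make_cohort(1, seed = 7)
#' length(coh$sessions)  # 4
#' @export
make_cohort <- function(n_participants, seed = 1, population = list(),
                        prbs_repetitions = 2, prbs_warmup = 210,
                        vt_frac = 0.65) {
  if (n_participants < 1) stop("n_participants must be >= 1")
  with_seed(seed, {
    sessions <- list()
    rows <- list()
    units <- prbs_sequence()
    for (i in seq_len(n_participants)) {
      id <- sprintf("P%02d", i)
      par <- draw_participant(population)
      sess_seeds <- sample.int(.Machine$integer.max - 1L, 4)
      ramp_proto <- protocol_ramp(peak_wr = ceiling(par$wr_peak))
      ramp <- simulate_session(par, ramp_proto, seed = sess_seeds[1],
                               participant_id = id)
      ra <- ramp_analysis(ramp, vt_frac = vt_frac)
      protos <- list(
        protocol_prbs(25, ra$wr_90vt, warmup_duration = prbs_warmup,
                      n_repetitions = prbs_repetitions, label = "L-M"),
        protocol_prbs(25, ra$wr_d50, warmup_duration = prbs_warmup,
                      n_repetitions = prbs_repetitions, label = "L-H"),
        protocol_prbs(ra$wr_vt, ra$wr_d50, warmup_duration = prbs_warmup,
                      n_repetitions = prbs_repetitions, label = "VT-H"))
      sess <- c(list(ramp),
                lapply(seq_along(protos), function(j)
                  simulate_session(par, protos[[j]], seed = sess_seeds[j + 1],
                                   participant_id = id, units = units)))
      sessions <- c(sessions, sess)
      rows[[i]] <- data.frame(
        participant_id = id, mass = par$mass, vo2peak = par$vo2peak,
        vo2_baseline = par$vo2_baseline, vo2_gain = par$vo2_gain,
        tau_vo2_on = par$tau_vo2_on, tau_hr_on = par$tau_hr_on,
        tau_ve_on = par$tau_ve_on, hr_rest = par$hr_rest,
        hr_max = par$hr_max, mrt = ra$mrt, vt_vo2 = ra$vt_vo2,
        wr_90vt = ra$wr_90vt, wr_vt = ra$wr_vt, wr_d50 = ra$wr_d50)
    }
    manifest <- data.frame(
      participant_id = vapply(sessions, function(s)
        attr(s, "participant_id"), ""),
      protocol = vapply(sessions, function(s) attr(s, "protocol")$label, ""))
    structure(list(sessions = sessions,
                   participants = do.call(rbind, rows),
                   manifest = manifest),
              class = "vo2_cohort")
  })
}

#' @export
print.vo2_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d participants, %d sessions\n",
              nrow(x$participants), length(x$sessions)))
  print(table(x$manifest$protocol))
  invisible(x)
}
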