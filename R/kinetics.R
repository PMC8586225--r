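#' Peak oxygen uptake from a 20 s moving average
#'
#' VO2peak is the highest value of the \code{width}-second moving average of
#' the 1 Hz VO2 series over the exercise test.
#'
#' @param vo2 1 Hz VO2 series (ml/min).
#' @param width averaging window in seconds (default 20).
#' @return VO2peak in ml/min.
#' @export
vo2peak_20s <- function(vo2, width = 20) {
  if (length(vo2) < width)
    stop("VO2 series must span at least ", width, " s")
  max(moving_average(vo2, width))
}

#' Mean response time from a double-linear ramp fit
#'
#' The VO2 mean response time (MRT) of a ramp-incremental test is the lag
#' between the work-rate ramp and the VO2 response.  It is estimated by
#' intersecting (i) the horizontal forward extrapolation of the mean VO2
#' during the 2 min of baseline cycling immediately before ramp onset with
#' (ii) the backward extrapolation of an ordinary least squares line fitted
#' to the linear portion of the ramp response, taken from
#' \code{ramp_onset + guard} up to \code{vt_time} (the ventilatory
#' threshold, above which linearity is not assumed).  MRT is the
#' intersection time minus the ramp onset.
#'
#' @param time time stamps (s), 1 Hz.
#' @param vo2 VO2 series (ml/min) aligned with \code{time}.
#' @param ramp_onset time (s) at which the ramp starts.
#' @param vt_time time (s) at which VO2 reaches the ventilatory threshold.
#' @param guard seconds after ramp onset excluded from the sloped fit, to
#'   skip the curvilinear lag region (default 60).
#' @return list with \code{mrt} (s), \code{baseline_vo2}, \code{slope},
#'   \code{intercept}, and \code{t_intersect}.
#' @export
fit_mrt <- function(time, vo2, ramp_onset, vt_time, guard = 60) {
  stopifnot(length(time) == length(vo2))
  pre <- time >= (ramp_onset - 120) & time <= ramp_onset
  if (!any(pre)) stop("no baseline data in the 2 min before ramp onset")
  base <- mean(vo2[pre])
  seg <- time > (ramp_onset + guard) & time <= vt_time
  if (sum(seg) < 3) stop("too few samples in the linear ramp segment")
  fit <- stats::lm.fit(cbind(1, time[seg]), vo2[seg])
  b0 <- fit$coefficients[1]; b1 <- fit$coefficients[2]
  if (!is.finite(b1) || b1 <= 0)
    stop("ramp VO2 slope is not positive; cannot intersect with baseline")
  t_int <- (base - b0) / b1
  list(mrt = as.numeric(t_int - ramp_onset), baseline_vo2 = base,
       slope = as.numeric(b1), intercept = as.numeric(b0),
       t_intersect = as.numeric(t_int))
}

#' Derive protocol work rates from a ramp test
#'
#' Maps target VO2 levels to work rates by left-shifting the ramp VO2
#' response by the mean response time (so VO2 and work-rate profiles are
#' aligned) and reading the work rate at the first time the shifted VO2
#' reaches each target.
#'
#' @param time,wr,vo2 aligned 1 Hz ramp series.
#' @param mrt mean response time (s) from \code{\link{fit_mrt}}.
#' @param targets named numeric vector of target VO2 levels (ml/min).
#' @return named numeric vector of work rates (W), same names as
#'   \code{targets}.
#' @export
derive_prbs_workrates <- function(time, wr, vo2, mrt, targets) {
  stopifnot(length(time) == length(wr), length(wr) == length(vo2))
  sh <- as.integer(round(mrt))
  n <- length(vo2)
  if (sh < 0) stop("mrt must be non-negative")
  # left shift: aligned VO2 at index i is the response observed mrt later
  vo2s <- if (sh == 0) vo2 else c(vo2[(sh + 1):n], rep(vo2[n], sh))
  out <- vapply(targets, function(tv) {
    if (tv > max(vo2s) || tv < min(vo2s))
      stop("target VO2 ", round(tv), " ml/min is outside the ramp range [",
           round(min(vo2s)), ", ", round(max(vo2s)), "]")
    wr[which(vo2s >= tv)[1]]
  }, numeric(1))
  names(out) <- names(targets)
  out
}

#' Ramp-test analysis
#'
#' Computes VO2peak (20 s moving average), mean response time (double-linear
#' fit), the ventilatory-threshold VO2 (from the session's latent truth
#' channel as a configured fraction of peak, or supplied directly), and the
#' protocol work rates at 90% VT, VT, and the VT-to-peak midpoint (delta-50%).
#'
#' @param session a ramp \code{vo2_session} (see \code{\link{simulate_session}}
#'   or \code{\link{read_session}}).
#' @param vt_vo2 ventilatory-threshold VO2 (ml/min); if \code{NULL}, taken as
#'   \code{vt_frac} of the peak of the latent truth channel when present,
#'   else of the measured VO2peak.
#' @param vt_frac fraction of VO2peak used for the synthetic VT (default 0.65).
#' @param guard see \code{\link{fit_mrt}}.
#' @return object of class \code{ramp_analysis} with fields
#'   \code{vo2peak}, \code{vo2peak_kg}, \code{mrt}, \code{vt_vo2},
#'   \code{wr_90vt}, \code{wr_vt}, \code{wr_d50}.
#' @export
ramp_analysis <- function(session, vt_vo2 = NULL, vt_frac = 0.65, guard = 60) {
  proto <- attr(session, "protocol")
  if (is.null(proto) || proto$kind != "ramp")
    stop("ramp_analysis requires a ramp session")
  vo2 <- session$vo2_mlmin
  time <- session$time_s
  peak <- vo2peak_20s(vo2)
  truth <- session$vo2_truth_mlmin %||% vo2
  if (is.null(vt_vo2)) vt_vo2 <- vt_frac * vo2peak_20s(truth)
  if (vt_vo2 >= peak) stop("VT VO2 must lie below VO2peak")
  onset <- proto$baseline_duration
  vt_time <- time[which(truth >= vt_vo2)[1]]
  if (is.na(vt_time)) stop("VO2 never reaches the VT level during the ramp")
  mrt <- fit_mrt(time, vo2, onset, vt_time, guard = guard)$mrt
  targets <- c(wr_90vt = 0.9 * vt_vo2, wr_vt = vt_vo2,
               wr_d50 = (vt_vo2 + peak) / 2)
  # light centred smoothing so breath noise does not trigger early crossings
  sm <- stats::filter(vo2, rep(1 / 21, 21), sides = 2)
  vo2_sm <- ifelse(is.na(sm), vo2, as.numeric(sm))
  wrs <- derive_prbs_workrates(time, session$wr_w, vo2_sm, max(0, mrt), targets)
  mass <- attr(session, "mass")
  structure(list(vo2peak = peak,
                 vo2peak_kg = if (is.null(mass)) NA_real_ else peak / mass,
                 mrt = mrt, vt_vo2 = vt_vo2,
                 wr_90vt = unname(wrs["wr_90vt"]),
                 wr_vt = unname(wrs["wr_vt"]),
                 wr_d50 = unname(wrs["wr_d50"])),
            class = "ramp_analysis")
}

#' @export
print.ramp_analysis <- function(x, ...) {
  cat(sprintf("Ramp analysis: VO2peak %.0f ml/min", x$vo2peak))
  if (is.finite(x$vo2peak_kg)) cat(sprintf(" (%.1f ml/min/kg)", x$vo2peak_kg))
  cat(sprintf("; MRT %.1f s; VT %.0f ml/min\n", x$mrt, x$vt_vo2))
  cat(sprintf("  work rates: 90%%VT %.0f W, VT %.0f W, d50 %.0f W\n",
              x$wr_90vt, x$wr_vt, x$wr_d50))
  invisible(x)
}
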