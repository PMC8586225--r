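#' Maximal-length pseudorandom binary sequence from a shift register
#'
#' Generates one full period of an m-sequence with a Fibonacci linear
#' feedback shift register (a digital shift register with modulo-2 adder
#' feedback).  The register holds \code{n_stages} bits; each step outputs
#' the last stage, XORs the tapped stages into a new first bit, and shifts.
#' A maximal tap polynomial visits all \eqn{2^n - 1} nonzero states, so the
#' period is \eqn{2^n - 1} and the counts of ones and zeros differ by
#' exactly one.
#'
#' @param n_stages register length n (the default 4 gives the 15-unit
#'   sequence used for the cycling protocols).
#' @param taps stage indices fed into the XOR; \code{c(4, 3)} is a
#'   primitive polynomial for n = 4.
#' @param seed_state initial register bits (0/1), most-significant first;
#'   must not be all zero.
#' @return integer 0/1 vector of length \eqn{2^{n\_stages} - 1}.
#' @examples
#' u <- prbs_sequence()
#' length(u)          # 15
#' abs(sum(u == 1) - sum(u == 0))  # 1
#' @export
prbs_sequence <- function(n_stages = 4, taps = c(4, 3),
                          seed_state = rep(1L, n_stages)) {
  n <- as.integer(n_stages)
  if (n < 2) stop("n_stages must be >= 2")
  taps <- as.integer(taps)
  if (any(taps < 1 | taps > n)) stop("taps must be stage indices in 1..n_stages")
  state <- as.integer(seed_state)
  if (length(state) != n || any(!state %in% c(0L, 1L)))
    stop("seed_state must be a 0/1 vector of length n_stages")
  if (all(state == 0L))
    stop("seed_state must be nonzero: the all-zero register is a fixed point")
  period <- 2L^n - 1L
  out <- integer(period)
  start <- state
  for (i in seq_len(period)) {
    out[i] <- state[n]
    fb <- sum(state[taps]) %% 2L
    state <- c(fb, state[-n])
    if (i < period && all(state == start))
      stop("taps ", paste(taps, collapse = ","),
           " are not maximal for n_stages = ", n,
           ": sequence repeats with period ", i)
  }
  if (!all(state == start))
    stop("taps ", paste(taps, collapse = ","),
         " are not maximal for n_stages = ", n,
         ": period exceeds ", period, " without returning to the seed state")
  out
}

#' Exercise protocol specifications
#'
#' \code{protocol_prbs} describes a pseudorandom binary sequence cycling
#' test: work rate alternates between \code{low_wr} and \code{high_wr} in
#' 15 units of \code{unit_duration} seconds, preceded by a warm-up equal to
#' the final \code{warmup_duration} seconds of one sequence period, then
#' \code{n_repetitions} full periods.  The defaults give the 18.5-minute
#' session: 210 s warm-up + 2 x 450 s.
#'
#' \code{protocol_ramp} describes a ramp-incremental test: \code{baseline_wr}
#' for \code{baseline_duration} seconds, then work rate rising continuously
#' at \code{ramp_rate} W/min until \code{peak_wr}.
#'
#' @param low_wr,high_wr the two PRBS work rates (W); \code{low_wr < high_wr}.
#' @param unit_duration duration of one binary unit (s).
#' @param warmup_duration warm-up length (s), taken from the sequence tail.
#' @param n_repetitions number of full sequence periods after warm-up.
#' @param label protocol label (e.g. "L-M", "L-H", "VT-H", "MAX").
#' @return an object of class \code{protocol_spec}.
#' @export
protocol_prbs <- function(low_wr = 25, high_wr = 100, unit_duration = 30,
                          warmup_duration = 210, n_repetitions = 2,
                          label = "PRBS") {
  if (low_wr >= high_wr) stop("low_wr must be < high_wr")
  if (unit_duration <= 0) stop("unit_duration must be positive")
  if (warmup_duration < 0 || n_repetitions < 0)
    stop("warmup_duration and n_repetitions must be non-negative")
  structure(list(kind = "prbs", low_wr = low_wr, high_wr = high_wr,
                 unit_duration = unit_duration,
                 warmup_duration = warmup_duration,
                 n_repetitions = as.integer(n_repetitions), label = label),
            class = "protocol_spec")
}

#' @rdname protocol_prbs
#' @param baseline_wr ramp baseline work rate (W).
#' @param baseline_duration baseline duration before ramp onset (s).
#' @param ramp_rate ramp slope (W/min).
#' @param peak_wr work rate at which the ramp terminates (W).
#' @export
protocol_ramp <- function(baseline_wr = 25, baseline_duration = 240,
                          ramp_rate = 25, peak_wr = 250, label = "MAX") {
  if (ramp_rate <= 0) stop("ramp_rate must be positive")
  if (peak_wr <= baseline_wr) stop("peak_wr must exceed baseline_wr")
  structure(list(kind = "ramp", baseline_wr = baseline_wr,
                 baseline_duration = baseline_duration,
                 ramp_rate = ramp_rate, peak_wr = peak_wr, label = label),
            class = "protocol_spec")
}

#' @export
print.protocol_spec <- function(x, ...) {
  if (x$kind == "prbs")
    cat(sprintf("PRBS protocol '%s': %g/%g W, %g s units, %g s warm-up, %d repetition(s)\n",
                x$label, x$low_wr, x$high_wr, x$unit_duration,
                x$warmup_duration, x$n_repetitions))
  else
    cat(sprintf("Ramp protocol '%s': %g W x %g s baseline, %g W/min to %g W\n",
                x$label, x$baseline_wr, x$baseline_duration, x$ramp_rate,
                x$peak_wr))
  invisible(x)
}

#' Render a protocol to a 1 Hz work-rate profile
#'
#' For a PRBS spec the binary units (1 -> \code{high_wr}, 0 -> \code{low_wr})
#' are expanded to \code{unit_duration} seconds each; the warm-up segment is
#' the final \code{warmup_duration} seconds of one period, followed by
#' \code{n_repetitions} full periods.  For a ramp spec the profile is the
#' baseline followed by the continuous linear ramp, ending when
#' \code{peak_wr} is reached.
#'
#' @param spec a \code{\link{protocol_prbs}} or \code{\link{protocol_ramp}}.
#' @param units binary sequence for PRBS specs (default
#'   \code{prbs_sequence()}); must have 15 units for the standard protocol.
#' @return numeric vector of work rates (W), one per second, starting at
#'   t = 1 s.
#' @examples
#' length(wr_profile(protocol_prbs()))  # 1110
#' @export
wr_profile <- function(spec, units = prbs_sequence()) {
  stopifnot(inherits(spec, "protocol_spec"))
  if (spec$kind == "ramp") {
    base <- rep(spec$baseline_wr, spec$baseline_duration)
    ramp_dur <- ceiling((spec$peak_wr - spec$baseline_wr) / spec$ramp_rate * 60)
    t <- seq_len(ramp_dur)
    ramp <- pmin(spec$baseline_wr + spec$ramp_rate * t / 60, spec$peak_wr)
    return(c(base, ramp))
  }
  n_units <- length(units)
  period <- n_units * spec$unit_duration
  if (spec$warmup_duration > period)
    stop("warmup_duration exceeds one sequence period (", period, " s)")
  one <- rep(ifelse(units == 1, spec$high_wr, spec$low_wr),
             each = spec$unit_duration)
  warm <- if (spec$warmup_duration > 0)
    one[(period - spec$warmup_duration + 1):period] else numeric(0)
  c(warm, rep(one, times = spec$n_repetitions))
}
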