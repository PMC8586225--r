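#' Sliding median filter for breath-by-breath VO2
#'
#' Replaces each breath's VO2 by the median of the \code{width}-breath
#' window centred on it, correcting spurious outlier breaths.  At the
#' series edges the window shrinks symmetrically (so the first and last
#' breaths are unchanged, the second uses 3 breaths, and so on); breath
#' times and the other columns are untouched.
#'
#' @param breaths data.frame with at least \code{breath_time_s} and
#'   \code{vo2_mlmin} (as returned by \code{\link{sample_breaths}}).
#' @param width odd window width in breaths (default 5).
#' @return the input data.frame with filtered \code{vo2_mlmin}.
#' @export
median_filter_breaths <- function(breaths, width = 5) {
  if (width < 3 || width %% 2 == 0) stop("width must be odd and >= 3")
  n <- nrow(breaths)
  if (n < 1) return(breaths[0, , drop = FALSE])
  x <- breaths$vo2_mlmin
  h <- (width - 1) %/% 2
  out <- x
  for (i in seq_len(n)) {
    hh <- min(h, i - 1L, n - i)
    if (hh > 0) out[i] <- stats::median(x[(i - hh):(i + hh)])
  }
  breaths$vo2_mlmin <- out
  breaths
}

#' Linear interpolation of breath values onto a 1 Hz grid
#'
#' @param times breath time stamps (s), strictly increasing.
#' @param values values at those times.
#' @param t_grid target grid (s); points outside the breath span are
#'   clamped to the nearest breath value.
#' @return numeric vector of length \code{length(t_grid)}.
#' @export
interpolate_1hz <- function(times, values, t_grid) {
  if (length(times) < 2) stop("need at least 2 breaths to interpolate")
  if (is.unsorted(times, strictly = TRUE))
    stop("breath times must be strictly increasing")
  stats::approx(times, values, xout = t_grid, method = "linear", rule = 2)$y
}

#' Time alignment by cross-correlation of two heart-rate signals
#'
#' Finds the integer-second lag of \code{hr_b} relative to \code{hr_a} that
#' maximizes the Pearson correlation of the overlapping samples, scanning
#' lags in \code{-max_lag..max_lag}.  A positive lag means \code{hr_b} is
#' delayed by that many seconds.  Ties are broken toward the smallest
#' absolute lag.
#'
#' @param hr_a,hr_b 1 Hz series (e.g. the chest-strap and textile ECG HR).
#' @param max_lag maximum lag magnitude to scan (s).
#' @return integer lag in seconds.
#' @export
align_by_crosscorr <- function(hr_a, hr_b, max_lag = 30) {
  if (length(hr_a) < 2 * max_lag || length(hr_b) < 2 * max_lag)
    stop("series must be at least twice max_lag long")
  if (stats::sd(hr_a) == 0 || stats::sd(hr_b) == 0)
    stop("cross-correlation undefined for a constant series")
  lags <- order(abs(seq(-max_lag, max_lag)))  # scan small |lag| first
  lags <- seq(-max_lag, max_lag)[lags]
  best <- -Inf; best_lag <- 0L
  n <- min(length(hr_a), length(hr_b))
  for (lag in lags) {
    if (lag >= 0) { a <- hr_a[1:(n - lag)]; b <- hr_b[(1 + lag):n] }
    else          { a <- hr_a[(1 - lag):n]; b <- hr_b[1:(n + lag)] }
    if (stats::sd(a) == 0 || stats::sd(b) == 0) next
    r <- stats::cor(a, b)
    if (r > best + 1e-12) { best <- r; best_lag <- lag }
  }
  as.integer(best_lag)
}

#' Calibrate a ventilation estimate against a reference
#'
#' Per-session ordinary least squares of the reference minute ventilation
#' (turbine) on the garment estimate; returns the calibrated series
#' \code{slope * ve_shirt + intercept} together with the coefficients.
#'
#' @param ve_shirt estimated ventilation series (L/min).
#' @param ve_ref reference ventilation series (L/min), same length.
#' @return list with \code{ve} (calibrated series), \code{slope},
#'   \code{intercept}.
#' @export
calibrate_ve <- function(ve_shirt, ve_ref) {
  if (length(ve_shirt) != length(ve_ref) || length(ve_ref) < 3)
    stop("series must have equal length >= 3")
  if (stats::sd(ve_shirt) == 0)
    stop("cannot calibrate against a constant predictor")
  fit <- stats::lm.fit(cbind(1, ve_shirt), ve_ref)
  b <- fit$coefficients
  list(ve = b[1] + b[2] * ve_shirt, slope = unname(b[2]),
       intercept = unname(b[1]))
}

#' Heart-rate reserve
#'
#' \code{(hr - hr_rest) / (hr_max - hr_rest)}, elementwise and unclipped
#' (values may slightly exceed \code{[0, 1]} with sensor noise).
#'
#' @param hr heart-rate series (bpm).
#' @param hr_rest,hr_max resting and maximal HR (bpm), \code{hr_max > hr_rest}.
#' @return fraction series.
#' @export
compute_hrr <- function(hr, hr_rest, hr_max) {
  if (hr_max <= hr_rest) stop("hr_max must exceed hr_rest")
  (hr - hr_rest) / (hr_max - hr_rest)
}

FEATURES_FULL <- c("wr_w", "ve_lmin", "bf_brpm", "hr_bpm", "hrr_frac")

#' Feature scaler fitted on training sessions
#'
#' Work rate is min-max normalized to [0, 1]; every other feature and the
#' VO2 target are standardized to zero mean and unit variance.  Statistics
#' are computed over the pooled training sessions only, so applying the
#' scaler to held-out sessions may produce values outside [0, 1] (work
#' rate) or with nonzero mean -- that is intended: no test-set leakage.
#'
#' @param train_sessions list of \code{vo2_session} (or data.frames with
#'   the session columns) forming the training pool.
#' @param features feature column names (default the full 5-channel set).
#' @return object of class \code{feature_scaler}.
#' @export
fit_scaler <- function(train_sessions, features = FEATURES_FULL) {
  if (inherits(train_sessions, "data.frame"))
    train_sessions <- list(train_sessions)
  pool <- do.call(rbind, lapply(train_sessions, function(s)
    as.data.frame(s)[, c(features, "vo2_mlmin")]))
  stats_for <- function(col, method) {
    x <- pool[[col]]
    if (method == "minmax01") {
      if (max(x) == min(x)) stop("constant feature '", col,
                                 "' cannot be min-max scaled")
      list(method = "minmax01", min = min(x), max = max(x))
    } else {
      s <- stats::sd(x)
      if (s == 0) stop("constant feature '", col, "' cannot be z-scored")
      list(method = "zscore", mean = mean(x), sd = s)
    }
  }
  st <- lapply(features, function(f)
    stats_for(f, if (f == "wr_w") "minmax01" else "zscore"))
  names(st) <- features
  st$vo2_mlmin <- stats_for("vo2_mlmin", "zscore")
  structure(list(features = features, stats = st), class = "feature_scaler")
}

scale_col <- function(x, s) {
  if (s$method == "minmax01") (x - s$min) / (s$max - s$min)
  else (x - s$mean) / s$sd
}

unscale_col <- function(z, s) {
  if (s$method == "minmax01") z * (s$max - s$min) + s$min
  else z * s$sd + s$mean
}

#' Apply (or invert) a fitted feature scaler
#'
#' @param scaler a \code{\link{fit_scaler}} result.
#' @param session a session data.frame.
#' @return data.frame with scaled feature columns and, when present, a
#'   scaled \code{vo2_mlmin} target column.
#' @export
apply_scaler <- function(scaler, session) {
  stopifnot(inherits(scaler, "feature_scaler"))
  df <- as.data.frame(session)
  for (f in scaler$features) {
    if (is.null(df[[f]])) stop("session lacks feature column '", f, "'")
    df[[f]] <- scale_col(df[[f]], scaler$stats[[f]])
  }
  if (!is.null(df$vo2_mlmin))
    df$vo2_mlmin <- scale_col(df$vo2_mlmin, scaler$stats$vo2_mlmin)
  df
}

#' @rdname apply_scaler
#' @param z standardized VO2 values (model output scale).
#' @return \code{unscale_vo2}: VO2 in ml/min.
#' @export
unscale_vo2 <- function(scaler, z) unscale_col(z, scaler$stats$vo2_mlmin)

#' Sliding-window extraction
#'
#' Extracts every length-\code{T} window at stride 1 s from a (scaled)
#' session: the first window spans seconds \code{1..T} and targets time
#' \code{T}, the last targets the final second, giving
#' \code{N = L - T + 1} windows.  No window contains any sample after its
#' target time (strict causality), and no prediction target exists for
#' \code{t < T} (the cold start).
#'
#' @param session a scaled session data.frame (see \code{\link{apply_scaler}}).
#' @param T window length in seconds (the model receptive field).
#' @param features feature columns, in channel order.
#' @return object of class \code{window_set}: list with \code{x} (array
#'   \code{N x T x F}), \code{y} (length-N standardized targets, when the
#'   session has a VO2 column), and \code{target_time} (length-N seconds).
#' @export
extract_windows <- function(session, T, features = FEATURES_FULL) {
  df <- as.data.frame(session)
  L <- nrow(df)
  if (L < T) {
    warning("session (", L, " s) shorter than window length ", T,
            "; no windows extracted")
    return(structure(list(
      x = array(0, c(0, T, length(features))), y = numeric(0),
      target_time = numeric(0)), class = "window_set"))
  }
  N <- L - T + 1L
  feat <- as.matrix(df[, features, drop = FALSE])  # L x F
  x <- array(0, c(N, T, length(features)))
  for (j in seq_len(T)) x[, j, ] <- feat[j:(j + N - 1L), , drop = FALSE]
  y <- if (!is.null(df$vo2_mlmin)) df$vo2_mlmin[T:L] else numeric(0)
  structure(list(x = x, y = y, target_time = df$time_s[T:L] %||% (T:L)),
            class = "window_set")
}
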