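#' Fit a temporal convolutional VO2 prediction model
#'
#' Trains the causal dilated-convolution network on 1 Hz exercise sessions.
#' Features are scaled with statistics from the training sessions only
#' (z-scores; work rate min-max to [0, 1]); the VO2 target is z-scored for
#' the mean-squared-error loss and predictions are inverse-transformed back
#' to ml/min.  Length-RF windows are extracted at stride 1 s and optimized
#' with Adam in shuffled minibatches.  After each epoch the validation MSE
#' (standardized units) is computed on the held-out sessions and the
#' weights of the epoch with the lowest validation loss are kept.
#'
#' @param train_sessions list of training \code{vo2_session} objects (a
#'   single session is accepted).
#' @param val_sessions optional list of validation sessions (held-out
#'   participants); without them the final epoch's weights are kept.
#' @param config a \code{\link{tcn_config}}.
#' @param epochs maximum training epochs (0 returns initialized weights).
#' @param batch_size minibatch size (default 32).
#' @param lr Adam learning rate (default 0.0005).
#' @param seed RNG seed for weight initialization, shuffling, and dropout.
#' @param features feature columns used as input channels; must have
#'   \code{length(features) == config$in_features}.
#' @param scaler optional pre-fitted \code{\link{fit_scaler}}; fitted on
#'   \code{train_sessions} when \code{NULL}.
#' @param verbose print per-epoch losses.
#' @return an object of class \code{tcn_vo2} with the fitted parameters,
#'   scaler, per-epoch training log, and best epoch.
#' @seealso \code{\link{predict.tcn_vo2}}, \code{\link{grid_search_tcn}}
#' @export
tcn_vo2 <- function(train_sessions, val_sessions = NULL,
                    config = tcn_config(), epochs = 100, batch_size = 32,
                    lr = 5e-4, seed = 1, features = NULL, scaler = NULL,
                    verbose = FALSE) {
  if (inherits(train_sessions, "data.frame")) train_sessions <- list(train_sessions)
  if (inherits(val_sessions, "data.frame")) val_sessions <- list(val_sessions)
  features <- features %||%
    (if (config$in_features == length(FEATURES_FULL)) FEATURES_FULL
     else if (config$in_features == 1L) "hr_bpm"
     else stop("supply 'features' matching config$in_features"))
  if (length(features) != config$in_features)
    stop("length(features) must equal config$in_features")
  scaler <- scaler %||% fit_scaler(train_sessions, features)
  RF <- config$receptive_field
  ws <- lapply(train_sessions, function(s)
    extract_windows(apply_scaler(scaler, s), RF, features))
  ws <- ws[vapply(ws, function(w) length(w$y) > 0, TRUE)]
  if (length(ws) == 0) stop("no training session is at least RF seconds long")
  x <- do.call(abind1, lapply(ws, `[[`, "x"))
  y <- unlist(lapply(ws, `[[`, "y"))
  N <- dim(x)[1]
  x <- aperm(x, c(3, 2, 1))  # (F, T, N): minibatch slices need no transpose
  val_scaled <- lapply(val_sessions %||% list(), function(s)
    apply_scaler(scaler, s))

  params <- init_tcn_params(config, seed = seed)
  log <- data.frame(epoch = integer(0), train_mse = numeric(0),
                    val_mse = numeric(0))
  best <- list(params = params, val = Inf, epoch = 0L)
  if (epochs > 0) with_seed(seed + 1L, {
    state <- adam_init(params)
    for (ep in seq_len(epochs)) {
      idx <- sample.int(N)
      tr_loss <- 0; nb <- 0L
      for (start in seq(1, N, by = batch_size)) {
        bi <- idx[start:min(start + batch_size - 1L, N)]
        X <- x[, , bi, drop = FALSE]  # (F, T, B)
        fw <- tcn_forward(params, config, X, train = TRUE)
        err <- fw$yhat[RF, ] - y[bi]
        loss <- mean(err^2)
        if (!is.finite(loss))
          stop("training loss became non-finite at epoch ", ep,
               " (exploding gradients; reduce lr)")
        dyhat <- matrix(0, RF, length(bi))
        dyhat[RF, ] <- 2 * err / length(bi)
        grads <- tcn_backward(params, config, fw$cache, dyhat)
        upd <- adam_step(params, grads, state, lr)
        params <- upd$params; state <- upd$state
        tr_loss <- tr_loss + loss; nb <- nb + 1L
      }
      vl <- if (length(val_scaled)) val_mse_scaled(params, config,
                                                   val_scaled, features)
            else NA_real_
      log[ep, ] <- list(ep, tr_loss / nb, vl)
      if (verbose)
        message(sprintf("epoch %3d  train %.5f  val %s", ep, tr_loss / nb,
                        ifelse(is.na(vl), "-", sprintf("%.5f", vl))))
      if (!is.na(vl) && vl < best$val)
        best <- list(params = params, val = vl, epoch = ep)
    }
    if (is.infinite(best$val))  # no validation set: keep final weights
      best <- list(params = params, val = NA_real_, epoch = epochs)
  })
  structure(list(config = config, params = best$params, scaler = scaler,
                 features = features, log = log, best_epoch = best$epoch,
                 best_val_mse = best$val, seed = seed,
                 hyper = list(epochs = epochs, batch_size = batch_size,
                              lr = lr),
                 train_sessions = train_sessions, call = match.call()),
            class = "tcn_vo2")
}

# bind window arrays along the first (window) dimension
abind1 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  out <- array(0, c(sum(vapply(parts, function(p) dim(p)[1], 1L)), d[2], d[3]))
  at <- 0L
  for (p in parts) {
    n <- dim(p)[1]
    if (n > 0) out[(at + 1):(at + n), , ] <- p
    at <- at + n
  }
  out
}

# standardized predictions for t >= RF over one scaled session (sequence mode)
predict_scaled <- function(params, config, scaled_df, features) {
  L <- nrow(scaled_df)
  RF <- config$receptive_field
  if (L < RF) return(numeric(0))
  X <- array(t(as.matrix(scaled_df[, features, drop = FALSE])),
             c(length(features), L, 1))
  fw <- tcn_forward(params, config, X, train = FALSE, keep_cache = FALSE)
  fw$yhat[RF:L, 1]
}

val_mse_scaled <- function(params, config, val_scaled, features) {
  se <- 0; n <- 0L
  RF <- config$receptive_field
  for (df in val_scaled) {
    if (nrow(df) < RF) next
    p <- predict_scaled(params, config, df, features)
    err <- p - df$vo2_mlmin[RF:nrow(df)]
    se <- se + sum(err^2); n <- n + length(err)
  }
  if (n == 0) NA_real_ else se / n
}

#' Predict second-by-second VO2 for a session
#'
#' Applies the fitted network causally along the session: the prediction at
#' time t uses only samples in \code{[t - RF + 1, t]}.  No prediction is
#' emitted for the cold-start prefix \code{t < RF}.  Output is
#' inverse-transformed to ml/min.
#'
#' @param object a fitted \code{\link{tcn_vo2}} model.
#' @param newdata a \code{vo2_session} (or data.frame with the feature
#'   columns); defaults to the first training session.
#' @param ... unused.
#' @return data.frame with \code{time_s} and \code{vo2_pred_mlmin}.
#' @export
predict.tcn_vo2 <- function(object, newdata = NULL, ...) {
  sess <- newdata %||% object$train_sessions[[1]]
  RF <- object$config$receptive_field
  if (nrow(sess) < RF) {
    warning("session (", nrow(sess), " s) shorter than the receptive field (",
            RF, " s); no predictions")
    return(data.frame(time_s = numeric(0), vo2_pred_mlmin = numeric(0)))
  }
  df <- apply_scaler(object$scaler, sess)
  z <- predict_scaled(object$params, object$config, df, object$features)
  data.frame(time_s = df$time_s[RF:nrow(df)],
             vo2_pred_mlmin = unscale_vo2(object$scaler, z))
}

#' @export
print.tcn_vo2 <- function(x, ...) {
  cat("Temporal convolutional VO2 model\n")
  cat(sprintf("  features: %s\n", paste(x$features, collapse = ", ")))
  cat(sprintf("  filters %d, kernel %d s, %d dilations -> receptive field %d s\n",
              x$config$filters, x$config$kernel_size, x$config$n_dilations,
              x$config$receptive_field))
  cat(sprintf("  trainable parameters: %d\n", count_parameters(x$config)$total))
  if (nrow(x$log))
    cat(sprintf("  trained %d epoch(s); best epoch %d (val MSE %s)\n",
                nrow(x$log), x$best_epoch,
                ifelse(is.na(x$best_val_mse), "n/a",
                       sprintf("%.5f", x$best_val_mse))))
  else cat("  untrained (initialized weights)\n")
  invisible(x)
}

#' @export
summary.tcn_vo2 <- function(object, ...) {
  structure(list(model = object,
                 params = count_parameters(object$config),
                 log = object$log), class = "summary.tcn_vo2")
}

#' @export
print.summary.tcn_vo2 <- function(x, ...) {
  print(x$model)
  cat("\nParameter breakdown:\n")
  print(x$params$breakdown, row.names = FALSE)
  if (nrow(x$log)) {
    cat("\nTraining log (last 5 epochs):\n")
    print(utils::tail(x$log, 5), row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.tcn_vo2 <- function(object, ...) {
  unlist(object$params)
}

#' @export
residuals.tcn_vo2 <- function(object, sessions = NULL, ...) {
  sessions <- sessions %||% object$train_sessions
  if (inherits(sessions, "data.frame")) sessions <- list(sessions)
  RF <- object$config$receptive_field
  unlist(lapply(sessions, function(s) {
    if (nrow(s) < RF) return(numeric(0))
    predict(object, s)$vo2_pred_mlmin - s$vo2_mlmin[RF:nrow(s)]
  }))
}

#' @export
plot.tcn_vo2 <- function(x, newdata = NULL, which = c("fit", "loss"), ...) {
  which <- match.arg(which)
  if (which == "loss") {
    if (!nrow(x$log)) stop("model has no training log")
    graphics::matplot(x$log$epoch, cbind(x$log$train_mse, x$log$val_mse),
                      type = "l", lty = 1, col = c("grey40", "firebrick"),
                      xlab = "epoch", ylab = "MSE (standardized)", ...)
    graphics::legend("topright", c("train", "validation"), lty = 1,
                     col = c("grey40", "firebrick"), bty = "n")
    return(invisible(x))
  }
  sess <- newdata %||% x$train_sessions[[1]]
  pr <- predict(x, sess)
  graphics::plot(sess$time_s, sess$vo2_mlmin, type = "l", col = "grey60",
                 xlab = "time (s)", ylab = "VO2 (ml/min)", ...)
  graphics::lines(pr$time_s, pr$vo2_pred_mlmin, col = "firebrick")
  graphics::legend("topleft", c("measured", "predicted"), lty = 1,
                   col = c("grey60", "firebrick"), bty = "n")
  invisible(x)
}
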