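# Forward / backward engine for the causal dilated convolution network.
#
# Activations are kept as f x (T*B) matrices whose columns are (time, batch)
# pairs with time fastest, i.e. column t + (b-1)*T.  A causal shift by s
# seconds is then pure column-index arithmetic within each batch block:
# output column c draws on input column c - s whenever its time exceeds s,
# and on zero-padding otherwise.  Layer normalization acts per column, so
# the convolutions are the only operations that mix time steps and the
# output at time t depends on inputs in [t - RF + 1, t] only.

LN_EPS <- 1e-5

conv_causal_fwd <- function(Xm, W, bias, d, tvec) {
  f <- dim(W)[1]; C <- dim(W)[2]; k <- dim(W)[3]
  Zm <- matrix(bias, f, ncol(Xm))
  for (j in seq_len(k)) {
    s <- (k - j) * d
    if (s == 0) {
      Zm <- Zm + matrix(W[, , j], f, C) %*% Xm
    } else {
      cols <- which(tvec > s)
      if (!length(cols)) next
      Zm[, cols] <- Zm[, cols] +
        matrix(W[, , j], f, C) %*% Xm[, cols - s, drop = FALSE]
    }
  }
  Zm
}

conv_causal_bwd <- function(Xm, W, d, dZm, tvec) {
  f <- dim(W)[1]; C <- dim(W)[2]; k <- dim(W)[3]
  dW <- array(0, dim(W))
  dX <- matrix(0, C, ncol(Xm))
  for (j in seq_len(k)) {
    s <- (k - j) * d
    if (s == 0) {
      dW[, , j] <- dZm %*% t(Xm)
      dX <- dX + t(matrix(W[, , j], f, C)) %*% dZm
    } else {
      cols <- which(tvec > s)
      if (!length(cols)) next
      dZs <- dZm[, cols, drop = FALSE]
      dW[, , j] <- dZs %*% t(Xm[, cols - s, drop = FALSE])
      dX[, cols - s] <- dX[, cols - s, drop = FALSE] +
        t(matrix(W[, , j], f, C)) %*% dZs
    }
  }
  list(dX = dX, dW = dW, db = rowSums(dZm))
}

# layer norm over channels (rows) within each column
layernorm_fwd <- function(Zm, g, beta) {
  f <- nrow(Zm)
  mu <- colMeans(Zm)
  cen <- Zm - rep(mu, each = f)
  inv <- 1 / sqrt(colMeans(cen * cen) + LN_EPS)
  Zh <- cen * rep(inv, each = f)
  list(Y = Zh * g + beta, Zh = Zh, inv = inv)
}

layernorm_bwd <- function(dYm, cache, g) {
  f <- length(g)
  Zh <- cache$Zh
  dZh <- dYm * g
  m1 <- colMeans(dZh)
  m2 <- colMeans(dZh * Zh)
  list(dZ = (dZh - rep(m1, each = f) - Zh * rep(m2, each = f)) *
         rep(cache$inv, each = f),
       dg = rowSums(dYm * Zh), dbeta = rowSums(dYm))
}

# Full forward pass.  X: array (in_features, T, B).  Returns yhat (T x B
# matrix of standardized predictions at every time step) and, when
# keep_cache, the intermediates for the backward pass.  Dropout masks are
# drawn from the current RNG stream when train = TRUE.
tcn_forward <- function(params, config, X, train = FALSE, keep_cache = train) {
  f <- config$filters
  Tn <- dim(X)[2]; B <- dim(X)[3]
  tvec <- rep.int(seq_len(Tn), B)
  p <- if (train) config$dropout else 0
  cache <- if (keep_cache) list(blocks = list(), Tn = Tn, B = B, tvec = tvec)
           else NULL
  cur <- matrix(X, dim(X)[1])
  li <- 0L
  for (b in seq_along(config$blocks)) {
    X0 <- cur
    lcache <- list()
    for (d in config$blocks[[b]]) {
      li <- li + 1L
      Zm <- conv_causal_fwd(cur, params[[sprintf("conv%d.W", li)]],
                            params[[sprintf("conv%d.b", li)]], d, tvec)
      ln <- layernorm_fwd(Zm, params[[sprintf("conv%d.g", li)]],
                          params[[sprintf("conv%d.beta", li)]])
      pos <- ln$Y > 0
      A <- ln$Y * pos
      if (p > 0) {
        mask <- matrix((stats::runif(length(A)) >= p) / (1 - p), nrow(A))
        D <- A * mask
      } else {
        mask <- NULL
        D <- A
      }
      if (keep_cache)
        lcache[[length(lcache) + 1L]] <-
          list(li = li, d = d, X_in = cur, ln = ln, pos = pos, mask = mask)
      cur <- D
    }
    if (b == 1L && !is.null(params[["skip.W"]])) {
      cur <- cur + (params[["skip.W"]] %*% X0 + params[["skip.b"]])
      skip_kind <- "conv"
    } else {
      cur <- cur + X0
      skip_kind <- "identity"
    }
    if (keep_cache)
      cache$blocks[[b]] <- list(layers = lcache, X0 = X0, skip = skip_kind)
  }
  yhat <- matrix(params[["dense.w"]] %*% cur + params[["dense.b"]], Tn, B)
  if (keep_cache) cache$H <- cur
  list(yhat = yhat, cache = cache)
}

# Backward pass from d(loss)/d(yhat); returns gradient list parallel to params.
tcn_backward <- function(params, config, cache, dyhat) {
  f <- config$filters
  tvec <- cache$tvec
  dv <- as.vector(dyhat)
  grads <- list()
  grads[["dense.w"]] <- as.vector(cache$H %*% dv)
  grads[["dense.b"]] <- sum(dv)
  dcur <- params[["dense.w"]] %o% dv
  for (b in rev(seq_along(cache$blocks))) {
    blk <- cache$blocks[[b]]
    if (blk$skip == "conv") {
      grads[["skip.W"]] <- dcur %*% t(blk$X0)
      grads[["skip.b"]] <- rowSums(dcur)
      dX0 <- t(params[["skip.W"]]) %*% dcur
    } else {
      dX0 <- dcur
    }
    dD <- dcur
    for (l in rev(seq_along(blk$layers))) {
      lc <- blk$layers[[l]]
      dA <- if (is.null(lc$mask)) dD else dD * lc$mask
      dY <- dA * lc$pos
      lnb <- layernorm_bwd(dY, lc$ln, params[[sprintf("conv%d.g", lc$li)]])
      grads[[sprintf("conv%d.g", lc$li)]] <- lnb$dg
      grads[[sprintf("conv%d.beta", lc$li)]] <- lnb$dbeta
      cb <- conv_causal_bwd(lc$X_in, params[[sprintf("conv%d.W", lc$li)]],
                            lc$d, lnb$dZ, tvec)
      grads[[sprintf("conv%d.W", lc$li)]] <- cb$dW
      grads[[sprintf("conv%d.b", lc$li)]] <- cb$db
      dD <- cb$dX
    }
    dcur <- dX0 + dD
  }
  grads
}

adam_init <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}
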