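#' Receptive field of a causal dilated convolution stack
#'
#' For a stack of \code{n_dilations} causal convolution layers with kernel
#' size \code{k} and dilation factors doubling from 1 (1, 2, 4, ...,
#' \eqn{2^{N-1}}), the number of past seconds (at 1 Hz) that can influence
#' the output at the current time is
#' \deqn{RF = 1 + (k - 1)(2^N - 1).}
#'
#' @param kernel_size convolution kernel size \eqn{k} (seconds at 1 Hz).
#' @param n_dilations number of dilated convolution layers \eqn{N}.
#' @return integer receptive field in seconds.
#' @examples
#' receptive_field(8, 5)  # 218
#' receptive_field(7, 5)  # 187
#' @export
receptive_field <- function(kernel_size, n_dilations) {
  stopifnot_scalar(kernel_size, "kernel_size")
  stopifnot_scalar(n_dilations, "n_dilations")
  if (kernel_size < 1 || n_dilations < 1)
    stop("kernel_size and n_dilations must both be >= 1")
  as.integer(1 + (kernel_size - 1) * (2^n_dilations - 1))
}

#' Residual-block plan for a given dilation depth
#'
#' Dilation factors 1, 2, ..., 2^(N-1) are grouped into residual blocks of
#' successive pairs; when N is odd the first three dilations form a single
#' block (a three-layer residual function), so every block has at least two
#' convolution layers except the trivial N = 1 case.
#'
#' @param n_dilations number of dilated convolution layers N (>= 1).
#' @return list of integer vectors, one per residual block, giving the
#'   dilation factors of its convolution layers in order.
#' @examples
#' plan_blocks(5)  # list(c(1, 2, 4), c(8, 16))
#' @export
plan_blocks <- function(n_dilations) {
  stopifnot_scalar(n_dilations, "n_dilations")
  N <- as.integer(n_dilations)
  if (N < 1) stop("n_dilations must be >= 1")
  d <- 2^(0:(N - 1))
  if (N <= 1) return(list(d))
  if (N %% 2 == 1) {
    starts <- if (N > 3L) c(1L, seq(4L, N, by = 2L)) else 1L
    sizes  <- c(3L, rep(2L, (N - 3L) %/% 2L))
  } else {
    starts <- seq(1L, N, by = 2L)
    sizes  <- rep(2L, N %/% 2L)
  }
  mapply(function(s, n) d[s:(s + n - 1L)], starts, sizes, SIMPLIFY = FALSE)
}

#' Temporal convolutional network configuration
#'
#' Bundles the architecture hyperparameters and derives the residual-block
#' plan and receptive field.  The default feature set is the five-channel
#' input (work rate, minute ventilation, breathing frequency, heart rate,
#' heart-rate reserve); a heart-rate-only model uses \code{in_features = 1}.
#'
#' @param in_features number of input channels.
#' @param filters number of convolution filters per layer.
#' @param kernel_size convolution kernel size in seconds.
#' @param n_dilations number of dilated convolution layers.
#' @param dropout dropout rate applied after each activation during training.
#' @return an object of class \code{tcn_config}.
#' @examples
#' cfg <- tcn_config(5, 24, 8, 5)
#' cfg$receptive_field  # 218
#' @export
tcn_config <- function(in_features = 5, filters = 24, kernel_size = 8,
                       n_dilations = 5, dropout = 0.2) {
  stopifnot_scalar(in_features, "in_features")
  stopifnot_scalar(filters, "filters")
  stopifnot_scalar(dropout, "dropout")
  if (in_features < 1 || filters < 1) stop("in_features and filters must be >= 1")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  structure(list(
    in_features     = as.integer(in_features),
    filters         = as.integer(filters),
    kernel_size     = as.integer(kernel_size),
    n_dilations     = as.integer(n_dilations),
    dropout         = dropout,
    blocks          = plan_blocks(n_dilations),
    receptive_field = receptive_field(kernel_size, n_dilations)
  ), class = "tcn_config")
}

#' @export
print.tcn_config <- function(x, ...) {
  cat("TCN configuration\n")
  cat("  input channels :", x$in_features, "\n")
  cat("  filters        :", x$filters, "\n")
  cat("  kernel size    :", x$kernel_size, "s\n")
  cat("  dilations      :", x$n_dilations,
      sprintf("(%d residual block%s: %s)\n", length(x$blocks),
              if (length(x$blocks) > 1) "s" else "",
              paste(vapply(x$blocks, function(b) paste(b, collapse = ","), ""),
                    collapse = " | ")))
  cat("  receptive field:", x$receptive_field, "s\n")
  cat("  parameters     :", count_parameters(x)$total, "\n")
  invisible(x)
}

#' Trainable-parameter count of a TCN configuration
#'
#' Per convolution layer: a biased dilated convolution (k * c_in * f + f
#' weights) followed by layer normalization over the channel dimension
#' (gain + offset, 2f).  The skip path of the first residual block is a
#' biased 1x1 convolution (c_in * f + f) because the channel count changes
#' there; later blocks use identity skips.  The output head is a biased
#' dense layer f -> 1 applied to the spliced final time step.
#'
#' @param config a \code{\link{tcn_config}}.
#' @return object of class \code{tcn_summary}: per-layer breakdown
#'   (data.frame with columns layer, parameters) and \code{total}.
#' @examples
#' count_parameters(tcn_config(5, 24, 8, 5))$total  # 19921
#' @export
count_parameters <- function(config) {
  stopifnot(inherits(config, "tcn_config"))
  f <- config$filters; k <- config$kernel_size
  layer <- character(0); n <- integer(0)
  c_in <- config$in_features
  for (b in seq_along(config$blocks)) {
    for (d in config$blocks[[b]]) {
      layer <- c(layer, sprintf("block%d conv d=%d", b, d),
                 sprintf("block%d layernorm", b))
      n <- c(n, k * c_in * f + f, 2L * f)
      c_in <- f
    }
    if (b == 1L && config$in_features != f) {
      layer <- c(layer, "block1 skip 1x1 conv")
      n <- c(n, config$in_features * f + f)
    }
  }
  layer <- c(layer, "dense head")
  n <- c(n, f + 1L)
  structure(list(breakdown = data.frame(layer = layer, parameters = as.integer(n)),
                 total = as.integer(sum(n)), config = config),
            class = "tcn_summary")
}

#' @export
print.tcn_summary <- function(x, ...) {
  print(x$breakdown, row.names = FALSE)
  cat("total trainable parameters:", x$total, "\n")
  invisible(x)
}

# Uniform fan-in initialization: U(-1/sqrt(fan_in), 1/sqrt(fan_in)) for conv
# and dense weights/biases; layer-norm gain 1, offset 0.  Returns the flat
# parameter list the engine consumes.
init_tcn_params <- function(config, seed = NULL) {
  f <- config$filters; k <- config$kernel_size
  runifw <- function(n, fan_in) {
    lim <- 1 / sqrt(fan_in)
    stats::runif(n, -lim, lim)
  }
  build <- function() {
    params <- list()
    c_in <- config$in_features
    li <- 0L
    for (b in seq_along(config$blocks)) {
      for (d in config$blocks[[b]]) {
        li <- li + 1L
        fan <- c_in * k
        params[[sprintf("conv%d.W", li)]] <- array(runifw(f * c_in * k, fan),
                                                   dim = c(f, c_in, k))
        params[[sprintf("conv%d.b", li)]]  <- runifw(f, fan)
        params[[sprintf("conv%d.g", li)]]  <- rep(1, f)
        params[[sprintf("conv%d.beta", li)]] <- rep(0, f)
        c_in <- f
      }
      if (b == 1L && config$in_features != f) {
        fan <- config$in_features
        params[["skip.W"]] <- matrix(runifw(f * config$in_features, fan),
                                     f, config$in_features)
        params[["skip.b"]] <- runifw(f, fan)
      }
    }
    params[["dense.w"]] <- runifw(f, f)
    params[["dense.b"]] <- runifw(1, f)
    params
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

# number of scalars across a parameter list
n_params <- function(params) sum(vapply(params, length, 1L))
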