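#' Participant-level train/validation/test split
#'
#' Assigns whole participants (never individual sessions) to exactly one of
#' the train, validation, or test partitions, so no participant's data can
#' leak across partitions.  Fractions apply to participant counts and are
#' rounded; every partition with a positive fraction receives at least one
#' participant.
#'
#' @param cohort a \code{vo2_cohort} or a list of \code{vo2_session}.
#' @param fractions named numeric (train, val, test) summing to 1.
#' @param seed RNG seed for the participant shuffle.
#' @return object of class \code{split_spec}: list with participant-id
#'   vectors \code{train}, \code{val}, \code{test} and a \code{map}
#'   data.frame.
#' @export
split_cohort <- function(cohort, fractions = c(train = 0.5, val = 0.25,
                                               test = 0.25), seed = 1) {
  sessions <- if (inherits(cohort, "vo2_cohort")) cohort$sessions else cohort
  ids <- unique(vapply(sessions, function(s) attr(s, "participant_id"), ""))
  if (length(ids) < 3) stop("need at least 3 participants to split")
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  ord <- with_seed(seed, sample(ids))
  n <- length(ord)
  n_train <- max(1L, round(fractions[["train"]] * n))
  n_val <- max(1L, round(fractions[["val"]] * n))
  if (n_train + n_val >= n) n_train <- n - n_val - 1L
  parts <- list(train = ord[seq_len(n_train)],
                val = ord[n_train + seq_len(n_val)],
                test = ord[(n_train + n_val + 1L):n])
  stopifnot(length(Reduce(intersect, parts)) == 0)
  structure(c(parts, list(
    map = data.frame(participant_id = unlist(parts),
                     partition = rep(names(parts), lengths(parts))))),
    class = "split_spec")
}

#' Select a cohort's sessions by partition
#'
#' @param cohort a \code{vo2_cohort} or session list.
#' @param split a \code{\link{split_cohort}} result.
#' @param partition one of "train", "val", "test".
#' @param protocols optional protocol labels to keep (e.g. exclude "MAX").
#' @return list of sessions.
#' @export
partition_sessions <- function(cohort, split, partition, protocols = NULL) {
  sessions <- if (inherits(cohort, "vo2_cohort")) cohort$sessions else cohort
  keep <- vapply(sessions, function(s) {
    ok <- attr(s, "participant_id") %in% split[[partition]]
    if (!is.null(protocols))
      ok <- ok && attr(s, "protocol")$label %in% protocols
    ok
  }, TRUE)
  sessions[keep]
}

#' Hyperparameter grid of the architecture search
#'
#' The full search space: filters in \{2, 4, 8, 16, 24\}, kernel size 1-8,
#' dilation depth 1-5 (200 configurations).
#'
#' @return data.frame with columns \code{filters}, \code{kernel_size},
#'   \code{n_dilations}.
#' @export
tcn_grid <- function() {
  expand.grid(filters = c(2, 4, 8, 16, 24), kernel_size = 1:8,
              n_dilations = 1:5, KEEP.OUT.ATTRS = FALSE)
}

#' Grid search over TCN hyperparameters
#'
#' Trains one model per grid row and ranks configurations by their best
#' validation MSE (standardized units).  The full grid is expensive; pass a
#' subset for desk-scale runs.
#'
#' @param train_sessions,val_sessions session lists (see \code{\link{tcn_vo2}}).
#' @param grid data.frame of configurations (default \code{\link{tcn_grid}()}).
#' @param epochs,lr,batch_size training settings passed to \code{\link{tcn_vo2}}.
#' @param seed base RNG seed (each config trains with the same seed so the
#'   ranking is reproducible).
#' @param in_features,dropout fixed architecture settings.
#' @param verbose print progress.
#' @return data.frame: the grid plus \code{receptive_field}, \code{n_params},
#'   \code{val_mse}, \code{best_epoch}, sorted by \code{val_mse}.
#' @export
grid_search_tcn <- function(train_sessions, val_sessions, grid = tcn_grid(),
                            epochs = 20, lr = 5e-4, batch_size = 32,
                            seed = 1, in_features = 5, dropout = 0.2,
                            verbose = FALSE) {
  if (nrow(grid) == 0) stop("grid must be nonempty")
  res <- grid
  res$receptive_field <- NA_integer_
  res$n_params <- NA_integer_
  res$val_mse <- NA_real_
  res$best_epoch <- NA_integer_
  for (i in seq_len(nrow(grid))) {
    cfg <- tcn_config(in_features, grid$filters[i], grid$kernel_size[i],
                      grid$n_dilations[i], dropout)
    fit <- tcn_vo2(train_sessions, val_sessions, cfg, epochs = epochs,
                   batch_size = batch_size, lr = lr, seed = seed)
    res$receptive_field[i] <- cfg$receptive_field
    res$n_params[i] <- count_parameters(cfg)$total
    res$val_mse[i] <- fit$best_val_mse
    res$best_epoch[i] <- fit$best_epoch
    if (verbose)
      message(sprintf("[%d/%d] f=%d k=%d N=%d  val MSE %.5f", i, nrow(grid),
                      cfg$filters, cfg$kernel_size, cfg$n_dilations,
                      res$val_mse[i]))
  }
  res[order(res$val_mse), ]
}

#' Filter grid-search results to within a percentage of the minimum loss
#'
#' @param results a \code{\link{grid_search_tcn}} result.
#' @param pct tolerance: keep configurations with
#'   \code{val_mse <= (1 + pct/100) * min(val_mse)}.
#' @return filtered data.frame.
#' @export
within_pct_of_min <- function(results, pct = 5) {
  results[results$val_mse <= (1 + pct / 100) * min(results$val_mse), ,
          drop = FALSE]
}

#' Seconds lying in an off-transient
#'
#' Marks every second within \code{horizon} seconds after a downward
#' work-rate step -- the recovery phases in which instantaneous
#' (no-history) predictors systematically overestimate VO2 because HR and
#' ventilation recover more slowly than VO2.
#'
#' @param wr 1 Hz work-rate profile.
#' @param horizon look-back horizon in seconds (default 45, longer than the
#'   typical VO2 time constant).
#' @return logical vector, same length as \code{wr}.
#' @export
off_transient_mask <- function(wr, horizon = 45) {
  n <- length(wr)
  drops <- which(diff(wr) < 0) + 1L
  mask <- rep(FALSE, n)
  for (d in drops) mask[d:min(n, d + horizon - 1L)] <- TRUE
  mask
}
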