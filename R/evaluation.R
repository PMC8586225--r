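#' Bland-Altman agreement analysis with repeated measures
#'
#' Assesses agreement between predicted and measured VO2.  With repeated
#' observations per subject the ordinary SD of the differences understates
#' the population limits of agreement, so the SD used here combines the
#' within-subject variance with the between-subject variance of the
#' differences estimated by one-way random-effects ANOVA (differences
#' grouped by subject).  For unbalanced designs the between-subject
#' component uses the standard average-cluster-size correction
#' \eqn{n_0 = (N - \sum n_i^2 / N) / (K - 1)}.  Limits of agreement are
#' \code{bias +/- 1.96 * sd}; proportional bias is the OLS slope of the
#' differences on the pair means with its 95% CI.
#'
#' @param pred,true paired measurements (e.g. predicted and measured VO2,
#'   ml/min).
#' @param subject subject identifier for each pair; with a single subject
#'   (or \code{method = "standard"}) the ordinary Bland-Altman SD is used.
#' @param method "repeated_measures" (default) or "standard".
#' @return object of class \code{agreement_report}: \code{bias},
#'   \code{loa_low}, \code{loa_high}, \code{sd_used},
#'   \code{proportional_slope}, \code{proportional_ci}, \code{n_points},
#'   \code{n_subjects}, \code{method}.
#' @export
bland_altman_rm <- function(pred, true, subject = NULL,
                            method = c("repeated_measures", "standard")) {
  method <- match.arg(method)
  stopifnot(length(pred) == length(true))
  d <- pred - true
  m <- (pred + true) / 2
  N <- length(d)
  if (is.null(subject)) subject <- rep("s1", N)
  subject <- as.factor(as.character(subject))
  K <- nlevels(subject)
  if (method == "repeated_measures" && K < 2) {
    warning("single subject: falling back to standard Bland-Altman")
    method <- "standard"
  }
  if (method == "standard") {
    sd_used <- stats::sd(d)
  } else {
    ni <- as.numeric(table(subject))
    if (any(ni < 2)) warning("some subjects contribute a single point")
    if (N == K) {
      # one point per subject: nothing to decompose, use the plain SD
      sd_used <- stats::sd(d)
    } else {
      dbar_i <- tapply(d, subject, mean)
      dbar <- mean(d)
      msb <- sum(ni * (dbar_i - dbar)^2) / (K - 1)
      msw <- sum((d - dbar_i[subject])^2) / (N - K)
      n0 <- (N - sum(ni^2) / N) / (K - 1)
      sigma2_b <- max(0, (msb - msw) / n0)
      sd_used <- sqrt(sigma2_b + msw)
    }
  }
  bias <- mean(d)
  slope <- NA_real_; ci <- c(NA_real_, NA_real_)
  if (stats::sd(d) == 0) {
    # identical differences: exactly no proportional bias
    slope <- 0; ci <- c(0, 0)
  } else if (stats::sd(m) > 0 && N > 2) {
    fit <- stats::lm(d ~ m)
    slope <- unname(stats::coef(fit)[2])
    ci <- unname(stats::confint(fit, "m", level = 0.95))
  }
  structure(list(bias = bias, loa_low = bias - 1.96 * sd_used,
                 loa_high = bias + 1.96 * sd_used, sd_used = sd_used,
                 proportional_slope = slope, proportional_ci = as.numeric(ci),
                 n_points = N, n_subjects = K, method = method),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Bland-Altman (%s): bias %.1f, LoA [%.1f, %.1f] (SD %.1f)\n",
              x$method, x$bias, x$loa_low, x$loa_high, x$sd_used))
  cat(sprintf("  %d points, %d subject(s); proportional slope %.4f [%.4f, %.4f]\n",
              x$n_points, x$n_subjects, x$proportional_slope,
              x$proportional_ci[1], x$proportional_ci[2]))
  invisible(x)
}

#' Per-protocol signed-error summary
#'
#' Mean and SD of the signed prediction error (pred - true, ml/min) per
#' protocol label plus the combined pool, matching the "mean +/- SD"
#' error-reporting convention.
#'
#' @param pred,true paired second-by-second values (ml/min).
#' @param protocol protocol label per pair; allowed labels are "L-M",
#'   "L-H", "VT-H", "MAX".
#' @return data.frame with columns \code{protocol}, \code{n},
#'   \code{mean_error}, \code{sd_error}; the last row is "combined".
#' @export
error_summary <- function(pred, true, protocol) {
  stopifnot(length(pred) == length(true), length(true) == length(protocol))
  allowed <- c("L-M", "L-H", "VT-H", "MAX")
  bad <- setdiff(unique(protocol), allowed)
  if (length(bad))
    stop("unknown protocol label(s): ", paste(bad, collapse = ", "))
  err <- pred - true
  one <- function(lab, e) data.frame(protocol = lab, n = length(e),
                                     mean_error = mean(e),
                                     sd_error = if (length(e) > 1)
                                       stats::sd(e) else 0)
  rows <- lapply(intersect(allowed, unique(protocol)), function(lab)
    one(lab, err[protocol == lab]))
  do.call(rbind, c(rows, list(one("combined", err))))
}

#' VO2peak agreement between predicted and measured ramp signals
#'
#' For each participant's ramp session, VO2peak is the highest 20 s moving
#' average of the predicted and of the measured series; agreement over
#' participants uses the standard Bland-Altman (one pair per participant).
#'
#' @param pred_list list of predicted VO2 series (ml/min), one per
#'   participant's ramp.
#' @param true_list matching list of measured VO2 series.
#' @return an \code{agreement_report} (standard method).
#' @export
vo2peak_agreement <- function(pred_list, true_list) {
  if (length(pred_list) == 0) stop("no ramp sessions supplied")
  stopifnot(length(pred_list) == length(true_list))
  pk_pred <- vapply(pred_list, vo2peak_20s, numeric(1))
  pk_true <- vapply(true_list, vo2peak_20s, numeric(1))
  bland_altman_rm(pk_pred, pk_true, method = "standard")
}

#' Metabolic equivalents from VO2
#'
#' METs = (VO2 / mass) / 3.5, with VO2 in ml/min and mass in kg.
#'
#' @param vo2 VO2 in ml/min.
#' @param mass body mass in kg (> 0).
#' @return MET values.
#' @export
vo2_to_mets <- function(vo2, mass) {
  if (!is.numeric(mass) || any(mass <= 0)) stop("mass must be positive")
  (vo2 / mass) / 3.5
}

MET_LEVELS <- c("light", "moderate", "vigorous")

#' Physical-activity intensity class from METs
#'
#' Light: < 3.0 METs; moderate: 3.0-5.9 METs (half-open [3, 6)); vigorous:
#' >= 6.0 METs.
#'
#' @param mets MET values.
#' @return factor with levels light, moderate, vigorous.
#' @export
classify_mets <- function(mets) {
  cls <- ifelse(mets >= 6, "vigorous", ifelse(mets >= 3, "moderate", "light"))
  factor(cls, levels = MET_LEVELS)
}

#' Second-by-second activity classification report
#'
#' 3x3 confusion matrix (rows: true class, columns: predicted class, counts
#' in seconds), overall accuracy (trace / total) and per-class accuracy
#' (diagonal / row sum), as percentages.
#'
#' @param true_class,pred_class equal-length class sequences (factors or
#'   strings among light/moderate/vigorous).
#' @return object of class \code{activity_report}: \code{confusion},
#'   \code{overall_accuracy}, \code{class_accuracy}, \code{total_seconds}.
#' @export
confusion_and_accuracy <- function(true_class, pred_class) {
  if (length(true_class) != length(pred_class))
    stop("class sequences must have equal length")
  tc <- factor(as.character(true_class), levels = MET_LEVELS)
  pc <- factor(as.character(pred_class), levels = MET_LEVELS)
  if (anyNA(tc) || anyNA(pc))
    stop("classes must be among: ", paste(MET_LEVELS, collapse = ", "))
  cm <- table(true = tc, predicted = pc)
  total <- sum(cm)
  rs <- rowSums(cm)
  structure(list(confusion = cm,
                 overall_accuracy = 100 * sum(diag(cm)) / total,
                 class_accuracy = ifelse(rs > 0, 100 * diag(cm) / rs,
                                         NA_real_),
                 total_seconds = total),
            class = "activity_report")
}

#' @export
print.activity_report <- function(x, ...) {
  cat("Activity classification over", x$total_seconds, "s\n")
  print(x$confusion)
  cat(sprintf("overall accuracy: %.1f%%\n", x$overall_accuracy))
  for (l in names(x$class_accuracy))
    if (!is.na(x$class_accuracy[[l]]))
      cat(sprintf("  %-8s %.1f%%\n", l, x$class_accuracy[[l]]))
  invisible(x)
}
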