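# Classification performance metrics. AUC goes through pROC; an internal
# rank-statistic AUC is kept as a cross-check (they agree to ~1e-10).

# Mann-Whitney rank AUC: P(score_pos > score_neg) + 0.5 P(tie).
auc_rank <- function(prob, label) {
  pos <- prob[label == 1]
  neg <- prob[label == 0]
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# Trapezoidal integral of the empirical ROC curve.
auc_trapezoid <- function(prob, label) {
  ord <- order(prob, decreasing = TRUE)
  lab <- label[ord]
  pr <- prob[ord]
  # collapse score ties into single ROC vertices
  tp <- cumsum(lab == 1)
  fp <- cumsum(lab == 0)
  last <- c(pr[-1] != pr[-length(pr)], TRUE)
  tpr <- c(0, tp[last] / sum(label == 1))
  fpr <- c(0, fp[last] / sum(label == 0))
  sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
}

# Area under the precision-recall curve (step-wise interpolation as in the
# Davis-Goadrich convention via trapezoids on recall).
auc_pr <- function(prob, label) {
  n_pos <- sum(label == 1)
  if (n_pos == 0) return(NA_real_)
  ord <- order(prob, decreasing = TRUE)
  lab <- label[ord]
  pr <- prob[ord]
  tp <- cumsum(lab == 1)
  fp <- cumsum(lab == 0)
  last <- c(pr[-1] != pr[-length(pr)], TRUE)
  recall <- tp[last] / n_pos
  precision <- tp[last] / (tp[last] + fp[last])
  r <- c(0, recall)
  p <- c(precision[1], precision)
  sum(diff(r) * (head(p, -1) + p[-1]) / 2)
}

brier_score <- function(prob, label) mean((prob - label)^2)

# Slope of the logistic recalibration regression of outcomes on predicted
# log-odds (1 = calibrated). Probabilities are clamped away from 0/1.
calibration_slope <- function(prob, label) {
  lp <- stats::qlogis(pmin(pmax(prob, 1e-12), 1 - 1e-12))
  fit <- suppressWarnings(glm(label ~ lp, family = binomial()))
  unname(coef(fit)[2])
}

# One-row tibble of every evaluation metric at the 0.5 decision threshold.
evaluate_predictions <- function(prob, label) {
  pred <- as.integer(prob >= 0.5)
  tp <- sum(pred == 1 & label == 1)
  tn <- sum(pred == 0 & label == 0)
  fp <- sum(pred == 1 & label == 0)
  fn <- sum(pred == 0 & label == 1)
  auc <- if (length(unique(label)) == 2) {
    as.numeric(pROC::auc(pROC::roc(label, prob,
      quiet = TRUE, direction = "<", levels = c(0, 1)
    )))
  } else {
    NA_real_
  }
  tibble(
    auc = auc,
    accuracy = (tp + tn) / length(label),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    auc_pr = auc_pr(prob, label),
    brier = brier_score(prob, label),
    calibration_slope = if (length(unique(label)) == 2) {
      calibration_slope(prob, label)
    } else {
      NA_real_
    },
    n = length(label),
    n_positive = sum(label == 1)
  )
}

#' Calibration report for predicted probabilities
#'
#' Reliability curve over equal-frequency bins, the calibration slope (from
#' a logistic regression of outcomes on predicted log-odds; 1 = calibrated),
#' and the Brier score. With `recalibrate = "platt"` or `"isotonic"` the
#' probabilities are recalibrated on one half of a seeded split and the
#' report describes the recalibrated predictions on the held-out half.
#'
#' @param prob Predicted probabilities in [0, 1].
#' @param label Binary outcomes (0/1).
#' @param bins Number of equal-frequency bins. Default 10.
#' @param recalibrate `"none"`, `"platt"` (logistic) or `"isotonic"`.
#' @param seed Seed for the recalibration split.
#' @return An object of class `calibration_report`: `curve` tibble (bin,
#'   mean_predicted, observed_rate, n), `slope`, `brier`, `recalibrate`.
#' @export
calibration_report <- function(prob, label, bins = 10,
                               recalibrate = c("none", "platt", "isotonic"),
                               seed = 1L) {
  recalibrate <- match.arg(recalibrate)
  if (any(prob < 0 | prob > 1)) abort("probabilities must lie in [0, 1]")
  if (length(unique(label)) < 2) abort("labels are single-class")
  if (recalibrate != "none") {
    idx <- with_seed(seed, stratified_split(label, 0.5))
    p_fit <- prob[idx$train]
    y_fit <- label[idx$train]
    p_app <- prob[idx$validation]
    label <- label[idx$validation]
    if (recalibrate == "platt") {
      lp <- stats::qlogis(pmin(pmax(p_fit, 1e-12), 1 - 1e-12))
      fit <- suppressWarnings(glm(y_fit ~ lp, family = binomial()))
      lp_new <- stats::qlogis(pmin(pmax(p_app, 1e-12), 1 - 1e-12))
      prob <- stats::plogis(coef(fit)[1] + coef(fit)[2] * lp_new)
    } else {
      iso <- stats::isoreg(p_fit, y_fit)
      f <- stats::approxfun(iso$x, iso$yf, rule = 2, ties = mean)
      prob <- pmin(pmax(f(p_app), 0), 1)
    }
  }
  br <- cut(rank(prob, ties.method = "first"),
    breaks = seq(0, length(prob), length.out = bins + 1),
    include.lowest = TRUE, labels = FALSE
  )
  curve <- tibble(bin = br, prob = prob, label = label) |>
    group_by(.data$bin) |>
    summarise(
      mean_predicted = mean(.data$prob),
      observed_rate = mean(.data$label),
      n = n(), .groups = "drop"
    )
  structure(
    list(
      curve = curve,
      slope = calibration_slope(prob, label),
      brier = brier_score(prob, label),
      recalibrate = recalibrate
    ),
    class = "calibration_report"
  )
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(
    "<calibration_report>", x$recalibrate,
    "| slope =", round(x$slope, 4), "| Brier =", round(x$brier, 4), "\n"
  )
  print(x$curve, n = Inf)
  invisible(x)
}

#' @export
tidy.calibration_report <- function(x, ...) x$curve

#' @export
glance.calibration_report <- function(x, ...) {
  tibble(slope = x$slope, brier = x$brier, recalibrate = x$recalibrate)
}
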