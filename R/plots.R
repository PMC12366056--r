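# ggplot2 displays for the main result types.

#' Elbow-curve plot
#'
#' @param x An `elbow_curve` from [elbow_scan()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.elbow_curve <- function(x, ...) {
  ggplot2::ggplot(x$curve, ggplot2::aes(x = .data$k, y = .data$inertia)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = x$selected_k, linetype = "dashed") +
    ggplot2::labs(
      x = "k", y = "Within-cluster sum of squares",
      title = paste0(
        "Elbow scan (selected k = ", x$selected_k,
        if (x$weak) ", weak elbow" else "", ")"
      )
    ) +
    ggplot2::theme_minimal()
}

# Parametric outline of a Hotelling ellipse for plotting.
ellipse_outline <- function(ellipse, n = 200) {
  th <- seq(0, 2 * pi, length.out = n)
  circ <- rbind(ellipse$semi_axes[1] * cos(th), ellipse$semi_axes[2] * sin(th))
  rot <- matrix(c(
    cos(ellipse$angle), sin(ellipse$angle),
    -sin(ellipse$angle), cos(ellipse$angle)
  ), 2, 2)
  pts <- t(rot %*% circ) + rep(ellipse$center, each = n)
  tibble(x = pts[, 1], y = pts[, 2])
}

#' OPLS-DA score plot with the Hotelling 95% ellipse
#'
#' Predictive score against the first orthogonal score (or index when the
#' model has no orthogonal component), colored by class.
#'
#' @param x An `opls_model`.
#' @param y Optional class labels (in score row order) for coloring.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.opls_model <- function(x, y = NULL, ...) {
  sc <- x$scores
  if ("t_ortho1" %in% names(sc)) {
    df <- tibble(t1 = sc$t_pred, t2 = sc$t_ortho1)
    ylab <- "Orthogonal score t_o1"
  } else {
    df <- tibble(t1 = sc$t_pred, t2 = seq_len(nrow(sc)))
    ylab <- "Observation index"
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t1, y = .data$t2))
  if (!is.null(y)) {
    df$class <- factor(y)
    p <- ggplot2::ggplot(
      df, ggplot2::aes(x = .data$t1, y = .data$t2, color = .data$class)
    )
  }
  p <- p + ggplot2::geom_point(alpha = 0.7)
  if ("t_ortho1" %in% names(sc)) {
    ell <- hotelling_ellipse(df[c("t1", "t2")])
    p <- p + ggplot2::geom_path(
      data = ellipse_outline(ell),
      ggplot2::aes(x = .data$x, y = .data$y),
      inherit.aes = FALSE, linetype = "dashed"
    )
  }
  p + ggplot2::labs(
    x = "Predictive score t_p", y = ylab,
    title = sprintf(
      "OPLS-DA: %s vs %s (R2Y = %.3f, Q2 = %.3f)",
      x$classes[1], x$classes[2], x$r2y, x$q2
    )
  ) +
    ggplot2::theme_minimal()
}

#' Manhattan plot of per-SNP association p-values
#'
#' @param results An `association_result` with chrom/pos.
#' @param threshold Optional significance threshold drawn as a line
#'   (on the p scale).
#' @return A ggplot.
#' @export
plot_manhattan <- function(results, threshold = NULL) {
  tab <- manhattan_table(results)
  p <- ggplot2::ggplot(
    tab,
    ggplot2::aes(x = .data$genome_pos, y = .data$neg_log10_p, color = .data$chrom)
  ) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::labs(x = "Genome position", y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = -log10(threshold), linetype = "dashed")
  }
  p
}

#' Calibration (reliability) curve plot
#'
#' @param x A `calibration_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.calibration_report <- function(x, ...) {
  ggplot2::ggplot(
    x$curve,
    ggplot2::aes(x = .data$mean_predicted, y = .data$observed_rate)
  ) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Mean predicted probability", y = "Observed event rate",
      title = sprintf("Calibration (slope = %.2f, Brier = %.3f)", x$slope, x$brier)
    ) +
    ggplot2::theme_minimal()
}

#' Consensus feature-selection ranking plot
#'
#' Cumulative selection counts of the top-ranked features, stacked by method.
#'
#' @param x A `feature_ranking`.
#' @param top Number of features shown. Default 16.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.feature_ranking <- function(x, top = 16, ...) {
  df <- head(x$counts, top) |>
    tidyr::pivot_longer(c("lasso", "rf", "svm"),
      names_to = "method", values_to = "count"
    )
  ggplot2::ggplot(
    df,
    ggplot2::aes(
      x = stats::reorder(.data$feature, .data$count, sum),
      y = .data$count, fill = .data$method
    )
  ) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Cumulative selection count") +
    ggplot2::theme_minimal()
}

#' Heatmap-ready matrix export
#'
#' Returns the feature matrix with subjects in the canonical display order
#' (see [order_subjects_for_heatmap()]), each feature mean-centered and
#' divided by its range, for external heatmap rendering.
#'
#' @param x Tibble: subject_id + numeric features.
#' @param cohort Phenotype tibble with group/sex/age.
#' @return A tibble in display order with scaled values.
#' @export
heatmap_matrix <- function(x, cohort) {
  check_same_subjects(x, cohort, "matrix", "cohort")
  ordered <- order_subjects_for_heatmap(cohort)
  m <- feature_matrix(x)[as.character(ordered$subject_id), , drop = FALSE]
  rng <- apply(m, 2, function(v) diff(range(v)))
  rng[rng == 0] <- 1
  m <- sweep(sweep(m, 2, colMeans(m)), 2, rng, "/")
  bind_cols(tibble(subject_id = ordered$subject_id), as_tibble(as.data.frame(m)))
}
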