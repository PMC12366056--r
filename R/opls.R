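# Orthogonal partial least squares discriminant analysis (OPLS-DA), written
# as a NIPALS-style orthogonal signal correction followed by a single
# predictive PLS component, with stratified k-fold Q2 and the Hotelling T2
# ellipse for the 2-D score plot.

# Core estimator on a centered X and centered numeric y. Extracts n_ortho
# orthogonal components (structured variation in X uncorrelated with y),
# deflates X, then fits one predictive component.
opls_core <- function(X, y, n_ortho) {
  normalize <- function(v) v / sqrt(sum(v^2))
  W_o <- P_o <- NULL
  T_o <- NULL
  Xd <- X
  for (h in seq_len(n_ortho)) {
    w <- normalize(drop(crossprod(Xd, y)))
    t_p <- drop(Xd %*% w)
    p <- drop(crossprod(Xd, t_p)) / sum(t_p^2)
    w_o <- p - drop(crossprod(w, p)) * w
    nrm <- sqrt(sum(w_o^2))
    if (nrm < 1e-12) break # no y-orthogonal structure left
    w_o <- w_o / nrm
    t_o <- drop(Xd %*% w_o)
    p_o <- drop(crossprod(Xd, t_o)) / sum(t_o^2)
    Xd <- Xd - tcrossprod(t_o, p_o)
    W_o <- cbind(W_o, w_o)
    P_o <- cbind(P_o, p_o)
    T_o <- cbind(T_o, t_o)
  }
  w <- normalize(drop(crossprod(Xd, y)))
  t_p <- drop(Xd %*% w)
  p <- drop(crossprod(Xd, t_p)) / sum(t_p^2)
  q <- sum(y * t_p) / sum(t_p^2)
  fitted <- t_p * q
  r2y <- 1 - sum((y - fitted)^2) / sum(y^2)
  list(
    w = w, p = p, q = q, t_pred = t_p, W_ortho = W_o, P_ortho = P_o,
    T_ortho = T_o, r2y = r2y, n_ortho = if (is.null(W_o)) 0L else ncol(W_o)
  )
}

# Apply a fitted core to new (already centered) data: remove the orthogonal
# components, then project on the predictive weight.
opls_core_predict <- function(core, Xnew) {
  if (core$n_ortho > 0) {
    for (h in seq_len(core$n_ortho)) {
      t_o <- drop(Xnew %*% core$W_ortho[, h])
      Xnew <- Xnew - tcrossprod(t_o, core$P_ortho[, h])
    }
  }
  t_p <- drop(Xnew %*% core$w)
  list(t_pred = t_p, yhat = t_p * core$q)
}

#' Fit an OPLS-DA model
#'
#' One predictive component plus `n_ortho` orthogonal (y-uncorrelated)
#' components, estimated NIPALS-style on a unit-variance-scaled feature
#' matrix. The two-class response is coded +1/-1 and centered. R2Y is the
#' fitted explained variance of the response; Q2 is its cross-validated
#' analogue, 1 - PRESS/SS from stratified k-fold cross-validation (folds
#' re-centered on their training data). With `n_ortho = "auto"`, orthogonal
#' components are added while Q2 improves by more than `q2_tol`.
#'
#' @param x Tibble (subject_id + numeric features) or matrix, unit-variance
#'   scaled (see [unit_variance_scale()]).
#' @param y Two-class response (factor, character or numeric with 2 levels),
#'   one value per row of `x`.
#' @param n_ortho Number of orthogonal components, or `"auto"`.
#' @param folds Cross-validation folds. Default 7.
#' @param seed Seed for the stratified fold assignment.
#' @param q2_tol Minimum Q2 improvement to accept another orthogonal
#'   component under `"auto"`. Default 0.01.
#' @param max_ortho Upper bound for `"auto"`. Default 5.
#' @return An object of class `opls_model`: scores tibble (subject_id,
#'   t_pred, t_ortho1 when present), weights/loadings, `r2y`, `q2`,
#'   `n_ortho`, `folds`, class coding.
#' @export
opls_fit <- function(x, y, n_ortho = "auto", folds = 7, seed = 1L,
                     q2_tol = 0.01, max_ortho = 5) {
  m <- feature_matrix(x)
  if (anyNA(m)) abort("missing values in x")
  cls <- factor(y)
  if (nlevels(cls) != 2) abort("y must have exactly 2 classes")
  if (min(table(cls)) < 2) abort("both classes need at least 2 observations")
  y_num <- ifelse(as.integer(cls) == 2L, 1, -1)
  x_center <- colMeans(m)
  Xc <- sweep(m, 2, x_center)
  y_mean <- mean(y_num)
  yc <- y_num - y_mean

  cv_q2 <- function(no) {
    fold <- with_seed(seed, stratified_folds(cls, folds))
    press <- ss <- 0
    for (f in seq_len(folds)) {
      tr <- fold != f
      Xtr <- m[tr, , drop = FALSE]
      ctr <- colMeans(Xtr)
      ytr <- y_num[tr]
      core <- opls_core(sweep(Xtr, 2, ctr), ytr - mean(ytr), no)
      pr <- opls_core_predict(core, sweep(m[!tr, , drop = FALSE], 2, ctr))
      press <- press + sum((y_num[!tr] - (pr$yhat + mean(ytr)))^2)
      ss <- ss + sum((y_num[!tr] - mean(ytr))^2)
    }
    1 - press / ss
  }

  if (identical(n_ortho, "auto")) {
    q2_best <- cv_q2(0)
    no <- 0L
    while (no < max_ortho) {
      q2_next <- cv_q2(no + 1L)
      if (q2_next > q2_best + q2_tol) {
        no <- no + 1L
        q2_best <- q2_next
      } else {
        break
      }
    }
    q2 <- q2_best
  } else {
    no <- as.integer(n_ortho)
    if (no < 0) abort("n_ortho must be >= 0")
    if (no >= qr(Xc)$rank) abort("n_ortho must be smaller than rank(x)")
    q2 <- cv_q2(no)
  }

  core <- opls_core(Xc, yc, no)
  ids <- rownames(m) %||% as.character(seq_len(nrow(m)))
  scores <- tibble(subject_id = ids, t_pred = core$t_pred)
  if (core$n_ortho > 0) {
    for (h in seq_len(core$n_ortho)) {
      scores[[paste0("t_ortho", h)]] <- core$T_ortho[, h]
    }
  }
  structure(
    list(
      scores = scores,
      weights = core$w,
      loadings = core$p,
      q_loading = core$q,
      W_ortho = core$W_ortho,
      P_ortho = core$P_ortho,
      r2y = core$r2y,
      q2 = q2,
      n_ortho = core$n_ortho,
      folds = as.integer(folds),
      classes = levels(cls),
      x_center = x_center,
      y_mean = y_mean,
      feature_names = colnames(m),
      seed = as.integer(seed)
    ),
    class = "opls_model"
  )
}

#' @export
print.opls_model <- function(x, ...) {
  cat(
    "<opls_model>", x$classes[1], "vs", x$classes[2],
    "| 1 predictive +", x$n_ortho, "orthogonal component(s)\n",
    "R2Y =", round(x$r2y, 4), "| Q2 =", round(x$q2, 4),
    paste0("(", x$folds, "-fold CV)\n")
  )
  invisible(x)
}

#' @export
glance.opls_model <- function(x, ...) {
  tibble(
    r2y = x$r2y, q2 = x$q2, n_ortho = x$n_ortho, folds = x$folds,
    n = nrow(x$scores), n_features = length(x$feature_names)
  )
}

#' @export
tidy.opls_model <- function(x, ...) {
  tibble(
    feature = x$feature_names,
    weight = unname(x$weights),
    loading = unname(x$loadings)
  )
}

#' @export
predict.opls_model <- function(object, newdata, ...) {
  m <- feature_matrix(newdata)
  m <- m[, object$feature_names, drop = FALSE]
  pr <- opls_core_predict(object, sweep(m, 2, object$x_center))
  yhat <- pr$yhat + object$y_mean
  tibble(
    subject_id = rownames(m) %||% as.character(seq_len(nrow(m))),
    t_pred = pr$t_pred,
    score = yhat,
    class = object$classes[ifelse(yhat >= 0, 2L, 1L)]
  )
}

#' Hotelling T2 95% ellipse for a 2-D score plot
#'
#' Critical value from the F-distribution mapping
#' T2 = 2(n-1)/(n-2) F(level; 2, n-2); the ellipse semi-axes are
#' sqrt(lambda_i T2crit) along the covariance eigenvectors.
#'
#' @param scores Two-column numeric matrix or data frame of scores.
#' @param level Coverage level. Default 0.95.
#' @return An object of class `hotelling_ellipse`: center, covariance,
#'   `t2_crit`, semi-axes, rotation angle (radians).
#' @export
hotelling_ellipse <- function(scores, level = 0.95) {
  m <- feature_matrix(scores)
  if (ncol(m) != 2) abort("scores must have exactly 2 columns")
  n <- nrow(m)
  if (n < 3) abort("need at least 3 points")
  S <- cov(m)
  if (abs(det(S)) < 1e-300) abort("degenerate score covariance")
  t2_crit <- 2 * (n - 1) / (n - 2) * qf(level, 2, n - 2)
  eg <- eigen(S, symmetric = TRUE)
  structure(
    list(
      center = colMeans(m),
      covariance = S,
      level = level,
      t2_crit = t2_crit,
      semi_axes = sqrt(eg$values * t2_crit),
      angle = atan2(eg$vectors[2, 1], eg$vectors[1, 1])
    ),
    class = "hotelling_ellipse"
  )
}

#' Which points fall inside a Hotelling ellipse
#'
#' @param ellipse A `hotelling_ellipse`.
#' @param scores Two-column matrix/data frame of points.
#' @return Logical vector, `TRUE` for points inside or on the ellipse.
#' @export
ellipse_contains <- function(ellipse, scores) {
  m <- feature_matrix(scores)
  mahalanobis(m, ellipse$center, ellipse$covariance) <= ellipse$t2_crit
}

#' @export
print.hotelling_ellipse <- function(x, ...) {
  cat(
    "<hotelling_ellipse>", paste0(100 * x$level, "%"),
    "T2 crit =", round(x$t2_crit, 4),
    "| semi-axes =", paste(round(x$semi_axes, 4), collapse = ", "), "\n"
  )
  invisible(x)
}
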