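# Model training, evaluation schemes, stepwise odds ratios, and the
# sampling-robustness experiments.

#' The XGBoost hyperparameter grid
#'
#' Learning rates eta in \{0.1, 0.3, 0.5, 0.7, 0.9\}, max_depth in
#' \{6, 12, 29\} and min_child_weight in \{1, 2, 4, 8, 10\}: 75 combinations.
#'
#' @return A tibble with one row per combination.
#' @export
xgboost_grid <- function() {
  tidyr::expand_grid(
    eta = c(0.1, 0.3, 0.5, 0.7, 0.9),
    max_depth = c(6L, 12L, 29L),
    min_child_weight = c(1, 2, 4, 8, 10)
  )
}

# Fit one model on a train matrix and return predicted probabilities for a
# validation matrix.
fit_predict <- function(model, xt, yt, xv, params = NULL, num_trees = 500) {
  switch(model,
    rf = {
      fit <- ranger::ranger(
        x = xt, y = factor(yt, levels = c(0, 1)), probability = TRUE,
        num.trees = num_trees, num.threads = 1
      )
      predict(fit, data = xv, num.threads = 1)$predictions[, "1"]
    },
    svm = {
      fit <- e1071::svm(xt, factor(yt, levels = c(0, 1)),
        kernel = "radial", probability = TRUE, scale = TRUE
      )
      at <- attr(predict(fit, xv, probability = TRUE), "probabilities")
      at[, "1"]
    },
    lasso = {
      cv <- glmnet::cv.glmnet(xt, yt, family = "binomial", alpha = 1, nfolds = 5)
      drop(predict(cv, xv, s = "lambda.1se", type = "response"))
    },
    xgboost = {
      p <- as.list(params %||% list(eta = 0.3, max_depth = 6, min_child_weight = 1))
      booster <- xgboost::xgb.train(
        params = c(p, list(
          objective = "binary:logistic", nthread = 1,
          eval_metric = "logloss"
        )),
        data = xgboost::xgb.DMatrix(xt, label = yt),
        nrounds = 50, verbose = 0
      )
      predict(booster, xgboost::xgb.DMatrix(xv))
    },
    abort(paste0("unknown model: ", model))
  )
}

# Draw a stratified split, re-drawing (with a warning) if a side ends up
# single-class.
safe_split <- function(y, prop, max_tries = 10) {
  for (i in seq_len(max_tries)) {
    s <- stratified_split(y, prop)
    if (length(unique(y[s$train])) == 2 && length(unique(y[s$validation])) == 2) {
      return(s)
    }
    warn("degenerate single-class split, re-drawing")
  }
  abort("could not draw a two-class split")
}

#' Train and evaluate a prediction model
#'
#' Either a stratified 80:20 holdout or stratified 10-fold cross-validation,
#' seeded. Metrics: AUC (ROC), accuracy, sensitivity, specificity, AUC-PR,
#' Brier score and calibration slope, per fold and averaged. For XGBoost a
#' hyperparameter grid can be supplied (holdout scheme): every combination
#' is trained and the best by validation AUC is reported along with the full
#' grid table.
#'
#' @param ft A `feature_table`.
#' @param features Character vector of feature columns to use (e.g. from
#'   [top_k_features()]).
#' @param scheme `"holdout"` (80:20) or `"cv"` (k-fold).
#' @param model `"rf"`, `"svm"`, `"lasso"` or `"xgboost"`.
#' @param grid Optional hyperparameter grid (tibble) for `model = "xgboost"`
#'   with `scheme = "holdout"`, e.g. [xgboost_grid()].
#' @param split Training fraction for the holdout. Default 0.8.
#' @param folds CV folds. Default 10.
#' @param seed Integer seed.
#' @param num_trees Trees for the random forest. Default 500.
#' @return An object of class `model_evaluation`: `metrics` tibble (one row
#'   per fold plus a `mean` row for CV; one row for holdout), `scheme`,
#'   `model`, optional `grid_results` and `best_params`, `predictions`.
#' @export
train_and_evaluate <- function(ft, features, scheme = c("holdout", "cv"),
                               model = c("rf", "svm", "lasso", "xgboost"),
                               grid = NULL, split = 0.8, folds = 10,
                               seed = 1L, num_trees = 500) {
  scheme <- match.arg(scheme)
  model <- match.arg(model)
  if (length(features) == 0) abort("empty feature list")
  missing_f <- setdiff(features, names(ft))
  if (length(missing_f) > 0) {
    abort(paste0("feature(s) not in table: ", paste(missing_f, collapse = ", ")))
  }
  y <- ft$response
  x <- feature_matrix(ft[c("subject_id", features)])
  if (!is.null(grid) && !(model == "xgboost" && scheme == "holdout")) {
    abort("grids are supported for model = 'xgboost' with scheme = 'holdout'")
  }

  grid_results <- NULL
  best_params <- NULL
  with_seed(seed, {
    if (scheme == "holdout") {
      s <- safe_split(y, split)
      xt <- x[s$train, , drop = FALSE]
      yt <- y[s$train]
      xv <- x[s$validation, , drop = FALSE]
      yv <- y[s$validation]
      if (!is.null(grid)) {
        grid_results <- grid
        grid_results$auc <- map_dbl(seq_len(nrow(grid)), function(i) {
          pr <- fit_predict("xgboost", xt, yt, xv, params = grid[i, ])
          auc_rank(pr, yv)
        })
        best <- which.max(grid_results$auc)
        best_params <- grid[best, ]
        prob <- fit_predict("xgboost", xt, yt, xv, params = best_params)
      } else {
        prob <- fit_predict(model, xt, yt, xv, num_trees = num_trees)
      }
      metrics <- mutate(evaluate_predictions(prob, yv), fold = "holdout", .before = 1)
      predictions <- tibble(
        subject_id = ft$subject_id[s$validation], fold = "holdout",
        prob = prob, label = yv
      )
    } else {
      fold <- stratified_folds(y, folds)
      rows <- vector("list", folds)
      preds <- vector("list", folds)
      for (f in seq_len(folds)) {
        xt <- x[fold != f, , drop = FALSE]
        yt <- y[fold != f]
        xv <- x[fold == f, , drop = FALSE]
        yv <- y[fold == f]
        prob <- fit_predict(model, xt, yt, xv, num_trees = num_trees)
        rows[[f]] <- mutate(evaluate_predictions(prob, yv),
          fold = as.character(f), .before = 1
        )
        preds[[f]] <- tibble(
          subject_id = ft$subject_id[fold == f], fold = as.character(f),
          prob = prob, label = yv
        )
      }
      per_fold <- bind_rows(rows)
      mean_row <- per_fold |>
        summarise(across(dplyr::where(is.numeric), \(v) mean(v, na.rm = TRUE))) |>
        mutate(fold = "mean", .before = 1)
      metrics <- bind_rows(per_fold, mean_row)
      predictions <- bind_rows(preds)
    }
  })
  structure(
    list(
      metrics = metrics, scheme = scheme, model = model,
      grid_results = grid_results, best_params = best_params,
      predictions = predictions, seed = as.integer(seed)
    ),
    class = "model_evaluation"
  )
}

#' @export
print.model_evaluation <- function(x, ...) {
  cat("<model_evaluation>", x$model, "|", x$scheme, "\n")
  print(x$metrics)
  invisible(x)
}

#' @export
tidy.model_evaluation <- function(x, ...) x$metrics

#' @export
glance.model_evaluation <- function(x, ...) {
  row <- x$metrics[x$metrics$fold %in% c("holdout", "mean"), ]
  bind_cols(tibble(model = x$model, scheme = x$scheme), row["fold" != names(row)])
}

#' Adjusted odds ratios by backward stepwise logistic regression
#'
#' Fits a logistic regression of the response on the given features,
#' eliminates backwards by AIC, and reports exponentiated coefficients with
#' 95% Wald confidence intervals for the retained features. Quasi-complete
#' separation (exploding coefficients / standard errors) is flagged and the
#' interval suppressed.
#'
#' @param ft A `feature_table`.
#' @param features Feature columns to offer the model.
#' @return A tibble: term, estimate (log-OR), or, or_low, or_high, p_value,
#'   separation flag. Empty (zero rows) if nothing is retained or no
#'   features were offered.
#' @export
backward_stepwise_or <- function(ft, features) {
  y <- ft$response
  if (length(features) == 0) {
    return(tibble(
      term = character(), estimate = numeric(), or = numeric(),
      or_low = numeric(), or_high = numeric(), p_value = numeric(),
      separation = logical()
    ))
  }
  dat <- as.data.frame(ft[features])
  dat$.response <- y
  full <- suppressWarnings(glm(.response ~ ., data = dat, family = binomial()))
  fit <- suppressWarnings(step(full, direction = "backward", trace = 0))
  sm <- summary(fit)$coefficients
  terms_kept <- setdiff(rownames(sm), "(Intercept)")
  if (length(terms_kept) == 0) {
    return(tibble(
      term = character(), estimate = numeric(), or = numeric(),
      or_low = numeric(), or_high = numeric(), p_value = numeric(),
      separation = logical()
    ))
  }
  est <- sm[terms_kept, "Estimate"]
  se <- sm[terms_kept, "Std. Error"]
  sep <- abs(est) > 15 | se > 10
  z <- qnorm(0.975)
  tibble(
    term = terms_kept,
    estimate = unname(est),
    or = exp(unname(est)),
    or_low = ifelse(sep, NA_real_, exp(unname(est - z * se))),
    or_high = ifelse(sep, NA_real_, exp(unname(est + z * se))),
    p_value = unname(sm[terms_kept, "Pr(>|z|)"]),
    separation = unname(sep)
  )
}

# 1:1 nearest-neighbour matching of controls to cases on standardized
# continuous covariates, exact on binary/factor covariates, with an age
# caliper in years. Greedy, processed in case order.
match_controls <- function(ft, covariates, exact = character(0),
                           caliper_age = 5) {
  cases <- which(ft$response == 1)
  ctls <- which(ft$response == 0)
  cont <- setdiff(covariates, exact)
  z <- scale(as.matrix(ft[cont]))
  matched <- integer(0)
  pairs <- list()
  for (i in cases) {
    pool <- setdiff(ctls, matched)
    for (e in exact) pool <- pool[ft[[e]][pool] == ft[[e]][i]]
    if ("age" %in% cont) {
      pool <- pool[abs(ft$age[pool] - ft$age[i]) <= caliper_age]
    }
    if (length(pool) == 0) next
    d <- colSums((t(z[pool, , drop = FALSE]) - z[i, ])^2)
    j <- pool[which.min(d)]
    matched <- c(matched, j)
    pairs[[length(pairs) + 1L]] <- tibble(
      case_id = ft$subject_id[i], control_id = ft$subject_id[j]
    )
  }
  list(case_idx = cases, control_idx = matched, pairs = bind_rows(pairs))
}

#' Sampling-robustness experiments for the prediction model
#'
#' Rebalances the training data and evaluates on an untouched validation
#' split: `subsample_1to1` draws training controls without replacement to
#' equal the training case count; `match_age_sex` and `match_age_sex_statin`
#' build a 1:1 nearest-neighbour matched training set (standardized age,
#' exact sex / statin, age caliper in years). Validation subjects are never
#' reused in training.
#'
#' @param ft A `feature_table`.
#' @param features Feature columns for the model.
#' @param mode `"subsample_1to1"`, `"match_age_sex"` or
#'   `"match_age_sex_statin"`.
#' @param model Model passed to the evaluator. Default `"rf"`.
#' @param split Training fraction. Default 0.8.
#' @param seed Integer seed.
#' @param caliper_age Age caliper (years) for matching. Default 5.
#' @param num_trees Trees for the random forest. Default 500.
#' @return An object of class `model_evaluation` with an extra
#'   `matched_pairs` element (tibble, matching modes only) and `mode`.
#' @export
balance_experiments <- function(ft, features,
                                mode = c(
                                  "subsample_1to1", "match_age_sex",
                                  "match_age_sex_statin"
                                ),
                                model = "rf", split = 0.8, seed = 1L,
                                caliper_age = 5, num_trees = 500) {
  mode <- match.arg(mode)
  missing_f <- setdiff(features, names(ft))
  if (length(missing_f) > 0) {
    abort(paste0("feature(s) not in table: ", paste(missing_f, collapse = ", ")))
  }
  y <- ft$response
  x <- feature_matrix(ft[c("subject_id", features)])
  pairs <- NULL
  out <- with_seed(seed, {
    s <- safe_split(y, split)
    tr_tbl <- ft[s$train, ]
    attr(tr_tbl, "features") <- attr(ft, "features")
    if (mode == "subsample_1to1") {
      n_case <- sum(tr_tbl$response == 1)
      ctl_rows <- which(tr_tbl$response == 0)
      if (length(ctl_rows) < n_case) abort("not enough controls to subsample 1:1")
      keep <- c(which(tr_tbl$response == 1), sample(ctl_rows, n_case))
    } else {
      covs <- if (mode == "match_age_sex") c("age", "male") else c("age", "male", "statin")
      missing_c <- setdiff(covs, names(tr_tbl))
      if (length(missing_c) > 0) {
        abort(paste0("matching covariate(s) missing: ", paste(missing_c, collapse = ", ")))
      }
      mt <- match_controls(tr_tbl,
        covariates = covs,
        exact = intersect(c("male", "statin"), covs),
        caliper_age = caliper_age
      )
      if (nrow(mt$pairs) == 0) abort("no matchable controls")
      pairs <- mt$pairs
      keep <- c(
        which(tr_tbl$subject_id %in% mt$pairs$case_id),
        which(tr_tbl$subject_id %in% mt$pairs$control_id)
      )
    }
    train_idx <- s$train[sort(keep)]
    xt <- x[train_idx, , drop = FALSE]
    yt <- y[train_idx]
    xv <- x[s$validation, , drop = FALSE]
    yv <- y[s$validation]
    prob <- fit_predict(model, xt, yt, xv, num_trees = num_trees)
    list(
      metrics = mutate(evaluate_predictions(prob, yv), fold = mode, .before = 1),
      predictions = tibble(
        subject_id = ft$subject_id[s$validation], fold = mode,
        prob = prob, label = yv
      )
    )
  })
  structure(
    list(
      metrics = out$metrics, scheme = "holdout", model = model, mode = mode,
      matched_pairs = pairs, predictions = out$predictions,
      seed = as.integer(seed)
    ),
    class = "model_evaluation"
  )
}
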