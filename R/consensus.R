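# Bootstrapped cross-method consensus feature selection.

# Per-method selectors operating on a numeric feature matrix + 0/1 response.
# LASSO defines k (its non-zero support size); RF and SVM then contribute
# their own top-k.
select_lasso <- function(x, y, nfolds = 5) {
  # shortened lambda path and relaxed convergence: the 1-SE support is
  # insensitive to these solver knobs, and selection runs B x 3 methods
  cv <- glmnet::cv.glmnet(x, y,
    family = "binomial", alpha = 1, nfolds = nfolds,
    nlambda = 60, thresh = 1e-5
  )
  cf <- coef(cv, s = "lambda.1se")
  nz <- rownames(cf)[as.vector(cf != 0)]
  setdiff(nz, "(Intercept)")
}

select_rf <- function(x, y, k, num_trees = 200) {
  fit <- ranger::ranger(
    x = x, y = factor(y), num.trees = num_trees,
    importance = "impurity", num.threads = 1
  )
  imp <- sort(fit$variable.importance, decreasing = TRUE)
  names(imp)[seq_len(k)]
}

select_svm <- function(x, y, k) {
  fit <- e1071::svm(x, factor(y), kernel = "linear", scale = TRUE)
  w <- drop(t(fit$coefs) %*% fit$SV) # primal weights of the linear SVM
  names(sort(abs(w), decreasing = TRUE))[seq_len(k)]
}

#' Bootstrapped consensus feature selection (LASSO / RF / SVM)
#'
#' For each of `B` iterations: draw a stratified train/validation split,
#' fit a LASSO logistic regression on the training part (penalty by internal
#' cross-validation, 1-SE rule) and record its non-zero features — their
#' count k sets the iteration's budget; a random forest (impurity
#' importance) and a linear SVM (absolute primal weights) then each
#' contribute their top-k features. Features are ranked by cumulative
#' selection count across all iterations and methods; an iteration with
#' k = 0 contributes no selections.
#'
#' @param ft A `feature_table` from [assemble_features()].
#' @param B Number of bootstrap replications. Default 100.
#' @param split Training fraction of each stratified resplit. Default 0.8.
#' @param seed Integer seed.
#' @param num_trees Trees per random forest. Default 200.
#' @param resample `"resplit"` (default; fresh stratified 80:20 split per
#'   iteration) or `"bootstrap"` (sample subjects with replacement for
#'   training).
#' @return An object of class `feature_ranking`: `counts` tibble (feature,
#'   lasso, rf, svm, total, rank), `k_per_iter`, `B`.
#' @export
consensus_select <- function(ft, B = 100, split = 0.8, seed = 1L,
                             num_trees = 200,
                             resample = c("resplit", "bootstrap")) {
  resample <- match.arg(resample)
  if (B < 1) abort("B must be >= 1")
  feats <- feature_names(ft)
  if (length(feats) < 2) abort("need at least 2 features")
  y <- ft$response
  if (!all(y %in% c(0, 1)) || length(unique(y)) != 2) {
    abort("response must be binary 0/1 with both classes present")
  }
  x <- feature_matrix(ft[c("subject_id", feats)])

  counts <- matrix(0L, length(feats), 3,
    dimnames = list(feats, c("lasso", "rf", "svm"))
  )
  k_per_iter <- integer(B)
  with_seed(seed, {
    for (iter in seq_len(B)) {
      if (resample == "resplit") {
        tr <- stratified_split(y, split)$train
      } else {
        tr <- sample(seq_along(y), length(y), replace = TRUE)
      }
      xt <- x[tr, , drop = FALSE]
      yt <- y[tr]
      s_l <- select_lasso(xt, yt)
      k <- length(s_l)
      k_per_iter[iter] <- k
      if (k == 0) {
        inform(paste0("iteration ", iter, ": LASSO selected 0 features, skipped"))
        next
      }
      counts[s_l, "lasso"] <- counts[s_l, "lasso"] + 1L
      s_r <- select_rf(xt, yt, k, num_trees)
      counts[s_r, "rf"] <- counts[s_r, "rf"] + 1L
      s_s <- select_svm(xt, yt, k)
      counts[s_s, "svm"] <- counts[s_s, "svm"] + 1L
    }
  })
  tbl <- as_tibble(counts) |>
    mutate(feature = feats, .before = 1) |>
    mutate(total = .data$lasso + .data$rf + .data$svm) |>
    arrange(
      dplyr::desc(.data$total), dplyr::desc(.data$lasso), .data$feature
    ) |>
    mutate(rank = row_number())
  structure(
    list(counts = tbl, k_per_iter = k_per_iter, B = as.integer(B),
         seed = as.integer(seed), resample = resample),
    class = "feature_ranking"
  )
}

#' @export
print.feature_ranking <- function(x, ...) {
  cat(
    "<feature_ranking>", x$B, "iterations | mean k =",
    round(mean(x$k_per_iter), 2), "\n"
  )
  print(head(x$counts, 16), n = 16)
  invisible(x)
}

#' @export
tidy.feature_ranking <- function(x, ...) x$counts

#' @export
glance.feature_ranking <- function(x, ...) {
  tibble(
    B = x$B, mean_k = mean(x$k_per_iter),
    zero_k_iterations = sum(x$k_per_iter == 0),
    total_selections = sum(x$counts$total)
  )
}

#' Top-k features of a consensus ranking
#'
#' Ties on cumulative count break by higher LASSO count, then feature name.
#'
#' @param ranking A `feature_ranking`.
#' @param k Number of features. Default 16.
#' @return Character vector of k feature names in rank order.
#' @export
top_k_features <- function(ranking, k = 16) {
  stopifnot(inherits(ranking, "feature_ranking"))
  if (k > nrow(ranking$counts)) abort("k exceeds the number of ranked features")
  ranking$counts$feature[seq_len(k)]
}
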