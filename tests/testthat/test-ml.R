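# Shared small cohort for feature-table tests.
ml_cohort <- function(seed = 2, n = c(40, 40, 30), n_met = 12, n_inf = 3,
                      effect = 1.5) {
  cfg <- simulation_config(
    n_per_group = n, n_snps = 10, n_metabolites = n_met,
    n_informative_features = n_inf, effect_size = effect,
    cluster_separation = 0, seed = seed
  )
  generate_cohort(cfg)
}

test_that("feature tables assemble the expected shape and labels", {
  ch <- ml_cohort()
  nm <- normalize_metabolites(ch$metabolites)
  hap <- call_haplotypes(ch$genotypes)
  ft <- assemble_features(ch$phenotype, nm, hap)
  # clinical (age, bmi, male) + 6 medications + 12 metabolites + hap2/hap3
  expect_equal(length(attr(ft, "features")), 3 + 6 + 12 + 2)
  expect_equal(nrow(ft), 110)
  expect_equal(sum(ft$response), 30) # CAD = 1 in the full-cohort task
  expect_false(anyNA(ft[attr(ft, "features")]))

  ft2 <- assemble_features(ch$phenotype, nm, hap, task = "highrisk_vs_cad")
  expect_equal(nrow(ft2), 70)
  expect_equal(sum(ft2$response), 30)

  # full 271/363/147 cohort yields 147 positives
  big <- simulation_config(
    n_per_group = c(271, 363, 147), n_snps = 6, n_metabolites = 3,
    n_informative_features = 0, seed = 3
  )
  chb <- generate_cohort(big)
  ftb <- assemble_features(chb$phenotype, metabolites = NULL, include = "clinical")
  expect_equal(sum(ftb$response), 147)
  expect_equal(nrow(ftb), 781)
})

test_that("RF and SVM each contribute exactly k selections per iteration", {
  ch <- ml_cohort()
  ft <- assemble_features(
    ch$phenotype, normalize_metabolites(ch$metabolites),
    include = "metabolites"
  )
  rk <- consensus_select(ft, B = 5, seed = 9)
  expect_equal(sum(rk$counts$lasso), sum(rk$k_per_iter))
  expect_equal(sum(rk$counts$rf), sum(rk$k_per_iter))
  expect_equal(sum(rk$counts$svm), sum(rk$k_per_iter))
  expect_equal(sum(rk$counts$total), 3 * sum(rk$k_per_iter))
})

test_that("consensus selection is deterministic under a fixed seed", {
  ch <- ml_cohort()
  ft <- assemble_features(
    ch$phenotype, normalize_metabolites(ch$metabolites),
    include = "metabolites"
  )
  a <- consensus_select(ft, B = 1, seed = 33)
  b <- consensus_select(ft, B = 1, seed = 33)
  expect_identical(a$counts, b$counts)
  expect_identical(a$k_per_iter, b$k_per_iter)
})

test_that("top-k extraction breaks ties by LASSO count then name", {
  rk <- structure(
    list(
      counts = tibble::tibble(
        feature = c("b", "a", "c"),
        lasso = c(10, 5, 10), rf = c(5, 10, 6), svm = c(5, 5, 4),
        total = c(20, 20, 20)
      ) |>
        dplyr::arrange(
          dplyr::desc(total), dplyr::desc(lasso), feature
        ) |>
        dplyr::mutate(rank = dplyr::row_number()),
      k_per_iter = rep(3L, 10), B = 10L
    ),
    class = "feature_ranking"
  )
  expect_equal(top_k_features(rk, 2), c("b", "c")) # lasso 10 beats 5; b < c
  expect_equal(top_k_features(rk, 3), c("b", "c", "a"))
  expect_error(top_k_features(rk, 4), "exceeds")
})

test_that("the hyperparameter grid enumerates 75 combinations", {
  grid <- xgboost_grid()
  expect_equal(nrow(grid), 75)
  expect_equal(nrow(dplyr::distinct(grid)), 75)
  expect_setequal(unique(grid$eta), c(0.1, 0.3, 0.5, 0.7, 0.9))
  expect_setequal(unique(grid$max_depth), c(6, 12, 29))
  expect_setequal(unique(grid$min_child_weight), c(1, 2, 4, 8, 10))
})

test_that("perfectly separable data is classified perfectly", {
  withr::with_seed(4, {
    n <- 120
    y <- rep(c(0, 1), each = n / 2)
    ft <- tibble::tibble(
      subject_id = sprintf("S%03d", 1:n),
      response = y,
      sep = y * 10 + rnorm(n, sd = 0.1),
      noise = rnorm(n)
    )
  })
  attr(ft, "features") <- c("sep", "noise")
  class(ft) <- c("feature_table", class(ft))
  ev <- train_and_evaluate(ft, c("sep", "noise"),
    scheme = "holdout", model = "rf", seed = 5
  )
  expect_equal(ev$metrics$auc, 1)
  expect_lt(ev$metrics$brier, 0.05)
})

test_that("permuted labels give chance-level CV AUC", {
  ch <- ml_cohort(seed = 6, n = c(70, 70, 60), n_met = 10, n_inf = 0)
  ft <- assemble_features(
    ch$phenotype, normalize_metabolites(ch$metabolites),
    include = "metabolites"
  )
  aucs <- vapply(1:5, function(s) {
    ft2 <- ft
    ft2$response <- withr::with_seed(s, sample(ft$response))
    attr(ft2, "features") <- attr(ft, "features")
    ev <- train_and_evaluate(ft2, attr(ft, "features"),
      scheme = "cv", folds = 5, model = "lasso", seed = s
    )
    ev$metrics$auc[ev$metrics$fold == "mean"]
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.08)
})

test_that("rank AUC equals the trapezoidal ROC integral", {
  withr::with_seed(12, {
    for (i in 1:10) {
      n <- 80
      label <- rbinom(n, 1, 0.4)
      if (length(unique(label)) < 2) next
      prob <- runif(n)
      if (i %% 2 == 0) prob <- round(prob, 1) # force ties
      expect_equal(
        cadtrans:::auc_rank(prob, label),
        cadtrans:::auc_trapezoid(prob, label),
        tolerance = 1e-10
      )
      # and agrees with pROC
      expect_equal(
        cadtrans:::auc_rank(prob, label),
        as.numeric(pROC::auc(pROC::roc(label, prob,
          quiet = TRUE, direction = "<", levels = c(0, 1)
        ))),
        tolerance = 1e-10
      )
    }
  })
})

test_that("the stepwise OR of a single strong binary predictor matches the 2x2 OR", {
  # outcome-by-exposure table 40/10 vs 20/30 -> OR = (40*30)/(10*20) = 6
  y <- rep(c(1, 1, 0, 0), c(40, 10, 20, 30))
  x <- rep(c(1, 0, 1, 0), c(40, 10, 20, 30))
  ft <- tibble::tibble(
    subject_id = sprintf("S%03d", seq_along(y)), response = y, exposure = x
  )
  attr(ft, "features") <- "exposure"
  class(ft) <- c("feature_table", class(ft))
  res <- backward_stepwise_or(ft, "exposure")
  expect_equal(nrow(res), 1)
  expect_equal(res$or, 6, tolerance = 1e-6)
  expect_false(res$separation)
})

test_that("stepwise elimination discards pure-noise features", {
  retained <- vapply(1:5, function(s) {
    withr::with_seed(s, {
      n <- 600
      ft <- dplyr::bind_cols(
        tibble::tibble(
          subject_id = sprintf("S%03d", 1:n), response = rbinom(n, 1, 0.3)
        ),
        tibble::as_tibble(as.data.frame(matrix(rnorm(n * 10), n,
          dimnames = list(NULL, paste0("x", 1:10))
        )))
      )
    })
    attr(ft, "features") <- paste0("x", 1:10)
    class(ft) <- c("feature_table", class(ft))
    nrow(backward_stepwise_or(ft, paste0("x", 1:10)))
  }, numeric(1))
  # AIC keeps a noise feature when its deviance drop exceeds 2 (p ~ 0.157),
  # so about 1.6 of 10 survive on average; a strong excess signals a defect
  expect_lte(mean(retained), 2.5)
  expect_true(all(retained <= 4))
  # empty offer -> empty table
  ch <- ml_cohort()
  ft0 <- assemble_features(ch$phenotype, include = "clinical")
  expect_equal(nrow(backward_stepwise_or(ft0, character(0))), 0)
})

test_that("interaction features widen the table without altering originals", {
  ch <- ml_cohort()
  nm <- normalize_metabolites(ch$metabolites)
  ft <- assemble_features(ch$phenotype, nm)
  p0 <- length(attr(ft, "features"))
  wide <- interaction_features(ft, "statin")
  n_met <- length(attr(ft, "metabolite_features"))
  expect_equal(length(attr(wide, "features")), p0 + n_met)
  expect_equal(wide$met001, ft$met001)
  expect_equal(wide$statin_x_met001, wide$statin * wide$met001)
  # flag all zero -> interaction columns all zero
  ft0 <- ft
  ft0$statin <- 0L
  attr(ft0, "features") <- attr(ft, "features")
  attr(ft0, "metabolite_features") <- attr(ft, "metabolite_features")
  wide0 <- interaction_features(ft0, "statin")
  expect_true(all(wide0$statin_x_met001 == 0))
  # evaluation runs unchanged on the widened table
  ev <- train_and_evaluate(wide, attr(wide, "features"),
    scheme = "holdout", model = "lasso", seed = 2
  )
  expect_true(is.finite(ev$metrics$auc))
  expect_error(interaction_features(ft, "nonexistent"), "flag")
})

test_that("balanced subsampling trains on 1:1 classes and is reproducible", {
  ch <- ml_cohort(seed = 8, n = c(80, 80, 40))
  ft <- assemble_features(ch$phenotype, normalize_metabolites(ch$metabolites))
  a <- balance_experiments(ft, attr(ft, "features"),
    mode = "subsample_1to1", seed = 21, num_trees = 100
  )
  b <- balance_experiments(ft, attr(ft, "features"),
    mode = "subsample_1to1", seed = 21, num_trees = 100
  )
  expect_identical(a$predictions, b$predictions)
  expect_true(is.finite(a$metrics$auc))
})

test_that("matched sampling respects exact sex and the age caliper", {
  ch <- ml_cohort(seed = 15, n = c(100, 100, 50))
  ft <- assemble_features(ch$phenotype, normalize_metabolites(ch$metabolites))
  res <- balance_experiments(ft, attr(ft, "features"),
    mode = "match_age_sex", seed = 3, num_trees = 100
  )
  pairs <- res$matched_pairs
  expect_gt(nrow(pairs), 0)
  lookup <- function(id, col) ft[[col]][match(id, ft$subject_id)]
  expect_true(all(
    lookup(pairs$case_id, "male") == lookup(pairs$control_id, "male")
  ))
  expect_true(all(
    abs(lookup(pairs$case_id, "age") - lookup(pairs$control_id, "age")) <= 5
  ))
  # no control matched twice; validation never used in training
  expect_equal(anyDuplicated(pairs$control_id), 0)
  expect_equal(
    length(intersect(res$predictions$subject_id, pairs$control_id)), 0
  )
  expect_equal(
    length(intersect(res$predictions$subject_id, pairs$case_id)), 0
  )
})

test_that("calibration diagnostics match closed forms and recalibration helps", {
  withr::with_seed(30, {
    n <- 10000
    p <- runif(n, 0.05, 0.95)
    y <- rbinom(n, 1, p)
  })
  rep0 <- calibration_report(p, y)
  expect_lt(abs(rep0$slope - 1), 0.05)
  expect_lt(abs(rep0$brier - mean(p * (1 - p))), 0.01)

  # all predictions 0.5 on balanced labels: Brier = 0.25
  yb <- rep(c(0, 1), 50)
  expect_equal(
    calibration_report(rep(0.5, 100), yb)$brier, 0.25
  )

  # overconfident probabilities: slope < 1, recalibration moves it toward 1
  p_over <- stats::plogis(2 * stats::qlogis(p))
  rep_raw <- calibration_report(p_over, y)
  expect_lt(rep_raw$slope, 1)
  rep_platt <- calibration_report(p_over, y, recalibrate = "platt", seed = 4)
  expect_lt(abs(rep_platt$slope - 1), abs(rep_raw$slope - 1))
  expect_error(calibration_report(rep(0.5, 4), rep(1, 4)), "single-class")
})

test_that("an XGBoost grid search reports every combination with its AUC", {
  ch <- ml_cohort(seed = 22, n = c(30, 30, 30), n_met = 6, n_inf = 2)
  ft <- assemble_features(
    ch$phenotype, normalize_metabolites(ch$metabolites),
    include = "metabolites"
  )
  small_grid <- xgboost_grid()[c(1, 20, 75), ]
  ev <- train_and_evaluate(ft, attr(ft, "features"),
    scheme = "holdout", model = "xgboost", grid = small_grid, seed = 3
  )
  expect_equal(nrow(ev$grid_results), 3)
  expect_true(all(is.finite(ev$grid_results$auc)))
  expect_equal(
    ev$best_params$eta,
    ev$grid_results$eta[which.max(ev$grid_results$auc)]
  )
  expect_error(
    train_and_evaluate(ft, attr(ft, "features"),
      scheme = "cv", model = "xgboost", grid = small_grid, seed = 1
    ),
    "holdout"
  )
})
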