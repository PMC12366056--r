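test_that("separable blobs split perfectly with zero-ish inertia", {
  x <- rbind(
    matrix(0, 3, 2), matrix(10, 3, 2)
  )
  rownames(x) <- paste0("S", 1:6)
  colnames(x) <- c("a", "b")
  sol <- kmeans_fit(x, 2, seed = 1, compute_silhouette = FALSE)
  expect_equal(sol$inertia, 0)
  expect_equal(length(unique(sol$assignments$cluster[1:3])), 1)
  expect_equal(length(unique(sol$assignments$cluster[4:6])), 1)
  expect_false(sol$assignments$cluster[1] == sol$assignments$cluster[4])
})

test_that("fits are deterministic given the seed and reject bad input", {
  x <- blob_data(20, rbind(c(0, 0), c(5, 5), c(-5, 5)), seed = 4)
  a <- kmeans_fit(x, 3, seed = 7)
  b <- kmeans_fit(x, 3, seed = 7)
  expect_identical(a$assignments, b$assignments)
  expect_identical(a$inertia, b$inertia)
  expect_error(kmeans_fit(x, 1, seed = 1), "k")
  expect_error(kmeans_fit(x, nrow(x), seed = 1), "k")
  x2 <- x
  x2[1, 1] <- NA
  expect_error(kmeans_fit(x2, 2, seed = 1), "finite")
})

test_that("within-cluster SS never increases across Lloyd iterations", {
  for (seed in 1:5) {
    x <- blob_data(30, rbind(c(0, 0, 0), c(2, 0, 1), c(0, 3, 1)),
      sd = 1.5, seed = seed
    )
    sol <- kmeans_fit(x, 3, n_restarts = 3, seed = seed, compute_silhouette = FALSE)
    expect_true(all(diff(sol$wss_trace) <= 1e-8))
  }
})

test_that("final inertia is no worse than stats::kmeans on the same data", {
  x <- blob_data(40, rbind(c(0, 0), c(4, 0), c(0, 4), c(4, 4)), seed = 12)
  sol <- kmeans_fit(x, 4, n_restarts = 25, seed = 3, compute_silhouette = FALSE)
  ref <- withr::with_seed(3, suppressWarnings(stats::kmeans(x, 4, nstart = 25, algorithm = "Lloyd", iter.max = 100)))
  expect_lte(sol$inertia, ref$tot.withinss * (1 + 1e-8))
})

test_that("planted metabolite clusters are recovered almost perfectly", {
  cfg <- simulation_config(
    n_per_group = c(170, 170, 160), n_snps = 6, n_metabolites = 30,
    n_informative_features = 0, cluster_separation = 4,
    metabolite_missing_rate = 0, metabolite_zero_rate = 0, seed = 31
  )
  ch <- generate_cohort(cfg)
  nm <- normalize_metabolites(ch$metabolites)
  sol <- kmeans_fit(nm, 5, seed = 2, compute_silhouette = FALSE)
  truth <- ch$truth$subjects$metabolomic_cluster
  # adjusted agreement via best label matching on the confusion matrix
  jac <- compare_partitions(
    sol,
    structure(list(
      k = 5L,
      assignments = tibble::tibble(
        subject_id = ch$truth$subjects$subject_id,
        cluster = truth, silhouette = NA_real_
      )
    ), class = "cluster_solution")
  )
  agreement <- sum(vapply(seq_len(nrow(jac$pairs)), function(i) {
    sum(sol$assignments$cluster == jac$pairs$cluster_a[i] &
      truth == jac$pairs$cluster_b[i])
  }, numeric(1))) / length(truth)
  expect_gte(agreement, 0.9)
})

test_that("elbow scan picks the planted k on well-separated clusters", {
  centers <- 6 * rbind(
    c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 1, 0), c(0, 0, 0, 1), c(1, 1, 1, 1)
  )
  x <- blob_data(60, centers, seed = 9)
  curve <- elbow_scan(x, k_range = 2:9, n_restarts = 5, seed = 2)
  expect_equal(curve$selected_k, 5L)
  expect_false(curve$weak)
  expect_true(all(diff(curve$curve$inertia) <= 0))
})

test_that("a single Gaussian blob yields a weak elbow, and short ranges error", {
  x <- blob_data(200, matrix(0, 1, 4), seed = 5)
  curve <- elbow_scan(x, k_range = 2:8, n_restarts = 5, seed = 3)
  expect_true(curve$weak)
  expect_error(elbow_scan(x, k_range = 4), "at least 2")
})

test_that("identical partitions have Jaccard 1 for every cluster", {
  x <- blob_data(25, rbind(c(0, 0), c(8, 0), c(0, 8)), seed = 6)
  a <- kmeans_fit(x, 3, seed = 1, compute_silhouette = FALSE)
  rep <- compare_partitions(a, a)
  expect_true(all(rep$pairs$jaccard == 1))
  expect_equal(rep$min_jaccard, 1)
})

test_that("matched-pair Jaccard agrees with brute force over label matchings", {
  # brute-force oracle: maximize total Jaccard over all permutations, k <= 4
  brute_force_min_jaccard <- function(la, lb) {
    k <- max(la)
    jac <- matrix(0, k, k)
    for (i in seq_len(k)) {
      for (j in seq_len(k)) {
        a_set <- which(la == i)
        b_set <- which(lb == j)
        jac[i, j] <- length(intersect(a_set, b_set)) /
          length(union(a_set, b_set))
      }
    }
    perms <- function(v) {
      if (length(v) == 1) return(list(v))
      unlist(lapply(seq_along(v), function(i) {
        lapply(perms(v[-i]), function(p) c(v[i], p))
      }), recursive = FALSE)
    }
    best <- -Inf
    best_min <- NA
    for (p in perms(seq_len(k))) {
      s <- sum(jac[cbind(seq_len(k), p)])
      if (s > best) {
        best <- s
        best_min <- min(jac[cbind(seq_len(k), p)])
      }
    }
    best_min
  }
  withr::with_seed(8, {
    for (rep_i in 1:5) {
      n <- 60
      la <- sample(1:4, n, TRUE)
      lb <- la
      flip <- sample(n, 6)
      lb[flip] <- sample(1:4, 6, TRUE)
      mk <- function(lbl) {
        structure(list(
          k = 4L,
          assignments = tibble::tibble(
            subject_id = sprintf("S%02d", 1:n), cluster = lbl,
            silhouette = NA_real_
          )
        ), class = "cluster_solution")
      }
      rep <- compare_partitions(mk(la), mk(lb))
      expect_equal(rep$min_jaccard, brute_force_min_jaccard(la, lb),
        tolerance = 1e-12
      )
    }
  })
})

test_that("a partition against its random permutation has low min Jaccard", {
  withr::with_seed(14, {
    la <- rep(1:5, each = 100)
    lb <- sample(la)
  })
  mk <- function(lbl) {
    structure(list(
      k = 5L,
      assignments = tibble::tibble(
        subject_id = sprintf("S%03d", seq_along(lbl)), cluster = lbl,
        silhouette = NA_real_
      )
    ), class = "cluster_solution")
  }
  rep <- compare_partitions(mk(la), mk(lb))
  expect_lt(rep$min_jaccard, 0.4)
})

test_that("comparison is symmetric up to pair orientation", {
  x <- blob_data(30, rbind(c(0, 0), c(6, 0), c(0, 6)), sd = 2, seed = 3)
  a <- kmeans_fit(x, 3, seed = 1, compute_silhouette = FALSE)
  b <- kmeans_fit(x, 3, seed = 99, n_restarts = 1, compute_silhouette = FALSE)
  ab <- compare_partitions(a, b)
  ba <- compare_partitions(b, a)
  expect_equal(sort(ab$pairs$jaccard), sort(ba$pairs$jaccard), tolerance = 1e-12)
  expect_equal(ab$min_jaccard, ba$min_jaccard, tolerance = 1e-12)
})

test_that("heatmap ordering sorts by group, sex, then age, stably", {
  cohort <- toy_cohort(
    group = c("CAD", "control", "control", "high-risk", "control", "control"),
    sex = c("female", "male", "female", "female", "female", "female"),
    age = c(50, 45, 40, 30, 35, 35),
    ids = paste0("S", 1:6)
  )
  ord <- order_subjects_for_heatmap(cohort)
  expect_equal(ord$subject_id, c("S5", "S6", "S3", "S2", "S4", "S1"))
  # control male (S2) before CAD female (S1): group dominates
  expect_lt(which(ord$subject_id == "S2"), which(ord$subject_id == "S1"))
  # ties on all keys (S5, S6) preserve input order
  expect_lt(which(ord$subject_id == "S5"), which(ord$subject_id == "S6"))
  expect_error(order_subjects_for_heatmap(cohort[c("subject_id", "group")]), "sex")
})

test_that("coupled layers produce a significant cluster cross-tab", {
  cfg <- simulation_config(
    n_per_group = c(120, 120, 110), n_snps = 110, n_metabolites = 30,
    n_informative_features = 0, coupling_strength = 0.9, seed = 17
  )
  ch <- generate_cohort(cfg)
  nm <- normalize_metabolites(ch$metabolites)
  enc <- encode_genotypes(ch$genotypes)
  met_sol <- kmeans_fit(nm, 5, seed = 2, compute_silhouette = FALSE)
  gen_sol <- kmeans_fit(enc, 5, seed = 3, compute_silhouette = FALSE)
  en <- crosstab_enrichment(met_sol, gen_sol)
  expect_lt(glance(en)$p_value, 1e-6)
})
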