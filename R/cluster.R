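# K-means clustering of each omics layer, model-order selection, stability.

# k-means++ seeding (Arthur & Vassilvitskii): spread initial centers
# proportionally to squared distance from the nearest chosen center.
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  i <- sample.int(n, 1)
  centers[1, ] <- x[i, ]
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  for (j in seq_len(k)[-1]) {
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    i <- sample.int(n, 1, prob = prob)
    centers[j, ] <- x[i, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
  }
  centers
}

# Squared Euclidean distances of every row of x to every center.
dist2_to_centers <- function(x, centers) {
  cross <- x %*% t(centers)
  d2 <- outer(rowSums(x^2), rowSums(centers^2), "+") - 2 * cross
  pmax(d2, 0)
}

# Lloyd's algorithm from given centers. The within-cluster sum of squares is
# asserted non-increasing across iterations (a defining property of the
# assignment/update alternation).
lloyd <- function(x, centers, max_iter = 100) {
  wss_trace <- numeric(0)
  assign_old <- rep(0L, nrow(x))
  for (iter in seq_len(max_iter)) {
    d2 <- dist2_to_centers(x, centers)
    assignment <- max.col(-d2, ties.method = "first")
    # Re-seed empty clusters with the points farthest from their center
    empty <- setdiff(seq_len(nrow(centers)), unique(assignment))
    if (length(empty) > 0) {
      far <- order(d2[cbind(seq_len(nrow(x)), assignment)], decreasing = TRUE)
      for (e in seq_along(empty)) {
        centers[empty[e], ] <- x[far[e], ]
      }
      d2 <- dist2_to_centers(x, centers)
      assignment <- max.col(-d2, ties.method = "first")
    }
    wss <- sum(d2[cbind(seq_len(nrow(x)), assignment)])
    if (length(wss_trace) > 0 && wss > utils::tail(wss_trace, 1) + 1e-8) {
      abort("internal error: within-cluster SS increased across Lloyd iterations")
    }
    wss_trace <- c(wss_trace, wss)
    if (identical(assignment, assign_old)) break
    assign_old <- assignment
    for (j in seq_len(nrow(centers))) {
      centers[j, ] <- colMeans(x[assignment == j, , drop = FALSE])
    }
  }
  # Final inertia under the final centers
  d2 <- dist2_to_centers(x, centers)
  assignment <- max.col(-d2, ties.method = "first")
  inertia <- sum(d2[cbind(seq_len(nrow(x)), assignment)])
  list(
    assignment = assignment, centers = centers, inertia = inertia,
    wss_trace = wss_trace
  )
}

#' K-means clustering of an omics layer
#'
#' Best-of-restarts Lloyd's algorithm with k-means++ seeding and Euclidean
#' distance; deterministic given `seed`. Returns per-subject assignments,
#' centroids, inertia (within-cluster sum of squared distances) and
#' silhouette widths.
#'
#' @param x Tibble (subject_id + numeric features) or numeric matrix: a
#'   normalized metabolite matrix or encoded genotype matrix.
#' @param k Number of clusters (>= 2).
#' @param n_restarts Number of independent k-means++ starts; the lowest-
#'   inertia fit is kept. Default 25.
#' @param seed Integer seed for the restarts.
#' @param layer Optional label, e.g. `"metabolomic"` or `"genetic"`.
#' @param compute_silhouette Compute per-subject silhouette widths (requires
#'   the full distance matrix; disable for very large cohorts).
#' @return An object of class `cluster_solution`.
#' @export
kmeans_fit <- function(x, k, n_restarts = 25, seed = 1L, layer = NA_character_,
                       compute_silhouette = TRUE) {
  m <- feature_matrix(x)
  if (!all(is.finite(m))) abort("non-finite values in clustering input")
  if (k < 2) abort("k must be >= 2")
  if (k >= nrow(m)) abort("k must be smaller than the number of subjects")
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      fit <- lloyd(m, kmeanspp_init(m, k))
      if (is.null(best) || fit$inertia < best$inertia) best <- fit
    }
  })
  ids <- rownames(m) %||% as.character(seq_len(nrow(m)))
  sil_mean <- NA_real_
  sil <- rep(NA_real_, nrow(m))
  if (isTRUE(compute_silhouette)) {
    sw <- cluster::silhouette(best$assignment, stats::dist(m))
    sil <- sw[, "sil_width"]
    sil_mean <- mean(sil)
  }
  structure(
    list(
      k = as.integer(k),
      assignments = tibble(
        subject_id = ids, cluster = as.integer(best$assignment),
        silhouette = sil
      ),
      centroids = best$centers,
      inertia = best$inertia,
      silhouette = sil_mean,
      wss_trace = best$wss_trace,
      layer = layer,
      seed = as.integer(seed)
    ),
    class = "cluster_solution"
  )
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(
    "<cluster_solution>", if (!is.na(x$layer)) x$layer, "k =", x$k,
    "| inertia =", signif(x$inertia, 6),
    "| mean silhouette =", signif(x$silhouette, 3), "\n"
  )
  print(table(x$assignments$cluster))
  invisible(x)
}

#' @export
tidy.cluster_solution <- function(x, ...) x$assignments

#' @export
glance.cluster_solution <- function(x, ...) {
  tibble(
    k = x$k, inertia = x$inertia, silhouette = x$silhouette,
    layer = x$layer, seed = x$seed
  )
}

#' Elbow scan over candidate cluster counts
#'
#' Fits K-means for each k in `k_range` and selects the point of maximal
#' curvature of the inertia curve (largest second difference). When the
#' strongest curvature is small relative to the total inertia drop the
#' selection is flagged as a weak elbow.
#'
#' @inheritParams kmeans_fit
#' @param k_range Integer vector of candidate k (length >= 3 for curvature;
#'   length >= 2 accepted, length < 2 is an error).
#' @param weak_threshold Peakedness cutoff for the weak-elbow flag: the
#'   selection is flagged weak when the largest second difference is less
#'   than `weak_threshold` times the mean positive second difference (a
#'   smooth convex curve has ratio near 2; a genuine elbow spikes well
#'   above). Default 3.5.
#' @return An object of class `elbow_curve`: tibble (k, inertia), selected k,
#'   `weak` flag.
#' @export
elbow_scan <- function(x, k_range = 2:10, n_restarts = 10, seed = 1L,
                       weak_threshold = 3.5) {
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) < 2) abort("k_range must contain at least 2 values")
  fits <- map(seq_along(k_range), function(i) {
    kmeans_fit(x, k_range[i],
      n_restarts = n_restarts,
      seed = derive_seed(seed, paste0("elbow", k_range[i])),
      compute_silhouette = FALSE
    )
  })
  inertia <- map_dbl(fits, "inertia")
  # Best-of-restarts inertia should be non-increasing in k; enforce by
  # carrying forward the running minimum (protects against rare restart luck)
  inertia <- cummin(inertia)
  selected <- k_range[1]
  weak <- TRUE
  if (length(k_range) >= 3) {
    d2 <- diff(diff(inertia)) # positive at a convex elbow
    i <- which.max(d2)
    selected <- k_range[i + 1L]
    mean_pos <- mean(pmax(d2, 0))
    weak <- mean_pos <= 0 || max(d2) / mean_pos < weak_threshold
  }
  structure(
    list(
      curve = tibble(k = k_range, inertia = inertia),
      selected_k = as.integer(selected),
      weak = weak
    ),
    class = "elbow_curve"
  )
}

#' @export
print.elbow_curve <- function(x, ...) {
  cat(
    "<elbow_curve> selected k =", x$selected_k,
    if (x$weak) "(weak elbow)" else "", "\n"
  )
  print(x$curve, n = Inf)
  invisible(x)
}

#' @export
tidy.elbow_curve <- function(x, ...) x$curve

# All permutations of 1..n (n small) as a list of integer vectors.
permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- permutations(n - 1L)
  out <- vector("list", n * length(sub))
  idx <- 1L
  for (i in seq_len(n)) {
    for (p in sub) {
      q <- integer(n)
      q[1] <- i
      q[-1] <- setdiff(seq_len(n), i)[p]
      out[[idx]] <- q
      idx <- idx + 1L
    }
  }
  out
}

# Jaccard matrix between the clusters of two partitions (vectors of labels
# over the same subjects).
jaccard_matrix <- function(a, b) {
  la <- sort(unique(a))
  lb <- sort(unique(b))
  ct <- table(factor(a, la), factor(b, lb))
  sza <- rowSums(ct)
  szb <- colSums(ct)
  inter <- as.matrix(ct)
  inter / (outer(sza, szb, "+") - inter)
}

# Optimal one-to-one matching maximizing total Jaccard: exhaustive over
# permutations for small k, greedy otherwise.
match_clusters <- function(jac, exhaustive_max = 8L) {
  ka <- nrow(jac)
  kb <- ncol(jac)
  swap <- ka > kb
  if (swap) jac <- t(jac)
  n_small <- nrow(jac)
  n_big <- ncol(jac)
  if (n_big <= exhaustive_max) {
    best <- NULL
    best_sum <- -Inf
    for (p in permutations(n_big)) {
      cols <- p[seq_len(n_small)]
      s <- sum(jac[cbind(seq_len(n_small), cols)])
      if (s > best_sum) {
        best_sum <- s
        best <- cols
      }
    }
    pairs <- cbind(seq_len(n_small), best)
  } else {
    pairs <- matrix(0L, n_small, 2)
    used <- logical(n_big)
    ord <- order(apply(jac, 1, max), decreasing = TRUE)
    for (i in ord) {
      j <- which.max(ifelse(used, -Inf, jac[i, ]))
      pairs[i, ] <- c(i, j)
      used[j] <- TRUE
    }
  }
  if (swap) pairs <- pairs[, 2:1, drop = FALSE]
  pairs
}

#' Compare two cluster partitions (stability report)
#'
#' Matches the clusters of two solutions one-to-one by maximizing total
#' per-pair Jaccard similarity (exhaustive over label permutations for k <= 8)
#' and reports each matched pair's Jaccard |A n B| / |A u B|, the minimum
#' across pairs, and the full cross-tabulation.
#'
#' @param a,b `cluster_solution` objects over the same subjects.
#' @return An object of class `stability_report`: `pairs` tibble
#'   (cluster_a, cluster_b, jaccard), `min_jaccard`, `crosstab`.
#' @export
compare_partitions <- function(a, b) {
  stopifnot(inherits(a, "cluster_solution"), inherits(b, "cluster_solution"))
  check_same_subjects(a, b, "solution a", "solution b")
  bb <- b$assignments[match(a$assignments$subject_id, b$assignments$subject_id), ]
  la <- a$assignments$cluster
  lb <- bb$cluster
  jac <- jaccard_matrix(la, lb)
  pairs <- match_clusters(jac)
  pair_tbl <- tibble(
    cluster_a = as.integer(rownames(jac)[pairs[, 1]] %||% pairs[, 1]),
    cluster_b = as.integer(colnames(jac)[pairs[, 2]] %||% pairs[, 2]),
    jaccard = jac[pairs]
  )
  structure(
    list(
      pairs = arrange(pair_tbl, .data$cluster_a),
      min_jaccard = min(pair_tbl$jaccard),
      crosstab = table(cluster_a = la, cluster_b = lb)
    ),
    class = "stability_report"
  )
}

#' @export
print.stability_report <- function(x, ...) {
  cat("<stability_report> min Jaccard =", signif(x$min_jaccard, 4), "\n")
  print(x$pairs, n = Inf)
  invisible(x)
}

#' @export
tidy.stability_report <- function(x, ...) x$pairs

#' @export
glance.stability_report <- function(x, ...) {
  tibble(min_jaccard = x$min_jaccard, n_pairs = nrow(x$pairs))
}

#' Canonical subject ordering for heatmap display
#'
#' Stable sort by group (control < high-risk < CAD), then sex (female first),
#' then ascending age; ties keep the input order.
#'
#' @param cohort Phenotype tibble with `group`, `sex`, `age`.
#' @return The cohort tibble reordered.
#' @export
order_subjects_for_heatmap <- function(cohort) {
  for (col in c("group", "sex", "age")) {
    if (!col %in% names(cohort)) abort(paste0("missing required column: ", col))
  }
  g <- factor(cohort$group, levels = GROUP_LEVELS)
  s <- factor(cohort$sex, levels = c("female", "male"))
  if (anyNA(g) || anyNA(s) || anyNA(cohort$age)) {
    abort("group, sex and age must be non-missing for ordering")
  }
  cohort[order(as.integer(g), as.integer(s), cohort$age, method = "radix"), ]
}
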