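# Small fixtures built in code, shared across test files.

# Tiny genotype table from a named list of call vectors.
toy_genotypes <- function(calls, ids = NULL) {
  n <- length(calls[[1]])
  tibble::tibble(
    subject_id = ids %||% sprintf("S%02d", seq_len(n)),
    !!!calls
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Genotype column with given counts of hom_ref / het / hom_alt / missing.
geno_col <- function(n_rr, n_ra, n_aa, n_mis = 0) {
  c(
    rep("hom_ref", n_rr), rep("het", n_ra), rep("hom_alt", n_aa),
    rep(NA_character_, n_mis)
  )
}

# Minimal phenotype tibble.
toy_cohort <- function(group, sex = NULL, age = NULL, ids = NULL) {
  n <- length(group)
  tibble::tibble(
    subject_id = ids %||% sprintf("S%02d", seq_len(n)),
    group = factor(group, levels = c("control", "high-risk", "CAD")),
    sex = factor(sex %||% rep("female", n), levels = c("female", "male")),
    age = age %||% rep(50, n)
  )
}

# Metabolite tibble from a named list of numeric vectors.
toy_metabolites <- function(values, ids = NULL) {
  n <- length(values[[1]])
  tibble::tibble(
    subject_id = ids %||% sprintf("S%02d", seq_len(n)),
    !!!values
  )
}

# Well-separated Gaussian blobs for clustering tests.
blob_data <- function(n_per, centers, sd = 1, seed = 1) {
  withr::with_seed(seed, {
    m <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
      matrix(rnorm(n_per * ncol(centers), sd = sd), n_per) +
        matrix(centers[i, ], n_per, ncol(centers), byrow = TRUE)
    }))
    colnames(m) <- paste0("f", seq_len(ncol(m)))
    rownames(m) <- sprintf("S%04d", seq_len(nrow(m)))
    m
  })
}

# Independent Pearson chi-square oracle for any contingency table,
# structured differently from the implementation (explicit double loop).
chisq_oracle <- function(tab) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  stat <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      e <- sum(tab[i, ]) * sum(tab[, j]) / n
      if (e > 0) stat <- stat + (tab[i, j] - e)^2 / e
    }
  }
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(statistic = stat, p = stats::pchisq(stat, df, lower.tail = FALSE))
}
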