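# Internal helpers shared across the pipeline.

GENOTYPE_CODES <- c("hom_ref", "het", "hom_alt")

#' Derive a reproducible child seed from a root seed
#'
#' Each stochastic stage of the pipeline draws from its own stream, derived
#' deterministically from one root seed and a stage label, so that e.g. adding
#' SNPs to a simulation does not perturb the metabolite draws.
#'
#' @param seed Integer root seed.
#' @param salt Character stage label.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, salt) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(salt))
  m <- 2147483647 # 2^31 - 1, keeps the result a valid 32-bit R integer
  h <- 0
  for (ch in utf8ToInt(salt)) h <- (h * 131 + ch) %% m
  as.integer((abs(seed) %% m * 48271 + h) %% m)
}

# Run code under a fixed seed without touching the caller's RNG state.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Extract the numeric feature matrix from a tibble that may carry a
# subject_id column; rownames are subject ids when available.
feature_matrix <- function(x, id_col = "subject_id") {
  if (is.matrix(x)) return(x)
  stopifnot(is.data.frame(x))
  ids <- NULL
  if (id_col %in% names(x)) {
    ids <- as.character(x[[id_col]])
    x <- x[setdiff(names(x), id_col)]
  }
  bad <- names(x)[!vapply(x, is.numeric, logical(1))]
  if (length(bad) > 0) {
    abort(paste0("non-numeric feature columns: ", paste(bad, collapse = ", ")))
  }
  m <- as.matrix(x)
  if (!is.null(ids)) rownames(m) <- ids
  m
}

# Fail loudly when two subject-indexed objects do not share an identical
# subject index (same ids, same order not required but same set, no silent
# intersection).
check_same_subjects <- function(a, b, what_a = "a", what_b = "b") {
  ia <- subject_ids(a)
  ib <- subject_ids(b)
  if (length(ia) != length(ib) || !setequal(ia, ib)) {
    abort(sprintf(
      "subject index mismatch between %s (%d subjects) and %s (%d subjects)",
      what_a, length(ia), what_b, length(ib)
    ))
  }
  invisible(TRUE)
}

subject_ids <- function(x) {
  if (is.data.frame(x) && "subject_id" %in% names(x)) {
    return(as.character(x$subject_id))
  }
  if (inherits(x, "cluster_solution")) return(as.character(x$assignments$subject_id))
  if (is.matrix(x) && !is.null(rownames(x))) return(rownames(x))
  abort("cannot extract subject ids")
}

# Stratified train/validation index split; returns list(train=, validation=).
stratified_split <- function(y, prop_train = 0.8) {
  idx <- split(seq_along(y), y)
  train <- unlist(lapply(idx, function(i) {
    n_tr <- max(1L, round(length(i) * prop_train))
    if (n_tr >= length(i)) n_tr <- length(i) - 1L
    sample(i, n_tr)
  }), use.names = FALSE)
  list(train = sort(train), validation = sort(setdiff(seq_along(y), train)))
}

# Stratified k-fold assignment (class proportions preserved); returns an
# integer fold label per observation.
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    i <- which(y == cls)
    fold[i] <- sample(rep_len(seq_len(k), length(i)))
  }
  fold
}

`%||%` <- rlang::`%||%`
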