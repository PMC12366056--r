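# Metabolite normalization and SNP QC / encoding.

#' Median/log2 normalization of metabolite concentrations
#'
#' Per metabolite, in order: (1) missing values are imputed with the median of
#' the observed values; (2) exact zeros are replaced with 0.001 so the log
#' transform is defined; (3) each value is divided by the metabolite's median,
#' recomputed after steps 1-2 so the divisor reflects the matrix actually
#' transformed; (4) log2. The per-metabolite medians used as divisors are
#' retained in the `scaling` attribute.
#'
#' The transform is scale-equivariant: multiplying a metabolite's raw values
#' by any c > 0 leaves the output unchanged.
#'
#' @param metabolites Tibble: subject_id + non-negative numeric metabolite
#'   columns (missing allowed).
#' @return A tibble of the same shape with attributes `method`
#'   (`"median_log2"`) and `scaling` (tibble: metabolite, median).
#' @export
normalize_metabolites <- function(metabolites) {
  m <- feature_matrix(metabolites)
  if (nrow(m) < 2) abort("need at least 2 subjects")
  med <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    obs <- v[!is.na(v)]
    if (length(obs) == 0) {
      abort(paste0("metabolite ", colnames(m)[j], " is entirely missing"))
    }
    if (!any(obs > 0)) {
      abort(paste0(
        "metabolite ", colnames(m)[j], " has no observed positive value"
      ))
    }
    v[is.na(v)] <- median(obs)
    v[v == 0] <- 0.001
    med[j] <- median(v)
    stopifnot(med[j] > 0) # guaranteed after zero substitution
    m[, j] <- log2(v / med[j])
  }
  out <- bind_cols(
    tibble(subject_id = as.character(metabolites$subject_id)),
    as_tibble(as.data.frame(m))
  )
  attr(out, "method") <- "median_log2"
  attr(out, "scaling") <- tibble(metabolite = colnames(m), median = med)
  out
}

#' Unit-variance scaling of a feature matrix
#'
#' Each column is mean-centered and divided by its sample standard deviation,
#' the standard pre-treatment for OPLS-DA (centering is required for the
#' Hotelling ellipse). Constant columns are an error.
#'
#' @param x Tibble: subject_id + numeric feature columns (no missing values).
#' @return A tibble of the same shape with attributes `method`
#'   (`"unit_variance"`) and `scaling` (tibble: feature, mean, sd).
#' @export
unit_variance_scale <- function(x) {
  m <- feature_matrix(x)
  if (anyNA(m)) abort("unit_variance_scale requires a complete matrix")
  mu <- colMeans(m)
  s <- apply(m, 2, sd)
  zero <- s <= 0
  if (any(zero)) {
    abort(paste0(
      "zero-variance feature(s): ",
      paste(head(colnames(m)[zero], 5), collapse = ", ")
    ))
  }
  m <- sweep(sweep(m, 2, mu), 2, s, "/")
  out <- bind_cols(
    tibble(subject_id = as.character(x$subject_id)),
    as_tibble(as.data.frame(m))
  )
  attr(out, "method") <- "unit_variance"
  attr(out, "scaling") <- tibble(feature = colnames(m), mean = unname(mu), sd = unname(s))
  out
}

# Alt-allele dose matrix (0/1/2, NA missing) from a genotype-call tibble or
# an encoded {0, 0.5, 1} tibble.
genotype_dose <- function(genotypes) {
  snps <- setdiff(names(genotypes), "subject_id")
  first <- genotypes[[snps[1]]]
  if (is.numeric(first)) {
    d <- 2 * feature_matrix(genotypes)
  } else {
    map <- c(hom_ref = 0, het = 1, hom_alt = 2)
    d <- vapply(snps, function(s) unname(map[genotypes[[s]]]), numeric(nrow(genotypes)))
    if (nrow(genotypes) == 1L) d <- matrix(d, nrow = 1, dimnames = list(NULL, snps))
    rownames(d) <- as.character(genotypes$subject_id)
  }
  d
}

# Chi-square goodness-of-fit test of Hardy-Weinberg proportions (1 df) on
# genotype counts c(n_hom_ref, n_het, n_hom_alt).
hwe_chisq <- function(counts) {
  n <- sum(counts)
  if (n == 0) {
    return(c(statistic = NA_real_, p = NA_real_))
  }
  p_alt <- (counts[3] * 2 + counts[2]) / (2 * n)
  expected <- n * c((1 - p_alt)^2, 2 * p_alt * (1 - p_alt), p_alt^2)
  if (p_alt == 0 || p_alt == 1) {
    return(c(statistic = 0, p = 1)) # monomorphic: fits trivially
  }
  stat <- sum((counts - expected)^2 / expected)
  c(statistic = stat, p = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Sequential SNP quality control
#'
#' Filters SNPs sequentially on minor allele frequency, deviation from
#' Hardy-Weinberg equilibrium in the controls (1-df goodness-of-fit
#' chi-square), and missing rate, in that order; a SNP failing several
#' filters is attributed to the first failing one. MAF is computed from
#' observed allele counts across all subjects.
#'
#' @param genotypes Tibble of genotype calls (subject_id + SNP columns).
#' @param controls Character vector of control subject ids (HWE is tested in
#'   controls only).
#' @param maf_min Minimum minor allele frequency (exclusive); default 0.01.
#' @param hwe_p_min Minimum HWE p-value in controls; default 1e-6.
#' @param missing_max Maximum missing-call rate; default 0.10.
#' @return A list with `genotypes` (the retained SNPs) and `report` (class
#'   `snp_qc_report`: per-SNP tibble of maf, hwe_p, missing_rate, pass,
#'   reason; plus filter counts).
#' @export
snp_qc <- function(genotypes, controls, maf_min = 0.01, hwe_p_min = 1e-6,
                   missing_max = 0.10) {
  controls <- as.character(controls)
  if (length(controls) == 0) abort("controls must be non-empty")
  missing_ctl <- setdiff(controls, genotypes$subject_id)
  if (length(missing_ctl) > 0) {
    abort(paste0(
      "control ids absent from genotypes: ",
      paste(head(missing_ctl, 5), collapse = ", ")
    ))
  }
  dose <- genotype_dose(genotypes)
  is_ctl <- genotypes$subject_id %in% controls

  n_obs <- colSums(!is.na(dose))
  alt <- colSums(dose, na.rm = TRUE)
  p_alt <- ifelse(n_obs > 0, alt / (2 * n_obs), NA_real_)
  maf <- pmin(p_alt, 1 - p_alt)
  missing_rate <- colMeans(is.na(dose))

  ctl <- dose[is_ctl, , drop = FALSE]
  hwe <- vapply(seq_len(ncol(ctl)), function(j) {
    v <- ctl[, j]
    hwe_chisq(c(
      sum(v == 0, na.rm = TRUE), sum(v == 1, na.rm = TRUE),
      sum(v == 2, na.rm = TRUE)
    ))
  }, numeric(2))

  reason <- rep(NA_character_, ncol(dose))
  reason[maf < maf_min | is.na(maf)] <- "maf"
  hwe_fail <- is.na(reason) & !is.na(hwe[2, ]) & hwe[2, ] < hwe_p_min
  reason[hwe_fail] <- "hwe"
  reason[is.na(reason) & missing_rate > missing_max] <- "missing_rate"

  per_snp <- tibble(
    snp_id = colnames(dose),
    maf = unname(maf),
    hwe_p = unname(hwe[2, ]),
    missing_rate = unname(missing_rate),
    pass = is.na(reason),
    reason = reason
  )
  kept <- per_snp$snp_id[per_snp$pass]
  if (length(kept) == 0) warn("all SNPs removed by QC")
  counts <- c(
    n_input = ncol(dose),
    n_removed_maf = sum(reason == "maf", na.rm = TRUE),
    n_removed_hwe = sum(reason == "hwe", na.rm = TRUE),
    n_removed_missing_rate = sum(reason == "missing_rate", na.rm = TRUE),
    n_retained = length(kept)
  )
  report <- structure(
    list(per_snp = per_snp, counts = counts,
         thresholds = c(maf_min = maf_min, hwe_p_min = hwe_p_min,
                        missing_max = missing_max)),
    class = "snp_qc_report"
  )
  list(
    genotypes = genotypes[c("subject_id", kept)],
    report = report
  )
}

#' @export
print.snp_qc_report <- function(x, ...) {
  cat("<snp_qc_report>\n")
  print(x$counts)
  invisible(x)
}

#' @export
glance.snp_qc_report <- function(x, ...) {
  as_tibble(as.list(x$counts))
}

#' @export
tidy.snp_qc_report <- function(x, ...) x$per_snp

#' Encode genotype calls as {0, 0.5, 1} and impute missing calls
#'
#' Maps `hom_ref` -> 0, `het` -> 0.5, `hom_alt` -> 1. Each missing cell is
#' imputed with the per-SNP median of the observed encoded values, snapped to
#' the nearest member of {0, 0.5, 1}; ties snap to 0.5.
#'
#' @param genotypes Tibble of genotype calls (QC already applied).
#' @return A tibble: subject_id + numeric columns with values in {0, 0.5, 1}
#'   and no missing cells.
#' @export
encode_genotypes <- function(genotypes) {
  dose <- genotype_dose(genotypes) / 2
  for (j in seq_len(ncol(dose))) {
    v <- dose[, j]
    if (all(is.na(v))) {
      abort(paste0("SNP ", colnames(dose)[j], " has no observed calls"))
    }
    if (anyNA(v)) {
      med <- median(v, na.rm = TRUE)
      legal <- c(0, 0.5, 1)
      d <- abs(legal - med)
      nearest <- legal[d == min(d)]
      fill <- if (length(nearest) > 1) 0.5 else nearest
      v[is.na(v)] <- fill
      dose[, j] <- v
    }
  }
  bind_cols(
    tibble(subject_id = as.character(genotypes$subject_id)),
    as_tibble(as.data.frame(dose))
  )
}
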