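# Per-SNP case-control association, candidate selection, proportion test.

#' Allelic case-control chi-square association
#'
#' For each SNP, builds the 2x2 allele-count table (two alleles per subject;
#' missing calls excluded), computes the 1-df Pearson chi-square without
#' continuity correction, the allelic odds ratio with a 95% confidence
#' interval (Haldane-Anscombe 0.5 correction when any cell is zero), and the
#' Bonferroni-adjusted p-value over all tested SNPs. SNPs monomorphic in both
#' groups get p = 1 and an undefined-OR flag.
#'
#' @param genotypes Genotype-call tibble or encoded {0, 0.5, 1} tibble
#'   (subject_id + SNP columns).
#' @param cases,controls Character vectors of subject ids.
#' @param snp_info Optional SNP metadata tibble (snp_id, chrom, pos, ref,
#'   alt) merged into the result.
#' @param adj_p_max,or_rule Candidate rule: Bonferroni-adjusted p below
#'   `adj_p_max` and OR satisfying `or_rule` (`"gt1_or_lt0.5"`, the printed
#'   asymmetric rule, or `"gt2_or_lt0.5"`).
#' @return An `association_result` tibble: per SNP the allele counts
#'   (case_alt, case_ref, control_alt, control_ref), chisq, p, or, or_low,
#'   or_high, p_adj, monomorphic, candidate.
#' @export
allelic_chi_square <- function(genotypes, cases, controls, snp_info = NULL,
                               adj_p_max = 1e-7,
                               or_rule = c("gt1_or_lt0.5", "gt2_or_lt0.5")) {
  or_rule <- match.arg(or_rule)
  cases <- as.character(cases)
  controls <- as.character(controls)
  if (length(cases) == 0 || length(controls) == 0) {
    abort("cases and controls must be non-empty")
  }
  if (length(intersect(cases, controls)) > 0) {
    abort("cases and controls overlap")
  }
  dose <- genotype_dose(genotypes)
  i_case <- genotypes$subject_id %in% cases
  i_ctl <- genotypes$subject_id %in% controls

  count_alleles <- function(d) {
    n_obs <- colSums(!is.na(d))
    alt <- colSums(d, na.rm = TRUE)
    cbind(alt = alt, ref = 2 * n_obs - alt)
  }
  cs <- count_alleles(dose[i_case, , drop = FALSE])
  ct <- count_alleles(dose[i_ctl, , drop = FALSE])
  a <- cs[, "alt"]
  b <- cs[, "ref"]
  c_ <- ct[, "alt"]
  d_ <- ct[, "ref"]

  n <- a + b + c_ + d_
  num <- n * (a * d_ - b * c_)^2
  den <- (a + b) * (c_ + d_) * (a + c_) * (b + d_)
  chisq <- ifelse(den > 0, num / den, NA_real_)
  mono <- (a + c_ == 0) | (b + d_ == 0)
  chisq[mono] <- 0
  p <- pchisq(chisq, df = 1, lower.tail = FALSE)
  p[mono] <- 1

  # Haldane-Anscombe correction for the OR/CI when any cell is zero
  any_zero <- a == 0 | b == 0 | c_ == 0 | d_ == 0
  a2 <- a + 0.5 * any_zero
  b2 <- b + 0.5 * any_zero
  c2 <- c_ + 0.5 * any_zero
  d2 <- d_ + 0.5 * any_zero
  or <- (a2 * d2) / (b2 * c2)
  se <- sqrt(1 / a2 + 1 / b2 + 1 / c2 + 1 / d2)
  z <- qnorm(0.975)
  or_low <- exp(log(or) - z * se)
  or_high <- exp(log(or) + z * se)
  or[mono] <- NA_real_
  or_low[mono] <- NA_real_
  or_high[mono] <- NA_real_

  m <- ncol(dose)
  res <- tibble(
    snp_id = colnames(dose),
    case_alt = unname(a), case_ref = unname(b),
    control_alt = unname(c_), control_ref = unname(d_),
    chisq = unname(chisq), p = unname(p),
    or = unname(or), or_low = unname(or_low), or_high = unname(or_high),
    p_adj = pmin(1, unname(p) * m),
    monomorphic = unname(mono)
  )
  res$candidate <- !res$monomorphic & res$p_adj < adj_p_max &
    or_passes(res$or, or_rule)
  if (!is.null(snp_info)) {
    res <- left_join(res, snp_info, by = "snp_id")
    res <- relocate(res, dplyr::any_of(c("chrom", "pos", "ref", "alt")),
      .after = "snp_id"
    )
    res <- arrange(res, .data$chrom, .data$pos)
  }
  class(res) <- c("association_result", class(res))
  res
}

or_passes <- function(or, rule) {
  switch(rule,
    "gt1_or_lt0.5" = !is.na(or) & (or > 1 | or < 0.5),
    "gt2_or_lt0.5" = !is.na(or) & (or > 2 | or < 0.5)
  )
}

#' Bonferroni significance threshold
#'
#' @param alpha Family-wise error rate (e.g. 0.05).
#' @param n_candidates Number of tests.
#' @return A tibble: alpha, n_candidates, threshold = alpha / n_candidates.
#' @export
bonferroni_threshold <- function(alpha, n_candidates) {
  if (alpha <= 0 || n_candidates < 1) abort("alpha and n_candidates must be positive")
  tibble(
    alpha = alpha, n_candidates = as.integer(n_candidates),
    threshold = alpha / n_candidates
  )
}

#' Select candidate SNPs from an association result
#'
#' SNPs with Bonferroni-adjusted p below `adj_p_max` and odds ratio passing
#' the rule, ordered by (chromosome, position) when positions are present.
#'
#' @param results An `association_result`.
#' @inheritParams allelic_chi_square
#' @return Character vector of SNP ids (possibly empty).
#' @export
select_candidates <- function(results, adj_p_max = 1e-7,
                              or_rule = c("gt1_or_lt0.5", "gt2_or_lt0.5")) {
  or_rule <- match.arg(or_rule)
  sel <- results[!results$monomorphic & results$p_adj < adj_p_max &
    or_passes(results$or, or_rule), ]
  if (all(c("chrom", "pos") %in% names(sel))) {
    sel <- arrange(sel, .data$chrom, .data$pos)
  }
  sel$snp_id
}

#' Two-proportion z-test (pooled variance)
#'
#' @param successes_a,n_a Successes and trials in group a.
#' @param successes_b,n_b Successes and trials in group b.
#' @return A tibble: p_a, p_b, statistic (z), p_value (two-sided).
#' @export
proportion_test <- function(successes_a, n_a, successes_b, n_b) {
  if (n_a <= 0 || n_b <= 0) abort("group sizes must be positive")
  p1 <- successes_a / n_a
  p2 <- successes_b / n_b
  pool <- (successes_a + successes_b) / (n_a + n_b)
  se <- sqrt(pool * (1 - pool) * (1 / n_a + 1 / n_b))
  z <- if (se == 0) 0 else (p1 - p2) / se
  tibble(
    p_a = p1, p_b = p2, statistic = z,
    p_value = 2 * pnorm(-abs(z))
  )
}

#' Manhattan-plot-ready table
#'
#' Columns chromosome, position, -log10(p), candidate flag, and a cumulative
#' genome coordinate for plotting; rows sorted by chromosome then position.
#' Underflowing p-values (p = 0) are capped at `log10p_cap` and flagged.
#'
#' @param results An `association_result` carrying `chrom` and `pos`.
#' @param log10p_cap Cap for -log10(p). Default 320.
#' @return A tibble.
#' @export
manhattan_table <- function(results, log10p_cap = 320) {
  if (!all(c("chrom", "pos") %in% names(results))) {
    abort("results must carry chrom and pos (pass snp_info to allelic_chi_square)")
  }
  key <- suppressWarnings(as.numeric(results$chrom))
  res <- results[order(is.na(key), key, results$chrom, results$pos), ]
  neglog <- -log10(res$p)
  capped <- !is.finite(neglog) | neglog > log10p_cap
  neglog[capped] <- log10p_cap
  offsets <- c(0, cumsum(as.numeric(tapply(res$pos, match(res$chrom, unique(res$chrom)), max))))
  tibble(
    snp_id = res$snp_id,
    chrom = res$chrom,
    pos = res$pos,
    neg_log10_p = neglog,
    capped = capped,
    candidate = res$candidate,
    genome_pos = res$pos + offsets[match(res$chrom, unique(res$chrom))]
  )
}
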