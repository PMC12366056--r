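# Intersection of the metabolomic and genetic cluster solutions into
# subtypes, enrichment testing, and rule-based five-SNP haplotype calling.

# Pearson chi-square on a contingency table, no continuity correction.
pearson_chisq <- function(tab) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  ok <- expected > 0
  stat <- sum((tab[ok] - expected[ok])^2 / expected[ok])
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  if (df <= 0) {
    return(c(statistic = 0, df = 0, p = 1)) # degenerate one-row/one-column table
  }
  c(statistic = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE))
}

#' Cross-tabulation enrichment between two cluster solutions
#'
#' Builds the full k x k cross-tab of the two partitions with the omnibus
#' Pearson chi-square, and, for every (cluster a, cluster b) pair, the 2x2
#' collapse (in/out of each cluster) with its chi-square p-value, the
#' standardized Pearson residual of the cell, and Bonferroni adjustment over
#' all tested pairs.
#'
#' @param a,b `cluster_solution` objects over the same subjects (e.g.
#'   metabolomic and genetic layers).
#' @return An object of class `enrichment_result`: `crosstab`, `omnibus`
#'   (statistic, df, p), and `pairs` tibble (cluster_a, cluster_b, observed,
#'   expected, std_residual, chisq, p, p_adj).
#' @export
crosstab_enrichment <- function(a, b) {
  stopifnot(inherits(a, "cluster_solution"), inherits(b, "cluster_solution"))
  check_same_subjects(a, b, "solution a", "solution b")
  bb <- b$assignments[match(a$assignments$subject_id, b$assignments$subject_id), ]
  la <- a$assignments$cluster
  lb <- bb$cluster
  tab <- table(cluster_a = la, cluster_b = lb)
  omnibus <- pearson_chisq(tab)
  n <- sum(tab)
  rs <- rowSums(tab)
  cs <- colSums(tab)
  pairs <- tidyr::expand_grid(
    i = seq_len(nrow(tab)), j = seq_len(ncol(tab))
  )
  pair_stats <- pmap(pairs, function(i, j) {
    o <- tab[i, j]
    two_by_two <- matrix(c(
      o, rs[i] - o,
      cs[j] - o, n - rs[i] - cs[j] + o
    ), 2, 2, byrow = TRUE)
    ch <- pearson_chisq(two_by_two)
    e <- rs[i] * cs[j] / n
    std_res <- (o - e) / sqrt(e * (1 - rs[i] / n) * (1 - cs[j] / n))
    tibble(
      cluster_a = as.integer(rownames(tab)[i]),
      cluster_b = as.integer(colnames(tab)[j]),
      observed = as.integer(o), expected = e, std_residual = std_res,
      chisq = ch[["statistic"]], p = ch[["p"]]
    )
  })
  pair_tbl <- bind_rows(pair_stats)
  pair_tbl$p_adj <- pmin(1, pair_tbl$p * nrow(pair_tbl))
  structure(
    list(crosstab = tab, omnibus = omnibus, pairs = pair_tbl),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(
    "<enrichment_result> omnibus chisq =", signif(x$omnibus[["statistic"]], 5),
    "df =", x$omnibus[["df"]], "p =", format(x$omnibus[["p"]], digits = 3), "\n"
  )
  print(x$crosstab)
  invisible(x)
}

#' @export
tidy.enrichment_result <- function(x, ...) x$pairs

#' @export
glance.enrichment_result <- function(x, ...) {
  tibble(
    statistic = x$omnibus[["statistic"]], df = x$omnibus[["df"]],
    p_value = x$omnibus[["p"]]
  )
}

#' Subtype rules from enrichment residuals
#'
#' For each targeted metabolomic cluster, selects the genetic clusters whose
#' standardized residual in the cross-tab exceeds `residual_min` — the
#' automated analogue of pairing each metabolomic cluster with its enriched
#' genetic clusters. Rules can also be written by hand (see
#' [assign_subtypes()]).
#'
#' @param enrichment An `enrichment_result` (metabolomic clusters as layer a,
#'   genetic as layer b).
#' @param met_clusters Metabolomic clusters to build rules for (one subtype
#'   per cluster, named Subtype-I, Subtype-II, ... in the order given).
#' @param residual_min Standardized-residual cutoff. Default 2.
#' @return A tibble of rules: subtype, met_cluster, gen_clusters (list col).
#' @export
derive_subtype_rules <- function(enrichment, met_clusters, residual_min = 2) {
  stopifnot(inherits(enrichment, "enrichment_result"))
  rules <- imap(met_clusters, function(mc, i) {
    gens <- enrichment$pairs |>
      filter(.data$cluster_a == mc, .data$std_residual > residual_min) |>
      pull("cluster_b")
    tibble(
      subtype = paste0("Subtype-", utils::as.roman(i)),
      met_cluster = mc,
      gen_clusters = list(gens)
    )
  })
  bind_rows(rules)
}

#' Assign genetic-metabolic subtypes from a pair of cluster solutions
#'
#' A subject matching (metabolomic cluster, genetic cluster) of one rule gets
#' that rule's subtype; everyone else is `unassigned`. Rules must be
#' disjoint: no (met, gen) pair may be claimed by two rules.
#'
#' @param met,gen `cluster_solution` objects over the same subjects.
#' @param rules Tibble with columns subtype, met_cluster, gen_clusters
#'   (list-column of integer vectors), e.g. from [derive_subtype_rules()].
#' @return A tibble: subject_id, met_cluster, gen_cluster, subtype (factor
#'   with `unassigned` last).
#' @export
assign_subtypes <- function(met, gen, rules) {
  check_same_subjects(met, gen, "metabolomic solution", "genetic solution")
  pairs_claimed <- list()
  for (r in seq_len(nrow(rules))) {
    for (g in rules$gen_clusters[[r]]) {
      key <- paste(rules$met_cluster[r], g)
      if (key %in% names(pairs_claimed)) {
        abort(paste0(
          "overlapping subtype rules: cluster pair (", key,
          ") claimed by ", pairs_claimed[[key]], " and ", rules$subtype[r]
        ))
      }
      pairs_claimed[[key]] <- rules$subtype[r]
    }
  }
  gg <- gen$assignments[match(met$assignments$subject_id, gen$assignments$subject_id), ]
  key <- paste(met$assignments$cluster, gg$cluster)
  subtype <- vapply(key, function(k) pairs_claimed[[k]] %||% "unassigned", "")
  tibble(
    subject_id = met$assignments$subject_id,
    met_cluster = met$assignments$cluster,
    gen_cluster = gg$cluster,
    subtype = factor(unname(subtype),
      levels = c(unique(rules$subtype), "unassigned")
    )
  )
}

#' The published five-SNP haplotype panel
#'
#' SNP ids with ref/alt alleles of the LPCAT1 block used for rule-based
#' haplotype calling: rs36993 (A>G), rs9799949 (C>T), rs10475026 (A>C),
#' rs1032751 (T>C), rs1032752 (G>A). The first SNP is the one whose
#' homozygous-alternate state, combined with homozygous reference at the
#' other four, defines haplotype 2.
#'
#' @return A tibble: snp_id, ref, alt, hap2_state.
#' @export
lpcat1_panel <- function() {
  tibble(
    snp_id = c("rs36993", "rs9799949", "rs10475026", "rs1032751", "rs1032752"),
    ref = c("A", "C", "A", "T", "G"),
    alt = c("G", "T", "C", "C", "A"),
    hap2_state = c("hom_alt", "hom_ref", "hom_ref", "hom_ref", "hom_ref")
  )
}

#' Rule-based haplotype calling over a five-SNP panel
#'
#' Haplotype 3: homozygous alternate at all five SNPs. Haplotype 2:
#' homozygous reference at four SNPs plus homozygous alternate at the
#' designated fifth (the panel's `hap2_state` column). Everything else —
#' including any subject with a missing call in the panel, conservatively —
#' is haplotype 1 (wild type); such subjects carry a missing-data flag.
#'
#' @param genotypes Genotype-call tibble (subject_id + SNP columns).
#' @param panel Panel definition as from [lpcat1_panel()]: tibble with
#'   snp_id and hap2_state (exactly 5 SNPs, all present in `genotypes`).
#' @return A tibble: subject_id, haplotype (integer 1/2/3), missing_panel
#'   (logical).
#' @export
call_haplotypes <- function(genotypes, panel = lpcat1_panel()) {
  if (nrow(panel) != 5) abort("panel must contain exactly 5 SNPs")
  absent <- setdiff(panel$snp_id, names(genotypes))
  if (length(absent) > 0) {
    abort(paste0(
      "panel SNP(s) absent from genotypes: ", paste(absent, collapse = ", ")
    ))
  }
  calls <- as.matrix(as.data.frame(genotypes[panel$snp_id]))
  missing_panel <- rowSums(is.na(calls)) > 0
  is3 <- !missing_panel & rowSums(calls == "hom_alt") == 5
  hap2_pattern <- matrix(panel$hap2_state,
    nrow(calls), 5,
    byrow = TRUE
  )
  is2 <- !missing_panel & rowSums(calls == hap2_pattern) == 5
  tibble(
    subject_id = as.character(genotypes$subject_id),
    haplotype = ifelse(is3, 3L, ifelse(is2, 2L, 1L)),
    missing_panel = missing_panel
  )
}

#' Haplotype frequencies by clinical group
#'
#' Per-group haplotype frequency table (fractions of each group carrying each
#' haplotype), the reverse conditioning (per-haplotype group shares), and the
#' Pearson chi-square test of haplotype x group.
#'
#' @param calls Haplotype calls from [call_haplotypes()].
#' @param cohort Phenotype tibble with subject_id and group.
#' @return An object of class `haplotype_frequencies`: `by_group` tibble
#'   (group, haplotype, n, frequency), `by_haplotype` tibble (haplotype,
#'   group, n, share), `test` (statistic, df, p_value).
#' @export
haplotype_group_frequencies <- function(calls, cohort) {
  check_same_subjects(calls, cohort, "haplotype calls", "cohort")
  joined <- left_join(calls, cohort[c("subject_id", "group")], by = "subject_id")
  if (any(table(joined$group) == 0)) abort("every group must be non-empty")
  tab <- table(
    haplotype = factor(joined$haplotype, levels = 1:3),
    group = factor(joined$group, levels = GROUP_LEVELS)
  )
  keep <- rowSums(tab) > 0
  test <- pearson_chisq(tab[keep, , drop = FALSE])
  by_group <- as_tibble(as.data.frame(tab, responseName = "n")) |>
    group_by(.data$group) |>
    mutate(frequency = .data$n / sum(.data$n)) |>
    ungroup() |>
    mutate(haplotype = as.integer(as.character(.data$haplotype))) |>
    select("group", "haplotype", "n", "frequency")
  by_haplotype <- as_tibble(as.data.frame(tab, responseName = "n")) |>
    group_by(.data$haplotype) |>
    mutate(share = if (sum(.data$n) > 0) .data$n / sum(.data$n) else NA_real_) |>
    ungroup() |>
    mutate(haplotype = as.integer(as.character(.data$haplotype))) |>
    select("haplotype", "group", "n", "share")
  structure(
    list(
      by_group = by_group,
      by_haplotype = by_haplotype,
      test = tibble(
        statistic = test[["statistic"]], df = test[["df"]],
        p_value = test[["p"]]
      )
    ),
    class = "haplotype_frequencies"
  )
}

#' @export
print.haplotype_frequencies <- function(x, ...) {
  cat(
    "<haplotype_frequencies> chisq =", signif(x$test$statistic, 4),
    "p =", format(x$test$p_value, digits = 3), "\n"
  )
  print(tidyr::pivot_wider(x$by_group[c("group", "haplotype", "frequency")],
    names_from = "haplotype", values_from = "frequency",
    names_prefix = "hap"
  ))
  invisible(x)
}

#' @export
tidy.haplotype_frequencies <- function(x, ...) x$by_group

#' @export
glance.haplotype_frequencies <- function(x, ...) x$test
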