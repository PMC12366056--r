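# Assembly of the modelling feature table from the omics layers.

#' Assemble the modelling feature table
#'
#' Joins normalized metabolites, clinical covariates, medication flags,
#' haplotype indicators and (optionally) candidate-SNP encodings into one
#' complete numeric table with a binary response. The full-cohort task codes
#' CAD = 1 against control + high-risk = 0; the `highrisk_vs_cad` task keeps
#' only the high-risk and CAD groups.
#'
#' @param cohort Phenotype tibble (subject_id, group, sex, age, ...).
#' @param metabolites Normalized metabolite tibble (subject_id + features),
#'   e.g. from [normalize_metabolites()]. Optional.
#' @param haplotypes Haplotype calls from [call_haplotypes()]; enter the
#'   model as two indicators (hap2, hap3) against the haplotype-1 baseline.
#'   Optional.
#' @param snp_encodings Encoded candidate-SNP tibble from
#'   [encode_genotypes()]. Optional.
#' @param task `"cad_vs_rest"` or `"highrisk_vs_cad"`.
#' @param include Character subset of
#'   `c("clinical", "medications", "metabolites", "haplotype", "snps")`
#'   selecting which blocks enter the table.
#' @return A `feature_table` tibble: subject_id, response (integer 0/1), and
#'   numeric feature columns; the feature names are in attribute `features`,
#'   the metabolite subset in attribute `metabolite_features`.
#' @export
assemble_features <- function(cohort, metabolites = NULL, haplotypes = NULL,
                              snp_encodings = NULL,
                              task = c("cad_vs_rest", "highrisk_vs_cad"),
                              include = c(
                                "clinical", "medications", "metabolites",
                                "haplotype", "snps"
                              )) {
  task <- match.arg(task)
  include <- match.arg(include, several.ok = TRUE)
  if (!"group" %in% names(cohort) || anyNA(cohort$group)) {
    abort("cohort must carry a non-missing group column")
  }
  out <- tibble(
    subject_id = as.character(cohort$subject_id),
    group = factor(cohort$group, levels = GROUP_LEVELS)
  )
  met_features <- character(0)

  if ("clinical" %in% include) {
    clin <- cohort[intersect(c("age", "bmi"), names(cohort))]
    if ("sex" %in% names(cohort)) {
      clin$male <- as.integer(cohort$sex == "male")
    }
    out <- bind_cols(out, clin)
  }
  if ("medications" %in% include) {
    meds <- intersect(
      c("statin", "fibrate", "ccb", "beta_blocker", "arb", "diuretics"),
      names(cohort)
    )
    for (mcol in meds) out[[mcol]] <- as.integer(cohort[[mcol]])
  }
  if ("metabolites" %in% include && !is.null(metabolites)) {
    check_same_subjects(cohort, metabolites, "cohort", "metabolites")
    met <- metabolites[match(out$subject_id, metabolites$subject_id), ]
    met_features <- setdiff(names(met), "subject_id")
    out <- bind_cols(out, met[met_features])
  }
  if ("haplotype" %in% include && !is.null(haplotypes)) {
    check_same_subjects(cohort, haplotypes, "cohort", "haplotypes")
    hap <- haplotypes[match(out$subject_id, haplotypes$subject_id), ]
    out$hap2 <- as.integer(hap$haplotype == 2L)
    out$hap3 <- as.integer(hap$haplotype == 3L)
  }
  if ("snps" %in% include && !is.null(snp_encodings)) {
    check_same_subjects(cohort, snp_encodings, "cohort", "snp_encodings")
    snp <- snp_encodings[match(out$subject_id, snp_encodings$subject_id), ]
    out <- bind_cols(out, snp[setdiff(names(snp), "subject_id")])
  }

  if (task == "highrisk_vs_cad") {
    keep <- out$group %in% c("high-risk", "CAD")
    out <- out[keep, ]
  }
  out$response <- as.integer(out$group == "CAD")
  out$group <- NULL
  out <- relocate(out, "subject_id", "response")
  feats <- setdiff(names(out), c("subject_id", "response"))
  if (anyDuplicated(feats)) abort("duplicate feature names")
  incomplete <- !complete.cases(out[feats])
  if (any(incomplete)) {
    abort(paste0(
      sum(incomplete), " subject(s) with missing feature values; ",
      "normalize/impute the inputs first"
    ))
  }
  attr(out, "features") <- feats
  attr(out, "metabolite_features") <- met_features
  attr(out, "task") <- task
  class(out) <- c("feature_table", class(out))
  out
}

feature_names <- function(ft) {
  attr(ft, "features") %||% setdiff(names(ft), c("subject_id", "response"))
}

#' Add statin-by-metabolite interaction features
#'
#' Adds one product column `<flag>_x_<metabolite>` per target metabolite;
#' original columns are retained.
#'
#' @param ft A `feature_table`.
#' @param flag Name of a binary feature column (default `"statin"`).
#' @param targets Metabolite columns to interact; defaults to the table's
#'   metabolite features.
#' @return The widened `feature_table`.
#' @export
interaction_features <- function(ft, flag = "statin", targets = NULL) {
  if (!flag %in% names(ft)) abort(paste0("flag column not found: ", flag))
  fv <- ft[[flag]]
  if (!all(fv %in% c(0, 1))) abort(paste0(flag, " must be binary 0/1"))
  targets <- targets %||% attr(ft, "metabolite_features")
  if (length(targets) == 0) abort("no target metabolite features")
  missing_t <- setdiff(targets, names(ft))
  if (length(missing_t) > 0) {
    abort(paste0("target(s) not in table: ", paste(missing_t, collapse = ", ")))
  }
  atts <- attributes(ft)
  for (tcol in targets) {
    ft[[paste0(flag, "_x_", tcol)]] <- fv * ft[[tcol]]
  }
  attr(ft, "features") <- c(atts$features, paste0(flag, "_x_", targets))
  attr(ft, "metabolite_features") <- atts$metabolite_features
  attr(ft, "task") <- atts$task
  class(ft) <- unique(c("feature_table", class(ft)))
  ft
}
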