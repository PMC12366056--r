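# Readers and writers for the standard formats the pipeline touches.
# Coordinates are 1-based throughout, as in VCF.

#' Read a VCF file into a genotype table
#'
#' Reads a biallelic VCF 4.2 file (GT field) and returns per-subject genotype
#' calls. `0/0` maps to `hom_ref`, `0/1` or `1/0` to `het`, `1/1` to
#' `hom_alt`, and `./.` to `NA`; the phasing separator (`|` vs `/`) is
#' ignored. Multiallelic records and duplicate SNP ids are rejected.
#'
#' @param path Path to a VCF file.
#' @return A list with `genotypes` (tibble: subject_id + one character column
#'   per SNP) and `snp_info` (tibble: snp_id, chrom, pos, ref, alt).
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    abort(paste0(
      "multiallelic record(s) not supported: ",
      paste(head(fix$ID[multi], 5), collapse = ", ")
    ))
  }
  if (anyDuplicated(fix$ID)) {
    abort(paste0(
      "duplicate SNP id(s): ",
      paste(head(unique(fix$ID[duplicated(fix$ID)]), 5), collapse = ", ")
    ))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt[] <- gsub("|", "/", gt, fixed = TRUE)
  bad <- !is.na(gt) & !gt %in% c("0/0", "0/1", "1/0", "1/1", "./.")
  if (any(bad)) {
    recs <- unique(rownames(gt)[which(bad, arr.ind = TRUE)[, 1]])
    abort(paste0(
      "unsupported GT value(s) at record(s): ",
      paste(head(recs, 5), collapse = ", ")
    ))
  }
  map <- c(
    "0/0" = "hom_ref", "0/1" = "het", "1/0" = "het",
    "1/1" = "hom_alt", "./." = NA_character_
  )
  calls <- matrix(map[gt],
    nrow = nrow(gt),
    dimnames = list(rownames(gt), colnames(gt))
  )
  geno <- as_tibble(t(calls))
  geno <- bind_cols(tibble(subject_id = colnames(gt)), geno)
  snp_info <- tibble(
    snp_id = fix$ID,
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT
  )
  validate_snp_info(snp_info)
  list(genotypes = geno, snp_info = snp_info)
}

validate_snp_info <- function(snp_info) {
  if (anyDuplicated(snp_info$snp_id)) abort("duplicate SNP ids in metadata")
  ok <- grepl("^[ACGT]$", snp_info$ref) & grepl("^[ACGT]$", snp_info$alt)
  if (!all(ok)) {
    abort(paste0(
      "non single-nucleotide alleles for: ",
      paste(head(snp_info$snp_id[!ok], 5), collapse = ", ")
    ))
  }
  invisible(snp_info)
}

#' Write genotype calls as a minimal VCF 4.2 file
#'
#' GT-only writer mirroring [read_vcf()]: `hom_ref` -> `0/0`, `het` -> `0/1`,
#' `hom_alt` -> `1/1`, missing -> `./.`.
#'
#' @param genotypes Tibble: subject_id + one character column per SNP.
#' @param snp_info Tibble: snp_id, chrom, pos, ref, alt.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(genotypes, snp_info, path) {
  snps <- setdiff(names(genotypes), "subject_id")
  stopifnot(setequal(snps, snp_info$snp_id))
  validate_snp_info(snp_info)
  map <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1")
  body <- vapply(snp_info$snp_id, function(s) {
    gt <- map[genotypes[[s]]]
    gt[is.na(gt)] <- "./."
    paste(gt, collapse = "\t")
  }, "")
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(
      c(
        "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
        "FORMAT", genotypes$subject_id
      ),
      collapse = "\t"
    ),
    paste(snp_info$chrom, snp_info$pos, snp_info$snp_id, snp_info$ref,
      snp_info$alt, ".", ".", ".", "GT", body,
      sep = "\t"
    )
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a phenotype table
#'
#' TSV/CSV with a header row; delimiter chosen from the file extension.
#' Requires unique `subject_id` and a non-missing `group` column with levels
#' control / high-risk / CAD. Empty cells become missing values.
#'
#' @param path File path (`.tsv`/`.txt` tab-separated, `.csv` comma-separated).
#' @return A tibble.
#' @export
read_phenotype <- function(path) {
  x <- read_delim_auto(path)
  for (col in c("subject_id", "group")) {
    if (!col %in% names(x)) abort(paste0("missing required column: ", col))
  }
  if (anyDuplicated(x$subject_id)) abort("duplicate subject_id values")
  if (anyNA(x$group)) abort("group must be non-missing")
  bad <- setdiff(unique(x$group), GROUP_LEVELS)
  if (length(bad) > 0) {
    abort(paste0("unknown group label(s): ", paste(bad, collapse = ", ")))
  }
  x$subject_id <- as.character(x$subject_id)
  x$group <- factor(x$group, levels = GROUP_LEVELS)
  if ("sex" %in% names(x)) x$sex <- factor(x$sex, levels = c("female", "male"))
  x
}

#' Read a metabolite concentration matrix
#'
#' Subjects x metabolites, concentrations in uM; empty cells are missing (not
#' zero); negative values are rejected.
#'
#' @inheritParams read_phenotype
#' @return A tibble with `subject_id` and numeric metabolite columns.
#' @export
read_metabolites <- function(path) {
  x <- read_delim_auto(path)
  if (!"subject_id" %in% names(x)) abort("missing required column: subject_id")
  if (anyDuplicated(x$subject_id)) abort("duplicate subject_id values")
  x$subject_id <- as.character(x$subject_id)
  feats <- setdiff(names(x), "subject_id")
  if (anyDuplicated(feats)) abort("duplicate metabolite names")
  for (f in feats) {
    x[[f]] <- as.numeric(x[[f]])
    v <- x[[f]]
    if (any(!is.na(v) & (v < 0 | !is.finite(v)))) {
      abort(paste0("metabolite ", f, " has negative or non-finite values"))
    }
  }
  x
}

#' Read a genotype matrix stored as TSV
#'
#' Mirror of the TSV written by [write_cohort()]: subject_id plus one column
#' per SNP with calls `hom_ref`/`het`/`hom_alt` (empty = missing).
#'
#' @inheritParams read_phenotype
#' @return A tibble of genotype calls.
#' @export
read_genotype_tsv <- function(path) {
  x <- read_delim_auto(path)
  if (!"subject_id" %in% names(x)) abort("missing required column: subject_id")
  x$subject_id <- as.character(x$subject_id)
  snps <- setdiff(names(x), "subject_id")
  for (s in snps) {
    v <- as.character(x[[s]])
    bad <- !is.na(v) & !v %in% GENOTYPE_CODES
    if (any(bad)) abort(paste0("invalid genotype call in SNP ", s))
    x[[s]] <- v
  }
  x
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::read_delim(path, delim = delim, show_col_types = FALSE, progress = FALSE)
}

#' Write an analysis result to TSV
#'
#' Generic serializer: every tabular result type in the package writes to a
#' TSV with a documented header and a deterministic row order. Numeric fields
#' survive a round trip to 12 significant digits or better.
#'
#' @param object A result object (tibble, association table, cluster
#'   solution, feature ranking, ...).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(object, path) {
  UseMethod("write_results")
}

#' @export
write_results.data.frame <- function(object, path) {
  ord <- intersect(c("chrom", "pos", "snp_id", "subject_id", "feature"), names(object))
  if (length(ord) > 0) {
    object <- arrange(object, across(dplyr::all_of(ord)))
  }
  readr::write_tsv(as_tibble(object), path)
  invisible(path)
}

#' @export
write_results.cluster_solution <- function(object, path) {
  readr::write_tsv(arrange(object$assignments, .data$subject_id), path)
  invisible(path)
}

#' @export
write_results.feature_ranking <- function(object, path) {
  readr::write_tsv(tidy(object), path)
  invisible(path)
}

#' @export
write_results.model_evaluation <- function(object, path) {
  readr::write_tsv(object$metrics, path)
  invisible(path)
}

#' @export
write_results.opls_model <- function(object, path) {
  readr::write_tsv(object$scores, path)
  invisible(path)
}
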