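#' Run the full trans-omics pipeline on a cohort
#'
#' End-to-end convenience wrapper: metabolite normalization, SNP QC and
#' encoding, K-means clustering of both layers, cluster cross-tab enrichment
#' and subtype assignment, haplotype calling with group frequencies,
#' case-control association, consensus feature selection and a final
#' cross-validated model evaluation on the top-ranked features.
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()], or a list
#'   with the same elements (`phenotype`, `metabolites`, `genotypes`,
#'   `snp_info`) assembled from files via the `read_*` functions.
#' @param k Number of clusters per layer. Default 5.
#' @param panel Haplotype panel (see [call_haplotypes()]); `NULL` skips
#'   haplotype calling.
#' @param B Consensus-selection iterations. Default 100.
#' @param top_k Features carried into the final model. Default 16.
#' @param seed Integer root seed.
#' @param num_trees Random-forest size for selection/evaluation.
#' @return A list with the intermediate results: `normalized`, `qc`,
#'   `encoded`, `clusters` (metabolomic, genetic), `enrichment`, `subtypes`,
#'   `haplotypes`, `haplotype_frequencies`, `association`, `ranking`,
#'   `evaluation`.
#' @export
run_pipeline <- function(cohort, k = 5, panel = lpcat1_panel(), B = 100,
                         top_k = 16, seed = 1L, num_trees = 200) {
  normalized <- normalize_metabolites(cohort$metabolites)
  controls <- cohort$phenotype$subject_id[cohort$phenotype$group == "control"]
  cases <- cohort$phenotype$subject_id[cohort$phenotype$group == "CAD"]
  qc <- snp_qc(cohort$genotypes, controls = controls)
  encoded <- encode_genotypes(qc$genotypes)

  assoc <- allelic_chi_square(qc$genotypes,
    cases = cases, controls = controls,
    snp_info = cohort$snp_info[cohort$snp_info$snp_id %in%
      setdiff(names(qc$genotypes), "subject_id"), ]
  )

  met_clusters <- kmeans_fit(normalized,
    k = k, seed = derive_seed(seed, "met"),
    layer = "metabolomic", compute_silhouette = nrow(normalized) <= 2000
  )
  gen_clusters <- kmeans_fit(encoded,
    k = k, seed = derive_seed(seed, "gen"),
    layer = "genetic", compute_silhouette = nrow(encoded) <= 2000
  )
  enrichment <- crosstab_enrichment(met_clusters, gen_clusters)

  haplotypes <- NULL
  hap_freq <- NULL
  if (!is.null(panel) && all(panel$snp_id %in% names(cohort$genotypes))) {
    haplotypes <- call_haplotypes(cohort$genotypes, panel)
    hap_freq <- haplotype_group_frequencies(haplotypes, cohort$phenotype)
  }

  ft <- assemble_features(cohort$phenotype, normalized, haplotypes)
  ranking <- consensus_select(ft,
    B = B, seed = derive_seed(seed, "consensus"),
    num_trees = num_trees
  )
  features <- top_k_features(ranking, min(top_k, nrow(ranking$counts)))
  evaluation <- train_and_evaluate(ft, features,
    scheme = "cv", model = "rf",
    seed = derive_seed(seed, "eval"), num_trees = num_trees
  )

  list(
    normalized = normalized, qc = qc$report, encoded = encoded,
    clusters = list(metabolomic = met_clusters, genetic = gen_clusters),
    enrichment = enrichment,
    subtypes = tryCatch(
      assign_subtypes(
        met_clusters, gen_clusters,
        derive_subtype_rules(enrichment, met_clusters = seq_len(min(2, k)))
      ),
      error = function(e) NULL
    ),
    haplotypes = haplotypes, haplotype_frequencies = hap_freq,
    association = assoc, ranking = ranking, evaluation = evaluation
  )
}
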