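#' Configuration for the synthetic cohort generator
#'
#' Defines the statistical structure of a simulated three-group
#' (control / high-risk / CAD) cohort with a metabolomics layer and a SNP
#' layer: group sizes, a five-SNP haplotype block whose all-alternate-
#' homozygous diplotype rises in frequency across groups, latent clusters in
#' both omics layers coupled with a configurable probability, a set of
#' metabolites with a monotone group-wise mean shift, and missing-data rates.
#'
#' @param n_per_group Integer vector of length 3: subjects in the control,
#'   high-risk and CAD groups. Defaults to the 271/363/147 cohort structure.
#' @param n_snps Total number of SNPs, including the five haplotype-block SNPs.
#' @param n_metabolites Number of metabolites (concentrations in uM).
#' @param haplotype_snps Character vector of 5 SNP ids forming the block.
#' @param hap3_freq Per-group target frequency (fractions) of the
#'   all-alternate-homozygous diplotype (haplotype 3), control/high-risk/CAD.
#' @param hap2_freq Per-group target frequency of the haplotype-2 diplotype
#'   (homozygous reference at four block SNPs, homozygous alternate at the
#'   fifth).
#' @param n_informative_features Number of metabolites given a monotone mean
#'   shift across control -> high-risk -> CAD.
#' @param effect_size Standardized mean shift per group step (log2 scale, in
#'   units of the within-group SD) applied to informative metabolites.
#' @param n_clusters Number of latent clusters planted in each omics layer.
#' @param cluster_separation Centroid shift (in within-cluster SDs) of each
#'   latent cluster on its marker metabolites.
#' @param snps_per_cluster Number of cluster-marker SNPs per genetic latent
#'   cluster (allele frequency elevated within the cluster).
#' @param metabolite_missing_rate,metabolite_zero_rate Fractions of metabolite
#'   cells set missing / set to exactly zero.
#' @param snp_missing_rate Fraction of non-block genotype calls set missing.
#' @param coupling_strength Probability that a subject's metabolomic latent
#'   cluster equals its genetic latent cluster.
#' @param seed Integer root seed; stage-specific child streams are derived
#'   from it with [derive_seed()].
#'
#' @return An object of class `simulation_config` (a named list).
#' @export
simulation_config <- function(n_per_group = c(271, 363, 147),
                              n_snps = 500,
                              n_metabolites = 143,
                              haplotype_snps = c(
                                "rs36993", "rs9799949", "rs10475026",
                                "rs1032751", "rs1032752"
                              ),
                              hap3_freq = c(0.1333, 0.1928, 0.2721),
                              hap2_freq = c(0.10, 0.06, 0.02),
                              n_informative_features = 10,
                              effect_size = 1.5,
                              n_clusters = 5,
                              cluster_separation = 4,
                              snps_per_cluster = 20,
                              metabolite_missing_rate = 0.01,
                              metabolite_zero_rate = 0.005,
                              snp_missing_rate = 0.02,
                              coupling_strength = 0.9,
                              seed = 1L) {
  cfg <- list(
    n_per_group = as.integer(n_per_group),
    n_snps = as.integer(n_snps),
    n_metabolites = as.integer(n_metabolites),
    haplotype_snps = as.character(haplotype_snps),
    hap3_freq = as.numeric(hap3_freq),
    hap2_freq = as.numeric(hap2_freq),
    n_informative_features = as.integer(n_informative_features),
    effect_size = as.numeric(effect_size),
    n_clusters = as.integer(n_clusters),
    cluster_separation = as.numeric(cluster_separation),
    snps_per_cluster = as.integer(snps_per_cluster),
    metabolite_missing_rate = as.numeric(metabolite_missing_rate),
    metabolite_zero_rate = as.numeric(metabolite_zero_rate),
    snp_missing_rate = as.numeric(snp_missing_rate),
    coupling_strength = as.numeric(coupling_strength),
    seed = as.integer(seed)
  )
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  if (length(cfg$n_per_group) != 3 || any(cfg$n_per_group <= 0)) {
    abort("n_per_group must be 3 positive integers")
  }
  if (length(cfg$haplotype_snps) != 5) {
    abort("haplotype block must contain exactly 5 SNPs")
  }
  if (length(cfg$hap3_freq) != 3 || length(cfg$hap2_freq) != 3) {
    abort("hap2_freq and hap3_freq must have one target per group")
  }
  fr <- c(
    cfg$hap3_freq, cfg$hap2_freq, cfg$metabolite_missing_rate,
    cfg$metabolite_zero_rate, cfg$snp_missing_rate, cfg$coupling_strength
  )
  if (any(fr < 0 | fr > 1)) abort("all fractions must lie in [0, 1]")
  if (any(cfg$hap2_freq + cfg$hap3_freq > 1)) {
    abort("hap2_freq + hap3_freq must not exceed 1 in any group")
  }
  if (cfg$n_informative_features > cfg$n_metabolites) {
    abort("n_informative_features must not exceed n_metabolites")
  }
  if (cfg$n_informative_features < 0) abort("n_informative_features must be >= 0")
  if (cfg$n_snps < 5) abort("n_snps must be at least 5 (the haplotype block)")
  if (cfg$n_clusters < 1) abort("n_clusters must be >= 1")
  invisible(cfg)
}

#' Read / write a simulation configuration as YAML
#'
#' @param path File path.
#' @return `read_simulation_config()` returns a `simulation_config`;
#'   `write_simulation_config()` returns `path` invisibly.
#' @export
read_simulation_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(simulation_config, vals)
}

#' @rdname read_simulation_config
#' @param config A `simulation_config`.
#' @export
write_simulation_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

GROUP_LEVELS <- c("control", "high-risk", "CAD")

#' Generate a synthetic trans-omics cohort
#'
#' Simulates a three-group cohort with the structure the downstream analysis
#' assumes: a phenotype table, a subjects x metabolites concentration matrix
#' (log-normal, with latent-cluster structure, group-shifted informative
#' features, missing values and zeros), and a subjects x SNPs genotype matrix
#' containing a five-SNP haplotype block generated at the diplotype level,
#' cluster-marker SNPs carrying the genetic latent clusters, and independent
#' background SNPs at random minor allele frequencies in [0.05, 0.5].
#'
#' @param config A [simulation_config()].
#' @return An object of class `synthetic_cohort`: a list with elements
#'   `phenotype` (tibble), `metabolites` (tibble, subject_id + one column per
#'   metabolite), `genotypes` (tibble, subject_id + one character column per
#'   SNP with values `hom_ref`/`het`/`hom_alt`/`NA`), `snp_info` (tibble:
#'   snp_id, chrom, pos, ref, alt), and `truth` (list: per-subject latent
#'   clusters and planted haplotype, informative feature names, cluster-marker
#'   maps).
#' @export
generate_cohort <- function(config) {
  validate_simulation_config(config)
  cfg <- config
  n <- sum(cfg$n_per_group)
  group <- factor(rep(GROUP_LEVELS, cfg$n_per_group), levels = GROUP_LEVELS)
  subject_id <- sprintf("S%04d", seq_len(n))

  phenotype <- with_seed(derive_seed(cfg$seed, "phenotype"), {
    simulate_phenotype(subject_id, group)
  })

  clusters <- with_seed(derive_seed(cfg$seed, "clusters"), {
    gc <- sample.int(cfg$n_clusters, n, replace = TRUE)
    same <- runif(n) < cfg$coupling_strength
    mc <- ifelse(same, gc, sample.int(cfg$n_clusters, n, replace = TRUE))
    list(genetic = gc, metabolomic = as.integer(mc))
  })

  gen <- with_seed(derive_seed(cfg$seed, "genotypes"), {
    simulate_genotypes(cfg, group, clusters$genetic)
  })

  met <- with_seed(derive_seed(cfg$seed, "metabolites"), {
    simulate_metabolites(cfg, group, clusters$metabolomic)
  })

  truth <- list(
    subjects = tibble(
      subject_id = subject_id,
      group = group,
      genetic_cluster = clusters$genetic,
      metabolomic_cluster = clusters$metabolomic,
      haplotype = gen$haplotype
    ),
    informative_features = met$informative,
    metabolite_cluster_markers = met$markers,
    snp_cluster_markers = gen$markers
  )

  structure(
    list(
      phenotype = phenotype,
      metabolites = bind_cols(tibble(subject_id = subject_id), met$data),
      genotypes = bind_cols(tibble(subject_id = subject_id), gen$calls),
      snp_info = gen$snp_info,
      truth = truth,
      config = cfg
    ),
    class = "synthetic_cohort"
  )
}

# Clinical covariates are cosmetic (group-specific normals/Bernoullis with
# plausible means) unless used by matched-sampling experiments.
simulate_phenotype <- function(subject_id, group) {
  n <- length(subject_id)
  g <- as.integer(group)
  age_mean <- c(56.3, 65.7, 63.8)[g]
  age_sd <- c(14.4, 10.6, 10.1)[g]
  bmi_mean <- c(23.6, 27.4, 27.6)[g]
  p_male <- c(0.354, 0.416, 0.741)[g]
  p_statin <- c(0.066, 0.237, 0.714)[g]
  p_fibrate <- c(0.001, 0.028, 0.027)[g]
  p_ccb <- c(0.004, 0.196, 0.211)[g]
  p_bblocker <- c(0.074, 0.127, 0.320)[g]
  p_arb <- c(0.015, 0.251, 0.293)[g]
  p_diuretics <- c(0.018, 0.061, 0.109)[g]
  tibble(
    subject_id = subject_id,
    group = group,
    sex = factor(ifelse(runif(n) < p_male, "male", "female"),
      levels = c("female", "male")
    ),
    age = round(pmax(20, rnorm(n, age_mean, age_sd)), 1),
    bmi = round(pmax(15, rnorm(n, bmi_mean, 4)), 1),
    statin = runif(n) < p_statin,
    fibrate = runif(n) < p_fibrate,
    ccb = runif(n) < p_ccb,
    beta_blocker = runif(n) < p_bblocker,
    arb = runif(n) < p_arb,
    diuretics = runif(n) < p_diuretics
  )
}

# Haplotype block rendered from a per-subject 3-class diplotype draw:
# class 3 -> hom_alt at all five block SNPs; class 2 -> hom_ref at four,
# hom_alt at the first (rs36993-like) SNP; class 1 -> per-SNP random
# genotypes, resampled if they collide with the two defining patterns.
simulate_genotypes <- function(cfg, group, genetic_cluster) {
  n <- length(group)
  g <- as.integer(group)
  k <- cfg$n_clusters

  # Per-subject diplotype class for the block
  u <- runif(n)
  p3 <- cfg$hap3_freq[g]
  p2 <- cfg$hap2_freq[g]
  hap <- ifelse(u < p3, 3L, ifelse(u < p3 + p2, 2L, 1L))

  block <- matrix("", n, 5)
  block[hap == 3L, ] <- "hom_alt"
  block[hap == 2L, ] <- rep(c("hom_alt", rep("hom_ref", 4)),
    each = sum(hap == 2L)
  )
  n1 <- sum(hap == 1L)
  if (n1 > 0) {
    draw_other <- function(m) {
      matrix(
        sample(GENOTYPE_CODES, m * 5, replace = TRUE, prob = c(0.5, 0.35, 0.15)),
        m, 5
      )
    }
    b1 <- draw_other(n1)
    repeat {
      is3 <- rowSums(b1 == "hom_alt") == 5
      is2 <- b1[, 1] == "hom_alt" & rowSums(b1[, -1, drop = FALSE] == "hom_ref") == 4
      bad <- which(is3 | is2)
      if (length(bad) == 0) break
      b1[bad, ] <- draw_other(length(bad))
    }
    block[hap == 1L, ] <- b1
  }

  # Cluster-marker SNPs: elevated alt-allele frequency within the own cluster
  n_marker <- min(cfg$snps_per_cluster * k, cfg$n_snps - 5L)
  marker_cluster <- rep_len(seq_len(k), n_marker)
  marker <- matrix("", n, n_marker)
  if (n_marker > 0) {
    f <- matrix(0.15, n, n_marker)
    f[outer(genetic_cluster, marker_cluster, "==")] <- 0.7
    dose <- matrix(rbinom(n * n_marker, 2, as.vector(f)), n, n_marker)
    marker[] <- GENOTYPE_CODES[dose + 1L]
  }

  # Background SNPs: independent, MAF ~ U(0.05, 0.5), HWE proportions
  n_bg <- cfg$n_snps - 5L - n_marker
  bg <- matrix("", n, max(n_bg, 0))
  if (n_bg > 0) {
    maf <- runif(n_bg, 0.05, 0.5)
    dose <- matrix(
      rbinom(n * n_bg, 2, rep(maf, each = n)),
      n, n_bg
    )
    bg[] <- GENOTYPE_CODES[dose + 1L]
  }

  calls <- cbind(block, marker, bg)
  snp_id <- c(
    cfg$haplotype_snps,
    if (n_marker > 0) sprintf("snpc%04d", seq_len(n_marker)),
    if (n_bg > 0) sprintf("snpb%05d", seq_len(n_bg))
  )
  colnames(calls) <- snp_id

  # Inject missing calls outside the haplotype block so the planted
  # haplotype ground truth stays exact.
  if (cfg$snp_missing_rate > 0 && ncol(calls) > 5) {
    rest <- calls[, -(1:5), drop = FALSE]
    miss <- runif(length(rest)) < cfg$snp_missing_rate
    rest[miss] <- NA_character_
    calls[, -(1:5)] <- rest
  }

  nucleotides <- c("A", "C", "G", "T")
  ref <- sample(nucleotides, length(snp_id), replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(nucleotides, r), 1), "")
  # The block mirrors the published LPCAT1 panel alleles and lives on chr5.
  ref[1:5] <- c("A", "C", "A", "T", "G")
  alt[1:5] <- c("G", "T", "C", "C", "A")
  snp_info <- tibble(
    snp_id = snp_id,
    chrom = c(rep("5", 5), sample(as.character(1:22), length(snp_id) - 5, TRUE)),
    pos = NA_integer_,
    ref = unname(ref),
    alt = unname(alt)
  )
  snp_info$pos[1:5] <- 1461000L + 1000L * (0:4)
  other <- which(is.na(snp_info$pos))
  snp_info$pos[other] <- as.integer(sample.int(5e7, length(other)))

  list(
    calls = as_tibble(as.data.frame(calls, stringsAsFactors = FALSE)),
    snp_info = snp_info,
    haplotype = hap,
    markers = tibble(snp_id = snp_id[5 + seq_len(n_marker)], cluster = marker_cluster)
  )
}

# Metabolite concentrations are log-normal: effects act additively on the
# log2 scale (multiplicative noise), matching the positivity of measured
# concentrations and the later log2 transform.
simulate_metabolites <- function(cfg, group, metabolomic_cluster) {
  n <- length(group)
  p <- cfg$n_metabolites
  k <- cfg$n_clusters
  met_names <- sprintf("met%03d", seq_len(p))

  baseline <- rnorm(p, mean = 5, sd = 1) # log2 uM
  marker_cluster <- rep_len(seq_len(k), p)
  shift_cluster <- cfg$cluster_separation *
    (matrix(marker_cluster, n, p, byrow = TRUE) == metabolomic_cluster)

  step <- as.integer(group) - 1L # 0 / 1 / 2
  informative <- head(met_names, cfg$n_informative_features)
  shift_group <- matrix(0, n, p)
  if (cfg$n_informative_features > 0) {
    shift_group[, seq_len(cfg$n_informative_features)] <-
      outer(step, rep(cfg$effect_size, cfg$n_informative_features))
  }

  log2_conc <- matrix(baseline, n, p, byrow = TRUE) + shift_cluster +
    shift_group + matrix(rnorm(n * p), n, p)
  conc <- 2^log2_conc

  if (cfg$metabolite_zero_rate > 0) {
    conc[runif(n * p) < cfg$metabolite_zero_rate] <- 0
  }
  if (cfg$metabolite_missing_rate > 0) {
    conc[runif(n * p) < cfg$metabolite_missing_rate] <- NA_real_
  }
  colnames(conc) <- met_names

  list(
    data = as_tibble(as.data.frame(conc)),
    informative = informative,
    markers = tibble(metabolite = met_names, cluster = marker_cluster)
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(
    "<synthetic_cohort>", nrow(x$phenotype), "subjects |",
    ncol(x$metabolites) - 1L, "metabolites |",
    ncol(x$genotypes) - 1L, "SNPs\n"
  )
  print(dplyr::count(x$phenotype, .data$group))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Writes the phenotype and metabolite tables as TSV, the genotypes both as a
#' VCF 4.2 file (GT field only) and as a mirrored TSV matrix, the SNP metadata
#' and the ground truth as TSVs. The files round-trip losslessly through the
#' package's readers.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Directory to write into (created if needed).
#' @return A tibble manifest (file, path), invisibly written as
#'   `manifest.tsv` too.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) abort(paste0("cannot create directory ", dir))
  paths <- c(
    phenotype = file.path(dir, "phenotype.tsv"),
    metabolites = file.path(dir, "metabolites.tsv"),
    genotypes_vcf = file.path(dir, "genotypes.vcf"),
    genotypes_tsv = file.path(dir, "genotypes.tsv"),
    snp_info = file.path(dir, "snp_info.tsv"),
    truth_subjects = file.path(dir, "truth_subjects.tsv"),
    truth_features = file.path(dir, "truth_features.tsv"),
    config = file.path(dir, "config.yaml")
  )
  readr::write_tsv(cohort$phenotype, paths[["phenotype"]])
  readr::write_tsv(cohort$metabolites, paths[["metabolites"]])
  write_vcf(cohort$genotypes, cohort$snp_info, paths[["genotypes_vcf"]])
  readr::write_tsv(cohort$genotypes, paths[["genotypes_tsv"]])
  readr::write_tsv(cohort$snp_info, paths[["snp_info"]])
  readr::write_tsv(cohort$truth$subjects, paths[["truth_subjects"]])
  readr::write_tsv(
    tibble(metabolite = cohort$truth$informative_features, role = "informative"),
    paths[["truth_features"]]
  )
  write_simulation_config(cohort$config, paths[["config"]])
  manifest <- tibble(file = names(paths), path = unname(paths))
  readr::write_tsv(manifest, file.path(dir, "manifest.tsv"))
  manifest
}
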