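# 2x2 allele-table oracle, structured independently of the implementation.
table_oracle <- function(a, b, c_, d_) {
  tab <- matrix(c(a, b, c_, d_), 2, 2, byrow = TRUE)
  n <- sum(tab)
  stat <- 0
  for (i in 1:2) {
    for (j in 1:2) {
      e <- sum(tab[i, ]) * sum(tab[, j]) / n
      stat <- stat + (tab[i, j] - e)^2 / e
    }
  }
  list(
    chisq = stat,
    p = stats::pchisq(stat, 1, lower.tail = FALSE),
    or = (a * d_) / (b * c_)
  )
}

# Genotype tibble realizing exact case/control ALLELE counts (each subject
# contributes 2 alleles; allele totals must be even).
geno_from_alleles <- function(case_alt, case_alleles, ctl_alt, ctl_alleles) {
  render <- function(alt, alleles) {
    n_subj <- alleles / 2
    aa <- alt %/% 2
    het <- alt %% 2
    geno_col(n_subj - aa - het, het, aa)
  }
  calls <- c(render(case_alt, case_alleles), render(ctl_alt, ctl_alleles))
  g <- toy_genotypes(list(rs = calls), ids = sprintf("S%03d", seq_along(calls)))
  n_case <- case_alleles / 2
  list(
    genotypes = g,
    cases = g$subject_id[seq_len(n_case)],
    controls = g$subject_id[n_case + seq_len(ctl_alleles / 2)]
  )
}

test_that("the allelic chi-square and OR match hand computation", {
  # alleles: cases 30 alt / 70 ref, controls 10 alt / 90 ref
  gg <- geno_from_alleles(30, 100, 10, 100)
  res <- allelic_chi_square(gg$genotypes, gg$cases, gg$controls)
  oracle <- table_oracle(30, 70, 10, 90)
  expect_equal(res$case_alt, 30)
  expect_equal(res$control_ref, 90)
  expect_equal(res$or, oracle$or, tolerance = 1e-12)
  expect_equal(res$or, 3.857142857, tolerance = 1e-9)
  expect_equal(res$chisq, oracle$chisq, tolerance = 1e-12)
  expect_equal(res$chisq, 12.5, tolerance = 1e-12)
  # cross-check against the standard implementation
  ref <- suppressWarnings(stats::chisq.test(
    matrix(c(30, 70, 10, 90), 2, byrow = TRUE),
    correct = FALSE
  ))
  expect_equal(res$chisq, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$p, ref$p.value, tolerance = 1e-12)
})

test_that("equal allele frequencies give a null result", {
  gg <- geno_from_alleles(25, 100, 25, 100)
  res <- allelic_chi_square(gg$genotypes, gg$cases, gg$controls)
  expect_equal(res$chisq, 0)
  expect_equal(res$p, 1)
  expect_equal(res$or, 1)
})

test_that("chi-square matches the exhaustive small-table oracle", {
  for (r1 in c(4, 10, 20)) {
    for (alt1 in seq(0, r1, by = 2)) {
      for (alt2 in seq(0, 20, by = 5)) {
        gg <- geno_from_alleles(alt1, r1, alt2, 20)
        res <- allelic_chi_square(gg$genotypes, gg$cases, gg$controls)
        if (res$monomorphic) {
          expect_equal(res$p, 1)
          next
        }
        oracle <- table_oracle(alt1, r1 - alt1, alt2, 20 - alt2)
        expect_equal(res$chisq, oracle$chisq, tolerance = 1e-10)
        expect_equal(res$p, oracle$p, tolerance = 1e-10)
      }
    }
  }
})

test_that("swapping cases and controls inverts the OR, chi-square unchanged", {
  gg <- geno_from_alleles(30, 80, 12, 90)
  fwd <- allelic_chi_square(gg$genotypes, gg$cases, gg$controls)
  rev <- allelic_chi_square(gg$genotypes, gg$controls, gg$cases)
  expect_equal(fwd$chisq, rev$chisq, tolerance = 1e-12)
  expect_equal(fwd$or, 1 / rev$or, tolerance = 1e-12)
})

test_that("Bonferroni adjustment and threshold arithmetic are exact", {
  th <- bonferroni_threshold(0.05, 195)
  expect_equal(th$threshold, 0.05 / 195, tolerance = 1e-15)
  expect_equal(signif(th$threshold, 2), 2.6e-4)
  expect_equal(bonferroni_threshold(0.05, 1)$threshold, 0.05)
  expect_equal(bonferroni_threshold(0.05, 370394)$threshold, 1.349914e-7,
    tolerance = 1e-6
  )
  expect_error(bonferroni_threshold(0, 5))
  expect_error(bonferroni_threshold(0.05, 0))
  # adjusted p = min(1, p * m): one SNP tested alone has p_adj = p
  gg <- geno_from_alleles(30, 100, 10, 100)
  res <- allelic_chi_square(gg$genotypes, gg$cases, gg$controls)
  expect_equal(res$p_adj, res$p)
})

test_that("candidate selection applies the printed asymmetric OR rule", {
  res <- tibble::tibble(
    snp_id = c("a", "b", "c", "d"),
    chrom = c("1", "1", "2", "2"),
    pos = c(200L, 100L, 50L, 60L),
    p_adj = c(5e-8, 5e-8, 1e-6, 5e-8),
    or = c(2.0, 0.7, 3.0, 0.3),
    monomorphic = FALSE
  )
  sel <- select_candidates(res)
  # a: p ok, OR 2 > 1 -> in; b: OR 0.7 in [0.5, 1] -> out; c: p too big -> out;
  # d: OR 0.3 < 0.5 -> in. Ordered by (chrom, pos).
  expect_equal(sel, c("a", "d"))
  expect_equal(select_candidates(res, or_rule = "gt2_or_lt0.5"), c("d"))
})

test_that("the pooled two-proportion z-test matches hand computation", {
  eq <- proportion_test(50, 100, 50, 100)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)

  t2 <- proportion_test(40, 100, 20, 100)
  # pooled p = 0.3, se = sqrt(0.3*0.7*0.02), z = 0.2/se
  expect_equal(t2$statistic, 0.2 / sqrt(0.3 * 0.7 * 0.02), tolerance = 1e-12)
  expect_equal(t2$statistic, 3.086067, tolerance = 1e-6)
  expect_equal(t2$p_value, 2 * stats::pnorm(-0.2 / sqrt(0.3 * 0.7 * 0.02)), tolerance = 1e-12)
  # z^2 equals the uncorrected chi-square of prop.test
  ref <- stats::prop.test(c(40, 20), c(100, 100), correct = FALSE)
  expect_equal(t2$statistic^2, unname(ref$statistic), tolerance = 1e-10)

  t3 <- proportion_test(0, 10, 10, 10)
  expect_gt(abs(t3$statistic), 3.9)
  expect_lt(t3$p_value, 1e-4)
})

test_that("raw p-values are calibrated under the null", {
  # 5 seeds x 2,000 null SNPs, 500 cases / 500 controls, MAF 0.3
  fracs <- vapply(1:5, function(seed) {
    withr::with_seed(seed, {
      n <- 1000
      p_snps <- 2000
      dose <- matrix(rbinom(n * p_snps, 2, 0.3) / 2, n, p_snps)
      colnames(dose) <- paste0("s", seq_len(p_snps))
      enc <- dplyr::bind_cols(
        tibble::tibble(subject_id = sprintf("P%04d", 1:n)),
        tibble::as_tibble(as.data.frame(dose))
      )
      res <- allelic_chi_square(
        enc,
        cases = enc$subject_id[1:500], controls = enc$subject_id[501:1000]
      )
      mean(res$p < 0.05)
    })
  }, numeric(1))
  expect_true(all(abs(fracs - 0.05) <= 0.01 + 1e-12))
})

test_that("manhattan tables sort by genome position and cap underflow", {
  gg <- geno_from_alleles(30, 100, 10, 100)
  info <- tibble::tibble(snp_id = "rs", chrom = "3", pos = 42L, ref = "A", alt = "G")
  res <- allelic_chi_square(gg$genotypes, gg$cases, gg$controls, snp_info = info)
  tab <- manhattan_table(res)
  expect_equal(tab$neg_log10_p, -log10(res$p), tolerance = 1e-12)

  res2 <- res[rep(1, 3), ]
  res2$snp_id <- c("x", "y", "z")
  res2$chrom <- c("2", "1", "10")
  res2$pos <- c(10L, 20L, 5L)
  res2$p <- c(0.01, 0, 0.5)
  tab2 <- manhattan_table(res2)
  expect_equal(tab2$snp_id, c("y", "x", "z")) # numeric chromosome order
  expect_equal(tab2$neg_log10_p[tab2$snp_id == "x"], 2)
  expect_true(tab2$capped[tab2$snp_id == "y"])
  expect_equal(tab2$neg_log10_p[tab2$snp_id == "y"], 320)
  expect_true(all(diff(tab2$genome_pos) > 0))
})
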