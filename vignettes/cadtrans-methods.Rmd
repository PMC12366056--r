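---
title: "Methods: trans-omics CAD subtyping and prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trans-omics CAD subtyping and prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`cadtrans` implements a trans-omics analysis of coronary artery disease
(CAD): it couples a targeted plasma metabolomics panel with genome-wide SNP
genotypes on a three-group cohort (control, high-risk, CAD), clusters each
omics layer, intersects the clusterings into genetic–metabolic subtypes,
calls a five-SNP haplotype, and trains a bootstrapped consensus prediction
model. This vignette explains each model, its assumptions, the tunable
parameters, and the numerical conventions, and states what the synthetic
cohort generator does and does not emulate.

## Data model

All user-facing functions take tibbles keyed by `subject_id` and return
tibbles (or small S3 result objects with `tidy()`/`glance()` methods).
Genotype calls are categorical (`hom_ref`, `het`, `hom_alt`, `NA`) with SNP
metadata (chromosome, 1-based position as in VCF, single-nucleotide ref/alt
alleles) kept in a separate `snp_info` tibble. Any operation joining two
subject-indexed objects fails loudly on an index mismatch rather than
silently intersecting.

## Normalization

**Median/log2** (`normalize_metabolites()`), per metabolite, in order:
missing values are imputed with the median of the observed values; exact
zeros become 0.001 µM so the logarithm is defined; values are divided by
the metabolite's median; log2. The divisor median is recomputed *after*
imputation and zero replacement so it describes the matrix actually
transformed — the two pre-processing steps and the median division are
individually standard, but their ordering is a convention this package
fixes and tests (the worked triples in the test suite pin it down). The
transform is scale-equivariant: rescaling a metabolite's raw unit leaves
the output unchanged.

**Unit variance** (`unit_variance_scale()`): each feature is mean-centered
and divided by its sample standard deviation. Centering is applied even
though only the division is essential to the name, because discriminant
projection and the Hotelling ellipse both assume centered scores; constant
features are an error naming the feature.

## SNP quality control and encoding

`snp_qc()` applies three filters *sequentially* — minor allele frequency
< 0.01 (computed from observed allele counts, missing calls excluded),
Hardy–Weinberg disequilibrium in controls at p < 10⁻⁶, missing rate > 10% —
and attributes a SNP failing several filters to the first failing one, so
the removal counts add up to the input count exactly. The HWE test is the
1-df goodness-of-fit χ² on genotype counts against p², 2pq, q²
expectations: simple, the legacy default of standard GWAS tooling, and at
the 10⁻⁶ threshold insensitive to the choice versus an exact test at
array-scale counts. Monomorphic SNPs fit trivially (p = 1) and are left to
the MAF filter.

`encode_genotypes()` maps hom-ref → 0, het → 0.5, hom-alt → 1 and imputes
each missing cell with the per-SNP median of observed encoded values,
snapped to the nearest legal code; an exact tie (median 0.25 or 0.75)
snaps to 0.5, the least-committal code. "Median allele" imputation could
also be read allele-wise; the genotype-level median with snapping keeps
every column inside {0, 0.5, 1}, which downstream clustering and modelling
assume.

## Clustering and stability

`kmeans_fit()` is k-means++ seeding followed by Lloyd iterations on
Euclidean distance, best of `n_restarts = 25` restarts, seeded and hence
reproducible. The within-cluster sum of squares is asserted non-increasing
across iterations on every fit — this is why the Lloyd loop is written out
rather than delegated (the standard `stats::kmeans` implementation is used
as an independent oracle in the tests: the best-of-restarts inertia must
not be worse). Empty clusters are re-seeded with the points farthest from
their centers. Silhouette widths come from the `cluster` package and can
be disabled for large cohorts, where the n × n distance matrix dominates
memory.

`elbow_scan()` selects k at the maximal second difference of the inertia
curve (the discrete curvature). A *weak elbow* is flagged when the largest
second difference is less than 3.5× the mean positive second difference: a
smooth convex decay (single Gaussian blob) has a peakedness ratio near 2
across seeds, while five planted clusters push it above 5, so 3.5 splits
the two regimes with margin on both sides (measured on simulated reference
shapes of both kinds). A forced k is always accepted downstream — the
elbow is advisory, as it is in practice.

`compare_partitions()` reports per-cluster *normalized Jaccard* similarity
|A∩B|/|A∪B| after matching the two solutions' labels one-to-one to
maximize total Jaccard — exhaustively over permutations for k ≤ 8,
greedily above. "Normalized Jaccard" is not given a formula in the
clustering literature it is quoted from; the per-matched-cluster set
Jaccard is the interpretation implemented, and it is validated against a
brute-force matcher in the tests. The stability claim mirrored by the
acceptance script is that on well-separated data two independently
initialized runs agree at Jaccard ≥ 0.80 for every cluster.

## Association

`allelic_chi_square()` uses the allelic 2×2 table (two alleles per
subject, missing excluded) rather than a genotypic 2×3 table: it is the
GWAS default and yields a single odds ratio compatible with the candidate
rule. The χ² is Pearson's, without continuity correction; odds ratios use
the Haldane–Anscombe 0.5 correction only when a cell is zero. The
candidate rule — Bonferroni-adjusted p < 10⁻⁷ and OR > 1 or OR < 0.5 — is
implemented literally, asymmetry included, with a symmetric variant
(OR > 2 or < 0.5) behind an argument. The Bonferroni factor is the number
of SNPs actually tested, recomputed per run. Mixed-model machinery
(GRM + saddlepoint) is out of scope; a plain χ² is the exploratory test
here, and the per-SNP `proportion_test()` (pooled two-proportion z) covers
the haplotype-panel comparisons.

## Haplotype calling and subtypes

`call_haplotypes()` is a deterministic rule over five panel SNPs:
haplotype 3 is homozygous-alternate at all five; haplotype 2 is
homozygous-reference at four plus homozygous-alternate at the designated
fifth (rs36993 in the shipped LPCAT1 panel); all 241 remaining genotype
combinations are haplotype 1 (wild type). A missing call anywhere in the
panel yields haplotype 1 with a flag — conservative toward wild type,
since the defining patterns require full observation. The classification
map is tested against exhaustive enumeration of all 3⁵ combinations.

`crosstab_enrichment()` reports the omnibus Pearson χ² of the k×k cluster
cross-tab plus, for every cluster pair, a 2×2 collapse (in/out of each
margin) with its own χ² and a Bonferroni adjustment over the pairs —
pairwise collapses because the enrichment claims of interest are pairwise.
`derive_subtype_rules()` turns the cross-tab into Subtype-I/II rules by
selecting, for each targeted metabolomic cluster, the genetic clusters
with standardized residual > 2; cluster labels are arbitrary to a fit, so
the rules are data-driven configuration, not constants, and can be written
by hand. `assign_subtypes()` rejects overlapping rules and always
partitions the cohort into Subtype-I, Subtype-II and unassigned.

## OPLS-DA

`opls_fit()` estimates, NIPALS-style, `n_ortho` orthogonal components —
structured variation in X uncorrelated with the class — then a single
predictive component on the deflated matrix. The two-class response is
coded ±1 and centered; orthogonal score vectors have zero sample
correlation with the response by construction (asserted to 10⁻⁸). R²Y is
the fitted explained variance of the response; Q² = 1 − PRESS/SS from
stratified 7-fold cross-validation, each fold re-centered on its training
data. With `n_ortho = "auto"` components are added while Q² improves by
more than 0.01 — a SIMCA-like stopping rule standing in for the
unspecified "cross-validation rules". With no orthogonal component the
model is exactly a 1-component PLS regression on the coded response
(verified against an independent PLS implementation to 10⁻⁸); under label
permutation the mean Q² is ≤ 0, the standard validity check.
`hotelling_ellipse()` draws the 95% region from
T² = 2(n−1)/(n−2)·F(0.95; 2, n−2) on the 2-D score covariance; on large
bivariate-normal samples it excludes 5% ± 1% of points.

## Consensus feature selection and models

`consensus_select()` runs B = 100 iterations. Each iteration draws a fresh
stratified 80:20 split ("bootstrapped replications" is implemented as
repeated random resplits, matching the description of the data being
randomly split per iteration; sampling with replacement is available via
`resample = "bootstrap"`). On the training part, a LASSO logistic
regression (penalty by internal 5-fold cross-validation, 1-SE rule)
defines the selected set and its size k; a random forest (impurity
importance, 200 trees) and a linear SVM (absolute primal weights
`|w| = |Σ αᵢ yᵢ xᵢ|`) each contribute their top-k. An iteration where
LASSO selects nothing contributes nothing and is logged. Features are
ranked by cumulative count across methods and iterations; ties break by
higher LASSO count, then name, so rankings are reproducible.
`top_k_features()` takes the top 16 by default, the size of the
interpretable feature set the pipeline targets.

`train_and_evaluate()` supports stratified 80:20 holdout and stratified
10-fold cross-validation for RF, radial SVM, LASSO-logistic and XGBoost,
reporting AUC (via pROC, cross-checked against a rank-statistic AUC to
10⁻¹⁰), accuracy/sensitivity/specificity at the 0.5 threshold, AUC-PR,
Brier score and calibration slope per fold and averaged. The XGBoost grid
is eta ∈ {0.1, 0.3, 0.5, 0.7, 0.9} × max_depth ∈ {6, 12, 29} ×
min_child_weight ∈ {1, 2, 4, 8, 10} — 75 combinations, scored by
validation AUC with the full grid table returned. Degenerate single-class
splits are re-drawn with a warning.

`backward_stepwise_or()` fits a logistic model and eliminates backwards by
AIC (`stats::step`), reporting exponentiated coefficients with 95% Wald
intervals; quasi-complete separation (|β| > 15 or SE > 10) flags the term
and suppresses its interval. Note the operating characteristic of AIC:
a pure-noise regressor survives when its deviance drop exceeds 2
(tail probability ≈ 0.16), so on 10 noise features roughly 1.6 survive in
expectation — the null test asserts exactly this behaviour.

`balance_experiments()` rebalances only the *training* side of a seeded
holdout: 1:1 subsampling of controls, or greedy 1:1 nearest-neighbour
matching on standardized age (exact on sex, and on statin use in the
three-covariate mode) with a 5-year age caliper. Validation subjects are
never reused in training, and matched sets are returned for audit.
`interaction_features()` adds statin × metabolite product columns;
`calibration_report()` gives the reliability curve over equal-frequency
bins, the calibration slope (logistic refit of outcomes on predicted
log-odds; 1 = calibrated) and optional Platt or isotonic recalibration fit
on one half of a seeded split and evaluated on the other.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the analysis
assumes, with full ground truth:

- **Groups** sized 271/363/147 by default (the study proportions), with
  cosmetic clinical covariates (age, BMI, sex, six medication flags) drawn
  from group-specific normal/Bernoulli distributions with means taken from
  the published cohort description; they matter only to the
  matched-sampling experiments.
- **Haplotype block**: a per-subject diplotype class is drawn from a
  3-class distribution — haplotype-3 target frequencies 13.33% / 19.28% /
  27.21% per group by default, haplotype-2 defaults 10% / 6% / 2% — and
  rendered to the five genotypes; "other" subjects get per-SNP random
  genotypes resampled away from the two defining patterns. Generating at
  the diplotype level guarantees the planted classes exist at controllable
  frequency without modelling recombination. The haplotype-2 per-group
  frequencies are not published as population parameters (only conditional
  group shares within each haplotype), so the defaults here are a
  configurable, plausible declining profile, not an asserted fact.
- **Latent clusters**: each subject gets a genetic cluster (uniform over
  `n_clusters = 5`) and a metabolomic cluster equal to it with probability
  `coupling_strength` (default 0.9). Genetic clusters are carried by 20
  marker SNPs per cluster (alt-allele frequency 0.7 inside, 0.15 outside);
  metabolomic clusters by a round-robin partition of the metabolites
  shifted `cluster_separation` (default 4) within-cluster SDs on the log2
  scale. The marker-SNP mixture produces a genuine Wahlund-style
  heterozygote deficit, so a few marker SNPs legitimately fail HWE QC in
  finite control samples.
- **Metabolites** are log-normal: effects act additively on log2
  concentration with unit noise SD, so concentrations stay positive and
  the median/log2 transform is natural. The first
  `n_informative_features` metabolites get a monotone shift of
  `effect_size` (default 1.5) SDs per group step; all others are null with
  respect to group. Missing cells and exact zeros are injected completely
  at random at 1% and 0.5% by default.
- **Background SNPs** are independent with MAF ~ U(0.05, 0.5) under HWE;
  2% of non-block calls are set missing so the missing-rate filter and the
  VCF `./.` path are exercised. The five block SNPs are kept free of
  injected missingness so the planted haplotype ground truth is exact.

What it does **not** emulate: linkage disequilibrium beyond the single
block, population structure and relatedness, medication effects on
metabolite levels (the statin flag is only a flag), batch effects, or
realistic genome-wide allele-frequency spectra. Tests that pass on this
generator therefore demonstrate that the *methods* behave as specified
under their own assumptions — recovery of planted structure, calibration
under the null — not that the biological conclusions transfer to any real
cohort.

## Determinism and problem sizes

Every stochastic function takes an explicit seed and restores the caller's
RNG state; the generator derives independent child streams per stage
(phenotype, clusters, genotypes, metabolites) from one root seed, so
enlarging one layer does not perturb another. The test suite uses
deliberately scaled problem sizes — cohorts of 500–6,000 subjects, 2,000
null SNPs per calibration replicate, 20 replicates of the B = 100
consensus-selection recovery study at n = 600 with 50 features — chosen so
the full suite exercises every claim at meaningful power on a single CPU.
The acceptance script's cluster-stability computation uses n = 500
subjects × 143 metabolites with 25 restarts per K-means run.

## Known limitations

- The greedy fallback in cluster matching (k > 8) is not guaranteed
  optimal; at the package's k = 5 default the matching is exhaustive.
- The HWE test is asymptotic; at very small control counts an exact test
  would differ, but the QC threshold of 10⁻⁶ makes the choice immaterial
  at cohort scale.
- OPLS-DA is two-class; the three-group design is analysed pairwise.
- `backward_stepwise_or()` inherits AIC's permissiveness toward weak
  predictors (see above); it reports associations, not a parsimonious
  causal model.
- Probability calibration reports assume enough events per bin; with rare
  outcomes use fewer bins.
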