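#' Specification for the synthetic trio generator
#'
#' Describes a genotype-stratified expression/biomarker dataset: biallelic
#' genotypes drawn under Hardy-Weinberg proportions, a Gaussian imaging
#' biomarker, and gene expression that for planted causal (SNP, gene) pairs
#' follows a per-genotype-group linear relationship with the biomarker
#' (distinct slopes per group) while all other genes share one common slope.
#'
#' Defaults realize the strong-effect stratified-slope structure used
#' throughout the test surfaces: equal intercepts so detected structure is
#' attributable to slopes alone, slopes (0.5, 0.5, 3.0) with noise sd 0.2 for
#' causal genes, and 1000 samples as in the multi-site stability analysis.
#'
#' @param n_samples Number of subjects. Default 1000.
#' @param allele_freq Alternate-allele frequency in (0, 1). Default 0.3.
#' @param group_intercepts Per-genotype-group intercepts. Default c(0, 0, 0).
#' @param group_slopes Per-genotype-group slopes for causal genes.
#'   Default c(0.5, 0.5, 3).
#' @param noise_sd Gaussian noise sd of expression around the group line.
#'   Default 0.2.
#' @param n_genes,n_causal_genes Panel size and number of planted causal
#'   genes. Defaults 200 and 1.
#' @param n_snps,n_causal_snps Number of SNPs and of causal (slope-modulating)
#'   SNPs. Defaults 20 and 1.
#' @param missing_rate Independent genotype missingness rate. Default 0.02.
#' @param n_sites Hypothetical institutions for partitioning. Default 1.
#' @param biomarker_mean,biomarker_sd Biomarker distribution. Default N(0, 1).
#' @param seed Seed; every generator is seed-deterministic. Default 1.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(n_samples = 1000L, allele_freq = 0.3,
                            group_intercepts = c(0, 0, 0),
                            group_slopes = c(0.5, 0.5, 3),
                            noise_sd = 0.2,
                            n_genes = 200L, n_causal_genes = 1L,
                            n_snps = 20L, n_causal_snps = 1L,
                            missing_rate = 0.02, n_sites = 1L,
                            biomarker_mean = 0, biomarker_sd = 1,
                            seed = 1L) {
  stopifnot(n_samples >= 1, allele_freq > 0, allele_freq < 1,
            length(group_intercepts) == 3L, length(group_slopes) == 3L,
            noise_sd > 0, n_causal_genes <= n_genes,
            n_causal_snps <= n_snps, missing_rate >= 0, missing_rate < 1,
            n_sites >= 1, biomarker_sd > 0)
  structure(as.list(environment()), class = "simulation_spec")
}

#' Simulate a biallelic genotype matrix under Hardy-Weinberg proportions
#'
#' Each SNP is drawn independently with genotype probabilities
#' (p^2, 2pq, q^2) at the spec's alternate-allele frequency q, then thinned
#' with independent missingness.
#'
#' @param spec A [simulation_spec].
#' @return A [genotype_matrix] (samples x SNPs allele counts).
#' @export
simulate_genotypes <- function(spec) {
  set.seed(spec$seed)
  sim_genotypes_impl(spec)
}

sim_genotypes_impl <- function(spec) {
  q <- spec$allele_freq
  probs <- c((1 - q)^2, 2 * q * (1 - q), q^2)
  calls <- matrix(sample(0:2, spec$n_samples * spec$n_snps, replace = TRUE,
                         prob = probs),
                  nrow = spec$n_samples, ncol = spec$n_snps)
  if (spec$missing_rate > 0) {
    miss <- stats::runif(length(calls)) < spec$missing_rate
    calls[miss] <- NA_integer_
  }
  sample_ids <- sprintf("S%04d", seq_len(spec$n_samples))
  snp_ids <- sprintf("snp%04d", seq_len(spec$n_snps))
  dimnames(calls) <- list(sample_ids, snp_ids)
  genotype_matrix(calls,
                  snp_info = data.frame(id = snp_ids, chrom = "1",
                                        pos = seq_len(spec$n_snps) * 1000L,
                                        ref = "G", alt = "A",
                                        stringsAsFactors = FALSE))
}

#' Simulate a full genotype/expression/biomarker trio dataset
#'
#' Draws genotypes under HWE, a Gaussian biomarker, and an expression panel.
#' Causal genes are assigned (without replacement) to causal SNPs; for a
#' causal pair the sample's expression follows
#' `intercept[g] + slope[g] * biomarker + N(0, noise_sd)` where `g` is the
#' sample's genotype group at the assigned SNP (samples with a missing call at
#' that SNP fall back to the common slope); all other genes use the group-1
#' intercept and slope for every sample.
#'
#' @param spec A [simulation_spec].
#' @return List with elements `genotypes` ([genotype_matrix]), `expression`
#'   (genes x samples matrix), `biomarker` (named vector), and `truth`
#'   (data.frame of planted `snp_id`, `gene_id` pairs).
#' @export
simulate_trio_dataset <- function(spec) {
  set.seed(spec$seed)
  geno <- sim_genotypes_impl(spec)
  n <- spec$n_samples
  sample_ids <- geno$sample_ids
  biomarker <- stats::rnorm(n, spec$biomarker_mean, spec$biomarker_sd)
  names(biomarker) <- sample_ids
  gene_ids <- sprintf("gene%04d", seq_len(spec$n_genes))
  causal_snps <- if (spec$n_causal_snps > 0)
    sample(geno$snp_info$id, spec$n_causal_snps) else character()
  causal_genes <- if (spec$n_causal_genes > 0)
    sample(gene_ids, spec$n_causal_genes) else character()
  truth <- if (length(causal_genes) > 0 && length(causal_snps) > 0) {
    data.frame(snp_id = rep_len(causal_snps, length(causal_genes)),
               gene_id = causal_genes, stringsAsFactors = FALSE)
  } else {
    data.frame(snp_id = character(), gene_id = character(),
               stringsAsFactors = FALSE)
  }
  expr <- matrix(NA_real_, nrow = spec$n_genes, ncol = n,
                 dimnames = list(gene_ids, sample_ids))
  base_mu <- spec$group_intercepts[1L] + spec$group_slopes[1L] * biomarker
  for (j in seq_len(spec$n_genes)) {
    gid <- gene_ids[j]
    hit <- match(gid, truth$gene_id)
    if (!is.na(hit)) {
      g <- geno$calls[, truth$snp_id[hit]] + 1L   # genotype group 1..3
      mu <- ifelse(is.na(g), base_mu,
                   spec$group_intercepts[pmax(g, 1L)] +
                     spec$group_slopes[pmax(g, 1L)] * biomarker)
    } else {
      mu <- base_mu
    }
    expr[j, ] <- mu + stats::rnorm(n, 0, spec$noise_sd)
  }
  list(genotypes = geno, expression = expr, biomarker = biomarker,
       truth = truth)
}

#' Simulate grouped biomarker/expression data with exact group sizes
#'
#' Direct generator for the stratified-slope structure with balanced (or any
#' requested) subgroup sizes: `y = intercept[g] + slope[g] * x + N(0, sd)`.
#' Used for calibration and power studies where exact per-group sample counts
#' are part of the study design (HWE genotype draws cannot fix group sizes).
#'
#' @param n_per_group Integer vector of group sizes (length 2 or 3).
#' @param intercepts,slopes Per-group intercepts and slopes (recycled).
#' @param noise_sd Gaussian noise sd.
#' @param seed Optional seed; `NULL` uses the current RNG state.
#' @return List with `x`, `y`, `groups` (labels "1", "2", ...).
#' @export
simulate_grouped_data <- function(n_per_group, intercepts = 0, slopes = 1,
                                  noise_sd = 0.2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  G <- length(n_per_group)
  intercepts <- rep_len(intercepts, G)
  slopes <- rep_len(slopes, G)
  groups <- rep(as.character(seq_len(G)), times = n_per_group)
  n <- sum(n_per_group)
  x <- stats::rnorm(n)
  g <- as.integer(groups)
  y <- intercepts[g] + slopes[g] * x + stats::rnorm(n, 0, noise_sd)
  list(x = x, y = y, groups = groups)
}

#' Simulate a scan-ready gene panel with one planted differential-slope gene
#'
#' Builds a stratifier with exact per-group sizes, a standard-normal
#' biomarker, and an expression panel in which one planted gene follows
#' per-group slopes while all others share the group-1 slope.
#'
#' @param n_per_group Per-group sample counts (length 3 by default usage).
#' @param slopes Per-group slopes for the planted gene.
#' @param noise_sd Noise sd.
#' @param n_genes Panel size.
#' @param seed Seed.
#' @return List with `stratifier`, `biomarker`, `expression` and
#'   `planted_gene`.
#' @export
simulate_scan_panel <- function(n_per_group = c(100, 100, 100),
                                slopes = c(0.5, 0.5, 3), noise_sd = 0.2,
                                n_genes = 200L, seed = 1L) {
  set.seed(seed)
  n <- sum(n_per_group)
  sample_ids <- sprintf("S%04d", seq_len(n))
  groups <- rep(as.character(seq_along(n_per_group)), times = n_per_group)
  names(groups) <- sample_ids
  biomarker <- stats::rnorm(n)
  names(biomarker) <- sample_ids
  gene_ids <- sprintf("gene%04d", seq_len(n_genes))
  planted <- sample(gene_ids, 1L)
  g <- as.integer(groups)
  expr <- matrix(NA_real_, n_genes, n, dimnames = list(gene_ids, sample_ids))
  for (j in seq_len(n_genes)) {
    s <- if (gene_ids[j] == planted) slopes[g] else slopes[1L]
    expr[j, ] <- s * biomarker + stats::rnorm(n, 0, noise_sd)
  }
  strat <- structure(list(source = "planted_stratifier", groups = groups,
                          dropped_samples = character()),
                     class = "stratifier")
  list(stratifier = strat, biomarker = biomarker, expression = expr,
       planted_gene = planted)
}

#' Randomly partition samples across hypothetical institutions
#'
#' Assigns every sample to exactly one of `n_sites` sites (a random disjoint
#' cover), reproducing the multi-institution setting in-process.
#'
#' @param x,y Numeric vectors (biomarker, expression).
#' @param groups Subgroup label per sample.
#' @param n_sites Number of sites (1 <= n_sites <= number of samples).
#' @param seed Seed for the random assignment.
#' @return List of [site_data] objects, one per site.
#' @export
partition_sites <- function(x, y, groups, n_sites = 1L, seed = 1L) {
  n <- length(x)
  if (n_sites < 1L || n_sites > n)
    stop_fedchow("n_sites must lie in [1, n_samples]", "fedchow_invalid")
  set.seed(seed)
  assign <- sample(rep_len(seq_len(n_sites), n))
  lapply(seq_len(n_sites), function(i) {
    idx <- which(assign == i)
    site_data(paste0("site", i), x[idx], y[idx], groups[idx])
  })
}
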