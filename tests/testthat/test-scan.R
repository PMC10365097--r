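toy_genotypes <- function(calls_by_snp, sample_ids = NULL) {
  calls <- do.call(cbind, calls_by_snp)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%03d", seq_len(nrow(calls)))
  dimnames(calls) <- list(sample_ids, names(calls_by_snp))
  genotype_matrix(calls, data.frame(id = names(calls_by_snp), chrom = "1",
                                    pos = seq_along(calls_by_snp), ref = "G",
                                    alt = "A", stringsAsFactors = FALSE))
}

test_that("genotype stratification maps allele counts and drops missing", {
  gm <- toy_genotypes(list(snpA = c(0, 0, 1, 1, 2, NA)))
  st <- stratify_by_genotype(gm, "snpA")
  expect_equal(as.integer(table(factor(st$groups, levels = 1:3))),
               c(2L, 2L, 1L))
  expect_equal(st$dropped_samples, "S006")
  expect_false("S006" %in% names(st$groups))
  expect_error(stratify_by_genotype(gm, "nope"), class = "fedchow_lookup")
})

test_that("stratified group proportions follow HWE expectations", {
  spec <- simulation_spec(n_samples = 600, allele_freq = 0.3, n_snps = 1,
                          missing_rate = 0, seed = 33)
  gm <- simulate_genotypes(spec)
  st <- stratify_by_genotype(gm, "snp0001")
  prop <- as.numeric(table(factor(st$groups, levels = 1:3))) / 600
  expected <- c(0.49, 0.42, 0.09)
  se <- sqrt(expected * (1 - expected) / 600)
  expect_true(all(abs(prop - expected) < 3 * se))
})

test_that("label stratifiers handle categorical columns", {
  lab <- setNames(c("e3/e3", "e3/e4", "e4/e4", "e3/e3", NA),
                  sprintf("S%d", 1:5))
  st <- stratifier_from_labels(lab, source = "apoe")
  expect_equal(unname(st$groups[c("S1", "S2", "S3", "S4")]),
               c("1", "2", "3", "1"))
  expect_equal(st$dropped_samples, "S5")
  expect_error(stratifier_from_labels(setNames(letters[1:4], letters[1:4])),
               class = "fedchow_invalid")
})

test_that("scan recovers a planted differential-slope gene", {
  panel <- simulate_scan_panel(n_per_group = c(60, 60, 60), n_genes = 40,
                               seed = 3)
  rec <- scan_genes(panel$stratifier, panel$biomarker, panel$expression,
                    federated_config(n_sites = 3, seed = 5))
  expect_equal(rec$gene_id[which.min(rec$p_value)], panel$planted_gene)
  expect_equal(rec$n_g1[1], 60L)
  expect_equal(rec$q_value, bh_fdr(rec$p_value))
  # planted gene shows strong third-group correlation, weak pooled break genes
  planted <- rec[rec$gene_id == panel$planted_gene, ]
  expect_gt(abs(planted$r_g3), abs(planted$r_g1))
})

test_that("scan output matches per-gene federated chow tests", {
  panel <- simulate_scan_panel(n_per_group = c(20, 25, 30), n_genes = 8,
                               seed = 9)
  cfg <- federated_config(n_sites = 4, seed = 13)
  rec <- scan_genes(panel$stratifier, panel$biomarker, panel$expression, cfg)
  for (gid in rec$gene_id[c(1, 4, 8)]) {
    aligned <- names(panel$stratifier$groups)
    sites <- partition_sites(panel$biomarker[aligned],
                             panel$expression[gid, aligned],
                             panel$stratifier$groups[aligned],
                             n_sites = 4, seed = 21)
    ref <- federated_chow(sites, cfg)
    row <- rec[rec$gene_id == gid, ]
    expect_equal(row$f_value, ref$f_value, tolerance = 1e-7)
    expect_equal(row$p_value, ref$p_value, tolerance = 1e-7)
  }
})

test_that("scan is invariant to gene and sample permutations", {
  panel <- simulate_scan_panel(n_per_group = c(15, 15, 15), n_genes = 12,
                               seed = 17)
  cfg <- federated_config(n_sites = 2, seed = 19)
  base <- scan_genes(panel$stratifier, panel$biomarker, panel$expression, cfg)
  set.seed(23)
  gperm <- sample(nrow(panel$expression))
  sperm <- sample(ncol(panel$expression))
  shuffled <- scan_genes(panel$stratifier,
                         panel$biomarker[sperm],
                         panel$expression[gperm, sperm],
                         cfg)
  reordered <- shuffled[match(base$gene_id, shuffled$gene_id), ]
  expect_equal(reordered$p_value, base$p_value, tolerance = 1e-9)
  expect_equal(reordered$f_value, base$f_value, tolerance = 1e-9)
})

test_that("degenerate scans report missing p-values, not errors", {
  panel <- simulate_scan_panel(n_per_group = c(10, 10, 10), n_genes = 5,
                               seed = 29)
  flat <- setNames(rep(1, length(panel$biomarker)), names(panel$biomarker))
  rec <- scan_genes(panel$stratifier, flat, panel$expression)
  expect_true(all(is.na(rec$p_value)))

  # disjoint sample ids are fatal
  bad <- panel$biomarker
  names(bad) <- paste0("X", names(bad))
  expect_error(scan_genes(panel$stratifier, bad, panel$expression),
               class = "fedchow_invalid")
})

test_that("gene selection modes are deterministic about ties", {
  rec <- data.frame(gene_id = c("gB", "gA", "gC", "gD"),
                    p_value = c(0.01, 0.01, 0.2, NA),
                    stringsAsFactors = FALSE)
  expect_equal(select_genes(rec, "p_threshold", alpha = 0.05), c("gA", "gB"))
  expect_equal(select_genes(rec, "top_n", n = 1), "gA")  # tie -> lexicographic
  expect_equal(select_genes(rec, "top_n", n = 3), c("gA", "gB", "gC"))
  expect_warning(all_of <- select_genes(rec, "top_n", n = 10), "only 3")
  expect_equal(all_of, c("gA", "gB", "gC"))
  expect_equal(select_genes(data.frame(gene_id = "g", p_value = 0.5),
                            "p_threshold", alpha = 0.05), character(0))
})

test_that("enrichment of a selection counts overlaps in the universe", {
  uni <- paste0("G", 1:50)
  res <- enrich_selection(uni, uni, uni)
  expect_equal(res$overlap, 50)
  expect_equal(res$p_value, 0)

  disj <- enrich_selection(paste0("G", 1:10), paste0("G", 11:20), uni)
  expect_equal(disj$overlap, 0)

  # case-insensitive matching, out-of-universe ids dropped with a message
  expect_message(res2 <- enrich_selection(c("g1", "G2", "ZZZ"),
                                          c("G2", "G3"), uni),
                 "outside the universe")
  expect_equal(res2$overlap, 1)
  expect_equal(res2$draw_size, 2)
  expect_error(enrich_selection("a", "b", character(0)),
               class = "fedchow_invalid")
})

test_that("enrichment p is monotone non-increasing in overlap", {
  p <- vapply(0:20, function(k) hypergeom_enrichment(100, 30, 20, k)$p_value, 0)
  expect_true(all(diff(p) <= 1e-15))
})

test_that("snp ranking ties equal overlaps and ranks unscannable snps last", {
  set.seed(31)
  spec <- simulation_spec(n_samples = 150, n_genes = 30, n_snps = 4,
                          n_causal_snps = 1, n_causal_genes = 5,
                          allele_freq = 0.5, missing_rate = 0, seed = 31)
  ds <- simulate_trio_dataset(spec)
  # make one non-causal SNP monomorphic
  mono <- setdiff(ds$genotypes$snp_info$id, ds$truth$snp_id)[1]
  ds$genotypes$calls[, mono] <- 0L
  ranking <- rank_snps(ds$genotypes$snp_info$id, ds$genotypes, ds$biomarker,
                       ds$expression, reference = ds$truth$gene_id,
                       top_n = 5, config = federated_config(seed = 37))
  expect_true(is.na(ranking$enrichment_p[ranking$snp_id == mono]))
  expect_equal(ranking$snp_id[nrow(ranking)], mono)
  expect_equal(ranking$rank, seq_len(nrow(ranking)))
  # causal SNP carries the strongest enrichment
  expect_equal(ranking$snp_id[1], ds$truth$snp_id[1])
  # equal overlap counts imply equal enrichment p
  same_k <- split(ranking$enrichment_p, ranking$overlap)
  for (grp in same_k)
    expect_lt(diff(range(grp)), 1e-15)
})

test_that("tpr_at_m measures ranking quality", {
  ranked <- data.frame(snp_id = paste0("s", 1:10), rank = 1:10)
  expect_equal(tpr_at_m(ranked, paste0("s", 1:3), 3), 1)
  expect_equal(tpr_at_m(ranked, paste0("s", c(2, 4, 6, 8, 10)), 10), 0.5)
  expect_error(tpr_at_m(ranked, "s1", 0), class = "fedchow_invalid")
  expect_error(tpr_at_m(ranked, "s1", 11), class = "fedchow_invalid")

  # random rankings average to prevalence at every depth
  set.seed(41)
  pos <- paste0("s", 1:4)
  tprs <- replicate(1000, {
    perm <- data.frame(snp_id = sample(paste0("s", 1:10)))
    tpr_at_m(perm, pos, 5)
  })
  expect_lt(abs(mean(tprs) - 0.4), 3 * sd(tprs) / sqrt(1000))
})

test_that("ICV adjustment divides volumes elementwise", {
  expect_equal(adjust_by_icv(c(2, 4), c(2, 2)), c(1, 2))
  v <- c(10, 20, 30)
  expect_equal(rank(adjust_by_icv(v, rep(7, 3))), rank(v))
  set.seed(43)
  vol <- runif(20, 1, 5); icv <- runif(20, 1000, 2000)
  expect_equal(adjust_by_icv(vol, icv), vol / icv)
  expect_error(adjust_by_icv(c(1, 2), c(1, 0)), class = "fedchow_invalid")
})
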