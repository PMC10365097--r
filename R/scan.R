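#' Stratify samples by genotype at one SNP
#'
#' Maps allele counts \{0, 1, 2\} at the SNP to subgroup labels \{1, 2, 3\};
#' samples with a missing call are dropped from all downstream fits.
#'
#' @param genotypes A [genotype_matrix].
#' @param snp_id SNP identifier present in the matrix.
#' @return A `stratifier`: list with `source`, `groups` (named label vector)
#'   and `dropped_samples`.
#' @export
stratify_by_genotype <- function(genotypes, snp_id) {
  j <- match(snp_id, genotypes$snp_info$id)
  if (is.na(j))
    stop_fedchow(paste0("SNP not found: ", snp_id), "fedchow_lookup")
  calls <- genotypes$calls[, j]
  dropped <- genotypes$sample_ids[is.na(calls)]
  keep <- !is.na(calls)
  groups <- as.character(calls[keep] + 1L)
  names(groups) <- genotypes$sample_ids[keep]
  structure(list(source = snp_id, groups = groups, dropped_samples = dropped),
            class = "stratifier")
}

#' Stratify samples by a precomputed categorical column
#'
#' For stratifiers given as labels rather than allele counts (e.g. an
#' APOE-class column with levels e3/e3, e3/e4, e4/e4). At most three distinct
#' non-missing levels are allowed; they are mapped to subgroup labels 1..3 in
#' sorted order.
#'
#' @param labels Vector of class labels, named by sample id.
#' @param source Identifier recorded as the stratifier source.
#' @return A `stratifier`.
#' @export
stratifier_from_labels <- function(labels, source = "labels") {
  if (is.null(names(labels)))
    stop_fedchow("labels must be named by sample id", "fedchow_invalid")
  lab <- as.character(labels)
  dropped <- names(labels)[is.na(lab)]
  keep <- !is.na(lab)
  lev <- sort(unique(lab[keep]))
  if (length(lev) > 3L)
    stop_fedchow("at most 3 subgroup levels are supported", "fedchow_invalid")
  groups <- as.character(match(lab[keep], lev))
  names(groups) <- names(labels)[keep]
  structure(list(source = source, groups = groups, dropped_samples = dropped),
            class = "stratifier")
}

#' @exportS3Method base::print
print.stratifier <- function(x, ...) {
  cat("Stratifier '", x$source, "': ", sep = "")
  tab <- table(x$groups)
  cat(paste(sprintf("group %s: %d", names(tab), as.integer(tab)),
            collapse = ", "),
      "; ", length(x$dropped_samples), " dropped (missing)\n", sep = "")
  invisible(x)
}

#' Adjust regional brain volumes for head size
#'
#' Elementwise division of a regional volume by the subject's intracranial
#' vault volume (volume / ICV).
#'
#' @param volume Numeric vector of regional volumes.
#' @param icv Numeric vector of intracranial vault volumes, strictly positive.
#' @return `volume / icv`, preserving names.
#' @export
adjust_by_icv <- function(volume, icv) {
  if (length(volume) != length(icv))
    stop_fedchow("volume and icv must have equal length", "fedchow_invalid")
  if (any(!is.na(icv) & icv <= 0))
    stop_fedchow("ICV values must be strictly positive", "fedchow_invalid")
  volume / icv
}

# vectorized Pearson r and two-sided t-based p for one group across genes;
# Yt is n x G (samples x genes)
group_pearson <- function(x, Yt) {
  n <- length(x)
  if (n < 3L || stats::sd(x) == 0)
    return(list(r = rep(NA_real_, ncol(Yt)), p = rep(NA_real_, ncol(Yt)), n = n))
  sdy <- apply(Yt, 2L, stats::sd)
  r <- suppressWarnings(as.numeric(stats::cor(x, Yt)))
  r[sdy == 0] <- NA_real_
  tt <- r * sqrt((n - 2) / pmax(1e-300, 1 - r^2))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  p[!is.na(r) & abs(r) >= 1] <- 0
  list(r = r, p = p, n = n)
}

#' Scan all genes for one stratifier/biomarker pair
#'
#' For every gene, fits the per-subgroup and pooled federated regressions of
#' expression on the biomarker and computes the generalized Chow F and
#' p-value; q-values are Benjamini-Hochberg over the scan's non-missing
#' p-values, and per-subgroup Pearson correlations are reported alongside.
#' Sample ids are aligned by intersection across the stratifier, biomarker
#' and expression matrix (the dropped count is messaged). Samples are
#' randomly partitioned once into `config$n_sites` institutions; all genes
#' are fitted under that partition by aggregating per-site gradient
#' contributions, exactly as [federated_chow] does gene by gene.
#'
#' @param stratifier A `stratifier` (see [stratify_by_genotype]).
#' @param biomarker Named numeric vector of biomarker values.
#' @param expression Numeric matrix, genes x samples.
#' @param config A [federated_config].
#' @param biomarker_id Label recorded in the output. Default "biomarker".
#' @return A data.frame of class `trio_scan`, one row per gene, with columns
#'   `stratifier_id, gene_id, biomarker_id, f_value, p_value, q_value,
#'   n_g1..n_g3, r_g1, p_g1, ..., r_g3, p_g3`.
#' @export
scan_genes <- function(stratifier, biomarker, expression,
                       config = federated_config(),
                       biomarker_id = "biomarker") {
  aligned <- Reduce(intersect, list(names(stratifier$groups), names(biomarker),
                                    colnames(expression)))
  aligned <- sort(aligned)
  if (length(aligned) == 0L)
    stop_fedchow("no samples shared by stratifier, biomarker and expression",
                 "fedchow_invalid")
  n_union <- length(union(union(names(stratifier$groups), names(biomarker)),
                          colnames(expression)))
  if (n_union > length(aligned))
    message(n_union - length(aligned),
            " sample id(s) absent from at least one input dropped by alignment")
  x <- as.numeric(biomarker[aligned])
  grp <- stratifier$groups[aligned]
  E <- expression[, aligned, drop = FALSE]
  genes <- rownames(E)
  n <- length(aligned)
  set.seed(config$seed)
  site_of <- sample(rep_len(seq_len(config$n_sites), n))

  labs <- sort(unique(grp))
  eligible <- labs[vapply(labs, function(g) {
    idx <- grp == g
    sum(idx) >= 3L && stats::sd(x[idx]) > 0
  }, logical(1L))]

  nG <- length(genes)
  res <- data.frame(stratifier_id = stratifier$source, gene_id = genes,
                    biomarker_id = biomarker_id,
                    f_value = NA_real_, p_value = NA_real_, q_value = NA_real_,
                    n_g1 = 0L, n_g2 = 0L, n_g3 = 0L,
                    r_g1 = NA_real_, p_g1 = NA_real_,
                    r_g2 = NA_real_, p_g2 = NA_real_,
                    r_g3 = NA_real_, p_g3 = NA_real_,
                    stringsAsFactors = FALSE)
  for (g in labs) {
    gi <- suppressWarnings(as.integer(g))
    if (!is.na(gi) && gi >= 1L && gi <= 3L)
      res[[paste0("n_g", gi)]] <- sum(grp == g)
  }
  # per-group Pearson reporting (Figures-style output), all groups with data
  for (g in labs) {
    gi <- suppressWarnings(as.integer(g))
    if (is.na(gi) || gi < 1L || gi > 3L) next
    idx <- which(grp == g)
    if (length(idx) < 3L) next
    pc <- group_pearson(x[idx], t(E[, idx, drop = FALSE]))
    res[[paste0("r_g", gi)]] <- pc$r
    res[[paste0("p_g", gi)]] <- pc$p
  }

  pooled_ok <- length(eligible) >= 2L
  if (pooled_ok) {
    comb_idx <- which(grp %in% eligible)
    fits <- list()
    ok <- TRUE
    for (g in c(eligible, "combined")) {
      idx <- if (g == "combined") comb_idx else which(grp == g)
      fit <- batch_group_fit(x, E, idx, site_of, config)
      if (is.null(fit)) { ok <- FALSE; break }
      fits[[g]] <- fit
    }
    if (ok) {
      k <- 2L
      Gn <- length(eligible)
      S_groups <- Reduce(`+`, lapply(fits[eligible], `[[`, "rss"))
      S_comb <- fits[["combined"]]$rss
      N <- length(comb_idx)
      df_num <- (Gn - 1L) * k
      df_den <- N - Gn * k
      if (df_den > 0L) {
        den <- S_groups / df_den
        f <- pmax(0, ((S_comb - S_groups) / df_num) / den)
        f[den <= 0] <- ifelse(S_comb[den <= 0] - S_groups[den <= 0] <= 0, 0, Inf)
        res$f_value <- f
        res$p_value <- stats::pf(f, df_num, df_den, lower.tail = FALSE)
        res$q_value <- bh_fdr(res$p_value)
        attr(res, "df") <- c(df_num, df_den)
      }
    }
  }
  attr(res, "n_aligned") <- n
  attr(res, "groups_used") <- eligible
  attr(res, "config") <- config
  class(res) <- c("trio_scan", "data.frame")
  res
}

# Batch federated fit of all genes for one set of sample indices.
# Aggregates per-site standardized crossproducts (the same quantities the
# per-gene gradient messages sum to) and runs one gradient-descent loop
# updating a 2 x n_genes coefficient matrix. Returns per-gene rss vector.
batch_group_fit <- function(x, E, idx, site_of, config) {
  n <- length(idx)
  if (n < 3L) return(NULL)
  xg <- x[idx]
  if (stats::sd(xg) == 0) return(NULL)
  mx <- mean(xg); sx <- stats::sd(xg)
  Yt <- t(E[, idx, drop = FALSE])             # n x G
  my <- colMeans(Yt)
  sy <- sqrt(pmax(0, (colSums(Yt^2) - n * my^2) / (n - 1)))
  sy[sy == 0] <- 1
  xs <- (xg - mx) / sx
  Ys <- sweep(sweep(Yt, 2L, my, `-`), 2L, sy, `/`)
  sites <- sort(unique(site_of[idx]))
  A <- matrix(0, 2L, 2L)
  B <- matrix(0, 2L, ncol(Ys))
  for (s in sites) {
    sub <- site_of[idx] == s
    X <- cbind(1, xs[sub])
    A <- A + crossprod(X)
    B <- B + crossprod(X, Ys[sub, , drop = FALSE])
  }
  sol <- fed_gd_solve(A, B, n, config)
  if (!sol$converged)
    warning("batch federated solve hit max_iterations (worst gradient norm ",
            format(sol$grad_norm, digits = 3), ")")
  slope <- sol$W[2L, ] * sy / sx
  intercept <- my + sy * sol$W[1L, ] - slope * mx
  resid <- Yt - rep(intercept, each = n) - outer(xg, slope)
  list(rss = colSums(resid^2), n = n,
       coefficients = rbind(intercept = intercept, slope = slope))
}

#' Select genes from a scan by p-value threshold or top-N rank
#'
#' @param records A `trio_scan` data.frame from [scan_genes].
#' @param mode `"p_threshold"` (keep p < alpha) or `"top_n"` (N smallest
#'   p-values, ties broken by gene id).
#' @param alpha Threshold for `"p_threshold"`. Default 0.05.
#' @param n Selection size for `"top_n"`. Default 100.
#' @return Character vector of gene ids (deterministic order). Missing
#'   p-values are never selected.
#' @export
select_genes <- function(records, mode = c("p_threshold", "top_n"),
                         alpha = 0.05, n = 100L) {
  mode <- match.arg(mode)
  if (nrow(records) == 0L)
    stop_fedchow("empty scan records", "fedchow_invalid")
  ok <- records[!is.na(records$p_value), , drop = FALSE]
  ok <- ok[order(ok$p_value, ok$gene_id), , drop = FALSE]
  if (mode == "p_threshold") {
    ok$gene_id[ok$p_value < alpha]
  } else {
    if (n > nrow(ok)) {
      warning("requested top ", n, " genes but only ", nrow(ok),
              " have non-missing p; returning all")
      n <- nrow(ok)
    }
    ok$gene_id[seq_len(n)]
  }
}

#' Hypergeometric enrichment of a selected gene set
#'
#' Counts the overlap between the selection and a reference list within a
#' gene universe and calls [hypergeom_enrichment] with M = |universe|,
#' n = |reference|, N = |selected|, k = |selected intersect reference|.
#' Identifiers are matched case-insensitively; selection or reference members
#' outside the universe are messaged and dropped.
#'
#' @param selected Character vector of selected gene ids.
#' @param reference Character vector of reference gene ids.
#' @param universe Character vector of all scanned gene ids.
#' @param convention Tail convention passed to [hypergeom_enrichment].
#' @return An `enrichment_result`.
#' @export
enrich_selection <- function(selected, reference, universe,
                             convention = c("greater", "geq", "pmf")) {
  convention <- match.arg(convention)
  uni <- unique(toupper(universe))
  if (length(uni) == 0L)
    stop_fedchow("empty gene universe", "fedchow_invalid")
  sel <- unique(toupper(selected))
  ref <- unique(toupper(reference))
  out_sel <- setdiff(sel, uni); out_ref <- setdiff(ref, uni)
  if (length(out_sel) > 0L)
    message(length(out_sel), " selected gene(s) outside the universe dropped")
  if (length(out_ref) > 0L)
    message(length(out_ref), " reference gene(s) outside the universe dropped")
  sel <- intersect(sel, uni); ref <- intersect(ref, uni)
  hypergeom_enrichment(length(uni), length(ref), length(sel),
                       length(intersect(sel, ref)), convention = convention)
}

#' Rank stratifying SNPs by enrichment of their top genes
#'
#' For each SNP: stratify samples by genotype, scan all genes, select the
#' top-N by p-value, and test enrichment of the selection against the
#' reference gene list. SNPs are ranked by ascending enrichment p-value with
#' lexicographic tie-breaking (SNPs with equal overlap necessarily tie on p);
#' SNPs that cannot be scanned (e.g. monomorphic) are ranked last with
#' missing p.
#'
#' @param snp_ids SNPs to evaluate.
#' @param genotypes A [genotype_matrix].
#' @param biomarker Named biomarker vector.
#' @param expression Genes x samples matrix.
#' @param reference Reference gene ids.
#' @param top_n Selection size per SNP. Default 100.
#' @param config A [federated_config].
#' @param universe Gene universe; default all rows of `expression`.
#' @param convention Enrichment tail convention.
#' @return Data.frame (`snp_rank` class) with columns `snp_id`, `overlap`,
#'   `enrichment_p`, `rank`.
#' @export
rank_snps <- function(snp_ids, genotypes, biomarker, expression, reference,
                      top_n = 100L, config = federated_config(),
                      universe = rownames(expression),
                      convention = c("greater", "geq", "pmf")) {
  convention <- match.arg(convention)
  rows <- lapply(snp_ids, function(s) {
    out <- data.frame(snp_id = s, overlap = NA_integer_,
                      enrichment_p = NA_real_, stringsAsFactors = FALSE)
    enr <- tryCatch({
      strat <- stratify_by_genotype(genotypes, s)
      rec <- scan_genes(strat, biomarker, expression, config)
      if (all(is.na(rec$p_value))) NULL
      else {
        sel <- suppressWarnings(select_genes(rec, "top_n", n = top_n))
        enrich_selection(sel, reference, universe, convention = convention)
      }
    }, fedchow_error = function(e) NULL)
    if (!is.null(enr)) {
      out$overlap <- enr$overlap
      out$enrichment_p <- enr$p_value
    }
    out
  })
  res <- do.call(rbind, rows)
  ord <- order(is.na(res$enrichment_p), res$enrichment_p, res$snp_id)
  res <- res[ord, , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  class(res) <- c("snp_rank", "data.frame")
  res
}

#' True positive rate among the top-m ranked SNPs
#'
#' @param ranked A `snp_rank` data.frame from [rank_snps].
#' @param positives Character vector of known-positive SNP ids.
#' @param m Depth of the ranking to evaluate (1 <= m <= nrow(ranked)).
#' @return Fraction of the top-m SNPs that are positives.
#' @export
tpr_at_m <- function(ranked, positives, m) {
  if (m < 1L || m > nrow(ranked))
    stop_fedchow("m must lie in [1, number of ranked SNPs]", "fedchow_invalid")
  top <- ranked$snp_id[seq_len(m)]
  length(intersect(top, positives)) / m
}

#' Write scan records as TSV with a provenance comment header
#'
#' @param records A `trio_scan` or `snp_rank` data.frame.
#' @param path Output path.
#' @param comments Character vector of comment lines (written with `# `).
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(records, path, comments = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  utils::write.table(as.data.frame(records), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
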