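#' Construct a genotype matrix container
#'
#' @param calls Integer matrix, samples x SNPs, values in \{0, 1, 2\} or NA
#'   (alternate-allele counts), with sample ids as rownames and SNP ids as
#'   colnames.
#' @param snp_info Data frame with columns `id`, `chrom`, `pos`, `ref`, `alt`
#'   matching the columns of `calls`.
#' @return A `genotype_matrix` object.
#' @export
genotype_matrix <- function(calls, snp_info) {
  stopifnot(is.matrix(calls), !is.null(rownames(calls)), !is.null(colnames(calls)))
  vals <- calls[!is.na(calls)]
  if (length(vals) && !all(vals %in% 0:2))
    stop_fedchow("genotype calls must be allele counts in {0, 1, 2} or NA",
                 "fedchow_invalid")
  req <- c("id", "chrom", "pos", "ref", "alt")
  if (!all(req %in% names(snp_info)))
    stop_fedchow("snp_info must have columns id, chrom, pos, ref, alt",
                 "fedchow_invalid")
  if (!identical(as.character(snp_info$id), colnames(calls)))
    stop_fedchow("snp_info ids must match the columns of calls in order",
                 "fedchow_invalid")
  mode(calls) <- "integer"
  structure(list(sample_ids = rownames(calls),
                 snp_info = snp_info[, req],
                 calls = calls),
            class = "genotype_matrix")
}

#' @exportS3Method base::print
print.genotype_matrix <- function(x, ...) {
  cat("Genotype matrix:", length(x$sample_ids), "samples x",
      nrow(x$snp_info), "SNPs;",
      sum(is.na(x$calls)), "missing calls\n")
  invisible(x)
}

gt_to_count <- function(gt, allele = "1") {
  # "0/1", "1|2", "./." (or NA) -> count of `allele` among the two calls
  vapply(strsplit(gt, "[/|]"), function(a) {
    if (length(a) == 0L || anyNA(a) || any(a == "."))
      return(NA_integer_)
    sum(a == allele)
  }, NA_integer_)
}

#' Read a genotype matrix from VCF or TSV
#'
#' VCF: only the GT field is used; phased and unphased calls are treated
#' identically and `./.` becomes missing. Multi-allelic records are skipped
#' (default, with a message) or split into one record per alternate allele
#' with `multiallelic = "split"`.
#'
#' TSV dialect: tab-separated, header row `snp_id` then sample ids, one row
#' per SNP, cells in \{0, 1, 2, NA\}; empty cells are rejected.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @param multiallelic `"skip"` or `"split"`.
#' @return A [genotype_matrix].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tsv"),
                           multiallelic = c("skip", "split")) {
  format <- match.arg(format)
  multiallelic <- match.arg(multiallelic)
  if (!file.exists(path))
    stop_fedchow(paste0("file not found: ", path), "fedchow_io")
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  if (format == "vcf") read_genotypes_vcf(path, multiallelic)
  else read_genotypes_tsv(path)
}

read_genotypes_vcf <- function(path, multiallelic) {
  # pre-validate field counts so a truncated record is reported by line
  lines <- readLines(path)
  body <- which(!startsWith(lines, "#"))
  hdr <- grep("^#CHROM", lines)
  if (length(hdr) != 1L)
    stop_fedchow(paste0(path, ": no #CHROM header line"), "fedchow_io")
  n_fields <- length(strsplit(lines[hdr], "\t", fixed = TRUE)[[1L]])
  for (i in body) {
    nf <- length(strsplit(lines[i], "\t", fixed = TRUE)[[1L]])
    if (nf != n_fields)
      stop_fedchow(sprintf("%s: line %d has %d fields, expected %d",
                           path, i, nf, n_fields), "fedchow_io")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, ":", fix$POS), fix$ID)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  rows <- list(); info <- list()
  for (i in seq_len(nrow(fix))) {
    if (multi[i] && multiallelic == "skip") next
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1L]]
    for (a in seq_along(alts)) {
      if (a > 1L && multiallelic == "skip") break
      id <- if (length(alts) > 1L) paste0(ids[i], "_alt", a) else ids[i]
      rows[[id]] <- gt_to_count(gt[i, ], allele = as.character(a))
      info[[id]] <- data.frame(id = id, chrom = fix$CHROM[i],
                               pos = as.integer(fix$POS[i]),
                               ref = fix$REF[i], alt = alts[a],
                               stringsAsFactors = FALSE)
    }
  }
  if (any(multi) && multiallelic == "skip")
    message(sum(multi), " multi-allelic record(s) skipped")
  if (length(rows) == 0L)
    stop_fedchow(paste0(path, ": no usable biallelic records"), "fedchow_io")
  calls <- do.call(cbind, rows)             # samples x SNPs
  rownames(calls) <- colnames(gt)
  genotype_matrix(calls, do.call(rbind, info))
}

read_genotypes_tsv <- function(path) {
  nf <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "#")
  if (length(unique(nf)) != 1L) {
    bad <- which(nf != nf[1L])[1L]
    stop_fedchow(sprintf("%s: line %d has %d fields, expected %d",
                         path, bad, nf[bad], nf[1L]), "fedchow_io")
  }
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                          comment.char = "#", na.strings = character(0))
  if (ncol(df) < 2L)
    stop_fedchow(paste0(path, ": need a snp_id column plus sample columns"),
                 "fedchow_io")
  snp_ids <- df[[1L]]
  if (anyDuplicated(snp_ids))
    stop_fedchow(paste0(path, ": duplicate SNP ids"), "fedchow_io")
  cells <- as.matrix(df[, -1L, drop = FALSE])
  blank <- which(cells == "", arr.ind = TRUE)
  if (nrow(blank) > 0L)
    stop_fedchow(sprintf("%s: empty cell at SNP '%s', sample '%s' (use NA)",
                         path, snp_ids[blank[1L, 1L]],
                         colnames(cells)[blank[1L, 2L]]), "fedchow_io")
  bad <- matrix(!(cells %in% c("0", "1", "2", "NA")), nrow = nrow(cells))
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1L, ]
    stop_fedchow(sprintf("%s: invalid call '%s' at SNP '%s', sample '%s'",
                         path, cells[w[1L], w[2L]], snp_ids[w[1L]],
                         colnames(cells)[w[2L]]), "fedchow_io")
  }
  calls <- t(matrix(suppressWarnings(as.integer(cells)), nrow = nrow(cells),
                    dimnames = dimnames(cells)))
  colnames(calls) <- snp_ids
  genotype_matrix(calls,
                  data.frame(id = snp_ids, chrom = NA_character_,
                             pos = NA_integer_, ref = NA_character_,
                             alt = NA_character_, stringsAsFactors = FALSE))
}

#' Write a genotype matrix to VCF or TSV
#'
#' The VCF writer emits a minimal GT-only VCF 4.2 text file; unknown
#' chrom/pos/ref/alt metadata fall back to placeholders.
#'
#' @param gm A [genotype_matrix].
#' @param path Output path.
#' @param format `"vcf"` or `"tsv"` (default by extension).
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gm, path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf$", path)) "vcf" else "tsv"
  if (format == "vcf") {
    info <- gm$snp_info
    chrom <- ifelse(is.na(info$chrom), "1", info$chrom)
    pos <- ifelse(is.na(info$pos), seq_len(nrow(info)) * 1000L, info$pos)
    ref <- ifelse(is.na(info$ref), "G", info$ref)
    alt <- ifelse(is.na(info$alt), "A", info$alt)
    gt_str <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
    lines <- c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", gm$sample_ids), collapse = "\t"))
    for (j in seq_len(nrow(info))) {
      calls <- gm$calls[, j]
      gts <- ifelse(is.na(calls), "./.", gt_str[as.character(calls)])
      lines <- c(lines, paste(c(chrom[j], pos[j], info$id[j], ref[j], alt[j],
                                ".", ".", ".", "GT", gts), collapse = "\t"))
    }
    writeLines(lines, path)
  } else {
    mat <- t(gm$calls)
    df <- data.frame(snp_id = rownames(mat), mat, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA")
  }
  invisible(path)
}

#' Read a gene expression matrix (genes x samples TSV)
#'
#' First column = gene id, header = sample ids. Duplicate gene ids and
#' non-finite values are rejected with their location. Set
#' `samples_in_rows = TRUE` to transpose input stored samples-in-rows.
#'
#' @param path File path.
#' @param samples_in_rows Transpose after reading? Default `FALSE`.
#' @return Numeric matrix, genes in rows.
#' @export
read_expression <- function(path, samples_in_rows = FALSE) {
  if (!file.exists(path))
    stop_fedchow(paste0("file not found: ", path), "fedchow_io")
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop_fedchow(sprintf("%s: duplicate row id '%s'", path,
                         ids[duplicated(ids)][1L]), "fedchow_io")
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    w <- which(is.na(suppressWarnings(matrix(as.numeric(m), nrow(m)))) & !is.na(m),
               arr.ind = TRUE)
    loc <- if (nrow(w)) sprintf(" at row '%s', column '%s'",
                                ids[w[1L, 1L]], colnames(m)[w[1L, 2L]]) else ""
    stop_fedchow(paste0(path, ": non-numeric expression values", loc),
                 "fedchow_io")
  }
  if (any(!is.finite(m)))
    stop_fedchow(paste0(path, ": non-finite expression values"), "fedchow_io")
  rownames(m) <- ids
  if (samples_in_rows) m <- t(m)
  m
}

#' Write an expression matrix as TSV (genes in rows)
#' @param mat Numeric matrix with row and column names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype table
#'
#' TSV with header; first column = sample id (must be unique), remaining
#' columns numeric (imaging biomarkers, optionally an intracranial-vault
#' volume column for head-size adjustment).
#'
#' @param path File path.
#' @return Data frame with rownames = sample ids and numeric columns.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path))
    stop_fedchow(paste0("file not found: ", path), "fedchow_io")
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop_fedchow(sprintf("%s: duplicate sample id '%s'", path,
                         ids[duplicated(ids)][1L]), "fedchow_io")
  out <- df[, -1L, drop = FALSE]
  for (nm in names(out)) {
    v <- suppressWarnings(as.numeric(out[[nm]]))
    if (any(is.na(v) & !is.na(out[[nm]]) & out[[nm]] != "NA"))
      stop_fedchow(sprintf("%s: non-numeric value in column '%s'", path, nm),
                   "fedchow_io")
    out[[nm]] <- v
  }
  rownames(out) <- ids
  out
}

#' Write a phenotype table as TSV
#' @param pheno Data frame with rownames = sample ids.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(pheno, path) {
  df <- data.frame(sample_id = rownames(pheno), pheno, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter SNPs deviating from Hardy-Weinberg equilibrium
#'
#' Applies the conditional exact HWE test ([hwe_exact_test]) to the genotype
#' counts of the designated control samples and drops SNPs with p < `alpha`.
#'
#' @param gm A [genotype_matrix].
#' @param control_samples Sample ids on which to test (e.g. the cognitively
#'   unimpaired group).
#' @param alpha Removal threshold; default 1e-6. `alpha = 0` removes nothing.
#' @return Filtered [genotype_matrix]; the retained count is messaged.
#' @export
filter_hwe <- function(gm, control_samples, alpha = 1e-6) {
  control_samples <- as.character(control_samples)
  if (length(control_samples) == 0L)
    stop_fedchow("control sample set is empty", "fedchow_invalid")
  missing <- setdiff(control_samples, gm$sample_ids)
  if (length(missing) > 0L)
    stop_fedchow(paste0("control samples not in genotype matrix: ",
                        paste(utils::head(missing, 3L), collapse = ", ")),
                 "fedchow_invalid")
  sub <- gm$calls[control_samples, , drop = FALSE]
  keep <- vapply(seq_len(ncol(sub)), function(j) {
    g <- sub[, j]
    g <- g[!is.na(g)]
    if (length(g) == 0L) return(TRUE)   # no control information: retain
    p <- hwe_exact_test(sum(g == 0L), sum(g == 1L), sum(g == 2L))
    p >= alpha
  }, logical(1L))
  message(sum(keep), " of ", length(keep), " SNPs retained by the HWE filter (alpha = ",
          format(alpha), ")")
  genotype_matrix(gm$calls[, keep, drop = FALSE],
                  gm$snp_info[keep, , drop = FALSE])
}
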