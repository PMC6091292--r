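#' Read a gene expression matrix from TSV
#'
#' The file must have a header row of sample identifiers, a first column of
#' gene identifiers, and a numeric body (log-scale intensities are assumed
#' downstream but not enforced). No imputation is performed: any missing or
#' non-numeric cell is a hard error.
#'
#' @param path path to a tab-separated file.
#' @return numeric matrix (genes x samples) with gene ids as row names and
#'   sample ids as column names, values preserved exactly as written.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character", quote = "")
  if (nrow(df) == 0L || ncol(df) < 2L)
    stopf("expression file '%s' is empty or has no sample columns", path)
  gene_ids <- df[[1L]]
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup))
    stopf("duplicate gene identifier(s) in expression file: %s",
          paste(unique(dup), collapse = ", "))
  sample_ids <- colnames(df)[-1L]
  dup_s <- sample_ids[duplicated(sample_ids)]
  if (length(dup_s))
    stopf("duplicate sample identifier(s) in expression file: %s",
          paste(unique(dup_s), collapse = ", "))
  body <- as.matrix(df[, -1L, drop = FALSE])
  vals <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body)))
  bad <- which(!is.finite(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    stopf("non-numeric or non-finite expression value '%s' at gene '%s', sample '%s'",
          body[bad[1L, 1L], bad[1L, 2L]], gene_ids[bad[1L, 1L]],
          sample_ids[bad[1L, 2L]])
  }
  dimnames(vals) <- list(gene_ids, sample_ids)
  vals
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression()]; first column `gene`, one column per sample.
#'
#' @param expr numeric matrix with gene row names and sample column names.
#' @param path output path.
#' @export
write_expression <- function(expr, path) {
  # %.17g so a write/read round trip reproduces every double bit-exactly
  body <- matrix(sprintf("%.17g", expr), nrow = nrow(expr))
  df <- data.frame(gene = rownames(expr), body, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("gene", colnames(expr))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a binary phenotype vector from TSV
#'
#' Two tab-separated columns: sample identifier and label, where 1 marks a
#' tumor/case sample and 0 a normal/control sample. A single header line is
#' tolerated and skipped when its second field is not 0/1. Both classes must
#' be present.
#'
#' @param path path to a tab-separated file.
#' @return named integer vector of 0/1 labels, names = sample ids.
#' @export
read_phenotype <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE, colClasses = "character",
                          quote = "")
  if (ncol(df) < 2L) stopf("phenotype file '%s' needs two columns", path)
  if (nrow(df) >= 1L && !df[1L, 2L] %in% c("0", "1"))
    df <- df[-1L, , drop = FALSE]
  if (nrow(df) == 0L) stopf("phenotype file '%s' has no samples", path)
  labels <- suppressWarnings(as.integer(df[[2L]]))
  if (anyNA(labels) || !all(labels %in% c(0L, 1L)))
    stopf("phenotype labels must all be 0 or 1")
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stopf("duplicate sample identifier(s) in phenotype file")
  names(labels) <- ids
  check_binary_labels(labels)
  labels
}

#' Write a phenotype vector as TSV
#' @param pheno named 0/1 vector.
#' @param path output path.
#' @export
write_phenotype <- function(pheno, path) {
  utils::write.table(data.frame(sample = names(pheno), label = as.integer(pheno)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
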