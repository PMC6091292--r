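`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Align a phenotype vector to an expression matrix
#'
#' Reorders the phenotype to the expression matrix's sample order. The two
#' must cover exactly the same sample identifiers.
#'
#' @param expr expression matrix (genes x samples) with sample column names.
#' @param pheno named 0/1 integer vector as returned by [read_phenotype()].
#' @return the phenotype vector in `colnames(expr)` order.
#' @export
align_phenotype <- function(expr, pheno) {
  if (is.null(colnames(expr)) || is.null(names(pheno)))
    stopf("expression matrix and phenotype must carry sample identifiers")
  if (!setequal(colnames(expr), names(pheno)))
    stopf("sample identifiers of expression matrix and phenotype differ")
  pheno[colnames(expr)]
}

check_binary_labels <- function(labels) {
  if (!all(labels %in% c(0L, 1L)))
    stopf("phenotype labels must be 0 (normal) or 1 (tumor)")
  if (length(unique(labels)) < 2L)
    stopf("both phenotype classes must be present")
  invisible(labels)
}
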