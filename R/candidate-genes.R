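# Welch statistics vectorized over the rows of a genes x samples matrix.
# Returns one row per gene; sentinel t of +/-1e8 (flagged) when both groups
# have zero variance but different means.
welch_row_stats <- function(expr, labels) {
  i1 <- which(labels == 1L); i0 <- which(labels == 0L)
  n1 <- length(i1); n0 <- length(i0)
  x1 <- expr[, i1, drop = FALSE]; x0 <- expr[, i0, drop = FALSE]
  m1 <- rowMeans(x1); m0 <- rowMeans(x0)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v0 <- rowSums((x0 - m0)^2) / (n0 - 1)
  diff <- m1 - m0
  se2 <- v1 / n1 + v0 / n0
  df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v0^2 / (n0^2 * (n0 - 1)))
  t <- diff / sqrt(se2)
  degenerate <- se2 == 0
  flagged <- degenerate & diff != 0
  t[degenerate & diff == 0] <- 0
  t[flagged] <- sign(diff[flagged]) * 1e8
  df[degenerate] <- n1 + n0 - 2
  p <- 2 * stats::pt(-abs(t), df)
  p[degenerate & diff == 0] <- 1
  p[flagged] <- 0
  data.frame(gene = rownames(expr), t = t, df = df, p = p, diff = diff,
             flagged = flagged, row.names = NULL, stringsAsFactors = FALSE)
}

#' Identify differentially expressed genes (Welch t-test + BH)
#'
#' Compares tumor (label 1) against normal (label 0) samples per gene with a
#' Welch two-sample t-test, adjusts p-values by Benjamini-Hochberg, and
#' retains genes with adjusted `q <= q_threshold` and absolute mean
#' difference `>= min_abs_diff` (on the matrix's own scale; for log2 data
#' the default 1.0 means a two-fold change). Genes with zero variance in
#' both groups get t = 0 when the means agree; when the means differ the
#' statistic is capped at a large finite sentinel and the gene is flagged.
#'
#' @param expr genes x samples numeric matrix.
#' @param pheno named 0/1 vector aligned with `colnames(expr)`.
#' @param q_threshold BH-adjusted significance level (default 0.05).
#' @param min_abs_diff minimum absolute mean difference (default 1.0).
#' @return class `"deg_set"`: list with `table` (gene, t, df, p, q, diff,
#'   flagged for every gene) and `degs` (character vector of retained genes),
#'   plus the thresholds used.
#' @export
differential_genes <- function(expr, pheno, q_threshold = 0.05,
                               min_abs_diff = 1.0) {
  pheno <- align_phenotype(expr, pheno)
  check_binary_labels(pheno)
  if (sum(pheno == 1L) < 2L || sum(pheno == 0L) < 2L)
    stopf("each phenotype class needs at least 2 samples")
  tab <- welch_row_stats(expr, pheno)
  tab$q <- stats::p.adjust(tab$p, method = "BH")
  tab <- tab[, c("gene", "t", "df", "p", "q", "diff", "flagged")]
  degs <- tab$gene[tab$q <= q_threshold & abs(tab$diff) >= min_abs_diff]
  structure(list(table = tab, degs = degs, q_threshold = q_threshold,
                 min_abs_diff = min_abs_diff),
            class = "deg_set")
}

#' @export
print.deg_set <- function(x, ...) {
  cat("deg_set:", length(x$degs), "of", nrow(x$table),
      sprintf("genes at q <= %g, |diff| >= %g\n", x$q_threshold,
              x$min_abs_diff))
  invisible(x)
}

#' Filter differentially expressed genes through the PPI network
#'
#' A PPI edge is retained only when both endpoints are differentially
#' expressed; the candidate gene set (CGS) is the union of the endpoints of
#' the retained edges. Genes without any such edge are discarded.
#'
#' @param degs a `deg_set` (or plain character vector of DEG ids).
#' @param ppi a `ppi_network`.
#' @return sorted character vector of candidate genes (possibly empty).
#' @export
ppi_filter <- function(degs, ppi) {
  ids <- if (inherits(degs, "deg_set")) degs$degs else as.character(degs)
  both <- ppi[, "from"] %in% ids & ppi[, "to"] %in% ids
  cgs <- sort(unique(c(ppi[both, "from"], ppi[both, "to"])))
  if (!length(cgs))
    message("ppi_filter: no PPI edge connects two differentially expressed genes; CGS is empty")
  cgs
}

#' Project candidate genes onto pathways
#'
#' Intersects each pathway's member list (in file order) with the candidate
#' gene set and the expression matrix's genes. Pathways left with no
#' candidate gene are dropped (their activity score would be undefined).
#'
#' @param cgs character vector of candidate genes.
#' @param pathways named list of gene sets from [read_gene_sets()].
#' @param expr expression matrix whose row names define the measurable genes.
#' @return class `"pathway_candidate_map"`: list with `candidates` (named
#'   list pathway -> ordered candidate genes), `p` (candidate counts),
#'   `size_total` (full pathway sizes, including genes absent from `expr`),
#'   and `n_dropped`.
#' @export
map_to_pathways <- function(cgs, pathways, expr) {
  measurable <- rownames(expr)
  cand <- lapply(pathways, function(members)
    members[members %in% cgs & members %in% measurable])
  keep <- lengths(cand) > 0L
  n_dropped <- sum(!keep)
  if (n_dropped)
    message("map_to_pathways: dropped ", n_dropped,
            " pathway(s) without candidate genes")
  structure(list(candidates = cand[keep],
                 p = lengths(cand[keep]),
                 size_total = lengths(pathways)[keep],
                 n_dropped = n_dropped),
            class = "pathway_candidate_map")
}

#' @export
print.pathway_candidate_map <- function(x, ...) {
  cat("pathway_candidate_map:", length(x$candidates), "pathways retained (",
      x$n_dropped, "dropped ); candidate genes per pathway:",
      paste(range(x$p), collapse = "-"), "\n")
  invisible(x)
}
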