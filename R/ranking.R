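#' GeneRank random walk over the pathway network
#'
#' Iterates \code{r_j <- (1 - d) * ex_j + d * sum_i w_ij * r_i / deg_i}
#' starting from the seed vector `ex` normalized to unit L1 norm, until
#' the L1 norm of successive differences drops to `epsilon` or `max_iter`
#' iterations are reached. Nodes with degree 0 contribute nothing to their
#' neighbors but still receive `(1 - d) * ex_j`. The result is not
#' renormalized.
#'
#' @param ex_raw non-negative seed vector (e.g. per-pathway mutual
#'   information); at least one entry must be positive.
#' @param w symmetric adjacency matrix with zero diagonal (binary or
#'   weighted).
#' @param deg degree vector (defaults to `rowSums(w)`).
#' @param d damping factor in \[0, 1\] (default 0.85); d = 0 returns the
#'   normalized seed, d near 1 leans on the network.
#' @param epsilon L1 convergence tolerance (default 1e-10).
#' @param max_iter iteration cap (default 1000).
#' @return list with `r` (named scores), `ex` (normalized seed), `d`,
#'   `epsilon`, `iterations`, `converged`, `residuals` (per-iteration L1
#'   residuals).
#' @export
generank <- function(ex_raw, w, deg = rowSums(w), d = 0.85,
                     epsilon = 1e-10, max_iter = 1000L) {
  if (d < 0 || d > 1) stopf("damping factor d must lie in [0, 1]")
  if (any(ex_raw < 0)) stopf("seed vector must be non-negative")
  if (sum(ex_raw) == 0) stopf("seed vector is all zero: nothing to rank")
  n <- length(ex_raw)
  if (!is.matrix(w) || nrow(w) != n || ncol(w) != n)
    stopf("adjacency matrix must be %d x %d", n, n)
  if (any(abs(w - t(w)) > 1e-12)) stopf("adjacency matrix must be symmetric")
  if (any(diag(w) != 0)) stopf("adjacency matrix must have a zero diagonal")
  ex <- ex_raw / sum(ex_raw)
  r <- ex
  inv_deg <- ifelse(deg > 0, 1 / deg, 0)
  residuals <- numeric()
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    r_new <- (1 - d) * ex + d * as.vector(crossprod(w, r * inv_deg))
    res <- sum(abs(r_new - r))
    residuals <- c(residuals, res)
    r <- r_new
    if (res <= epsilon) { converged <- TRUE; break }
  }
  names(r) <- names(ex_raw)
  list(r = r, ex = ex, d = d, epsilon = epsilon, iterations = iter,
       converged = converged, residuals = residuals)
}

#' Hypergeometric enrichment p-value for a pathway
#'
#' Probability of observing at least `x` differential genes in a pathway of
#' `M` genes, given `Nd` differential genes in a universe of `U`:
#' `p = 1 - sum_{i=0}^{x-1} C(M,i) C(U-M, Nd-i) / C(U, Nd)`, evaluated as
#' the numerically safe upper tail of the hypergeometric distribution.
#' All arguments are vectorized.
#'
#' @param U universe size (e.g. genes in the expression matrix, or a fixed
#'   genome size).
#' @param Nd number of differential genes in the universe.
#' @param M pathway size.
#' @param x differential genes in the pathway.
#' @return p-value(s) in (0, 1]; `x = 0` gives exactly 1.
#' @export
hypergeometric_pvalue <- function(U, Nd, M, x) {
  n <- max(length(U), length(Nd), length(M), length(x))
  U <- rep_len(U, n); Nd <- rep_len(Nd, n)
  M <- rep_len(M, n); x <- rep_len(x, n)
  if (any(M > U) || any(Nd > U))
    stopf("pathway size and differential gene count cannot exceed the universe")
  if (any(x < 0) || any(x > pmin(M, Nd)))
    stopf("x must satisfy 0 <= x <= min(M, Nd)")
  stats::phyper(x - 1, M, U - M, Nd, lower.tail = FALSE)
}

#' Rank pathways by GeneRank with hypergeometric annotation
#'
#' Runs [generank()] seeded with the per-pathway mutual information on the
#' thresholded pathway network, orders pathways by descending score (ties:
#' descending MI, then pathway name), and attaches the enrichment p-value of
#' each pathway.
#'
#' @param mi named per-pathway mutual information vector (the seed).
#' @param net a `pathway_network` from [build_network()].
#' @param enrich list/data frame with per-pathway `U`, `Nd`, `M`, `x` (see
#'   [hypergeometric_pvalue()]); `U` and `Nd` may be scalars.
#' @param d,epsilon,max_iter passed to [generank()].
#' @param adjust_p apply Benjamini-Hochberg to the p-values (default FALSE:
#'   raw hypergeometric p-values are reported).
#' @return class `"rank_result"`: the [generank()] fields plus `mi`,
#'   `pvalues`, `order` (integer ranking permutation) and `table`, a data
#'   frame in final rank order with columns rank, pathway, size, x, mi, r,
#'   pvalue.
#' @export
rank_pathways <- function(mi, net, enrich, d = 0.85, epsilon = 1e-10,
                          max_iter = 1000L, adjust_p = FALSE) {
  if (!identical(names(mi), net$pathways))
    stopf("pathway names of the seed and the network are not aligned")
  gr <- generank(mi, net$w, net$deg, d = d, epsilon = epsilon,
                 max_iter = max_iter)
  p <- hypergeometric_pvalue(enrich$U, enrich$Nd, enrich$M, enrich$x)
  if (adjust_p) p <- stats::p.adjust(p, method = "BH")
  names(p) <- names(mi)
  ord <- order(-gr$r, -mi, names(mi))
  tab <- data.frame(rank = seq_along(ord),
                    pathway = names(mi)[ord],
                    size = rep_len(enrich$M, length(mi))[ord],
                    x = rep_len(enrich$x, length(mi))[ord],
                    mi = unname(mi[ord]),
                    r = unname(gr$r[ord]),
                    pvalue = unname(p[ord]),
                    stringsAsFactors = FALSE)
  structure(c(gr, list(mi = mi, pvalues = p, order = ord, table = tab)),
            class = "rank_result")
}

#' @export
print.rank_result <- function(x, n = 10L, ...) {
  cat("rank_result:", length(x$r), "pathways; GeneRank d =", x$d,
      "; converged =", x$converged, "in", x$iterations, "iterations\n")
  print(utils::head(x$table, n))
  invisible(x)
}

#' Write a ranked pathway table as TSV
#'
#' One row per retained pathway in final rank order (descending GeneRank
#' score; ties by descending mutual information, then pathway name).
#'
#' @param result a `rank_result`.
#' @param path output path.
#' @export
write_rank_table <- function(result, path) {
  utils::write.table(result$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
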