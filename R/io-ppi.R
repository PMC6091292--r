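#' Read an undirected protein-protein interaction network
#'
#' Expects a tab-separated edge list with two identifier columns; extra
#' columns are ignored. Edges are undirected: duplicated edges and reversed
#' orientations collapse to one edge; self-loops are dropped (count reported
#' via a message). The file must not contain a header row unless
#' `skip_header = TRUE`.
#'
#' @param path path to the edge-list TSV.
#' @param skip_header skip the first line.
#' @return two-column character matrix of canonical edges (columns `from`,
#'   `to` with `from < to` lexicographically), class `"ppi_network"`; the
#'   number of dropped self-loops is attached as attribute `n_self_loops`.
#' @export
read_ppi <- function(path, skip_header = FALSE) {
  df <- tryCatch(
    utils::read.delim(path, header = FALSE, sep = "\t",
                      stringsAsFactors = FALSE, colClasses = "character",
                      quote = "", skip = if (skip_header) 1L else 0L),
    error = function(e) stopf("PPI file '%s' is empty or unreadable", path))
  if (nrow(df) == 0L || ncol(df) < 2L)
    stopf("PPI file '%s' is empty or lacks two columns", path)
  ppi_network(df[[1L]], df[[2L]])
}

#' Construct a canonical undirected PPI network from endpoint vectors
#' @param a,b character vectors of interacting gene identifiers.
#' @return see [read_ppi()].
#' @export
ppi_network <- function(a, b) {
  self <- a == b
  n_self <- sum(self)
  if (n_self) message("read_ppi: dropped ", n_self, " self-loop(s)")
  a2 <- pmin(a[!self], b[!self])
  b2 <- pmax(a[!self], b[!self])
  keep <- !duplicated(paste(a2, b2, sep = "\r"))
  m <- cbind(from = a2[keep], to = b2[keep])
  class(m) <- c("ppi_network", class(m))
  attr(m, "n_self_loops") <- n_self
  m
}

#' Write a PPI network as an edge-list TSV
#' @param ppi object from [read_ppi()] / [ppi_network()].
#' @param path output path.
#' @export
write_ppi <- function(ppi, path) {
  utils::write.table(unclass(ppi)[, 1:2, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
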