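#' Pathway activity scores
#'
#' The activity of a pathway in a sample is the arithmetic mean of the
#' expression values of the pathway's candidate genes in that sample.
#'
#' @param pcm a `pathway_candidate_map` (every pathway must have >= 1
#'   candidate gene).
#' @param expr genes x samples numeric matrix.
#' @return pathways x samples numeric matrix.
#' @export
activity_scores <- function(pcm, expr) {
  if (any(pcm$p == 0L))
    stopf("activity_scores: pathway(s) with zero candidate genes must be pre-filtered")
  a <- t(vapply(pcm$candidates, function(g)
    colMeans(expr[g, , drop = FALSE]), numeric(ncol(expr))))
  rownames(a) <- names(pcm$candidates)
  a
}

#' Discretize an activity vector into equal-width bins
#'
#' Uses `B = floor(log2(m) + 1)` equal-width bins spanning the observed
#' range of the vector (m = number of samples). The maximum lands in the top
#' bin; a constant vector collapses into bin 0.
#'
#' @param a_row numeric activity vector.
#' @param m number of samples used for the bin count (defaults to
#'   `length(a_row)`).
#' @return integer vector of bin indices in `0 .. B-1`, with the bin count
#'   attached as attribute `B`.
#' @export
discretize_activity <- function(a_row, m = length(a_row)) {
  if (m < 2L) stopf("discretize_activity needs at least 2 samples")
  B <- as.integer(floor(log2(m) + 1))
  lo <- min(a_row); hi <- max(a_row)
  if (hi == lo) {
    idx <- rep(0L, length(a_row))
  } else {
    idx <- as.integer(floor((a_row - lo) / (hi - lo) * B))
    idx[idx == B] <- B - 1L
  }
  attr(idx, "B") <- B
  idx
}

#' Mutual information between two discrete vectors, in bits
#'
#' Plug-in estimate from empirical joint frequencies:
#' `sum p(x,y) log2(p(x,y) / (p(x) p(y)))`, with zero-count cells
#' contributing 0. No pseudo-counts or bias correction.
#'
#' @param a_disc integer vector (e.g. discretized activity).
#' @param labels integer vector of the same length (e.g. 0/1 phenotype).
#' @return non-negative scalar mutual information in bits.
#' @export
mutual_information <- function(a_disc, labels) {
  if (length(a_disc) != length(labels))
    stopf("mutual_information: vectors differ in length (%d vs %d)",
          length(a_disc), length(labels))
  joint <- table(a_disc, labels)
  pj <- joint / sum(joint)
  px <- rowSums(pj); py <- colSums(pj)
  nz <- pj > 0
  expected <- outer(px, py)
  sum(pj[nz] * log2(pj[nz] / expected[nz]))
}

#' Per-pathway mutual information with the phenotype
#'
#' Discretizes each pathway's activity vector and scores it against the
#' binary phenotype with [mutual_information()].
#'
#' @param activity pathways x samples matrix from [activity_scores()].
#' @param pheno named 0/1 vector; sample names must match the activity
#'   matrix's columns.
#' @return named numeric vector of mutual information (bits) per pathway.
#' @export
phenotype_scores <- function(activity, pheno) {
  pheno <- align_phenotype(activity, pheno)
  check_binary_labels(pheno)
  apply(activity, 1L, function(row)
    mutual_information(discretize_activity(row), pheno))
}

#' Build a full activity profile (activity, discretization, MI)
#'
#' @param pcm a `pathway_candidate_map`.
#' @param expr genes x samples matrix.
#' @param pheno named 0/1 phenotype vector.
#' @return class `"activity_profile"`: list with `activity` (matrix),
#'   `disc` (integer matrix of bin indices), `B` (bin count), `mi`
#'   (named vector, bits).
#' @export
activity_profile <- function(pcm, expr, pheno) {
  a <- activity_scores(pcm, expr)
  pheno <- align_phenotype(a, pheno)
  disc <- t(apply(a, 1L, discretize_activity))
  dimnames(disc) <- dimnames(a)
  structure(list(activity = a, disc = disc,
                 B = as.integer(floor(log2(ncol(a)) + 1)),
                 mi = phenotype_scores(a, pheno)),
            class = "activity_profile")
}

#' @export
print.activity_profile <- function(x, ...) {
  cat("activity_profile:", nrow(x$activity), "pathways x", ncol(x$activity),
      "samples;", x$B, "bins; MI range",
      sprintf("%.3f-%.3f bits\n", min(x$mi), max(x$mi)))
  invisible(x)
}
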