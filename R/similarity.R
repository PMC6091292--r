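#' Contribution factors for the Wang term-similarity measure
#'
#' Each edge on a path toward the root multiplies the semantic contribution
#' of an ancestor by the relation's factor.
#'
#' @param is_a factor for `is_a` edges (default 0.8).
#' @param part_of factor for `part_of` edges (default 0.6).
#' @return named list of factors, each in (0, 1).
#' @export
term_similarity_params <- function(is_a = 0.8, part_of = 0.6) {
  if (!(is_a > 0 && is_a < 1 && part_of > 0 && part_of < 1))
    stopf("contribution factors must lie in (0, 1)")
  list(is_a = is_a, part_of = part_of)
}

# S-values of a term over its ancestor closure (term included): S(t) = 1,
# and each ancestor's S is the max over its children (within the closure) of
# child S times the edge factor. Relaxation terminates because factors < 1.
term_svalues <- function(term, dag, params, cache = NULL) {
  if (!is.null(cache)) {
    hit <- cache[[term]]
    if (!is.null(hit)) return(hit)
  }
  s <- c(1); names(s) <- term
  queue <- term
  while (length(queue)) {
    node <- queue[[1L]]; queue <- queue[-1L]
    rows <- dag$parent_idx[[node]]
    for (i in rows) {
      parent <- dag$edges$parent[i]
      w <- params[[dag$edges$relation[i]]]
      cand <- s[[node]] * w
      if (is.na(s[parent]) || cand > s[[parent]]) {
        s[parent] <- cand
        queue <- c(queue, parent)
      }
    }
  }
  if (!is.null(cache)) cache[[term]] <- s
  s
}

#' Wang graph-based semantic similarity between two ontology terms
#'
#' Both terms' ancestor closures are scored with semantic contributions
#' (S-values) that decay by the relation factors along each path to the
#' root; the similarity is the summed S-values of the shared ancestors
#' divided by the two terms' total semantic values.
#'
#' @param t1,t2 term identifiers (must share a namespace).
#' @param dag an [ontology_dag()].
#' @param params factors from [term_similarity_params()].
#' @return similarity in \[0, 1\]; 1 iff the terms coincide (for factors
#'   < 1).
#' @export
wang_term_similarity <- function(t1, t2, dag,
                                 params = term_similarity_params()) {
  if (term_namespace(dag, t1) != term_namespace(dag, t2))
    stopf("terms '%s' and '%s' are in different namespaces", t1, t2)
  s1 <- term_svalues(t1, dag, params)
  s2 <- term_svalues(t2, dag, params)
  common <- intersect(names(s1), names(s2))
  if (!length(common)) return(0)
  sum(s1[common] + s2[common]) / (sum(s1) + sum(s2))
}

# Best-match average of a term-similarity matrix: the mean of the row maxima
# averaged with the mean of the column maxima.
bma <- function(simmat) {
  (mean(apply(simmat, 1L, max)) + mean(apply(simmat, 2L, max))) / 2
}

#' Gene-gene semantic similarity (best-match average over namespaces)
#'
#' Within each namespace where both genes carry annotations, the pairwise
#' term similarities are combined by best-match average; the final score is
#' the mean over those namespaces. Genes without a shared annotated
#' namespace score 0.
#'
#' @param g1,g2 gene identifiers.
#' @param ann an `annotation_map`.
#' @param dag an [ontology_dag()].
#' @param params factors from [term_similarity_params()].
#' @param namespaces namespaces considered (default BP, MF, CC).
#' @return similarity in \[0, 1\].
#' @export
gene_similarity <- function(g1, g2, ann, dag,
                            params = term_similarity_params(),
                            namespaces = c("BP", "MF", "CC")) {
  per_ns <- numeric()
  for (space in namespaces) {
    ts1 <- ann[[space]][[g1]]; ts2 <- ann[[space]][[g2]]
    if (is.null(ts1) || is.null(ts2)) next
    m <- outer(ts1, ts2, Vectorize(function(a, b)
      wang_term_similarity(a, b, dag, params)))
    per_ns <- c(per_ns, bma(matrix(m, nrow = length(ts1))))
  }
  if (!length(per_ns)) 0 else mean(per_ns)
}

#' Pathway-pathway similarity from candidate-gene similarities
#'
#' The similarity of two pathways is the sum of the semantic similarities
#' over all ordered cross pairs of their candidate genes, divided by the
#' total number of genes `M + N`. Note the value is not bounded by 1: its
#' maximum `M*N/(M+N)` is attained when every gene pair has similarity 1,
#' and identical singleton sets score 0.5.
#'
#' @param genes_i,genes_j non-empty character vectors of candidate genes.
#' @param gene_sim symmetric numeric matrix of gene-gene similarities with
#'   gene ids as dimnames (as produced by [similarity_matrix()]), or a
#'   function `(g1, g2) -> similarity`.
#' @param floor minimum per-pair similarity to count (default 0 = all pairs).
#' @return non-negative scalar.
#' @export
pathway_similarity <- function(genes_i, genes_j, gene_sim, floor = 0) {
  if (!length(genes_i) || !length(genes_j))
    stopf("pathway_similarity: empty gene set")
  vals <- if (is.function(gene_sim)) {
    m <- matrix(0, length(genes_i), length(genes_j))
    for (i in seq_along(genes_i))
      for (j in seq_along(genes_j))
        m[i, j] <- gene_sim(genes_i[i], genes_j[j])
    m
  } else {
    gene_sim[genes_i, genes_j, drop = FALSE]
  }
  vals[vals < floor] <- 0
  sum(vals) / (length(genes_i) + length(genes_j))
}

#' Pairwise pathway similarity matrix
#'
#' Computes the gene-gene semantic similarity once for every pair of
#' candidate genes across the retained pathways (S-values and term-pair
#' similarities are cached), then evaluates the pathway-level similarity for
#' every pathway pair.
#'
#' @param pcm a `pathway_candidate_map` with >= 2 retained pathways.
#' @param ann an `annotation_map`.
#' @param dag an [ontology_dag()].
#' @param params factors from [term_similarity_params()].
#' @param namespaces namespaces to combine (default BP, MF, CC).
#' @param floor per-pair similarity floor passed to [pathway_similarity()].
#' @return list with `sim` (symmetric pathways x pathways matrix, including
#'   the diagonal self-similarities) and `gene_sim` (the cached gene-gene
#'   similarity matrix).
#' @export
similarity_matrix <- function(pcm, ann, dag,
                              params = term_similarity_params(),
                              namespaces = c("BP", "MF", "CC"),
                              floor = 0) {
  pws <- names(pcm$candidates)
  if (length(pws) < 2L) stopf("need at least 2 retained pathways")
  genes <- sort(unique(unlist(pcm$candidates, use.names = FALSE)))
  svcache <- new.env(parent = emptyenv())
  tcache <- new.env(parent = emptyenv())
  term_sim_cached <- function(a, b) {
    key <- if (a < b) paste(a, b) else paste(b, a)
    hit <- tcache[[key]]
    if (!is.null(hit)) return(hit)
    if (term_namespace(dag, a) != term_namespace(dag, b))
      stopf("terms '%s' and '%s' are in different namespaces", a, b)
    s1 <- term_svalues(a, dag, params, svcache)
    s2 <- term_svalues(b, dag, params, svcache)
    common <- intersect(names(s1), names(s2))
    val <- if (!length(common)) 0 else
      sum(s1[common] + s2[common]) / (sum(s1) + sum(s2))
    tcache[[key]] <- val
    val
  }
  gene_sim_pair <- function(g1, g2) {
    per_ns <- numeric()
    for (space in namespaces) {
      ts1 <- ann[[space]][[g1]]; ts2 <- ann[[space]][[g2]]
      if (is.null(ts1) || is.null(ts2)) next
      m <- matrix(0, length(ts1), length(ts2))
      for (i in seq_along(ts1))
        for (j in seq_along(ts2))
          m[i, j] <- term_sim_cached(ts1[i], ts2[j])
      per_ns <- c(per_ns, bma(m))
    }
    if (!length(per_ns)) 0 else mean(per_ns)
  }
  ng <- length(genes)
  G <- matrix(0, ng, ng, dimnames = list(genes, genes))
  for (i in seq_len(ng)) {
    G[i, i] <- gene_sim_pair(genes[i], genes[i])
    for (j in seq_len(i - 1L)) {
      G[i, j] <- G[j, i] <- gene_sim_pair(genes[i], genes[j])
    }
  }
  n <- length(pws)
  S <- matrix(0, n, n, dimnames = list(pws, pws))
  for (i in seq_len(n)) {
    for (j in seq_len(i)) {
      S[i, j] <- S[j, i] <- pathway_similarity(pcm$candidates[[i]],
                                               pcm$candidates[[j]],
                                               G, floor = floor)
    }
  }
  list(sim = S, gene_sim = G)
}

#' Threshold a pathway similarity matrix into a network
#'
#' Pathways i and j (i != j) are connected when their similarity is at
#' least `theta`; the diagonal is always 0. Degrees are row sums of the
#' adjacency. Isolated pathways are retained (the ranking step handles
#' them).
#'
#' @param sim symmetric similarity matrix (e.g. `similarity_matrix()$sim`).
#' @param theta absolute threshold; if `NULL`, taken as the `percentile`-th
#'   percentile of the off-diagonal similarity distribution.
#' @param percentile percentile (0-100) used when `theta` is `NULL`
#'   (default 75).
#' @param weighted if `TRUE`, edges carry the similarity as weight instead
#'   of 1.
#' @return class `"pathway_network"`: list with `pathways`, `sim`, `theta`,
#'   `w` (adjacency), `deg` (degree vector), `weighted`.
#' @export
build_network <- function(sim, theta = NULL, percentile = 75,
                          weighted = FALSE) {
  off <- sim[upper.tri(sim)]
  if (is.null(theta)) {
    theta <- as.numeric(stats::quantile(off, percentile / 100,
                                        names = FALSE, type = 7))
  }
  if (theta < 0) stopf("theta must be non-negative")
  w <- (sim >= theta) * (if (weighted) sim else 1)
  diag(w) <- 0
  structure(list(pathways = rownames(sim), sim = sim, theta = theta,
                 w = w, deg = rowSums(w), weighted = weighted),
            class = "pathway_network")
}

#' @export
print.pathway_network <- function(x, ...) {
  cat("pathway_network:", length(x$pathways), "pathways,",
      sum(x$w[upper.tri(x$w)] > 0), "edges at theta =",
      format(x$theta, digits = 4),
      if (x$weighted) "(weighted)\n" else "(binary)\n")
  invisible(x)
}
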