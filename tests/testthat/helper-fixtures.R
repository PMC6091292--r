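# shared fixtures, all built in code at test time

# two siblings under one root, is_a edges: the worked Wang example
toy_sibling_dag <- function() {
  ontology_dag(
    terms = data.frame(id = c("GO:0000001", "GO:0000002", "GO:0000003"),
                       name = c("root", "A", "B"), namespace = "BP",
                       obsolete = FALSE, stringsAsFactors = FALSE),
    edges = data.frame(child = c("GO:0000002", "GO:0000003"),
                       parent = "GO:0000001", relation = "is_a",
                       stringsAsFactors = FALSE))
}

# random single-namespace DAG: term i >= 2 attaches to 1-2 earlier terms
random_dag <- function(n_terms = 40L, seed = 1L, namespace = "BP",
                       id_offset = 0L) {
  set.seed(seed)
  ids <- sprintf("GO:%07d", seq_len(n_terms) + id_offset)
  child <- character(); parent <- character(); rel <- character()
  for (i in 2:n_terms) {
    k <- sample(1:2, 1L)
    ps <- sample(seq_len(i - 1L), min(k, i - 1L))
    child <- c(child, rep(ids[i], length(ps)))
    parent <- c(parent, ids[ps])
    rel <- c(rel, sample(c("is_a", "part_of"), length(ps), replace = TRUE))
  }
  ontology_dag(
    terms = data.frame(id = ids, name = ids, namespace = namespace,
                       obsolete = FALSE, stringsAsFactors = FALSE),
    edges = data.frame(child = child, parent = parent, relation = rel,
                       stringsAsFactors = FALSE))
}

# small, cheap synthetic benchmark for module tests
tiny_spec <- function(seed = 1L, effect_size = 1.5, ...) {
  synthetic_spec(n_genes = 300L, n_normal = 20L, n_tumor = 20L,
                 n_pathways = 10L, pathway_size_range = c(5L, 10L),
                 n_planted = 2L, effect_size = effect_size,
                 ppi_p_within = 0.4, ppi_p_background = 0.01,
                 seed = seed, ...)
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# independent brute-force MI oracle: explicit loops over the joint support
mi_oracle <- function(a, c) {
  m <- length(a)
  total <- 0
  for (x in unique(a)) {
    for (y in unique(c)) {
      pxy <- sum(a == x & c == y) / m
      if (pxy > 0) {
        px <- sum(a == x) / m
        py <- sum(c == y) / m
        total <- total + pxy * log2(pxy / (px * py))
      }
    }
  }
  total
}

# independent hypergeometric oracle: log-space cumulative sum of Eq terms
hyper_oracle <- function(U, Nd, M, x) {
  if (x == 0) return(1)
  i <- 0:(x - 1)
  1 - sum(exp(lchoose(M, i) + lchoose(U - M, Nd - i) - lchoose(U, Nd)))
}

# independent GeneRank oracle: direct linear solve of the stationary system
generank_oracle <- function(ex_raw, w, d) {
  ex <- ex_raw / sum(ex_raw)
  deg <- rowSums(w)
  inv_deg <- ifelse(deg > 0, 1 / deg, 0)
  n <- length(ex)
  A <- diag(n) - d * t(w) %*% diag(inv_deg)
  as.vector(solve(A, (1 - d) * ex))
}
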