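#' Specification for a synthetic case-control benchmark
#'
#' Defines the statistical structure of a generated dataset: standard-normal
#' log-scale expression background, a set of pathways sampled from the gene
#' universe with bounded pairwise overlap, a subset of "planted" disease
#' pathways whose member genes gain `effect_size` (in SD units) in tumor
#' samples, a PPI network enriched within pathways, and a three-namespace
#' ontology in which each pathway owns a small theme of leaf terms annotated
#' to most of its members (making within-pathway genes semantically close).
#'
#' @param n_genes gene universe size (default 2000).
#' @param n_normal,n_tumor samples per class (default 50 each).
#' @param n_pathways number of pathways (default 50).
#' @param pathway_size_range inclusive size range (default 10-40).
#' @param n_planted number of planted disease pathways (default 3).
#' @param effect_size tumor mean shift for planted genes, SD units
#'   (default 1.5).
#' @param ppi_p_within PPI edge probability within a pathway (default 0.3).
#' @param ppi_p_background background PPI edge probability (default 0.002).
#' @param ontology_depth depth of each namespace DAG, root included
#'   (default 4).
#' @param terms_per_pathway_theme leaf terms per pathway theme (default 3).
#' @param max_overlap maximum genes shared by any two pathways (default 2).
#' @param seed integer seed.
#' @return class `"synthetic_spec"` (validated list of the above).
#' @export
synthetic_spec <- function(n_genes = 2000L, n_normal = 50L, n_tumor = 50L,
                           n_pathways = 50L, pathway_size_range = c(10L, 40L),
                           n_planted = 3L, effect_size = 1.5,
                           ppi_p_within = 0.3, ppi_p_background = 0.002,
                           ontology_depth = 4L, terms_per_pathway_theme = 3L,
                           max_overlap = 2L, seed = 1L) {
  spec <- list(n_genes = as.integer(n_genes), n_normal = as.integer(n_normal),
               n_tumor = as.integer(n_tumor),
               n_pathways = as.integer(n_pathways),
               pathway_size_range = rep_len(as.integer(pathway_size_range), 2L),
               n_planted = as.integer(n_planted),
               effect_size = effect_size, ppi_p_within = ppi_p_within,
               ppi_p_background = ppi_p_background,
               ontology_depth = as.integer(ontology_depth),
               terms_per_pathway_theme = as.integer(terms_per_pathway_theme),
               max_overlap = as.integer(max_overlap),
               seed = as.integer(seed))
  if (spec$n_planted > spec$n_pathways)
    stopf("n_planted cannot exceed n_pathways")
  if (spec$effect_size < 0) stopf("effect_size must be >= 0")
  if (spec$ppi_p_within < 0 || spec$ppi_p_within > 1 ||
      spec$ppi_p_background < 0 || spec$ppi_p_background > 1)
    stopf("PPI edge probabilities must lie in [0, 1]")
  if (spec$pathway_size_range[2L] > spec$n_genes)
    stopf("pathway sizes cannot exceed the gene universe")
  if (spec$ontology_depth < 4L) stopf("ontology_depth must be >= 4")
  structure(spec, class = "synthetic_spec")
}

# one namespace DAG: root -> domain chain(s) -> per-pathway theme -> leaves
make_namespace_dag <- function(space, n_pathways, depth, n_leaves, counter) {
  new_id <- function() {
    counter$n <- counter$n + 1L
    sprintf("GO:%07d", counter$n)
  }
  n_domains <- 5L
  root <- new_id()
  terms <- data.frame(id = root, name = paste0(space, " root"),
                      namespace = space, obsolete = FALSE,
                      stringsAsFactors = FALSE)
  edges <- data.frame(child = character(), parent = character(),
                      relation = character(), stringsAsFactors = FALSE)
  add_term <- function(id, name) {
    terms <<- rbind(terms, data.frame(id = id, name = name, namespace = space,
                                      obsolete = FALSE,
                                      stringsAsFactors = FALSE))
  }
  add_edge <- function(child, parent, relation) {
    edges <<- rbind(edges, data.frame(child = child, parent = parent,
                                      relation = relation,
                                      stringsAsFactors = FALSE))
  }
  # chain of (depth - 3) internal levels per domain so total depth is met
  domain_tips <- character(n_domains)
  for (dmn in seq_len(n_domains)) {
    parent <- root
    for (lvl in seq_len(depth - 3L)) {
      id <- new_id()
      add_term(id, sprintf("%s domain %d level %d", space, dmn, lvl))
      add_edge(id, parent, "is_a")
      parent <- id
    }
    domain_tips[dmn] <- parent
  }
  theme_leaves <- vector("list", n_pathways)
  for (pw in seq_len(n_pathways)) {
    theme <- new_id()
    add_term(theme, sprintf("%s theme %d", space, pw))
    add_edge(theme, domain_tips[((pw - 1L) %% n_domains) + 1L],
             if (pw %% 4L == 0L) "part_of" else "is_a")
    leaves <- character(n_leaves)
    for (l in seq_len(n_leaves)) {
      leaves[l] <- new_id()
      add_term(leaves[l], sprintf("%s theme %d leaf %d", space, pw, l))
      add_edge(leaves[l], theme, "is_a")
    }
    theme_leaves[[pw]] <- leaves
  }
  list(terms = terms, edges = edges, theme_leaves = theme_leaves)
}

#' Generate a synthetic benchmark bundle
#'
#' Draws a complete dataset (expression, phenotype, pathways, PPI network,
#' ontology, annotations) from a [synthetic_spec()], deterministically under
#' the spec's seed. The returned `truth` element names the planted pathways
#' and their member genes.
#'
#' @param spec a [synthetic_spec()].
#' @return class `"synthetic_bundle"`: list with `expr`, `pheno`,
#'   `pathways`, `ppi`, `dag`, `ann`, `truth`, `spec`.
#' @export
generate_bundle <- function(spec = synthetic_spec()) {
  set.seed(spec$seed)
  genes <- sprintf("G%05d", seq_len(spec$n_genes))
  samples <- sprintf("S%03d", seq_len(spec$n_normal + spec$n_tumor))
  labels <- c(rep(0L, spec$n_normal), rep(1L, spec$n_tumor))
  names(labels) <- samples

  # pathways: uniform sizes, resample until pairwise overlap is bounded
  size_choices <- seq.int(spec$pathway_size_range[1L],
                          spec$pathway_size_range[2L])
  sizes <- size_choices[sample.int(length(size_choices), spec$n_pathways,
                                   replace = TRUE)]
  pathways <- vector("list", spec$n_pathways)
  names(pathways) <- sprintf("PW%02d", seq_len(spec$n_pathways))
  for (i in seq_len(spec$n_pathways)) {
    for (try in seq_len(200L)) {
      cand <- sample(genes, sizes[i])
      ok <- TRUE
      for (j in seq_len(i - 1L)) {
        if (length(intersect(cand, pathways[[j]])) > spec$max_overlap) {
          ok <- FALSE; break
        }
      }
      if (ok) break
    }
    if (!ok) stopf("could not sample pathway %d within the overlap bound", i)
    pathways[[i]] <- cand
  }
  attr(pathways, "description") <- sprintf("synthetic pathway %d",
                                           seq_len(spec$n_pathways))
  planted <- sort(sample(names(pathways), spec$n_planted))
  planted_genes <- sort(unique(unlist(pathways[planted], use.names = FALSE)))

  # expression: N(0,1) background, planted genes shifted in tumor samples
  expr <- matrix(stats::rnorm(spec$n_genes * length(samples)),
                 nrow = spec$n_genes, dimnames = list(genes, samples))
  expr[planted_genes, labels == 1L] <-
    expr[planted_genes, labels == 1L] + spec$effect_size

  # PPI: Bernoulli background over all pairs plus within-pathway enrichment
  n_bg <- stats::rbinom(1L, choose(spec$n_genes, 2L), spec$ppi_p_background)
  bg_a <- sample(genes, n_bg, replace = TRUE)
  bg_b <- sample(genes, n_bg, replace = TRUE)
  within_a <- character(); within_b <- character()
  for (members in pathways) {
    prs <- utils::combn(sort(members), 2L)
    pick <- stats::runif(ncol(prs)) < spec$ppi_p_within
    within_a <- c(within_a, prs[1L, pick])
    within_b <- c(within_b, prs[2L, pick])
  }
  keep <- bg_a != bg_b
  ppi <- ppi_network(c(bg_a[keep], within_a), c(bg_b[keep], within_b))

  # ontology + annotations: per namespace, each pathway owns a leaf theme
  counter <- new.env(parent = emptyenv()); counter$n <- 0L
  terms <- NULL; edges <- NULL
  theme_leaves <- list()
  for (space in c("BP", "MF", "CC")) {
    ns <- make_namespace_dag(space, spec$n_pathways, spec$ontology_depth,
                             spec$terms_per_pathway_theme, counter)
    terms <- rbind(terms, ns$terms)
    edges <- rbind(edges, ns$edges)
    theme_leaves[[space]] <- ns$theme_leaves
  }
  dag <- ontology_dag(terms, edges)
  ann <- list(BP = list(), MF = list(), CC = list())
  all_leaves <- lapply(theme_leaves, function(x) unlist(x))
  for (space in c("BP", "MF", "CC")) {
    per_gene <- stats::setNames(vector("list", spec$n_genes), genes)
    for (pw in seq_len(spec$n_pathways)) {
      members <- pathways[[pw]]
      n_annot <- ceiling(0.8 * length(members)) +
        stats::rbinom(1L, length(members) - ceiling(0.8 * length(members)), 0.5)
      chosen <- sample(members, n_annot)
      for (g in chosen) {
        k <- sample(spec$terms_per_pathway_theme, 1L)
        per_gene[[g]] <- c(per_gene[[g]],
                           sample(theme_leaves[[space]][[pw]], k))
      }
    }
    # sparse background annotations to random theme leaves
    bg_genes <- genes[stats::runif(spec$n_genes) < 0.1]
    for (g in bg_genes)
      per_gene[[g]] <- c(per_gene[[g]], sample(all_leaves[[space]], 1L))
    per_gene <- lapply(per_gene, unique)
    ann[[space]] <- per_gene[lengths(per_gene) > 0L]
  }
  ann <- structure(ann, class = "annotation_map")

  structure(list(expr = expr, pheno = labels, pathways = pathways,
                 ppi = ppi, dag = dag, ann = ann,
                 truth = list(planted_pathways = planted,
                              planted_genes = planted_genes),
                 spec = spec),
            class = "synthetic_bundle")
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat("synthetic_bundle:", nrow(x$expr), "genes x", ncol(x$expr), "samples;",
      length(x$pathways), "pathways (", length(x$truth$planted_pathways),
      "planted, effect", x$spec$effect_size, "SD );",
      nrow(x$ppi), "PPI edges\n")
  invisible(x)
}

#' Export a synthetic bundle to standard-format files
#'
#' Writes `expression.tsv`, `phenotype.tsv`, `pathways.gmt`, `ppi.tsv`,
#' `ontology.obo`, `annotations.gaf` and `truth.json` into a directory; the
#' first six round-trip through the package's readers.
#'
#' @param bundle a `synthetic_bundle`.
#' @param dir output directory (created if needed).
#' @return named vector of written paths, invisibly.
#' @export
export_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             phenotype = file.path(dir, "phenotype.tsv"),
             pathways = file.path(dir, "pathways.gmt"),
             ppi = file.path(dir, "ppi.tsv"),
             ontology = file.path(dir, "ontology.obo"),
             annotations = file.path(dir, "annotations.gaf"),
             truth = file.path(dir, "truth.json"))
  write_expression(bundle$expr, paths[["expression"]])
  write_phenotype(bundle$pheno, paths[["phenotype"]])
  write_gene_sets(bundle$pathways, paths[["pathways"]])
  write_ppi(bundle$ppi, paths[["ppi"]])
  write_ontology(bundle$dag, paths[["ontology"]])
  write_annotations(bundle$ann, paths[["annotations"]])
  jsonlite::write_json(bundle$truth, paths[["truth"]], auto_unbox = FALSE)
  invisible(paths)
}
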