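#' Build and validate a pipeline run configuration
#'
#' Input paths plus every tunable parameter of the pipeline. Unknown keys
#' are rejected; parameters are checked against their documented ranges.
#'
#' @param expression,phenotype,gene_sets,ppi,ontology,annotations input file
#'   paths (see the `read_*` readers); may be `NULL` when the pipeline is
#'   run on in-memory objects.
#' @param q_threshold,min_abs_diff DEG thresholds ([differential_genes()]).
#' @param theta absolute network threshold, or `NULL` to use
#'   `theta_percentile`.
#' @param theta_percentile percentile fallback for theta (default 75).
#' @param d,epsilon,max_iter GeneRank parameters ([generank()]).
#' @param k_features feature genes for evaluation (default 80).
#' @param folds,repeats cross-validation shape (default 10 x 10).
#' @param seed integer seed for the evaluation.
#' @param weighted_network use similarity weights instead of 0/1 edges.
#' @param namespaces ontology namespaces combined in the gene similarity.
#' @param adjust_p BH-adjust the hypergeometric p-values.
#' @param universe `"expression"` (genes in the matrix) or a fixed integer
#'   genome size for the enrichment universe.
#' @param evaluate run the classification evaluation stage (default TRUE).
#' @return class `"pathnet_config"` (validated named list).
#' @export
pathnet_config <- function(expression = NULL, phenotype = NULL,
                           gene_sets = NULL, ppi = NULL, ontology = NULL,
                           annotations = NULL,
                           q_threshold = 0.05, min_abs_diff = 1.0,
                           theta = NULL, theta_percentile = 75,
                           d = 0.85, epsilon = 1e-10, max_iter = 1000L,
                           k_features = 80L, folds = 10L, repeats = 10L,
                           seed = 1L, weighted_network = FALSE,
                           namespaces = c("BP", "MF", "CC"),
                           adjust_p = FALSE, universe = "expression",
                           evaluate = TRUE) {
  cfg <- as.list(environment())
  if (cfg$q_threshold <= 0 || cfg$q_threshold > 1)
    stopf("q_threshold must lie in (0, 1]")
  if (cfg$min_abs_diff < 0) stopf("min_abs_diff must be >= 0")
  if (cfg$d < 0 || cfg$d > 1) stopf("d must lie in [0, 1]")
  if (cfg$epsilon <= 0) stopf("epsilon must be positive")
  if (cfg$theta_percentile < 0 || cfg$theta_percentile > 100)
    stopf("theta_percentile must lie in [0, 100]")
  if (!all(cfg$namespaces %in% c("BP", "MF", "CC")))
    stopf("namespaces must be a subset of BP/MF/CC")
  if (!identical(cfg$universe, "expression") && !is.numeric(cfg$universe))
    stopf("universe must be \"expression\" or a fixed gene count")
  structure(cfg, class = "pathnet_config")
}

#' Load a pipeline configuration from a flat YAML file
#'
#' The file must contain only keys accepted by [pathnet_config()]; unknown
#' keys are a hard error. Values given on the command line (or in
#' `overrides`) take precedence.
#'
#' @param path YAML file of `key: value` pairs.
#' @param overrides named list merged over the file's values.
#' @return a `pathnet_config`.
#' @export
read_config <- function(path, overrides = list()) {
  vals <- yaml::read_yaml(path)
  vals[names(overrides)] <- overrides
  known <- names(formals(pathnet_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stopf("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
  do.call(pathnet_config, vals)
}

#' Run the full pathway-network analysis on in-memory objects
#'
#' Executes the method end to end: differential expression, PPI filtering,
#' pathway projection, activity + mutual information, GO-similarity pathway
#' network, GeneRank ranking with hypergeometric p-values and (optionally)
#' the SVM cross-validation evaluation against the t-test baseline.
#'
#' @param expr genes x samples matrix.
#' @param pheno named 0/1 phenotype vector.
#' @param pathways named list of gene sets.
#' @param ppi a `ppi_network`.
#' @param dag an `ontology_dag`.
#' @param ann an `annotation_map`.
#' @param config a [pathnet_config()] (paths therein are ignored).
#' @return class `"pathnet_result"`: list with `degs`, `cgs`, `pcm`,
#'   `profile`, `simnet` (similarity matrix + network), `rank`
#'   (`rank_result`), `evaluation` (method and baseline `cv_result`s or
#'   `NULL`), `metadata` (stage counts and parameters).
#' @export
pathnet_analyze <- function(expr, pheno, pathways, ppi, dag, ann,
                            config = pathnet_config()) {
  pheno <- align_phenotype(expr, pheno)
  degs <- differential_genes(expr, pheno, config$q_threshold,
                             config$min_abs_diff)
  message("stage deg: ", length(degs$degs), " differential genes of ",
          nrow(expr))
  cgs <- ppi_filter(degs, ppi)
  if (!length(cgs))
    stopf("candidate gene set is empty; relax q_threshold/min_abs_diff or check the PPI network")
  message("stage cgs: ", length(cgs), " candidate genes")
  pcm <- map_to_pathways(cgs, pathways, expr)
  if (length(pcm$candidates) < 2L)
    stopf("fewer than 2 pathways retain candidate genes; nothing to rank")
  message("stage pathways: ", length(pcm$candidates), " of ",
          length(pathways), " pathways retained")
  profile <- activity_profile(pcm, expr, pheno)
  sm <- similarity_matrix(pcm, ann, dag, namespaces = config$namespaces)
  net <- build_network(sm$sim, theta = config$theta,
                       percentile = config$theta_percentile,
                       weighted = config$weighted_network)
  message("stage network: ", sum(net$w[upper.tri(net$w)] > 0),
          " edges at theta = ", format(net$theta, digits = 4))
  U <- if (identical(config$universe, "expression")) nrow(expr)
       else as.integer(config$universe)
  deg_ids <- degs$degs
  enrich <- list(U = U, Nd = length(deg_ids),
                 M = pcm$size_total,
                 x = vapply(names(pcm$candidates), function(pw)
                   sum(pathways[[pw]] %in% deg_ids), integer(1L)))
  rank <- rank_pathways(profile$mi, net, enrich, d = config$d,
                        epsilon = config$epsilon,
                        max_iter = config$max_iter,
                        adjust_p = config$adjust_p)
  message("stage rank: GeneRank converged = ", rank$converged, " in ",
          rank$iterations, " iterations")
  evaluation <- NULL
  if (isTRUE(config$evaluate)) {
    feats <- select_feature_genes(rank, pcm, degs, k = config$k_features)
    base <- ttest_baseline(expr, pheno, k = length(feats$genes))
    evaluation <- list(
      features = feats,
      baseline_features = base,
      method = cv_auc(expr, pheno, feats, folds = config$folds,
                      repeats = config$repeats, seed = config$seed),
      baseline = cv_auc(expr, pheno, base, folds = config$folds,
                        repeats = config$repeats, seed = config$seed))
    message(sprintf("stage evaluate: method AUC %.4f vs t-test AUC %.4f",
                    evaluation$method$mean_auc,
                    evaluation$baseline$mean_auc))
  }
  metadata <- list(
    parameters = unclass(config)[setdiff(names(config),
                                         c("expression", "phenotype",
                                           "gene_sets", "ppi", "ontology",
                                           "annotations"))],
    theta_used = net$theta,
    counts = list(genes = nrow(expr), samples = ncol(expr),
                  degs = length(degs$degs), cgs = length(cgs),
                  pathways_input = length(pathways),
                  pathways_retained = length(pcm$candidates),
                  network_edges = sum(net$w[upper.tri(net$w)] > 0),
                  generank_iterations = rank$iterations))
  structure(list(degs = degs, cgs = cgs, pcm = pcm, profile = profile,
                 simnet = c(sm, list(network = net)), rank = rank,
                 evaluation = evaluation, metadata = metadata),
            class = "pathnet_result")
}

#' @export
print.pathnet_result <- function(x, ...) {
  cnt <- x$metadata$counts
  cat("pathnet_result:", cnt$degs, "DEGs ->", cnt$cgs, "candidate genes ->",
      cnt$pathways_retained, "pathways ranked\n")
  print(utils::head(x$rank$table, 5))
  invisible(x)
}

#' Run the configured pipeline from input files
#'
#' Reads every input named in the configuration, calls [pathnet_analyze()],
#' and writes the outputs (`rank_table.tsv`, `deg_table.tsv`,
#' `evaluation.json`, `metadata.json`) into `out_dir`.
#'
#' @param config a [pathnet_config()] with input paths set, or the path of
#'   a YAML configuration file.
#' @param out_dir output directory (created if needed); `NULL` writes
#'   nothing.
#' @return the `pathnet_result`, invisibly.
#' @export
run_pathnet <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_config(config)
  expr <- read_expression(config$expression)
  pheno <- read_phenotype(config$phenotype)
  pathways <- read_gene_sets(config$gene_sets)
  ppi <- read_ppi(config$ppi)
  dag <- read_ontology(config$ontology)
  ann <- read_annotations(config$annotations, dag)
  res <- pathnet_analyze(expr, pheno, pathways, ppi, dag, ann, config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_rank_table(res$rank, file.path(out_dir, "rank_table.tsv"))
    deg_tab <- res$degs$table
    deg_tab[c("t", "p", "q", "diff")] <-
      lapply(deg_tab[c("t", "p", "q", "diff")], function(v) sprintf("%.17g", v))
    utils::write.table(deg_tab, file.path(out_dir, "deg_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(res$evaluation)) {
      jsonlite::write_json(
        list(features = res$evaluation$features$genes,
             method_mean_auc = res$evaluation$method$mean_auc,
             baseline_mean_auc = res$evaluation$baseline$mean_auc,
             method_fold_auc = as.vector(res$evaluation$method$auc),
             baseline_fold_auc = as.vector(res$evaluation$baseline$auc)),
        file.path(out_dir, "evaluation.json"), auto_unbox = TRUE,
        digits = NA)
    }
    jsonlite::write_json(res$metadata, file.path(out_dir, "metadata.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(res)
}
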