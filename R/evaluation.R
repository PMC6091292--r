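#' Select feature genes from top-ranked pathways
#'
#' Walks the pathways in final rank order and, within each pathway, appends
#' its candidate genes in order of decreasing absolute t statistic (ties by
#' gene id), de-duplicating across pathways, until `k` genes are collected
#' or the candidates are exhausted.
#'
#' @param result a `rank_result`.
#' @param pcm the `pathway_candidate_map` the ranking was built from.
#' @param degs the `deg_set` supplying per-gene t statistics.
#' @param k target number of feature genes (default 80).
#' @return class `"feature_genes"`: list with `genes` (ordered character
#'   vector), `provenance` (data frame gene / pathway / pathway_rank) and
#'   `k`.
#' @export
select_feature_genes <- function(result, pcm, degs, k = 80L) {
  if (k < 1L) stopf("k must be >= 1")
  tstat <- stats::setNames(degs$table$t, degs$table$gene)
  genes <- character(); prov_pw <- character(); prov_rank <- integer()
  for (i in seq_len(nrow(result$table))) {
    pw <- result$table$pathway[i]
    cand <- pcm$candidates[[pw]]
    cand <- cand[order(-abs(tstat[cand]), cand)]
    new <- setdiff(cand, genes)
    if (length(new)) {
      genes <- c(genes, new)
      prov_pw <- c(prov_pw, rep(pw, length(new)))
      prov_rank <- c(prov_rank, rep(i, length(new)))
    }
    if (length(genes) >= k) break
  }
  if (length(genes) < k)
    warning(sprintf("only %d candidate genes available (requested %d)",
                    length(genes), k))
  keep <- seq_len(min(k, length(genes)))
  structure(list(genes = genes[keep],
                 provenance = data.frame(gene = genes[keep],
                                         pathway = prov_pw[keep],
                                         pathway_rank = prov_rank[keep],
                                         stringsAsFactors = FALSE),
                 k = as.integer(k)),
            class = "feature_genes")
}

#' T-test baseline feature selection
#'
#' Ranks all genes by the Welch t-test p-value against the phenotype and
#' returns the top `k` (ties broken by gene id), mirroring the conventional
#' differential-expression feature ranking the pathway-based selection is
#' compared against.
#'
#' @param expr genes x samples matrix.
#' @param pheno named 0/1 phenotype vector.
#' @param k number of genes.
#' @return class `"feature_genes"` (provenance pathway = `"ttest"`).
#' @export
ttest_baseline <- function(expr, pheno, k = 80L) {
  if (k < 1L) stopf("k must be >= 1")
  pheno <- align_phenotype(expr, pheno)
  tab <- welch_row_stats(expr, pheno)
  ord <- order(tab$p, tab$gene)
  genes <- tab$gene[ord][seq_len(min(k, nrow(tab)))]
  structure(list(genes = genes,
                 provenance = data.frame(gene = genes, pathway = "ttest",
                                         pathway_rank = NA_integer_,
                                         stringsAsFactors = FALSE),
                 k = as.integer(k)),
            class = "feature_genes")
}

#' Linear-kernel SVM classifier contract
#'
#' Default classifier for [cv_auc()]: fits `e1071::svm` with a linear
#' kernel (no feature scaling; expression input is assumed log-scale) and
#' returns a scoring function whose values increase with the tumor class.
#'
#' @param train_x samples x features numeric matrix.
#' @param train_y 0/1 labels for the training samples.
#' @return function mapping a samples x features matrix to decision scores.
#' @export
svm_linear_classifier <- function(train_x, train_y) {
  y <- factor(train_y, levels = c(0, 1))
  fit <- e1071::svm(train_x, y, kernel = "linear", scale = FALSE)
  function(test_x) {
    pred <- stats::predict(fit, test_x, decision.values = TRUE)
    dv <- attr(pred, "decision.values")
    # e1071 orients decision values toward the class named first in the
    # "a/b" column label; flip so larger = tumor (class 1)
    if (grepl("^1/", colnames(dv)[1L])) as.vector(dv) else -as.vector(dv)
  }
}

# stratified fold assignment: within each class, shuffle and deal round-robin
stratified_folds <- function(labels, folds) {
  assign <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    if (length(idx) < folds)
      stopf("class %s has %d samples; cannot stratify into %d folds",
            cls, length(idx), folds)
    assign[sample(idx)] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

auc_score <- function(labels, scores) {
  as.numeric(pROC::auc(pROC::roc(response = factor(labels, levels = c(0, 1)),
                                 predictor = scores, levels = c("0", "1"),
                                 direction = "<", quiet = TRUE)))
}

#' Repeated stratified cross-validated AUC
#'
#' Stratified k-fold cross-validation, repeated with seeds derived from
#' `seed`; in each fold the classifier is fit on the training samples and
#' the AUC is computed from its decision scores on the held-out samples.
#' Results are reproducible bit-for-bit under a fixed seed.
#'
#' @param expr genes x samples matrix.
#' @param pheno named 0/1 phenotype vector.
#' @param features a `feature_genes` object (or character vector of genes
#'   present in `expr`).
#' @param folds number of folds (default 10).
#' @param repeats number of repetitions (default 10).
#' @param seed integer seed.
#' @param classifier classifier factory following the
#'   [svm_linear_classifier()] contract.
#' @return class `"cv_result"`: list with `auc` (repeats x folds matrix),
#'   `mean_auc`, `folds`, `repeats`, `seed`, `features`.
#' @export
cv_auc <- function(expr, pheno, features, folds = 10L, repeats = 10L,
                   seed = 1L, classifier = svm_linear_classifier) {
  genes <- if (inherits(features, "feature_genes")) features$genes
           else as.character(features)
  missing <- setdiff(genes, rownames(expr))
  if (length(missing))
    stopf("feature gene(s) absent from expression matrix: %s",
          paste(utils::head(missing, 3), collapse = ", "))
  pheno <- align_phenotype(expr, pheno)
  check_binary_labels(pheno)
  x <- t(expr[genes, , drop = FALSE])  # samples x features
  aucs <- matrix(NA_real_, nrow = repeats, ncol = folds)
  for (rep_i in seq_len(repeats)) {
    set.seed(seed + rep_i - 1L)
    fold_of <- stratified_folds(pheno, folds)
    for (f in seq_len(folds)) {
      test <- fold_of == f
      score_fun <- classifier(x[!test, , drop = FALSE], pheno[!test])
      scores <- score_fun(x[test, , drop = FALSE])
      aucs[rep_i, f] <- auc_score(pheno[test], scores)
    }
  }
  structure(list(auc = aucs, mean_auc = mean(aucs), folds = as.integer(folds),
                 repeats = as.integer(repeats), seed = as.integer(seed),
                 features = genes),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: mean AUC %.4f over %d folds x %d repeats (%d features)\n",
              x$mean_auc, x$folds, x$repeats, length(x$features)))
  invisible(x)
}
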