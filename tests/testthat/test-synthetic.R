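test_that("generation is deterministic and respects the declared structure", {
  b1 <- generate_bundle(tiny_spec(seed = 3))
  b2 <- generate_bundle(tiny_spec(seed = 3))
  expect_identical(serialize(b1, NULL), serialize(b2, NULL))

  expect_identical(length(b1$pathways), 10L)
  expect_true(all(lengths(b1$pathways) >= 5 & lengths(b1$pathways) <= 10))
  expect_true(all(b1$truth$planted_pathways %in% names(b1$pathways)))
  # bounded pairwise overlap
  for (i in seq_along(b1$pathways))
    for (j in seq_len(i - 1))
      expect_lte(length(intersect(b1$pathways[[i]], b1$pathways[[j]])), 2L)
  # planted genes are shifted in tumor samples by the effect size
  shift <- rowMeans(b1$expr[b1$truth$planted_genes, b1$pheno == 1]) -
    rowMeans(b1$expr[b1$truth$planted_genes, b1$pheno == 0])
  expect_equal(mean(shift), 1.5, tolerance = 0.15)
  expect_error(generate_bundle(synthetic_spec(n_genes = 20,
                                              pathway_size_range = c(30, 40))),
               "universe")
})

test_that("within-pathway PPI density exceeds the background density", {
  b <- generate_bundle(tiny_spec(seed = 12))
  key <- paste(b$ppi[, 1], b$ppi[, 2])
  within_pairs <- unique(unlist(lapply(b$pathways, function(m) {
    prs <- combn(sort(m), 2)
    paste(prs[1, ], prs[2, ])
  })))
  n_within_possible <- length(within_pairs)
  n_within <- sum(within_pairs %in% key)
  n_total_possible <- choose(nrow(b$expr), 2)
  dens_within <- n_within / n_within_possible
  dens_bg <- (nrow(b$ppi) - n_within) / (n_total_possible - n_within_possible)
  expect_gt(dens_within, dens_bg)
})

test_that("export round-trips through the standard-format readers", {
  b <- generate_bundle(tiny_spec(seed = 6))
  dir <- tempfile()
  paths <- suppressMessages(export_bundle(b, dir))
  expect_identical(read_expression(paths[["expression"]]), b$expr)
  expect_identical(read_phenotype(paths[["phenotype"]]), b$pheno)
  back_sets <- read_gene_sets(paths[["pathways"]])
  expect_identical(length(readLines(paths[["pathways"]])),
                   length(b$pathways))
  expect_identical(names(back_sets), names(b$pathways))
  expect_identical(unname(unclass(back_sets)),
                   unname(unclass(b$pathways)))
  back_ppi <- suppressMessages(read_ppi(paths[["ppi"]]))
  expect_identical(unclass(back_ppi)[, 1:2],
                   unclass(b$ppi)[, 1:2])
  back_dag <- read_ontology(paths[["ontology"]])
  expect_identical(back_dag$terms$id, b$dag$terms$id)
  expect_identical(back_dag$terms$namespace, b$dag$terms$namespace)
  expect_identical(back_dag$edges[order(back_dag$edges$child,
                                        back_dag$edges$parent), ],
                   b$dag$edges[order(b$dag$edges$child,
                                     b$dag$edges$parent), ],
                   ignore_attr = TRUE)
  back_ann <- suppressMessages(read_annotations(paths[["annotations"]],
                                                back_dag))
  for (space in c("BP", "MF", "CC")) {
    genes <- sort(names(b$ann[[space]]))
    expect_identical(sort(names(back_ann[[space]])), genes)
    for (g in genes)
      expect_setequal(back_ann[[space]][[g]], b$ann[[space]][[g]])
  }
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_identical(sort(truth$planted_pathways),
                   sort(b$truth$planted_pathways))
  expect_length(truth$planted_pathways, b$spec$n_planted)
})

test_that("a zero effect size leaves planted and background MI alike", {
  planted_mi <- numeric(); background_mi <- numeric()
  for (seed in 1:10) {
    b <- generate_bundle(tiny_spec(seed = seed, effect_size = 0))
    pcm <- suppressMessages(map_to_pathways(rownames(b$expr), b$pathways,
                                            b$expr))
    mi <- activity_profile(pcm, b$expr, b$pheno)$mi
    planted_mi <- c(planted_mi, mi[b$truth$planted_pathways])
    background_mi <- c(background_mi,
                       mi[setdiff(names(mi), b$truth$planted_pathways)])
  }
  expect_gt(wilcox.test(planted_mi, background_mi)$p.value, 0.05)
})

test_that("planted pathways dominate the background MI distribution", {
  hits <- 0L
  for (seed in 1:10) {
    b <- generate_bundle(tiny_spec(seed = seed))
    pcm <- suppressMessages(map_to_pathways(rownames(b$expr), b$pathways,
                                            b$expr))
    mi <- activity_profile(pcm, b$expr, b$pheno)$mi
    bg <- mi[setdiff(names(mi), b$truth$planted_pathways)]
    if (all(mi[b$truth$planted_pathways] > quantile(bg, 0.95)))
      hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})
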