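test_that("activity scores are per-sample means over candidate genes", {
  expr <- matrix(c(2, 4, 1, 3, 5, 7), nrow = 3, byrow = TRUE,
                 dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  pcm <- structure(list(candidates = list(P = c("a", "b")),
                        p = c(P = 2L), size_total = c(P = 2L)),
                   class = "pathway_candidate_map")
  expect_equal(unname(activity_scores(pcm, expr)["P", ]), c(1.5, 3.5))

  pcm1 <- structure(list(candidates = list(P = "c"), p = c(P = 1L)),
                    class = "pathway_candidate_map")
  expect_equal(unname(activity_scores(pcm1, expr)["P", ]), expr["c", ],
               ignore_attr = TRUE)

  expr3 <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 3, byrow = TRUE,
                  dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  pcm3 <- structure(list(candidates = list(P = c("a", "b", "c")),
                         p = c(P = 3L)), class = "pathway_candidate_map")
  expect_equal(unname(activity_scores(pcm3, expr3)["P", ]), c(3, 4))

  pcm0 <- structure(list(candidates = list(P = character(0)), p = c(P = 0L)),
                    class = "pathway_candidate_map")
  expect_error(activity_scores(pcm0, expr), "zero candidate genes")
})

test_that("discretization uses floor(log2(m)+1) equal-width bins", {
  expect_identical(attr(discretize_activity(rnorm(8)), "B"), 4L)
  expect_identical(attr(discretize_activity(rnorm(100)), "B"), 7L)
  const <- discretize_activity(rep(3.2, 10))
  expect_true(all(const == 0L))
  # maximum goes into the top (right-closed) bin, minimum into bin 0
  v <- c(0, 1, 2, 3, 4, 5, 6, 7)
  d <- discretize_activity(v)
  expect_identical(d[1], 0L)
  expect_identical(d[8], attr(d, "B") - 1L)
  expect_true(all(d >= 0 & d <= attr(d, "B") - 1L))
})

test_that("mutual information matches closed forms and the counting oracle", {
  lab <- rep(c(0L, 1L), each = 4)
  expect_equal(mutual_information(lab, lab), 1.0)
  expect_equal(mutual_information(rep(0L, 8), lab), 0)
  expect_error(mutual_information(1:3, 1:4), "length")

  set.seed(21)
  for (i in 1:25) {
    m <- sample(8:64, 1)
    a <- sample(0:3, m, replace = TRUE)
    c <- sample(0:1, m, replace = TRUE)
    expect_equal(mutual_information(a, c), mi_oracle(a, c),
                 tolerance = 1e-12)
  }
})

test_that("MI respects its information-theoretic bounds and invariances", {
  entropy <- function(x) {
    p <- table(x) / length(x)
    -sum(p * log2(p))
  }
  set.seed(31)
  for (i in 1:20) {
    m <- sample(10:60, 1)
    a <- rnorm(m)
    c <- sample(0:1, m, replace = TRUE)
    while (length(unique(c)) < 2) c <- sample(0:1, m, replace = TRUE)
    d <- discretize_activity(a)
    mi <- mutual_information(d, c)
    expect_gte(mi, 0)
    expect_lte(mi, min(entropy(d), entropy(c)) + 1e-12)
    # joint permutation invariance
    perm <- sample(m)
    expect_equal(mutual_information(d[perm], c[perm]), mi, tolerance = 1e-12)
    # positive affine transforms preserve bins, hence MI
    d2 <- discretize_activity(2.5 * a + 1)
    expect_identical(as.integer(d2), as.integer(d))
  }
})

test_that("phenotype scores separate planted from background pathways", {
  b <- generate_bundle(synthetic_spec(n_genes = 500L, n_normal = 50L,
                                      n_tumor = 50L, n_pathways = 20L,
                                      pathway_size_range = c(8L, 15L),
                                      n_planted = 3L, effect_size = 1.5,
                                      seed = 99L))
  # score every pathway on its full gene set (no DEG filtering needed here)
  pcm <- suppressMessages(map_to_pathways(rownames(b$expr), b$pathways,
                                          b$expr))
  prof <- activity_profile(pcm, b$expr, b$pheno)
  planted <- b$truth$planted_pathways
  background <- setdiff(names(prof$mi), planted)
  expect_gt(mean(prof$mi[planted]), mean(prof$mi[background]))
  # identical activity rows give identical MI
  expect_equal(mutual_information(prof$disc[1, ], b$pheno),
               mutual_information(prof$disc[1, ], b$pheno))
  # misaligned sample ids are a hard error
  bad <- b$pheno
  names(bad)[1] <- "nope"
  expect_error(phenotype_scores(prof$activity, bad), "sample identifiers")
})
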