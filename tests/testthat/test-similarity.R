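test_that("Wang term similarity reproduces the hand-computed sibling case", {
  dag <- toy_sibling_dag()
  expect_equal(wang_term_similarity("GO:0000002", "GO:0000002", dag), 1)
  expect_equal(wang_term_similarity("GO:0000001", "GO:0000001", dag), 1)
  # siblings A,B under the root via is_a (0.8): (0.8+0.8)/(1.8+1.8) = 4/9
  expect_equal(wang_term_similarity("GO:0000002", "GO:0000003", dag), 4 / 9)
})

test_that("Wang similarity is symmetric, bounded, and 0 for disjoint trees", {
  # two disconnected subtrees in one namespace
  dag <- ontology_dag(
    terms = data.frame(id = sprintf("GO:%07d", 1:4), name = "t",
                       namespace = "BP", obsolete = FALSE),
    edges = data.frame(child = c("GO:0000002", "GO:0000004"),
                       parent = c("GO:0000001", "GO:0000003"),
                       relation = "is_a"))
  expect_equal(wang_term_similarity("GO:0000002", "GO:0000004", dag), 0)

  dag2 <- random_dag(40, seed = 8)
  ids <- dag2$terms$id
  set.seed(9)
  for (i in 1:200) {
    pair <- sample(ids, 2)
    s12 <- wang_term_similarity(pair[1], pair[2], dag2)
    s21 <- wang_term_similarity(pair[2], pair[1], dag2)
    expect_equal(s12, s21, tolerance = 1e-12)
    expect_gte(s12, 0); expect_lte(s12, 1)
  }
  # cross-namespace comparison is refused
  mf <- random_dag(5, seed = 1, namespace = "MF", id_offset = 1000L)
  both <- ontology_dag(rbind(dag2$terms, mf$terms),
                       rbind(dag2$edges, mf$edges))
  expect_error(wang_term_similarity(dag2$terms$id[1], mf$terms$id[1], both),
               "namespace")
})

test_that("gene similarity combines namespaces by best-match average", {
  dag <- toy_sibling_dag()
  ann <- structure(list(
    BP = list(g1 = c("GO:0000002", "GO:0000003"), g2 = "GO:0000002",
              g3 = c("GO:0000002", "GO:0000003")),
    MF = list(g4 = "GO:0000002"), CC = list()), class = "annotation_map")
  # identical annotation sets -> 1 (BMA of self-matches)
  expect_equal(gene_similarity("g1", "g3", ann, dag), 1)
  # no shared namespace -> 0
  expect_equal(gene_similarity("g1", "g4", ann, dag), 0)
  # 2x1 BMA oracle: (max(s1,s2) + mean(s1,s2)) / 2
  s1 <- wang_term_similarity("GO:0000002", "GO:0000002", dag)
  s2 <- wang_term_similarity("GO:0000003", "GO:0000002", dag)
  expect_equal(gene_similarity("g1", "g2", ann, dag),
               (max(s1, s2) + mean(c(s1, s2))) / 2)
  expect_equal(gene_similarity("g1", "g2", ann, dag),
               gene_similarity("g2", "g1", ann, dag))
})

test_that("pathway similarity follows the sum/(M+N) form with its bounds", {
  ones <- function(g1, g2) 1
  expect_equal(pathway_similarity("g", "g", ones), 0.5)
  expect_equal(pathway_similarity(c("a", "b"), c("c", "d"),
                                  function(...) 0), 0)
  # sims 0.4 and 0.6 for a 2x1 pair -> 1/3
  sims <- matrix(c(0.4, 0.6), 2, 1,
                 dimnames = list(c("g1", "g2"), "g3"))
  G <- matrix(0, 3, 3, dimnames = list(c("g1", "g2", "g3"),
                                       c("g1", "g2", "g3")))
  G["g1", "g3"] <- G["g3", "g1"] <- 0.4
  G["g2", "g3"] <- G["g3", "g2"] <- 0.6
  expect_equal(pathway_similarity(c("g1", "g2"), "g3", G), 1 / 3)
  expect_equal(pathway_similarity("g3", c("g1", "g2"), G), 1 / 3)
  # upper bound M*N/(M+N) attained at all-ones similarity
  set.seed(2)
  for (i in 1:10) {
    M <- sample(1:6, 1); N <- sample(1:6, 1)
    gi <- paste0("a", seq_len(M)); gj <- paste0("b", seq_len(N))
    expect_equal(pathway_similarity(gi, gj, ones), M * N / (M + N))
    rs <- matrix(runif(M * N), M, N,
                 dimnames = list(gi, gj))
    Gr <- matrix(0, M + N, M + N, dimnames = list(c(gi, gj), c(gi, gj)))
    Gr[gi, gj] <- rs; Gr[gj, gi] <- t(rs)
    v <- pathway_similarity(gi, gj, Gr)
    expect_equal(v, pathway_similarity(gj, gi, Gr), tolerance = 1e-12)
    expect_lte(v, M * N / (M + N) + 1e-12)
  }
  expect_error(pathway_similarity(character(0), "g", ones), "empty")
})

test_that("the cached similarity matrix equals uncached recomputation", {
  b <- generate_bundle(tiny_spec(seed = 4))
  pcm <- suppressMessages(map_to_pathways(rownames(b$expr),
                                          b$pathways[1:5], b$expr))
  sm <- similarity_matrix(pcm, b$ann, b$dag)
  expect_true(isSymmetric(sm$sim))
  expect_true(all(sm$sim >= 0))
  for (i in 1:5) {
    for (j in 1:i) {
      direct <- pathway_similarity(
        pcm$candidates[[i]], pcm$candidates[[j]],
        function(g1, g2) gene_similarity(g1, g2, b$ann, b$dag))
      expect_equal(sm$sim[i, j], direct, tolerance = 1e-12)
    }
  }
  # permutation equivariance
  pcm2 <- pcm
  perm <- c(3L, 1L, 5L, 2L, 4L)
  pcm2$candidates <- pcm$candidates[perm]
  pcm2$p <- pcm$p[perm]
  sm2 <- similarity_matrix(pcm2, b$ann, b$dag)
  expect_equal(sm2$sim, sm$sim[perm, perm], tolerance = 1e-12)
})

test_that("network thresholding matches the >= rule and degree sums", {
  nm <- paste0("P", 1:4)
  sim <- matrix(0.5, 4, 4, dimnames = list(nm, nm))
  sim[1, 2] <- sim[2, 1] <- 0.7
  sim[3, 4] <- sim[4, 3] <- 0.7 - 1e-9
  net <- build_network(sim, theta = 0.7)
  expect_identical(net$w[1, 2], 1)          # sim == theta -> edge
  expect_identical(net$w[3, 4], 0)          # just below theta -> none
  expect_identical(unname(diag(net$w)), rep(0, 4))
  expect_equal(unname(net$deg), unname(rowSums(net$w)))

  full <- build_network(matrix(0.9, 4, 4, dimnames = list(nm, nm)),
                        theta = 0.5)
  expect_identical(unname(full$deg), rep(3, 4))

  # edge count is non-increasing in theta
  set.seed(13)
  rs <- matrix(runif(36), 6, 6); rs <- (rs + t(rs)) / 2
  dimnames(rs) <- list(paste0("Q", 1:6), paste0("Q", 1:6))
  edges <- vapply(seq(0, 1, by = 0.1), function(th)
    sum(build_network(rs, theta = th)$w) / 2, numeric(1))
  expect_true(all(diff(edges) <= 0))

  # percentile default reproduces the explicit quantile
  q75 <- unname(quantile(rs[upper.tri(rs)], 0.75))
  expect_equal(build_network(rs)$theta, q75)
})
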