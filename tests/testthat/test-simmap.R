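test_that("pairwise scoring matches hand-worked and enumerated values", {
  # self-score is the sum of diagonal entries
  expect_equal(pairwise_score("ACDE", "ACDE", b62, "aligned"), 4 + 9 + 6 + 5)
  # as-is counts only doubly occupied columns
  expect_equal(pairwise_score("A-C", "AG-", b62, "as_is"), 4)
  expect_error(pairwise_score("A-C", "AG", b62, "as_is"), "equal-length")
  expect_error(pairwise_score("A-C", "AGC", b62, "aligned"), "ungapped")

  # aligned mode equals exhaustive enumeration over all global alignments
  set.seed(5)
  aas <- rownames(b62)[1:20]
  for (r in 1:10) {
    a <- paste(sample(aas, sample(3:6, 1), replace = TRUE), collapse = "")
    b <- paste(sample(aas, sample(2:6, 1), replace = TRUE), collapse = "")
    expect_equal(pairwise_score(a, b, b62, "aligned"),
                 oracle_global_score(a, b, b62), tolerance = 1e-9)
  }
})

test_that("similarity normalization maps identity to 1 and is symmetric", {
  m <- new_msa(c("a", "b", "c"), c("WADE", "WADE", "WKDE"))
  sim <- build_similarity(m, b62, "as_is")
  expect_equal(sim$cc["a", "b"], 1)
  expect_identical(sim$cc, t(sim$cc))
  expect_equal(unname(diag(sim$cc)), rep(1, 3))
  expect_true(all(sim$cc >= -1 & sim$cc <= 1))

  expect_error(build_similarity(new_msa(c("a", "b"), c("WA", "WA")), b62),
               "at least 3")
  # X-only rows self-score 0
  mx <- new_msa(c("a", "b", "x1"), c("WADE", "WKDE", "XXXX"))
  expect_error(build_similarity(mx, b62), "x1")
})

test_that("within-type similarity exceeds between-type on planted families", {
  fam <- small_synth(seed = 6)
  sim <- build_similarity(fam$msa, b62, "as_is")
  ty <- fam$truth$domain_type[sim$ids]
  same <- outer(ty, ty, "==") & upper.tri(sim$cc)
  diff <- outer(ty, ty, "!=") & upper.tri(sim$cc)
  expect_gt(mean(sim$cc[same]), mean(sim$cc[diff]))
})

test_that("embedding recovers a planted Gram matrix", {
  set.seed(9)
  V <- matrix(rnorm(12, sd = 0.4), 6, 2)
  G <- tcrossprod(V)
  stopifnot(all(abs(G) <= 1))
  sim <- structure(list(ids = paste0("s", 1:6),
                        raw = G, cc = `diag<-`(G, 1), mode = "as_is"),
                   class = "sim_matrix")
  # planted dot products carry their own diagonal, so fit with it
  sim$cc <- G
  diag(sim$cc) <- diag(G)
  map <- embed(sim, d = 2)
  rec <- tcrossprod(map$coords)
  off <- upper.tri(G)
  expect_lt(max(abs(rec[off] - G[off])), 1e-6)
})

test_that("degenerate and invariance properties of the embedding", {
  m <- new_msa(c("a", "b", "c", "d"), rep("WADEWADE", 4))
  map <- embed(build_similarity(m, b62), d = 2)
  expect_lt(max(dist(map$coords)), 1e-6)

  fam <- small_synth(seed = 7)
  sim <- build_similarity(fam$msa, b62)
  map1 <- embed(sim, d = 3)
  # eigenvalue ordering
  expect_true(all(diff(map1$eigenvalues) <= 1e-12))
  # deterministic bit-for-bit
  map2 <- embed(sim, d = 3)
  expect_identical(map1$coords, map2$coords)

  # permutation invariance of the dot-product structure
  perm <- sample(length(fam$msa$ids))
  mp <- new_msa(fam$msa$ids[perm], fam$msa$rows[perm])
  map_p <- embed(build_similarity(mp, b62), d = 3)
  g1 <- tcrossprod(map1$coords)
  gp <- tcrossprod(map_p$coords)[fam$msa$ids, fam$msa$ids]
  expect_equal(g1, gp, tolerance = 1e-6)

  # Gram residual is non-increasing in d
  r <- sapply(1:5, function(d) embed(sim, d = d)$residual)
  expect_true(all(diff(r) <= 1e-9))

  expect_error(embed(sim, d = 0), "d must be")
})

test_that("angular clustering separates planted bundles", {
  set.seed(13)
  ang <- rep(c(0, 2 * pi / 3, 4 * pi / 3), each = 10) +
    rnorm(30, sd = 5 * pi / 180)
  coords <- cbind(0.5, cos(ang), sin(ang))
  map <- make_map(coords)
  cl <- angular_clusters(map, dims = c(2, 3))
  expect_equal(cl$k, 3L)
  truth <- rep(1:3, each = 10)
  expect_equal(mclust::adjustedRandIndex(cl$labels, truth), 1)
  expect_true(all(cl$angles >= 0 & cl$angles < 2 * pi))

  # all points at the origin is an error
  map0 <- make_map(matrix(0, 5, 3))
  expect_error(angular_clusters(map0), "origin")
})

test_that("vector statistics: scaling, ranks, origin flags", {
  coords <- rbind(c(0.2, 0.3, 0.4), c(0.1, -0.2, 0.2), c(0, 0, 0))
  map <- make_map(coords)
  st <- vector_stats(map)
  expect_true(st$at_origin[3])
  expect_true(is.na(st$angle[3]))
  expect_equal(st$prototypicality_rank[1], 1L)

  map2 <- make_map(2 * coords)
  st2 <- vector_stats(map2)
  expect_equal(st2$length, 2 * st$length)
  expect_equal(st2$angle[1:2], st$angle[1:2])
})

test_that("subclustering re-runs the full analysis on the subset", {
  fam <- small_synth(seed = 8)
  whole <- embed(build_similarity(fam$msa, b62), d = 3)
  again <- subcluster(fam$msa, fam$msa$ids, b62, d = 3)
  expect_equal(whole$coords, again$coords)

  expect_error(subcluster(fam$msa, fam$msa$ids[1:2], b62), "at least 3")

  # position signal within one type: same-token pairs sit at closer angles
  ann <- fam$annotation
  ids <- ann$domain_id[ann$fniii_type == "A" & ann$zone == "C"]
  sub <- subcluster(fam$msa, ids, b62, d = 3)
  st <- vector_stats(sub)
  tok <- fam$truth$domain_token[st$id]
  d <- abs(outer(st$angle, st$angle, "-")) %% (2 * pi)
  d <- pmin(d, 2 * pi - d)
  same <- outer(tok, tok, "==") & upper.tri(d)
  diff <- outer(tok, tok, "!=") & upper.tri(d)
  expect_lt(mean(d[same]), mean(d[diff]))
})

test_that("synthetic three-type family is recovered by angular clustering", {
  fam <- small_synth(seed = 9)
  map <- embed(build_similarity(fam$msa, b62), d = 3)
  cl <- angular_clusters(map)
  ok <- !is.na(cl$labels)
  ari <- mclust::adjustedRandIndex(cl$labels[ok],
                                   fam$truth$domain_type[names(cl$labels)[ok]])
  expect_equal(cl$k, 3L)
  expect_gte(ari, 0.9)
})
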