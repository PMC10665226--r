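test_that("column masking is local and exact", {
  m <- tiny_msa()
  expect_identical(mask_columns(m, integer(0))$rows, m$rows)

  all_gone <- mask_columns(m, 1:m$n_cols)
  expect_true(all(strsplit(paste(all_gone$rows, collapse = ""), "")[[1]] == "-"))

  one <- mask_columns(m, 3L)
  cm <- as.matrix(one)
  expect_true(all(cm[, 3] == "-"))
  expect_identical(cm[, -3], as.matrix(m)[, -3])

  expect_error(mask_columns(m, 99L), "out of range")
})

test_that("map RMSD is invariant under orthogonal transforms and symmetric", {
  set.seed(31)
  X <- matrix(rnorm(16), 8, 2)
  mA <- make_map(X)
  expect_equal(map_rmsd(mA, mA), 0)

  th <- 1.1
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  refl <- matrix(c(1, 0, 0, -1), 2, 2)
  mB <- make_map(X %*% R, ids = mA$ids)
  mC <- make_map(X %*% (R %*% refl), ids = mA$ids)
  expect_lt(map_rmsd(mA, mB), 1e-9)
  expect_lt(map_rmsd(mA, mC), 1e-9)

  Y <- X + matrix(rnorm(16, sd = 0.3), 8, 2)
  mY <- make_map(Y, ids = mA$ids)
  expect_equal(map_rmsd(mA, mY), map_rmsd(mY, mA), tolerance = 1e-12)

  mZ <- make_map(X)
  mZ$ids[1] <- "other"
  rownames(mZ$coords)[1] <- "other"
  expect_error(map_rmsd(mA, mZ), "id mismatch")
})

test_that("map RMSD equals the sampled-orthogonal-transform oracle", {
  set.seed(32)
  for (r in 1:5) {
    n <- sample(4:8, 1)
    X <- matrix(rnorm(2 * n), n, 2)
    Y <- X
    Y[sample(n, 1), ] <- Y[sample(n, 1), ] + rnorm(2, sd = 0.5)
    got <- map_rmsd(make_map(X), make_map(Y, ids = paste0("p", 1:n)))
    want <- oracle_orthogonal_rmsd(X, Y)
    expect_equal(got, want, tolerance = 1e-4)
  }
})

test_that("removal curve obeys the weighted-difference algebra exactly", {
  fam <- generate_family(synth_config(d_repeats = 1, c_repeats = 2, seed = 4))
  prof <- sop_profile(fam$msa, b62)
  ord <- rank_positions(prof)
  ord <- ord[prof$sop[ord] > 0][1:10]
  tc <- removal_curve(fam$msa, ord, matrix = b62, d = 3, i_step = 1)

  expect_equal(tc$i, 0:10)
  expect_equal(tc$rmsd[1], 0)
  expect_equal(tc$adjusted[1], 0)
  # telescoping: cumulative delta reproduces rmsd exactly
  expect_equal(cumsum(tc$delta), tc$rmsd)
  # Eq. 2: linear weights, w(0) = 1, w(i_max) = 0
  expect_equal(tc$weight, (10 - tc$i) / 10)
  expect_equal(tc$weight[1], 1)
  expect_equal(tc$weight[11], 0)
  # Eq. 3: adjusted is the running weighted sum
  expect_equal(tc$adjusted, cumsum(tc$weight * tc$delta))
  # rmsd grows as conserved columns are removed
  expect_gt(tc$rmsd[11], 0)
})

test_that("masking already-gapped columns leaves the curve flat", {
  m <- tiny_msa()
  m2 <- mask_columns(m, c(2L, 5L))
  tc <- removal_curve(m2, c(2L, 5L), matrix = b62, d = 2, i_step = 1)
  expect_equal(tc$rmsd, rep(0, 3))
  expect_equal(tc$delta, rep(0, 3))
  # adjusted constant once delta is identically 0
  expect_equal(tc$adjusted, rep(0, 3))
})

test_that("sham curves are seed-reproducible and start at zero", {
  fam <- generate_family(synth_config(d_repeats = 1, c_repeats = 2, seed = 4))
  prof <- sop_profile(fam$msa, b62)
  s1 <- sham_curve(fam$msa, prof, i_grid = c(0, 4, 8), reps = 1, seed = 99,
                   matrix = b62, d = 3)
  s2 <- sham_curve(fam$msa, prof, i_grid = c(0, 4, 8), reps = 1, seed = 99,
                   matrix = b62, d = 3)
  expect_identical(s1$rmsd, s2$rmsd)
  expect_equal(s1$rmsd[1], 0)
  expect_equal(attr(s1, "kind"), "sham")
  expect_equal(attr(s1, "sham_reps"), 1L)
})

test_that("homogeneous MSAs show no differential signal", {
  # every column is a permutation of the same residue multiset, so the
  # conservation ranking is structureless and the 'true' removal order is
  # statistically equivalent to a random one
  set.seed(41)
  base <- c(rep("W", 6), rep("A", 5), rep("D", 5))
  cols <- replicate(30, sample(base))
  rows <- apply(cols, 1, paste, collapse = "")
  m <- new_msa(sprintf("s%02d", 1:16), rows)
  prof <- sop_profile(m, b62)
  ord <- rank_positions(prof)
  ord <- ord[prof$sop[ord] > 0][1:12]
  ref <- embed(build_similarity(m, b62), d = 2)
  tc <- removal_curve(m, ord, matrix = b62, d = 2, i_step = 4, ref_map = ref)
  finals <- vapply(1:8, function(s)
    utils::tail(sham_curve(m, prof, i_grid = tc$i, reps = 1, seed = s,
                           matrix = b62, d = 2, ref_map = ref)$adjusted, 1),
    numeric(1))
  spread <- max(stats::sd(finals), 1e-6)
  expect_lt(abs(utils::tail(tc$adjusted, 1) - mean(finals)), 4 * spread)
})

test_that("consensus thresholding recovers planted global columns", {
  # no differential signal -> empty consensus with a warning
  fake <- function(adj, i, ord) {
    structure(data.frame(i = i, rmsd = adj, delta = c(0, diff(adj)),
                         weight = (max(i) - i) / max(i), adjusted = adj),
              kind = "true", order = ord, i_max = max(i),
              class = c("removal_curve", "data.frame"))
  }
  prof <- structure(
    data.frame(col = 1:6, sop = c(5, 4, 3, 2, 1, 0.5), occupancy = 1,
               gap_fraction = 0, zeroed_by_gap_rule = FALSE),
    class = c("conservation_profile", "data.frame"))
  same <- fake(c(0, 0.1, 0.2, 0.3), 0:3, 1:6)
  expect_warning(res <- consensus_threshold(same, same, prof),
                 "no differential")
  expect_true(res$empty)
  expect_length(res$conserved_cols, 0)

  # true rises faster than sham for two steps, then falls below
  tc <- fake(c(0, 0.3, 0.5, 0.52), 0:3, 1:6)
  sc <- fake(c(0, 0.1, 0.2, 0.3), 0:3, 1:6)
  res2 <- consensus_threshold(tc, sc, prof)
  expect_equal(res2$n_removed, 2L)
  expect_equal(res2$sop_cutoff, 4)
  expect_equal(res2$conserved_cols, 1L)

  # end-to-end on a planted family
  fam <- small_synth(seed = 10)
  prof <- sop_profile(fam$msa, b62)
  ord <- rank_positions(prof)
  ord <- ord[prof$sop[ord] > 0]
  ord <- ord[seq_len(min(length(ord), floor(0.8 * fam$msa$n_cols)))]
  ref <- embed(build_similarity(fam$msa, b62), d = 3)
  tc <- removal_curve(fam$msa, ord, matrix = b62, d = 3, i_step = 3,
                      ref_map = ref)
  sc <- sham_curve(fam$msa, prof, i_grid = tc$i, reps = 3, seed = 1010,
                   matrix = b62, d = 3, ref_map = ref)
  cons <- consensus_threshold(tc, sc, prof)
  planted <- which(fam$truth$column_tier == "global")
  expect_gte(mean(cons$conserved_cols %in% planted), 0.8)
  expect_gte(mean(planted %in% cons$conserved_cols), 0.8)
})

test_that("conserved-first removal dominates least-conserved-first", {
  fam <- generate_family(synth_config(d_repeats = 2, c_repeats = 3, seed = 12))
  prof <- sop_profile(fam$msa, b62)
  ord <- rank_positions(prof)
  ord <- ord[prof$sop[ord] > 0]
  n <- min(15L, length(ord))
  ref <- embed(build_similarity(fam$msa, b62), d = 3)
  fwd <- removal_curve(fam$msa, ord[1:n], matrix = b62, d = 3, i_step = 5,
                       ref_map = ref)
  rev_ord <- rev(ord)[1:n]
  bwd <- removal_curve(fam$msa, rev_ord, matrix = b62, d = 3, i_step = 5,
                       ref_map = ref)
  expect_gt(utils::tail(fwd$adjusted, 1), utils::tail(bwd$adjusted, 1))
})
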