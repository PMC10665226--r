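# Independent oracles used to validate the implementation's numerics.

b62 <- load_substitution_matrix()

# Literal double loop over all sequence pairs of a column (gaps excluded),
# divided by the pair count.
oracle_sop <- function(column, mat = b62) {
  res <- column[column != "-"]
  m <- length(res)
  if (m < 2) return(0)
  tot <- 0
  for (i in seq_len(m - 1)) for (j in (i + 1):m)
    tot <- tot + mat[res[i], res[j]]
  tot / choose(m, 2)
}

# Exhaustive enumeration of all global alignments with affine gap penalties
# (gap of length L costs open + (L-1) * extend, end gaps charged).
oracle_global_score <- function(a, b, mat = b62, open = 11, extend = 1) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, state, score) {
    if (i > length(ca) && j > length(cb)) {
      best <<- max(best, score)
      return(invisible())
    }
    if (i <= length(ca) && j <= length(cb))
      rec(i + 1, j + 1, "m", score + mat[ca[i], cb[j]])
    if (i <= length(ca))
      rec(i + 1, j, "a", score - (if (state == "a") extend else open))
    if (j <= length(cb))
      rec(i, j + 1, "b", score - (if (state == "b") extend else open))
  }
  rec(1, 1, "m", 0)
  best
}

# Minimum RMSD over the full orthogonal group in d = 2: fine rotation grid,
# with and without reflection.
oracle_orthogonal_rmsd <- function(X, Y, n_grid = 20000) {
  angles <- seq(0, 2 * pi, length.out = n_grid)
  best <- Inf
  refl <- matrix(c(1, 0, 0, -1), 2, 2)
  for (th in angles) {
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    for (M in list(R, refl %*% R)) {
      r <- sqrt(mean(rowSums((X - Y %*% M)^2)))
      if (r < best) best <- r
    }
  }
  best
}

# Minimum RMSD over proper rotations (efficiently centred first): random
# quaternion sampling followed by Nelder-Mead refinement on the axis-angle
# parameters.
oracle_kabsch_rmsd <- function(A, B, n_samp = 20000) {
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  quat_rot <- function(q) {
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
             2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
             2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
           3, 3)
  }
  obj_q <- function(q) {
    if (sum(q^2) < 1e-12) return(Inf)
    sqrt(mean(rowSums((Ac - Bc %*% quat_rot(q))^2)))
  }
  qs <- matrix(stats::rnorm(4 * n_samp), ncol = 4)
  vals <- apply(qs, 1, obj_q)
  q0 <- qs[which.min(vals), ]
  fit <- stats::optim(q0, obj_q, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  fit$value
}

# Literal counting oracle for group identity of a column.
oracle_group_identity <- function(res, groups) {
  res <- res[res != "-"]
  if (length(res) == 0) return(0)
  best <- max(table(res)) / length(res)
  for (g in groups) best <- max(best, sum(res %in% g) / length(res))
  best
}
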