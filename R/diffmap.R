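# Differential mapping: cumulative removal of conserved columns,
# re-embedding, weighted map-RMSD curves against sham (random-removal)
# baselines, and the positive-slope consensus threshold.
#
# For i removed positions:
#   delta(i)    = RMSD(i) - RMSD(i - 1)
#   w(i)        = (i_max - i) / i_max
#   adjusted(i) = sum_{n <= i} w(n) * delta(n)
# The weight corrects for the shrinking column pool: a removal out of a small
# remaining pool perturbs the map more than the same removal out of a large
# one. i_max is the number of columns whose conservation score is > 0.

#' Replace alignment columns by gaps
#'
#' Produces a derivative MSA in which the listed columns are all-gap in every
#' row; all other columns are unchanged (same shape).
#'
#' @param msa An [new_msa()] object.
#' @param cols Integer vector of 1-based column indices.
#' @return A new `msa`.
#' @export
mask_columns <- function(msa, cols) {
  stopifnot(inherits(msa, "msa"))
  cols <- unique(as.integer(cols))
  if (length(cols) == 0L) return(msa)
  if (any(cols < 1L | cols > msa$n_cols))
    stop("column(s) out of range 1..", msa$n_cols, ": ",
         paste(cols[cols < 1L | cols > msa$n_cols], collapse = ", "))
  m <- as.matrix(msa)
  m[, cols] <- GAP
  new_msa(msa$ids, apply(m, 1, paste, collapse = ""))
}

#' RMSD between two vector maps after orthogonal superposition
#'
#' Superposes `mapB` onto `mapA` by the optimal orthogonal transform
#' (rotations and reflections; no translation, no scaling -- the embedding is
#' anchored at the origin and defined only up to an orthogonal transform,
#' reflections included because axis signs are arbitrary) and returns the
#' root-mean-square deviation between paired vectors. Symmetric in its
#' arguments.
#'
#' @param mapA,mapB `vector_map`s over the same ids and dimension.
#' @return Numeric RMSD.
#' @export
map_rmsd <- function(mapA, mapB) {
  stopifnot(inherits(mapA, "vector_map"), inherits(mapB, "vector_map"))
  if (!setequal(mapA$ids, mapB$ids)) {
    miss <- c(setdiff(mapA$ids, mapB$ids), setdiff(mapB$ids, mapA$ids))
    stop("id mismatch between maps: ", paste(miss, collapse = ", "))
  }
  X <- mapA$coords
  Y <- mapB$coords[mapA$ids, , drop = FALSE]
  if (ncol(X) != ncol(Y)) stop("maps differ in dimension")
  s <- svd(crossprod(Y, X))
  R <- s$u %*% t(s$v)
  sqrt(mean(rowSums((X - Y %*% R)^2)))
}

# Shared machinery: rmsd series for one removal order over an i grid.
#' @noRd
rmsd_series <- function(msa, order, i_grid, matrix, d, tol, max_iter,
                        ref_map) {
  vapply(i_grid, function(i) {
    if (i == 0L) return(0)
    derived <- mask_columns(msa, order[seq_len(i)])
    map_i <- tryCatch(
      embed(build_similarity(derived, matrix, mode = "as_is"), d = d,
            tol = tol, max_iter = max_iter),
      error = function(e) stop("embedding failed at i = ", i, ": ",
                               conditionMessage(e), call. = FALSE))
    map_rmsd(ref_map, map_i)
  }, numeric(1))
}

# Eq. 1-3 bookkeeping on an rmsd series over a (possibly coarse) i grid.
#' @noRd
curve_frame <- function(i_grid, rmsd, i_max) {
  delta <- c(0, diff(rmsd))
  weight <- (i_max - i_grid) / i_max
  adjusted <- cumsum(weight * delta)
  data.frame(i = i_grid, rmsd = rmsd, delta = delta, weight = weight,
             adjusted = adjusted)
}

#' Removal curve: map perturbation under cumulative column removal
#'
#' Builds the series of derivative MSAs by removing the first `i` columns of
#' `order` (most conserved first), re-embeds each in as-is mode at the
#' reference dimension, and records the RMSD to the reference map (the
#' embedding of the unedited MSA, also in as-is mode) together with the
#' weighted-difference bookkeeping.
#'
#' @param msa The unedited [new_msa()].
#' @param order Column removal order, e.g. from [rank_positions()], already
#'   restricted to columns with positive conservation.
#' @param i_max Total removable columns (defaults to `length(order)`).
#' @param matrix Substitution matrix.
#' @param d Embedding dimension (default 3).
#' @param i_step Grid step over i; 1 reproduces the full series, larger
#'   values coarsen it for speed (the final point `i_max` is always kept).
#' @param tol,max_iter Embedding controls.
#' @param ref_map Optional precomputed reference map.
#' @return Data frame of class `removal_curve` with columns `i`, `rmsd`,
#'   `delta`, `weight`, `adjusted`; attributes `kind = "true"`, `order`,
#'   `i_max`.
#' @export
removal_curve <- function(msa, order, i_max = length(order),
                          matrix = load_substitution_matrix(), d = 3L,
                          i_step = 1L, tol = 1e-10, max_iter = 2000L,
                          ref_map = NULL) {
  stopifnot(inherits(msa, "msa"))
  order <- as.integer(order)
  i_max <- as.integer(i_max)
  if (i_max > length(order)) stop("i_max exceeds removal order length")
  if (i_max < 1L) stop("i_max must be >= 1")
  i_grid <- unique(c(seq(0L, i_max, by = as.integer(i_step)), i_max))
  if (is.null(ref_map))
    ref_map <- embed(build_similarity(msa, matrix, mode = "as_is"), d = d,
                     tol = tol, max_iter = max_iter)
  rmsd <- rmsd_series(msa, order, i_grid, matrix, d, tol, max_iter, ref_map)
  out <- curve_frame(i_grid, rmsd, i_max)
  structure(out, kind = "true", order = order, i_max = i_max,
            class = c("removal_curve", "data.frame"))
}

#' Sham removal curve: the random-removal baseline
#'
#' For each grid value of `i`, removes `i` columns drawn at random (without
#' replacement) from the columns with positive conservation score, embeds the
#' derivative MSA and measures the map RMSD; the series is averaged over
#' `reps` independent random orders before the weighted-difference
#' bookkeeping is applied.
#'
#' @param msa The unedited [new_msa()].
#' @param profile [sop_profile()] of `msa` (defines the eligible columns).
#' @param i_grid Integer grid of removal counts (must start at 0), e.g. the
#'   `i` column of the matching true curve.
#' @param reps Number of random replicate orders (default 3).
#' @param seed Optional seed for the random orders (restores the caller's RNG
#'   state).
#' @param matrix,d,tol,max_iter,ref_map As in [removal_curve()].
#' @return A `removal_curve` data frame with `kind = "sham"`, attribute
#'   `sham_reps`, and the per-replicate orders in attribute `orders`.
#' @export
sham_curve <- function(msa, profile, i_grid, reps = 3L, seed = NULL,
                       matrix = load_substitution_matrix(), d = 3L,
                       tol = 1e-10, max_iter = 2000L, ref_map = NULL) {
  stopifnot(inherits(msa, "msa"), inherits(profile, "conservation_profile"))
  if (reps < 1L) stop("reps must be >= 1")
  eligible <- profile$col[profile$sop > 0]
  i_grid <- sort(unique(as.integer(i_grid)))
  if (i_grid[1] != 0L) i_grid <- c(0L, i_grid)
  i_max <- max(i_grid)
  if (i_max > length(eligible))
    stop("i grid exceeds the number of columns with positive score")
  if (is.null(ref_map))
    ref_map <- embed(build_similarity(msa, matrix, mode = "as_is"), d = d,
                     tol = tol, max_iter = max_iter)
  orders <- with_seed(seed, lapply(seq_len(reps), function(r)
    sample(eligible, i_max)))
  series <- vapply(orders, function(ord)
    rmsd_series(msa, ord, i_grid, matrix, d, tol, max_iter, ref_map),
    numeric(length(i_grid)))
  rmsd <- rowMeans(matrix(series, nrow = length(i_grid)))
  out <- curve_frame(i_grid, rmsd, i_max)
  structure(out, kind = "sham", sham_reps = as.integer(reps),
            orders = orders, i_max = i_max,
            class = c("removal_curve", "data.frame"))
}

#' Derive the conservation consensus from true vs sham curves
#'
#' Walks the shared i grid from the start and keeps the largest prefix over
#' which each increment of the true adjusted-RMSD curve exceeds the sham
#' increment by more than `delta_tol` (a positive differential slope). The
#' conservation cutoff is the score of the last column removed within that
#' prefix; the consensus is every column scoring strictly above it.
#'
#' @param true_curve [removal_curve()] result.
#' @param sham_curve [sham_curve()] result on the same i grid.
#' @param profile The [sop_profile()] the removal order was ranked from.
#' @param delta_tol Slope tolerance (default 0: any positive differential
#'   counts).
#' @return List of class `consensus_result`: `sop_cutoff`, `conserved_cols`,
#'   `n_removed` (prefix length in columns), `empty` flag, `curves`.
#' @export
consensus_threshold <- function(true_curve, sham_curve, profile,
                                delta_tol = 0) {
  stopifnot(inherits(true_curve, "removal_curve"),
            inherits(sham_curve, "removal_curve"),
            inherits(profile, "conservation_profile"))
  if (!identical(true_curve$i, sham_curve$i))
    stop("true and sham curves are on different i grids")
  inc_true <- diff(true_curve$adjusted)
  inc_sham <- diff(sham_curve$adjusted)
  pass <- inc_true - inc_sham > delta_tol
  n_steps <- if (!any(!pass)) length(pass) else which(!pass)[1] - 1L
  if (n_steps == 0L) {
    warning("no differential signal: consensus is empty")
    res <- list(sop_cutoff = Inf, conserved_cols = integer(0),
                n_removed = 0L, empty = TRUE,
                curves = list(true = true_curve, sham = sham_curve))
    class(res) <- "consensus_result"
    return(res)
  }
  n_removed <- true_curve$i[n_steps + 1L]
  order <- attr(true_curve, "order")
  last_col <- order[n_removed]
  cutoff <- profile$sop[profile$col == last_col]
  conserved <- profile$col[profile$sop > cutoff]
  res <- list(sop_cutoff = cutoff, conserved_cols = conserved,
              n_removed = n_removed, empty = FALSE,
              curves = list(true = true_curve, sham = sham_curve))
  class(res) <- "consensus_result"
  res
}

#' @export
print.consensus_result <- function(x, ...) {
  if (x$empty) {
    cat("consensus_result: empty (no differential signal)\n")
  } else {
    cat(sprintf(
      "consensus_result: cutoff %.4g, %d conserved columns (prefix %d)\n",
      x$sop_cutoff, length(x$conserved_cols), x$n_removed))
  }
  invisible(x)
}
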