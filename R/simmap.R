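# Pairwise-similarity mapping: pairwise scores, normalized similarity
# matrices, low-rank vector embedding, angular clustering and
# prototypicality (vector length) statistics.
#
# Sequences are embedded as vectors x_i minimizing
#   sum_{i<j} (x_i . x_j - cc_ij)^2
# where cc is the self-score-normalized pairwise similarity. The axes are
# ordered by eigenvalue, so dimension 1 carries the strongest systematic
# feature of the set, dimension 2 the next orthogonal one, and so on. The
# vector angle in a chosen plane encodes which systematic features a
# sequence carries; the vector length encodes how dominant they are (longer
# vectors = more prototypical sequences of their group).

#' Pairwise similarity score between two sequences
#'
#' Two scoring modes: `"aligned"` computes the optimal global
#' (Needleman-Wunsch) alignment score of two ungapped sequences with affine
#' gap penalties (a gap of length L costs `gap_open + (L-1) * gap_extend`,
#' end gaps included); `"as_is"` sums substitution scores over columns of two
#' equal-length gapped rows where both are non-gap, with no realignment --
#' the mode used when comparing rows lifted directly from an MSA.
#'
#' @param a,b Residue strings (ungapped for `"aligned"`, equal-length gapped
#'   rows for `"as_is"`).
#' @param matrix Substitution matrix from [load_substitution_matrix()].
#' @param mode `"aligned"` or `"as_is"`.
#' @param gap_open,gap_extend Affine gap penalties for aligned mode
#'   (defaults 11 / 1, the standard BLOSUM62 pairing).
#' @return Numeric score.
#' @export
pairwise_score <- function(a, b, matrix = load_substitution_matrix(),
                           mode = c("aligned", "as_is"),
                           gap_open = 11, gap_extend = 1) {
  mode <- match.arg(mode)
  if (mode == "as_is") {
    if (nchar(a) != nchar(b))
      stop("as_is mode requires equal-length rows (", nchar(a), " vs ",
           nchar(b), ")")
    ca <- strsplit(a, "", fixed = TRUE)[[1]]
    cb <- strsplit(b, "", fixed = TRUE)[[1]]
    keep <- ca != GAP & cb != GAP
    if (!any(keep)) return(0)
    sum(matrix[cbind(ca[keep], cb[keep])])
  } else {
    if (grepl("-", paste0(a, b), fixed = TRUE))
      stop("aligned mode requires ungapped sequences")
    # Biostrings charges gapOpening + L * gapExtension per gap of length L;
    # shift so the first gap position costs gap_open.
    Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      type = "global", substitutionMatrix = matrix,
      gapOpening = gap_open - gap_extend, gapExtension = gap_extend,
      scoreOnly = TRUE)
  }
}

#' Build the pairwise similarity matrix for a sequence set
#'
#' Computes raw pairwise scores for all pairs and normalizes them by the
#' geometric mean of the self-scores, `cc(i,j) = raw(i,j) /
#' sqrt(raw(i,i) * raw(j,j))`, clamped to `[-1, 1]` with unit diagonal.
#'
#' @param x An [new_msa()] (required for `"as_is"` mode) or a named character
#'   vector of ungapped sequences (`"aligned"` mode).
#' @param matrix Substitution matrix.
#' @param mode `"aligned"` or `"as_is"`.
#' @param gap_open,gap_extend Passed to [pairwise_score()] in aligned mode.
#' @return List of class `sim_matrix` with `ids`, `raw`, `cc`, `mode`.
#' @export
build_similarity <- function(x, matrix = load_substitution_matrix(),
                             mode = c("as_is", "aligned"),
                             gap_open = 11, gap_extend = 1) {
  mode <- match.arg(mode)
  if (inherits(x, "msa")) {
    ids <- x$ids
    rows <- unname(x$rows)
  } else {
    ids <- names(x)
    rows <- unname(x)
    if (is.null(ids)) stop("sequence vector must be named")
  }
  n <- length(ids)
  if (n < 3L) stop("need at least 3 sequences")

  if (mode == "as_is") {
    codes <- encode_rows(rows)
    p <- pad_gap(matrix)
    raw <- matrix(0, n, n)
    for (cc_col in seq_len(ncol(codes))) {
      idx <- codes[, cc_col]
      raw <- raw + p[idx, idx]
    }
  } else {
    if (any(grepl("-", rows, fixed = TRUE)))
      stop("aligned mode requires ungapped sequences")
    raw <- matrix(0, n, n)
    subj <- Biostrings::AAStringSet(rows)
    for (i in seq_len(n)) {
      sc <- Biostrings::pairwiseAlignment(
        subj[i:n], Biostrings::AAString(rows[i]),
        type = "global", substitutionMatrix = matrix,
        gapOpening = gap_open - gap_extend, gapExtension = gap_extend,
        scoreOnly = TRUE)
      raw[i, i:n] <- sc
      raw[i:n, i] <- sc
    }
  }
  dimnames(raw) <- list(ids, ids)
  self <- diag(raw)
  if (any(self <= 0))
    stop("non-positive self-score for sequence(s): ",
         paste(ids[self <= 0], collapse = ", "))
  cc <- raw / sqrt(outer(self, self))
  cc <- pmin(pmax(cc, -1), 1)
  diag(cc) <- 1
  structure(list(ids = ids, raw = raw, cc = cc, mode = mode),
            class = "sim_matrix")
}

#' Embed sequences as vectors from a similarity matrix
#'
#' Finds per-sequence vectors whose pairwise dot products reproduce the
#' normalized similarities, minimizing the off-diagonal Gram residual
#' `sum_{i<j} (x_i . x_j - cc_ij)^2` (the diagonal is excluded: self-scores
#' carry no relational information). The top-`d` positive eigenpairs of the
#' similarity matrix initialize a quasi-Newton (L-BFGS) refinement with
#' analytic gradient. The solution is defined only up to an orthogonal
#' transform; it is canonicalized by rotation to its principal axes (ordered
#' by decreasing captured variance, reported as `eigenvalues`) with signs
#' fixed so each coordinate sum is non-negative (first sequence non-negative
#' on ties), making maps reproducible bit-for-bit.
#'
#' @param sim A [build_similarity()] result.
#' @param d Number of dimensions (`<= n - 1`).
#' @param tol Convergence tolerance on the objective decrease.
#' @param max_iter Maximum refinement iterations; non-convergence is an error
#'   carrying the residual.
#' @return List of class `vector_map` with `ids`, `coords` (n x d, columns
#'   `D1..Dd`), `eigenvalues`, `residual`, `iterations`.
#' @export
embed <- function(sim, d = 3L, tol = 1e-10, max_iter = 2000L) {
  stopifnot(inherits(sim, "sim_matrix"))
  n <- length(sim$ids)
  d <- as.integer(d)
  if (d < 1L || d > n - 1L) stop("d must be in 1..(n-1)")

  cc <- sim$cc
  e <- eigen(cc, symmetric = TRUE)
  lam0 <- pmax(e$values[seq_len(d)], 0)
  X0 <- e$vectors[, seq_len(d), drop = FALSE] %*% diag(sqrt(lam0), d)

  objective <- function(x) {
    X <- matrix(x, n, d)
    E <- tcrossprod(X) - cc
    diag(E) <- 0
    sum(E * E) / 2
  }
  gradient <- function(x) {
    X <- matrix(x, n, d)
    E <- tcrossprod(X) - cc
    diag(E) <- 0
    as.vector(2 * (E %*% X))
  }
  fit <- stats::optim(as.vector(X0), objective, gradient,
                      method = "L-BFGS-B",
                      control = list(maxit = max_iter,
                                     factr = max(10, tol /
                                                   .Machine$double.eps),
                                     pgtol = 1e-8))
  residual <- fit$value
  if (fit$convergence == 1L)
    stop(sprintf(
      "embedding did not converge after %d iterations (residual %.3g)",
      max_iter, residual))
  X <- matrix(fit$par, n, d)

  # canonical representative: principal axes, then sign fixing
  s <- svd(X)
  X <- s$u %*% diag(s$d, d)
  lam <- s$d^2
  for (k in seq_len(d)) {
    cs <- sum(X[, k])
    if (cs < 0 || (cs == 0 && X[1, k] < 0)) X[, k] <- -X[, k]
  }
  dimnames(X) <- list(sim$ids, paste0("D", seq_len(d)))
  structure(list(ids = sim$ids, coords = X, eigenvalues = lam,
                 residual = residual, iterations = fit$counts[["function"]]),
            class = "vector_map")
}

#' @export
print.vector_map <- function(x, ...) {
  cat(sprintf("vector_map: %d sequences in %d dimensions\n",
              length(x$ids), ncol(x$coords)))
  cat("eigenvalues:", format(x$eigenvalues, digits = 4), "\n")
  invisible(x)
}

# Circular distance between angles in radians.
#' @noRd
circ_dist <- function(a, b) {
  d <- abs(outer(a, b, "-")) %% (2 * pi)
  pmin(d, 2 * pi - d)
}

#' Cluster sequences by vector angle
#'
#' Clusters the angular coordinate of the map in a chosen plane (default
#' dimensions 2 and 3, which resolve the finer systematic differences) with
#' k-medoids on the circular distance; `k` is chosen by maximum average
#' silhouette width over `k_range` unless given. Points with vector length
#' below `min_len_frac` of the longest vector carry no reliable angle and
#' are left unlabeled (`NA`).
#'
#' @param map A [embed()] result.
#' @param dims Length-2 integer: dimensions spanning the plane.
#' @param k Cluster count, or `NULL` to select by silhouette.
#' @param k_range Candidate `k` values when `k` is `NULL`.
#' @param min_len_frac Labeling threshold as a fraction of the longest vector.
#' @return List of class `cluster_result` with `labels` (named, `NA` for
#'   unlabeled), `k`, `dims_used`, `angles` (radians in `[0, 2*pi)`),
#'   `lengths`, `silhouette`.
#' @export
angular_clusters <- function(map, dims = c(2L, 3L), k = NULL, k_range = 2:6,
                             min_len_frac = 0.05) {
  stopifnot(inherits(map, "vector_map"))
  if (max(dims) > ncol(map$coords))
    stop("map has only ", ncol(map$coords), " dimensions")
  v <- map$coords[, dims, drop = FALSE]
  len <- sqrt(rowSums(v^2))
  ang <- atan2(v[, 2], v[, 1]) %% (2 * pi)
  ok <- len >= min_len_frac * max(len) & len > 0
  if (!any(ok)) stop("all points at the origin; no angles to cluster")

  dmat <- circ_dist(ang[ok], ang[ok])
  dst <- stats::as.dist(dmat)
  n_ok <- sum(ok)
  pick <- NULL
  sil <- NA_real_
  if (is.null(k)) {
    k_range <- k_range[k_range < n_ok]
    if (length(k_range) == 0L) k_range <- 2L
    best <- -Inf
    for (kk in k_range) {
      fit <- cluster::pam(dst, kk, pamonce = 5)
      w <- fit$silinfo$avg.width %||% -Inf
      if (w > best) {
        best <- w
        pick <- fit
      }
    }
    sil <- best
  } else {
    pick <- cluster::pam(dst, k, pamonce = 5)
    sil <- pick$silinfo$avg.width %||% NA_real_
  }
  labels <- rep(NA_integer_, length(len))
  labels[ok] <- pick$clustering
  names(labels) <- map$ids
  structure(list(labels = labels, k = length(unique(pick$clustering)),
                 dims_used = dims,
                 angles = stats::setNames(ang, map$ids),
                 lengths = stats::setNames(len, map$ids),
                 silhouette = sil),
            class = "cluster_result")
}

#' Per-sequence vector length, angle and prototypicality rank
#'
#' Length is the vector norm from the origin over all map dimensions -- the
#' prototypicality measure: long vectors carry strong systematic features,
#' short vectors are diversified sequences. The angle is measured in the
#' chosen plane. Within each cluster rank 1 is the longest vector, i.e. the
#' most prototypical sequence of its group. Points at the exact origin have
#' no angle and are flagged.
#'
#' @param map A [embed()] result.
#' @param dims Length-2 integer: plane the angle is measured in.
#' @param clusters Optional [angular_clusters()] result; ranks are computed
#'   within clusters when given, over the whole set otherwise.
#' @return Data frame with `id`, `length`, `angle`, `at_origin`, `cluster`,
#'   `prototypicality_rank`.
#' @export
vector_stats <- function(map, dims = c(2L, 3L), clusters = NULL) {
  stopifnot(inherits(map, "vector_map"))
  v <- map$coords[, dims, drop = FALSE]
  len <- sqrt(rowSums(map$coords^2))
  at_origin <- len == 0
  plane_zero <- rowSums(v^2) == 0
  ang <- ifelse(plane_zero, NA_real_, atan2(v[, 2], v[, 1]) %% (2 * pi))
  grp <- if (is.null(clusters)) rep(1L, length(len)) else
    clusters$labels[map$ids]
  rank <- rep(NA_integer_, length(len))
  for (g in unique(grp[!is.na(grp)])) {
    in_g <- which(!is.na(grp) & grp == g)
    rank[in_g] <- rank(-len[in_g], ties.method = "first")
  }
  data.frame(id = map$ids, length = unname(len), angle = unname(ang),
             at_origin = unname(at_origin),
             cluster = unname(if (is.null(clusters)) NA_integer_ else grp),
             prototypicality_rank = rank,
             row.names = NULL)
}

#' Re-embed a subset of sequences
#'
#' Runs a full new round of similarity + embedding on the members of one
#' cluster, resolving the finer systematic differences within it (e.g. the
#' position-in-tandem signal inside one domain type).
#'
#' @param x The original [new_msa()] or named sequence vector.
#' @param members Character vector of ids (>= 3) to keep.
#' @param matrix,mode,gap_open,gap_extend Passed to [build_similarity()].
#' @param d,tol,max_iter Passed to [embed()].
#' @return A `vector_map` over `members`.
#' @export
subcluster <- function(x, members, matrix = load_substitution_matrix(),
                       mode = c("as_is", "aligned"),
                       gap_open = 11, gap_extend = 1,
                       d = 3L, tol = 1e-10, max_iter = 2000L) {
  mode <- match.arg(mode)
  if (length(members) < 3L)
    stop("subcluster needs at least 3 members, got ", length(members))
  if (inherits(x, "msa")) {
    keep <- x$ids %in% members
    if (sum(keep) < length(members))
      stop("members missing from input: ",
           paste(setdiff(members, x$ids), collapse = ", "))
    sub <- new_msa(x$ids[keep], x$rows[keep])
  } else {
    if (!all(members %in% names(x)))
      stop("members missing from input: ",
           paste(setdiff(members, names(x)), collapse = ", "))
    sub <- x[members]
  }
  embed(build_similarity(sub, matrix, mode, gap_open, gap_extend),
        d = min(d, length(members) - 1L), tol = tol, max_iter = max_iter)
}

#' Scatter plot of a 2D slice of a vector map
#'
#' @param map A `vector_map`.
#' @param dims Length-2 integer: dimensions to plot.
#' @param clusters Optional `cluster_result` used to colour points.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the plotted coordinates.
#' @export
plot_map <- function(map, dims = c(2L, 3L), clusters = NULL, ...) {
  v <- map$coords[, dims, drop = FALSE]
  col <- if (is.null(clusters)) "grey30" else {
    lab <- clusters$labels[map$ids]
    ifelse(is.na(lab), "grey70", grDevices::hcl.colors(
      max(lab, na.rm = TRUE), "Dark 3")[lab])
  }
  graphics::plot(v[, 1], v[, 2], col = col, pch = 19,
                 xlab = colnames(v)[1], ylab = colnames(v)[2], ...)
  graphics::abline(h = 0, v = 0, col = "grey85", lty = 3)
  invisible(v)
}
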