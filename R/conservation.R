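# Per-column sum-of-pairs (SoP) conservation scoring of an MSA.
#
# SoP of a column is the expectation of the substitution score over unordered
# pairs of distinct sequence indices drawn without replacement from the
# non-gap entries of the column:
#   SoP = [ sum_{a} C(n_a,2) B(a,a) + sum_{a<b} n_a n_b B(a,b) ] / C(m,2)
# with n_a the count of residue a among the m non-gap entries. Gap entries
# never form pairs; separately, columns with >= 50% gaps are zeroed outright
# (the AL2CO gap rule) to avoid spurious conservation in under-occupied
# positions. Sequences are unweighted.

#' Sum-of-pairs conservation score of one alignment column
#'
#' @param column Character vector of single residues (gaps as `"-"`).
#' @param matrix Substitution matrix from [load_substitution_matrix()].
#' @return Numeric score; 0 (with attribute `insufficient = TRUE`) when fewer
#'   than two non-gap entries are present.
#' @export
sop_column <- function(column, matrix = load_substitution_matrix()) {
  res <- column[column != GAP]
  m <- length(res)
  if (m < 2L) return(structure(0, insufficient = TRUE))
  cnt <- table(factor(res, levels = rownames(matrix)))
  cnt <- as.numeric(cnt)
  d <- diag(matrix)
  # sum over unordered pairs = (quadratic form - self terms) / 2
  tot <- (drop(t(cnt) %*% matrix %*% cnt) - sum(cnt * d)) / 2
  tot / choose(m, 2)
}

#' Per-column conservation profile of an MSA
#'
#' Applies [sop_column()] to every column and the >= `gap_threshold` gap rule.
#'
#' @param msa An [new_msa()] object.
#' @param matrix Substitution matrix.
#' @param gap_threshold Gap fraction at or above which a column's score is set
#'   to 0 (default 0.5).
#' @return Data frame of class `conservation_profile` with 1-based `col`,
#'   `sop`, `occupancy`, `gap_fraction`, `zeroed_by_gap_rule`.
#' @export
sop_profile <- function(msa, matrix = load_substitution_matrix(),
                        gap_threshold = 0.5) {
  stopifnot(inherits(msa, "msa"))
  chars <- as.matrix(msa)
  n <- nrow(chars)
  gap_frac <- colMeans(chars == GAP)
  occupancy <- 1 - gap_frac
  zeroed <- gap_frac >= gap_threshold
  sop <- numeric(msa$n_cols)
  for (j in seq_len(msa$n_cols)) {
    if (zeroed[j]) next
    s <- sop_column(chars[, j], matrix)
    if (isTRUE(attr(s, "insufficient"))) {
      zeroed[j] <- TRUE
      s <- 0
    }
    sop[j] <- as.numeric(s)
  }
  sop[zeroed] <- 0
  out <- data.frame(col = seq_len(msa$n_cols), sop = sop,
                    occupancy = occupancy, gap_fraction = gap_frac,
                    zeroed_by_gap_rule = zeroed)
  class(out) <- c("conservation_profile", "data.frame")
  out
}

#' Rank alignment columns by conservation
#'
#' Orders columns by decreasing SoP score; ties are broken by ascending
#' column index so that the derivative-MSA series is deterministic.
#'
#' @param profile A [sop_profile()] result.
#' @return Integer vector of column indices, most conserved first.
#' @export
rank_positions <- function(profile) {
  stopifnot(inherits(profile, "conservation_profile"))
  profile$col[order(-profile$sop, profile$col)]
}
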