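# Internal helpers shared across modules.

# 20 standard amino acids, plus 'X' for anything nonstandard; '-' is the only
# gap character after normalization.
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
AA21 <- c(AA20, "X")
GAP <- "-"

# BLOSUM62 background (marginal) amino-acid frequencies, used as the residue
# distribution of the synthetic generator.
B62_FREQS <- c(
  A = 0.074, R = 0.052, N = 0.045, D = 0.054, C = 0.025,
  Q = 0.034, E = 0.054, G = 0.074, H = 0.026, I = 0.068,
  L = 0.099, K = 0.058, M = 0.025, F = 0.047, P = 0.039,
  S = 0.057, T = 0.051, W = 0.013, Y = 0.032, V = 0.073)

#' @noRd
normalize_residues <- function(x) {
  x <- toupper(x)
  x <- gsub("*", "", x, fixed = TRUE)
  # nonstandard residue codes collapse to 'X'
  gsub(sprintf("[^%s-]", paste(AA21, collapse = "")), "X", x)
}

# Split equal-length strings into a character matrix (rows = sequences).
#' @noRd
seq_char_matrix <- function(rows) {
  n_cols <- unique(nchar(rows))
  stopifnot(length(n_cols) == 1L)
  matrix(unlist(strsplit(rows, "", fixed = TRUE), use.names = FALSE),
         nrow = length(rows), ncol = n_cols, byrow = TRUE)
}

# Integer encoding of MSA rows: 1..21 = AA21, 22 = gap. Used with a padded
# score matrix so the gap row/column scores 0 everywhere.
#' @noRd
encode_rows <- function(rows) {
  m <- seq_char_matrix(rows)
  codes <- match(m, c(AA21, GAP))
  if (anyNA(codes)) stop("unexpected character in sequence rows")
  matrix(codes, nrow = nrow(m), ncol = ncol(m))
}

# Pad a 21x21 substitution matrix with a zero gap row/column (index 22).
#' @noRd
pad_gap <- function(mat) {
  p <- matrix(0, 22L, 22L)
  p[1:21, 1:21] <- mat[AA21, AA21]
  p
}

# Evaluate an expression with a temporary RNG seed, restoring the caller's
# RNG state afterwards (no-op when seed is NULL).
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
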