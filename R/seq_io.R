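# Sequence, alignment, annotation and substitution-matrix IO.

TANDEM_POSITIONS <- c("1", "2", "3", "4", "5",
                      "1'", "2'", "3'", "4'", "5'",
                      "3''", "4''", "5''")
FNIII_TYPES <- c("A", "B", "C", "Ig")

#' Read domain sequences from a FASTA file
#'
#' Reads ungapped protein sequences. Residues are upper-cased, `'*'` stripped
#' and nonstandard residue codes mapped to `'X'` on read.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of residue strings; names are domain ids
#'   (the first whitespace-delimited token of each header).
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "))
  raw <- as.character(set)
  if (any(grepl("-", raw, fixed = TRUE) | grepl(".", raw, fixed = TRUE)))
    stop("gap characters found; use read_msa() for aligned input")
  seqs <- normalize_residues(raw)
  if (any(nchar(seqs) == 0L))
    stop("empty sequence for id(s): ",
         paste(ids[nchar(seqs) == 0L], collapse = ", "))
  names(seqs) <- ids
  seqs
}

#' Write domain sequences to FASTA
#'
#' @param seqs Named character vector of residue strings.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  invisible(path)
}

#' Construct a multiple sequence alignment object
#'
#' An `msa` holds equal-length gapped rows with unique ids. The gap character
#' is `'-'`; `'.'` is accepted and normalized on construction.
#'
#' @param ids Character vector of unique row ids.
#' @param rows Character vector of gapped sequences, all the same length.
#' @return An object of class `msa` with elements `ids`, `rows`, `n_cols`.
#' @export
new_msa <- function(ids, rows) {
  ids <- as.character(ids)
  rows <- normalize_residues(gsub(".", "-", as.character(rows), fixed = TRUE))
  if (length(ids) != length(rows)) stop("ids and rows differ in length")
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop("duplicate id(s) in MSA: ", paste(unique(dup), collapse = ", "))
  lens <- nchar(rows)
  if (length(unique(lens)) != 1L) {
    bad <- which(lens != stats::median(lens))
    stop("ragged MSA rows: ",
         paste(sprintf("%s (length %d)", ids[bad], lens[bad]), collapse = ", "),
         "; expected length ", stats::median(lens))
  }
  if (lens[1] < 1L) stop("MSA must have at least one column")
  structure(list(ids = ids, rows = stats::setNames(rows, ids),
                 n_cols = lens[1]),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("msa: %d sequences x %d columns\n", length(x$ids), x$n_cols))
  invisible(x)
}

#' @exportS3Method base::as.matrix
as.matrix.msa <- function(x, ...) {
  m <- seq_char_matrix(x$rows)
  rownames(m) <- x$ids
  m
}

#' Read a multiple sequence alignment
#'
#' @param path Path to the alignment file.
#' @param dialect `"fasta"` or `"clustal"`.
#' @return An [new_msa()] object.
#' @export
read_msa <- function(path, dialect = c("fasta", "clustal")) {
  dialect <- match.arg(dialect)
  if (dialect == "fasta") {
    set <- Biostrings::readBStringSet(path)
    if (length(set) == 0L) stop("empty alignment file: ", path)
    new_msa(sub("\\s.*$", "", names(set)), as.character(set))
  } else {
    parse_clustal(readLines(path))
  }
}

# Minimal tolerant Clustal parser: first line is the header, sequence lines
# are "<name><spaces><gapped block>", conservation lines (only [.:* ]) and
# blanks are skipped, blocks are concatenated per name in first-seen order.
#' @noRd
parse_clustal <- function(lines) {
  if (length(lines) == 0L) stop("empty alignment file")
  body <- lines[-1]
  acc <- list()
  order_seen <- character(0)
  for (ln in body) {
    if (grepl("^\\s*$", ln)) next
    if (grepl("^\\s", ln)) next                   # conservation line
    m <- regmatches(ln, regexec("^(\\S+)\\s+(\\S+)\\s*\\d*\\s*$", ln))[[1]]
    if (length(m) != 3L) next
    id <- m[2]
    if (!id %in% order_seen) order_seen <- c(order_seen, id)
    acc[[id]] <- paste0(acc[[id]] %||% "", m[3])
  }
  if (length(acc) == 0L) stop("no sequence lines found in clustal input")
  new_msa(order_seen, unlist(acc[order_seen], use.names = FALSE))
}

#' Write an MSA as aligned FASTA
#'
#' One sequence line per record, so that `read_msa(write_msa(x))` round-trips
#' rows byte-for-byte.
#'
#' @param msa An `msa` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_msa <- function(msa, path) {
  stopifnot(inherits(msa, "msa"))
  writeLines(paste0(">", msa$ids, "\n", unname(msa$rows)), path)
  invisible(path)
}

#' Read a repeat-annotation table
#'
#' Tab-separated table with columns `domain_id`, `zone`, `repeat_index`,
#' `tandem_position`, `fniii_type`, `linker_seq` describing the organization
#' of domains into super-repeats (D-zone: repeats 1-6, tandem positions 1-5;
#' C-zone: repeats 1-11, positions 1'-5' and 3''-5''). An empty linker field
#' denotes a zero-length linker.
#'
#' @param path Path to a TSV file with a header row.
#' @return A `data.frame` of class `repeat_annotation`.
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", na.strings = NULL,
                          strip.white = TRUE)
  validate_annotation(df)
}

#' @noRd
validate_annotation <- function(df) {
  need <- c("domain_id", "zone", "repeat_index", "tandem_position",
            "fniii_type", "linker_seq")
  if (!all(need %in% names(df)))
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  df <- df[need]
  df$linker_seq[is.na(df$linker_seq)] <- ""
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    if (!r$zone %in% c("D", "C"))
      stop(sprintf("row %d: unknown zone '%s'", i, r$zone))
    if (!r$tandem_position %in% TANDEM_POSITIONS)
      stop(sprintf("row %d: unknown tandem position '%s'", i,
                   r$tandem_position))
    if (!r$fniii_type %in% FNIII_TYPES)
      stop(sprintf("row %d: unknown FnIII type '%s'", i, r$fniii_type))
    idx <- suppressWarnings(as.integer(r$repeat_index))
    if (is.na(idx) ||
        (r$zone == "D" && !(idx %in% 1:6)) ||
        (r$zone == "C" && !(idx %in% 1:11)))
      stop(sprintf("row %d: repeat index '%s' invalid for zone %s",
                   i, r$repeat_index, r$zone))
  }
  dup <- df$domain_id[duplicated(df$domain_id)]
  if (length(dup) > 0L)
    stop("duplicate domain id(s): ", paste(unique(dup), collapse = ", "))
  df$repeat_index <- as.integer(df$repeat_index)
  class(df) <- c("repeat_annotation", "data.frame")
  df
}

#' Write a repeat-annotation table
#'
#' @param annotation A `repeat_annotation` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Load a substitution matrix
#'
#' Either the built-in BLOSUM62 (from Biostrings) or a square whitespace-
#' separated text file with residue letters in the first row and one labelled
#' row per residue. The returned matrix covers the 20 standard amino acids
#' plus `'X'`; any pair involving `'X'` scores 0.
#'
#' @param source `"BLOSUM62"` or a file path.
#' @return Symmetric numeric matrix with residue dimnames.
#' @export
load_substitution_matrix <- function(source = "BLOSUM62") {
  if (identical(source, "BLOSUM62")) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    full <- e$BLOSUM62
    mat <- matrix(0, 21L, 21L, dimnames = list(AA21, AA21))
    mat[AA20, AA20] <- full[AA20, AA20]
  } else {
    tab <- utils::read.table(source, header = TRUE, row.names = 1,
                             check.names = FALSE)
    mat0 <- as.matrix(tab)
    if (!isTRUE(all.equal(mat0, t(mat0))))
      stop("substitution matrix is not symmetric: ", source)
    mat <- matrix(0, 21L, 21L, dimnames = list(AA21, AA21))
    keep <- intersect(rownames(mat0), AA20)
    mat[keep, keep] <- mat0[keep, keep]
  }
  storage.mode(mat) <- "double"
  mat
}
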