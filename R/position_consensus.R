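# Hierarchical conservation: global -> domain-type -> super-repeat-position
# tiers, plus interdomain linker classification.
#
# Tier columns are masked (replaced by gaps) before the next tier is scored,
# so the three tiers are disjoint by construction. Position-specific
# conservation is assessed over C-zone super-repeats 2..11 only, the
# functionally homogeneous part of the region.

# Identity groups for the position tier: residues within a group count as
# identical; residues outside any group match only themselves.
IDENTITY_GROUPS <- list(TIL = c("T", "I", "L"),
                        DEN = c("D", "E", "N"),
                        FY  = c("F", "Y"))

#' Extract the sub-alignment of one FnIII type
#'
#' @param msa The global [new_msa()].
#' @param annotation A `repeat_annotation`.
#' @param type FnIII type label (`"A"`, `"B"` or `"C"`).
#' @return An `msa` restricted to domains of that type.
#' @export
type_msa <- function(msa, annotation, type) {
  ids <- annotation$domain_id[annotation$fniii_type == type]
  ids <- intersect(msa$ids, ids)
  if (length(ids) < 3L)
    stop("fewer than 3 domains of type ", type)
  new_msa(ids, msa$rows[ids])
}

#' Type-specific conserved columns
#'
#' Masks the globally conserved columns out of a type-restricted MSA, rescores
#' conservation and returns the columns scoring strictly above `sop_cutoff`
#' (default 1, the smallest positive BLOSUM62 entry, i.e. the weakest
#' conservation among similar residues). Disjoint from the global tier by
#' construction.
#'
#' @param tmsa Type-restricted `msa` (see [type_msa()]).
#' @param global_cols Integer vector: the global consensus columns.
#' @param matrix Substitution matrix.
#' @param sop_cutoff Conservation threshold.
#' @return Integer vector of column indices.
#' @export
type_consensus <- function(tmsa, global_cols,
                           matrix = load_substitution_matrix(),
                           sop_cutoff = 1) {
  stopifnot(inherits(tmsa, "msa"))
  masked <- mask_columns(tmsa, global_cols)
  prof <- sop_profile(masked, matrix)
  setdiff(prof$col[prof$sop > sop_cutoff], as.integer(global_cols))
}

#' Build the masked per-position sub-alignment
#'
#' Rows are the domains sitting at one tandem-position token across C-zone
#' super-repeats `repeats` (default 2..11); columns of the global and
#' type tiers are masked out.
#'
#' @param msa The global `msa`.
#' @param annotation A `repeat_annotation`.
#' @param token Tandem-position token (e.g. `"5'"`).
#' @param global_cols,type_cols Tier columns to mask (type tier: columns of
#'   the type(s) occupying this token).
#' @param repeats C-zone repeat indices to include.
#' @return A masked `msa` with attribute `masked_cols`.
#' @export
position_msa <- function(msa, annotation, token, global_cols = integer(0),
                         type_cols = integer(0), repeats = 2:11) {
  sel <- annotation$zone == "C" &
    annotation$repeat_index %in% repeats &
    annotation$tandem_position == token
  ids <- intersect(msa$ids, annotation$domain_id[sel])
  if (length(ids) < 2L)
    stop("fewer than 2 domains at position ", token, " in repeats ",
         paste(range(repeats), collapse = "-"))
  sub <- new_msa(ids, msa$rows[ids])
  masked <- mask_columns(sub, c(global_cols, type_cols))
  attr(masked, "masked_cols") <- list(global = as.integer(global_cols),
                                      type = as.integer(type_cols))
  masked
}

# Fraction of non-gap entries identical under the group rule, and the
# consensus residue(s) achieving it.
#' @noRd
group_identity <- function(res, groups = IDENTITY_GROUPS) {
  res <- res[res != GAP]
  if (length(res) == 0L) return(list(identity = 0, consensus = character(0)))
  singles <- table(res) / length(res)
  best <- max(singles)
  cons <- names(singles)[which.max(singles)]
  for (g in groups) {
    frac <- mean(res %in% g)
    if (frac > best) {
      best <- frac
      cons <- sort(intersect(g, unique(res)))
    }
  }
  list(identity = best, consensus = cons)
}

#' Position-specific conserved residues
#'
#' Scores the remaining (unmasked) columns of a per-position alignment and
#' retains those meeting all three criteria: SoP score `>= sop_min`,
#' occupancy `>= occ_min`, and identity `>= ident_min` where identity is the
#' best fraction of non-gap entries matching a single residue or one of the
#' identity groups (TIL, DEN, FY).
#'
#' @param pmsa Masked per-position `msa` from [position_msa()].
#' @param token Tandem-position token the alignment represents.
#' @param matrix Substitution matrix.
#' @param sop_min,occ_min,ident_min The three criteria (defaults 1, 0.9, 0.7).
#' @param groups Identity groups.
#' @return List of class `position_consensus`: `tandem_position`, `conserved`
#'   (data frame `column`, `consensus`, `sop`, `occupancy`, `identity`),
#'   `motif_string`.
#' @export
position_specific_conserved <- function(pmsa, token,
                                        matrix = load_substitution_matrix(),
                                        sop_min = 1, occ_min = 0.9,
                                        ident_min = 0.7,
                                        groups = IDENTITY_GROUPS) {
  stopifnot(inherits(pmsa, "msa"))
  if (length(pmsa$ids) < 2L) stop("position alignment has fewer than 2 rows")
  chars <- as.matrix(pmsa)
  masked <- unlist(attr(pmsa, "masked_cols"), use.names = FALSE)
  prof <- sop_profile(pmsa, matrix)
  keep <- integer(0)
  cons_str <- character(0)
  idents <- numeric(0)
  for (j in setdiff(prof$col, masked)) {
    if (prof$occupancy[j] < occ_min) next
    if (prof$sop[j] < sop_min) next
    gi <- group_identity(chars[, j], groups)
    if (gi$identity < ident_min) next
    keep <- c(keep, j)
    cons_str <- c(cons_str, paste(gi$consensus, collapse = "/"))
    idents <- c(idents, gi$identity)
  }
  conserved <- data.frame(column = keep, consensus = cons_str,
                          sop = prof$sop[keep],
                          occupancy = prof$occupancy[keep],
                          identity = idents)
  structure(list(tandem_position = token, conserved = conserved,
                 motif_string = motif_string(conserved)),
            class = "position_consensus")
}

# Compact motif notation over the span of conserved columns: conserved
# positions print their consensus (alternatives bracketed as [D/E]),
# unconstrained positions print as 'x'.
#' @noRd
motif_string <- function(conserved) {
  if (nrow(conserved) == 0L) return("")
  span <- seq(min(conserved$column), max(conserved$column))
  out <- vapply(span, function(j) {
    hit <- match(j, conserved$column)
    if (is.na(hit)) return("x")
    cons <- conserved$consensus[hit]
    if (grepl("/", cons, fixed = TRUE)) paste0("[", cons, "]") else cons
  }, character(1))
  paste(out, collapse = "")
}

#' Classify an interdomain linker sequence
#'
#' The short FnIII-FnIII linkers fall into three motif classes: zero-length
#' (domains abut directly), `[N/Y]PF` and `DPI`; anything else (including
#' degenerate derivatives) is `other`. Matching is case-insensitive and exact
#' length 3 for the motif classes.
#'
#' @param linker_seq Character vector of linker sequences (may be empty
#'   strings or `NA` for zero-length).
#' @return Character vector with values `zero_length`, `NPF_type`,
#'   `DPI_type`, `other`.
#' @export
classify_linker <- function(linker_seq) {
  s <- toupper(ifelse(is.na(linker_seq), "", linker_seq))
  out <- rep("other", length(s))
  out[s == ""] <- "zero_length"
  out[grepl("^[NY]PF$", s)] <- "NPF_type"
  out[grepl("^DPI$", s)] <- "DPI_type"
  out
}

#' Per-position conservation report
#'
#' Collates the three tiers into one table keyed by tandem position, checks
#' tier disjointness, and projects each position-specific conserved column
#' onto the residues of a reference super-repeat (default the central C-zone
#' repeat present in the annotation).
#'
#' @param msa The global `msa`.
#' @param annotation A `repeat_annotation`.
#' @param tiers List with `global` (integer), `type` (named list of integer)
#'   and `position` (named list of `position_consensus`).
#' @param reference_repeat C-zone repeat index used for the sequence
#'   projection.
#' @return Data frame with `tandem_position`, `column`, `consensus`, `sop`,
#'   `occupancy`, `identity`, `reference_id`, `reference_residue`.
#' @export
consensus_report <- function(msa, annotation, tiers,
                             reference_repeat = NULL) {
  all_tiers <- list(global = tiers$global,
                    type = unlist(tiers$type, use.names = FALSE),
                    position = unlist(lapply(tiers$position, function(p)
                      p$conserved$column), use.names = FALSE))
  for (a in names(all_tiers)) for (b in names(all_tiers)) {
    if (a >= b) next
    ov <- intersect(all_tiers[[a]], all_tiers[[b]])
    if (length(ov) > 0L)
      stop("tier overlap between ", a, " and ", b, ": ",
           paste(ov, collapse = ", "))
  }
  c_reps <- sort(unique(annotation$repeat_index[annotation$zone == "C"]))
  if (is.null(reference_repeat))
    reference_repeat <- c_reps[ceiling(length(c_reps) / 2)]
  chars <- as.matrix(msa)
  rows <- list()
  for (token in names(tiers$position)) {
    pc <- tiers$position[[token]]
    if (nrow(pc$conserved) == 0L) next
    ref_id <- annotation$domain_id[annotation$zone == "C" &
      annotation$repeat_index == reference_repeat &
      annotation$tandem_position == token]
    ref_res <- if (length(ref_id) == 1L && ref_id %in% msa$ids)
      chars[ref_id, pc$conserved$column] else
      rep(NA_character_, nrow(pc$conserved))
    rows[[token]] <- data.frame(
      tandem_position = token,
      pc$conserved,
      reference_id = if (length(ref_id) == 1L) ref_id else NA_character_,
      reference_residue = unname(ref_res))
  }
  if (length(rows) == 0L)
    return(data.frame(tandem_position = character(0), column = integer(0),
                      consensus = character(0), sop = numeric(0),
                      occupancy = numeric(0), identity = numeric(0),
                      reference_id = character(0),
                      reference_residue = character(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
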