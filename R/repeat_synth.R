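# Synthetic repeat-protein families with planted conservation tiers.
#
# The generator emulates a poly-FnIII super-repeat region: ~100-120 domains of
# ~95 residues organized into D-zone (-AC-ABC, 6 repeats) and C-zone
# (-AC-ABC-ABC, 11 repeats) units, with a shared global consensus, three
# planted sequence types (A/B/C), position-in-repeat-specific conserved
# residues, and a V-shaped divergence gradient that makes central repeats
# closest to consensus. Families are emitted pre-aligned (no indels), so the
# alignment is trivially known and tier truth can be asserted downstream.

D_UNIT_POSITIONS <- c("1", "2", "3", "4", "5")
D_UNIT_TYPES     <- c("A", "C", "A", "B", "C")
C_UNIT_POSITIONS <- c("1'", "2'", "3'", "4'", "5'", "3''", "4''", "5''")
C_UNIT_TYPES     <- c("A", "C", "A", "B", "C", "A", "B", "C")

# Deterministic default planted columns for a given domain length: disjoint
# residue positions for the three tiers, spread along the domain.
#' @noRd
default_planted <- function(domain_length) {
  stopifnot(domain_length >= 95)
  global_cols <- seq(3L, by = 8L, length.out = 12L)
  global_res <- c("P", "W", "Y", "N", "G", "D", "S", "L", "A", "E", "F", "T")
  type_cols <- seq(5L, by = 8L, length.out = 12L)
  type_res <- list(A = c("K", "H", "M", "Q"),
                   B = c("R", "C", "V", "I"),
                   C = c("E", "F", "T", "S"))
  pos_pool <- c(seq(6L, by = 8L, length.out = 12L),
                seq(7L, by = 8L, length.out = 12L),
                c(8L, 16L))
  tokens <- TANDEM_POSITIONS
  pos_res <- c("D", "N", "E", "Q", "K", "R", "S", "T", "Y", "F", "W", "H", "G")
  position <- stats::setNames(vector("list", length(tokens)), tokens)
  for (i in seq_along(tokens)) {
    cols <- pos_pool[c(2L * i - 1L, 2L * i)]
    position[[i]] <- data.frame(column = cols,
                                residue = c(pos_res[i],
                                            pos_res[(i %% 13L) + 1L]))
  }
  list(
    global = data.frame(column = global_cols, residue = global_res),
    type = list(
      A = data.frame(column = type_cols[c(1, 4, 7, 10)], residue = type_res$A),
      B = data.frame(column = type_cols[c(2, 5, 8, 11)], residue = type_res$B),
      C = data.frame(column = type_cols[c(3, 6, 9, 12)], residue = type_res$C)),
    position = position)
}

#' Configuration for the synthetic repeat-family generator
#'
#' Defaults emulate the study system: a D-zone of 6 `-AC-ABC` repeat units and
#' a C-zone of 11 `-AC-ABC-ABC` units (118 FnIII domains of 95 residues), a
#' planted global consensus of 12 columns, 4 type-specific columns per
#' sequence type, 2 position-specific columns per tandem-position token, a
#' background substitution rate of 0.55 per non-planted column, and a
#' symmetric V-shaped gradient over repeat index multiplying that rate by 0.5
#' at the central repeat of each zone and 1.5 at its termini.
#'
#' @param d_repeats,c_repeats Number of D-zone / C-zone super-repeat units.
#' @param domain_length Residues per domain.
#' @param global_conserved Data frame `(column, residue)` planted in every
#'   domain, or `NULL` for the built-in default.
#' @param type_conserved Named list (`A`, `B`, `C`) of `(column, residue)`
#'   frames, or `NULL` for the default.
#' @param position_conserved Named list keyed by tandem-position token of
#'   `(column, residue)` frames, or `NULL` for the default.
#' @param background_sub_rate Substitution probability per non-planted column
#'   before the gradient multiplier.
#' @param gradient_range Length-2 numeric: multiplier at the central repeat
#'   and at the zone termini.
#' @param planted_motif_violation_rate Probability that a planted column
#'   mutates anyway.
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(d_repeats = 6L, c_repeats = 11L,
                         domain_length = 95L,
                         global_conserved = NULL,
                         type_conserved = NULL,
                         position_conserved = NULL,
                         background_sub_rate = 0.55,
                         gradient_range = c(0.5, 1.5),
                         planted_motif_violation_rate = 0.03,
                         seed = 1L) {
  planted <- default_planted(max(domain_length, 95L))
  cfg <- list(
    d_repeats = as.integer(d_repeats),
    c_repeats = as.integer(c_repeats),
    domain_length = as.integer(domain_length),
    global_conserved = global_conserved %||% planted$global,
    type_conserved = type_conserved %||% planted$type,
    position_conserved = position_conserved %||% planted$position,
    background_sub_rate = background_sub_rate,
    gradient_range = gradient_range,
    planted_motif_violation_rate = planted_motif_violation_rate,
    seed = as.integer(seed))
  rates <- c(cfg$background_sub_rate, cfg$planted_motif_violation_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  all_cols <- c(cfg$global_conserved$column,
                unlist(lapply(cfg$type_conserved, `[[`, "column")),
                unlist(lapply(cfg$position_conserved, `[[`, "column")))
  if (anyDuplicated(all_cols))
    stop("planted column collision across tiers: column(s) ",
         paste(unique(all_cols[duplicated(all_cols)]), collapse = ", "))
  if (any(all_cols > cfg$domain_length))
    stop("planted columns exceed domain length")
  class(cfg) <- "synth_config"
  cfg
}

# Per-repeat divergence multiplier: V-shape, minimum at the zone centre.
#' @noRd
gradient_multiplier <- function(repeat_index, n_repeats, range) {
  if (n_repeats == 1L) return(range[1])
  centre <- (n_repeats + 1) / 2
  frac <- abs(repeat_index - centre) / (n_repeats - centre)
  range[1] + frac * (range[2] - range[1])
}

#' Substitute residues of a sequence at a given per-column rate
#'
#' Each column is independently substituted with probability `rate`; the
#' replacement is drawn from the BLOSUM62 background residue distribution
#' excluding the original residue. Uses R's global RNG stream.
#'
#' @param consensus Residue string.
#' @param rate Substitution probability per column, in `[0, 1]`.
#' @return Mutated residue string.
#' @export
mutate_sequence <- function(consensus, rate) {
  stopifnot(rate >= 0, rate <= 1)
  chars <- strsplit(consensus, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    pool <- setdiff(names(B62_FREQS), chars[i])
    chars[i] <- sample(pool, 1L, prob = B62_FREQS[pool])
  }
  paste(chars, collapse = "")
}

#' Generate a synthetic repeat-protein family
#'
#' Produces a pre-aligned family (no indels), its repeat annotation, and a
#' truth table recording each domain's planted type and each column's tier.
#' Deterministic for a fixed `config$seed`.
#'
#' @param config A [synth_config()].
#' @return List of class `synth_family` with elements `msa` ([new_msa()]),
#'   `annotation` (`repeat_annotation`), and `truth` (list with
#'   `domain_type`, `domain_repeat`, `domain_token`, `column_tier`,
#'   `repeat_multiplier`).
#' @export
generate_family <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, generate_family_impl(config))
}

#' @noRd
generate_family_impl <- function(cfg) {
  L <- cfg$domain_length

  # layout -> one row per FnIII domain
  layout <- list()
  for (r in seq_len(cfg$d_repeats))
    layout[[length(layout) + 1L]] <-
      data.frame(zone = "D", repeat_index = r,
                 tandem_position = D_UNIT_POSITIONS, fniii_type = D_UNIT_TYPES)
  for (r in seq_len(cfg$c_repeats))
    layout[[length(layout) + 1L]] <-
      data.frame(zone = "C", repeat_index = r,
                 tandem_position = C_UNIT_POSITIONS, fniii_type = C_UNIT_TYPES)
  ann <- do.call(rbind, layout)
  ann$domain_id <- sprintf("%s%02d_%s", ann$zone, ann$repeat_index,
                           gsub("'", "p", ann$tandem_position, fixed = TRUE))
  ann$linker_seq <- assign_linkers(ann)
  ann <- validate_annotation(ann)

  # column tiers
  tier <- rep("background", L)
  g <- cfg$global_conserved
  tier[g$column] <- "global"
  for (ty in names(cfg$type_conserved))
    tier[cfg$type_conserved[[ty]]$column] <- paste0("type:", ty)
  for (tk in names(cfg$position_conserved))
    tier[cfg$position_conserved[[tk]]$column] <- paste0("position:", tk)

  # master consensus: planted residues at global columns, background draws
  # elsewhere (type/position columns hold background residues in the master
  # and are overlaid per domain)
  master <- sample(names(B62_FREQS), L, replace = TRUE, prob = B62_FREQS)
  master[g$column] <- g$residue

  viol <- cfg$planted_motif_violation_rate
  rows <- character(nrow(ann))
  mult <- numeric(nrow(ann))
  for (i in seq_len(nrow(ann))) {
    zone_n <- if (ann$zone[i] == "D") cfg$d_repeats else cfg$c_repeats
    m <- gradient_multiplier(ann$repeat_index[i], zone_n, cfg$gradient_range)
    mult[i] <- m
    rate <- min(1, cfg$background_sub_rate * m)

    chars <- master
    tyc <- cfg$type_conserved[[ann$fniii_type[i]]]
    if (!is.null(tyc)) chars[tyc$column] <- tyc$residue
    poc <- cfg$position_conserved[[ann$tandem_position[i]]]
    if (!is.null(poc)) chars[poc$column] <- poc$residue

    planted_here <- g$column
    if (!is.null(tyc)) planted_here <- c(planted_here, tyc$column)
    if (!is.null(poc)) planted_here <- c(planted_here, poc$column)
    col_rate <- rep(rate, L)
    col_rate[planted_here] <- viol

    hit <- which(stats::runif(L) < col_rate)
    for (j in hit) {
      pool <- setdiff(names(B62_FREQS), chars[j])
      chars[j] <- sample(pool, 1L, prob = B62_FREQS[pool])
    }
    rows[i] <- paste(chars, collapse = "")
  }

  rep_key <- paste0(ann$zone, ann$repeat_index)
  truth <- list(
    domain_type = stats::setNames(ann$fniii_type, ann$domain_id),
    domain_repeat = stats::setNames(rep_key, ann$domain_id),
    domain_token = stats::setNames(ann$tandem_position, ann$domain_id),
    column_tier = tier,
    repeat_multiplier = stats::setNames(mult, ann$domain_id))

  structure(list(msa = new_msa(ann$domain_id, rows),
                 annotation = ann, truth = truth, config = cfg),
            class = "synth_family")
}

# C-terminal linker assignment mirroring the periodic pattern of the study
# system: [D]PI at D-zone pairs 1-2 and 4-5 and C-zone 4'-5' / 4''-5'',
# [N/Y]PF at pairs 3-4 / 3'-4' / 3''-4'', zero-length at C-zone 1'-2' except
# in repeat C1 (which retains the ancestral DPI); domains followed by an Ig
# carry no FnIII-FnIII linker (empty field).
#' @noRd
assign_linkers <- function(ann) {
  lk <- character(nrow(ann))
  for (i in seq_len(nrow(ann))) {
    tok <- ann$tandem_position[i]
    lk[i] <- switch(tok,
      "1" = "DPI", "4" = "DPI", "4'" = "DPI", "4''" = "DPI",
      "3" = if (ann$repeat_index[i] %% 2L == 0L) "NPF" else "YPF",
      "3'" = "NPF", "3''" = "NPF",
      "1'" = if (ann$repeat_index[i] == 1L) "DPI" else "",
      "")
  }
  lk
}

#' Write a synthetic family to disk
#'
#' Emits the alignment (FASTA), the ungapped sequences, the annotation TSV and
#' a truth TSV (per-column tier plus per-domain labels).
#'
#' @param family A `synth_family`.
#' @param dir Output directory (created if missing).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_family <- function(family, dir) {
  stopifnot(inherits(family, "synth_family"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(msa = file.path(dir, "family_msa.fasta"),
             fasta = file.path(dir, "family_seqs.fasta"),
             annotation = file.path(dir, "family_annotation.tsv"),
             truth_cols = file.path(dir, "family_truth_columns.tsv"),
             truth_domains = file.path(dir, "family_truth_domains.tsv"))
  write_msa(family$msa, paths["msa"])
  write_fasta(gsub("-", "", family$msa$rows, fixed = TRUE), paths["fasta"])
  write_annotation(family$annotation, paths["annotation"])
  utils::write.table(
    data.frame(column = seq_along(family$truth$column_tier),
               tier = family$truth$column_tier),
    paths["truth_cols"], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(domain_id = names(family$truth$domain_type),
               type = family$truth$domain_type,
               repeat_key = family$truth$domain_repeat,
               tandem_position = family$truth$domain_token,
               divergence_multiplier = family$truth$repeat_multiplier),
    paths["truth_domains"], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
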