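# End-to-end orchestration: (synthesize | load) -> similarity/embedding/
# clustering -> conservation profile -> removal + sham curves -> consensus
# threshold -> type tier -> position tier -> report, with a run manifest.

#' Pipeline configuration
#'
#' Exactly one of `synth` (a [synth_config()]) or `inputs` (list with paths
#' `msa`, `annotation`, and optionally `msa_dialect`) must be given.
#'
#' @param synth A `synth_config`, or `NULL`.
#' @param inputs List of input paths, or `NULL`.
#' @param matrix Substitution matrix name or file.
#' @param d Embedding dimension.
#' @param i_step Grid step of the removal curves; the default of 3
#'   aggregates removals into 3-column steps, which damps the Monte-Carlo
#'   noise of the sham baseline (set 1 for the full series).
#' @param sham_reps Random-removal replicates.
#' @param delta_tol Slope tolerance of the consensus threshold.
#' @param type_sop_cutoff SoP cutoff of the type tier.
#' @param position_criteria List `sop_min`, `occ_min`, `ident_min`.
#' @param seed Root seed; all stage randomness derives from it.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(synth = NULL, inputs = NULL,
                            matrix = "BLOSUM62", d = 3L, i_step = 3L,
                            sham_reps = 3L, delta_tol = 0,
                            type_sop_cutoff = 1,
                            position_criteria = list(sop_min = 1,
                                                     occ_min = 0.9,
                                                     ident_min = 0.7),
                            seed = 0L) {
  if (is.null(synth) == is.null(inputs))
    stop("exactly one of 'synth' or 'inputs' must be given")
  structure(list(synth = synth, inputs = inputs, matrix = matrix,
                 d = as.integer(d), i_step = as.integer(i_step),
                 sham_reps = as.integer(sham_reps), delta_tol = delta_tol,
                 type_sop_cutoff = type_sop_cutoff,
                 position_criteria = position_criteria,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# Map cluster labels to type letters. With truth available, clusters are
# relabelled by majority vote against the true types; otherwise clusters are
# lettered A, B, C... by size.
#' @noRd
clusters_to_types <- function(clusters, truth = NULL) {
  lab <- clusters$labels
  types <- rep(NA_character_, length(lab))
  names(types) <- names(lab)
  if (!is.null(truth)) {
    for (g in sort(unique(lab[!is.na(lab)]))) {
      ids <- names(lab)[!is.na(lab) & lab == g]
      tt <- table(truth$domain_type[ids])
      types[!is.na(lab) & lab == g] <- names(tt)[which.max(tt)]
    }
  } else {
    sizes <- sort(table(lab), decreasing = TRUE)
    letters_for <- stats::setNames(LETTERS[seq_along(sizes)], names(sizes))
    types[!is.na(lab)] <- letters_for[as.character(lab[!is.na(lab)])]
  }
  types
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order and (optionally) writes all tabular and JSON
#' artifacts plus a manifest to `out_dir`. With synthetic input, the manifest
#' additionally records recovery metrics against the generator truth
#' (clustering adjusted Rand index; precision/recall of the differential
#' consensus against the planted global columns).
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @return List of class `tandemmap_run` with `msa`, `annotation`, `sim`,
#'   `map`, `clusters`, `stats`, `profile`, `curves`, `consensus`, `tiers`,
#'   `report`, `linker_classes`, `manifest`.
#' @export
run_all <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  matrix <- load_substitution_matrix(config$matrix)

  # stage 1: inputs
  truth <- NULL
  if (!is.null(config$synth)) {
    fam <- generate_family(config$synth)
    msa <- fam$msa
    annotation <- fam$annotation
    truth <- fam$truth
  } else {
    msa <- read_msa(config$inputs$msa,
                    dialect = config$inputs$msa_dialect %||% "fasta")
    annotation <- read_annotation(config$inputs$annotation)
  }
  log_stage("inputs", sprintf("%d sequences x %d columns",
                              length(msa$ids), msa$n_cols))

  # stage 2: map + clusters
  sim <- build_similarity(msa, matrix, mode = "as_is")
  map <- embed(sim, d = config$d)
  clusters <- angular_clusters(map)
  stats_tab <- vector_stats(map, clusters = clusters)
  types <- clusters_to_types(clusters, truth)
  log_stage("map", sprintf("d = %d, k = %d clusters", config$d, clusters$k))

  # stage 3: conservation + differential consensus
  profile <- sop_profile(msa, matrix)
  order <- rank_positions(profile)
  order <- order[profile$sop[order] > 0]
  # keep enough residual columns for the derivative maps to stay defined
  order <- order[seq_len(min(length(order), floor(0.8 * msa$n_cols)))]
  ref_map <- map
  true_curve <- removal_curve(msa, order, matrix = matrix, d = config$d,
                              i_step = config$i_step, ref_map = ref_map)
  sham <- sham_curve(msa, profile, i_grid = true_curve$i,
                     reps = config$sham_reps, seed = config$seed + 1L,
                     matrix = matrix, d = config$d, ref_map = ref_map)
  consensus <- consensus_threshold(true_curve, sham, profile,
                                   delta_tol = config$delta_tol)
  log_stage("diffmap", sprintf("i_max = %d, cutoff = %.4g, %d consensus cols",
                               max(true_curve$i), consensus$sop_cutoff,
                               length(consensus$conserved_cols)))

  # stage 4: type tier
  type_cols <- list()
  for (ty in sort(unique(stats::na.omit(types)))) {
    ids <- names(types)[!is.na(types) & types == ty]
    if (length(ids) < 3L) next
    tmsa <- new_msa(ids, msa$rows[ids])
    type_cols[[ty]] <- type_consensus(tmsa, consensus$conserved_cols, matrix,
                                      sop_cutoff = config$type_sop_cutoff)
  }
  log_stage("type tier", paste(vapply(names(type_cols), function(ty)
    sprintf("%s: %d cols", ty, length(type_cols[[ty]])), character(1)),
    collapse = ", "))

  # stage 5: position tier over C2..C11
  ann_types <- stats::setNames(types[annotation$domain_id],
                               annotation$domain_id)
  pos_cons <- list()
  c_tokens <- unique(annotation$tandem_position[annotation$zone == "C"])
  for (token in c_tokens) {
    sel <- annotation$zone == "C" & annotation$repeat_index %in% 2:11 &
      annotation$tandem_position == token
    if (sum(sel) < 2L) next
    # mask the union of all type tiers so the three tiers stay disjoint
    tcols <- unique(unlist(type_cols, use.names = FALSE))
    pmsa <- position_msa(msa, annotation, token,
                         global_cols = consensus$conserved_cols,
                         type_cols = tcols)
    crit <- config$position_criteria
    pos_cons[[token]] <- position_specific_conserved(
      pmsa, token, matrix, sop_min = crit$sop_min, occ_min = crit$occ_min,
      ident_min = crit$ident_min)
  }
  tiers <- list(global = consensus$conserved_cols, type = type_cols,
                position = pos_cons)
  report <- consensus_report(msa, annotation, tiers)
  log_stage("position tier", sprintf("%d tokens, %d conserved cols total",
                                     length(pos_cons), nrow(report)))

  linker_classes <- data.frame(
    domain_id = annotation$domain_id,
    linker_seq = annotation$linker_seq,
    class = classify_linker(annotation$linker_seq))

  manifest <- list(
    params = config[setdiff(names(config), c("synth", "inputs"))],
    synthetic = !is.null(truth),
    n_sequences = length(msa$ids), n_cols = msa$n_cols,
    eigenvalues = map$eigenvalues, k = clusters$k,
    sop_cutoff = consensus$sop_cutoff,
    n_consensus_cols = length(consensus$conserved_cols),
    seeds = list(root = config$seed, sham = config$seed + 1L))
  if (!is.null(truth)) {
    lab <- clusters$labels
    ok <- !is.na(lab)
    manifest$ari <- mclust::adjustedRandIndex(lab[ok],
                                              truth$domain_type[names(lab)[ok]])
    planted <- which(truth$column_tier == "global")
    got <- consensus$conserved_cols
    manifest$consensus_precision <-
      if (length(got) > 0) mean(got %in% planted) else NA_real_
    manifest$consensus_recall <- mean(planted %in% got)
  }

  run <- structure(list(msa = msa, annotation = annotation, truth = truth,
                        sim = sim, map = map, clusters = clusters,
                        stats = stats_tab, profile = profile,
                        curves = list(true = true_curve, sham = sham),
                        consensus = consensus, tiers = tiers,
                        report = report, linker_classes = linker_classes,
                        manifest = manifest),
                   class = "tandemmap_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @noRd
log_stage <- function(stage, detail) {
  message(sprintf("[tandemmap] %-14s %s", stage, detail))
}

#' Write the artifacts of a pipeline run
#'
#' @param run A `tandemmap_run`.
#' @param out_dir Output directory (created if missing).
#' @return Character vector of written paths, invisibly.
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  wt <- function(df, f) utils::write.table(df, p(f), sep = "\t",
                                           quote = FALSE, row.names = FALSE)
  coords <- data.frame(id = run$map$ids, run$map$coords, row.names = NULL)
  wt(coords, "coordinates.tsv")
  wt(data.frame(dimension = seq_along(run$map$eigenvalues),
                eigenvalue = run$map$eigenvalues), "eigenvalues.tsv")
  wt(cbind(run$stats, label = run$clusters$labels[run$stats$id]),
     "clusters.tsv")
  wt(run$profile, "conservation_profile.tsv")
  curves <- rbind(cbind(run$curves$true, kind = "true"),
                  cbind(run$curves$sham, kind = "sham"))
  wt(curves, "removal_curves.tsv")
  wt(run$report, "position_consensus.tsv")
  wt(run$linker_classes, "linker_classes.tsv")
  jsonlite::write_json(
    list(sop_cutoff = run$consensus$sop_cutoff,
         conserved_cols = run$consensus$conserved_cols,
         n_removed = run$consensus$n_removed,
         tiers = list(global = run$tiers$global,
                      type = run$tiers$type,
                      position = lapply(run$tiers$position, function(x)
                        x$conserved$column))),
    p("consensus.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(run$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(list.files(out_dir, full.names = TRUE))
}
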