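# End-to-end orchestration: delineate -> profile -> scan -> classify ->
# topology -> origins, with publication-style TSV/JSON reports and a run
# manifest recording every parameter left open by defaults.

#' Run the full structural pipeline
#'
#' Executes all stages on a sequence set and writes the report bundle:
#' `partitions.tsv`, `classes.tsv`, `clade_classes.tsv`,
#' `profile_tm.tsv` (canonical per-position conservation),
#' `band_counts.tsv`, `cross_conservation.tsv` (conserved canonical
#' positions also conserved in each non-canonical clade),
#' `self_identity.tsv` (within-clade band counts per subgroup),
#' `motif_matrix.tsv`, `helices.tsv` (modal helix positions),
#' `origins.json` and `manifest.json`.  The run is deterministic:
#' identical inputs and parameters give byte-identical outputs.
#'
#' @param records A [pin_records] data.frame.
#' @param cmap A [clade_map].
#' @param tree Optional clade-level `phylo` (tips = clade names) for
#'   origin counting.
#' @param out_dir Output directory (created if needed).
#' @param motifs Motif library (default [default_motif_library]).
#' @param consensus HC consensus (default derived from `motifs`).
#' @param exclude_clades Clades pruned before origin counting.
#' @param max_subs,min_coverage,reversals Stage parameters (see
#'   [delineate], [band_counts], [min_origins]).
#' @return Invisibly, a list with the in-memory results of every stage.
#' @export
run_pin_pipeline <- function(records, cmap, tree = NULL, out_dir,
                             motifs = default_motif_library(),
                             consensus = hc_consensus_from_library(motifs),
                             exclude_clades = character(),
                             max_subs = 3L, min_coverage = 10L,
                             reversals = "none") {
  stopifnot(inherits(records, "pin_records"), inherits(cmap, "pin_clade_map"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, name) utils::write.table(
    x, file.path(out_dir, name), sep = "\t", quote = FALSE,
    row.names = FALSE)

  # 1. delineation
  partitions <- delineate_all(records, max_subs = max_subs)
  ptab <- partition_table(partitions)
  tsv(ptab, "partitions.tsv")

  # 2. protein classification
  classes <- classify_all(partitions, consensus)
  tsv(classes, "classes.tsv")

  # 3. clade classification
  clades <- sort(unique(cmap$sequence_to_clade))
  clade_label <- vapply(clades, function(cd) {
    ids <- names(cmap$sequence_to_clade)[cmap$sequence_to_clade == cd]
    classify_clade(classes$label[classes$id %in% ids])
  }, "")
  clade_tab <- data.frame(
    clade = clades,
    n = as.integer(table(cmap$sequence_to_clade)[clades]),
    n_canonical = vapply(clades, function(cd) {
      ids <- names(cmap$sequence_to_clade)[cmap$sequence_to_clade == cd]
      sum(classes$label[classes$id %in% ids] == "canonical")
    }, 0L),
    label = clade_label, stringsAsFactors = FALSE)
  tsv(clade_tab, "clade_classes.tsv")

  # 4. canonical conservation profile over members of canonical clades
  canon_ids <- names(cmap$sequence_to_clade)[
    cmap$sequence_to_clade %in% clades[clade_label == "canonical"]]
  canon_parts <- partitions[names(partitions) %in% canon_ids]
  profile <- combine_profiles(build_profile(canon_parts, "n_domain"),
                              build_profile(canon_parts, "c_domain"))
  ptm <- as.data.frame(profile)
  ptm$consensus <- strsplit(consensus_string <- consensus(profile), "")[[1]]
  tsv(ptm, "profile_tm.tsv")
  bc <- band_counts(profile, band_scheme("self"), min_coverage)
  tsv(bc, "band_counts.tsv")

  # 5. conserved canonical positions retained in noncanonical clades
  cross_scheme <- band_scheme("cross")
  bands <- band_of(profile$modal_identity, cross_scheme)
  covered <- profile$coverage >= min_coverage
  ref_sets <- lapply(cross_scheme$label, function(lb)
    profile$positions[covered & !is.na(bands) & bands == lb])
  names(ref_sets) <- cross_scheme$label
  nc_clades <- clades[clade_label == "noncanonical"]
  cross <- NULL
  per_clade_profile <- function(cd) {
    ids <- names(cmap$sequence_to_clade)[cmap$sequence_to_clade == cd]
    pp <- partitions[names(partitions) %in% ids]
    combine_profiles(build_profile(pp, "n_domain"),
                     build_profile(pp, "c_domain"))
  }
  for (cd in nc_clades) {
    qp <- per_clade_profile(cd)
    cnt <- cross_conservation(ref_sets, qp, threshold = 0.90,
                              min_coverage = min_coverage)
    cross <- rbind(cross, data.frame(clade = cd, band = names(cnt),
                                     n_reference = lengths(ref_sets),
                                     n_conserved = as.integer(cnt),
                                     stringsAsFactors = FALSE))
  }
  if (!is.null(cross)) tsv(cross, "cross_conservation.tsv")

  # 6. within-clade self-identity band counts per subgroup
  self_tab <- NULL
  for (cd in clades) {
    ids <- names(cmap$sequence_to_clade)[cmap$sequence_to_clade == cd]
    if (length(ids) < min_coverage) next
    qp <- per_clade_profile(cd)
    sc <- band_counts(qp, band_scheme("self"), min_coverage)
    self_tab <- rbind(self_tab,
                      data.frame(clade = cd, label = sc$label,
                                 count = sc$count, n = length(ids),
                                 stringsAsFactors = FALSE))
  }
  if (!is.null(self_tab)) tsv(self_tab, "self_identity.tsv")

  # 7. loop motif matrix
  scans <- list()
  for (p in partitions) {
    if (is.na(p$loop) || !nzchar(p$loop)) next
    scans[[p$id]] <- scan_loop(p$loop, motifs)
  }
  mm <- if (length(scans)) motif_matrix(scans, cmap) else NULL
  if (!is.null(mm))
    utils::write.table(data.frame(clade = rownames(mm), mm,
                                  check.names = FALSE),
                       file.path(out_dir, "motif_matrix.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  # 8. helix topology on sequences with both domains
  helix_preds <- list()
  for (p in partitions) {
    if (is.na(p$n_domain) || is.na(p$c_domain)) next
    if (nchar(p$n_domain) < 19 || nchar(p$c_domain) < 19) next
    helix_preds[[p$id]] <- protein_helices(p)
  }
  modal <- if (length(helix_preds) >= 3)
    modal_helix_positions(helix_preds) else NULL
  if (!is.null(modal)) tsv(modal, "helices.tsv")

  # 9. origins on the clade tree
  origins <- NULL
  if (!is.null(tree)) {
    states <- structural_states(clade_label)
    usable <- names(states)[!is.na(states)]
    prune <- union(setdiff(tree$tip.label, usable), exclude_clades)
    origins <- min_origins(tree, states, reversals = reversals,
                           exclude = intersect(prune, tree$tip.label))
    jsonlite::write_json(
      list(origins = origins$origins, changes = origins$changes,
           reversals = reversals,
           labeling = as.list(origins$labeling)),
      file.path(out_dir, "origins.json"), auto_unbox = TRUE)
  }

  manifest <- list(
    package = "pinarch",
    version = as.character(utils::packageVersion("pinarch")),
    n_sequences = nrow(records),
    parameters = list(max_subs = max_subs, min_coverage = min_coverage,
                      reversals = reversals,
                      exclude_clades = exclude_clades,
                      present_min = 0.70, divergent_sim = 0.40,
                      identity_min = 0.50, similarity_min = 0.70,
                      hydropathy = list(window = 19, start_cutoff = 1.6,
                                        floor = 0.5, step = 0.1,
                                        min_run = 7, min_gap = 3),
                      semicanonical_counted_noncanonical = TRUE),
    input_checksum = digest_records(records))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(partitions = partitions, classes = classes,
                 clade_classes = clade_tab, profile = profile,
                 band_counts = bc, cross_conservation = cross,
                 self_identity = self_tab, motif_matrix = mm,
                 helices = helix_preds, modal_helices = modal,
                 origins = origins, manifest = manifest))
}

# Stable checksum of a record set (md5 of the serialized id/residue text).
digest_records <- function(records) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(records$id, records$residues, sep = "\t"), tmp)
  unname(tools::md5sum(tmp))
}
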