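# Per-position conservation profiles, consensus, identity bands and
# alignment statistics on canonical coordinates.

#' Build a per-position conservation profile
#'
#' For each canonical position of the chosen region, residue frequencies
#' are computed over the sequences that observe that position (`X` and
#' missing residues are excluded from the denominator; insertion-labelled
#' residues never contribute to canonical positions).  Loop profiles use
#' loop-relative positions L1, L2, ...
#'
#' @param partitions A list of `pin_partition` objects (see
#'   [delineate_all]).
#' @param region One of `"n_domain"`, `"c_domain"`, `"loop"`.
#' @return An object of class `pin_profile`: list with `region`,
#'   `positions` (ordered labels), `freq` (positions x 20 residue
#'   frequency matrix; rows sum to 1 where covered), `coverage`,
#'   `modal_residue`, `modal_identity`.
#' @export
build_profile <- function(partitions,
                          region = c("n_domain", "c_domain", "loop")) {
  region <- match.arg(region)
  positions <- switch(region,
    n_domain = canonical_positions("n_domain"),
    c_domain = canonical_positions("c_domain"),
    loop = NULL)
  if (is.null(positions)) {  # loop region: size to the longest loop
    maxlen <- max(c(0L, vapply(partitions, function(p)
      if (is.na(p$loop)) 0L else nchar(p$loop), 0L)))
    if (maxlen == 0L) fail("no observations: no partition has a loop")
    positions <- paste0("L", seq_len(maxlen))
  }
  n_obs <- 0L
  lab_all <- res_all <- vector("list", length(partitions))
  for (k in seq_along(partitions)) {
    p <- partitions[[k]]
    part <- p[[if (region == "loop") "loop" else region]]
    if (is.na(part)) next
    n_obs <- n_obs + 1L
    res <- strsplit(part, "")[[1]]
    labels <- switch(region,
      n_domain = p$n_coord_map,
      c_domain = p$c_coord_map,
      loop = paste0("L", seq_along(res)))
    keep <- !is.na(labels) & labels %in% positions & res %in% AA20
    lab_all[[k]] <- labels[keep]
    res_all[[k]] <- res[keep]
  }
  if (n_obs == 0L) fail("no observations: region %s absent in all inputs",
                        region)
  counts <- unclass(table(
    factor(unlist(lab_all), levels = positions),
    factor(unlist(res_all), levels = AA20)))
  coverage <- unname(rowSums(counts))
  freq <- counts / ifelse(coverage > 0, coverage, 1)
  modal_i <- max.col(freq, ties.method = "first")
  structure(list(
    region = region,
    positions = positions,
    freq = freq,
    coverage = as.integer(coverage),
    modal_residue = ifelse(coverage > 0, AA20[modal_i], NA_character_),
    modal_identity = ifelse(coverage > 0, freq[cbind(seq_along(modal_i),
                                                     modal_i)], NA_real_)),
    class = "pin_profile")
}

#' @export
as.data.frame.pin_profile <- function(x, ...) {
  data.frame(position = x$positions, coverage = x$coverage,
             modal_residue = x$modal_residue,
             modal_identity = x$modal_identity,
             stringsAsFactors = FALSE)
}

#' Combine N- and C-domain profiles
#'
#' Concatenates two profiles into one spanning all 312 canonical
#' transmembrane positions (N1..N158, C1..C154).
#'
#' @param n_profile,c_profile `pin_profile` objects for the two domains.
#' @return A `pin_profile` with region `"tm"`.
#' @export
combine_profiles <- function(n_profile, c_profile) {
  stopifnot(inherits(n_profile, "pin_profile"),
            inherits(c_profile, "pin_profile"))
  structure(list(
    region = "tm",
    positions = c(n_profile$positions, c_profile$positions),
    freq = rbind(n_profile$freq, c_profile$freq),
    coverage = c(n_profile$coverage, c_profile$coverage),
    modal_residue = c(n_profile$modal_residue, c_profile$modal_residue),
    modal_identity = c(n_profile$modal_identity, c_profile$modal_identity)),
    class = "pin_profile")
}

#' Consensus sequence of a profile
#'
#' @param profile A `pin_profile`.
#' @param floor Minimum modal identity; positions below it (or with no
#'   coverage) print `.`.
#' @return A single residue string, one character per position.
#' @export
consensus <- function(profile, floor = 0.5) {
  stopifnot(inherits(profile, "pin_profile"))
  ok <- !is.na(profile$modal_identity) & profile$modal_identity >= floor
  paste(ifelse(ok, profile$modal_residue, "."), collapse = "")
}

#' Count profile positions per identity band
#'
#' Positions with coverage below `min_coverage` are excluded from the
#' band counts and reported in the `"insufficient"` attribute (EST-heavy
#' data sets leave many positions thinly covered).
#'
#' @param profile A `pin_profile`.
#' @param scheme A [band_scheme].
#' @param min_coverage Minimum sequences covering a position (default 10).
#' @return data.frame with columns `label`, `count`; counts over the
#'   sufficiently covered positions partition them.  Attribute
#'   `insufficient` holds the number of excluded positions.
#' @export
band_counts <- function(profile, scheme = band_scheme("self"),
                        min_coverage = 10L) {
  stopifnot(inherits(profile, "pin_profile"))
  ok <- profile$coverage >= min_coverage
  bands <- band_of(profile$modal_identity[ok], scheme)
  out <- as.data.frame(table(bands), stringsAsFactors = FALSE)
  names(out) <- c("label", "count")
  attr(out, "insufficient") <- sum(!ok)
  out
}

#' Positions conserved above a threshold
#'
#' @param profile A `pin_profile`.
#' @param threshold Identity bound; positions with modal identity
#'   strictly above it are returned (default 0.90, the ">90% identity"
#'   convention).
#' @param min_coverage Minimum coverage (default 10).
#' @return Character vector of position labels.
#' @export
conserved_positions <- function(profile, threshold = 0.90,
                                min_coverage = 10L) {
  stopifnot(inherits(profile, "pin_profile"))
  ok <- profile$coverage >= min_coverage &
    !is.na(profile$modal_identity) & profile$modal_identity > threshold
  profile$positions[ok]
}

#' Cross-conservation of reference positions in a query profile
#'
#' Counts how many positions of a reference set (e.g. the positions
#' conserved in canonical proteins, by band) are also conserved above
#' `threshold` in a query group's profile.
#'
#' @param reference_positions Character vector of canonical position
#'   labels, or a named list of such vectors (one per reference band).
#' @param query_profile A `pin_profile` on the same coordinate system.
#' @param threshold Identity bound (strictly above; default 0.90).
#' @param min_coverage Minimum query coverage for a position to count
#'   (default 1).
#' @return An integer count, or a named integer vector when
#'   `reference_positions` is a list.
#' @export
cross_conservation <- function(reference_positions, query_profile,
                               threshold = 0.90, min_coverage = 1L) {
  stopifnot(inherits(query_profile, "pin_profile"))
  one <- function(ref) {
    if (!all(ref %in% query_profile$positions))
      fail("coordinate mismatch: position %s not in query profile",
           setdiff(ref, query_profile$positions)[1])
    i <- match(ref, query_profile$positions)
    sum(query_profile$coverage[i] >= min_coverage &
          !is.na(query_profile$modal_identity[i]) &
          query_profile$modal_identity[i] > threshold)
  }
  if (is.list(reference_positions))
    vapply(reference_positions, one, 0L)
  else one(reference_positions)
}

#' Alignment statistics
#'
#' A column is parsimony-informative iff at least two distinct
#' non-missing states each occur in at least two rows.  `-` and `?`
#' both count as missing.
#'
#' @param aln A `pin_alignment` matrix (see [read_alignment]).
#' @return List with `n_rows`, `n_cols`, `parsimony_informative`,
#'   `missing_fraction`.
#' @export
alignment_stats <- function(aln) {
  stopifnot(inherits(aln, "pin_alignment"))
  miss <- aln %in% MISSING_CHARS
  dim(miss) <- dim(aln)
  informative <- vapply(seq_len(ncol(aln)), function(j) {
    tb <- table(aln[!miss[, j], j])
    sum(tb >= 2) >= 2
  }, TRUE)
  list(n_rows = nrow(aln), n_cols = ncol(aln),
       parsimony_informative = sum(informative),
       missing_fraction = mean(miss))
}
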