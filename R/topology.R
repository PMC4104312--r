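# Transmembrane helix detection from smoothed hydropathy, with cryptic
# peak recovery: when fewer than the expected number of peaks clear the
# primary cutoff, the cutoff is relaxed stepwise until the expected
# count is reached (or the floor is hit); helices that only appear below
# the primary cutoff are flagged cryptic.

#' Smoothed hydropathy profile
#'
#' Centred moving average of the Kyte-Doolittle residue hydropathy over
#' an odd window.  Ends are truncated: the first and last
#' `(window-1)/2` positions carry `NA` (no padding is invented).
#'
#' @param seq Residue string.
#' @param window Odd integer >= 7, at most the sequence length
#'   (default 19, the classic transmembrane window).
#' @param scale Named hydropathy scale (default [kyte_doolittle]).
#' @return Numeric vector, one score per residue (`NA` at the flanks).
#' @export
hydropathy_profile <- function(seq, window = 19L,
                               scale = kyte_doolittle()) {
  L <- nchar(seq)
  if (window %% 2 == 0 || window < 7) fail("window must be odd and >= 7")
  if (L < window) fail("sequence (%d) shorter than window (%d)", L, window)
  chars <- strsplit(seq, "")[[1]]
  vals <- scale[chars]
  if (anyNA(vals)) fail("residue without a hydropathy value: %s",
                        chars[is.na(vals)][1])
  as.numeric(stats::filter(vals, rep(1 / window, window), sides = 2))
}

# Maximal runs of profile >= cutoff (NA counts as below); runs separated
# by fewer than min_gap below-cutoff positions are merged; runs shorter
# than min_run are dropped.  Returns data.frame(start, end, height).
find_peaks <- function(profile, cutoff, min_run = 7L, min_gap = 3L) {
  above <- !is.na(profile) & profile >= cutoff
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  if (nrow(runs) > 1) {  # merge across short dips
    keep <- TRUE
    merged <- runs[1, , drop = FALSE]
    for (i in 2:nrow(runs)) {
      if (runs$start[i] - merged$end[nrow(merged)] - 1L < min_gap)
        merged$end[nrow(merged)] <- runs$end[i]
      else merged <- rbind(merged, runs[i, ])
    }
    runs <- merged
  }
  runs <- runs[runs$end - runs$start + 1L >= min_run, , drop = FALSE]
  if (nrow(runs) == 0)
    return(data.frame(start = integer(), end = integer(),
                      height = numeric()))
  runs$height <- vapply(seq_len(nrow(runs)), function(i)
    max(profile[runs$start[i]:runs$end[i]], na.rm = TRUE), 0)
  runs
}

#' Detect transmembrane helices in one domain
#'
#' Peaks are maximal runs of at least `min_run` residues whose smoothed
#' hydropathy clears the cutoff (runs separated by fewer than `min_gap`
#' residues merge).  Starting from `start_cutoff`, the cutoff is lowered
#' by `step` until `expected` peaks are found or `floor` is reached;
#' peaks absent at the primary cutoff are flagged `cryptic`.  With more
#' peaks than expected, the `expected` highest are kept.
#'
#' @param profile Output of [hydropathy_profile] for one domain.
#' @param expected Expected helix count (default 5 per transmembrane
#'   domain; ten per protein).
#' @param start_cutoff,floor,step Cutoff schedule (defaults 1.6, 0.5,
#'   0.1).
#' @param min_run,min_gap Run constraints (defaults 7, 3).
#' @return data.frame of class `pin_helices`: `helix`, `start`, `end`,
#'   `height`, `method` (`"primary"`/`"cryptic"`); attributes
#'   `cutoff_used` and `floor_reached`.
#' @export
detect_helices <- function(profile, expected = 5L, start_cutoff = 1.6,
                           floor = 0.5, step = 0.1, min_run = 7L,
                           min_gap = 3L) {
  if (expected < 1) fail("expected must be >= 1")
  primary <- find_peaks(profile, start_cutoff, min_run, min_gap)
  cutoff <- start_cutoff
  peaks <- primary
  floor_reached <- FALSE
  while (nrow(peaks) < expected) {
    if (cutoff - step < floor - 1e-9) { floor_reached <- TRUE; break }
    cutoff <- cutoff - step
    peaks <- find_peaks(profile, cutoff, min_run, min_gap)
  }
  if (nrow(peaks) > expected)
    peaks <- peaks[order(-peaks$height, peaks$start), ][seq_len(expected), ]
  peaks <- peaks[order(peaks$start), , drop = FALSE]
  # a peak is primary if it overlaps a peak found at the start cutoff
  is_primary <- vapply(seq_len(nrow(peaks)), function(i)
    any(peaks$start[i] <= primary$end & peaks$end[i] >= primary$start),
    TRUE)
  out <- data.frame(helix = seq_len(nrow(peaks)),
                    start = peaks$start, end = peaks$end,
                    height = peaks$height,
                    method = ifelse(is_primary, "primary", "cryptic"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("pin_helices", "data.frame")
  attr(out, "cutoff_used") <- cutoff
  attr(out, "floor_reached") <- floor_reached
  out
}

#' Detect the ten helices of a delineated protein
#'
#' Runs [detect_helices] on the N- and C-domain of a partition and
#' offsets C-domain intervals into canonical C coordinates.
#'
#' @param partition A `pin_partition` with both domains present.
#' @param expected_per_domain Default 5.
#' @param ... Passed to [detect_helices].
#' @return data.frame: `helix` (1..10), `domain`, `start`, `end`
#'   (1-based within the domain), `height`, `method`.
#' @export
protein_helices <- function(partition, expected_per_domain = 5L, ...) {
  stopifnot(inherits(partition, "pin_partition"))
  if (is.na(partition$n_domain) || is.na(partition$c_domain))
    fail("both domains required (sequence %s)", partition$id)
  hn <- detect_helices(hydropathy_profile(partition$n_domain),
                       expected = expected_per_domain, ...)
  hc <- detect_helices(hydropathy_profile(partition$c_domain),
                       expected = expected_per_domain, ...)
  rbind(
    data.frame(helix = hn$helix, domain = rep("n_domain", nrow(hn)),
               start = hn$start, end = hn$end, height = hn$height,
               method = hn$method, stringsAsFactors = FALSE),
    data.frame(helix = expected_per_domain + hc$helix,
               domain = rep("c_domain", nrow(hc)),
               start = hc$start, end = hc$end, height = hc$height,
               method = hc$method, stringsAsFactors = FALSE))
}

# Smallest mode of an integer vector.
mode_int <- function(x) {
  ux <- sort(unique(x))
  ux[which.max(tabulate(match(x, ux)))]
}

#' Modal helix positions across sequences
#'
#' Aggregates per-sequence helix predictions (all on the same domain
#' coordinate system) to the modal start and end per helix index.
#' Sequences whose helix count differs from the modal count are dropped
#' with a warning.
#'
#' @param predictions List of `pin_helices` (or [protein_helices])
#'   data.frames; at least 3.
#' @return data.frame: `helix`, `start`, `end` (modal, ties to the
#'   smaller coordinate), `coverage` (sequences contributing).
#' @export
modal_helix_positions <- function(predictions) {
  if (length(predictions) < 3) fail("need at least 3 predictions")
  counts <- vapply(predictions, nrow, 0L)
  modal_n <- mode_int(counts)
  if (any(counts != modal_n)) {
    warning(sum(counts != modal_n),
            " prediction(s) without the modal helix count dropped")
    predictions <- predictions[counts == modal_n]
  }
  do.call(rbind, lapply(seq_len(modal_n), function(h) {
    data.frame(
      helix = h,
      start = mode_int(vapply(predictions, function(p) p$start[h], 0L)),
      end = mode_int(vapply(predictions, function(p) p$end[h], 0L)),
      coverage = length(predictions))
  }))
}
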