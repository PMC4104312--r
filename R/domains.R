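# Domain delineation by anchor motifs.
#
# The two transmembrane domains of a PIN protein run from the initiator
# to the end of the FLFEFRAAR anchor (N-domain, canonically N1..N158)
# and from the start of the VWRKLIRN anchor to the stop (C-domain,
# canonically C1..C154), with the intracellular loop in between.  All
# coordinates here are 1-based inclusive R indices.

#' Locate an anchor motif in a sequence
#'
#' Scans every window of the motif's length and returns the window with
#' the fewest substitutions (`X` in the motif matches any residue and is
#' not counted).  Ties are broken in favour of the window whose start is
#' nearest `expect_start`; remaining ties take the leftmost window.
#'
#' @param seq A residue string.
#' @param motif Residue pattern (may contain `X` wildcards), length >= 6.
#' @param max_subs Maximum substitutions allowed (must be < half the
#'   motif length).  Default 3.
#' @param expect_start Expected 1-based start of the anchor, used only
#'   to break ties.  `NULL` means leftmost wins.
#' @return A list with `start`, `end` (1-based inclusive) and
#'   `substitutions`, or `NULL` when no window passes `max_subs` (a
#'   sequence shorter than the motif also returns `NULL`).
#' @export
#' @examples
#' find_anchor("AAAFLFEFRAARGG", "FLFEFRAAR")$start  # 4
find_anchor <- function(seq, motif, max_subs = 3L, expect_start = NULL) {
  m <- nchar(motif); L <- nchar(seq)
  if (m < 6) fail("anchor motif must be at least 6 residues")
  if (max_subs >= m / 2) fail("max_subs must be below half the motif length")
  if (L < m) return(NULL)
  sq <- strsplit(seq, "")[[1]]
  mt <- strsplit(motif, "")[[1]]
  informative <- which(mt != "X")
  n_win <- L - m + 1L
  subs <- integer(n_win)
  for (j in informative)
    subs <- subs + (sq[j:(j + n_win - 1L)] != mt[j])
  best <- min(subs)
  if (best > max_subs) return(NULL)
  cand <- which(subs == best)
  if (!is.null(expect_start) && length(cand) > 1)
    cand <- cand[order(abs(cand - expect_start), cand)]
  s <- cand[1]
  list(start = s, end = s + m - 1L, substitutions = best)
}

#' Split a sequence into N-domain, loop and C-domain
#'
#' The N-domain includes its anchor (so a complete canonical N-domain is
#' 158 residues, ending with the anchor); the C-domain starts at its
#' anchor (154 residues).  The loop is everything strictly in between.
#' Canonical coordinate labels are attached per residue: N1..N158
#' counting from the initiator (sequences without a complete N-terminus
#' are instead counted backwards from the anchor, which is pinned at
#' N158), with surplus residues of long N-domains labelled as insertions
#' between N97 and N98; C labels count forwards from the anchor (C1).
#'
#' @param record One row of a [pin_records] data.frame (or the whole
#'   data.frame with one row).
#' @param n_anchor,c_anchor Anchor motifs; defaults are the canonical
#'   anchors.
#' @param max_subs Maximum substitutions per anchor (default 3).
#' @param insertion_max N-domain insertions longer than this set the
#'   `atypical_n` flag (default 18, the longest observed insertion).
#' @return An object of class `pin_partition`: a list with `id`,
#'   `n_domain`, `loop`, `c_domain` (character or `NA` when absent),
#'   `n_coord_map`, `c_coord_map` (character vectors of per-residue
#'   labels), `flags` (named logical: `n_partial`, `c_partial`,
#'   `no_n_anchor`, `no_c_anchor`, `atypical_n`), `anchor_subs_n`,
#'   `anchor_subs_c` and `seq` (the input residues).
#' @export
delineate <- function(record, n_anchor = N_ANCHOR, c_anchor = C_ANCHOR,
                      max_subs = 3L, insertion_max = 18L) {
  if (is.data.frame(record)) {
    stopifnot(nrow(record) == 1)
    record <- as.list(record)
  }
  seq <- record$residues
  L <- nchar(seq)
  n_hit <- find_anchor(seq, n_anchor, max_subs,
                       expect_start = N_DOMAIN_LEN - nchar(n_anchor) + 1L)
  c_hit <- find_anchor(seq, c_anchor, max_subs,
                       expect_start = L - C_DOMAIN_LEN + 1L)
  flags <- c(n_partial = !isTRUE(record$n_complete),
             c_partial = !isTRUE(record$c_complete),
             no_n_anchor = is.null(n_hit),
             no_c_anchor = is.null(c_hit),
             atypical_n = FALSE)
  # A C-anchor at or before the N-anchor signals a non-PIN or scrambled
  # input: reject both.
  if (!is.null(n_hit) && !is.null(c_hit) && c_hit$start <= n_hit$end) {
    n_hit <- c_hit <- NULL
    flags["no_n_anchor"] <- flags["no_c_anchor"] <- TRUE
  }
  n_dom <- loop <- c_dom <- NA_character_
  n_map <- c_map <- character()
  if (!is.null(n_hit)) {
    n_dom <- substr(seq, 1L, n_hit$end)
    n_len <- n_hit$end
    if (flags["n_partial"] || n_len < N_DOMAIN_LEN) {
      # count backwards from the anchor end, pinned at N158
      idx <- N_DOMAIN_LEN - n_len + seq_len(n_len)
      n_map <- ifelse(idx >= 1, paste0("N", idx), NA_character_)
    } else if (n_len == N_DOMAIN_LEN) {
      n_map <- paste0("N", seq_len(n_len))
    } else {
      k <- n_len - N_DOMAIN_LEN
      if (k > insertion_max) flags["atypical_n"] <- TRUE
      n_map <- c(paste0("N", seq_len(N_INSERTION_AFTER)),
                 paste0("N", N_INSERTION_AFTER, "+", seq_len(k)),
                 paste0("N", (N_INSERTION_AFTER + 1L):N_DOMAIN_LEN))
    }
  }
  if (!is.null(c_hit)) {
    c_dom <- substr(seq, c_hit$start, L)
    c_map <- paste0("C", seq_len(nchar(c_dom)))
  }
  if (!is.null(n_hit) && !is.null(c_hit))
    loop <- substr(seq, n_hit$end + 1L, c_hit$start - 1L)
  structure(list(
    id = record$id,
    n_domain = n_dom, loop = loop, c_domain = c_dom,
    n_coord_map = n_map, c_coord_map = c_map,
    flags = flags,
    anchor_subs_n = if (is.null(n_hit)) NA_integer_ else n_hit$substitutions,
    anchor_subs_c = if (is.null(c_hit)) NA_integer_ else c_hit$substitutions,
    seq = seq), class = "pin_partition")
}

#' Delineate every sequence in a record set
#'
#' @param records A [pin_records] data.frame.
#' @param ... Passed to [delineate].
#' @return A named list of `pin_partition` objects (names = ids).
#' @export
delineate_all <- function(records, ...) {
  stopifnot(inherits(records, "pin_records"))
  out <- lapply(seq_len(nrow(records)), function(i)
    delineate(records[i, ], ...))
  names(out) <- records$id
  out
}

#' Summarise partitions as a table
#'
#' @param partitions List of `pin_partition` objects.
#' @return data.frame with columns `id`, `n_len`, `loop_len`, `c_len`,
#'   `flags` (comma-separated set flags), `anchor_subs_n`,
#'   `anchor_subs_c`, `loop_class`.
#' @export
partition_table <- function(partitions) {
  len0 <- function(x) if (is.na(x)) NA_integer_ else nchar(x)
  data.frame(
    id = vapply(partitions, `[[`, "", "id"),
    n_len = vapply(partitions, function(p) len0(p$n_domain), 0L),
    loop_len = vapply(partitions, function(p) len0(p$loop), 0L),
    c_len = vapply(partitions, function(p) len0(p$c_domain), 0L),
    flags = vapply(partitions, function(p)
      paste(names(p$flags)[p$flags], collapse = ","), ""),
    anchor_subs_n = vapply(partitions, `[[`, 0L, "anchor_subs_n"),
    anchor_subs_c = vapply(partitions, `[[`, 0L, "anchor_subs_c"),
    loop_class = vapply(partitions, loop_length_class, ""),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify a loop by length
#'
#' Short loops (the noncanonical range) are at most 120 residues; long
#' loops (canonical) exceed 150; lengths in (120, 150] are
#' intermediate.  The class is `unknown` when the loop is absent or
#' either flanking anchor was not found.  The canonical observed short
#' range is 32-120 residues; anything at or below 120 is reported
#' short.
#'
#' @param partition A `pin_partition`.
#' @return One of `"short"`, `"long"`, `"intermediate"`, `"unknown"`.
#' @export
loop_length_class <- function(partition) {
  stopifnot(inherits(partition, "pin_partition"))
  if (is.na(partition$loop) ||
      partition$flags[["no_n_anchor"]] || partition$flags[["no_c_anchor"]])
    return("unknown")
  len <- nchar(partition$loop)
  if (len > 150) "long" else if (len > 120) "intermediate" else "short"
}
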