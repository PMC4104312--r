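# Canonical / semicanonical / noncanonical classification.
#
# A protein is canonical when its loop matches the consensus of the four
# highly conserved regions HC1-HC4 with at least 50% identity or 70%
# similarity (pooled over the four regions, all regions located).
# Clades are canonical when 90% of their members are (clear majority in
# clades with fewer than ten members).

#' HC1-HC4 consensus regions
#'
#' Builds the four-region consensus either from explicit strings or from
#' the `hc_group` column of a motif library (patterns of each group
#' concatenated in rank order).
#'
#' @param HC1,HC2,HC3,HC4 Residue patterns (wildcard `X`, `[SN]`-style
#'   alternatives allowed), each at least 8 columns.
#' @return Named list of class `pin_hc_consensus`.
#' @export
hc_consensus <- function(HC1, HC2, HC3, HC4) {
  cons <- list(HC1 = HC1, HC2 = HC2, HC3 = HC3, HC4 = HC4)
  ncols <- vapply(cons, function(p) length(parse_pattern(p)), 0L)
  if (any(ncols < 8)) fail("HC consensus regions must be >= 8 columns")
  structure(cons, class = "pin_hc_consensus")
}

#' @rdname hc_consensus
#' @param library A `pin_motif_library` with `hc_group` assignments
#'   covering HC1..HC4.
#' @export
hc_consensus_from_library <- function(library) {
  stopifnot(inherits(library, "pin_motif_library"))
  grp <- function(g) {
    pats <- library$pattern[!is.na(library$hc_group) & library$hc_group == g]
    if (!length(pats)) fail("motif library has no %s motifs", g)
    paste(pats, collapse = "")
  }
  hc_consensus(grp("HC1"), grp("HC2"), grp("HC3"), grp("HC4"))
}

#' Score a loop against the HC1-HC4 consensus
#'
#' Each region is placed at its best gapless window subject to the
#' HC1 < HC2 < HC3 < HC4 order (maximum-weight increasing assignment);
#' pooled identity is matched identical columns over all consensus
#' columns (wildcards excluded), similarity additionally accepts
#' positive BLOSUM62 substitutions.  A region is located when its window
#' identity reaches `locate_min`.
#'
#' @param loop Residue string.
#' @param consensus A [hc_consensus].
#' @param locate_min Identity needed to call a region located
#'   (default 0.50: a region counts as located when at least half of
#'   its consensus columns match).
#' @return List: `identity`, `similarity` (pooled), `regions_located`
#'   (character subset of HC1..HC4), `per_region` (data.frame `region`,
#'   `start`, `identity`, `similarity`, `located`), `loop_len`,
#'   `total_cols`.
#' @export
hc_score <- function(loop, consensus, locate_min = 0.50) {
  stopifnot(inherits(consensus, "pin_hc_consensus"))
  if (is.na(loop) || !nzchar(loop)) fail("loop must be nonempty")
  chars <- strsplit(loop, "")[[1]]
  L <- length(chars)
  cols_list <- lapply(unclass(consensus), parse_pattern)
  lens <- vapply(cols_list, length, 0L)
  n_inf <- vapply(cols_list, function(cl)
    sum(!vapply(cl, is.null, TRUE)), 0L)
  score_list <- lapply(cols_list, function(cl) window_scores(chars, cl))
  starts <- assign_windows(score_list, lens, L)
  id_r <- sim_r <- numeric(4)
  for (k in 1:4) {
    if (!is.na(starts[k])) {
      row <- score_list[[k]][score_list[[k]]$start == starts[k], ]
      id_r[k] <- row$identity; sim_r[k] <- row$similarity
    }
  }
  located <- !is.na(starts) & id_r >= locate_min
  per_region <- data.frame(region = names(consensus), start = starts,
                           identity = id_r, similarity = sim_r,
                           located = located, stringsAsFactors = FALSE)
  list(identity = sum(id_r * n_inf) / sum(n_inf),
       similarity = sum(sim_r * n_inf) / sum(n_inf),
       regions_located = names(consensus)[located],
       per_region = per_region,
       loop_len = L, total_cols = sum(lens))
}

#' Classify one protein from its HC scores
#'
#' Canonical: all four regions located and pooled identity >=
#' `identity_min` (default 0.50) or pooled similarity >= `similarity_min`
#' (default 0.70).  Semicanonical: at least two regions located and
#' passing the same thresholds per region, with at least one region
#' unlocated or failing (loops that keep homology to the canonical
#' template but lack at least one HC region).  Otherwise noncanonical.
#' `insufficient_data` when under half of the pooled consensus columns
#' are observable in the loop.
#'
#' @param scores Output of [hc_score] (or `NULL` for a sequence with no
#'   delineated loop).
#' @param identity_min,similarity_min Pooled thresholds (0.50 / 0.70).
#' @param strict_regions If `TRUE`, canonical additionally requires every
#'   region to pass the thresholds individually.
#' @param id Optional sequence id carried into the result.
#' @return data.frame row: `id`, `hc_identity`, `hc_similarity`,
#'   `regions_located`, `label`.
#' @export
classify_protein <- function(scores, identity_min = 0.50,
                             similarity_min = 0.70,
                             strict_regions = FALSE, id = NA_character_) {
  res <- function(label, idy = NA_real_, sim = NA_real_, regions = "")
    data.frame(id = id, hc_identity = idy, hc_similarity = sim,
               regions_located = regions, label = label,
               stringsAsFactors = FALSE)
  if (is.null(scores)) return(res("insufficient_data"))
  observable <- min(scores$loop_len, scores$total_cols) / scores$total_cols
  if (observable < 0.5)
    return(res("insufficient_data", scores$identity, scores$similarity,
               paste(scores$regions_located, collapse = ",")))
  pr <- scores$per_region
  pass_r <- pr$located & (pr$identity >= identity_min |
                          pr$similarity >= similarity_min)
  all_located <- all(pr$located)
  pooled_pass <- scores$identity >= identity_min ||
    scores$similarity >= similarity_min
  canonical <- all_located && pooled_pass &&
    (!strict_regions || all(pass_r))
  label <- if (canonical) "canonical"
    else if (sum(pass_r) >= 2 && any(!pass_r)) "semicanonical"
    else "noncanonical"
  res(label, scores$identity, scores$similarity,
      paste(scores$regions_located, collapse = ","))
}

#' Classify every delineated sequence
#'
#' @param partitions Named list of `pin_partition` objects.
#' @param consensus A [hc_consensus].
#' @param ... Passed to [classify_protein].
#' @return data.frame with one row per sequence (see [classify_protein]).
#' @export
classify_all <- function(partitions, consensus, ...) {
  rows <- lapply(partitions, function(p) {
    sc <- if (is.na(p$loop) || !nzchar(p$loop)) NULL
          else hc_score(p$loop, consensus)
    classify_protein(sc, ..., id = p$id)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify a clade from its members' labels
#'
#' Members labelled `insufficient_data` are excluded.  With ten or more
#' informative members the clade is canonical iff at least 90% of them
#' are canonical (noncanonical symmetrically, counting semicanonical
#' members on the noncanonical side); with fewer than ten a strict
#' (clear) majority decides.  Anything else is `mixed`;
#' `insufficient` when no member is informative.
#'
#' @param labels Character vector of member labels (from
#'   [classify_protein]).
#' @param canonical_frac Clade-level threshold (default 0.90).
#' @param small_n Clade size below which the majority rule applies
#'   (default 10).
#' @return One of `"canonical"`, `"noncanonical"`, `"mixed"`,
#'   `"insufficient"`.
#' @export
classify_clade <- function(labels, canonical_frac = 0.90, small_n = 10L) {
  labels <- labels[labels != "insufficient_data"]
  n <- length(labels)
  if (n == 0) return("insufficient")
  n_can <- sum(labels == "canonical")
  n_non <- sum(labels %in% c("noncanonical", "semicanonical"))
  if (n >= small_n) {
    if (n_can / n >= canonical_frac) "canonical"
    else if (n_non / n >= canonical_frac) "noncanonical"
    else "mixed"
  } else {
    if (n_can > n_non) "canonical"
    else if (n_non > n_can) "noncanonical"
    else "mixed"
  }
}

#' Map structural labels to binary origin-counting states
#'
#' Canonical structure codes 0; noncanonical and semicanonical
#' structure (loss of at least one HC region) codes 1.  `mixed` and
#' `insufficient` give `NA`.
#'
#' @param labels Character vector of protein or clade labels.
#' @return Integer vector of 0/1/NA.
#' @export
structural_states <- function(labels) {
  out <- rep(NA_integer_, length(labels))
  out[labels == "canonical"] <- 0L
  out[labels %in% c("noncanonical", "semicanonical")] <- 1L
  names(out) <- names(labels)
  out
}
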