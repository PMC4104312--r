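# Ordered loop-motif scanning and clade-level presence matrices.
#
# The canonical loop is a series of conserved motifs that always appear
# in the same order.  A motif library is an ordered table of patterns;
# scanning assigns each motif its best gapless window subject to the
# order constraint, then calls one of six presence states per
# (sequence, motif): present, partial, divergent, no_consensus, absent,
# no_data.

MOTIF_STATES <- c("present", "partial", "divergent", "no_consensus",
                  "absent", "no_data")

#' Construct a motif library
#'
#' @param name Motif names.
#' @param pattern Residue patterns; `X` is a wildcard (matches anything,
#'   excluded from identity denominators) and `[SN]` style brackets give
#'   alternatives for one column.  At least 4 columns per pattern.
#' @param rank Strictly increasing integer order within the loop.
#' @param hc_group Optional: one of `"HC1"`..`"HC4"` for motifs that
#'   constitute the four highly conserved loop regions, else `NA`.
#' @param phospho Logical: is the motif a (suspected) phosphorylation
#'   site, like the repeated TPRXS[SN] motif?
#' @return data.frame of class `pin_motif_library`.
#' @export
motif_library <- function(name, pattern, rank = seq_along(name),
                          hc_group = NA_character_, phospho = FALSE) {
  if (length(name) == 0) fail("empty motif library")
  lib <- data.frame(name = as.character(name),
                    pattern = toupper(as.character(pattern)),
                    rank = as.integer(rank),
                    hc_group = rep_len(as.character(hc_group), length(name)),
                    phospho = rep_len(as.logical(phospho), length(name)),
                    stringsAsFactors = FALSE)
  lib <- lib[order(lib$rank), , drop = FALSE]
  if (any(diff(lib$rank) <= 0)) fail("motif ranks must be strictly increasing")
  ncols <- vapply(lib$pattern, function(p) length(parse_pattern(p)), 0L)
  if (any(ncols < 4)) fail("motif pattern %s has fewer than 4 columns",
                           lib$name[ncols < 4][1])
  bad <- !is.na(lib$hc_group) & !lib$hc_group %in% paste0("HC", 1:4)
  if (any(bad)) fail("hc_group must be HC1..HC4 (motif %s)", lib$name[bad][1])
  rownames(lib) <- NULL
  class(lib) <- c("pin_motif_library", "data.frame")
  lib
}

#' Default loop-motif library
#'
#' The ordered motif library used by the synthetic-family generator and
#' as the default scanning library: the four highly conserved regions
#' HC1-HC4 (HC2 as the trio of consecutive motifs, led by the
#' phosphorylated TPRXS[SN] element, that repeats in canonical loops)
#' interleaved with ordinary loop motifs L1-L3.  Real-data analyses
#' should supply their own library ([read_motif_library]); the same
#' table ships as `extdata/pin_motifs.tsv`.
#'
#' @return A `pin_motif_library`.
#' @export
default_motif_library <- function() {
  motif_library(
    name = c("L1", "HC1", "R1", "R2", "R3", "L2", "HC3", "L3", "HC4"),
    pattern = c("GKEVDA", "FAPERSGXLIQE", "TPRXS[SN]", "SNAWGE", "DKLYGQ",
                "WEQNKE", "YSLQESNPGXME", "PKDQFS", "NKDLHMFVWSSK"),
    rank = 1:9,
    hc_group = c(NA, "HC1", "HC2", "HC2", "HC2", NA, "HC3", NA, "HC4"),
    phospho = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE,
                FALSE))
}

# Parse a pattern into a list of allowed residues per column
# (NULL = wildcard column).
parse_pattern <- function(pattern) {
  chars <- strsplit(pattern, "")[[1]]
  cols <- list(); i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      alt <- character()
      while (j <= length(chars) && chars[j] != "]") {
        alt <- c(alt, chars[j]); j <- j + 1L
      }
      if (j > length(chars)) fail("unclosed [ in pattern %s", pattern)
      cols[[length(cols) + 1L]] <- alt
      i <- j + 1L
    } else {
      cols[length(cols) + 1L] <- list(if (ch == "X") NULL else ch)
      i <- i + 1L
    }
  }
  cols
}

#' Read / write a motif library as TSV
#'
#' Columns: `name`, `pattern`, `rank`, `hc_group` (empty for none),
#' `phospho` (TRUE/FALSE).
#'
#' @param path TSV path.
#' @return A `pin_motif_library` ([read_motif_library]) or `path`
#'   invisibly ([write_motif_library]).
#' @export
read_motif_library <- function(path) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "")
  motif_library(tb$name, tb$pattern, tb$rank, tb$hc_group, tb$phospho)
}

#' @rdname read_motif_library
#' @param library A `pin_motif_library`.
#' @export
write_motif_library <- function(library, path) {
  utils::write.table(library, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

# Identity and similarity of every window of length |cols| in chars.
# Identity: fraction of non-wildcard columns whose residue is in the
# allowed set.  Similarity additionally accepts positive BLOSUM62
# substitutions against any allowed residue.
window_scores <- function(chars, cols) {
  m <- length(cols); L <- length(chars)
  n_win <- L - m + 1L
  if (n_win < 1L) return(data.frame(start = integer(), identity = numeric(),
                                    similarity = numeric()))
  inf <- which(!vapply(cols, is.null, TRUE))
  id <- sim <- numeric(n_win)
  B <- blosum62()
  for (j in inf) {
    allowed <- cols[[j]]
    obs <- chars[j:(j + n_win - 1L)]
    hit <- obs %in% allowed
    pos <- hit
    valid <- obs %in% rownames(B)
    if (any(!hit & valid)) {
      sc <- B[obs[!hit & valid], allowed, drop = FALSE]
      pos[!hit & valid] <- apply(sc, 1, max) > 0
    }
    id <- id + hit
    sim <- sim + pos
  }
  data.frame(start = seq_len(n_win), identity = id / length(inf),
             similarity = sim / length(inf))
}

# Cached BLOSUM62 from Biostrings.
blosum62 <- local({
  B <- NULL
  function() {
    if (is.null(B)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      B <<- e$BLOSUM62
    }
    B
  }
})

# Order-constrained maximum-weight assignment: one window (or none) per
# motif, windows non-overlapping and increasing in position by rank.
# Returns per-motif start indices (NA = unassigned) maximizing total
# identity; exact ties prefer assigning more motifs, then earlier
# windows.  Backward DP: suf[[k]][s] = best total for motifs k..M when
# every remaining window must start at or after s.
assign_windows <- function(score_list, lengths, L) {
  M <- length(score_list)
  EPS <- 1e-9  # favour assigning a motif over skipping it on exact ties
  suf <- vector("list", M + 1L)
  suf[[M + 1L]] <- rep(0, L + 1L)
  take <- vector("list", M)  # take[[k]][s]: best value using a window >= s
  for (k in rev(seq_len(M))) {
    sc <- score_list[[k]]
    nxt <- suf[[k + 1L]]
    tk <- rep(-Inf, L + 1L)
    if (nrow(sc) > 0) {
      after <- pmin(sc$start + lengths[k], L + 1L)
      val <- sc$identity + EPS + nxt[after]
      # reverse running max over window start
      for (i in rev(seq_len(nrow(sc)))) {
        s <- sc$start[i]
        if (val[i] > tk[s]) tk[s] <- val[i]
      }
      for (s in rev(seq_len(L))) tk[s] <- max(tk[s], tk[s + 1L])
    }
    suf[[k]] <- pmax(nxt, tk)
    take[[k]] <- tk
  }
  starts <- rep(NA_integer_, M)
  s <- 1L
  for (k in seq_len(M)) {
    sc <- score_list[[k]]
    tk_s <- take[[k]][s]
    if (nrow(sc) == 0 || !is.finite(tk_s) ||
        tk_s < suf[[k + 1L]][s] - 1e-12) next  # skipping motif k is better
    nxt <- suf[[k + 1L]]
    after <- pmin(sc$start + lengths[k], L + 1L)
    val <- sc$identity + EPS + nxt[after]
    ok <- which(sc$start >= s & abs(val - tk_s) < 1e-12)
    if (!length(ok)) next
    i <- ok[which.min(sc$start[ok])]
    starts[k] <- sc$start[i]
    s <- min(sc$start[i] + lengths[k], L + 1L)
  }
  starts
}

#' Scan a loop against an ordered motif library
#'
#' Each motif receives its best gapless window such that chosen windows
#' are non-overlapping and increase in position with rank (a
#' maximum-weight increasing assignment over window identities).  States:
#' `present` (identity >= `present_min`), `divergent` (similarity >=
#' `divergent_sim` with identity below `present_min`, the window in
#' order between located neighbours), `partial` (a clipped window at a
#' truncated loop edge covering >= `partial_cov` of the motif at
#' `present_min` identity), `no_data` (loop truncated over the motif's
#' span), else `absent`.
#'
#' @param loop Residue string (nonempty).
#' @param library A `pin_motif_library`.
#' @param present_min Identity threshold for `present` (default 0.70).
#' @param divergent_sim Similarity floor for `divergent` (default 0.40).
#' @param divergent_id Identity floor for `divergent` (default 0.40):
#'   a divergent motif keeps the general structure, which random
#'   spacer windows with chance positive-substitution similarity do not.
#' @param partial_cov Minimum fraction of motif columns observable for
#'   `partial` (default 0.5).
#' @param truncated Character vector: subset of `c("n", "c")` marking a
#'   loop clipped at its N and/or C end (e.g. by an EST fragment).
#' @return data.frame with one row per motif: `motif`, `rank`, `start`,
#'   `end`, `identity`, `similarity`, `state`.
#' @export
scan_loop <- function(loop, library, present_min = 0.70,
                      divergent_sim = 0.40, divergent_id = 0.40,
                      partial_cov = 0.5, truncated = character()) {
  if (!inherits(library, "pin_motif_library") || nrow(library) == 0)
    fail("empty motif library")
  if (is.na(loop) || !nzchar(loop)) fail("loop must be nonempty")
  chars <- strsplit(loop, "")[[1]]
  L <- length(chars)
  cols_list <- lapply(library$pattern, parse_pattern)
  lens <- vapply(cols_list, length, 0L)
  score_list <- lapply(cols_list, function(cl) window_scores(chars, cl))
  starts <- assign_windows(score_list, lens, L)
  id <- sim <- rep(NA_real_, nrow(library))
  for (k in seq_len(nrow(library))) {
    if (!is.na(starts[k])) {
      row <- score_list[[k]][score_list[[k]]$start == starts[k], ]
      id[k] <- row$identity; sim[k] <- row$similarity
    }
  }
  state <- rep("absent", nrow(library))
  state[!is.na(id) & id >= present_min] <- "present"
  # Partial: clipped window at a truncated edge matching well over the
  # observed columns.
  for (k in seq_len(nrow(library))) {
    if (state[k] == "present") next
    pc <- clipped_match(chars, cols_list[[k]], truncated, partial_cov,
                        present_min)
    if (pc) state[k] <- "partial"
  }
  # Divergent: similar-but-not-identical windows anchored in order by
  # located neighbours (the order itself is enforced by the assignment).
  located <- state %in% c("present", "partial")
  for (k in seq_len(nrow(library))) {
    if (state[k] != "absent" || is.na(sim[k]) || sim[k] < divergent_sim ||
        id[k] < divergent_id)
      next
    prev_ok <- k == 1 || any(located[seq_len(k - 1L)])
    next_ok <- k == nrow(library) || any(located[seq(k + 1L, nrow(library))])
    if (prev_ok && next_ok) state[k] <- "divergent"
  }
  # No data: unplaced motifs on a truncated side.
  if (length(truncated)) {
    unplaced <- is.na(starts)
    if ("n" %in% truncated && any(unplaced)) {
      k <- 1L
      while (k <= nrow(library) && unplaced[k]) {
        if (state[k] == "absent") state[k] <- "no_data"
        k <- k + 1L
      }
    }
    if ("c" %in% truncated && any(unplaced)) {
      k <- nrow(library)
      while (k >= 1L && unplaced[k]) {
        if (state[k] == "absent") state[k] <- "no_data"
        k <- k - 1L
      }
    }
  }
  data.frame(motif = library$name, rank = library$rank,
             start = starts,
             end = ifelse(is.na(starts), NA_integer_, starts + lens - 1L),
             identity = id, similarity = sim, state = state,
             stringsAsFactors = FALSE)
}

# Does a clipped window at a truncated loop edge match the motif over
# >= cov_min of its columns at >= id_min identity?
clipped_match <- function(chars, cols, truncated, cov_min, id_min) {
  m <- length(cols); L <- length(chars)
  check <- function(sub_cols, obs) {
    inf <- which(!vapply(sub_cols, is.null, TRUE))
    if (length(inf) == 0) return(FALSE)
    hits <- mapply(function(cl, ch) ch %in% cl, sub_cols[inf], obs[inf])
    length(inf) / m >= cov_min && mean(hits) >= id_min
  }
  ok <- FALSE
  if ("n" %in% truncated) {  # suffix of the motif at the loop start
    for (d in seq_len(m - 1L)) {
      n_obs <- m - d
      if (n_obs > L) next
      if (check(cols[(d + 1L):m], chars[seq_len(n_obs)])) { ok <- TRUE; break }
    }
  }
  if (!ok && "c" %in% truncated) {  # prefix of the motif at the loop end
    for (d in seq_len(m - 1L)) {
      n_obs <- m - d
      if (n_obs > L) next
      if (check(cols[seq_len(n_obs)], chars[(L - n_obs + 1L):L])) {
        ok <- TRUE; break
      }
    }
  }
  ok
}

#' Count consecutive repeats of a motif unit
#'
#' Greedy left-to-right count of consecutive occurrences of a unit (an
#' ordered group of motifs, e.g. the trio around HC2 that is repeated
#' four times).  A copy requires every unit motif present-or-divergent,
#' in order, with at most `max_gap` residues between consecutive
#' elements.
#'
#' @param loop Residue string.
#' @param unit A `pin_motif_library` (the unit's motifs, in order).
#' @param max_copies Upper bound on counted copies (default 8).
#' @param max_gap Maximum spacer between unit elements and between
#'   copies (default 10).
#' @param present_min,divergent_sim,divergent_id Thresholds as in
#'   [scan_loop].
#' @return List with `count`, `spans` (data.frame `copy`, `start`,
#'   `end`) and `partial_span` (`c(start, end)` of a trailing incomplete
#'   copy, or `NULL`).
#' @export
detect_repeats <- function(loop, unit, max_copies = 8L, max_gap = 10L,
                           present_min = 0.70, divergent_sim = 0.40,
                           divergent_id = 0.40) {
  if (!inherits(unit, "pin_motif_library") || nrow(unit) == 0)
    fail("empty repeat unit")
  chars <- strsplit(loop, "")[[1]]
  L <- length(chars)
  cols_list <- lapply(unit$pattern, parse_pattern)
  lens <- vapply(cols_list, length, 0L)
  scores <- lapply(cols_list, function(cl) window_scores(chars, cl))
  count <- 0L
  spans <- data.frame(copy = integer(), start = integer(), end = integer())
  partial_span <- NULL
  pos <- 1L
  while (count < max_copies) {
    cur <- pos
    copy_start <- NA_integer_
    matched <- 0L
    for (k in seq_len(nrow(unit))) {
      sc <- scores[[k]]
      okw <- sc$start >= cur & sc$start <= cur + max_gap &
        (sc$identity >= present_min |
           (sc$similarity >= divergent_sim & sc$identity >= divergent_id))
      if (!any(okw)) break
      s <- min(sc$start[okw])
      if (is.na(copy_start)) copy_start <- s
      cur <- s + lens[k]
      matched <- matched + 1L
    }
    if (matched == nrow(unit)) {
      count <- count + 1L
      spans <- rbind(spans, data.frame(copy = count, start = copy_start,
                                       end = cur - 1L))
      pos <- cur
    } else {
      if (matched > 0L)
        partial_span <- c(start = copy_start, end = cur - 1L)
      break
    }
  }
  list(count = count, spans = spans, partial_span = partial_span)
}

#' Clade-level motif presence matrix
#'
#' Aggregates per-sequence scans to one state per (clade, motif): the
#' strict-majority state over members with data; `no_consensus` when no
#' state exceeds half of the members with data; `no_data` when no member
#' covers the motif.
#'
#' @param scans Named list (sequence id -> [scan_loop] data.frame).
#' @param cmap A [clade_map]; sequences without a clade are excluded
#'   with a warning.
#' @return Character matrix, clades x motifs, of state words.
#' @export
motif_matrix <- function(scans, cmap) {
  stopifnot(inherits(cmap, "pin_clade_map"))
  ids <- names(scans)
  unmapped <- setdiff(ids, names(cmap$sequence_to_clade))
  if (length(unmapped)) {
    warning("excluding ", length(unmapped),
            " sequence(s) without a clade: ",
            paste(utils::head(unmapped, 3), collapse = ", "))
    ids <- setdiff(ids, unmapped)
  }
  if (!length(ids)) fail("no mapped sequences")
  motifs <- scans[[ids[1]]]$motif
  clades <- sort(unique(cmap$sequence_to_clade[ids]))
  out <- matrix("no_data", nrow = length(clades), ncol = length(motifs),
                dimnames = list(clades, motifs))
  for (cl in clades) {
    members <- ids[cmap$sequence_to_clade[ids] == cl]
    for (j in seq_along(motifs)) {
      st <- vapply(members, function(i) scans[[i]]$state[j], "")
      st <- st[st != "no_data"]
      if (!length(st)) next
      tb <- table(st)
      top <- which.max(tb)
      out[cl, j] <- if (tb[top] * 2L > length(st)) names(tb)[top]
                    else "no_consensus"
    }
  }
  out
}
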