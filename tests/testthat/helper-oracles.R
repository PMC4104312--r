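# Independent brute-force oracles, deliberately written without reusing
# any implementation internals.

# Exhaustive anchor scan: best window by substitution count, ties to the
# window nearest `expect_start` then leftmost.
oracle_anchor <- function(seq, motif, max_subs, expect_start = NULL) {
  m <- nchar(motif); L <- nchar(seq)
  if (L < m) return(NULL)
  best <- NULL
  for (s in seq_len(L - m + 1)) {
    win <- substr(seq, s, s + m - 1)
    subs <- sum(strsplit(win, "")[[1]] != strsplit(motif, "")[[1]] &
                  strsplit(motif, "")[[1]] != "X")
    if (is.null(best) || subs < best$substitutions ||
        (subs == best$substitutions && !is.null(expect_start) &&
         abs(s - expect_start) < abs(best$start - expect_start))) {
      best <- list(start = s, end = s + m - 1, substitutions = subs)
    }
  }
  if (best$substitutions > max_subs) NULL else best
}

# Identity of a gapless window against a pattern (wildcards excluded).
oracle_window_identity <- function(chars, pattern, s) {
  cols <- pinarch:::parse_pattern(pattern)
  inf <- !vapply(cols, is.null, TRUE)
  obs <- chars[s:(s + length(cols) - 1)]
  hits <- mapply(function(cl, ch) ch %in% cl, cols[inf], obs[inf])
  mean(hits)
}

# Exhaustive order-respecting assignment: maximum total identity over
# non-overlapping, rank-increasing windows with optional skips.
oracle_assignment <- function(loop, patterns) {
  chars <- strsplit(loop, "")[[1]]
  L <- length(chars)
  lens <- vapply(patterns, function(p)
    length(pinarch:::parse_pattern(p)), 0L)
  rec <- function(k, s) {
    if (k > length(patterns)) return(0)
    best <- rec(k + 1, s)  # skip motif k
    if (s + lens[k] - 1 <= L) {
      for (w in s:(L - lens[k] + 1)) {
        v <- oracle_window_identity(chars, patterns[k], w) +
          rec(k + 1, w + lens[k])
        if (v > best) best <- v
      }
    }
    best
  }
  rec(1, 1)
}

# Definitional parsimony-informative check, column by column.
oracle_informative <- function(col) {
  col <- col[!col %in% c("-", "?")]
  tb <- table(col)
  sum(tb >= 2) >= 2
}

# Exhaustive minimum origins: enumerate all internal labelings.
oracle_origins <- function(tree, states, root_state = 0L,
                           reversals = c("none", "equal")) {
  reversals <- match.arg(reversals)
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  tip_states <- as.integer(states[tree$tip.label])
  root <- n_tip + 1L
  grid <- as.matrix(expand.grid(rep(list(0:1), n_node)))
  grid <- grid[grid[, root - n_tip] == root_state, , drop = FALSE]
  S <- cbind(matrix(tip_states, nrow = nrow(grid), ncol = n_tip,
                    byrow = TRUE), grid)
  p <- S[, tree$edge[, 1], drop = FALSE]
  ch <- S[, tree$edge[, 2], drop = FALSE]
  changes <- rowSums(p != ch)
  origins <- rowSums(p == 0L & ch == 1L) + (S[, root] == 1L)
  if (reversals == "none") {
    ok <- rowSums(p == 1L & ch == 0L) == 0
    changes <- changes[ok]; origins <- origins[ok]
  }
  if (!length(changes)) return(NULL)
  best <- min(changes)
  list(changes = best, origins = min(origins[changes == best]))
}

# Random amino-acid string.
rand_aa <- function(n) paste(sample(pinarch:::AA20, n, replace = TRUE),
                             collapse = "")
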