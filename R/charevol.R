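# Minimum independent origins of noncanonical structure on a clade
# cladogram, and long-branch flagging.
#
# Origin counting is a small Sankoff-style dynamic programme over binary
# states (canonical = 0, noncanonical/semicanonical = 1) with the root
# fixed canonical (a single canonical PIN in the last common ancestor of
# land plants).  Because noncanonical structure reflects loss of the
# modular loop, regaining it is not assumed: by default 1 -> 0
# reversals are disallowed (`reversals = "none"`), which makes the
# count the minimum number of independent losses.  The equal-cost
# model (`reversals = "equal"`) minimises total changes first and the
# number of 0 -> 1 edges among minimum-change labelings second.

#' Minimum independent origins of a binary character
#'
#' @param tree A rooted `phylo` tree.
#' @param states Named integer/logical vector of tip states (0 =
#'   canonical, 1 = noncanonical); every tip used must be named.  `NA`
#'   states are not allowed.
#' @param root_state State fixed at the root (default 0, canonical).
#' @param reversals `"none"` (default): 1 -> 0 changes are forbidden;
#'   `"equal"`: reversals cost the same as origins, and among
#'   minimum-change labelings the one with fewest 0 -> 1 edges is
#'   reported.
#' @param exclude Tips to prune before counting (robustness reruns).
#' @return List: `origins` (count of 0 -> 1 edges, plus one if the root
#'   itself is 1), `changes` (total state changes), `labeling` (named
#'   0/1 vector over tips then internal nodes of the possibly pruned
#'   tree), `tree` (the tree used).
#' @export
min_origins <- function(tree, states, root_state = 0L,
                        reversals = c("none", "equal"),
                        exclude = character()) {
  reversals <- match.arg(reversals)
  stopifnot(inherits(tree, "phylo"))
  if (length(exclude)) {
    tree <- ape::drop.tip(tree, exclude)
    if (is.null(tree) || ape::Ntip(tree) < 2)
      fail("fewer than 2 tips left after exclusion")
  }
  tips <- tree$tip.label
  missing <- setdiff(tips, names(states))
  if (length(missing)) fail("unlabeled tip: %s", missing[1])
  st <- as.integer(states[tips])
  if (anyNA(st)) fail("unlabeled tip: %s", tips[is.na(st)][1])
  if (!all(st %in% 0:1)) fail("states must be binary 0/1")

  n_tip <- length(tips)
  n_node <- tree$Nnode
  root <- n_tip + 1L
  # lexicographic (changes, origins) packed into one number
  BIG <- 1e6
  edge_cost <- function(p, s) {
    if (p == s) return(0)
    if (p == 0L) return(BIG + 1)           # origin
    if (reversals == "none") return(Inf)   # reversal forbidden
    BIG                                    # reversal
  }
  cost <- matrix(Inf, nrow = n_tip + n_node, ncol = 2)
  cost[cbind(seq_len(n_tip), st + 1L)] <- 0
  eo <- ape::reorder.phylo(tree, "postorder")
  children <- split(eo$edge[, 2], eo$edge[, 1])
  for (v in unique(eo$edge[, 1])) {      # postorder guarantees children done
    for (s in 0:1) {
      tot <- 0
      for (ch in children[[as.character(v)]])
        tot <- tot + min(edge_cost(s, 0L) + cost[ch, 1],
                         edge_cost(s, 1L) + cost[ch, 2])
      cost[v, s + 1L] <- tot
    }
  }
  best <- cost[root, root_state + 1L]
  if (!is.finite(best)) fail("no labeling satisfies the constraints")
  # backtrack one optimal labeling (ties resolved toward canonical)
  lab <- integer(n_tip + n_node)
  lab[seq_len(n_tip)] <- st
  lab[root] <- root_state
  for (i in rev(seq_len(nrow(eo$edge)))) {  # preorder over edges
    p <- eo$edge[i, 1]; ch <- eo$edge[i, 2]
    if (ch <= n_tip) next
    s <- lab[p]
    take0 <- edge_cost(s, 0L) + cost[ch, 1]
    take1 <- edge_cost(s, 1L) + cost[ch, 2]
    lab[ch] <- if (take0 <= take1) 0L else 1L
  }
  origins <- sum(lab[tree$edge[, 1]] == 0L & lab[tree$edge[, 2]] == 1L) +
    as.integer(lab[root] == 1L)
  changes <- sum(lab[tree$edge[, 1]] != lab[tree$edge[, 2]])
  names(lab) <- c(tips, paste0("node", seq_len(n_node)))
  list(origins = origins, changes = changes, labeling = lab, tree = tree)
}

#' Flag long-branch clades
#'
#' A clade is flagged when the median path length from the clade's most
#' recent common ancestor to its tips exceeds `ratio` times the median
#' of that same quantity over all tips (for single-tip clades the
#' quantity is the terminal branch length).
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param cmap Optional [clade_map] assigning tips to clades; by default
#'   every tip is its own clade.
#' @param ratio Threshold multiple (default 2).
#' @return Character vector of flagged clade names.
#' @export
long_branch_clades <- function(tree, cmap = NULL, ratio = 2) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) fail("tree has no branch lengths")
  tips <- tree$tip.label
  cl <- if (is.null(cmap)) stats::setNames(tips, tips)
        else cmap$sequence_to_clade[tips]
  if (anyNA(cl)) fail("tip without clade: %s", tips[is.na(cl)][1])
  depths <- ape::node.depth.edgelength(tree)  # root-to-node path lengths
  per_tip <- numeric(length(tips))
  clades <- unique(cl)
  med_clade <- stats::setNames(numeric(length(clades)), clades)
  for (cd in clades) {
    idx <- which(cl == cd)
    anc <- if (length(idx) == 1) tree$edge[tree$edge[, 2] == idx, 1]
           else ape::getMRCA(tree, idx)
    d <- depths[idx] - depths[anc]
    per_tip[idx] <- d
    med_clade[cd] <- stats::median(d)
  }
  baseline <- stats::median(per_tip)
  names(med_clade)[med_clade > ratio * baseline]
}

#' Bundled reference cladogram and structural states
#'
#' A clade-level cladogram of the PIN family (tips are the named clades
#' across the major land-plant lineages: bryophyte canonical PINA/PINZ
#' with the divergent PIND and PINW/X/Y placed in their own lineages,
#' the lycophyte pair, and the three euphyllophyte lineages Eu1-Eu3),
#' together with each clade's structural state.  On this tree the seven
#' noncanonical/semicanonical lineages (PIN5, PIN6, PIN8, PIN9, PIN12,
#' PIND, PINW/X/Y) each represent an independent origin under the
#' default irreversible model.
#'
#' @return `reference_cladogram()`: a `phylo`; `reference_clade_states()`:
#'   a data.frame `clade`, `label`, `lineage`.
#' @export
reference_cladogram <- function() {
  read_tree(system.file("extdata", "pin_clades.nwk", package = "pinarch",
                        mustWork = TRUE))
}

#' @rdname reference_cladogram
#' @export
reference_clade_states <- function() {
  utils::read.delim(system.file("extdata", "pin_clade_states.tsv",
                                package = "pinarch", mustWork = TRUE),
                    stringsAsFactors = FALSE)
}
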