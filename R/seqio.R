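# Sequence, alignment, tree and clade-map IO.
#
# Sequence sets are plain data.frames (one row per sequence) with class
# "pin_records"; alignments are character matrices with class
# "pin_alignment"; trees are ape "phylo" objects.  Internally all
# coordinates are 1-based inclusive R indices; canonical position labels
# (N1.., C1..) are attached at the boundary.

#' Create a set of sequence records
#'
#' @param id Character vector of unique sequence identifiers.
#' @param residues Character vector of amino-acid strings (20 canonical
#'   letters plus `X`).
#' @param species Optional character vector of species names.
#' @param n_complete,c_complete Logical: does the sequence start at the
#'   initiator / run to the stop?  Partial EST-derived sequences carry
#'   `FALSE`.
#' @return A data.frame of class `pin_records` with columns `id`,
#'   `species`, `residues`, `n_complete`, `c_complete`.
#' @export
pin_records <- function(id, residues, species = NA_character_,
                        n_complete = TRUE, c_complete = TRUE) {
  id <- as.character(id); residues <- toupper(as.character(residues))
  if (length(id) != length(residues))
    fail("id and residues must have equal length")
  if (anyDuplicated(id))
    fail("duplicate sequence id: %s", id[duplicated(id)][1])
  if (any(!nzchar(residues)))
    fail("empty residue string for id %s", id[!nzchar(residues)][1])
  bad <- regexpr(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")), residues)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    fail("non-alphabet character '%s' at position %d of sequence %s",
         substr(residues[i], bad[i], bad[i]), bad[i], id[i])
  }
  out <- data.frame(id = id, species = rep_len(species, length(id)),
                    residues = residues,
                    n_complete = rep_len(n_complete, length(id)),
                    c_complete = rep_len(c_complete, length(id)),
                    stringsAsFactors = FALSE)
  class(out) <- c("pin_records", "data.frame")
  out
}

#' Read protein sequences from FASTA
#'
#' The header token before the first whitespace becomes the id.
#' Completeness flags default to `TRUE`; the plain header tokens
#' `n_partial` and `c_partial` mark sequences that do not start at the
#' initiator or do not run to the stop (this keeps the files standard
#' FASTA).
#'
#' @param path Path to a FASTA file.
#' @return A [pin_records] data.frame.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) fail("file not found: %s", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) {
    warning("empty FASTA file: ", path)
    return(pin_records(character(), character()))
  }
  headers <- names(set)
  toks <- strsplit(headers, "[ \t]+")
  ids <- vapply(toks, `[`, "", 1)
  if (anyDuplicated(ids))
    fail("duplicate sequence id: %s", ids[duplicated(ids)][1])
  flags <- function(tag) vapply(toks, function(tk) tag %in% tk[-1], TRUE)
  pin_records(id = ids,
              residues = as.character(set),
              n_complete = !flags("n_partial"),
              c_complete = !flags("c_partial"))
}

#' Write sequence records to FASTA
#'
#' Inverse of [read_fasta]: completeness flags are written as
#' `n_partial` / `c_partial` header tokens.
#'
#' @param records A [pin_records] data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(inherits(records, "pin_records"))
  hdr <- records$id
  hdr <- ifelse(records$n_complete, hdr, paste(hdr, "n_partial"))
  hdr <- ifelse(records$c_complete, hdr, paste(hdr, "c_partial"))
  set <- Biostrings::BStringSet(records$residues)
  names(set) <- hdr
  Biostrings::writeXStringSet(set, path, width = 70)
  invisible(path)
}

#' Read an aligned FASTA file into an alignment matrix
#'
#' Rows must be equal length.  Gap `-` and missing `?` are both
#' accepted (and both count as missing for statistics) but are kept
#' distinct in the matrix.
#'
#' @param path Path to an aligned FASTA file.
#' @return A character matrix (sequences x columns) of single
#'   characters, row names = ids, class `pin_alignment`.
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) fail("file not found: %s", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) fail("empty alignment: %s", path)
  ids <- vapply(strsplit(names(set), "[ \t]+"), `[`, "", 1)
  if (anyDuplicated(ids))
    fail("duplicate sequence id: %s", ids[duplicated(ids)][1])
  seqs <- toupper(as.character(set))
  w <- nchar(seqs)
  if (length(unique(w)) != 1)
    fail("ragged alignment: row %s has %d columns, expected %d",
         ids[w != w[1]][1], w[w != w[1]][1], w[1])
  as_alignment(seqs, ids)
}

# Build a pin_alignment from aligned strings.
as_alignment <- function(seqs, ids) {
  m <- do.call(rbind, strsplit(seqs, ""))
  rownames(m) <- ids
  class(m) <- c("pin_alignment", class(m))
  m
}

#' Write an alignment matrix to aligned FASTA
#'
#' @param aln A `pin_alignment` matrix (see [read_alignment]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "pin_alignment"))
  set <- Biostrings::BStringSet(apply(aln, 1, paste, collapse = ""))
  names(set) <- rownames(aln)
  Biostrings::writeXStringSet(set, path, width = 70)
  invisible(path)
}

#' Read a rooted tree from a Newick file
#'
#' Branch lengths are optional; when absent they stay missing (they are
#' never coerced to zero).  Duplicate tip labels are an error.
#'
#' @param path Path to a single-tree Newick file.
#' @return An [ape::read.tree] "phylo" object.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) fail("file not found: %s", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  if (nchar(gsub("[^(]", "", txt)) != nchar(gsub("[^)]", "", txt)))
    fail("unbalanced parentheses in Newick file %s", path)
  tr <- ape::read.tree(text = txt)
  if (is.null(tr)) fail("could not parse Newick file %s", path)
  if (inherits(tr, "multiPhylo")) fail("expected a single tree in %s", path)
  if (anyDuplicated(tr$tip.label))
    fail("duplicate tip label: %s", tr$tip.label[duplicated(tr$tip.label)][1])
  tr
}

#' Read a clade map from TSV
#'
#' Two tables travel in one file format: a sequence table with header
#' columns `sequence_id`, `clade` and an optional clade table with
#' columns `clade`, `lineage`.  Either file may be omitted (`NULL`).
#'
#' @param seq_path TSV with columns `sequence_id`, `clade`.
#' @param clade_path Optional TSV with columns `clade`, `lineage`
#'   (lineage one of Eu1, Eu2, Eu3, Lyco1, Lyco2, BC, BNC, other).
#' @return A list of class `pin_clade_map` with elements
#'   `sequence_to_clade` (named character) and `clade_to_lineage`
#'   (named character, possibly empty).
#' @export
read_clade_map <- function(seq_path, clade_path = NULL) {
  st <- utils::read.delim(seq_path, stringsAsFactors = FALSE)
  if (!all(c("sequence_id", "clade") %in% names(st)))
    fail("clade map %s must have columns sequence_id, clade", seq_path)
  if (any(!nzchar(st$clade))) fail("empty clade name in %s", seq_path)
  s2c <- stats::setNames(as.character(st$clade), st$sequence_id)
  c2l <- character()
  if (!is.null(clade_path)) {
    ct <- utils::read.delim(clade_path, stringsAsFactors = FALSE)
    if (!all(c("clade", "lineage") %in% names(ct)))
      fail("clade table %s must have columns clade, lineage", clade_path)
    c2l <- stats::setNames(as.character(ct$lineage), ct$clade)
    missing <- setdiff(unique(s2c), names(c2l))
    if (length(missing))
      fail("clade without lineage: %s", missing[1])
  }
  structure(list(sequence_to_clade = s2c, clade_to_lineage = c2l),
            class = "pin_clade_map")
}

#' Construct a clade map in code
#'
#' @param sequence_to_clade Named character vector, id -> clade.
#' @param clade_to_lineage Optional named character vector,
#'   clade -> lineage.
#' @return A `pin_clade_map` list.
#' @export
clade_map <- function(sequence_to_clade, clade_to_lineage = character()) {
  if (any(!nzchar(sequence_to_clade))) fail("empty clade name")
  if (length(clade_to_lineage)) {
    missing <- setdiff(unique(sequence_to_clade), names(clade_to_lineage))
    if (length(missing)) fail("clade without lineage: %s", missing[1])
  }
  structure(list(sequence_to_clade = sequence_to_clade,
                 clade_to_lineage = clade_to_lineage),
            class = "pin_clade_map")
}
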