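# Shared constants: residue alphabet, hydropathy scale, anchor motifs,
# canonical coordinate model and identity band schemes.

#' @keywords internal
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Residues accepted in sequence records; X = unknown residue.
AA_ALPHABET <- c(AA20, "X")

# Characters treated as missing data in alignments and profiles.
MISSING_CHARS <- c("-", "?")

#' Kyte-Doolittle hydropathy scale
#'
#' Per-residue hydropathy values on the standard Kyte-Doolittle scale
#' (isoleucine 4.5 ... arginine -4.5).  `X` is assigned 0 (neutral).
#'
#' @return Named numeric vector over the 20 canonical residues plus `X`.
#' @export
#' @examples
#' kyte_doolittle()[["I"]]
kyte_doolittle <- function() {
  c(A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
    L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2,
    X =  0.0)
}

# Anchor motifs delimiting the transmembrane domains: the N-terminal
# domain runs from the initiator to the end of FLFEFRAAR, the C-terminal
# domain from the start of VWRKLIRN to the stop.
N_ANCHOR <- "FLFEFRAAR"
C_ANCHOR <- "VWRKLIRN"

# Canonical domain lengths: N1..N158 and C1..C154 (312 assessed positions).
N_DOMAIN_LEN <- 158L
C_DOMAIN_LEN <- 154L

# Insertions in long N-domains sit between N97 and N98.
N_INSERTION_AFTER <- 97L

#' Canonical transmembrane coordinate labels
#'
#' The canonical coordinate model labels the N-terminal transmembrane
#' domain N1..N158 and the C-terminal domain C1..C154; together these
#' are the 312 assessed transmembrane positions.
#'
#' @param region `"n_domain"`, `"c_domain"` or `"both"` (default).
#' @return Character vector of position labels.
#' @export
#' @examples
#' length(canonical_positions())  # 312
canonical_positions <- function(region = c("both", "n_domain", "c_domain")) {
  region <- match.arg(region)
  n <- paste0("N", seq_len(N_DOMAIN_LEN))
  c_ <- paste0("C", seq_len(C_DOMAIN_LEN))
  switch(region, n_domain = n, c_domain = c_, both = c(n, c_))
}

#' Identity band schemes
#'
#' Named interval schemes used to bin per-position amino-acid identity.
#' Intervals are open at the lower edge and closed at the upper edge,
#' with 100% identity its own band:
#' \describe{
#'   \item{`"cross"`}{100%, >99%, >95%, >90% - the scheme used to report
#'     conserved canonical positions and their retention in noncanonical
#'     groups.}
#'   \item{`"self"`}{100%, 95-99%, 90-95%, 70-90%, 50-70%, <50% - the
#'     scheme used for within-clade self-identity, covering (0,1].}
#' }
#'
#' @param name `"cross"` or `"self"`.
#' @return A data.frame with columns `label`, `lower`, `upper`
#'   (lower-open, upper-closed; the 100% band is the point {1}).
#' @export
#' @examples
#' band_scheme("self")
band_scheme <- function(name = c("cross", "self")) {
  name <- match.arg(name)
  sch <- switch(name,
    cross = data.frame(
      label = c("100%", ">99%", ">95%", ">90%"),
      lower = c(1, 0.99, 0.95, 0.90),
      upper = c(1, 1, 0.99, 0.95),
      stringsAsFactors = FALSE),
    self = data.frame(
      label = c("100%", "95-99%", "90-95%", "70-90%", "50-70%", "<50%"),
      lower = c(1, 0.95, 0.90, 0.70, 0.50, 0),
      upper = c(1, 1, 0.95, 0.90, 0.70, 0.50),
      stringsAsFactors = FALSE))
  class(sch) <- c("pin_band_scheme", "data.frame")
  sch
}

# Assign identities to band labels of a scheme. 1 maps to the 100% band;
# other values x map to the band with lower < x <= upper (the upper edge
# of the topmost non-100% band is treated as open at 1).
band_of <- function(identity, scheme) {
  stopifnot(inherits(scheme, "pin_band_scheme"))
  lab <- rep(NA_character_, length(identity))
  for (i in seq_len(nrow(scheme))) {
    lo <- scheme$lower[i]; hi <- scheme$upper[i]
    hit <- if (lo == 1) identity == 1 else
      identity > lo & (identity < hi | (identity == hi & hi < 1))
    lab[hit & is.na(lab)] <- scheme$label[i]
  }
  factor(lab, levels = scheme$label)
}

# Internal validation helper: stop() with a clean message.
fail <- function(...) stop(sprintf(...), call. = FALSE)
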