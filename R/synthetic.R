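# Synthetic PIN-family generator with full ground truth.
#
# The generator emulates the statistical structure the analysis assumes:
# a canonical template with the two anchors planted verbatim, ten
# hydrophobic helix segments (helix 3 deliberately weak, so that it is
# only recovered as a cryptic hydropathy peak), a modular loop assembled
# from the default motif library with clade-specific retention patterns,
# per-position transmembrane conservation planted to configured identity
# bands (defaults mirror the published family-wide and within-clade band
# counts over the 312 canonical positions), rare insertions between N97
# and N98, noncanonical clades with short replacement loops (32-120 aa)
# and EST-style truncation targeting a configurable missing-data
# fraction.  Everything is seeded and deterministic.

HYDROPHOBIC <- c("I", "L", "V", "F", "M", "A")
HYDROPHILIC <- c("D", "E", "K", "R", "N", "Q", "S", "G", "T")
# non-positive Kyte-Doolittle: substitutions outside helices stay polar,
# so inter-helix spacers never turn membrane-like
POLAR <- c("R", "N", "D", "Q", "E", "G", "H", "K", "P", "S", "T", "W", "Y")

#' The synthetic canonical template
#'
#' N-domain (158 aa: initiator lead, helices 1-5, anchor FLFEFRAAR at
#' N150-N158) and C-domain (154 aa: anchor VWRKLIRN at C1-C8, helices
#' 6-10, the invariant tyrosine at C123).  Helix 3 is weakly
#' hydrophobic (alternating V/T) so that it is recovered as a cryptic
#' peak.
#'
#' @return List: `n_domain`, `c_domain` (strings), `helices`
#'   (data.frame `helix`, `domain`, `start`, `end` in domain
#'   coordinates), `weak_helix` (3).
#' @export
pin_template <- function() {
  n_dom <- paste0(
    "MSDGEK",
    "ILVFMVLIAVLFIVLMVIL", "DKESQNREGDKE",
    "VLIFAVMLIVFALIVLFIV", "ENKRSDQEGSKD",
    "VTVTVTVTVTVTVTVTVTV", "QDKESNRGEDKS",
    "LIVMAFVILVLFIAVLIVF", "RESDKQNEGDKE",
    "FVLIVAILMVFLIVALVIV", N_ANCHOR)
  c_dom <- paste0(
    C_ANCHOR, "DES",
    "IVLFMALIVVLFIMVLIVL", "KDQESNREGDKS",
    "LVIFAMVLIFVLAIVLVIF", "ENKDSQREGSDK",
    "VILMFAVLIVLIFAVLIVM", "RDKESQNEGDK",
    "FLVIAVMLIVFLAIVLIVV", "YDKQSNREGDK",
    "ILVFMVLIAVLFIVLMVILVA")
  stopifnot(nchar(n_dom) == N_DOMAIN_LEN, nchar(c_dom) == C_DOMAIN_LEN)
  helices <- data.frame(
    helix = 1:10,
    domain = rep(c("n_domain", "c_domain"), each = 5),
    start = c(7L, 38L, 69L, 100L, 131L, 12L, 43L, 74L, 104L, 134L),
    end   = c(25L, 56L, 87L, 118L, 149L, 30L, 61L, 92L, 122L, 154L),
    stringsAsFactors = FALSE)
  list(n_domain = n_dom, c_domain = c_dom, helices = helices,
       weak_helix = 3L)
}

#' Default clade table of the generator
#'
#' The 25 clades of the bundled reference cladogram with member counts
#' summing to 473 sequences; the reference canonical clade PIN1 and the
#' noncanonical PIN5, PIN6 and PIN8 carry the published subgroup sample
#' sizes (76, 42, 18 and 15).
#'
#' @return data.frame: `clade`, `type` (canonical / semicanonical /
#'   noncanonical), `size`.
#' @export
default_clades <- function() {
  st <- reference_clade_states()
  size <- stats::setNames(rep(15L, nrow(st)), st$clade)
  size[c("PINF", "PING", "PINH", "PIN11", "PIN2", "PIN3", "PIN9")] <- 16L
  size[c("PIN1", "PIN5", "PIN6", "PIN8")] <- c(76L, 42L, 18L, 15L)
  data.frame(clade = st$clade,
             type = ifelse(st$label == "canonical", "canonical",
                    ifelse(st$label == "semicanonical", "semicanonical",
                           "noncanonical")),
             size = as.integer(size[st$clade]),
             stringsAsFactors = FALSE)
}

#' Generator configuration
#'
#' Defaults are the emulated study conditions: 473 sequences in the 25
#' reference clades; family-wide transmembrane band counts 56 / 49 / 58 /
#' 30 over 312 positions (the remaining 119 positions are background,
#' identity 0.55-0.90); within-clade band counts for the reference
#' canonical clade (174, 53, 11, 39, 19, 16), for noncanonical clades
#' (50, 39, 42, 62, 76, 43) and for semicanonical clades (197, 0, 24,
#' 44, 30, 17); insertions of 1-18 aa between N97/N98 in 15% of
#' N-complete members; noncanonical replacement loops of 32-120 aa;
#' truncation targeting 45% missing data.
#'
#' @param seed Integer seed; the single source of randomness.
#' @param clades data.frame as [default_clades] (columns `clade`,
#'   `type`, `size`).
#' @param family_bands Named counts over 312 positions for the
#'   family-wide bands `b100`, `b99`, `b95`, `b90` (rest = background).
#' @param ref_clade Canonical clade receiving the published within-clade
#'   self-identity structure.
#' @param ref_bands,nc_bands,semi_bands Within-clade band counts
#'   (100%, 95-99, 90-95, 70-90, 50-70, <50), summing to 312.
#' @param insertion_rate,insertion_max Insertion probability (among
#'   members with a complete N-terminus) and maximum length.
#' @param loop_noise Per-residue substitution probability in loops.
#' @param nc_loop_range Length range of noncanonical replacement loops.
#' @param repeat_copies Copies of the HC2 trio in canonical loops.
#' @param l_retention Per-clade retention probability of the ordinary
#'   loop motifs L1-L3.
#' @param trunc_prob,trunc_mean Per-side truncation probability and mean
#'   truncated length (EST-style geometric fragments).
#' @param target_missing,missing_tol Missing-data target for the
#'   312-column alignment and tolerance of the correction pass.
#' @param min_length Sequences shorter than this are redrawn.
#' @param long_branch_multiplier Terminal-branch multiplier of
#'   non-canonical clades in the output tree.
#' @param motifs Motif library ([default_motif_library]).
#' @return List of class `pin_sim_config`.
#' @export
pin_sim_config <- function(seed = 1L,
                           clades = default_clades(),
                           family_bands = c(b100 = 56L, b99 = 49L,
                                            b95 = 58L, b90 = 30L),
                           ref_clade = "PIN1",
                           ref_bands = c(174L, 53L, 11L, 39L, 19L, 16L),
                           nc_bands = c(50L, 39L, 42L, 62L, 76L, 43L),
                           semi_bands = c(197L, 0L, 24L, 44L, 30L, 17L),
                           insertion_rate = 0.15, insertion_max = 18L,
                           loop_noise = 0.02,
                           nc_loop_range = c(32L, 120L),
                           repeat_copies = 4L,
                           l_retention = 0.6,
                           trunc_prob = 0.8, trunc_mean = 120,
                           target_missing = 0.45, missing_tol = 0.005,
                           min_length = 100L,
                           long_branch_multiplier = 5,
                           motifs = default_motif_library()) {
  stopifnot(all(c("clade", "type", "size") %in% names(clades)),
            all(clades$type %in% c("canonical", "semicanonical",
                                   "noncanonical")),
            all(clades$size >= 1))
  tm_total <- N_DOMAIN_LEN + C_DOMAIN_LEN
  if (any(family_bands < 0) || sum(family_bands) > tm_total)
    fail("infeasible family band counts")
  for (b in list(ref_bands, nc_bands, semi_bands))
    if (length(b) != 6 || any(b < 0) || sum(b) != tm_total)
      fail("within-clade band counts must be 6 nonnegative values summing to %d",
           tm_total)
  if (!ref_clade %in% clades$clade[clades$type == "canonical"])
    fail("ref_clade must be a canonical clade")
  structure(list(seed = as.integer(seed), clades = clades,
                 family_bands = family_bands, ref_clade = ref_clade,
                 ref_bands = ref_bands, nc_bands = nc_bands,
                 semi_bands = semi_bands,
                 insertion_rate = insertion_rate,
                 insertion_max = as.integer(insertion_max),
                 loop_noise = loop_noise,
                 nc_loop_range = as.integer(nc_loop_range),
                 repeat_copies = as.integer(repeat_copies),
                 l_retention = l_retention,
                 trunc_prob = trunc_prob, trunc_mean = trunc_mean,
                 target_missing = target_missing,
                 missing_tol = missing_tol,
                 min_length = as.integer(min_length),
                 long_branch_multiplier = long_branch_multiplier,
                 motifs = motifs),
            class = "pin_sim_config")
}

# -- loop assembly -------------------------------------------------------

rand_string <- function(n, pool) paste(sample(pool, n, replace = TRUE),
                                       collapse = "")

# Instantiate a pattern: X -> random residue, alternatives -> one pick.
instantiate_pattern <- function(pattern) {
  cols <- parse_pattern(pattern)
  paste(vapply(cols, function(cl) {
    if (is.null(cl)) sample(AA20, 1)
    else if (length(cl) > 1) sample(cl, 1)
    else cl
  }, ""), collapse = "")
}

# Build a clade's loop template and its motif-presence truth.
build_clade_loop <- function(type, config) {
  lib <- config$motifs
  present <- stats::setNames(rep(FALSE, nrow(lib)), lib$name)
  if (type == "noncanonical") {
    len <- sample(seq(config$nc_loop_range[1], config$nc_loop_range[2]), 1)
    return(list(loop = rand_string(len, c(HYDROPHILIC, "P", "Y", "H", "W")),
                present = present))
  }
  keep <- rep(TRUE, nrow(lib))
  is_l <- is.na(lib$hc_group)
  keep[is_l] <- stats::runif(sum(is_l)) < config$l_retention
  if (type == "semicanonical")
    keep[!is.na(lib$hc_group) & lib$hc_group == "HC3"] <- FALSE
  spacer <- function() rand_string(sample(4:8, 1), HYDROPHILIC)
  parts <- spacer()
  trio <- which(!is.na(lib$hc_group) & lib$hc_group == "HC2")
  for (k in seq_len(nrow(lib))) {
    if (!keep[k]) next
    if (k %in% trio && k != trio[1]) next  # trio handled as a block
    if (k == trio[1]) {
      # the repetitive region is dense: each copy of the trio is one
      # contiguous block, spacers only between copies
      for (cp in seq_len(config$repeat_copies)) {
        blk <- paste(vapply(trio, function(j)
          instantiate_pattern(lib$pattern[j]), ""), collapse = "")
        parts <- c(parts, blk, spacer())
      }
      present[trio] <- TRUE
    } else {
      parts <- c(parts, instantiate_pattern(lib$pattern[k]), spacer())
      present[k] <- TRUE
    }
  }
  list(loop = paste(parts, collapse = ""), present = present)
}

# Per-residue loop noise preserving length.
mutate_loop <- function(loop, rate) {
  if (rate <= 0) return(loop)
  chars <- strsplit(loop, "")[[1]]
  hit <- stats::runif(length(chars)) < rate
  if (any(hit))
    chars[hit] <- vapply(chars[hit], function(ch)
      sample(setdiff(AA20, ch), 1), "")
  paste(chars, collapse = "")
}

# -- transmembrane band machinery ---------------------------------------

# Substitution count realizing identity strictly above `lo` and at most
# `hi` (hi = 1 means "below 1": at least one substitution) at coverage n.
subs_for_band <- function(t, n, lo, hi) {
  if (n <= 0) return(0L)
  k <- round((1 - t) * n)
  kmin <- if (hi >= 1) 1L else max(1L, as.integer(ceiling((1 - hi) * n - 1e-9)))
  kmax <- as.integer(ceiling((1 - lo) * n) - 1L)
  if (kmax < kmin) kmax <- kmin  # band unrepresentable at this coverage
  max(kmin, min(kmax, k))
}

# Within-clade band table: identity interval (lo, hi] per class, in the
# order 100%, 95-99, 90-95, 70-90, 50-70, <50.
CLADE_BAND_BOUNDS <- data.frame(
  lo = c(1, 0.95, 0.90, 0.70, 0.50, 0.25),
  hi = c(1, 0.9999, 0.95, 0.90, 0.70, 0.50))

# Family band bounds keyed by name (background handled separately).
FAMILY_BAND_BOUNDS <- data.frame(
  band = c("b100", "b99", "b95", "b90"),
  lo = c(1, 0.99, 0.95, 0.90),
  hi = c(1, 0.9999, 0.99, 0.95),
  stringsAsFactors = FALSE)

#' Generate a synthetic PIN family
#'
#' @param config A [pin_sim_config].
#' @return List of class `pin_family`: `records` ([pin_records]),
#'   `alignment` (`pin_alignment` over the 312 canonical columns, `?`
#'   where a sequence does not cover a position), `tree` (`phylo`, tips
#'   = clades, terminal branches of non-canonical clades lengthened),
#'   `clade_map` ([clade_map]), `truth` (list: `members`, `clade_types`,
#'   `family_bands`, `clade_bands`, `motif_presence`, `helices`,
#'   `template`, `missing_fraction`) and `config`.
#' @export
generate_family <- function(config) {
  stopifnot(inherits(config, "pin_sim_config"))
  set.seed(config$seed)
  tmpl <- pin_template()
  tm_chars <- c(strsplit(tmpl$n_domain, "")[[1]],
                strsplit(tmpl$c_domain, "")[[1]])
  P <- length(tm_chars)  # 312
  pos_labels <- canonical_positions()
  is_helix <- rep(FALSE, P)
  for (i in seq_len(nrow(tmpl$helices))) {
    off <- if (tmpl$helices$domain[i] == "n_domain") 0L else N_DOMAIN_LEN
    is_helix[(tmpl$helices$start[i]:tmpl$helices$end[i]) + off] <- TRUE
  }
  weak_idx <- with(tmpl$helices[tmpl$helices$helix == tmpl$weak_helix, ],
                   start:end)
  forced <- c(1L,                                        # initiator N1
              (N_DOMAIN_LEN - nchar(N_ANCHOR) + 1L):N_DOMAIN_LEN,  # N anchor
              N_DOMAIN_LEN + seq_len(nchar(C_ANCHOR)),   # C anchor
              N_DOMAIN_LEN + 123L)                       # invariant Y at C123
  forced <- unique(forced)

  cl <- config$clades
  n_members <- sum(cl$size)
  member_clade <- rep(cl$clade, cl$size)
  member_type <- rep(cl$type, cl$size)
  ids <- unlist(lapply(seq_len(nrow(cl)), function(i)
    sprintf("%s_%03d", cl$clade[i], seq_len(cl$size[i]))))

  # clade loop templates and motif truth ---------------------------------
  clade_loops <- list(); motif_truth <- NULL
  for (i in seq_len(nrow(cl))) {
    bl <- build_clade_loop(cl$type[i], config)
    clade_loops[[cl$clade[i]]] <- bl$loop
    motif_truth <- rbind(motif_truth, bl$present)
  }
  rownames(motif_truth) <- cl$clade
  loop_len <- vapply(member_clade, function(cd)
    nchar(clade_loops[[cd]]), 0L)

  # truncation plan ------------------------------------------------------
  geom_cut <- function() stats::rgeom(1, 1 / (config$trunc_mean + 1)) + 1L
  n_cut <- c_cut <- integer(n_members)
  for (m in seq_len(n_members)) {
    Lm <- P + loop_len[m]
    repeat {
      nc <- if (stats::runif(1) < config$trunc_prob) geom_cut() else 0L
      cc <- if (stats::runif(1) < config$trunc_prob) geom_cut() else 0L
      if (Lm - nc - cc >= config$min_length) break
    }
    n_cut[m] <- nc; c_cut[m] <- cc
  }
  cov_fun <- function(nc, cc, ll) {
    # sequence position of each canonical column (no insertion: insertions
    # only occur in members with n_cut == 0, where they do not change
    # which canonical positions survive either cut)
    c((1:N_DOMAIN_LEN) > nc & (1:N_DOMAIN_LEN) <= P + ll - cc,
      (N_DOMAIN_LEN + ll + 1:C_DOMAIN_LEN) > nc &
        (1:C_DOMAIN_LEN) <= C_DOMAIN_LEN - cc)
  }
  cov <- t(vapply(seq_len(n_members), function(m)
    cov_fun(n_cut[m], c_cut[m], loop_len[m]), logical(P)))
  # correction pass toward the target missing fraction
  mf <- 1 - sum(cov) / (n_members * P)
  it <- 0L
  while (abs(mf - config$target_missing) > config$missing_tol &&
         it < 2000L) {
    it <- it + 1L
    m <- sample.int(n_members, 1)
    Lm <- P + loop_len[m]
    delta <- sample(10:40, 1)
    if (mf < config$target_missing) {
      side <- sample(c("n", "c"), 1)
      if (Lm - n_cut[m] - c_cut[m] - delta < config$min_length) next
      if (side == "n") n_cut[m] <- n_cut[m] + delta
      else c_cut[m] <- c_cut[m] + delta
    } else {
      if (n_cut[m] >= c_cut[m]) n_cut[m] <- max(0L, n_cut[m] - delta)
      else c_cut[m] <- max(0L, c_cut[m] - delta)
    }
    cov[m, ] <- cov_fun(n_cut[m], c_cut[m], loop_len[m])
    mf <- 1 - sum(cov) / (n_members * P)
  }

  # insertions (only members with a complete N-terminus) -----------------
  ins_len <- integer(n_members)
  eligible <- which(n_cut == 0L)
  take <- eligible[stats::runif(length(eligible)) < config$insertion_rate]
  ins_len[take] <- sample.int(config$insertion_max, length(take),
                              replace = TRUE)

  # positions visible to profiling: a domain's positions are only
  # recovered when its anchor survives the truncation, so substitutions
  # are planted among those members (the alignment keeps all covered
  # cells; conservation statistics are computed from delineations)
  n_anchor_ok <- n_cut < N_DOMAIN_LEN - nchar(N_ANCHOR) + 1L &
    c_cut <= C_DOMAIN_LEN + loop_len
  c_anchor_ok <- c_cut < C_DOMAIN_LEN - nchar(C_ANCHOR) + 1L &
    n_cut <= N_DOMAIN_LEN + loop_len
  vis <- cov
  vis[, 1:N_DOMAIN_LEN] <- vis[, 1:N_DOMAIN_LEN] & n_anchor_ok
  vis[, N_DOMAIN_LEN + 1:C_DOMAIN_LEN] <-
    vis[, N_DOMAIN_LEN + 1:C_DOMAIN_LEN] & c_anchor_ok

  # family-wide band assignment over the canonical clades ---------------
  tm <- matrix(rep(tm_chars, each = n_members), nrow = n_members)
  canon_members <- which(member_type == "canonical")
  ref_members <- which(member_clade == config$ref_clade)
  fb <- config$family_bands
  if (length(forced) > fb["b100"]) fail("b100 band smaller than forced set")
  helix_pool <- setdiff(which(is_helix), weak_idx)
  band_assign <- rep("bg", P)
  band_assign[forced] <- "b100"
  pick <- function(pool, n) {
    n <- min(n, length(pool))
    if (n <= 0) integer() else pool[sample.int(length(pool), n)]
  }
  # conserved bands sit preferentially on the helices (the helices are
  # the most conserved parts of the transmembrane domains, the weak
  # helix least so among them); near-invariant positions additionally
  # need enough observations for a >99% band to be expressible (one
  # substitution among n covering members), so they prefer well-covered
  # positions - in EST data the termini are thin.
  cov_canon <- colSums(vis[canon_members, , drop = FALSE])
  take <- function(n, prefer) {
    free <- which(band_assign == "bg")
    sel <- pick(intersect(prefer, free), n)
    if (length(sel) < n)
      sel <- c(sel, pick(setdiff(free, sel), n - length(sel)))
    sel
  }
  deep_helix <- helix_pool[cov_canon[helix_pool] >= 120]
  band_assign[take(fb["b100"] - length(forced), helix_pool)] <- "b100"
  band_assign[take(fb["b90"], weak_idx)] <- "b90"
  band_assign[take(fb["b99"], deep_helix)] <- "b99"
  band_assign[take(fb["b95"], helix_pool)] <- "b95"
  t_target <- rep(NA_real_, P)
  t_target[band_assign == "b100"] <- 1
  t_target[band_assign == "b99"] <- stats::runif(sum(band_assign == "b99"),
                                                 0.991, 0.999)
  t_target[band_assign == "b95"] <- stats::runif(sum(band_assign == "b95"),
                                                 0.951, 0.989)
  t_target[band_assign == "b90"] <- stats::runif(sum(band_assign == "b90"),
                                                 0.901, 0.949)
  t_target[band_assign == "bg"] <- stats::runif(sum(band_assign == "bg"),
                                                0.55, 0.90)

  # reference-clade within-clade classes, matched under s <= k ----------
  ref_class <- rep(NA_integer_, P)  # 1..6 over CLADE_BAND_BOUNDS rows
  k_expect <- (1 - t_target) * length(canon_members)
  ord_pos <- order(k_expect, stats::runif(P))        # ascending demand room
  demands <- rep(seq_len(6), times = config$ref_bands)  # class per position
  ref_class[ord_pos] <- demands                      # low k -> high identity
  alt_pool <- function(p) {
    pool <- if (is_helix[p]) HYDROPHOBIC else POLAR
    setdiff(pool, tm_chars[p])
  }
  plant <- function(members, p, count, block_clades = NULL) {
    # substitute `count` members at position p; block clades first
    if (count <= 0 || !length(members)) return(invisible())
    remaining <- count
    picked <- integer()
    if (!is.null(block_clades)) {
      for (cd in block_clades) {
        cm <- members[member_clade[members] == cd]
        if (length(cm) > 0 && length(cm) <= remaining) {
          res <- sample(alt_pool(p), 1)
          tm[cm, p] <<- res
          picked <- c(picked, cm)
          remaining <- remaining - length(cm)
        }
        if (remaining <= 0) break
      }
    }
    left <- setdiff(members, picked)
    if (remaining > 0 && length(left)) {
      scatter <- if (remaining >= length(left)) left
                 else left[sample.int(length(left), remaining)]
      pool <- alt_pool(p)
      tm[scatter, p] <<- sample(pool, length(scatter), replace = TRUE)
    }
    invisible()
  }
  fam_bounds <- stats::setNames(
    split(FAMILY_BAND_BOUNDS[, c("lo", "hi")],
          seq_len(nrow(FAMILY_BAND_BOUNDS))), FAMILY_BAND_BOUNDS$band)
  nonref_clades <- setdiff(cl$clade[cl$type == "canonical"],
                           config$ref_clade)
  for (p in seq_len(P)) {
    if (band_assign[p] == "b100") next
    cm <- canon_members[vis[canon_members, p]]
    n_cov <- length(cm)
    if (n_cov == 0) next
    k <- if (band_assign[p] == "bg")
      max(1L, min(n_cov, round((1 - t_target[p]) * n_cov)))
    else {
      b <- fam_bounds[[band_assign[p]]]
      subs_for_band(t_target[p], n_cov, b$lo, b$hi)
    }
    # reference-clade share
    rm_ <- intersect(cm, ref_members)
    rb <- CLADE_BAND_BOUNDS[ref_class[p], ]
    s <- if (ref_class[p] == 1L || length(rm_) == 0) 0L
         else subs_for_band(stats::runif(1, rb$lo + 0.001, rb$hi),
                            length(rm_), rb$lo, rb$hi)
    s <- min(s, k, length(rm_))
    s <- max(s, k - (n_cov - length(rm_)))  # others must absorb k - s
    if (s > 0) plant(rm_, p, s)
    plant(setdiff(cm, rm_), p, k - s,
          block_clades = sample(nonref_clades))
  }

  # within-clade divergence of noncanonical / semicanonical clades ------
  clade_bands <- list()
  fam_cons <- which(band_assign %in% c("b100", "b99"))
  for (i in which(cl$type != "canonical")) {
    cd <- cl$clade[i]
    counts <- if (cl$type[i] == "noncanonical") config$nc_bands
              else config$semi_bands
    cls <- rep(NA_integer_, P)
    inv_pool <- setdiff(fam_cons, forced)
    inv <- c(forced, pick(inv_pool, counts[1] - length(forced)))
    if (length(inv) < counts[1])
      inv <- c(inv, pick(setdiff(seq_len(P), inv), counts[1] - length(inv)))
    cls[inv] <- 1L
    rest <- sample(setdiff(seq_len(P), inv))
    cls[rest] <- rep(2:6, times = counts[2:6])
    members <- which(member_clade == cd)
    for (p in seq_len(P)) {
      if (cls[p] == 1L) next
      cm <- members[vis[members, p]]
      if (!length(cm)) next
      b <- CLADE_BAND_BOUNDS[cls[p], ]
      t_c <- stats::runif(1, b$lo + 0.001, b$hi)
      s <- subs_for_band(t_c, length(cm), b$lo, b$hi)
      plant(cm, p, s)
    }
    clade_bands[[cd]] <- cls
  }
  # reference clade class table is truth too
  clade_bands[[config$ref_clade]] <- ref_class

  # assemble sequences ----------------------------------------------------
  residues <- character(n_members)
  for (m in seq_len(n_members)) {
    nd <- tm[m, 1:N_DOMAIN_LEN]
    if (ins_len[m] > 0) {
      ins <- sample(HYDROPHILIC, ins_len[m], replace = TRUE)
      nd <- c(nd[1:N_INSERTION_AFTER], ins,
              nd[(N_INSERTION_AFTER + 1L):N_DOMAIN_LEN])
    }
    loop <- mutate_loop(clade_loops[[member_clade[m]]], config$loop_noise)
    full <- paste0(paste(nd, collapse = ""), loop,
                   paste(tm[m, (N_DOMAIN_LEN + 1L):P], collapse = ""))
    Lm <- nchar(full)
    residues[m] <- substr(full, n_cut[m] + 1L, Lm - c_cut[m])
  }
  records <- pin_records(ids, residues,
                         n_complete = n_cut == 0L,
                         c_complete = c_cut == 0L)

  # alignment over the 312 canonical columns ----------------------------
  aln <- tm
  aln[!cov] <- "?"
  aln_strings <- apply(aln, 1, paste, collapse = "")
  alignment <- as_alignment(aln_strings, ids)

  # clade tree ------------------------------------------------------------
  tree <- if (setequal(cl$clade, reference_clade_states()$clade))
    reference_cladogram()
  else ape::rtree(nrow(cl), tip.label = sample(cl$clade), br = NULL)
  tree$edge.length <- rep(0.1, nrow(tree$edge))
  term <- match(seq_len(ape::Ntip(tree)), tree$edge[, 2])
  lb <- cl$clade[cl$type != "canonical"]
  tree$edge.length[term[match(lb, tree$tip.label)]] <-
    0.1 * config$long_branch_multiplier

  cmap <- clade_map(stats::setNames(member_clade, ids),
                    stats::setNames(
                      reference_clade_states()$lineage[
                        match(cl$clade, reference_clade_states()$clade)],
                      cl$clade))
  if (anyNA(cmap$clade_to_lineage))
    cmap$clade_to_lineage[is.na(cmap$clade_to_lineage)] <- "other"

  # helix truth in domain coordinates (N helices 4-5 shift by insertion)
  helix_truth <- tmpl$helices

  members <- data.frame(
    id = ids, clade = member_clade, type = member_type,
    loop_len = loop_len, ins_len = ins_len,
    n_cut = n_cut, c_cut = c_cut,
    n_complete = n_cut == 0L, c_complete = c_cut == 0L,
    n_anchor_ok = n_cut < N_DOMAIN_LEN - nchar(N_ANCHOR) + 1L &
      c_cut <= C_DOMAIN_LEN + loop_len,
    c_anchor_ok = c_cut < C_DOMAIN_LEN - nchar(C_ANCHOR) + 1L &
      n_cut <= N_DOMAIN_LEN + loop_len,
    stringsAsFactors = FALSE)

  structure(list(
    records = records, alignment = alignment, tree = tree,
    clade_map = cmap,
    truth = list(
      members = members,
      clade_types = stats::setNames(cl$type, cl$clade),
      family_bands = data.frame(position = pos_labels, band = band_assign,
                                target_identity = t_target,
                                is_helix = is_helix,
                                stringsAsFactors = FALSE),
      clade_bands = clade_bands,
      motif_presence = motif_truth,
      helices = helix_truth,
      template = tmpl,
      missing_fraction = mf),
    config = config), class = "pin_family")
}
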