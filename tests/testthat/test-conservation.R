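# Conservation profiles, consensus, bands, alignment statistics.

mk_parts <- function(seqs) {
  tm <- pin_template()
  set.seed(11)
  loop <- rand_aa(160)
  recs <- pin_records(paste0("s", seq_along(seqs)),
                      vapply(seqs, function(nd)
                        paste0(nd, loop, tm$c_domain), ""))
  delineate_all(recs)
}

test_that("profiles count frequencies per canonical position", {
  tm <- pin_template()
  p1 <- build_profile(mk_parts(tm$n_domain), "n_domain")
  expect_equal(p1$positions, canonical_positions("n_domain"))
  expect_true(all(p1$modal_identity[p1$coverage > 0] == 1))

  nd2 <- tm$n_domain
  substr(nd2, 50, 50) <- if (substr(nd2, 50, 50) == "A") "G" else "A"
  p2 <- build_profile(mk_parts(c(tm$n_domain, nd2)), "n_domain")
  expect_equal(unname(p2$modal_identity[50]), 0.5)
  expect_true(all(p2$modal_identity[-50] == 1))
  # frequencies sum to 1 at covered positions
  expect_true(all(abs(rowSums(p2$freq[p2$coverage > 0, ]) - 1) < 1e-12))
})

test_that("consensus respects the identity floor", {
  tm <- pin_template()
  p1 <- build_profile(mk_parts(rep(tm$n_domain, 3)), "n_domain")
  expect_equal(consensus(p1), tm$n_domain)

  # 100 sequences, 49 substituted at position 10: modal identity 0.51;
  # at 51 substitutions to one alternative the alternative wins at 0.51
  seqs <- rep(tm$n_domain, 100)
  for (i in 1:49) substr(seqs[i], 10, 10) <- "W"
  p2 <- build_profile(mk_parts(seqs), "n_domain")
  expect_equal(unname(p2$modal_identity[10]), 0.51)
  expect_equal(substr(consensus(p2, floor = 0.52), 10, 10), ".")
  expect_equal(substr(consensus(p2, floor = 0.51), 10, 10),
               substr(tm$n_domain, 10, 10))
})

test_that("band counts partition covered positions and match a hand tally", {
  tm <- pin_template()
  p_all <- build_profile(mk_parts(rep(tm$n_domain, 12)), "n_domain")
  bc <- band_counts(p_all, band_scheme("self"))
  expect_equal(sum(bc$count), 158)
  expect_equal(bc$count[bc$label == "100%"], 158)

  # hand-planted substitution counts in 10 sequences (scattered over
  # three alternatives so the template stays modal).  Bands are open at
  # the lower edge: identity 0.9 falls in 70-90%, 0.5 in <50%.
  seqs <- rep(tm$n_domain, 10)
  plant <- function(seqs, pos, k) {
    for (i in seq_len(k))
      substr(seqs[i], pos, pos) <- c("W", "Y", "H")[i %% 3 + 1]
    seqs
  }
  seqs <- plant(seqs, 5, 1); seqs <- plant(seqs, 20, 2)
  seqs <- plant(seqs, 30, 5); seqs <- plant(seqs, 40, 6)
  bc2 <- band_counts(build_profile(mk_parts(seqs), "n_domain"),
                     band_scheme("self"))
  tally <- c("100%" = 154L, "95-99%" = 0L, "90-95%" = 0L, "70-90%" = 2L,
             "50-70%" = 0L, "<50%" = 2L)
  expect_equal(stats::setNames(bc2$count, bc2$label), tally[bc2$label])
})

test_that("the complete canonical coordinate model spans 312 positions", {
  fam <- clean_family()
  parts <- delineate_all(fam$records)
  canon <- parts[fam$truth$members$id[fam$truth$members$type == "canonical"]]
  prof <- combine_profiles(build_profile(canon, "n_domain"),
                           build_profile(canon, "c_domain"))
  bc <- band_counts(prof, band_scheme("self"), min_coverage = 10)
  expect_equal(sum(bc$count) + attr(bc, "insufficient"), 312)
  expect_equal(attr(bc, "insufficient"), 0)  # untruncated family
})

test_that("cross-conservation counts planted overlap", {
  tm <- pin_template()
  ref_profile <- build_profile(mk_parts(rep(tm$n_domain, 12)), "n_domain")
  ref <- conserved_positions(ref_profile, 0.90)
  expect_equal(cross_conservation(ref, ref_profile), length(ref))

  # query family conserved everywhere except 6 planted positions
  seqs <- rep(tm$n_domain, 12)
  drop_pos <- c(3, 17, 55, 90, 120, 150)
  for (pos in drop_pos)
    for (i in 1:6) substr(seqs[i], pos, pos) <- c("W", "Y", "H")[i %% 3 + 1]
  qp <- build_profile(mk_parts(seqs), "n_domain")
  expect_equal(cross_conservation(ref, qp),
               length(ref) - length(drop_pos))

  # family randomized at N1..N10 (anchors intact): nothing conserved there
  low_seqs <- vapply(1:6, function(i) {
    s <- tm$n_domain
    substr(s, 1, 10) <- rand_aa(10)
    s
  }, "")
  low <- build_profile(mk_parts(low_seqs), "n_domain")
  expect_equal(cross_conservation(paste0("N", 1:10), low, 0.90), 0)
  expect_error(cross_conservation("C1", qp), "coordinate mismatch")
})

test_that("alignment statistics match the per-column definition", {
  mk_aln <- function(rows) pinarch:::as_alignment(rows, paste0("r", seq_along(rows)))
  a1 <- mk_aln(c("AC", "AC", "AG", "AG"))
  s1 <- alignment_stats(a1)
  expect_equal(s1$parsimony_informative, 1)  # "AAAA" column not informative

  a2 <- mk_aln(c("??", "--", "?-"))
  s2 <- alignment_stats(a2)
  expect_equal(s2$missing_fraction, 1)
  expect_equal(s2$parsimony_informative, 0)

  set.seed(12)
  for (rep in 1:25) {
    rows <- replicate(6, paste(sample(c("A", "C", "G", "T", "-", "?"), 8,
                                      replace = TRUE), collapse = ""))
    aln <- mk_aln(rows)
    st <- alignment_stats(aln)
    expect_equal(st$parsimony_informative,
                 sum(vapply(seq_len(ncol(aln)), function(j)
                   oracle_informative(aln[, j]), TRUE)))
    expect_equal(st$missing_fraction, mean(aln %in% c("-", "?")))
  }
})
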