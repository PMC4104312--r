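# Anchor search and domain delineation.

test_that("find_anchor locates exact and variant anchors", {
  seq <- paste0(rand_aa(140), "FLFEFRAAR", rand_aa(40))
  hit <- find_anchor(seq, "FLFEFRAAR", max_subs = 0)
  expect_equal(hit$start, 141)
  expect_equal(hit$substitutions, 0)

  polyA <- strrep("A", 200)
  expect_null(find_anchor(polyA, "FLFEFRAAR", max_subs = 2))

  set.seed(2)
  seq2 <- paste0(rand_aa(100), "FLFEYRAAR", rand_aa(50))
  hit2 <- find_anchor(seq2, "FLFEFRAAR", max_subs = 2)
  orc <- oracle_anchor(seq2, "FLFEFRAAR", max_subs = 2)
  expect_equal(hit2$substitutions, 1)
  expect_equal(hit2[c("start", "end", "substitutions")],
               orc[c("start", "end", "substitutions")])
})

test_that("anchor search equals the exhaustive window scan", {
  set.seed(7)
  for (i in 1:500) {
    L <- sample(20:250, 1)
    seq <- rand_aa(L)
    motif <- if (i %% 2) "FLFEFRAAR" else "VWRKLIRN"
    expect_identical(
      find_anchor(seq, motif, max_subs = 3),
      oracle_anchor(seq, motif, max_subs = 3))
  }
})

make_canonical <- function(loop_len = 180) {
  tm <- pin_template()
  set.seed(99)
  pin_records("syn1", paste0(tm$n_domain, rand_aa(loop_len), tm$c_domain))
}

test_that("delineation recovers constructed canonical boundaries", {
  rec <- make_canonical(180)
  p <- delineate(rec[1, ])
  expect_equal(nchar(p$n_domain), 158)
  expect_equal(nchar(p$loop), 180)
  expect_equal(nchar(p$c_domain), 154)
  expect_false(any(p$flags))
  expect_equal(p$n_coord_map[1], "N1")
  expect_equal(p$n_coord_map[158], "N158")
  expect_equal(p$c_coord_map[1], "C1")
  expect_equal(p$c_coord_map[154], "C154")
  # concatenation identity
  expect_identical(paste0(p$n_domain, p$loop, p$c_domain), p$seq)
})

test_that("missing anchors set flags instead of failing", {
  tm <- pin_template()
  set.seed(3)
  no_c <- pin_records("x", paste0(tm$n_domain, rand_aa(60)))
  p <- delineate(no_c[1, ])
  expect_true(p$flags[["no_c_anchor"]])
  expect_true(is.na(p$c_domain))
  expect_true(is.na(p$loop))
  expect_equal(loop_length_class(p), "unknown")

  # C-anchor before N-anchor: scrambled input, both rejected
  scram <- pin_records("y", paste0("VWRKLIRN", rand_aa(120), "FLFEFRAAR",
                                   rand_aa(30)))
  ps <- delineate(scram[1, ])
  expect_true(ps$flags[["no_n_anchor"]] && ps$flags[["no_c_anchor"]])
})

test_that("N-domain insertions are labelled between N97 and N98", {
  tm <- pin_template()
  set.seed(4)
  ins <- strrep("Q", 18)
  nd <- paste0(substr(tm$n_domain, 1, 97), ins, substr(tm$n_domain, 98, 158))
  rec <- pin_records("ins1", paste0(nd, rand_aa(170), tm$c_domain))
  p <- delineate(rec[1, ])
  expect_equal(nchar(p$n_domain), 176)
  expect_equal(p$n_coord_map[97], "N97")
  expect_equal(p$n_coord_map[98], "N97+1")
  expect_equal(p$n_coord_map[115], "N97+18")
  expect_equal(p$n_coord_map[116], "N98")
  expect_equal(p$n_coord_map[176], "N158")
  expect_false(p$flags[["atypical_n"]])
})

test_that("partial sequences are labelled backwards from the anchor", {
  tm <- pin_template()
  set.seed(6)
  trunc <- substr(paste0(tm$n_domain, rand_aa(170), tm$c_domain), 41, 1e6)
  rec <- pin_records("p1", trunc, n_complete = FALSE)
  p <- delineate(rec[1, ])
  expect_equal(nchar(p$n_domain), 118)
  expect_equal(p$n_coord_map[118], "N158")
  expect_equal(p$n_coord_map[1], "N41")
})

test_that("loop length classes follow the stated ranges", {
  tm <- pin_template()
  set.seed(8)
  mk <- function(len) delineate(
    pin_records("z", paste0(tm$n_domain, rand_aa(len), tm$c_domain))[1, ])
  expect_equal(loop_length_class(mk(32)), "short")
  expect_equal(loop_length_class(mk(120)), "short")
  expect_equal(loop_length_class(mk(135)), "intermediate")
  expect_equal(loop_length_class(mk(151)), "long")
})

test_that("concatenation identity holds across a whole generated family", {
  parts <- default_partitions()
  full <- Filter(function(p) !is.na(p$n_domain) && !is.na(p$c_domain), parts)
  expect_gt(length(full), 100)
  for (p in full)
    expect_identical(paste0(p$n_domain, p$loop, p$c_domain), p$seq)
})

test_that("delineation recovers generator boundaries at >= 99% of sequences", {
  fam <- default_family()
  parts <- default_partitions()
  tr <- fam$truth$members
  ok <- 0L; tot <- 0L
  for (i in seq_len(nrow(tr))) {
    if (!tr$n_anchor_ok[i] || !tr$c_anchor_ok[i]) next
    tot <- tot + 1L
    p <- parts[[tr$id[i]]]
    n_true <- min(158L + tr$ins_len[i], 158L + tr$ins_len[i] - tr$n_cut[i])
    c_true <- min(154L, 154L - tr$c_cut[i])
    if (!is.na(p$n_domain) && !is.na(p$c_domain) &&
        nchar(p$n_domain) == n_true && nchar(p$c_domain) == c_true)
      ok <- ok + 1L
  }
  expect_gt(tot, 200)
  expect_gte(ok / tot, 0.99)
})
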