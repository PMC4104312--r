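# Ordered loop-motif scanning, repeats, clade matrices.

toy_lib <- function() motif_library(
  name = c("m1", "m2", "m3"),
  pattern = c("GKEVDA", "TPRXS[SN]", "WEQNKE"),
  rank = 1:3, phospho = c(FALSE, TRUE, FALSE))

test_that("motif libraries validate ranks and patterns", {
  expect_error(motif_library(c("a", "b"), c("AAAA", "CCCC"), rank = c(2, 2)),
               "strictly increasing")
  expect_error(motif_library("a", "AAA"), "fewer than 4")
  expect_error(motif_library("a", "AA[ST"), "unclosed")
  lib <- read_motif_library(system.file("extdata", "pin_motifs.tsv",
                                        package = "pinarch"))
  expect_identical(lib, default_motif_library())
})

test_that("planted motifs are all present in rank order", {
  set.seed(21)
  lib <- toy_lib()
  loop <- paste0("SSRN", "GKEVDA", "DDKE", "TPRLSS", "RRQE", "WEQNKE", "KDS")
  sc <- scan_loop(loop, lib)
  expect_equal(sc$state, rep("present", 3))
  expect_true(all(diff(sc$start) > 0))
  expect_true(all(sc$start[-1] > sc$end[-3]))  # non-overlapping
  expect_equal(sc$identity, rep(1, 3))
})

test_that("wildcards are excluded from identity denominators", {
  lib <- motif_library("tpr", "TPRXS[SN]", rank = 1)
  sc <- scan_loop(paste0("KDSE", "TPRASS", "QQDD"), lib)
  expect_equal(sc$state, "present")
  expect_equal(sc$identity, 1)  # X column (A here) not counted
  sc2 <- scan_loop(paste0("KDSE", "TPRASN", "QQDD"), lib)
  expect_equal(sc2$identity, 1)  # [SN] accepts either
})

test_that("assignment equals the exhaustive order-respecting oracle", {
  set.seed(22)
  lib <- toy_lib()
  pats <- lib$pattern
  for (i in 1:30) {
    loop <- rand_aa(sample(25:60, 1))
    sc <- scan_loop(loop, lib)
    got <- sum(sc$identity, na.rm = TRUE)
    expect_equal(got, oracle_assignment(loop, pats), tolerance = 1e-6)
    # invariant: windows non-overlapping, ordered by rank
    w <- sc[!is.na(sc$start), ]
    if (nrow(w) > 1) {
      expect_true(all(diff(w$start) > 0))
      expect_true(all(w$start[-1] > w$end[-nrow(w)]))
    }
  }
})

test_that("shuffling a loop never increases mean motif presence", {
  set.seed(23)
  lib <- default_motif_library()
  fam <- clean_family()
  parts <- delineate_all(fam$records[fam$records$id == "CanA_001", ])
  loop <- parts[[1]]$loop
  planted <- sum(scan_loop(loop, lib)$state == "present")
  chars <- strsplit(loop, "")[[1]]
  shuffled <- vapply(1:100, function(i) {
    sl <- paste(sample(chars), collapse = "")
    sum(scan_loop(sl, lib)$state == "present")
  }, 0)
  expect_lte(mean(shuffled), planted)
})

test_that("repeat units are counted greedily with partial trailing copies", {
  set.seed(24)
  unit <- motif_library(c("r1", "r2", "r3"),
                        c("TPRXS[SN]", "SNAWGE", "DKLYGQ"), rank = 1:3)
  blk <- function() paste0("TPRLSS", "SNAWGE", "DKLYGQ")
  loop4 <- paste0("KDE", blk(), "QD", blk(), "ES", blk(), "RN", blk(), "KD")
  expect_equal(detect_repeats(loop4, unit)$count, 4)
  expect_equal(detect_repeats(rand_aa(80), unit)$count, 0)

  loop_half <- paste0("KDE", blk(), "QD", blk(), "ES", "TPRLSS", "KDSSEE")
  r <- detect_repeats(loop_half, unit)
  expect_equal(r$count, 2)
  expect_false(is.null(r$partial_span))
})

test_that("clade matrix takes strict-majority states", {
  lib <- toy_lib()
  mk_scan <- function(states) data.frame(
    motif = lib$name, rank = lib$rank, start = NA_integer_,
    end = NA_integer_, identity = NA_real_, similarity = NA_real_,
    state = states, stringsAsFactors = FALSE)
  scans <- list(
    a1 = mk_scan(c("present", "present", "present")),
    a2 = mk_scan(c("present", "present", "absent")),
    a3 = mk_scan(c("present", "absent", "divergent")),
    a4 = mk_scan(c("present", "divergent", "no_data")),
    a5 = mk_scan(c("present", "present", "no_data")))
  cm <- clade_map(stats::setNames(rep("K", 5), paste0("a", 1:5)))
  mm <- motif_matrix(scans, cm)
  expect_equal(unname(mm["K", "m1"]), "present")     # 5/5
  expect_equal(unname(mm["K", "m2"]), "present")     # 3/5 strict majority
  expect_equal(unname(mm["K", "m3"]), "no_consensus")# 1/1/1 of 3 with data

  # 2 present of 4 informative members is not a majority
  scans2 <- list(
    b1 = mk_scan(c("present", "present", "present")),
    b2 = mk_scan(c("present", "present", "present")),
    b3 = mk_scan(c("absent", "absent", "absent")),
    b4 = mk_scan(c("divergent", "divergent", "divergent")))
  cm2 <- clade_map(stats::setNames(rep("K", 4), paste0("b", 1:4)))
  expect_equal(unname(motif_matrix(scans2, cm2)["K", "m1"]), "no_consensus")

  expect_warning(
    motif_matrix(c(scans2, list(zz = mk_scan(rep("present", 3)))), cm2),
    "without a clade")
})

test_that("generator motif-loss patterns are recovered clade by clade", {
  fam <- clean_family()
  parts <- delineate_all(fam$records)
  lib <- fam$config$motifs
  scans <- list()
  for (p in parts)
    if (!is.na(p$loop) && nzchar(p$loop))
      scans[[p$id]] <- scan_loop(p$loop, lib)
  mm <- motif_matrix(scans, fam$clade_map)
  truth <- fam$truth$motif_presence
  agree <- 0L; tot <- 0L
  for (cd in rownames(truth)) {
    for (mt in colnames(truth)) {
      tot <- tot + 1L
      want <- if (truth[cd, mt]) "present" else "absent"
      if (mm[cd, mt] == want) agree <- agree + 1L
    }
  }
  expect_gte(agree / tot, 0.95)
})
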