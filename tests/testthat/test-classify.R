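# HC scoring and canonical / semicanonical / noncanonical labels.

instantiate <- function(pattern) {
  cols <- pinarch:::parse_pattern(pattern)
  paste(vapply(cols, function(cl) {
    if (is.null(cl)) "A" else cl[1]
  }, ""), collapse = "")
}

test_that("a loop built from the consensus scores identity 1", {
  set.seed(31)
  cons <- hc_consensus_from_library(default_motif_library())
  loop <- paste0(rand_aa(8), instantiate(cons$HC1), rand_aa(10),
                 instantiate(cons$HC2), rand_aa(12),
                 instantiate(cons$HC3), rand_aa(9),
                 instantiate(cons$HC4), rand_aa(8))
  sc <- hc_score(loop, cons)
  expect_equal(sc$identity, 1)
  expect_equal(sort(sc$regions_located), paste0("HC", 1:4))
  expect_equal(classify_protein(sc)$label, "canonical")
})

test_that("short fragments give insufficient data, not a label", {
  cons <- hc_consensus_from_library(default_motif_library())
  # fragment covering only HC1 (12 of 54 consensus columns observable)
  frag <- instantiate(cons$HC1)
  sc <- hc_score(frag, cons)
  expect_equal(classify_protein(sc)$label, "insufficient_data")
  expect_gte(sc$per_region$identity[1], 0.9)
})

test_that("classification thresholds are inclusive and rule-faithful", {
  mk_scores <- function(id_r, located, sim_r = id_r) {
    n_inf <- c(11, 17, 11, 12)  # informative columns of the default regions
    list(identity = sum(id_r * n_inf) / sum(n_inf),
         similarity = sum(sim_r * n_inf) / sum(n_inf),
         regions_located = paste0("HC", 1:4)[located],
         per_region = data.frame(region = paste0("HC", 1:4),
                                 start = c(1, 20, 50, 80),
                                 identity = id_r, similarity = sim_r,
                                 located = located),
         loop_len = 180, total_cols = 54)
  }
  # identity 0.67, all regions located -> canonical
  expect_equal(classify_protein(mk_scores(rep(0.67, 4),
                                          rep(TRUE, 4)))$label, "canonical")
  # identity exactly 0.50, similarity 0.30 -> canonical (inclusive)
  expect_equal(classify_protein(mk_scores(rep(0.50, 4), rep(TRUE, 4),
                                          rep(0.30, 4)))$label, "canonical")
  # HC1, HC2 pass at 0.8; HC3, HC4 unlocated with full loop -> semicanonical
  expect_equal(classify_protein(mk_scores(c(0.8, 0.8, 0.1, 0.1),
                                          c(TRUE, TRUE, FALSE, FALSE)))$label,
               "semicanonical")
  # nothing located -> noncanonical
  expect_equal(classify_protein(mk_scores(rep(0.1, 4),
                                          rep(FALSE, 4)))$label,
               "noncanonical")

  # monotonicity: raising identity never turns canonical into noncanonical
  labels <- vapply(seq(0.1, 1, by = 0.05), function(idv)
    classify_protein(mk_scores(rep(idv, 4), rep(TRUE, 4)))$label, "")
  first_can <- match("canonical", labels)
  expect_true(all(labels[seq_along(labels) >= first_can] == "canonical"))
})

test_that("pooled identity of a shuffled loop equals the exhaustive oracle", {
  set.seed(32)
  # equal-width regions without wildcards, so the pooled identity is
  # proportional to the plain sum the oracle maximizes
  cons <- hc_consensus("NKDLHMFV", "TPRESSDN", "YSLQESNP", "WEQNKEDS")
  chars <- strsplit(paste0(cons$HC1, cons$HC2, cons$HC3, cons$HC4,
                           rand_aa(20)), "")[[1]]
  for (i in 1:5) {
    loop <- paste(sample(chars), collapse = "")
    sc <- hc_score(loop, cons)
    want <- oracle_assignment(loop, unlist(unclass(cons))) / 4
    expect_equal(sc$identity, want, tolerance = 1e-6)
  }
})

test_that("clade classification follows the 90% / clear-majority rule", {
  expect_equal(classify_clade(rep(c("canonical", "noncanonical"),
                                  c(9, 1))), "canonical")
  expect_equal(classify_clade("canonical"), "canonical")
  expect_equal(classify_clade(rep(c("canonical", "noncanonical"),
                                  c(17, 3))), "mixed")
  expect_equal(classify_clade(rep(c("noncanonical", "semicanonical",
                                    "canonical"), c(10, 8, 2))),
               "noncanonical")  # semicanonical counts on that side
  expect_equal(classify_clade(c("canonical", "noncanonical")), "mixed")
  expect_equal(classify_clade(rep("insufficient_data", 5)), "insufficient")

  set.seed(33)
  labs <- rep(c("canonical", "semicanonical", "noncanonical",
                "insufficient_data"), c(12, 2, 3, 4))
  base <- classify_clade(labs)
  for (i in 1:10)
    expect_equal(classify_clade(sample(labs)), base)  # permutation invariant
})

test_that("generator structural labels are recovered at >= 95% accuracy", {
  fam <- default_family()
  parts <- default_partitions()
  cons <- hc_consensus_from_library(fam$config$motifs)
  cls <- classify_all(parts, cons)
  truth <- stats::setNames(fam$truth$members$type, fam$truth$members$id)
  informative <- cls$label != "insufficient_data"
  expect_gt(sum(informative), 200)
  acc <- mean(cls$label[informative] == truth[cls$id[informative]])
  expect_gte(acc, 0.95)
})
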