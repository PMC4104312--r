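# The synthetic-family generator: determinism, planted structure.

test_that("identical configs give identical output", {
  cfg <- pin_sim_config(seed = 77, clades = small_clades(),
                       ref_clade = "CanA")
  f1 <- generate_family(cfg)
  f2 <- generate_family(cfg)
  expect_identical(f1$records, f2$records)
  expect_identical(unclass(f1$alignment), unclass(f2$alignment))
  expect_identical(f1$truth$members, f2$truth$members)
})

test_that("zero substitution probability reproduces the template exactly", {
  clades <- data.frame(clade = c("OnlyA", "OnlyB"), type = "canonical",
                       size = c(6L, 6L), stringsAsFactors = FALSE)
  cfg <- pin_sim_config(seed = 5, clades = clades, ref_clade = "OnlyA",
                        family_bands = c(b100 = 312L, b99 = 0L,
                                         b95 = 0L, b90 = 0L),
                        ref_bands = c(312L, 0L, 0L, 0L, 0L, 0L),
                        loop_noise = 0, insertion_rate = 0,
                        trunc_prob = 0, target_missing = 0,
                        missing_tol = 1)
  fam <- generate_family(cfg)
  tm <- pin_template()
  for (cd in clades$clade) {
    members <- fam$records$residues[grepl(cd, fam$records$id)]
    expect_length(unique(members), 1)  # identical within a clade
    expect_true(startsWith(members[1], tm$n_domain))
    expect_true(endsWith(members[1], tm$c_domain))
  }
})

test_that("configured band fractions and missing data are realized", {
  fam <- default_family()
  expect_equal(nrow(fam$records), 473)
  expect_lt(abs(fam$truth$missing_fraction - 0.45), 0.03)
  st <- alignment_stats(fam$alignment)
  expect_equal(st$n_rows, 473)
  expect_lt(abs(st$missing_fraction - 0.45), 0.03)

  # realized family-wide band fractions within +/- 0.05 of configured
  parts <- default_partitions()
  canon <- fam$truth$members$id[fam$truth$members$type == "canonical"]
  prof <- combine_profiles(
    build_profile(parts[names(parts) %in% canon], "n_domain"),
    build_profile(parts[names(parts) %in% canon], "c_domain"))
  bands <- pinarch:::band_of(prof$modal_identity, band_scheme("cross"))
  realized <- table(bands) / 312
  cfg_bands <- fam$config$family_bands / 312
  expect_lt(abs(realized[["100%"]] - cfg_bands[["b100"]]), 0.05)
  expect_lt(abs(realized[[">99%"]] - cfg_bands[["b99"]]), 0.05)
  expect_lt(abs(realized[[">95%"]] - cfg_bands[["b95"]]), 0.05)
  expect_lt(abs(realized[[">90%"]] - cfg_bands[["b90"]]), 0.05)

  # recovered modal identities track the generator targets closely
  tt <- fam$truth$family_bands$target_identity
  covered <- prof$coverage >= 30
  expect_gte(mean(abs(prof$modal_identity[covered] - tt[covered]) <= 0.03),
             0.99)
})

test_that("planted invariants land in the 100% band", {
  fam <- default_family()
  parts <- default_partitions()
  canon <- fam$truth$members$id[fam$truth$members$type == "canonical"]
  cprof <- build_profile(parts[names(parts) %in% canon], "c_domain")
  i <- match("C123", cprof$positions)
  expect_equal(cprof$modal_residue[i], "Y")   # the tyrosine at C123
  expect_equal(cprof$modal_identity[i], 1)
  # and in every noncanonical clade too (it is invariant in all PINs)
  for (cd in names(fam$truth$clade_types)[
      fam$truth$clade_types == "noncanonical"]) {
    ids <- fam$truth$members$id[fam$truth$members$clade == cd]
    qp <- build_profile(parts[names(parts) %in% ids], "c_domain")
    expect_equal(qp$modal_identity[match("C123", qp$positions)], 1)
  }
})

test_that("within-clade self-identity mirrors the configured tables", {
  fam <- default_family()
  parts <- default_partitions()
  self_prof <- function(cd) {
    ids <- fam$truth$members$id[fam$truth$members$clade == cd]
    pp <- parts[names(parts) %in% ids]
    combine_profiles(build_profile(pp, "n_domain"),
                     build_profile(pp, "c_domain"))
  }
  inv_frac <- function(cd) {
    p <- self_prof(cd)
    ok <- p$coverage >= 5
    sum(p$modal_identity[ok] == 1) / 312
  }
  # reference canonical clade: ~56% invariant; noncanonical PIN5: ~16%
  expect_lt(abs(inv_frac("PIN1") - 174 / 312), 0.02)
  expect_lt(abs(inv_frac("PIN5") - 50 / 312), 0.02)
  expect_gt(inv_frac("PIN1"), 3 * inv_frac("PIN5"))
})

test_that("noncanonical loops are short and canonical loops long", {
  fam <- clean_family()
  parts <- delineate_all(fam$records)
  cls <- vapply(parts, loop_length_class, "")
  types <- stats::setNames(fam$truth$members$type, fam$truth$members$id)
  expect_true(all(cls[types[names(cls)] == "noncanonical"] == "short"))
  expect_true(all(cls[types[names(cls)] == "canonical"] == "long"))
})

test_that("generated sequences respect the minimum length", {
  fam <- default_family()
  expect_true(all(nchar(fam$records$residues) >= 100))
})
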