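test_that("signal peptide cleavage is recovered on template precursors", {
  cat <- family_catalogue()
  for (i in seq_len(nrow(cat))) {
    full <- paste0(cat$signal_template[i], cat$pro_template[i],
                   cat$mature_core[i])
    res <- call_signal_peptide(full)
    expect_equal(res$cleavage, nchar(cat$signal_template[i]),
                 info = cat$template_id[i])
    expect_false(res$partial_n_terminus)
  }
})

test_that("signal calling flags truncation and rejects hydrophilic N-termini", {
  trunc <- call_signal_peptide(paste0("A", random_protein(40)))
  expect_true(is.na(trunc$cleavage))
  expect_true(trunc$partial_n_terminus)

  hydrophilic <- paste0("M", strrep("DKNQES", 10))
  res <- call_signal_peptide(hydrophilic)
  expect_true(is.na(res$cleavage))
  expect_false(res$partial_n_terminus)

  expect_true(is.na(call_signal_peptide("MLLLLLAS")$cleavage))
})

test_that("the PQM rule cleaves after a glutamate-bearing quadruplet's R", {
  expect_equal(call_propeptide("SSSSEERAFCWWCC"), 7)   # after ...SEER
  expect_true(is.na(call_propeptide("SSSSSSRAFCWWCC")))  # no E in quadruplet
  ## two qualifying sites before the first cysteine: the later one wins
  expect_equal(call_propeptide("QEERSSSSEERAFCWW"), 11)
  ## a site at or beyond the first cysteine does not count
  expect_true(is.na(call_propeptide("AFCWWSEERSSCC")))
})

test_that("amidation strips at most one K then a terminal G", {
  g <- apply_amidation("ACDKWG")
  expect_true(g$amidated); expect_equal(g$mature, "ACDKW")
  gk <- apply_amidation("ACDWGK")
  expect_true(gk$amidated); expect_equal(gk$mature, "ACDW")
  ggk <- apply_amidation("ACDWGGK")
  expect_true(ggk$amidated); expect_equal(ggk$mature, "ACDWG")
  f <- apply_amidation("ACDWF")
  expect_false(f$amidated); expect_equal(f$mature, "ACDWF")
  expect_error(apply_amidation("G"), "degenerate")
})

test_that("toxin names compose serial, partial and transcriptomic marks", {
  expect_equal(assign_name(64, FALSE, FALSE), "LcTx-64")
  expect_equal(assign_name(1436, TRUE, TRUE), "LcTx-1436-P-T")
  expect_equal(assign_name(1421, FALSE, TRUE), "LcTx-1421-T")
  expect_equal(assign_name(7, TRUE, FALSE, prefix = "XxTx"), "XxTx-7-P")
  expect_error(assign_name(0))
})

test_that("segmentation composes signal, propeptide and amidation calls", {
  cat <- family_catalogue()
  row <- cat[cat$template_id == "E1", ]
  full <- paste0(row$signal_template, row$pro_template, row$mature_core, "G")
  seg <- segment_precursor(full)
  expect_equal(seg$signal, c(0L, nchar(row$signal_template)))
  expect_equal(seg$propeptide[2],
               nchar(row$signal_template) + nchar(row$pro_template))
  expect_true(seg$amidated)
  expect_equal(seg$mature, row$mature_core)
  expect_equal(seg$mature_region[2], nchar(full))
})

test_that("peptide masses match frozen values and reject bad input", {
  expect_equal(peptide_mass("AG")$monoisotopic_da, 146.0691, tolerance = 1e-4)
  expect_equal(peptide_mass("CC", 1)$monoisotopic_da, 222.0133,
               tolerance = 1e-4)
  expect_equal(peptide_mass("AG", amidated = TRUE)$monoisotopic_da,
               145.0851, tolerance = 1e-4)
  expect_error(peptide_mass("AXG"), "X")
  expect_error(peptide_mass("CC", 2), "cysteine")
})

test_that("peptide masses obey additivity and constant modification deltas", {
  set.seed(21)
  for (i in 1:10) {
    p <- random_protein(sample(5:30, 1))
    q <- random_protein(sample(5:30, 1))
    expect_equal(peptide_mass(paste0(p, q))$monoisotopic_da,
                 peptide_mass(p)$monoisotopic_da +
                   peptide_mass(q)$monoisotopic_da - 18.010565,
                 tolerance = 1e-9)
    ## amidation delta independent of sequence
    expect_equal(peptide_mass(p)$monoisotopic_da -
                   peptide_mass(p, amidated = TRUE)$monoisotopic_da,
                 0.984016, tolerance = 1e-9)
  }
  ## each disulfide removes exactly two hydrogens
  p <- "ACCWCCK"
  for (b in 1:2)
    expect_equal(peptide_mass(p, b - 1)$monoisotopic_da -
                   peptide_mass(p, b)$monoisotopic_da,
                 2.015650, tolerance = 1e-9)
  expect_lt(peptide_mass("AG")$monoisotopic_da,
            peptide_mass("AG")$average_da)
})

test_that("peptide masses agree with the atomic-composition oracle", {
  set.seed(22)
  for (i in 1:20) {
    p <- random_protein(sample(4:40, 1))
    n_cys <- lengths(regmatches(p, gregexpr("C", p)))
    bonds <- if (n_cys >= 2) sample(0:(n_cys %/% 2), 1) else 0
    amid <- sample(c(TRUE, FALSE), 1)
    expect_equal(peptide_mass(p, bonds, amid)$monoisotopic_da,
                 mass_oracle(p, bonds, amid), tolerance = 2e-4)
  }
})
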