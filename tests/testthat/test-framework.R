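test_that("framework extraction writes adjacency without separators", {
  ick <- extract_framework(chartr("X", "A", "XCXXCXCCXXCXXC"))
  expect_equal(ick$notation, "C1-C2-C3C4-C5-C6")
  expect_equal(ick$n_cys, 6)
  expect_equal(extract_framework("CC")$notation, "C1C2")
  none <- extract_framework("WWWW")
  expect_equal(none$notation, "")
  expect_equal(none$n_cys, 0)
})

test_that("framework notation round-trips through parsing (property)", {
  set.seed(31)
  for (i in 1:30) {
    n <- sample(1:14, 1)
    adj <- if (n > 1) runif(n - 1) < 0.3 else logical(0)
    notation <- venomest:::framework_notation(n, adj)
    parsed <- parse_framework(notation)
    expect_equal(parsed$n_cys, n)
    expect_equal(parsed$adj, adj)
    expect_equal(parsed$notation, notation)
    ## positions realize the adjacency, so extraction round-trips too
    mature <- paste0(strrep("A", parsed$positions[1] - 1),
                     paste0(c("C", vapply(seq_len(n)[-1], function(k) {
                       gap <- parsed$positions[k] - parsed$positions[k - 1] - 1
                       paste0(strrep("A", gap), "C")
                     }, "")), collapse = ""))
    expect_equal(extract_framework(mature)$notation, notation)
  }
  expect_error(parse_framework("C1-C3"), "order")
})

test_that("scaffold assignment returns catalogue connectivities", {
  ick6 <- assign_scaffold("C1-C2-C3C4-C5-C6")
  expect_equal(ick6$motif, "ICK6")
  expect_equal(ick6$disulfide_pairs,
               list(c(1L, 4L), c(2L, 5L), c(3L, 6L)))
  ick8 <- assign_scaffold("C1-C2-C3C4-C5-C6-C7-C8")
  expect_equal(ick8$motif, "ICK8")
  expect_equal(ick8$disulfide_pairs,
               list(c(1L, 4L), c(2L, 5L), c(3L, 8L), c(6L, 7L)))
  i14 <- assign_scaffold("C1-C2-C3-C4C5-C6-C7-C8-C9-C10-C11-C12-C13-C14")
  expect_equal(i14$disulfide_pairs,
               list(c(1L, 5L), c(2L, 6L), c(3L, 10L), c(4L, 9L), c(7L, 8L),
                    c(11L, 12L), c(13L, 14L)))
  un <- assign_scaffold("C1-C2-C3C4-C5-C6C7-C8-C9-C10")
  expect_equal(un$motif, "unassigned")
  expect_null(un$disulfide_pairs)
})

test_that("scaffold pairs form a partial perfect matching", {
  cat <- scaffold_catalogue()
  for (i in seq_len(nrow(cat))) {
    pairs <- venomest:::parse_pairs(cat$pairs[i])
    idx <- unlist(pairs)
    expect_equal(anyDuplicated(idx), 0)
    expect_lte(length(pairs), cat$n_cys[i] %/% 2)
    expect_true(all(idx >= 1 & idx <= cat$n_cys[i]))
  }
  ## the bundled catalogue spans 2-14 cysteines and 1-7 disulfide pairs
  expect_equal(range(cat$n_cys), c(2, 14))
  n_pairs <- vapply(cat$pairs, function(p)
    length(venomest:::parse_pairs(p)), 0L, USE.NAMES = FALSE)
  expect_equal(range(n_pairs), c(1, 7))
})

test_that("family matching tolerates the loss of one cysteine", {
  fm <- venomest:::framework_matches
  ick8 <- parse_framework("C1-C2-C3C4-C5-C6-C7-C8")
  expect_true(fm(ick8, ick8))
  ## 7th cysteine mutated away: adjacency elsewhere survives
  seven <- parse_framework("C1-C2-C3C4-C5-C6-C7")
  expect_true(fm(seven, ick8))
  ## losing one of the adjacent pair dissolves the adjacency
  seven_b <- parse_framework("C1-C2-C3-C4-C5-C6-C7")
  expect_true(fm(seven_b, ick8))
  ## an adjacency at the N-terminal pair can never arise from one loss
  expect_false(fm(parse_framework("C1C2-C3-C4-C5-C6-C7"), ick8))
  expect_false(fm(parse_framework("C1-C2-C3C4-C5-C6"), ick8))
})

test_that("families are classified by framework plus template homology", {
  set.seed(32)
  cfg <- generator_config()
  for (fam in c("E", "I", "A")) {
    prec <- make_toxin_precursor(fam, cfg)
    call <- classify_family(prec$mature)
    expect_equal(call$family, fam)
    expect_match(call$evidence, "framework-match")
    expect_gte(call$identity_pct, 60)
  }
  ## low-homology 2-cysteine peptide lands in the K catch-all
  odd <- paste0("WW", strrep("PLHW", 6), "C", strrep("DWNH", 5), "CWW")
  call <- classify_family(odd)
  expect_equal(call$family, "K")
})
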