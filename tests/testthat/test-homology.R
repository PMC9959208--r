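## ORF finding, local protein alignment and homology categorization.

## a clean 40-codon ORF flanked by stop-rich padding
orf_fixture <- function() {
  prot <- paste0("MA", paste0(rep("GLV", 12), collapse = ""), "K")
  cds <- paste0("ATGGCT", strrep("GGACTTGTA", 12), "AAA", "TAA")
  list(prot = prot, cds = cds,
       seq = paste0("TAATTATAG", cds, "TTATAACTA"))
}

test_that("six-frame ORF calling finds the coding stretch with flags", {
  fx <- orf_fixture()
  orfs <- six_frame_orfs(fx$seq)
  hit <- orfs[orfs$protein == fx$prot, ]
  expect_equal(nrow(hit), 1)
  expect_true(hit$has_start)
  expect_true(hit$has_stop)
  expect_true(startsWith(hit$frame, "+"))
  ## coordinates point back at the CDS (stop codon included)
  sub <- substr(fx$seq, hit$cds_start + 1, hit$cds_end)
  expect_equal(sub, fx$cds)

  ## strand symmetry: the reverse complement carries the same protein
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(fx$seq)))
  orfs_rc <- six_frame_orfs(rc)
  hit_rc <- orfs_rc[orfs_rc$protein == fx$prot, ]
  expect_equal(nrow(hit_rc), 1)
  expect_true(startsWith(hit_rc$frame, "-"))
})

test_that("sequences without long ORFs yield no calls", {
  expect_equal(nrow(six_frame_orfs("")), 0)          # tail-only remainder
  expect_equal(nrow(six_frame_orfs("ACG")), 0)
  set.seed(44)
  expect_equal(nrow(six_frame_orfs(random_dna(85))), 0)  # < 30 codons
})

test_that("best_orf applies length then start-codon then frame tie-breaks", {
  orfs <- data.frame(
    frame = c("+1", "+2"), cds_start = c(0L, 1L), cds_end = c(120L, 271L),
    protein = c(strrep("A", 40), strrep("G", 90)),
    has_start = c(TRUE, FALSE), has_stop = TRUE)
  expect_equal(best_orf(orfs)$protein, strrep("G", 90))

  tie <- data.frame(
    frame = c("+1", "+3"), cds_start = c(0L, 2L), cds_end = c(120L, 122L),
    protein = c(strrep("L", 40), paste0("M", strrep("L", 39))),
    has_start = c(FALSE, TRUE), has_stop = TRUE)
  expect_true(best_orf(tie)$has_start)

  single <- orfs[1, ]
  expect_equal(best_orf(single), single)
  expect_error(best_orf(orfs[0, ]), "no ORF")
})

test_that("local protein alignment matches its definition on identities", {
  p <- random_protein(40)
  self <- align_protein(p, p)
  expect_equal(self$identity_pct, 100)
  expect_equal(self$query_cov_pct, 100)

  ## optimality: the self-score bounds any other alignment's score
  q <- paste(rev(strsplit(p, "")[[1]]), collapse = "")
  expect_lt(align_protein(p, q)$score, self$score)
})

test_that("alignment score equals the naive DP oracle on a classic pair", {
  expect_equal(align_protein("HEAGAWGHEE", "PAWHEAE")$score,
               sw_score_oracle("HEAGAWGHEE", "PAWHEAE"))
})

test_that("alignment score is symmetric for a symmetric scoring scheme", {
  set.seed(33)
  for (i in 1:10) {
    a <- random_protein(sample(10:40, 1))
    b <- random_protein(sample(10:40, 1))
    expect_equal(align_protein(a, b)$score, align_protein(b, a)$score)
  }
})

test_that("an EST encoding a panel protein verbatim is toxin-like", {
  panel <- toxin_panel_default()
  prot <- panel$seq[1]
  set.seed(5)
  pkg <- venomest:::packaged_transcript(prot, generator_config())
  est <- list(trimmed_seq = pkg$seq)
  call <- categorize(est)
  expect_equal(call$category, "toxin-like")
  expect_equal(call$best_hit$identity_pct, 100)
  expect_equal(call$best_hit$subject_id, panel$id[1])
})

test_that("ESTs without a qualifying ORF or hit are non-matched", {
  short <- list(trimmed_seq = random_dna(50))
  expect_equal(categorize(short)$category, "non-matched")
  expect_equal(categorize(short)$reason, "no-orf")
})

test_that("raising the identity threshold never rescues a non-match", {
  set.seed(77)
  panel <- toxin_panel_default()
  cell <- cellular_panel_default()
  ests <- c(vapply(1:6, function(i) random_dna(400), ""),
            paste0(venomest:::rt_cds(panel$seq[2]), "TAA"))
  prots <- vapply(ests, function(s) {
    orfs <- six_frame_orfs(s)
    if (nrow(orfs)) best_orf(orfs)$protein else NA_character_
  }, "", USE.NAMES = FALSE)
  cat_fun <- venomest:::categorize_proteins
  at40 <- cat_fun(prots, panel, cell, 40, 50)$category
  at80 <- cat_fun(prots, panel, cell, 80, 50)$category
  expect_false(any(at40 == "non-matched" & at80 != "non-matched"))
})
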