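small_config <- function(...) {
  generator_config(n_toxin_genes = 8, n_cellular_genes = 3,
                   n_random_genes = 2, n_transcriptomic = 1, n_ests = 40,
                   family_weights = c(E = 0.5, F = 0.25, I = 0.125,
                                      K = 0.125),
                   sub_rate = 0, trunc_prob = 0, ...)
}

test_that("generator configuration is validated", {
  expect_error(generator_config(family_weights = c(A = 0.5, B = 0.4)),
               "sum to 1")
  expect_error(generator_config(sub_rate = 1.5), "probabilities")
  expect_error(generator_config(n_toxin_genes = -1))
  expect_error(generate_library(
    generator_config(n_toxin_genes = 0, n_cellular_genes = 0,
                     n_random_genes = 0, n_transcriptomic = 0,
                     family_weights = c(E = 1))), "empty library")
})

test_that("precursor construction realizes family templates exactly", {
  cfg <- generator_config()
  set.seed(51)
  e <- make_toxin_precursor("E", cfg)
  fw <- extract_framework(e$mature)
  expect_equal(fw$n_cys, 8)
  expect_true(fw$adj[3])                 # 3rd and 4th cysteines adjacent
  expect_true(e$amidated)                # terminal G stripped into amide
  expect_true(endsWith(e$full_seq, "G"))

  i <- make_toxin_precursor("I", cfg)
  expect_equal(extract_framework(i$mature)$n_cys, 14)

  expect_error(make_toxin_precursor("Z", cfg), "unknown family")

  ## determinism under a fixed seed
  set.seed(99); a <- make_toxin_precursor("F", cfg)
  set.seed(99); b <- make_toxin_precursor("F", cfg)
  expect_identical(a, b)
})

test_that("reverse translation round-trips and packages the cDNA", {
  cfg <- generator_config()
  set.seed(52)
  prec <- make_toxin_precursor("E", cfg)
  pkg <- reverse_translate_and_package(prec$full_seq, cfg)
  cds <- substr(pkg$cdna, 1, pkg$cds_len - 3)
  expect_equal(venomest:::translate_chr(cds), prec$full_seq)
  expect_gte(pkg$polya_len, cfg$polya_len[1])
  expect_true(endsWith(pkg$cdna, strrep("A", cfg$polya_len[1])))

  ## zero-length 3'UTR: stop codon directly followed by the tail
  long_prec <- paste0(prec$full_seq, strrep(prec$mature, 2))
  cfg0 <- generator_config(utr_len = c(0, 0))
  set.seed(53)
  pkg0 <- venomest:::packaged_transcript(long_prec, cfg0)
  expect_equal(pkg0$utr_len, 0)
  expect_equal(nchar(pkg0$seq), pkg0$cds_len)
})

test_that("the library is reproducible and conserves truth labels", {
  lib1 <- generate_library(small_config(seed = 7))
  lib2 <- generate_library(small_config(seed = 7))
  expect_identical(lib1$ests, lib2$ests)
  expect_identical(lib1$truth, lib2$truth)

  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  generate_library(small_config(seed = 7), out_fasta = f1)
  generate_library(small_config(seed = 7), out_fasta = f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  ## exactly one truth row per EST, ids matching
  expect_equal(nrow(lib1$truth), nrow(lib1$ests))
  expect_identical(lib1$truth$est_id, lib1$ests$id)

  lib3 <- generate_library(small_config(seed = 8))
  expect_false(identical(lib1$ests$seq, lib3$ests$seq))
})

test_that("per-gene copy numbers follow the Zipf ranking", {
  lib <- generate_library(small_config(seed = 9))
  g <- lib$genes[lib$genes$origin == "library", ]
  g <- g[order(g$rank), ]
  expect_true(all(diff(g$copies) <= 0))
  counts <- table(lib$truth$gene_id)[g$gene_id]
  expect_equal(as.integer(counts), g$copies)
})

test_that("peaked family weights make family E dominate the library", {
  lib <- generate_library(small_config(seed = 10, copy_law = 1.3))
  tox <- lib$truth[lib$truth$category == "toxin-like", ]
  by_fam <- sort(table(tox$family), decreasing = TRUE)
  expect_equal(names(by_fam)[1], "E")
  ## the most-copied gene is a family E gene
  top_gene <- names(sort(table(tox$gene_id), decreasing = TRUE))[1]
  expect_equal(unique(tox$family[tox$gene_id == top_gene]), "E")
})

test_that("noise-free ESTs translate back to their source precursors", {
  lib <- generate_library(small_config(seed = 11))
  tr <- lib$truth
  idx <- which(tr$category != "non-matched")
  for (i in idx[seq_len(min(12, length(idx)))]) {
    est <- lib$ests$seq[i]
    trimmed <- detect_polya(est)$trimmed_seq
    call <- categorize(list(trimmed_seq = trimmed))
    expect_equal(call$protein, tr$precursor[i])
  }
})
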