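mutate_dna <- function(s, k) {
  ch <- strsplit(s, "")[[1]]
  for (p in sample.int(nchar(s), k))
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste0(ch, collapse = "")
}

test_that("identical ESTs form one contig; unrelated ESTs stay singletons", {
  set.seed(11)
  s <- random_dna(400)
  two <- data.frame(id = c("a", "b"), seq = c(s, s))
  cl <- greedy_cluster(two)
  expect_equal(length(cl$clusters), 1)
  expect_equal(cl$clusters[[1]]$size, 2)
  expect_equal(cl$clusters[[1]]$size_bin, "2-5")
  expect_equal(cl$clusters[[1]]$consensus, s)

  three <- data.frame(id = c("x", "y", "z"),
                      seq = c(random_dna(350), random_dna(350),
                              random_dna(350)))
  cl3 <- greedy_cluster(three)
  expect_equal(length(cl3$clusters), 3)
  expect_true(all(vapply(cl3$clusters, `[[`, 0L, "size") == 1L))
})

test_that("17 noisy copies of one gene form a single 16-30 bin contig", {
  set.seed(12)
  base <- random_dna(420)
  copies <- data.frame(id = sprintf("c%02d", 1:17),
                       seq = vapply(1:17, function(i) mutate_dna(base, 3), ""))
  cl <- greedy_cluster(copies)
  expect_equal(length(cl$clusters), 1)
  expect_equal(cl$clusters[[1]]$size, 17L)
  expect_equal(cl$clusters[[1]]$size_bin, "16-30")
})

test_that("clustering partitions the input deterministically", {
  set.seed(13)
  inst <- random_est_instance(n_genes = 5, max_copies = 5)
  cl1 <- greedy_cluster(inst)
  cl2 <- greedy_cluster(inst[sample(nrow(inst)), ])  # shuffled input
  all1 <- sort(unlist(lapply(cl1$clusters, `[[`, "members")))
  expect_equal(all1, sort(inst$id))                 # partition
  expect_equal(sum(vapply(cl1$clusters, `[[`, 0L, "size")), nrow(inst))
  expect_identical(partition_sets(lapply(cl1$clusters, `[[`, "members")),
                   partition_sets(lapply(cl2$clusters, `[[`, "members")))
})

test_that("raising the identity threshold never merges clusters", {
  set.seed(14)
  for (rep in 1:5) {
    inst <- random_est_instance(n_genes = 3, max_copies = 4, sub = 0.03)
    lo <- greedy_cluster(inst, min_identity_pct = 90)
    hi <- greedy_cluster(inst, min_identity_pct = 98)
    expect_gte(length(hi$clusters), length(lo$clusters))
    ## refinement: every high-threshold cluster sits inside one low cluster
    lo_of <- lo$membership$cluster_id[match(hi$membership$est_id,
                                            lo$membership$est_id)]
    for (cid in unique(hi$membership$cluster_id))
      expect_equal(length(unique(lo_of[hi$membership$cluster_id == cid])), 1)
  }
})

test_that("greedy clustering equals brute-force graph components", {
  set.seed(15)
  for (rep in 1:8) {
    inst <- random_est_instance(n_genes = sample(2:4, 1), max_copies = 3)
    stopifnot(nrow(inst) <= 12)
    got <- partition_sets(lapply(greedy_cluster(inst)$clusters,
                                 `[[`, "members"))
    want <- partition_sets(cluster_oracle(inst))
    expect_identical(got, want)
  }
})

test_that("overlap detection reports full-length identity and real overlaps", {
  set.seed(16)
  s <- random_dna(400)
  ov <- pairwise_overlap_identity(s, s)
  expect_equal(ov$overlap_len, 400)
  expect_equal(ov$identity_pct, 100)

  a <- random_dna(300)
  tailseq <- substr(a, 101, 300)
  b <- paste0(tailseq, random_dna(150))   # 200-nt suffix-prefix overlap
  ov2 <- pairwise_overlap_identity(a, b)
  expect_gte(ov2$overlap_len, 200)
  expect_equal(ov2$identity_pct, 100)

  ov3 <- pairwise_overlap_identity(random_dna(250), random_dna(250))
  expect_lt(ov3$identity_pct, 96)
})

test_that("unique genes collapse at nucleotide level, proteins at translation", {
  prot <- paste0("M", strrep("TGK", 15))
  set.seed(17)
  cds1 <- venomest:::rt_cds(prot)
  cds2 <- venomest:::rt_cds(prot)           # synonymous variant
  stopifnot(cds1 != cds2)
  orf_tab <- data.frame(est_id = c("e1", "e2", "e3", "e4"),
                        cds = c(cds1, cds1, cds2, cds1),
                        protein = c(prot, prot, prot, sub("K", "R", prot)))
  expect_equal(tally_genes_proteins(c("e1", "e2"), orf_tab),
               list(unique_genes = 1L, proteins = 1L))
  expect_equal(tally_genes_proteins(c("e1", "e3"), orf_tab),
               list(unique_genes = 2L, proteins = 1L))
  expect_equal(tally_genes_proteins(c("e3", "e4"), orf_tab),
               list(unique_genes = 2L, proteins = 2L))
})

test_that("cluster summaries bin sizes and compute clustering percentages", {
  set.seed(18)
  base1 <- random_dna(400); base2 <- random_dna(380)
  inst <- data.frame(
    id = sprintf("e%d", 1:7),
    seq = c(base1, base1, base1, base2, base2,
            random_dna(360), random_dna(340)))
  cl <- greedy_cluster(inst)
  sm <- summarize_clusters(cl, category = "demo")
  expect_equal(sm$n_ests, 7)
  expect_equal(sm$n_contigs, 2)
  expect_equal(sm$n_singletons, 2)
  expect_equal(sm$n_clusters, sm$n_contigs + sm$n_singletons)
  expect_equal(sm$pct_clustered, round_half_up(100 * 5 / 7))
  contig_bins <- sm$per_bin$bin != "1"
  expect_equal(sum(sm$per_bin$ests[contig_bins]) + sm$n_singletons, 7)
  expect_error(summarize_clusters(greedy_cluster(inst[0, ])), "empty")
})

test_that("consensus is the majority base with alphabetical tie-break", {
  set.seed(19)
  base <- random_dna(400)
  v1 <- base; substr(v1, 50, 50) <- "T"
  v2 <- base; substr(v2, 50, 50) <- "G"
  substr(base, 50, 50) <- "C"
  cl <- greedy_cluster(data.frame(id = c("a", "b", "c"),
                                  seq = c(base, v1, v2)))
  expect_equal(length(cl$clusters), 1)
  ## three-way tie at position 50 resolves alphabetically
  expect_equal(substr(cl$clusters[[1]]$consensus, 50, 50), "C")
  expect_equal(substr(cl$clusters[[1]]$consensus, 1, 49),
               substr(base, 1, 49))
})
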