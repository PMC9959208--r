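## Independent oracles used by the test suite. These are deliberately
## naive implementations kept separate from the package code paths they
## check.

## BLOSUM62 scoring matrix (from Biostrings' bundled data)
blosum62_oracle <- local({
  env <- new.env()
  function() {
    if (is.null(env$m)) {
      utils::data("BLOSUM62", package = "Biostrings", envir = env)
      env$m <- env$BLOSUM62
    }
    env$m
  }
})

## Naive O(nm) Gotoh local-alignment score: affine gaps where a gap of
## length L costs open + L * extend.
sw_score_oracle <- function(a, b, open = 11, extend = 1,
                            mat = blosum62_oracle()) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)  # gap in x (consume y)
  F <- matrix(-Inf, n + 1, m + 1)  # gap in y (consume x)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - open - extend, E[i, j - 1] - extend)
      F[i, j] <- max(H[i - 1, j] - open - extend, F[i - 1, j] - extend)
      H[i, j] <- max(0,
                     H[i - 1, j - 1] + mat[x[i - 1], y[j - 1]],
                     E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

## peptide mass by atomic composition (independent of the residue-mass
## table used by the package)
ELEMENT_MONO <- c(C = 12, H = 1.0078250319, N = 14.0030740052,
                  O = 15.9949146221, S = 31.97207069)
RESIDUE_FORMULA <- list(
  G = c(C = 2, H = 3, N = 1, O = 1),  A = c(C = 3, H = 5, N = 1, O = 1),
  S = c(C = 3, H = 5, N = 1, O = 2),  P = c(C = 5, H = 7, N = 1, O = 1),
  V = c(C = 5, H = 9, N = 1, O = 1),  T = c(C = 4, H = 7, N = 1, O = 2),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1), I = c(C = 6, H = 11, N = 1, O = 1),
  N = c(C = 4, H = 6, N = 2, O = 2),  D = c(C = 4, H = 5, N = 1, O = 3),
  Q = c(C = 5, H = 8, N = 2, O = 2),  K = c(C = 6, H = 12, N = 2, O = 1),
  E = c(C = 5, H = 7, N = 1, O = 3),  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7, N = 3, O = 1),  F = c(C = 9, H = 9, N = 1, O = 1),
  R = c(C = 6, H = 12, N = 4, O = 1), Y = c(C = 9, H = 9, N = 1, O = 2),
  W = c(C = 11, H = 10, N = 2, O = 1))

formula_mass <- function(f) sum(ELEMENT_MONO[names(f)] * f)

mass_oracle <- function(peptide, n_disulfides = 0, amidated = FALSE) {
  aa <- strsplit(peptide, "")[[1]]
  total <- sum(vapply(aa, function(r) formula_mass(RESIDUE_FORMULA[[r]]), 0))
  total <- total + formula_mass(c(H = 2, O = 1))          # water
  total <- total - 2 * ELEMENT_MONO["H"] * n_disulfides   # -2H per bond
  if (amidated)                                           # -OH +NH2
    total <- total - ELEMENT_MONO["O"] + ELEMENT_MONO["N"] + ELEMENT_MONO["H"]
  unname(total)
}

## brute-force single-linkage clustering: connected components of the
## exact pairwise-similarity graph
cluster_oracle <- function(ests, min_overlap = 100, min_identity_pct = 96) {
  seqs <- ests$trimmed_seq
  if (is.null(seqs)) seqs <- ests$seq
  n <- length(seqs)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    ov <- pairwise_overlap_identity(seqs[i], seqs[j])
    if (ov$overlap_len >= min_overlap && ov$identity_pct >= min_identity_pct)
      parent[find(j)] <- find(i)
  }
  comp <- vapply(seq_len(n), find, 0L)
  unname(split(ests$id, comp))
}

## partition as a canonical set of member-id sets, for comparison
partition_sets <- function(groups) {
  s <- lapply(groups, function(g) sort(g))
  s[order(vapply(s, `[`, "", 1))]
}

random_dna <- function(n) paste0(sample(c("A", "C", "G", "T"), n,
                                        replace = TRUE), collapse = "")
random_protein <- function(n) paste0(sample(names(venomest:::AA_MONO), n,
                                            replace = TRUE), collapse = "")

## small EST instance: a few "genes" with noisy copies
random_est_instance <- function(n_genes = 3, max_copies = 4, sub = 0.01) {
  seqs <- character(0); ids <- character(0)
  for (g in seq_len(n_genes)) {
    base <- random_dna(sample(150:300, 1))
    for (cp in seq_len(sample(1:max_copies, 1))) {
      s <- base
      k <- rbinom(1, nchar(s), sub)
      if (k > 0) {
        ch <- strsplit(s, "")[[1]]
        for (p in sample.int(nchar(s), k))
          ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
        s <- paste0(ch, collapse = "")
      }
      seqs <- c(seqs, s)
      ids <- c(ids, sprintf("g%d_c%d", g, cp))
    }
  }
  data.frame(id = ids, seq = seqs, stringsAsFactors = FALSE)
}
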