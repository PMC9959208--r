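## Greedy single-linkage clustering of ESTs into contigs and singletons.
## An incoming EST joins every existing cluster containing a member it
## overlaps (>= min_overlap aligned columns at >= min_identity_pct); when it
## links several clusters they are merged, so the final partition equals
## the connected components of the pairwise-similarity graph. An exact
## shared k-mer prescreen (k = 11: any 100-nt overlap at >= 96% identity
## must contain an intact 11-mer) keeps the number of alignments small.

CLUSTER_KMER <- 11L

SIZE_BINS <- c("1", "2-5", "6-10", "11-15", "16-30", ">30")

## positions of all k-mers of s (first occurrence), as a named vector
kmer_positions <- function(s, k = CLUSTER_KMER) {
  n <- nchar(s)
  if (n < k) return(integer(0))
  km <- substring(s, 1:(n - k + 1L), k:n)
  first <- !duplicated(km)
  structure(which(first), names = km[first])
}

## ungapped overlap at the dominant shared-k-mer diagonal: a cheap,
## sufficient check for the near-identical overlaps that dominate EST
## libraries (sequencing copies differ by substitutions, not indels).
## Returns NULL when the two sequences share no k-mer.
diagonal_overlap <- function(a, b, pos_a = kmer_positions(a),
                             pos_b = kmer_positions(b)) {
  shared <- intersect(names(pos_a), names(pos_b))
  if (!length(shared)) return(NULL)
  d <- table(pos_b[shared] - pos_a[shared])
  best <- which.max(d)
  off <- as.integer(names(d)[best])              # modal diagonal
  ## overlap of a[i] with b[i + off]
  start_a <- max(1L, 1L - off)
  end_a <- min(nchar(a), nchar(b) - off)
  if (end_a < start_a) return(NULL)
  ra <- charToRaw(substr(a, start_a, end_a))
  rb <- charToRaw(substr(b, start_a + off, end_a + off))
  list(overlap_len = length(ra),
       identity_pct = 100 * sum(ra == rb) / length(ra),
       offset = off, modal_kmers = as.integer(d[best]))
}

#' Cluster size bin
#'
#' Bins cluster sizes into the conventional groups 1 (singleton), 2-5,
#' 6-10, 11-15, 16-30 and >30.
#'
#' @param size integer vector of member counts
#' @return character vector of bin labels
#' @export
cluster_size_bin <- function(size) {
  cut(size, breaks = c(0, 1, 5, 10, 15, 30, Inf), labels = SIZE_BINS,
      right = TRUE) |> as.character()
}

#' Greedy single-linkage clustering of ESTs
#'
#' ESTs are seeded in deterministic order (length descending, then id
#' ascending). Each EST joins the clusters in which it overlaps at least
#' one member by `min_overlap` aligned columns at `min_identity_pct`
#' identity or better; joining several clusters merges them. The result is
#' a partition of the input.
#'
#' @param ests data.frame with `id` and `trimmed_seq` (or `seq`) columns
#' @param min_overlap minimum aligned overlap in nt
#' @param min_identity_pct minimum identity over the overlap, percent
#' @return object of class `est_clusters`: a list with `clusters` (each a
#'   list `members` (EST ids), `consensus`, `size`, `size_bin`) and
#'   `membership` (data.frame `cluster_id`, `est_id`)
#' @export
greedy_cluster <- function(ests, min_overlap = 100, min_identity_pct = 96) {
  seqs <- ests$trimmed_seq %||% ests$seq
  ids <- ests$id
  if (!length(ids))
    return(structure(list(clusters = list(),
                          membership = data.frame(cluster_id = character(0),
                                                  est_id = character(0))),
                     class = "est_clusters"))
  ord <- order(-nchar(seqs), ids)
  seqs <- seqs[ord]; ids <- ids[ord]

  ## deduplicate identical sequences: twins always satisfy the thresholds
  first_of <- match(seqs, seqs)
  uq <- which(first_of == seq_along(seqs))

  kindex <- new.env(hash = TRUE, parent = emptyenv())  # kmer -> member idx
  assign_cluster <- integer(length(seqs))              # member -> cluster id
  members <- list()                                    # cluster id -> idx vec
  kpos <- vector("list", length(seqs))                 # member k-mer maps
  for (i in uq) {
    kpos[[i]] <- kmer_positions(seqs[i])
    km <- unique(names(kpos[[i]]))
    hits <- unlist(lapply(km, function(x) kindex[[x]]), use.names = FALSE)
    hit_clusters <- integer(0)
    if (length(hits)) {
      shared_by_member <- table(hits)           # shared k-mers per member
      cand <- as.integer(names(shared_by_member))
      nshare <- as.integer(shared_by_member)
      ## any qualifying overlap implies many intact shared 11-mers (a
      ## 100-nt overlap at 96% identity yields >= 46); prune far below that
      min_share <- max(1L, (min_overlap - CLUSTER_KMER + 1L) %/% 4L)
      keep_c <- nshare >= min_share
      cand <- cand[keep_c]; nshare <- nshare[keep_c]
      cand_cl <- assign_cluster[cand]
      for (cl in unique(cand_cl[order(-nshare)])) {
        mem <- cand[cand_cl == cl]
        ## test members sharing the most k-mers first. The ungapped
        ## diagonal check settles near-identical pairs without a full
        ## alignment; the Smith-Waterman fallback runs only when enough
        ## shared k-mers sit on one diagonal to make a qualifying
        ## (possibly gapped) overlap plausible — a 100-nt overlap at 96%
        ## identity puts at least ~46 intact 11-mers on its diagonal
        dia_floor <- max(1L, (min_overlap - CLUSTER_KMER + 1L) %/% 8L)
        for (m in utils::head(mem[order(-nshare[cand_cl == cl])], 8L)) {
          f <- diagonal_overlap(seqs[i], seqs[m], kpos[[i]], kpos[[m]])
          if (is.null(f)) next
          hit <- f$overlap_len >= min_overlap &&
            f$identity_pct >= min_identity_pct
          if (!hit && f$modal_kmers >= dia_floor) {
            ov <- pairwise_overlap_identity(seqs[i], seqs[m])
            hit <- ov$overlap_len >= min_overlap &&
              ov$identity_pct >= min_identity_pct
          }
          if (hit) {
            hit_clusters <- c(hit_clusters, cl)
            break
          }
        }
      }
    }
    if (!length(hit_clusters)) {
      cl <- length(members) + 1L
      members[[cl]] <- i
      assign_cluster[i] <- cl
    } else {
      hit_clusters <- sort(hit_clusters)
      cl <- hit_clusters[1]
      merged <- unlist(members[hit_clusters], use.names = FALSE)
      for (other in hit_clusters[-1]) members[[other]] <- integer(0)
      members[[cl]] <- c(merged, i)
      assign_cluster[c(merged, i)] <- cl
    }
    for (x in km) kindex[[x]] <- c(kindex[[x]], i)
  }
  ## attach duplicates to their twin's cluster
  for (i in setdiff(seq_along(seqs), uq)) {
    cl <- assign_cluster[first_of[i]]
    members[[cl]] <- c(members[[cl]], i)
    assign_cluster[i] <- cl
  }

  keep <- which(lengths(members) > 0)
  clusters <- lapply(seq_along(keep), function(k) {
    idx <- sort(members[[keep[k]]])
    list(members = ids[idx],
         consensus = cluster_consensus(seqs[idx]),
         size = length(idx),
         size_bin = cluster_size_bin(length(idx)))
  })
  membership <- data.frame(
    cluster_id = rep(sprintf("cluster%04d", seq_along(clusters)),
                     vapply(clusters, `[[`, 0L, "size")),
    est_id = unlist(lapply(clusters, `[[`, "members")),
    stringsAsFactors = FALSE)
  structure(list(clusters = clusters, membership = membership),
            class = "est_clusters")
}

## majority-base consensus anchored on the longest member (the seed).
## Member offsets come from local alignment against the seed; columns with
## ties are resolved alphabetically.
cluster_consensus <- function(seqs) {
  if (length(seqs) == 1L) return(seqs)
  seed <- seqs[which.max(nchar(seqs))]
  L <- nchar(seed)
  counts <- matrix(0L, nrow = 5, ncol = L,
                   dimnames = list(c("A", "C", "G", "T", "N"), NULL))
  add <- function(s, offset) {
    ch <- seq_chars(s)
    pos <- seq_along(ch) + offset
    ok <- pos >= 1 & pos <= L & ch %in% rownames(counts)
    for (j in which(ok)) counts[ch[j], pos[j]] <<- counts[ch[j], pos[j]] + 1L
  }
  add(seed, 0L)
  seed_pos <- kmer_positions(seed)
  for (s in seqs[-which.max(nchar(seqs))]) {
    if (identical(s, seed)) { add(s, 0L); next }
    f <- diagonal_overlap(s, seed, kmer_positions(s), seed_pos)
    off <- if (!is.null(f)) f$offset else {
      al <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(s), Biostrings::DNAString(seed),
        type = "local", substitutionMatrix = dna_submat(),
        gapOpening = 5, gapExtension = 2)
      Biostrings::start(Biostrings::subject(al)@range) -
        Biostrings::start(Biostrings::pattern(al)@range)
    }
    add(s, off)
  }
  paste0(rownames(counts)[apply(counts, 2, which.max)], collapse = "")
}

#' Tally unique genes and proteins within a cluster
#'
#' A unique gene is a distinct coding nucleotide sequence (exact string
#' equality); a protein is a distinct translated precursor. Members lacking
#' an ORF contribute to neither tally.
#'
#' @param member_ids EST ids of the cluster members
#' @param orf_calls data.frame indexed by `est_id` with `cds` (coding
#'   nucleotide string) and `protein` columns; NA when the member has no ORF
#' @return list `unique_genes`, `proteins`
#' @export
tally_genes_proteins <- function(member_ids, orf_calls) {
  rows <- orf_calls[match(member_ids, orf_calls$est_id), , drop = FALSE]
  cds <- rows$cds[!is.na(rows$cds)]
  prot <- rows$protein[!is.na(rows$protein)]
  list(unique_genes = length(unique(cds)), proteins = length(unique(prot)))
}

#' Summarize the clusters of one EST category
#'
#' @param clusters an `est_clusters` object for a single category
#' @param orf_calls optional data.frame (`est_id`, `cds`, `protein`) for
#'   unique-gene and protein tallies
#' @param category label recorded in the summary
#' @return list of class `cluster_summary`: totals, per-bin table and
#'   `pct_clustered` (percentage of ESTs in contigs, half-up, 2 decimals)
#' @export
summarize_clusters <- function(clusters, orf_calls = NULL, category = "all") {
  sizes <- vapply(clusters$clusters, function(cl) as.integer(cl$size), 0L)
  n <- sum(sizes)
  if (n == 0L) stop("empty category")
  n_singletons <- sum(sizes == 1L)
  bins <- factor(vapply(clusters$clusters, `[[`, "", "size_bin"),
                 levels = SIZE_BINS)
  per_bin <- data.frame(bin = SIZE_BINS,
                        contigs = as.integer(table(bins)),
                        ests = as.integer(tapply(sizes, bins, sum,
                                                 default = 0L)))
  if (!is.null(orf_calls)) {
    tal <- lapply(clusters$clusters, function(cl)
      tally_genes_proteins(cl$members, orf_calls))
    ug <- vapply(tal, `[[`, 0L, "unique_genes")
    pr <- vapply(tal, `[[`, 0L, "proteins")
    per_bin$unique_genes <- as.integer(tapply(ug, bins, sum, default = 0L))
    per_bin$proteins <- as.integer(tapply(pr, bins, sum, default = 0L))
  }
  structure(list(category = category, n_ests = n,
                 n_clusters = length(sizes), n_singletons = n_singletons,
                 n_contigs = sum(sizes > 1L), per_bin = per_bin,
                 pct_clustered = round_half_up(100 * (n - n_singletons) / n)),
            class = "cluster_summary")
}

#' @export
print.cluster_summary <- function(x, ...) {
  cat(sprintf("%s: %d ESTs in %d clusters (%d singletons, %d contigs); %.2f%% clustered\n",
              x$category, x$n_ests, x$n_clusters, x$n_singletons, x$n_contigs,
              x$pct_clustered))
  print(x$per_bin, row.names = FALSE)
  invisible(x)
}

#' @export
print.est_clusters <- function(x, ...) {
  sizes <- vapply(x$clusters, `[[`, 0L, "size")
  cat(sprintf("est_clusters: %d ESTs in %d clusters (%d singletons)\n",
              sum(sizes), length(sizes), sum(sizes == 1L)))
  invisible(x)
}
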