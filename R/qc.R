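## EST quality control: the high-quality EST rule (raw length strictly
## greater than 300 nt), alphabet checks, poly-A tail detection/trimming,
## and pooling of library-derived and transcriptomic sequences.

#' Read ESTs from a FASTA file
#'
#' @param path FASTA file of nucleotide sequences
#' @param origin provenance tag for every record: `"library"` (cDNA library
#'   clone) or `"transcriptomic"` (assembled transcript)
#' @return data.frame with columns `id`, `seq`, `origin`
#' @export
read_ests <- function(path, origin = c("library", "transcriptomic")) {
  origin <- match.arg(origin)
  df <- read_fasta_df(path, "DNA")
  df$seq <- toupper(df$seq)
  df$origin <- origin
  df
}

#' Filter ESTs by the high-quality length rule
#'
#' Keeps records whose raw length is strictly greater than
#' `min_len_exclusive` nucleotides (so 301 nt is the shortest kept length at
#' the default). Records containing characters outside A/C/G/T/N, or more
#' than `max_n_frac` N bases, are rejected regardless of length.
#'
#' @param ests data.frame with columns `id`, `seq` (and optionally `origin`)
#' @param min_len_exclusive length threshold in nt; kept iff length > this
#' @param max_n_frac maximum tolerated fraction of N bases
#' @return list with `kept` (subset of `ests`) and `rejected`
#'   (data.frame `id`, `reason` in `{"short", "alphabet", "n-content"}`)
#' @export
qc_filter <- function(ests, min_len_exclusive = 300, max_n_frac = 0.05) {
  stopifnot(min_len_exclusive >= 0)
  if (!nrow(ests))
    return(list(kept = ests,
                rejected = data.frame(id = character(0), reason = character(0))))
  seqs <- toupper(ests$seq)
  len <- nchar(seqs)
  bad_alpha <- grepl("[^ACGTN]", seqs)
  n_frac <- vapply(seqs, function(s) {
    lengths(regmatches(s, gregexpr("N", s, fixed = TRUE))) / nchar(s)
  }, 0, USE.NAMES = FALSE)
  reason <- rep(NA_character_, nrow(ests))
  reason[len <= min_len_exclusive] <- "short"
  reason[n_frac > max_n_frac] <- "n-content"
  reason[bad_alpha] <- "alphabet"
  keep <- is.na(reason)
  kept <- ests[keep, , drop = FALSE]
  kept$seq <- seqs[keep]
  rownames(kept) <- NULL
  list(kept = kept,
       rejected = data.frame(id = ests$id[!keep], reason = reason[!keep],
                             stringsAsFactors = FALSE))
}

#' Detect and trim a 3' poly-A tail
#'
#' Finds the longest 3'-terminal run of A allowing at most `max_mismatch`
#' non-A bases inside it. Runs shorter than `min_run` are not treated as
#' tails (no trimming). A record that is tail from end to end is flagged
#' `tail_only`.
#'
#' @param seq nucleotide string
#' @param min_run minimum tail length in nt
#' @param max_mismatch maximum non-A bases tolerated within the tail
#' @return list `polya_len`, `trimmed_seq`, `tail_only`
#' @export
detect_polya <- function(seq, min_run = 10, max_mismatch = 1) {
  stopifnot(nzchar(seq))
  ch <- rev(seq_chars(seq))
  mism <- 0L
  tail_len <- 0L
  for (i in seq_along(ch)) {
    if (ch[i] == "A") {
      tail_len <- i
    } else {
      mism <- mism + 1L
      if (mism > max_mismatch) break
    }
  }
  ## the tail must end on an A run; tail_len stops at the last A seen
  if (tail_len < min_run)
    return(list(polya_len = 0L, trimmed_seq = seq, tail_only = FALSE))
  n <- nchar(seq)
  list(polya_len = tail_len,
       trimmed_seq = substr(seq, 1L, n - tail_len),
       tail_only = tail_len == n)
}

## vectorized helper used by the pipeline
add_polya_columns <- function(ests, min_run = 10, max_mismatch = 1) {
  det <- lapply(ests$seq, detect_polya, min_run = min_run,
                max_mismatch = max_mismatch)
  ests$polya_len <- vapply(det, `[[`, 0L, "polya_len")
  ests$trimmed_seq <- vapply(det, `[[`, "", "trimmed_seq")
  ests$tail_only <- vapply(det, `[[`, FALSE, "tail_only")
  ests
}

#' Pool library-derived and transcriptomic ESTs
#'
#' Concatenates the two sources, tagging provenance. Identical trimmed
#' sequences occurring in both sources are kept (deduplication happens at
#' the protein level later) but cross-referenced.
#'
#' @param library,transcriptomic data.frames with `id`, `seq` (and
#'   optionally `trimmed_seq`)
#' @return data.frame of all records with an `origin` column; attribute
#'   `"xref"` lists id pairs whose trimmed sequences are identical across
#'   sources
#' @export
merge_sources <- function(library, transcriptomic) {
  library$origin <- "library"
  if (nrow(transcriptomic)) transcriptomic$origin <- "transcriptomic"
  if (anyDuplicated(library$id) || anyDuplicated(transcriptomic$id))
    stop("id collision: duplicate ids within a source")
  if (length(intersect(library$id, transcriptomic$id)))
    stop("id collision: ",
         paste(intersect(library$id, transcriptomic$id), collapse = ", "))
  cols <- union(names(library), names(transcriptomic))
  for (cc in setdiff(cols, names(library)))
    library[[cc]] <- rep(NA, nrow(library))
  for (cc in setdiff(cols, names(transcriptomic)))
    transcriptomic[[cc]] <- rep(NA, nrow(transcriptomic))
  pooled <- rbind(library[cols], transcriptomic[cols])
  rownames(pooled) <- NULL
  key <- function(df) if ("trimmed_seq" %in% names(df) &&
                          !anyNA(df$trimmed_seq)) df$trimmed_seq else df$seq
  shared <- intersect(key(library), key(transcriptomic))
  xref <- if (length(shared)) {
    do.call(rbind, lapply(shared, function(s) {
      expand.grid(library_id = library$id[key(library) == s],
                  transcriptomic_id = transcriptomic$id[key(transcriptomic) == s],
                  stringsAsFactors = FALSE)
    }))
  } else data.frame(library_id = character(0), transcriptomic_id = character(0))
  attr(pooled, "xref") <- xref
  pooled
}
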