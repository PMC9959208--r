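## Six-frame translation and ORF calling. An ORF is a maximal stop-free
## stretch of codons in one of the six reading frames; stretches shorter
## than 30 codons (the shortest plausible toxin precursor region) are
## dropped. Frames follow the BLAST convention: -1 is the first phase of
## the reverse complement. Coordinates are 0-based half-open on the
## trimmed EST (plus strand).

FRAME_ORDER <- c("+1", "+2", "+3", "-1", "-2", "-3")

## codon -> amino acid lookup (standard genetic code, "*" = stop);
## codons containing N or other ambiguity translate to "X"
codon_lookup <- local({
  env <- new.env()
  function() {
    if (is.null(env$tab)) env$tab <- Biostrings::GENETIC_CODE
    env$tab
  }
})

translate_chr <- function(seq) {
  n <- nchar(seq)
  if (n < 3) return("")
  usable <- n - n %% 3L
  codons <- substring(seq, seq(1L, usable, 3L), seq(3L, usable, 3L))
  aa <- codon_lookup()[codons]
  aa[is.na(aa)] <- "X"
  paste0(aa, collapse = "")
}

revcomp_chr <- function(seq) {
  paste0(rev(seq_chars(chartr("ACGTN", "TGCAN", seq))), collapse = "")
}

## stretches between stops in one translated frame
frame_orfs <- function(prot, frame, offset, est_len, min_codons) {
  if (!nzchar(prot)) return(NULL)
  parts <- strsplit(prot, "*", fixed = TRUE)[[1]]
  ends_with_stop <- endsWith(prot, "*")
  out <- NULL
  aa_pos <- 0L  # 0-based aa offset of current part within the frame
  for (k in seq_along(parts)) {
    p <- parts[k]
    npc <- nchar(p)
    if (npc >= min_codons) {
      has_stop <- k < length(parts) || ends_with_stop
      ## nt coords in frame space (on the translated strand)
      nt_start <- offset + 3L * aa_pos
      nt_end <- nt_start + 3L * (npc + has_stop)
      if (startsWith(frame, "-")) {       # map back to plus strand
        tmp <- est_len - nt_end
        nt_end <- est_len - nt_start
        nt_start <- tmp
      }
      out <- rbind(out, data.frame(
        frame = frame, cds_start = nt_start, cds_end = nt_end,
        protein = p, has_start = startsWith(p, "M"), has_stop = has_stop,
        stringsAsFactors = FALSE))
    }
    aa_pos <- aa_pos + npc + 1L
  }
  out
}

#' Find ORFs in all six reading frames
#'
#' @param seq trimmed nucleotide string (post poly-A removal)
#' @param min_codons minimum ORF length in codons
#' @return data.frame with one row per ORF: `frame`, `cds_start`, `cds_end`
#'   (0-based half-open nt coordinates on `seq`, stop codon included when
#'   present), `protein`, `has_start` (first codon is ATG), `has_stop`.
#'   Zero rows when no ORF reaches `min_codons`.
#' @export
six_frame_orfs <- function(seq, min_codons = 30) {
  est_len <- nchar(seq)
  empty <- data.frame(frame = character(0), cds_start = integer(0),
                      cds_end = integer(0), protein = character(0),
                      has_start = logical(0), has_stop = logical(0))
  if (est_len < 3) return(empty)
  rc <- revcomp_chr(seq)
  out <- NULL
  for (f in FRAME_ORDER) {
    off <- as.integer(substr(f, 2, 2)) - 1L
    s <- if (startsWith(f, "+")) seq else rc
    prot <- translate_chr(substr(s, off + 1L, est_len))
    out <- rbind(out, frame_orfs(prot, f, off, est_len, min_codons))
  }
  if (is.null(out)) empty else out
}

#' Select the best ORF call
#'
#' The ORF with the longest protein wins; ties prefer an ATG-initiated ORF,
#' then the lowest frame in the order +1, +2, +3, -1, -2, -3, then the
#' smallest `cds_start`.
#'
#' @param orfs data.frame as returned by [six_frame_orfs()]
#' @return single-row data.frame
#' @export
best_orf <- function(orfs) {
  if (is.null(orfs) || !nrow(orfs)) stop("no ORF")
  o <- order(-nchar(orfs$protein), !orfs$has_start,
             match(orfs$frame, FRAME_ORDER), orfs$cds_start)
  orfs[o[1], , drop = FALSE]
}

## batch ORF caller: all ORFs of every EST in one flat table with the
## source index in `est_i`; ESTs without ORFs contribute no rows
all_orfs_flat <- function(seqs, min_codons = 30) {
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    orfs <- six_frame_orfs(seqs[i], min_codons)
    if (nrow(orfs)) {
      orfs$est_i <- i
      out[[i]] <- orfs
    }
  }
  out <- out[!vapply(out, is.null, FALSE)]
  if (!length(out))
    return(data.frame(frame = character(0), cds_start = integer(0),
                      cds_end = integer(0), protein = character(0),
                      has_start = logical(0), has_stop = logical(0),
                      est_i = integer(0)))
  do.call(rbind, out)
}

## fast identifiability check used by the generator: the encoded precursor
## must be the unique longest stop-free stretch over all six frames
orf_recovery_ok <- function(seq, precursor, min_codons = 30) {
  rc <- revcomp_chr(seq)
  found <- FALSE
  for (f in FRAME_ORDER) {
    off <- as.integer(substr(f, 2, 2)) - 1L
    s <- if (startsWith(f, "+")) seq else rc
    parts <- strsplit(translate_chr(substr(s, off + 1L, nchar(seq))),
                      "*", fixed = TRUE)[[1]]
    for (p in parts) {
      if (identical(p, precursor)) found <- TRUE
      else if (nchar(p) >= nchar(precursor)) return(FALSE)
    }
  }
  found
}
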