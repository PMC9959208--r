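## Toxin precursor segmentation: signal peptide, PQM-terminated propeptide,
## mature peptide and the C-terminal amidation rule.

## Kyte-Doolittle hydropathy
KD <- c(I = 4.5, V = 4.2, L = 3.8, F = 2.8, C = 2.5, M = 1.9, A = 1.8,
        G = -0.4, T = -0.7, S = -0.8, W = -0.9, Y = -1.3, P = -1.6,
        H = -3.2, E = -3.5, Q = -3.5, D = -3.5, N = -3.5, K = -3.9, R = -4.5)

SMALL_RESIDUES <- c("A", "G", "S", "C", "T")

#' Call a signal-peptide cleavage site
#'
#' Heuristic signal-peptide caller: scans candidate cleavage positions
#' 15-35 of an M-initiated sequence; a site qualifies when the mean
#' Kyte-Doolittle hydropathy over the 8 residues preceding position -5
#' (the hydrophobic core) is at least `min_hydropathy` and the residues at
#' -1 and -3 relative to cleavage are small (A, G, S, C, T). The
#' highest-scoring site (core hydropathy; first on ties) is returned. A
#' sequence not starting with M is treated as N-terminally truncated. The
#' caller is deliberately pluggable: any function with this signature can
#' replace it in the pipeline configuration.
#'
#' @param seq precursor amino-acid string
#' @param range candidate cleavage positions (signal-peptide lengths)
#' @param min_hydropathy hydrophobic-core gate
#' @return list `cleavage` (signal length in residues, or NA),
#'   `partial_n_terminus` (no initiator M)
#' @export
call_signal_peptide <- function(seq, range = 15:35, min_hydropathy = 1.5) {
  n <- nchar(seq)
  if (n < 18)
    return(list(cleavage = NA_integer_, partial_n_terminus = FALSE))
  aa <- seq_chars(seq)
  if (aa[1] != "M")
    return(list(cleavage = NA_integer_, partial_n_terminus = TRUE))
  best <- NA_integer_
  best_score <- -Inf
  for (c_pos in range) {
    if (c_pos >= n || c_pos - 12 < 2) next
    core <- aa[(c_pos - 12):(c_pos - 5)]
    if (any(!core %in% names(KD))) next
    h <- mean(KD[core])
    if (h < min_hydropathy) next
    if (!(aa[c_pos] %in% SMALL_RESIDUES) || !(aa[c_pos - 2] %in% SMALL_RESIDUES))
      next
    if (h > best_score) {
      best_score <- h
      best <- c_pos
    }
  }
  list(cleavage = best, partial_n_terminus = FALSE)
}

#' Call a propeptide cleavage site by the PQM rule
#'
#' The processing quadruplet motif (PQM) is operationalized as a
#' four-residue window ending in arginine with at least one glutamate at
#' its first three positions; cleavage falls immediately after the R. When
#' several windows qualify, the last one preceding the first cysteine is
#' taken; mature peptides are cysteine-anchored, so a site at or beyond
#' the first cysteine is not a propeptide boundary.
#'
#' @param seq amino-acid string with the signal peptide already removed
#' @return cleavage position (propeptide length in residues) or NA
#' @export
call_propeptide <- function(seq) {
  aa <- seq_chars(seq)
  first_c <- match("C", aa)
  limit <- if (is.na(first_c)) length(aa) else first_c - 1L
  sites <- integer(0)
  if (limit >= 4L) {
    for (p in 4:min(limit, length(aa))) {
      if (aa[p] == "R" && any(aa[(p - 3):(p - 1)] == "E")) sites <- c(sites, p)
    }
  }
  if (!length(sites)) NA_integer_ else max(sites)
}

#' Apply the C-terminal amidation rule
#'
#' Recognizes the -G, -GK and -GGK amidation signals: at most one trailing
#' K is removed, then a terminal G marks the peptide as amidated and is
#' removed (so -GGK leaves a terminal G on the amidated peptide).
#'
#' @param mature_candidate mature peptide before C-terminal processing
#' @return list `mature` (processed peptide), `amidated`
#' @export
apply_amidation <- function(mature_candidate) {
  stopifnot(nzchar(mature_candidate))
  s <- mature_candidate
  if (endsWith(s, "K")) s <- substr(s, 1, nchar(s) - 1)
  amid <- endsWith(s, "G")
  if (amid) s <- substr(s, 1, nchar(s) - 1)
  if (!nzchar(s)) stop("degenerate mature peptide after C-terminal processing")
  list(mature = s, amidated = amid)
}

#' Build a toxin name
#'
#' Names follow the `<prefix>-<serial>` convention with `-P` appended for
#' partial (N-terminally truncated) sequences and `-T` for transcriptomic
#' provenance, in that order.
#'
#' @param serial positive integer
#' @param partial,transcriptomic flags
#' @param prefix species prefix, default `"LcTx"`
#' @return name string
#' @examples
#' assign_name(64, FALSE, FALSE)        # "LcTx-64"
#' assign_name(1436, TRUE, TRUE)        # "LcTx-1436-P-T"
#' @export
assign_name <- function(serial, partial = FALSE, transcriptomic = FALSE,
                        prefix = "LcTx") {
  stopifnot(serial >= 1)
  paste0(prefix, "-", serial,
         if (partial) "-P" else "", if (transcriptomic) "-T" else "")
}

#' Segment a toxin precursor
#'
#' Runs the signal-peptide caller, the PQM propeptide rule and the
#' amidation rule on a full precursor, returning 0-based half-open
#' amino-acid coordinates of each segment. The mature segment coordinates
#' refer to the unprocessed precursor (amidation residues included); the
#' processed mature peptide is returned separately.
#'
#' @param full_seq precursor amino-acid string
#' @param signal_fun signal-peptide caller, by default
#'   [call_signal_peptide()]
#' @return list of class `precursor_call`: `full_seq`, `signal`
#'   (c(start, end) or NULL), `propeptide` (or NULL), `mature_region`
#'   (pre-processing coordinates), `mature` (processed peptide),
#'   `amidated`, `partial_n_terminus`
#' @export
segment_precursor <- function(full_seq, signal_fun = call_signal_peptide) {
  sig <- signal_fun(full_seq)
  sig_end <- if (is.na(sig$cleavage)) 0L else sig$cleavage
  rest <- substr(full_seq, sig_end + 1L, nchar(full_seq))
  pro_len <- if (nzchar(rest)) call_propeptide(rest) else NA_integer_
  pro_end <- sig_end + if (is.na(pro_len)) 0L else pro_len
  mature_raw <- substr(full_seq, pro_end + 1L, nchar(full_seq))
  am <- if (nzchar(mature_raw)) apply_amidation(mature_raw)
        else list(mature = "", amidated = FALSE)
  structure(list(
    full_seq = full_seq,
    signal = if (sig_end > 0L) c(0L, sig_end) else NULL,
    propeptide = if (!is.na(pro_len)) c(sig_end, pro_end) else NULL,
    mature_region = c(pro_end, nchar(full_seq)),
    mature = am$mature, amidated = am$amidated,
    partial_n_terminus = sig$partial_n_terminus
  ), class = "precursor_call")
}

#' @export
print.precursor_call <- function(x, ...) {
  seg <- function(v) if (is.null(v)) "-" else sprintf("[%d,%d)", v[1], v[2])
  cat(sprintf("precursor (%d aa): signal %s, propeptide %s, mature %s%s%s\n",
              nchar(x$full_seq), seg(x$signal), seg(x$propeptide),
              seg(x$mature_region),
              if (x$amidated) ", amidated" else "",
              if (x$partial_n_terminus) ", N-terminally truncated" else ""))
  invisible(x)
}
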