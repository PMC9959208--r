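## Local alignment wrappers. Protein homology search uses Smith-Waterman
## with BLOSUM62 and affine gaps (open 11, extend 1; a gap of length L costs
## 11 + L). Nucleotide overlap detection uses +1/-1 match/mismatch scoring.

blosum62 <- local({
  env <- new.env()
  function() {
    if (is.null(env$m)) {
      utils::data("BLOSUM62", package = "Biostrings", envir = env)
      env$m <- env$BLOSUM62
    }
    env$m
  }
})

#' Local protein alignment (Smith-Waterman, BLOSUM62)
#'
#' @param query,subject amino-acid strings
#' @param gap_open,gap_extend affine gap penalties; a gap of length L costs
#'   `gap_open + L * gap_extend`
#' @return list of class `homology_hit` core: `score` (BLOSUM62 units),
#'   `identity_pct` (exact matches over alignment columns, including gap
#'   columns), `query_cov_pct` (aligned query residues over query length)
#' @export
align_protein <- function(query, subject, gap_open = 11, gap_extend = 1) {
  stopifnot(nzchar(query), nzchar(subject))
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(subject),
    type = "local", substitutionMatrix = blosum62(),
    gapOpening = gap_open, gapExtension = gap_extend)
  al_len <- Biostrings::nchar(al)
  qr <- Biostrings::pattern(al)
  aligned_q <- Biostrings::width(qr@range)
  list(score = as.numeric(Biostrings::score(al)),
       identity_pct = if (al_len > 0) 100 * Biostrings::nmatch(al) / al_len else 0,
       query_cov_pct = 100 * aligned_q / nchar(query))
}

## vectorized protein alignment: many queries against one subject.
## Returns a data.frame(score, identity_pct, query_cov_pct), one row per query.
align_protein_many <- function(queries, subject, gap_open = 11, gap_extend = 1) {
  if (!length(queries))
    return(data.frame(score = numeric(0), identity_pct = numeric(0),
                      query_cov_pct = numeric(0)))
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(queries), Biostrings::AAString(subject),
    type = "local", substitutionMatrix = blosum62(),
    gapOpening = gap_open, gapExtension = gap_extend)
  al_len <- Biostrings::nchar(al)
  aligned_q <- Biostrings::width(Biostrings::pattern(al)@range)
  data.frame(score = as.numeric(Biostrings::score(al)),
             identity_pct = ifelse(al_len > 0,
                                   100 * Biostrings::nmatch(al) / al_len, 0),
             query_cov_pct = 100 * aligned_q / nchar(queries))
}

#' Best local overlap between two nucleotide sequences
#'
#' Used by the greedy EST clustering stage: the overlap is the best-scoring
#' local alignment under +1/-1 match/mismatch scoring with affine gaps.
#'
#' @param a,b nucleotide strings
#' @param gap_open,gap_extend gap penalties for the overlap alignment
#' @return list with `overlap_len` (alignment columns) and `identity_pct`
#'   (matches over alignment columns)
#' @export
dna_submat <- local({
  env <- new.env()
  function() {
    if (is.null(env$m))
      env$m <- Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -1, baseOnly = FALSE)
    env$m
  }
})

pairwise_overlap_identity <- function(a, b, gap_open = 5, gap_extend = 2) {
  stopifnot(nzchar(a), nzchar(b))
  mat <- dna_submat()
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "local",
    substitutionMatrix = mat, gapOpening = gap_open, gapExtension = gap_extend)
  len <- Biostrings::nchar(al)
  list(overlap_len = len,
       identity_pct = if (len > 0) 100 * Biostrings::nmatch(al) / len else 0)
}
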