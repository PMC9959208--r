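#' Round half away from zero
#'
#' Fixed-point rounding in which a digit of exactly 5 always rounds up
#' (2.345 -> 2.35), unlike [base::round()]'s round-half-to-even. All
#' percentages reported by the pipeline use this rule.
#'
#' @param x numeric vector (non-negative in all pipeline uses)
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

## split a sequence string into a character vector of residues
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

`%||%` <- function(a, b) if (is.null(a)) b else a

## deterministic FASTA writer (one sequence per line, LF endings)
write_fasta <- function(ids, seqs, path) {
  stopifnot(length(ids) == length(seqs))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste0(">", ids, "\n", seqs), con, sep = "\n")
  invisible(path)
}

read_fasta_df <- function(path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  x <- if (type == "DNA") Biostrings::readDNAStringSet(path)
       else Biostrings::readAAStringSet(path)
  data.frame(id = sub("\\s.*$", "", names(x)), seq = as.character(x),
             stringsAsFactors = FALSE, row.names = NULL)
}
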