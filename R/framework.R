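## Cysteine frameworks: ordered cysteine positions of a mature peptide
## written C1..Cn, with "-" between consecutive cysteines separated by at
## least one residue and no separator when they are sequence-adjacent
## (e.g. "C1-C2-C3C4-C5-C6" for the classic six-cysteine knottin layout).

#' Extract the cysteine framework of a mature peptide
#'
#' @param mature amino-acid string
#' @return object of class `cys_framework`: `positions` (1-based indices of
#'   cysteines), `n_cys`, `adj` (logical, `adj[i]` = cysteines i and i+1 are
#'   sequence-adjacent), `notation` (the framework string; empty when the
#'   peptide has no cysteines)
#' @examples
#' extract_framework("XCXXCXCCXXCXXC")$notation  # "C1-C2-C3C4-C5-C6"
#' @export
extract_framework <- function(mature) {
  stopifnot(is.character(mature), length(mature) == 1L)
  pos <- which(seq_chars(mature) == "C")
  adj <- if (length(pos) > 1L) diff(pos) == 1L else logical(0)
  new_framework(pos, adj)
}

new_framework <- function(positions, adj) {
  n <- length(positions)
  structure(list(positions = as.integer(positions), n_cys = n,
                 adj = as.logical(adj),
                 notation = framework_notation(n, adj)),
            class = "cys_framework")
}

framework_notation <- function(n_cys, adj) {
  if (n_cys == 0L) return("")
  toks <- paste0("C", seq_len(n_cys))
  if (n_cys == 1L) return(toks)
  sep <- ifelse(adj, "", "-")
  paste0(paste0(toks[-n_cys], sep, collapse = ""), toks[n_cys])
}

#' Parse a cysteine-framework notation string
#'
#' Inverse of the serialization used by [extract_framework()]: tokens
#' `C1..Cn` joined by `-`, with adjacent cysteines concatenated.
#'
#' @param notation framework string, e.g. `"C1-C2-C3C4-C5-C6"`
#' @return a `cys_framework` (positions are a canonical realization with one
#'   residue between non-adjacent cysteines)
#' @export
parse_framework <- function(notation) {
  stopifnot(is.character(notation), length(notation) == 1L)
  if (!nzchar(notation)) return(new_framework(integer(0), logical(0)))
  m <- gregexpr("C\\d+", notation)[[1]]
  if (m[1] == -1) stop("not a framework notation: ", notation)
  toks <- regmatches(notation, gregexpr("C\\d+", notation))[[1]]
  if (sum(nchar(toks)) + sum(grepl("-", seq_len(0))) == 0) stop("empty")
  idx <- as.integer(sub("C", "", toks))
  if (!identical(idx, seq_along(idx)))
    stop("framework tokens must be C1..Cn in order: ", notation)
  ends <- m + attr(m, "match.length") - 1L
  adj <- if (length(toks) > 1L) m[-1] == ends[-length(ends)] + 1L else logical(0)
  ## positions: canonical spacing (gap of 1 residue unless adjacent)
  pos <- integer(length(idx))
  pos[1] <- 2L
  if (length(idx) > 1L)
    for (i in 2:length(idx)) pos[i] <- pos[i - 1L] + if (adj[i - 1L]) 1L else 2L
  new_framework(pos, adj)
}

#' @export
print.cys_framework <- function(x, ...) {
  cat(sprintf("cysteine framework: %s (%d cysteines)\n",
              if (nzchar(x$notation)) x$notation else "<none>", x$n_cys))
  invisible(x)
}

#' Bundled disulfide-scaffold catalogue
#'
#' Framework patterns with their disulfide connectivities: the inhibitor
#' cystine knot in its 6- and 8-cysteine forms, the disulfide-directed
#' hairpin (DDH), the Kunitz fold, the 10- and 14-cysteine spider-toxin
#' scaffolds, the 8-cysteine non-adjacent scaffold, and the single-disulfide
#' 2-cysteine entry. Connectivities are assigned by framework similarity
#' only, never predicted de novo.
#'
#' @return data.frame with columns `pattern`, `motif`, `pairs` (string form
#'   `"1-4,2-5,..."`), plus parsed `n_cys`
#' @export
scaffold_catalogue <- function() {
  path <- system.file("extdata", "scaffold_catalogue.tsv", package = "venomest",
                      mustWork = TRUE)
  cat <- utils::read.delim(path, stringsAsFactors = FALSE)
  cat$n_cys <- vapply(cat$pattern, function(p) parse_framework(p)$n_cys, 0L)
  cat
}

parse_pairs <- function(s) {
  if (!nzchar(s)) return(list())
  lapply(strsplit(strsplit(s, ",", fixed = TRUE)[[1]], "-", fixed = TRUE),
         as.integer)
}

#' Assign a disulfide scaffold to a cysteine framework
#'
#' Looks the framework up in the bundled catalogue by exact match on
#' cysteine count and adjacency layout. When two catalogue folds share a
#' layout (DDH and Kunitz both have six well-separated cysteines) the first
#' catalogue entry wins. Frameworks absent from the catalogue are returned
#' as motif `"unassigned"` with no pairs.
#'
#' @param framework a `cys_framework` (or notation string)
#' @param catalogue optional catalogue data.frame, default [scaffold_catalogue()]
#' @return list of class `scaffold_entry`: `motif`, `pattern`,
#'   `disulfide_pairs` (list of integer pairs, or `NULL`)
#' @export
assign_scaffold <- function(framework, catalogue = scaffold_catalogue()) {
  if (is.character(framework)) framework <- parse_framework(framework)
  stopifnot(inherits(framework, "cys_framework"))
  for (i in seq_len(nrow(catalogue))) {
    pat <- parse_framework(catalogue$pattern[i])
    if (pat$n_cys == framework$n_cys && identical(pat$adj, framework$adj)) {
      pairs <- parse_pairs(catalogue$pairs[i])
      return(structure(list(motif = catalogue$motif[i],
                            pattern = catalogue$pattern[i],
                            disulfide_pairs = pairs),
                       class = "scaffold_entry"))
    }
  }
  structure(list(motif = "unassigned", pattern = framework$notation,
                 disulfide_pairs = NULL), class = "scaffold_entry")
}

#' @export
print.scaffold_entry <- function(x, ...) {
  p <- if (is.null(x$disulfide_pairs)) "none" else
    paste(vapply(x$disulfide_pairs, paste, "", collapse = "-"), collapse = ", ")
  cat(sprintf("scaffold %s (%s); disulfide pairs: %s\n", x$motif, x$pattern, p))
  invisible(x)
}

## adjacency layout after loss of one cysteine (point mutation of cysteine i):
## every adjacency involving i disappears; remaining indices close ranks.
drop_cys_adj <- function(adj, i) {
  n <- length(adj) + 1L
  keep <- setdiff(seq_len(n), i)
  out <- logical(length(keep) - 1L)
  for (k in seq_along(out)) {
    a <- keep[k]; b <- keep[k + 1L]
    out[k] <- (b == a + 1L) && adj[a]
  }
  out
}

framework_matches <- function(framework, pattern_fw, allow_one_loss = TRUE) {
  if (pattern_fw$n_cys == framework$n_cys &&
      identical(pattern_fw$adj, framework$adj)) return(TRUE)
  if (allow_one_loss && framework$n_cys == pattern_fw$n_cys - 1L &&
      pattern_fw$n_cys >= 2L) {
    for (i in seq_len(pattern_fw$n_cys))
      if (identical(drop_cys_adj(pattern_fw$adj, i), framework$adj)) return(TRUE)
  }
  FALSE
}
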