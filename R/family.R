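## Family classification of toxin precursors: candidate families are those
## whose framework pattern matches the observed cysteine framework (allowing
## the loss of one cysteine by point mutation); among candidates the family
## with the highest mature-peptide identity to any of its templates wins.
## Toxin-like precursors matching no family are collected in family K, the
## low-homology catch-all.

## Template similarity is scored as alignment identity weighted by query
## coverage (identity_pct * query_cov_pct / 100), so a short, locally
## perfect alignment to the wrong family cannot outscore full-length
## similarity to the right one.

#' Classify a toxin precursor into a family
#'
#' @param mature processed mature peptide (amino-acid string)
#' @param framework its `cys_framework`; computed from `mature` when NULL
#' @param templates family catalogue data.frame, default [family_catalogue()]
#' @param min_identity_pct minimum template identity (matches over query
#'   length, percent)
#' @return list of class `family_assignment`: `family` (letter or
#'   `"unassigned"`), `template_id`, `identity_pct`, `evidence` (character
#'   vector among `"framework-match"`, `"homology-best-hit"`,
#'   `"identity-cluster"`)
#' @export
classify_family <- function(mature, framework = NULL,
                            templates = family_catalogue(),
                            min_identity_pct = 60) {
  res <- classify_families(mature, list(framework %||% extract_framework(mature)),
                           templates, min_identity_pct)
  structure(as.list(res[1, ]), class = "family_assignment")
}

## batch version; frameworks is a list of cys_framework (or NULL entries)
classify_families <- function(matures, frameworks = NULL,
                              templates = family_catalogue(),
                              min_identity_pct = 60) {
  if (!nrow(templates)) stop("empty family template set")
  n <- length(matures)
  if (is.null(frameworks)) frameworks <- lapply(matures, extract_framework)
  pat_fw <- lapply(templates$framework, parse_framework)
  ## identity of every mature to every template (matches / query length)
  idm <- matrix(0, nrow = n, ncol = nrow(templates))
  ok <- nzchar(matures) & !is.na(matures)
  uq <- unique(matures[ok])
  for (j in seq_len(nrow(templates))) {
    h <- align_protein_many(uq, templates$mature_core[j])
    ident_q <- ifelse(nchar(uq) > 0,
                      h$identity_pct * h$query_cov_pct / 100, 0)
    idm[ok, j] <- ident_q[match(matures[ok], uq)]
  }
  out <- data.frame(family = rep("unassigned", n),
                    template_id = NA_character_, identity_pct = NA_real_,
                    evidence = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    if (!ok[i]) next
    fw <- frameworks[[i]]
    cand <- which(vapply(pat_fw, function(p)
      framework_matches(fw, p, allow_one_loss = TRUE), FALSE))
    scores <- idm[i, ]
    if (length(cand) && max(scores[cand]) >= min_identity_pct) {
      j <- cand[which.max(scores[cand])]
      out$family[i] <- templates$family[j]
      out$template_id[i] <- templates$template_id[j]
      out$identity_pct[i] <- scores[j]
      out$evidence[i] <- "framework-match+homology-best-hit"
    } else if (max(scores) >= min_identity_pct) {
      j <- which.max(scores)
      out$family[i] <- templates$family[j]
      out$template_id[i] <- templates$template_id[j]
      out$identity_pct[i] <- scores[j]
      out$evidence[i] <- "homology-best-hit"
    } else {
      ## low homology, odd framework: the family K catch-all
      out$family[i] <- "K"
      out$identity_pct[i] <- max(scores)
      out$evidence[i] <- "identity-cluster"
    }
  }
  out
}

#' @export
print.family_assignment <- function(x, ...) {
  cat(sprintf("family %s (%s; identity %.1f%%)\n", x$family,
              x$evidence, x$identity_pct))
  invisible(x)
}
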