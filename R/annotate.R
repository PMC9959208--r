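## Homology-based categorization of ESTs into toxin-like / cellular
## component / non-matched classes, by translated local alignment of the
## best ORF against two reference protein panels.

#' Bundled reference panels
#'
#' `toxin_panel_default()` returns the synthetic family-template precursor
#' proteins (signal peptide + propeptide + mature peptide) bundled with the
#' package; `cellular_panel_default()` returns the synthetic
#' housekeeping-like panel. Both are stand-ins users can replace with their
#' own FASTA panels.
#'
#' @return data.frame with columns `id`, `seq`
#' @export
toxin_panel_default <- function() {
  cat <- family_catalogue()
  data.frame(id = cat$template_id,
             seq = paste0(cat$signal_template, cat$pro_template,
                          cat$mature_core),
             stringsAsFactors = FALSE)
}

#' @rdname toxin_panel_default
#' @export
cellular_panel_default <- function() {
  read_fasta_df(system.file("extdata", "cellular_panel.fasta",
                            package = "venomest", mustWork = TRUE), "AA")
}

## best hit of each query protein against one panel.
## Returns data.frame(subject_id, score, identity_pct, query_cov_pct).
panel_best_hits <- function(proteins, panel) {
  n <- length(proteins)
  best <- data.frame(subject_id = rep(NA_character_, n), score = -Inf,
                     identity_pct = 0, query_cov_pct = 0)
  if (!n || !nrow(panel)) return(best)
  for (j in seq_len(nrow(panel))) {
    h <- align_protein_many(proteins, panel$seq[j])
    upd <- h$score > best$score
    if (any(upd)) {
      best$subject_id[upd] <- panel$id[j]
      best$score[upd] <- h$score[upd]
      best$identity_pct[upd] <- h$identity_pct[upd]
      best$query_cov_pct[upd] <- h$query_cov_pct[upd]
    }
  }
  best
}

#' Categorize an EST by translated homology search
#'
#' Translates the EST in six frames, takes the best ORF and aligns its
#' protein against the toxin and cellular panels. The best hit passing both
#' the identity and coverage thresholds decides the category; the toxin
#' panel wins ties on equal score. With no ORF or no passing hit the EST is
#' non-matched.
#'
#' @param est a single-row data.frame or list with a `trimmed_seq` (or
#'   `seq`) element
#' @param toxin_panel,cellular_panel data.frames with `id`, `seq`
#' @param min_identity_pct,min_cov_pct acceptance thresholds (percent)
#' @param min_codons minimum ORF length in codons
#' @return list of class `category_call`: `category`, `best_hit` (or NULL),
#'   `reason` (for non-matched), `protein` (best-ORF protein or NA)
#' @export
categorize <- function(est, toxin_panel = toxin_panel_default(),
                       cellular_panel = cellular_panel_default(),
                       min_identity_pct = 40, min_cov_pct = 50,
                       min_codons = 30) {
  stopifnot(nrow(toxin_panel) > 0, nrow(cellular_panel) > 0)
  s <- est$trimmed_seq %||% est$seq
  orfs <- six_frame_orfs(s, min_codons = min_codons)
  if (!nrow(orfs))
    return(structure(list(category = "non-matched", best_hit = NULL,
                          reason = "no-orf", protein = NA_character_),
                     class = "category_call"))
  ## every ORF is searched; the best passing hit over all of them decides
  calls <- categorize_proteins(orfs$protein, toxin_panel, cellular_panel,
                               min_identity_pct, min_cov_pct)
  j <- select_category_call(calls)
  if (is.na(j))
    return(structure(list(category = "non-matched", best_hit = NULL,
                          reason = "no-hit",
                          protein = best_orf(orfs)$protein),
                     class = "category_call"))
  hit <- list(subject_id = calls$subject_id[j], panel = calls$panel[j],
              identity_pct = calls$identity_pct[j],
              query_cov_pct = calls$query_cov_pct[j], score = calls$score[j])
  structure(list(category = calls$category[j], best_hit = hit,
                 reason = NA_character_, protein = orfs$protein[j]),
            class = "category_call")
}

## index of the winning call among a set of ORF-level category calls:
## best score among passing hits, toxin panel first on ties; NA when no
## ORF passes the thresholds
select_category_call <- function(calls) {
  passing <- which(calls$category != "non-matched")
  if (!length(passing)) return(NA_integer_)
  passing[order(-calls$score[passing], calls$panel[passing] != "toxin")][1]
}

## vectorized category calls for a set of proteins (NA protein = no ORF).
## Deduplicates identical proteins before aligning.
categorize_proteins <- function(proteins, toxin_panel, cellular_panel,
                                min_identity_pct = 40, min_cov_pct = 50) {
  n <- length(proteins)
  out <- data.frame(category = rep("non-matched", n),
                    panel = NA_character_, subject_id = NA_character_,
                    score = NA_real_, identity_pct = NA_real_,
                    query_cov_pct = NA_real_, stringsAsFactors = FALSE)
  ok <- !is.na(proteins) & nzchar(proteins)
  uq <- unique(proteins[ok])
  if (!length(uq)) return(out)
  tox <- panel_best_hits(uq, toxin_panel)
  cel <- panel_best_hits(uq, cellular_panel)
  pass_t <- tox$identity_pct >= min_identity_pct & tox$query_cov_pct >= min_cov_pct
  pass_c <- cel$identity_pct >= min_identity_pct & cel$query_cov_pct >= min_cov_pct
  cat_u <- rep("non-matched", length(uq))
  use_t <- pass_t & (!pass_c | tox$score >= cel$score)  # toxin wins ties
  use_c <- pass_c & !use_t
  cat_u[use_t] <- "toxin-like"
  cat_u[use_c] <- "cellular"
  idx <- match(proteins[ok], uq)
  out$category[ok] <- cat_u[idx]
  pick <- function(col) ifelse(use_t, tox[[col]], ifelse(use_c, cel[[col]], NA))
  out$panel[ok] <- ifelse(use_t, "toxin", ifelse(use_c, "cellular",
                                                 NA_character_))[idx]
  out$subject_id[ok] <- pick("subject_id")[idx]
  out$score[ok] <- pick("score")[idx]
  out$identity_pct[ok] <- pick("identity_pct")[idx]
  out$query_cov_pct[ok] <- pick("query_cov_pct")[idx]
  out
}

#' @export
print.category_call <- function(x, ...) {
  cat("category:", x$category)
  if (!is.null(x$best_hit))
    cat(sprintf(" (best hit %s [%s], %.1f%% identity, %.1f%% coverage)",
                x$best_hit$subject_id, x$best_hit$panel,
                x$best_hit$identity_pct, x$best_hit$query_cov_pct))
  cat("\n")
  invisible(x)
}
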