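## End-to-end pipeline: QC -> homology annotation -> clustering ->
## precursor processing -> framework/family classification -> optional
## peptide-mass census -> report.

#' Pipeline parameters
#'
#' Every tunable threshold of the pipeline with its default: the
#' high-quality EST length rule, poly-A detection, ORF and homology
#' thresholds, clustering thresholds, family classification identity and
#' the mass-census window and tolerance.
#'
#' @param min_len_exclusive high-quality rule: keep ESTs longer than this (nt)
#' @param max_n_frac maximum N fraction tolerated per EST
#' @param polya_min_run,polya_max_mismatch poly-A tail detection
#' @param min_codons minimum ORF length (codons)
#' @param min_identity_pct,min_cov_pct homology categorization thresholds (%)
#' @param cluster_min_overlap,cluster_min_identity_pct clustering thresholds
#' @param family_min_identity_pct family template identity threshold (%)
#' @param mass_lo,mass_hi peptide mass window (Da)
#' @param mass_tolerance_da species merge / match tolerance (Da)
#' @param assume_protonated treat observed peaks as [M+H]+
#' @param prefix toxin name prefix
#' @param signal_fun signal-peptide caller (pluggable)
#' @return list of class `pipeline_params`
#' @export
pipeline_params <- function(min_len_exclusive = 300, max_n_frac = 0.05,
                            polya_min_run = 10, polya_max_mismatch = 1,
                            min_codons = 30, min_identity_pct = 40,
                            min_cov_pct = 50, cluster_min_overlap = 100,
                            cluster_min_identity_pct = 96,
                            family_min_identity_pct = 60,
                            mass_lo = 1000, mass_hi = 10000,
                            mass_tolerance_da = 0.5,
                            assume_protonated = FALSE, prefix = "LcTx",
                            signal_fun = call_signal_peptide) {
  structure(as.list(environment()), class = "pipeline_params")
}

#' Run the full EST annotation pipeline
#'
#' @param input a `synthetic_library` (from [generate_library()]), or a
#'   data.frame with `id`, `seq`, `origin` columns, or a character vector
#'   of one or two FASTA paths (library, and optionally transcriptomic)
#' @param params a [pipeline_params()] list
#' @param peaks optional per-fraction peak list (data.frame `fraction_id`,
#'   `mz`, or a path readable by [read_peak_list()]) for the mass census
#' @param toxin_panel,cellular_panel reference protein panels
#' @param out_dir optional directory; when given, tables, FASTA files and a
#'   JSON manifest are written there
#' @return object of class `venomest_report`; see [print.venomest_report()]
#' @export
run_pipeline <- function(input, params = pipeline_params(), peaks = NULL,
                         toxin_panel = toxin_panel_default(),
                         cellular_panel = cellular_panel_default(),
                         out_dir = NULL) {
  ests <- pipeline_input(input)

  ## --- QC ------------------------------------------------------------------
  qc <- qc_filter(ests, params$min_len_exclusive, params$max_n_frac)
  kept <- add_polya_columns(qc$kept, params$polya_min_run,
                            params$polya_max_mismatch)
  if (!nrow(kept)) stop("stage qc: no EST passed quality control")

  ## --- ORFs and homology categories ---------------------------------------
  ## every ORF of every EST is searched against both panels (as a translated
  ## database search would); the best passing hit over all ORFs decides the
  ## category, and that ORF becomes the EST's representative coding region
  flat <- all_orfs_flat(kept$trimmed_seq, params$min_codons)
  calls <- categorize_proteins(flat$protein, toxin_panel, cellular_panel,
                               params$min_identity_pct, params$min_cov_pct)
  kept$category <- "non-matched"
  kept$protein <- NA_character_
  kept$cds <- NA_character_
  kept$best_hit <- NA_character_
  kept$hit_identity_pct <- NA_real_
  if (nrow(flat)) {
    for (i in unique(flat$est_i)) {
      idx <- which(flat$est_i == i)
      jj <- select_category_call(calls[idx, , drop = FALSE])
      j <- if (!is.na(jj)) idx[jj]
           else idx[order(-nchar(flat$protein[idx]))][1]  # longest ORF
      kept$protein[i] <- flat$protein[j]
      kept$cds[i] <- substr(kept$trimmed_seq[i], flat$cds_start[j] + 1L,
                            flat$cds_end[j])
      kept$category[i] <- calls$category[j]
      kept$best_hit[i] <- calls$subject_id[j]
      kept$hit_identity_pct[i] <- calls$identity_pct[j]
    }
  }

  tally <- category_percentages(sum(kept$category == "toxin-like"),
                                sum(kept$category == "cellular"),
                                sum(kept$category == "non-matched"))

  ## --- clustering per category --------------------------------------------
  orf_tab <- data.frame(est_id = kept$id, cds = kept$cds,
                        protein = kept$protein, stringsAsFactors = FALSE)
  clusters <- list(); summaries <- list()
  for (cat in c("toxin-like", "cellular", "non-matched")) {
    sub <- kept[kept$category == cat, , drop = FALSE]
    if (!nrow(sub)) next
    cl <- greedy_cluster(sub, params$cluster_min_overlap,
                         params$cluster_min_identity_pct)
    clusters[[cat]] <- cl
    summaries[[cat]] <- summarize_clusters(cl, orf_tab, cat)
  }

  ## --- toxin precursors ----------------------------------------------------
  tox <- kept[kept$category == "toxin-like" & !is.na(kept$protein), ,
              drop = FALSE]
  precursors <- NULL
  if (nrow(tox)) {
    first <- !duplicated(tox$protein)   # non-redundant precursor proteins
    uq <- tox[first, , drop = FALSE]
    segs <- lapply(uq$protein, segment_precursor, signal_fun = params$signal_fun)
    matures <- vapply(segs, `[[`, "", "mature")
    fws <- lapply(matures, extract_framework)
    fam <- classify_families(matures, fws, min_identity_pct =
                               params$family_min_identity_pct)
    scaf <- lapply(fws, assign_scaffold)
    n_ss <- vapply(seq_along(fws), function(i) {
      if (!is.null(scaf[[i]]$disulfide_pairs))
        length(scaf[[i]]$disulfide_pairs)
      else fws[[i]]$n_cys %/% 2L
    }, 0L)
    partial <- vapply(segs, `[[`, FALSE, "partial_n_terminus")
    amid <- vapply(segs, `[[`, FALSE, "amidated")
    masses <- lapply(seq_along(matures), function(i)
      if (nzchar(matures[i])) peptide_mass(matures[i], n_ss[i], amid[i])
      else list(monoisotopic_da = NA_real_, average_da = NA_real_))
    precursors <- data.frame(
      name = mapply(assign_name, seq_along(matures), partial,
                    uq$origin == "transcriptomic",
                    MoreArgs = list(prefix = params$prefix)),
      est_id = uq$id, origin = uq$origin,
      protein = uq$protein,
      signal_end = vapply(segs, function(s)
        if (is.null(s$signal)) NA_integer_ else s$signal[2], NA_integer_),
      pro_end = vapply(segs, function(s)
        if (!is.null(s$propeptide)) s$propeptide[2]
        else if (!is.null(s$signal)) s$signal[2] else 0L, NA_integer_),
      mature = matures, amidated = amid, partial = partial,
      framework = vapply(fws, `[[`, "", "notation"),
      n_cys = vapply(fws, `[[`, 0L, "n_cys"),
      scaffold = vapply(scaf, `[[`, "", "motif"),
      n_disulfides = n_ss,
      family = fam$family, template_id = fam$template_id,
      family_identity_pct = fam$identity_pct,
      monoisotopic_da = vapply(masses, `[[`, 0, "monoisotopic_da"),
      average_da = vapply(masses, `[[`, 0, "average_da"),
      n_ests = as.integer(table(tox$protein)[uq$protein]),
      stringsAsFactors = FALSE)
  }
  family_sizes <- family_size_table(precursors$family)
  shares <- if (!is.null(precursors)) {
    per_fam <- tapply(precursors$n_ests, precursors$family, sum)
    data.frame(family = names(per_fam),
               ests = as.integer(per_fam),
               share_pct = vapply(as.integer(per_fam), abundance_share,
                                  0, category_size = nrow(tox)),
               stringsAsFactors = FALSE)
  } else NULL

  ## --- optional mass census ------------------------------------------------
  census <- NULL
  if (!is.null(peaks)) {
    if (is.character(peaks)) peaks <- read_peak_list(peaks)
    inwin <- window_filter(peaks, params$mass_lo, params$mass_hi)
    species <- dedup_species(inwin, params$mass_tolerance_da)
    predicted <- if (!is.null(precursors))
      data.frame(name = precursors$name,
                 monoisotopic_da = precursors$monoisotopic_da,
                 average_da = precursors$average_da)
      else data.frame(name = character(0), monoisotopic_da = numeric(0),
                      average_da = numeric(0))
    matches <- match_predictions(species, predicted,
                                 params$mass_tolerance_da,
                                 params$assume_protonated)
    census <- list(n_peaks_in = nrow(peaks), n_peaks_window = nrow(inwin),
                   species = species, matches = matches)
  }

  report <- structure(list(
    ests = kept, rejected = qc$rejected, tally = tally,
    clusters = clusters, summaries = summaries,
    precursors = precursors, family_sizes = family_sizes, shares = shares,
    census = census, params = params,
    xref = attr(ests, "xref")), class = "venomest_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

pipeline_input <- function(input) {
  if (inherits(input, "synthetic_library")) return(input$ests)
  if (is.data.frame(input)) {
    stopifnot(all(c("id", "seq") %in% names(input)))
    if (is.null(input$origin)) input$origin <- "library"
    return(input)
  }
  if (is.character(input)) {
    for (p in input) if (!file.exists(p)) stop("missing input path: ", p)
    lib <- read_ests(input[1], "library")
    if (length(input) > 1) {
      txm <- read_ests(input[2], "transcriptomic")
      return(merge_sources(lib, txm))
    }
    return(lib)
  }
  stop("unsupported input type: ", paste(class(input), collapse = "/"))
}

#' @export
print.venomest_report <- function(x, ...) {
  cat("venomest pipeline report\n")
  cat(sprintf("  ESTs kept: %d (rejected: %d)\n", nrow(x$ests),
              nrow(x$rejected)))
  print(x$tally)
  for (s in x$summaries) cat(sprintf("  %s: %.2f%% clustered (%d clusters)\n",
                                     s$category, s$pct_clustered, s$n_clusters))
  if (!is.null(x$precursors)) {
    cat(sprintf("  %d non-redundant toxin precursors in %d families\n",
                nrow(x$precursors), sum(x$family_sizes$n > 0)))
  }
  if (!is.null(x$census))
    cat(sprintf("  mass census: %d distinct species from %d in-window peaks\n",
                x$census$species$n_species, x$census$n_peaks_window))
  invisible(x)
}

#' @export
summary.venomest_report <- function(object, ...) {
  cat("Category tally\n"); print(object$tally)
  cat("\nCluster summaries\n")
  for (s in object$summaries) print(s)
  if (!is.null(object$precursors)) {
    cat("\nFamily sizes\n")
    print(object$family_sizes, row.names = FALSE)
    cat("\nAbundance shares (of toxin-like ESTs)\n")
    print(object$shares, row.names = FALSE)
  }
  invisible(object)
}

## write the report bundle: tables, FASTA, JSON summary, manifest
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) utils::write.table(
    df, file.path(out_dir, name), sep = "\t", quote = FALSE,
    row.names = FALSE)
  w(report$ests[c("id", "origin", "category", "polya_len", "best_hit")],
    "est_annotations.tsv")
  w(report$rejected, "qc_rejections.tsv")
  for (cat in names(report$clusters)) {
    tag <- sub("-like", "", cat)
    w(report$clusters[[cat]]$membership,
      paste0("clusters_", tag, ".tsv"))
    cons <- vapply(report$clusters[[cat]]$clusters, `[[`, "", "consensus")
    write_fasta(sprintf("%s_cluster%04d", tag, seq_along(cons)), cons,
                file.path(out_dir, paste0("consensus_", tag, ".fasta")))
  }
  if (!is.null(report$precursors)) {
    w(report$precursors[setdiff(names(report$precursors), "protein")],
      "precursors.tsv")
    write_fasta(report$precursors$name, report$precursors$mature,
                file.path(out_dir, "mature_peptides.fasta"))
  }
  summary_json <- list(
    tally = unclass(report$tally),
    pct_clustered = lapply(report$summaries, `[[`, "pct_clustered"),
    family_sizes = report$family_sizes,
    n_species = if (!is.null(report$census))
      report$census$species$n_species else NULL)
  jsonlite::write_json(summary_json, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(
    package = "venomest",
    version = as.character(utils::packageVersion("venomest")),
    params = lapply(unclass(report$params), function(p)
      if (is.function(p)) "custom-function" else p))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Recovery of ground truth by the pipeline
#'
#' Joins a pipeline report against the generator's truth table and scores,
#' per EST: category recovery (all kept ESTs), and family, framework,
#' amidation and segmentation recovery (toxin ESTs; segmentation over
#' full-length, non-truncated records only). Used by the end-to-end
#' validation of the pipeline on synthetic libraries.
#'
#' @param report a `venomest_report`
#' @param truth the truth table of the `synthetic_library` that produced it
#' @return list of percentages (half-up, 2 decimals) and counts
#' @export
evaluate_recovery <- function(report, truth) {
  k <- report$ests
  t <- truth[match(k$id, truth$est_id), ]
  pct <- function(x) if (!length(x)) NA_real_ else round_half_up(100 * mean(x))
  category_ok <- k$category == t$category

  ## per-EST toxin annotations via the precursor table (joined on protein)
  tox_idx <- which(t$category == "toxin-like" & k$category == "toxin-like" &
                     !is.na(k$protein))
  p <- report$precursors
  m <- match(k$protein[tox_idx], p$protein)
  fam_ok <- p$family[m] == t$family[tox_idx]
  fw_ok <- p$framework[m] == t$framework[tox_idx]
  amid_ok <- p$amidated[m] == t$amidated[tox_idx]
  full <- !t$truncated[tox_idx]
  seg_ok <- p$signal_end[m] == t$signal_end[tox_idx] &
    p$pro_end[m] == t$pro_end[tox_idx]
  seg_ok[is.na(seg_ok)] <- FALSE     # unsegmentable counts as a miss
  list(n_ests = nrow(k),
       n_toxin_evaluated = length(tox_idx),
       category_pct = pct(category_ok),
       family_pct = pct(fam_ok),
       framework_pct = pct(fw_ok),
       amidation_pct = pct(amid_ok),
       segmentation_pct = pct(seg_ok[full]))
}
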