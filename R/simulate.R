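## Synthetic venom-gland EST library generator. Emulates a cDNA library:
## heavy-tailed per-gene transcript copy numbers dominated by toxin
## transcripts, toxin precursors built from the bundled family templates
## (signal peptide + optional PQM-terminated propeptide + cysteine-patterned
## mature peptide + optional -G/-GK/-GGK amidation signal), housekeeping-like
## cellular transcripts, unannotatable random cDNAs, sequencing
## substitutions and 5' truncations. Every emitted EST carries a ground
## truth row, and every gene is checked at build time to be recoverable by
## the pipeline on noise-free data (identifiability by construction).

AA20 <- names(AA_MONO)
PRO_FILL <- c("S", "T", "N", "Q", "D", "G", "P", "H", "K", "A")

#' Configuration for the synthetic library generator
#'
#' Defaults describe a mid-sized venom-gland library: 200 genes (100 toxin,
#' 60 cellular, 40 unannotatable), family weights proportional to the
#' family sizes of a lycosid venom gland (E the most abundant), ~2000 ESTs
#' with Zipf-distributed copy numbers, 0.5% substitution rate and 8%
#' 5'-truncation probability.
#'
#' @param n_toxin_genes,n_cellular_genes,n_random_genes gene counts
#' @param family_weights named probabilities over families A-K (sum to 1)
#' @param n_transcriptomic extra toxin transcripts tagged as assembled
#'   transcriptomic sequences (one copy each, no poly-A)
#' @param n_ests target total EST count for the copy-number law
#' @param copy_law Zipf exponent: gene of rank r receives ~ r^(-copy_law)
#'   copies
#' @param sub_rate per-base substitution probability
#' @param trunc_prob probability that an EST is 5'-truncated
#' @param trunc_extent range of the truncated fraction of the clone
#' @param polya_len poly-A tail length range (nt)
#' @param utr_len 3'UTR length range (nt); short-CDS genes get a longer
#'   3'UTR so that full-length clones stay above the 300-nt quality rule
#' @param mut_frac per-residue divergence of a toxin gene from its family
#'   template
#' @param cellular_mut_frac same for cellular genes
#' @param prefix toxin name prefix
#' @param seed integer random seed
#' @return validated list of class `generator_config`
#' @export
generator_config <- function(n_toxin_genes = 100,
                             family_weights = c(A = 3, B = 4, C = 5, D = 4,
                                                E = 32, F = 10, G = 14,
                                                H = 10, I = 3, J = 5,
                                                K = 8) / 98,
                             n_cellular_genes = 60, n_random_genes = 40,
                             n_transcriptomic = 5, n_ests = 2000,
                             copy_law = 1.0, sub_rate = 0.005,
                             trunc_prob = 0.08,
                             trunc_extent = c(0.05, 0.35),
                             polya_len = c(20, 60), utr_len = c(60, 120),
                             mut_frac = 0.15, cellular_mut_frac = 0.10,
                             prefix = "LcTx", seed = 1L) {
  cfg <- list(n_toxin_genes = n_toxin_genes, family_weights = family_weights,
              n_cellular_genes = n_cellular_genes,
              n_random_genes = n_random_genes,
              n_transcriptomic = n_transcriptomic, n_ests = n_ests,
              copy_law = copy_law, sub_rate = sub_rate,
              trunc_prob = trunc_prob, trunc_extent = trunc_extent,
              polya_len = polya_len, utr_len = utr_len, mut_frac = mut_frac,
              cellular_mut_frac = cellular_mut_frac, prefix = prefix,
              seed = as.integer(seed))
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  stopifnot(cfg$n_toxin_genes >= 0, cfg$n_cellular_genes >= 0,
            cfg$n_random_genes >= 0, cfg$n_transcriptomic >= 0)
  if (abs(sum(cfg$family_weights) - 1) > 1e-9)
    stop("family_weights must sum to 1")
  if (!all(names(cfg$family_weights) %in% LETTERS[1:11]))
    stop("family_weights names must be family letters A-K")
  probs <- c(cfg$family_weights, cfg$sub_rate, cfg$trunc_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$n_toxin_genes + cfg$n_cellular_genes + cfg$n_random_genes +
      cfg$n_transcriptomic == 0) stop("empty library")
  invisible(cfg)
}

## ---- sequence-building helpers -------------------------------------------

sample_chr <- function(pool, n) paste0(sample(pool, n, replace = TRUE),
                                       collapse = "")

## point mutations at the given rate; position i draws from alpha_fun(i)
mutate_seq <- function(s, rate, positions = NULL, alpha = AA20) {
  ch <- seq_chars(s)
  if (is.null(positions)) positions <- seq_along(ch)
  hit <- positions[stats::runif(length(positions)) < rate]
  for (i in hit) ch[i] <- sample(setdiff(alpha, ch[i]), 1)
  paste0(ch, collapse = "")
}

## mature-core mutation preserving the framework and the processing rules:
## cysteines fixed; no new C anywhere; no R before the first cysteine (the
## PQM window); no G/K at the C-terminal residue
mutate_core <- function(core, rate) {
  ch <- seq_chars(core)
  first_c <- match("C", ch) %||% NA
  for (i in seq_along(ch)) {
    if (ch[i] == "C" || stats::runif(1) >= rate) next
    alpha <- setdiff(AA20, c("C", ch[i]))
    if (!is.na(first_c) && i < first_c) alpha <- setdiff(alpha, "R")
    if (i == length(ch)) alpha <- setdiff(alpha, c("G", "K"))
    ch[i] <- sample(alpha, 1)
  }
  paste0(ch, collapse = "")
}

## signal mutation: keep the initiator M and the small residues at -1/-3
mutate_signal <- function(sig, rate = 0.08) {
  n <- nchar(sig)
  mutate_seq(sig, rate, positions = setdiff(2:(n - 1), c(n - 2)),
             alpha = setdiff(AA20, "C"))
}

## propeptide mutation: body only, PQM quadruplet untouched, no R/E/C
mutate_pro <- function(pro, rate = 0.08) {
  n <- nchar(pro)
  if (n <= 4) return(pro)
  mutate_seq(pro, rate, positions = 1:(n - 4), alpha = PRO_FILL)
}

draw_amidation_motif <- function(mode) {
  switch(mode,
         "G" = "G",
         "most" = if (stats::runif(1) < 0.9) "G" else "",
         "mixed" = sample(c("G", "GK", "GGK"), 1),
         "none" = "")
}

draw_propeptide_flag <- function(mode) {
  switch(mode,
         "always" = TRUE,
         "most" = stats::runif(1) < 0.9,
         "some" = stats::runif(1) < 0.4,
         "none" = FALSE)
}

#' Build one synthetic toxin precursor
#'
#' Draws a member of the given family from the bundled templates: the
#' mature core, signal peptide and (when the family carries one) the
#' propeptide are template sequences mutated at the configured divergence,
#' and the family's amidation signal is appended. The precursor is
#' rejected and redrawn until the pipeline's own segmentation and family
#' classification recover the intended ground truth on the noise-free
#' sequence, so that zero-noise recovery failures downstream indicate real
#' pipeline defects rather than ambiguous simulated genes.
#'
#' @param family family letter A-K
#' @param config a `generator_config` (controls divergence)
#' @param templates family catalogue data.frame
#' @return list: `full_seq`, `signal_end`, `pro_end` (aa, 0-based half-open
#'   segment ends), `mature` (processed), `framework`, `amidated`,
#'   `family`, `template_id`
#' @export
make_toxin_precursor <- function(family, config = generator_config(),
                                 templates = family_catalogue(),
                                 toxin_panel = toxin_panel_default(),
                                 cellular_panel = cellular_panel_default()) {
  rows <- templates[templates$family == family, , drop = FALSE]
  if (!nrow(rows)) stop("unknown family letter: ", family)
  for (try in 1:50) {
    tpl <- rows[sample(nrow(rows), 1), ]
    sig <- mutate_signal(tpl$signal_template)
    has_pro <- draw_propeptide_flag(tpl$propeptide)
    pro <- if (has_pro) mutate_pro(tpl$pro_template) else ""
    core <- mutate_core(tpl$mature_core, config$mut_frac)
    motif <- draw_amidation_motif(tpl$amidation)
    full <- paste0(sig, pro, core, motif)
    expected_mature <- if (identical(motif, "GGK")) paste0(core, "G") else core
    seg <- segment_precursor(full)
    if (is.null(seg$signal) || seg$signal[2] != nchar(sig)) next
    if (has_pro != !is.null(seg$propeptide)) next
    if (has_pro && seg$propeptide[2] != nchar(sig) + nchar(pro)) next
    if (!identical(seg$mature, expected_mature)) next
    if (seg$amidated != nzchar(motif)) next
    fam_call <- classify_families(seg$mature,
                                  list(extract_framework(seg$mature)),
                                  templates)
    if (!identical(fam_call$family[1], family)) next
    cat_call <- categorize_proteins(full, toxin_panel, cellular_panel)
    if (!identical(cat_call$category[1], "toxin-like")) next
    return(list(full_seq = full, signal_end = nchar(sig),
                pro_end = nchar(sig) + nchar(pro),
                mature = seg$mature,
                framework = extract_framework(seg$mature)$notation,
                amidated = nzchar(motif), family = family,
                template_id = tpl$template_id))
  }
  stop("could not build an identifiable precursor for family ", family)
}

## ---- reverse translation --------------------------------------------------

codon_table <- local({
  env <- new.env()
  function() {
    if (is.null(env$tab)) {
      gc <- Biostrings::GENETIC_CODE
      env$tab <- split(names(gc), unname(gc))
    }
    env$tab
  }
})

rt_cds <- function(protein) {
  tab <- codon_table()
  aa <- seq_chars(protein)
  paste0(vapply(aa, function(a) {
    opts <- tab[[a]]
    if (is.null(opts)) stop("cannot reverse-translate residue ", a)
    if (length(opts) == 1) opts else sample(opts, 1)
  }, "", USE.NAMES = FALSE), collapse = "")
}

#' Reverse-translate a precursor and package it as a cDNA
#'
#' Builds an ATG-initiated coding sequence (synonymous codons drawn
#' uniformly), appends a stop codon, a random 3'UTR and a poly-A tail.
#' Translating the CDS reproduces the precursor exactly.
#'
#' @param precursor amino-acid string (starting with M)
#' @param config a `generator_config` (UTR and poly-A length ranges)
#' @return list `cdna` (full sequence), `cds_len`, `utr_len`, `polya_len`
#' @export
reverse_translate_and_package <- function(precursor,
                                          config = generator_config()) {
  stopifnot(nzchar(precursor))
  base <- packaged_transcript(precursor, config)
  tail_len <- sample_range_int(config$polya_len)
  list(cdna = paste0(base$seq, strrep("A", tail_len)),
       cds_len = base$cds_len, utr_len = base$utr_len, polya_len = tail_len)
}

sample_range_int <- function(rg) {
  if (rg[2] <= rg[1]) as.integer(rg[1]) else sample(rg[1]:rg[2], 1)
}

## 3'UTR built from 7-nt units, each carrying a stop codon for the plus
## strand and one for the minus strand; the unit length is coprime to 3,
## so the stops rotate through all reading-frame phases within three
## units and no open reading frame can run far into the UTR
make_utr <- function(len) {
  units <- c("TAATTA", "TTATAA", "TAGCTA", "CTATAG")
  n_units <- len %/% 10L + 1L
  spacers <- vapply(seq_len(n_units), function(i)
    sample_chr(c("A", "C", "G", "T"), 4L), "")
  parts <- paste0(sample(units, n_units, replace = TRUE), spacers)
  substr(paste0(parts, collapse = ""), 1L, len)
}

## transcript without the poly-A tail. When a recovery check is supplied
## the codons and UTR are redrawn until either the encoded precursor is
## the unique longest ORF (cheap test) or the check — which emulates the
## pipeline's homology-driven ORF selection — accepts the sequence.
packaged_transcript <- function(precursor, config, recovery_check = NULL) {
  for (try in 1:100) {
    cds <- paste0(rt_cds(precursor), sample(c("TAA", "TAG", "TGA"), 1))
    utr_lo <- max(config$utr_len[1], 305L - nchar(cds) - config$polya_len[1])
    utr_hi <- max(config$utr_len[2], utr_lo)
    utr <- make_utr(sample_range_int(c(utr_lo, utr_hi)))
    seq <- paste0(cds, utr)
    if (!is.null(recovery_check) &&
        !orf_recovery_ok(seq, precursor) && !recovery_check(seq)) next
    return(list(seq = seq, cds_len = nchar(cds), utr_len = nchar(utr)))
  }
  stop("could not package an identifiable transcript")
}

## random cDNA with no homology to either panel in any reading frame
## (rejected and redrawn otherwise)
make_random_cdna <- function(config, toxin_panel, cellular_panel) {
  for (try in 1:100) {
    s <- sample_chr(c("A", "C", "G", "T"), sample(350:500, 1))
    orfs <- six_frame_orfs(s)
    if (!nrow(orfs)) return(s)
    call <- categorize_proteins(unique(orfs$protein), toxin_panel,
                                cellular_panel)
    if (all(call$category == "non-matched")) return(s)
  }
  stop("could not draw a non-matched cDNA")
}

## ---- the library ----------------------------------------------------------

#' Generate a synthetic venom-gland EST library with ground truth
#'
#' @param config a `generator_config`
#' @param out_fasta,out_truth optional output paths (FASTA / tab-separated
#'   truth table); written deterministically when given
#' @return list of class `synthetic_library`: `ests` (data.frame `id`,
#'   `seq`, `origin`), `truth` (one row per EST: `est_id`, `gene_id`,
#'   `origin`, `category`, `family`, `template_id`, `signal_end`,
#'   `pro_end`, `precursor_len`, `precursor`, `mature`, `framework`,
#'   `amidated`, `truncated`), `genes` (per-gene table with `copies` and
#'   Zipf `rank`), `config`
#' @export
generate_library <- function(config = generator_config(), out_fasta = NULL,
                             out_truth = NULL) {
  validate_generator_config(config)
  set.seed(config$seed)
  templates <- family_catalogue()
  toxin_panel <- toxin_panel_default()
  cellular_panel <- cellular_panel_default()

  ## family letters for the toxin genes: largest-remainder apportionment,
  ## genes ordered by family weight (ties by letter) so that high-weight
  ## families take the top Zipf ranks
  fam_letters <- apportion_families(config$family_weights,
                                    config$n_toxin_genes)
  genes <- list()
  add_gene <- function(g) genes[[length(genes) + 1L]] <<- g

  ## the transcript is identifiable when the pipeline's homology-driven
  ## ORF selection would pick exactly the encoded protein
  pipeline_picks <- function(expected_protein, expected_category) {
    function(seq) {
      orfs <- six_frame_orfs(seq)
      if (!nrow(orfs)) return(FALSE)
      calls <- categorize_proteins(orfs$protein, toxin_panel, cellular_panel)
      j <- select_category_call(calls)
      !is.na(j) && identical(orfs$protein[j], expected_protein) &&
        identical(calls$category[j], expected_category)
    }
  }

  for (i in seq_along(fam_letters)) {
    prec <- make_toxin_precursor(fam_letters[i], config, templates,
                                 toxin_panel, cellular_panel)
    base <- packaged_transcript(prec$full_seq, config,
                                pipeline_picks(prec$full_seq, "toxin-like"))
    add_gene(list(gene_id = sprintf("tox%03d", i), category = "toxin-like",
                  origin = "library", precursor = prec, transcript = base))
  }
  for (i in seq_len(config$n_cellular_genes)) {
    prot <- NULL
    for (try in 1:50) {
      tpl <- cellular_panel[sample(nrow(cellular_panel), 1), ]
      cand <- paste0("M", mutate_seq(substr(tpl$seq, 2, nchar(tpl$seq)),
                                     config$cellular_mut_frac,
                                     alpha = setdiff(AA20, "C")))
      cc <- categorize_proteins(cand, toxin_panel, cellular_panel)
      if (identical(cc$category[1], "cellular")) { prot <- cand; break }
    }
    if (is.null(prot)) stop("could not draw an identifiable cellular gene")
    base <- packaged_transcript(prot, config, pipeline_picks(prot, "cellular"))
    add_gene(list(gene_id = sprintf("cel%03d", i), category = "cellular",
                  origin = "library",
                  precursor = list(full_seq = prot, signal_end = NA,
                                   pro_end = NA, mature = NA, framework = NA,
                                   amidated = NA, family = NA,
                                   template_id = tpl$id),
                  transcript = base))
  }
  for (i in seq_len(config$n_random_genes)) {
    s <- make_random_cdna(config, toxin_panel, cellular_panel)
    add_gene(list(gene_id = sprintf("rnd%03d", i), category = "non-matched",
                  origin = "library",
                  precursor = list(full_seq = NA, signal_end = NA,
                                   pro_end = NA, mature = NA, framework = NA,
                                   amidated = NA, family = NA,
                                   template_id = NA),
                  transcript = list(seq = s, cds_len = NA, utr_len = NA)))
  }
  ## transcriptomic toxin transcripts: one copy each, no poly-A tail
  txm_fams <- if (config$n_transcriptomic > 0)
    sample(names(config$family_weights), config$n_transcriptomic,
           replace = TRUE, prob = config$family_weights) else character(0)
  cfg_notail <- config
  cfg_notail$polya_len <- c(0L, 0L)   # no tail: UTR alone carries the length
  for (i in seq_along(txm_fams)) {
    prec <- make_toxin_precursor(txm_fams[i], config, templates,
                                 toxin_panel, cellular_panel)
    base <- packaged_transcript(prec$full_seq, cfg_notail,
                                pipeline_picks(prec$full_seq, "toxin-like"))
    add_gene(list(gene_id = sprintf("txm%03d", i), category = "toxin-like",
                  origin = "transcriptomic", precursor = prec,
                  transcript = base))
  }

  ## Zipf copy numbers over the library genes (rank order = insertion
  ## order: toxins by family weight, then cellular, then random)
  lib <- which(vapply(genes, `[[`, "", "origin") == "library")
  ranks <- seq_along(lib)
  w <- ranks^(-config$copy_law)
  copies <- pmax(1L, as.integer(round(config$n_ests * w / sum(w))))
  gene_tab <- data.frame(
    gene_id = vapply(genes, `[[`, "", "gene_id"),
    category = vapply(genes, `[[`, "", "category"),
    origin = vapply(genes, `[[`, "", "origin"),
    rank = NA_integer_, copies = 1L, stringsAsFactors = FALSE)
  gene_tab$rank[lib] <- ranks
  gene_tab$copies[lib] <- copies

  ests <- list(); truth <- list()
  for (gi in seq_along(genes)) {
    g <- genes[[gi]]
    for (cp in seq_len(gene_tab$copies[gi])) {
      s <- g$transcript$seq
      if (g$origin == "library")
        s <- paste0(s, strrep("A", sample_range_int(config$polya_len)))
      truncated <- FALSE
      if (stats::runif(1) < config$trunc_prob) {
        frac <- stats::runif(1, config$trunc_extent[1], config$trunc_extent[2])
        cut <- floor(frac * nchar(s))
        if (cut >= 1) { s <- substr(s, cut + 1L, nchar(s)); truncated <- TRUE }
      }
      if (config$sub_rate > 0) s <- substitute_bases(s, config$sub_rate)
      id <- paste0("sim|", g$gene_id, "|", cp)
      ests[[length(ests) + 1L]] <- data.frame(id = id, seq = s,
                                              origin = g$origin,
                                              stringsAsFactors = FALSE)
      p <- g$precursor
      truth[[length(truth) + 1L]] <- data.frame(
        est_id = id, gene_id = g$gene_id, origin = g$origin,
        category = g$category,
        family = p$family %||% NA_character_,
        template_id = p$template_id %||% NA_character_,
        signal_end = p$signal_end %||% NA_integer_,
        pro_end = p$pro_end %||% NA_integer_,
        precursor_len = if (is.na(p$full_seq %||% NA)) NA_integer_
                        else nchar(p$full_seq),
        precursor = p$full_seq %||% NA_character_,
        mature = p$mature %||% NA_character_,
        framework = p$framework %||% NA_character_,
        amidated = p$amidated %||% NA,
        truncated = truncated, stringsAsFactors = FALSE)
    }
  }
  ests <- do.call(rbind, ests)
  truth <- do.call(rbind, truth)
  stopifnot(nrow(ests) == nrow(truth))
  if (!is.null(out_fasta)) write_fasta(ests$id, ests$seq, out_fasta)
  if (!is.null(out_truth))
    utils::write.table(truth, out_truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  structure(list(ests = ests, truth = truth, genes = gene_tab,
                 config = config),
            class = "synthetic_library")
}

#' @export
print.synthetic_library <- function(x, ...) {
  cat(sprintf("synthetic venom-gland library: %d ESTs from %d genes (seed %d)\n",
              nrow(x$ests), nrow(x$genes), x$config$seed))
  print(table(x$truth$category))
  invisible(x)
}

substitute_bases <- function(s, rate) {
  n <- nchar(s)
  k <- stats::rbinom(1, n, rate)
  if (k == 0) return(s)
  ch <- seq_chars(s)
  pos <- sample.int(n, k)
  for (i in pos) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  paste0(ch, collapse = "")
}

apportion_families <- function(weights, n) {
  if (n == 0) return(character(0))
  w <- sort(weights, decreasing = TRUE)
  exact <- w * n
  base <- floor(exact)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  rep(names(w), times = base)
}

#' Simulate per-fraction MALDI peak lists from peptide masses
#'
#' Distributes the given neutral masses over HPLC-style fractions (each
#' species elutes in one or two adjacent fractions) with optional mass
#' jitter, producing the peak-list table consumed by the mass-census
#' stage.
#'
#' @param masses numeric vector of neutral monoisotopic masses (Da)
#' @param n_fractions number of fractions collected
#' @param jitter_da standard deviation of mass error per observation (0 =
#'   noise-free)
#' @return data.frame `fraction_id`, `mz`
#' @export
simulate_peak_lists <- function(masses, n_fractions = 51, jitter_da = 0) {
  rows <- lapply(seq_along(masses), function(i) {
    fr <- sample.int(n_fractions, 1)
    frs <- unique(c(fr, if (stats::runif(1) < 0.3 && fr < n_fractions) fr + 1L))
    data.frame(fraction_id = sprintf("F%02d", frs),
               mz = masses[i] + if (jitter_da > 0)
                 stats::rnorm(length(frs), 0, jitter_da) else 0)
  })
  do.call(rbind, rows)
}
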