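## Peptide-mass census of per-fraction MALDI-TOF peak lists: mass-window
## filtering, deduplication of peaks across fractions into distinct
## molecular species, and matching against predicted mature-peptide masses.

#' Read a per-fraction peak list
#'
#' Accepts delimited text with a header naming a fraction column
#' (`fraction` or `fraction_id`) and an m/z column (`mz`, `mass` or `mw`).
#' Tab, comma and semicolon delimiters are auto-detected.
#'
#' @param path file path
#' @return data.frame with columns `fraction_id` (character), `mz` (numeric)
#' @export
read_peak_list <- function(path) {
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else if (grepl(";", header)) ";" else ","
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  fr <- intersect(c("fraction_id", "fraction"), names(df))[1]
  mz <- intersect(c("mz", "mass", "mw"), names(df))[1]
  if (is.na(fr) || is.na(mz))
    stop("peak list needs a fraction column and an mz column: ", path)
  data.frame(fraction_id = as.character(df[[fr]]), mz = as.numeric(df[[mz]]),
             stringsAsFactors = FALSE)
}

#' Mass-window filter
#'
#' Keeps peaks with `lo <= mz <= hi`. The defaults bracket the peptide
#' window between the matrix-dominated region (< 1 kDa) and the protein
#' region (> 10 kDa).
#'
#' @param peaks data.frame with an `mz` column
#' @param lo,hi window bounds in Da (inclusive)
#' @return filtered data.frame
#' @export
window_filter <- function(peaks, lo = 1000, hi = 10000) {
  peaks[peaks$mz >= lo & peaks$mz <= hi, , drop = FALSE]
}

#' Deduplicate peaks into distinct molecular species
#'
#' Sorts all in-window peaks by mass and merges greedily: a peak joins the
#' current species when it lies within `tolerance_da` of the species
#' representative (the running mean of its peaks), otherwise it starts a
#' new species. The species count is therefore invariant under peak-list
#' permutation.
#'
#' @param peaks data.frame with `mz` (and optionally `fraction_id`)
#' @param tolerance_da merge tolerance in Da
#' @return list of class `species_set`: `species` (data.frame
#'   `representative_da`, `n_peaks`), `peak_species` (species index per
#'   input peak, in input order), `tolerance_da`, `n_species`
#' @export
dedup_species <- function(peaks, tolerance_da = 0.5) {
  n <- nrow(peaks)
  if (!n)
    return(structure(list(species = data.frame(representative_da = numeric(0),
                                               n_peaks = integer(0)),
                          peak_species = integer(0),
                          tolerance_da = tolerance_da, n_species = 0L),
                     class = "species_set"))
  ord <- order(peaks$mz)
  mz <- peaks$mz[ord]
  sp <- integer(n)
  reps <- numeric(0)
  counts <- integer(0)
  cur <- 0L
  for (i in seq_len(n)) {
    if (cur == 0L || mz[i] - reps[cur] > tolerance_da) {
      cur <- cur + 1L
      reps[cur] <- mz[i]
      counts[cur] <- 1L
    } else {
      counts[cur] <- counts[cur] + 1L
      reps[cur] <- reps[cur] + (mz[i] - reps[cur]) / counts[cur]
    }
    sp[ord[i]] <- cur
  }
  structure(list(species = data.frame(representative_da = reps,
                                      n_peaks = counts),
                 peak_species = sp, tolerance_da = tolerance_da,
                 n_species = cur),
            class = "species_set")
}

#' @export
print.species_set <- function(x, ...) {
  cat(sprintf("species_set: %d distinct molecular species (tolerance %.2f Da)\n",
              x$n_species, x$tolerance_da))
  invisible(x)
}

#' Match observed species to predicted peptide masses
#'
#' Each species is matched to every prediction whose monoisotopic or
#' average mass lies within `tolerance_da` of the species mass. When peaks
#' are singly-charged [M+H]+ values, set `assume_protonated` to subtract
#' one proton mass before comparison.
#'
#' @param species_set a `species_set`
#' @param predicted data.frame with `name`, `monoisotopic_da`, `average_da`
#' @param tolerance_da match tolerance in Da
#' @param assume_protonated treat species masses as [M+H]+
#' @return data.frame, one row per (species, matching prediction) plus one
#'   row with NA prediction for each unmatched species
#' @export
match_predictions <- function(species_set, predicted, tolerance_da = 0.5,
                              assume_protonated = FALSE) {
  reps <- species_set$species$representative_da
  neutral <- if (assume_protonated) reps - PROTON else reps
  rows <- lapply(seq_along(neutral), function(i) {
    if (nrow(predicted)) {
      d_mono <- abs(neutral[i] - predicted$monoisotopic_da)
      d_avg <- abs(neutral[i] - predicted$average_da)
      hit <- which(d_mono <= tolerance_da | d_avg <= tolerance_da)
    } else hit <- integer(0)
    if (!length(hit))
      return(data.frame(species = i, species_da = reps[i],
                        prediction = NA_character_, delta_da = NA_real_))
    data.frame(species = i, species_da = reps[i],
               prediction = predicted$name[hit],
               delta_da = pmin(d_mono[hit], d_avg[hit]))
  })
  do.call(rbind, rows)
}
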