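## Residue masses (Da) for the 20 standard amino acids.
## Monoisotopic values from the IUPAC 2021 atomic masses; average values from
## the standard atomic weights. Residue = amino acid minus water.

AA_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

AA_AVG <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)

WATER_MONO <- 18.010565
WATER_AVG  <- 18.01528
H_MONO     <- 1.007825
H_AVG      <- 1.00794
## C-terminal amide: -OH replaced by -NH2 (O -> N + H)
AMIDE_DELTA_MONO <- 0.984016
AMIDE_DELTA_AVG  <- 0.98476
PROTON <- 1.00728

#' Mass of a mature peptide
#'
#' Computes the monoisotopic and average mass of a peptide from its residue
#' composition, subtracting two hydrogens per disulfide bond and applying the
#' C-terminal amidation correction (-0.984016 Da monoisotopic) when flagged.
#'
#' @param mature amino-acid string (standard 20 residues)
#' @param n_disulfides number of disulfide bonds formed
#' @param amidated logical; is the C-terminus amidated?
#' @return a list of class `peptide_mass` with elements `monoisotopic_da`,
#'   `average_da`, `n_disulfides`, `amidated`
#' @examples
#' peptide_mass("AG")                      # 146.0691 Da monoisotopic
#' peptide_mass("CC", n_disulfides = 1)    # 222.0133 Da
#' @export
peptide_mass <- function(mature, n_disulfides = 0L, amidated = FALSE) {
  stopifnot(is.character(mature), length(mature) == 1L, nzchar(mature))
  aa <- seq_chars(mature)
  bad <- setdiff(unique(aa), names(AA_MONO))
  if (length(bad))
    stop("non-standard residue(s): ", paste(bad, collapse = ", "))
  n_cys <- sum(aa == "C")
  if (2L * n_disulfides > n_cys)
    stop("n_disulfides (", n_disulfides, ") exceeds cysteine capacity")
  mono <- sum(AA_MONO[aa]) + WATER_MONO - 2 * H_MONO * n_disulfides -
    if (amidated) AMIDE_DELTA_MONO else 0
  avg <- sum(AA_AVG[aa]) + WATER_AVG - 2 * H_AVG * n_disulfides -
    if (amidated) AMIDE_DELTA_AVG else 0
  structure(list(monoisotopic_da = mono, average_da = avg,
                 n_disulfides = as.integer(n_disulfides),
                 amidated = isTRUE(amidated)),
            class = "peptide_mass")
}

#' @export
print.peptide_mass <- function(x, ...) {
  cat(sprintf("peptide mass: %.4f Da (mono), %.3f Da (avg); %d S-S bond(s)%s\n",
              x$monoisotopic_da, x$average_da, x$n_disulfides,
              if (x$amidated) ", C-terminally amidated" else ""))
  invisible(x)
}
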