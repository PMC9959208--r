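#' Bundled family catalogue
#'
#' Synthetic exemplars for the eleven toxin families A-K: one or more
#' template mature peptides per family, each realizing the family's
#' cysteine framework, together with the family's propeptide behaviour
#' (`"always"`, `"most"`, `"some"`, `"none"`) and amidation behaviour
#' (`"G"`: all members carry a C-terminal -G signal; `"most"`: all but an
#' occasional member; `"mixed"`: -G, -GK or -GGK; `"none"`). The templates
#' are invented sequences (no database material) and are user-replaceable.
#'
#' @return data.frame with columns `family`, `template_id`, `framework`,
#'   `propeptide`, `amidation`, `mature_core`
#' @export
family_catalogue <- function() {
  path <- system.file("extdata", "family_catalogue.tsv", package = "venomest",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
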