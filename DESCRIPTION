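Package: venomest
Title: Venom-Gland EST Annotation and Toxin Precursor Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: A reusable pipeline for annotating venom-gland cDNA/EST
    libraries of spiders and other venomous animals. Provides quality
    control of expressed sequence tags (ESTs) with poly-A detection,
    six-frame translation and homology-based categorization into
    toxin-like, cellular-component and non-matched classes, greedy
    clustering into contigs with unique-gene and protein tallies,
    toxin precursor segmentation (signal peptide, processing quadruplet
    motif propeptide, C-terminal amidation), cysteine-framework
    extraction with disulfide-scaffold assignment from a bundled
    catalogue, family classification, and a MALDI-style peptide-mass
    census. A synthetic venom-gland library generator with full ground
    truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
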