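---
title: "Annotating a venom-gland EST library: methods and design"
author: "venomest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating a venom-gland EST library: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Spider venom glands express peptide toxins at very high levels. Sequencing
randomly picked clones from a venom-gland cDNA library therefore yields a
redundant sample of the gland's transcriptome in which toxin transcripts
dominate, accompanied by ordinary housekeeping transcripts and a residue of
cDNAs with no recognizable homology. Turning such a library into a toxin
inventory involves a fixed sequence of decisions: which reads are usable,
what each one encodes, how reads collapse into genes and proteins, how each
toxin precursor is processed into its secreted mature peptide, and how the
mature peptides group into families defined by their cysteine scaffolds.
`venomest` implements that pipeline as composable, individually tested
functions, and ships a synthetic-library generator so the whole chain can
be validated against known ground truth.

## Pipeline stages and their parameters

**Quality control** (`qc_filter`, `detect_polya`). A read is a high-quality
EST when its raw insert length is strictly greater than 300 nt
(`min_len_exclusive = 300`; 301 nt is the shortest kept read). Reads with
characters outside A/C/G/T/N are rejected outright, as are reads with more
than 5% N — nucleotide identity against an N-rich read is not meaningful
for clustering. Poly-A tails are the longest 3'-terminal A run, allowing
one interior non-A base (`min_run = 10`, `max_mismatch = 1`); runs shorter
than 10 nt are not treated as tails. The thresholds other than the length
rule are conventions of this package, exposed in `pipeline_params()`.

**Homology categorization** (`six_frame_orfs`, `align_protein`,
`categorize`). Each trimmed EST is translated in all six frames; every
maximal stop-free stretch of at least 30 codons is an ORF candidate —
30 codons is about the shortest plausible toxin-precursor fragment. Every
candidate is searched against two protein panels (toxin templates and
housekeeping-like sequences) by Smith–Waterman local alignment under
BLOSUM62 with affine gaps (open 11, extend 1, the BLAST defaults; a gap of
length L costs 11 + L). The best hit with at least 40% identity over the
alignment and 50% query coverage decides the category; the toxin panel
wins score ties; an EST with no passing hit in any frame is non-matched.
Considering all ORFs rather than only the longest matters on noisy data:
a single substitution that introduces a premature stop splits the coding
region, and the longest-stretch rule would then hand a junk ORF to the
aligner.

**Clustering** (`greedy_cluster`). ESTs within each category are clustered
by single linkage: two reads are linked when their best local overlap
spans at least 100 nt at 96% identity or better (SeqMan-style defaults;
the original assembler's parameters are proprietary, so these are
explicit, tunable conventions). Reads are seeded deterministically
(length descending, then id), and a read that links several existing
clusters merges them, so the result is exactly the connected components
of the pairwise-similarity graph — an invariant the test suite checks by
brute force on small instances. A shared 11-mer prescreen bounds the
number of alignments: any qualifying overlap (100 nt at 96%) must
contain dozens of intact 11-mers, and — substitutions being the dominant
error mode — those sit on a single alignment diagonal. Candidate pairs
are therefore screened by their modal-diagonal 11-mer count, settled by
a fast ungapped comparison along that diagonal when it is decisive, and
only sent to the full Smith–Waterman alignment when enough diagonal
evidence remains without an ungapped decision (e.g. an indel-shifted
overlap). Within a cluster, a *unique
gene* is a distinct coding nucleotide string and a *protein* a distinct
translated precursor; both tallies are emitted because silent
substitutions collapse only at the protein level.

**Precursor processing** (`call_signal_peptide`, `call_propeptide`,
`apply_amidation`). Toxin precursors are segmented
signal → propeptide → mature:

* The signal-peptide caller is a deliberately simple stand-in for a full
  predictor (and is pluggable via `pipeline_params(signal_fun = )`): it
  scans cleavage positions 15–35, requires a hydrophobic core (mean
  Kyte–Doolittle hydropathy ≥ 1.5 over the 8 residues preceding position
  −5) and small residues (A/G/S/C/T) at −1 and −3, and returns the
  highest-scoring site. A sequence not starting with M is flagged as
  N-terminally truncated and contributes a `-P` suffix to the toxin name.
* The propeptide boundary is the processing quadruplet motif (PQM),
  operationalized as a four-residue window ending in R with at least one
  E among its first three positions; cleavage falls after the R. Spider
  propeptides end at such quadruplets, and mature peptides are anchored
  by their first cysteine, so when several windows qualify the last one
  before the first cysteine wins, and windows at or beyond it are ignored.
* Amidation follows the -G/-GK/-GGK signals: at most one trailing K is
  stripped, then a terminal G marks the peptide amidated and is removed
  (-GGK therefore leaves one G on the amidated peptide). Monoisotopic and
  average masses are computed from residue composition, −2 H per disulfide
  and −0.984016 Da (monoisotopic) for the C-terminal amide.

**Frameworks and families** (`extract_framework`, `assign_scaffold`,
`classify_family`). The cysteine framework is the ordered list of
cysteines written `C1…Cn`, with sequence-adjacent cysteines concatenated
(`C1-C2-C3C4-C5-C6`). Disulfide connectivities are assigned by looking the
framework up in a bundled catalogue (inhibitor cystine knot in 6- and
8-cysteine forms, DDH, Kunitz, the 10- and 14-cysteine spider scaffolds,
an 8-cysteine non-adjacent scaffold and a single-disulfide entry) — by
similarity only, never predicted. DDH and Kunitz share the plain
six-cysteine layout; the catalogue's order makes DDH the default answer
and Kunitz remains addressable by name. Family classification first
collects candidate families whose framework pattern matches, tolerating
the loss of one cysteine by point mutation (observed in real toxins where
a cysteine mutates to arginine or phenylalanine), then ranks candidates by
mature-peptide identity to the family templates, weighted by query
coverage so a short perfect local match cannot beat full-length
similarity; the winner needs ≥ 60%. Toxin-like precursors that match no
family are collected in family K, the low-homology catch-all.

**Mass census** (`window_filter`, `dedup_species`, `match_predictions`).
Per-fraction MALDI-TOF peak lists are windowed to 1–10 kDa (below lie
matrix peaks, above lie proteins), pooled, sorted, and merged greedily: a
peak joins the current species when it is within 0.5 Da of the species'
running-mean representative. Sorting first makes the species count
invariant under peak-list permutation. The 0.5 Da tolerance is a
reflectron-scale convention, configurable; observed species are matched
against predicted mature-peptide masses (monoisotopic and average, with
an optional [M+H]+ proton correction).

## The synthetic library generator

`generate_library()` emulates the structure of a venom-gland cDNA library;
its defaults are the package's study conditions and are not tuned per run:

* 200 genes — 100 toxin genes with family weights proportional to a
  lycosid gland's family sizes (E heaviest at 32/98), 60 housekeeping-like
  genes mutated from a bundled invented panel, 40 unannotatable random
  cDNAs — plus 5 transcriptomic toxin transcripts pooled in without
  poly-A tails.
* ~2000 ESTs with per-gene copy numbers following a Zipf law
  (exponent 1.0) over gene ranks, toxin genes ranked first, so toxin
  transcripts dominate and the heaviest families form the largest
  clusters, as in a real gland.
* Toxin precursors are family templates (bundled, invented sequences)
  mutated at 15% of non-cysteine positions, with a compliant signal
  peptide, a PQM-terminated propeptide where the family carries one, and
  the family's amidation signal. Substitutions are uniform, indel-free
  (sequencing-substitution rate 0.5% by default); 8% of clones are
  5'-truncated by 5–35% of their length, emulating partial reads.
* 3'UTRs (60–120 nt) are random but salted with stop cassettes on both
  strands, and short coding sequences receive longer UTRs, so every
  full-length clone clears the 300-nt rule and the encoded precursor is
  the unique longest ORF.

Each gene is rejection-sampled until the pipeline's own callers recover
its intended segmentation, framework, family and category from the
noise-free sequence. This is an identifiability guarantee, not a
circularity: the ground truth is the intended construction, the redraws
merely exclude accidentally ambiguous genes (for instance a mature peptide
whose second residue is small enough to mimic a cleavage site), so
zero-noise recovery failures downstream always indicate pipeline defects.
What passing the zero-noise test does **not** show: robustness to indels,
chimeric clones, vector contamination, heterogeneous error profiles, or
real signal-peptide diversity — none of which the generator emulates.

## Numerical and degenerate-input choices

* Percentages are rounded half-up at two decimals (`round_half_up`) —
  `base::round`'s half-to-even would print 57.99 where the field's
  conventions print 57.98-style values.
* Coordinates are 0-based half-open throughout; frames follow the BLAST
  convention; ORF tie-breaks are: longest, then ATG-initiated, then frame
  order +1..+3,-1..-3, then leftmost.
* Consensus ties are resolved alphabetically; cluster seeding order is
  total (length, then id), so clustering is platform-independent.
* Degenerate inputs: an empty EST list filters to an empty list; a
  tail-only read trims to the empty string and is flagged; a mature
  peptide reduced to nothing by amidation stripping is an error; an empty
  category cannot be summarized (error), and a zero total cannot be
  percentaged (error).

## Problem sizes

The bundled validation runs use the generator's default scale — 200 genes
and roughly 2000 ESTs per library, with one noise-free and one
0.5%-substitution arm — and a 51-fraction synthetic census; small
property-style tests use instances of a dozen reads where brute-force
oracles are feasible.

## Known limitations

* The signal-peptide heuristic is a hydropathy rule, not a trained
  predictor; on real data it should be swapped for one via the pluggable
  hook, and `-P` flags should be reviewed.
* The PQM rule is a documented operationalization of the quadruplet
  motif; the literature defines the motif family more loosely.
* Clustering has no indel-aware consensus polishing; it is a
  similarity-partition tool, not an assembler.
* E-value statistics are deliberately absent; identity/coverage
  thresholds stand in for them and are configuration, not claims about
  any particular database search.
* The species count of a mass census depends on instrument tolerance and
  fraction overlap; it is reported as data, not as a reproducible
  constant.
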