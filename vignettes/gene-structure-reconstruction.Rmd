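---
title: "Exact gene-structure reconstruction and splice-variant mapping: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact gene-structure reconstruction and splice-variant mapping: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the models and
procedures, the parameters that matter, what the synthetic-data generator
does and does not emulate, the numerical choices made where the design was
genuinely open, and the known limits. Nothing here states an empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## The reconstruction model

A gene structure is an ordered, alternating tiling of exons and introns on
one contig strand whose concatenated exonic sequence (the CDS) translates
to the protein query at every position not covered by a typed discrepancy.
Coordinates are 0-based and half-open on the forward strand throughout the
package; conversion to 1-based inclusive coordinates happens only in the
GFF3 writer. Minus-strand genes store forward coordinates plus a strand
flag; all gene-order logic consults the strand, and internally the engine
works on the reverse complement ("working strand") so that gene order is
always ascending.

Reconstruction proceeds in five stages.

**Seeding.** Exact amino-acid `seed_word_len`-mers (default 5 residues)
shared between the query and a six-frame translation of the contig define
candidate diagonals. Each diagonal is extended to its maximal-scoring
BLOSUM62 segments. Two extraction passes are used: one with a mild
per-residue tax (−2) that merges through occasional mismatches, and one
with a strong tax (−4) that splits a diagonal at sustained junk — the
signature of a frame disruption inside the diagonal. Both decompositions
enter the candidate set; the chain stage picks whichever scores best. This
matters because a 1–2 nt indel shifts the reading frame: the pre- and
post-indel parts of an exon lie on different diagonals, and a single
maximal segment would silently bridge the junk in between.

**Chaining.** A dynamic program selects a colinear, non-overlapping subset
of hits maximising total score. Gaps between chained hits are classified
by `delta = genomic_gap − 3 × protein_gap`: `delta` at least
`min_intron_len` is a candidate intron, penalised affinely in log length
(`intron_open + intron_scale·log(delta)`, defaults 4 and 1.5 — strong
enough to prefer compact structures, weak enough never to forbid a long
intron); `|delta| ≤ 2` is a candidate sequence shift. Query overlaps of up
to `max_chain_protein_overlap` residues (default 30) between consecutive
hits are resolved by trimming, because diagonal extension routinely
overshoots exon ends when the first intron bases happen to score
positively.

**Boundary refinement.** For each candidate intron the boundary placement
is a single offset `x` (the intron slides; its length is fixed by the
chain). Every `x` in a ±`boundary_window` window (default 90 nt) is
scored by translating the re-assembled exonic context (~32 codons each
side) and counting matches to the query; among equal-scoring placements an
allowed splice pair wins, canonical GT–AG before GC–AG, then the most 5′
donor. The scan is exhaustive, so split codons (phase 1/2 introns) need no
special casing. A junction with no allowed pair keeps its intron with a
non-canonical flag — never silently dropped.

**Short-exon placement.** Residues that no seeded hit covers are placed by
exhaustive, exact, codon-aligned search: every occurrence of the missing
peptide with an AG immediately upstream, an allowed donor downstream, and
introns of at least `min_intron_len` on both sides (relaxed at gene
termini). Placements compete with the boundary solution by a deficit rule:
an intron-internal placement of `k` pieces is accepted only when the
boundary solution leaves more than `1.2·k` of the claimed residues
unmatched. The 1.2-residue-per-intron cost is the package's guard against
spurious micro-exon calls in diverged (cross-species) searches, where a
mutated residue could otherwise be "found" by chance in a long intron;
with it, a genuine two-residue exon (two unmatched residues > 1.2) is
seated while a single mutated residue (1 < 1.2) is not. Because the
anchoring hits may overshoot, placements are retried with small (≤3
residue) retractions of either anchor.

**Discrepancy annotation.** The four categories are assigned exhaustively
and disjointly: translation differences become `mismatch` (or
`inframe_stop` when the target shows a stop), 1–2 nt indels become
`sequence_shift` with a signed length (positive = extra genomic bases
excised from the CDS, negative = missing bases padded with `N` so
downstream codons stay in frame), and unplaceable residues stay
`unmatched` with an `N`-padded gap so the CDS/query alignment never loses
register. A dedicated rescue pass detects *compensating* indel pairs
inside one exon (frame shifts that cancel, leaving boundaries intact but a
garbled stretch in between): every placement of an excision + pad pair is
tested and accepted only when it restores the translation exactly outside
the padded codons.

A reconstruction is accepted when query coverage and identity clear
`min_coverage` (default 0.8) and `min_identity` (default 0.9; relax to
~0.8 for cross-species searches). Failures return a diagnostic plus the
partial structure. The practical working range mirrors the ~80% identity
envelope familiar for protein-to-genome mapping: the test suite verifies
exact boundary recovery at 85% planted identity and graceful failure
below 60%.

## Two-step cDNA mapping and event classification

Step 1 filters the cDNA set by best local alignment (Gotoh, affine gaps,
match +5 / mismatch −4, both orientations) against the chosen target
space: the CDS by default, the genomic span to also retain
intron-only sequences, or the translation (all six cDNA frames against
the protein) for cDNA sets from a different species. The filter asks for
one gapless window of `min_aligned_len` (30 nt) at `min_identity` (0.9)
rather than judging the whole local path, because reads spanning a
retained intron or skipped exon meander through junk between clean exonic
stretches.

Step 2 maps each retained cDNA against the genomic span as a spliced
alignment: exact `anchor_len`-mers (10 nt) are chained colinearly,
same-diagonal runs merge into gapless blocks, and every inter-block
junction is placed by the same exhaustive matched-bases-then-splice-pair
scan used in reconstruction. Genomic gaps of at least `min_intron_len`
become junctions; smaller gaps merge. Terminal blocks shorter than
`min_terminal_block` (15 nt) are dropped — a random adapter tail can
anchor a single k-mer somewhere in the span and fabricate a junction.
Unmatched cDNA tails are reported but never classified as events.

Classification is per deviation and mutually exclusive: a block extending
an exon across its donor into the downstream intron is an alternative 5′
splice site (anchored at that exon), across the acceptor an alternative 3′
site; a junction spanning complete exons is exon skipping (one event per
skipped exon); a block covering an entire intron plus flanking exon
sequence is intron retention; a block wholly inside an intron bounded by
junctions is a novel exon. An extension must be at least
`min_event_extension` (3 nt) and end at a junction inside the hit;
anything shorter or truncated is reported with a diagnostic and `type =
NA`, never guessed — and deviations below the evidence floor do not
contradict an otherwise consistent hit. Substitution effects are called by
translating both codons under the gene's code; mismatches in codons split
by block edges are reported without an effect call.

## MXE candidates and tandem duplicates

MXE candidates are enumerated as AG…GT/GC-flanked windows in the introns
adjacent to the source exon (optionally all introns and up/downstream
flanks), constrained to the source length ± `max_length_difference`
(default 20%) and to length ≡ source length mod 3 (frame preservation).
Similarity is the fraction of identical aligned positions after global
alignment of the two translations read in the source exon's frame —
symmetric, in [0, 1], zero-and-flagged for windows whose frame contains an
internal stop. The floor defaults to 0.15; both defaults are clean-room
configuration values. Cluster members are kept mutually non-overlapping
(greedy by similarity). Recursive mode re-runs enumeration with accepted
candidates as sources until fixpoint; accepted intervals are masked, so
termination is structural. Terminal exons are excluded by default
(internal-exon geometry).

Tandem duplicates reuse the reconstruction engine on both strands of the
up/downstream windows with relaxed floors (identity 0.6, coverage 0.8 by
default). Query and duplicate describe the same protein, so exon
homologies are read off the shared CDS coordinate system: a duplicate exon
covering ≥2 query exons is `fused`, ≥2 duplicate exons inside one query
exon are `split`, else `one_to_one`. Overlaps up to `boundary_tolerance`
(12 nt) are ignored as reconstruction jitter of a diverged copy; genuine
fused/split overlaps are exon-sized and far exceed it.

## The synthetic-data generator

`make_locus()` encodes a random protein (uniform over the 20 residues,
initial M) with uniformly drawn synonymous codons, cuts the CDS at
arbitrary positions (so split codons are routine), interleaves GT…AG
introns and embeds the gene in random flanks at 45% GC. Intron bodies are
re-drawn until no slid placement within ±96 nt has both a valid splice
pair and an identical spliced *translation* — synonymous slides count — so
the planted structure is the unique exact optimum and "boundaries
recovered exactly" is a well-posed test. Defaults reflect compact
eukaryotic genes: 3–20 exons of 60–300 nt and introns of 30–2000 nt in
the self-recovery panels.

Identifiability shapes three further generator choices, each a property of
the data rather than of the algorithm:

- **Indels are planted ≥60 nt from exon edges.** A 1–2 nt indel closer to
  a splice site than the boundary-search window is mathematically
  indistinguishable from an alternative boundary placement with the same
  translation.
- **Cross-species queries avoid junction-adjacent codons**
  (`junction_residues()`, ±2 codons). A mutation in a split codon can make
  a slid boundary the genuinely better-scoring alignment, so uniform
  mutation would occasionally move a boundary by a codon no matter the
  aligner.
- **Planted micro-exons are codon-aligned.** The placer seats codon-aligned
  micro-exons; mid-codon micro-exons are out of scope (a documented
  limitation, below).

EST simulation builds variant transcripts for the five event types
(planting the necessary GT/AG dinucleotides), samples reads that cover
each event with ≥60 nt margins, and optionally adds 25-nt random adapter
tails and uniform per-base substitution noise. The generator does **not**
model realistic EST quality profiles (indel errors, 3′ bias, chimeras),
paralogous cross-mapping, or non-canonical splice chemistry; passing tests
therefore demonstrate correctness of the algorithms under the stated
error model, not robustness to every artefact of real EST archives. All
outputs are pure functions of the seed; sub-generators draw from forked
streams so adding a feature never perturbs earlier draws.

Reported positions of planted indels are compared with ±2 residues of
tolerance: the attachment point of an indel inside a repeat run is only
defined up to that run.

## Numerical and interface choices

- Alignment kernels (local and global Gotoh over char-indexed score
  matrices) are compiled code; gap costs default to open 12 / extend 2 for
  DNA and follow BLOSUM62 conventions for protein. The independent
  reference used in the tests is the Biostrings implementation.
- Translation in hot loops uses a table-driven codon lookup; the
  Biostrings genetic-code machinery is the API-level reference and the
  cross-check in the tests. Codons containing `N` translate to `X`; `X`
  positions are excluded from mismatch calls.
- Ties are always broken deterministically (canonical pair, then most 5′;
  smallest offset; first-found placement at equal score), so identical
  inputs give byte-identical outputs.
- The YAML result dialect is versioned (`1.0`), round-trips losslessly,
  preserves unknown future keys, and carries provenance (parameters and
  input MD5 checksums). It makes no attempt to be byte-compatible with any
  other tool's files. GFF output is fixed to GFF3 for its unambiguous
  parent/child structure.
- SVG rendering is a pure function of the document: exons dark grey,
  introns light grey, discrepancies in type-specific colours, MXE
  candidates with opacity equal to similarity clamped at 0.15, unmatched
  cDNA as red bars and mismatches as red lines; event types appear as
  `<title>` tooltips. Colours are fixed colour-blind-safe constants.
- The command line (`exec/genestructr`) is a thin wrapper over the
  exported functions; the package API is the primary interface.
- Degenerate inputs fail loudly: empty FASTA, duplicate identifiers,
  illegal characters, unknown genetic codes, version-mismatched result
  files and zero-length genes all raise informative errors; IUPAC
  ambiguity codes collapse to `N` with a warning.

The test panels use problem sizes chosen to exercise the full parameter
ranges while keeping the whole suite fast on one CPU: 100 loci for
self-recovery, 50 for discrepancy typing, 15 for the cross-species
envelope, 4–5 loci × 13 reads for event classification, 20 fixtures for
duplicates, and >1000 random mismatches for substitution calls.

## Known limitations

- Micro-exon placement requires exact translation match and codon-aligned
  boundaries; a 1-residue internal exon loses the deficit competition by
  design.
- Trans-spliced genes are not modelled; flank-search MXE hits can flag
  candidates, nothing more.
- The spliced cDNA mapper assumes substitution-dominated read error;
  indel-rich reads would fragment blocks.
- Scoring is self-defined (BLOSUM62 + the penalties above); scores are
  comparable within a run, not across tools.
- A sequence shift inside an exon closer than ~15 nt to a planted
  mismatch cluster may be attached a residue or two away from its true
  position (repeat-run ambiguity).
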