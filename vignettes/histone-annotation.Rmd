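---
title: "Annotating a histone gene complement: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating a histone gene complement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histannot)
```

`histannot` annotates the histone gene complement of a genome from three
kinds of signal: protein similarity to reference histones, the regulatory
architecture of the locus (promoter and 3'-UTR elements), and sequencing
read depth over repeated regions. This vignette explains each model, the
parameters that matter, and the design decisions taken where the
literature leaves the procedure open.

## Family and variant classification

Queries are globally aligned (Needleman–Wunsch with affine gaps; BLOSUM62,
gap open 10, gap extend 1) against a bundled reference set containing the
human canonical H1, H2A, H2B, H3.1 and H4 proteins plus the variants
H3.3, H2A.X and H2A.Z. Two entries — macroH2A and CENP-A — are synthetic
constructs (an H2A fold plus a macro-domain-length extension, and an
H3-derived centromeric protein) and are marked `synthetic` in the FASTA;
they provide classification anchors where full-length reference proteins
were not bundled verbatim. The best-scoring reference sets the family when
the alignment identity (matches over aligned columns, gaps included)
reaches `min_identity`.

`min_identity` defaults to 0.35. Histone folds are deeply conserved, so
genuine histones score far above this, while composition-preserving
shuffles of a histone score below it; the test suite calibrates the floor
empirically from 100 shuffles rather than trusting the constant.

The variant label is then refined by diagnostic rules, which take
precedence over the best-reference tag:

* **H3.3** — five sites on the canonical H3 numbering (31: A→S; 87/89/90:
  SAVM→AAIG; 96: C→S) are transferred onto the query through the
  alignment; three or more sites in the variant state call H3.3. Site 96
  is accepted in either the S or A state, because the two letters are
  reported interchangeably for this site; the observed residue is always
  recorded. An alignment gap at a site is reported `indeterminate` and
  excluded from the count. Hydrozoan-style H3.3 proteins, in which the
  site-96 change is absent, therefore score 4/5.
* **H2A.X** — the extreme C terminus must fit `S-Q-[E/D/I]-[Y/F/L]`; a
  tail fitting positions 1, 2 and 4 only (the SQAY type) is a near match
  and still calls the variant, with the observed tetrad in the evidence.
* **macroH2A** — any H2A-family query longer than 1.8× the canonical H2A
  reference is macro-domain carrying (true macroH2A is roughly 2.8×).
* **sperm-H2B** — an H2B-family query with two or more SPKK/SPKR repeats
  in its N-terminal tail.
* **CENP-A** — called when the H3-derived centromeric reference is the
  best hit; an H3-family query with a long (≥ 20 residue) N-terminal
  extension and identity to canonical H3 below that of H3.3 is treated
  the same way. Phylogenetic confirmation is out of scope; diagnostic
  residues plus alignment scores stand in for tree-based assignment.

References are scored in a fixed (family, variant) sort order, so
permuting the reference file never changes a call.

## Regulatory features and replication-dependency

Replication-dependent histone mRNAs are not polyadenylated; they end in a
conserved 16-nt stem-loop followed, within a couple of dozen bases, by a
purine-rich histone downstream element. `histannot` operationalises this
as follows.

* **TATA-box**: forward-strand matches of `TAWAAA` within 120 nt upstream
  of the start codon (no window is standardised in the literature; 120 nt
  covers core promoters comfortably).
* **Stem-loop**: the element geometry is fixed at a 6-bp stem and 4-nt
  loop (16 nt total); alternative geometries are rejected rather than
  scored, because a single conserved element class is being detected.
  Offsets 0–40 nt after the stop codon are scanned (the non-conserved
  spacer observed in real loci is 6–17 nt; 40 leaves slack). Stems are
  scored additively per pair — GC = 3, AT = 2, GU = 1, mismatch = −2 —
  and a window needs at least `6 − max_mismatch` intact pairs
  (`max_mismatch` defaults to 3). The best-scoring window wins; ties go
  left. The score is a deliberate simplification of thermodynamic
  folding: no folding parameters are standardised for this element, and
  the additive score preserves the one property the verdict needs —
  it decreases monotonically as stem pairs break.
* **Stability threshold**: a hit is *stable* when its score reaches 12,
  the score of a perfect all-AT stem, i.e. the weakest possible intact
  stem. Any stem with even one broken pair and no compensating GC
  enrichment falls below; three broken pairs can score at most 3.
* **HDE**: the best 10-nt window by purine (A/G) fraction within 25 nt
  downstream of the stem-loop, reported when the fraction reaches 0.7
  (random sequence averages 0.5). An HDE is only sought downstream of a
  found stem-loop.
* **polyA signal**: first occurrence of `AATAAA` or `ATTAAA` in the
  3'-UTR (DNA alphabet enforced).

The replication-dependency verdict applies four rules in order:
stable stem-loop + HDE + no polyA → `replication_dependent`;
polyA + no stem-loop → `replication_independent`;
unstable stem-loop + no polyA + no expression evidence in any stage →
`pseudogene_candidate`; otherwise `ambiguous`. Every verdict carries the
fired rules as rationale, and the call is a pure function of the feature
set and expression table.

## Sperm-histone motifs and the protamine screen

SPKK/SPKR repeats are counted non-overlapping and leftmost-first, so a
tandem array like `SPKKSPKK` counts once per repeat and `SPKKK` once;
the scan covers the N-terminal 60 residues by default (the histone-fold
start from classification can be passed instead; the literature gives no
fixed tail boundary). All families are scanned, since SPKK motifs also
occur outside H2B.

The protamine screen computes global R, K and R+K fractions plus a
windowed maximum (30 residues). A protein is protamine-like when its R+K
fraction reaches 0.45 with an R fraction of at least 0.25; R ≥ 0.45 hints
at the protamine (P) type, otherwise protamine-like (PL). No quantitative
definition exists in the literature; these calibration constants are
exposed as arguments, and the tests verify that a planted R-rich
protamine passes while every bundled and generated histone fails.

## Copy number from k-mer depth

Reads are decomposed into canonical 17-mers (lexicographic minimum of
k-mer and reverse complement, collapsing strands; k-mers containing N are
skipped). The diploid coverage peak is the modal multiplicity of the
histogram after a width-3 moving average, ignoring multiplicities ≤ 4 to
exclude the sequencing-error peak — a deliberate cut-off rather than a
mixture model. The region's coverage is the *median* multiplicity of its
k-mers (absent k-mers count 0); the median resists unique flanking
k-mers and repeat-edge effects.

The estimate divides region coverage by the diploid peak to give copies
per diploid nucleus and halves that for per-haplotype copies. Under the
alternative reading in which the diploid peak already represents two
copies, both numbers would be exactly 2× larger; the implementation
follows the division-then-halve convention and records the divisor in
every report. Note the expected k-mer depth of single-copy sequence is
`coverage × (L − k + 1) / L` for read length L, slightly below the
nominal fold coverage; the ratio estimator cancels this factor.

## The synthetic-data generator

`generate_genome()` plants a complete histone complement with
machine-readable truth: a tandem cluster of five intron-less canonical
genes (TATA-box, perfect stem-loop, HDE, no polyA) repeated
`cluster_copies` times head-to-tail together with a placeholder block
standing in for the non-histone cluster residents (5S rRNA, U1/U2 snRNA,
Arg-tRNA), plus fourteen dispersed loci: replication-independent variants
with polyA signals and 1–7 introns (GT...AG), a replication-dependent
H3.3 analogue, five variant H2B genes (SPKK repeats 0, 6, 7, 5, 6; the
counts follow the sperm-H2B configuration the pipeline is designed to
detect), and an H1.3-style pseudogene whose coding sequence is identical
to canonical H1 but whose stem-loop carries three mismatches, with no
polyA signal and no expression evidence.

Coding sequences derive from the bundled references through seeded random
codon choice (synonymous divergence) plus residue substitutions at 5%
outside protected regions — together roughly 15% nucleotide divergence,
synonymous-biased — so classification against the same references is
exercised across genuine sequence change. Protected regions keep the
planted truth well-defined: the five H3 diagnostic sites, the H2A
C-terminal tetrad, and the first 60 residues of H2B-family genes (so
SPKK counts cannot drift). Intron positions are placed uniformly within
the CDS; exon counts, not positions, are the modelled quantity.

Inter-feature spacers are random pyrimidine (C/T) sequence: pyrimidines
cannot pair with each other, so spacers can never harbour spurious
TATA-boxes, stem-loops, HDEs or polyA signals, while their random
composition keeps spacer k-mers locus-specific so repeat-cluster k-mer
depths reflect the planted copy number. The polyA signal is placed past
the stem-loop search span because an A-run adjacent to pyrimidine filler
would otherwise seed a legitimate (if weak) hairpin window. Stem
mismatches are introduced loop-proximal-first with pyrimidine
substitutions, so a degenerate element gains no wobble pairs in shifted
windows. The background is i.i.d. nucleotide sequence at GC 0.35
(emulating an AT-rich genome).

Reads are sampled uniformly with random strand and optional per-base
substitution errors; everything is a pure function of `(config, seed)`
and byte-reproducible.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: sequencing indels and quality structure,
non-uniform coverage (GC bias, library artefacts), repeat families beyond
the planted cluster, diverged cluster copies, split or mispredicted gene
models, and genuine phylogenetic signal (the variant analogues are
mutated references, not orthologues). Verdict accuracy of 100% on
error-free synthetic loci is a correctness check of the rules, not an
accuracy estimate for draft-genome annotation.

## Problem sizes and numerical choices

The validation suite runs desk-scale versions of each analysis: copy
recovery uses a compact two-gene cluster unit over a 40-kb background at
20× coverage with planted copy numbers 5, 50 and 200 (recovered within
15%; the integer-valued peak and median are the dominant error source at
this scale), and the annotation analyses use the full 19-gene complement
with one cluster copy. Genome-scale quantities (hundreds of cluster
copies, tens of millions of reads) follow the same arithmetic but are not
re-computed at this scale. Ties are resolved deterministically
throughout: leftmost window for equal stem-loop scores and HDE fractions,
lower multiplicity for equal histogram peaks, lexicographic label pairs
for equal cluster-merge heights, and the (family, variant) sort order for
equal alignment scores.

## Known limitations

* Family assignment relies on a small reference set; deeply diverged
  linker histones or lineage-specific variants may fall below the
  identity floor and return `unclassified`.
* The stem-loop scorer is not a thermodynamic model; it ranks elements by
  pair composition only and is calibrated solely to separate intact from
  degenerate stems.
* The copy estimator assumes the diploid peak is identifiable; very
  high-coverage or very repetitive genomes may need a different
  `min_multiplicity`.
* The kmacs-style average-common-substring comparison is replaced by a
  Jaccard distance over k-mer sets, which is well-behaved for 16-nt
  elements and provably metric; for long sequences a different distance
  may be preferable (the distance function is pluggable).
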