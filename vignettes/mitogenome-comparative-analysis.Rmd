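---
title: "Methods: comparative mitogenome characterization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative mitogenome characterization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocompare)
```

This vignette is the package's own account of what it computes, the
conventions and numerical choices behind each stage, what the synthetic
generator does and does not emulate, and the known limitations.

## The data model

An annotated mitogenome (`mito_genome`) is a DNA string plus an ordered
feature table: canonical gene name, category (PCG / tRNA / rRNA / CR),
0-based half-open coordinates, and strand. On file I/O (GenBank, TSV
feature tables) coordinates are 1-based inclusive, the convention of the
deposit format; converting once at the boundary removes a whole class of
off-by-one slicing errors. A feature may wrap the origin only on a
circular genome; it is stored with `end > length` and sliced across the
junction.

Published descriptions of the same assemblies sometimes call them
"linear" (an assembly artifact) and sometimes "circular" (the biology of
animal mtDNA). We do not guess which is meant for any particular record:
topology is an explicit flag, read from the LOCUS line and defaulting to
circular for gene-order work. Composition never counts any genomic
position twice regardless of topology.

Gene nomenclature in GenBank records is inconsistent (`COI` vs `COX1`,
`l-rRNA` vs `rrnL`, anticodon vs codon-family qualifiers on the
duplicated Leu/Ser tRNAs). Normalization is deliberately table-driven —
a synonym TSV shipped with the package plus a small tRNA grammar — and
never heuristic: anything unrecognized maps to the sentinel `"unknown"`,
stays in the feature table for composition, and is excluded (loudly)
from gene-order analysis.

## Composition and skews

`composition_table()` produces the eight conventional rows: whole
genome, concatenated PCGs, codon positions 1–3, tRNAs, rRNAs, CR.
Choices that matter:

- Gene regions are taken in *reading orientation* (minus-strand genes
  reverse-complemented), so PCG skews describe the coding strand.
  Concatenation order is genomic feature order; counts are
  order-independent (asserted by test).
- Codon positions are assigned per gene: the 1→2→3 counter restarts at
  each PCG's first base and runs through any incomplete terminal codon.
  This makes `site1 + site2 + site3` equal the PCG total *always* —
  e.g. an 11,114 bp PCG complement splits 3705/3705/3704, which is only
  possible if partial codons are counted.
- Ambiguity codes (N etc.) stay in the sequence, are excluded from the
  percentage denominator, and the `length` column keeps the raw span.
- `AT-skew = (A − T)/(A + T)` and `GC-skew = (G − C)/(G + C)` are
  scale-invariant, so printed percentages are as valid an input as raw
  counts; a zero denominator returns `NA` with a warning, never 0 and
  never an error.
- Report rounding is half-away-from-zero (the convention of printed
  tables; R's `round()` is round-half-even), percentages to 2 decimals
  and skews to 3. Recomputing skews from two-decimal percentages can
  disagree with values computed from raw counts by ±0.001 in the third
  decimal, and much more when a denominator is tiny: at GC ≈ 1.5%, a
  0.01-point rounding of the c or g percentage moves the GC-skew by
  about 0.004. The test suite treats published cells affected this way
  as bounded, not exact, and one published cell (a Site-3 GC-skew of
  0.620 whose printed percentages give 0.624) falls outside even the
  documented ±0.002 artifact band — it is left failing rather than
  widened away.
- Overlapping same-category features (rare, e.g. ATP8/ATP6 overlaps)
  are counted once per category: later features are trimmed at the
  leading edge with a warning.

## Codon usage

Codon counting pools all PCGs in reading orientation, taking consecutive
triplets from each gene's first base and discarding a trailing 1–2 base
remainder (that remainder is exactly the incomplete stop, which belongs
to the census, not to codon usage). RSCU follows the textbook
definition: observed count over the mean count of the synonymous family.
Two decisions were genuinely open:

- **Family definition for Leu/Ser.** The definition speaks of "all
  codons coding the amino acid", so the default normalizes leucine
  (6 codons) and serine (8 codons under table 5, UCN + AGN) each as one
  family, while the display column still uses the conventional split
  labels Leu1/Leu2/Ser1/Ser2. Because published figures produced by
  external tools do not always state which mode they used,
  `split_families = TRUE` switches to split-class normalization; the
  test suite pins the joint mode.
- **Stops.** Stop codons are tallied (they are informative in a census)
  but never enter RSCU families.

The census takes the first triplet as the start codon (`is_atn_start`
flags `AT[ACGT]`; TTG starts exist in real bees and are reported, not
errors) and classifies the stop purely by length mod 3: a full final
triplet must be TAA/TAG (anything else is `"other"` with a
misannotation warning), a remainder of 2 or 1 is the incomplete `TA` or
`T` terminator. No polyadenylation modeling is attempted — the biology
is noted, the computation is length arithmetic.

`rank_codons()` orders by descending RSCU with alphabetical tie-breaks,
so outputs are reproducible to the byte.

## Gene order and rearrangements

The packaged reference is the ancestral insect arrangement
(*D. yakuba*): 37 genes + CR with strands. Extraction sorts canonical
features by start and, on circular genomes, rotates to begin at `trnI`
(or just after the CR) so different annotation offsets compare equal.

`diff_against()` aligns the two orders by the rotation minimizing
position-wise mismatches (ties to the smallest offset — deterministic),
factors out maximal identical blocks, and reports each remaining run of
differences as one event. Events are spelled with the preceding
unchanged gene as an anchor, the way comparative papers write clusters
(`COX2-trnK-trnD` → `COX2-trnD-trnK`); the CR is never part of a
cluster (it anchors rotation instead), and an event at the start of the
order simply has no anchor.

Classification uses order and sign evidence only:

- *shuffle*: two adjacent genes exchange positions, signs unchanged;
- *inversion*: a contiguous block reversed with all signs flipped
  (a single sign flip is the degenerate case);
- *transposition*: one contiguous block moved to another slot, signs
  unchanged (found by enumeration over blocks and insertion points);
- *inverse transposition*: moved and flipped;
- anything else is reported as *complex* with clusters preserved.

This evidence-based typing can disagree with narrative usage: a
strand-unchanged adjacent swap such as `trnA`/`trnR` is sometimes
described as an "inversion" in the literature, but without a sign flip
there is no order/sign evidence for one, so it is reported as a shuffle
and the event row carries a note saying exactly that. If deposited
annotations show a strand change, the classifier will call it an
inversion with no special-casing.

`breakpoint_count()` is the standard signed, circular-aware adjacency
distance: an adjacency (a, b) survives as (a, b) or (−b, −a); the count
is the number of reference adjacencies absent from the order. Missing
genes (partial annotations) are excluded pairwise and reported before
any comparison.

`catalog_patterns()` canonicalizes each derived cluster (minus-strand
tokens suffixed `(-)`; a cluster and its reverse-complement reading
collapse to the lexicographically smaller spelling) and unions patterns
across taxa with set semantics, so the same change in two taxa is one
pattern attributed to both. `halictid_gene_orders()` packages the four
recently characterized halictid bee orders, reconstructed by applying
their reported tRNA cluster changes to the ancestral constant; run
through the catalog they yield exactly five distinct patterns.

## Supermatrices

Alignment (MAFFT L-INS-I) and trimming (TrimAl) are deliberately out of
scope — they are mature external tools; `build_bundle()` consumes their
per-gene FASTA output and produces the five standard matrices with
partitions. Numerical/structural rules:

- translation is codon-wise under the chosen table; a codon containing
  a gap becomes a gap; an internal stop becomes `X` with a warning, a
  terminal stop `*`;
- third-position stripping keeps columns 1–2 of each codon and stamps
  provenance, so stripping twice is an error rather than silent data
  loss;
- genes concatenate in the genomic order of the ancestral plan, rRNAs
  after PCGs; partitions are 1-based inclusive and tile each matrix;
- the width identities `w(cds12_fna) = 2/3 · w(cds_fna)` and
  `w(cds_rrna) = w(cds_fna) + w(rRNA)` hold for every input by
  construction. Note that strict stripping makes it arithmetically
  impossible for a stripped matrix to have the same site count as its
  source — a useful sanity check when comparing against reported matrix
  dimensions, which depend on trimmed alignments that are usually not
  distributed.
- taxon-set mismatches are fatal by default; `fill = "gaps"` pads
  missing rows explicitly and warns per padded row.

## The synthetic generator

`synthetic_spec()`/`generate_genome()` exist so that every stage has a
ground-truth oracle without network access. The generator emits genes
along the (optionally edited) ancestral plan and keeps its own tallies
of every draw — base counts per region, codon counts, applied events —
independent of the analysis code; a generation-time self-check compares
the whole-genome tally against the emitted sequence.

Defaults are fixed at realistic halictid-scale conditions and are not
tuning knobs: a 13-PCG complement totalling 11,114 bp in which `ND5`
(1718 bp, ≡ 2 mod 3) ends in the incomplete `TA` stop — so the codon
positions split 3705/3705/3704; 22 tRNAs of 66 bp (within the observed
50–77 bp range); rRNAs of 1300/797 bp; a 2755 bp control region (real
CRs span roughly 1.5–6.6 kb and `cr_length` is the dial); overall AT
target 0.85 with per-codon-position base frequencies echoing observed
Site 1/2/3 compositions; intergenic spacers uniform on 0–20 bp. Stop
completeness is driven entirely by gene length mod 3 (0 → TAA/TAG,
2 → `TA`, 1 → `T`), which keeps the length plan and the census
consistent by construction.

Model simplifications, stated plainly:

- Sequences are i.i.d. per site within each region class (codons i.i.d.
  from the positional composition, optionally reweighted per codon).
  There is no autocorrelation, no secondary structure, no among-gene
  heterogeneity beyond the plan. This is sufficient for validating
  counting, skew, RSCU and rearrangement code; it says nothing about
  how the package behaves on misannotated or structurally unusual real
  genomes.
- Because stop codons are excluded from the internal-codon pool and the
  pool is renormalized, realized PCG base composition sits slightly off
  the raw positional targets (excluding the AT-rich TAA/TAG shifts AT
  down by under a percent). The directly targeted regions are the
  i.i.d. ones, so the calibration tests check tRNA/rRNA/CR AT against
  their configured targets at 3 binomial standard errors, pooled over
  20 seeds.
- Rearrangement edits are validated to be contiguous runs of the
  ancestral order, disjoint, and separated by at least one untouched
  gene. Touching clusters would merge into a single diff event, making
  "recover exactly k events" ill-posed; requiring separation keeps
  planted-edit recovery an exact test (100/100 random manifests in the
  suite).
- Randomness comes from R's Mersenne-Twister, seeded from the spec and
  restored afterwards, so identical specs give byte-identical genomes
  and manifests and never disturb the caller's RNG stream.

## Problem sizes and runtime choices

The test suite runs full-scale synthetic genomes (~17.8 kb, the real
magnitude) rather than miniatures, since generation is cheap; the
heavier property blocks are sized to stay exact yet fast: exhaustive
signed permutations up to n = 5 plus 200 random n = 7 cases for the
breakpoint oracle, 100 random edit manifests for recovery, 20 seeds for
generator calibration. All stochastic tests fix their seeds.

## Known limitations

- The GenBank parser is minimal by design: LOCUS topology, the feature
  table (`CDS`/`tRNA`/`rRNA`/`D-loop`/control-region `misc_feature`,
  `complement`, origin-wrapping `join`), and ORIGIN. Multi-interval
  joins that are not origin wraps collapse to their overall span;
  records without ORIGIN are rejected.
- Rearrangement analysis reports observed differences; it does not
  infer rearrangement scenarios, distances beyond breakpoints, or
  TDRL/common-interval structures, and does not build gene-order
  phylogenies.
- Ka/Ks and other evolutionary-rate statistics are out of scope, as is
  every inference stage around the supermatrices (model selection, tree
  search, support values).
- Strand assignment of "inverted" tRNAs in published figures cannot be
  recovered from prose; classification trusts the annotations it is
  given.
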