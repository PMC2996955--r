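---
title: "Methods: characterizing a full-length cDNA library by comparative mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: characterizing a full-length cDNA library by comparative mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flcdna)
```

## The problem

A full-length-enriched, directional cDNA library from a non-model
primate (the motivating case is rhesus monkey placenta) is sequenced by
single-pass 5' reads of roughly 0.8--1 kb. Because the species' own
genome annotation is sparse, the reads are characterized *comparatively*
against a well-annotated reference transcriptome and genome from a close
relative (human): after cleaning, each read either matches a reference
mRNA -- in which case the part of the gene it covers (5'UTR, CDS, 3'UTR)
and its divergence from the reference are informative -- or it does not,
in which case database, genome and coding-potential evidence triage it
into candidate novel transcripts. Alignment differences (substitutions,
INDELs, extra exons) measure what changed between the two genomes;
cassette exons derived from lineage-specific transposable elements are
the most striking such change.

`flcdna` implements this workflow end to end, plus a synthetic-data
generator that emulates the statistical structure the analysis assumes,
with a complete ground-truth ledger so every stage can be tested by
parameter recovery rather than by eyeballing.

## Pipeline stages and their parameters

### Cleaning

* **Quality trimming** keeps the longest interval of a read in which
  every sliding window (default `window = 10` nt) has mean Phred quality
  at or above `min_mean_q = 20`. The published protocol names only the
  threshold ("quality score > 20"); the longest-window-clean-interval
  rule is this package's concrete choice, and `quality_trim()` is tested
  against an exhaustive interval-scanning oracle.
* **Vector screening** (`vector_screen()`) aligns each read to the
  cloning-vector library; terminal hits (>= 20 nt at >= 0.95 identity,
  defaults chosen since the original tool class, cross_match, was named
  without parameters) are trimmed off, whole-vector reads and internal
  vector hits with >= 50 nt clean flanks (multiple-cloning-site
  chimeras) are removed.
* **Host screening** removes reads with a strong (>= 100 nt) hit to
  user-supplied host sequences (E. coli / phage).
* **Length filter**: "longer than 100 bp" is read strictly -- a 100-nt
  read is removed, a 101-nt read kept.

Stage order is quality -> vector -> host -> length. The source protocol
does not state whether vector removal preceded quality trimming; the
order here is a package decision, stated rather than inferred.

### Alignment

All database matching uses affine-gap Smith--Waterman local alignment
(match +1, mismatch -2, gap open -5, gap extend -1; a gap of length L
costs 5 + L; `N` never matches). The published analysis used BLAST; at
desk scale (kilobase queries against thousands of references) the exact
DP is affordable and makes scores reproducible and testable -- the test
suite checks `align_local()` against an independently written
brute-force DP on random pairs. A k-mer seed index (`kmer_index()`)
merely pre-selects candidate references; it never changes a score.
Acceptance thresholds for a database hit: identity >= 0.90 over >= 100
aligned columns (the original BLAST cutoffs are unpublished). Ties are
broken by score, then aligned span, then lexicographic target id, so
`best_hit()` is deterministic.

Genome mapping (`map_to_genome()`) seeds the candidate locus with exact
16-mers, then chains local alignments recursively on the unaligned
flanks. Target-side gaps of at least `min_intron = 30` nt are introns
and delimit the reported blocks; shorter gaps are deletions inside a
block. Splice-junction placement is ambiguous by a few nucleotides when
intron ends coincide with exon ends -- recovery tests therefore compare
block boundaries within a 4-nt window, never exactly.

All internal coordinates are 0-based half-open. Exports follow each
format's convention (GFF3 1-based inclusive, BED half-open), and the
tabular genome-hit export keeps the published convention
`matched_length = query_end - query_start`.

### Region categories and the summary table

`classify_region()` labels a read by the set of reference regions its
aligned span overlaps by at least 1 nt (the threshold is exposed but
1 nt is the choice consistent with a per-base labeling oracle), giving
the seven categories 5UTR, 5UTR_CDS, CDS, CDS_3UTR, 3UTR,
5UTR_CDS_3UTR and NR_XR (non-coding/predicted reference models).
`summarize_categories()` reports, per category, cDNA counts, gene
counts and the gene count as a percentage of all distinct genes,
rounded half away from zero to one decimal -- the denominator choice is
verifiable from the published table (499/1462 = 34.1%). In that table
the per-category gene counts sum exactly to the distinct-gene total, so
each gene must be counted once: this package assigns a gene the
category of its longest-spanning cDNA (ties resolved in canonical
category order). cDNA counts remain per-read.

### Consensus identity

For every reference transcript with >= 2 assigned reads,
`build_consensus()` anchors the members to the reference through their
alignments and takes a column-wise majority, ties broken toward the
reference base, then alphabetically. The original study names no
multiple-alignment method; reference-anchored majority voting is
deterministic, testable, and exact in the regime that matters here
(members of a cluster share their divergence, see below).
`per_region_identity()` then reports percent identity between consensus
and reference over the covered span, and `identity_report()` aggregates
per category in the fixed order 5UTR_CDS, 5UTR_CDS_3UTR, CDS,
CDS_3UTR, 3UTR.

## The synthetic world

`sim_config()` + `make_reference_set()` + `simulate_cdna_reads()`
generate a deterministic toy world: an annotated "human" transcriptome
(ATG-initiated, stop-terminated CDS divisible by 3, a 3.4% non-coding
fraction matching the published NR/XR share), a single-chromosome
genome embedding each transcript as 2--12 exons with >= 50-nt introns,
repeat annotation, a cloning vector, host contaminants, and pools of
non-reference transcripts.

Design points that define what a green test establishes:

* **Divergence is planted per gene, not per read.** Each reference
  transcript gets one diverged "rhesus" ortholog (region-specific
  substitution rates, occasional indels, possibly a TE-derived cassette
  exon), and all reads from that gene sample the same ortholog. This is
  what the real analysis measures -- species divergence shared across
  clones -- and it is what makes consensus identity a consistent
  estimator of the planted rate. Had mutations been drawn independently
  per read, majority voting would cancel them and the recovery targets
  would be unreachable in principle.
* **The library profile encodes the published identities.** The
  per-category preset of `paper_profile_rates()` (CDS 0.032, 3'UTR
  0.067, ...) is chosen so that 100 x (1 - rate) equals the published
  per-category consensus identities (96.8% CDS, 93.3% 3'UTR, ...);
  recovery tests then check estimator accuracy to within 3 Monte-Carlo
  standard errors, with >= 100 genes per category.
* **Reads are 5'-anchored-or-truncated.** A read starts at the
  transcript 5' end with probability `p_5prime_complete = 0.2`
  (matching the published 367/1835 5'-complete share) and at a uniform
  internal position otherwise; lengths are normal with mean 858 nt,
  clamped to the published 170--1174 range. The real library's
  truncation mechanism is unknown; this model is a free parameter of
  the generator, not a claim about the chemistry.
* **Contamination**: 8.25% of raw reads are pure vector (the published
  165/2000), a quarter of reference reads carry a trimmable terminal
  vector segment, and 0.5% are host reads. Qualities decay linearly
  from Phred 40 to 10 along the read so the quality stage does real
  work.
* **Indels are planted only at homopolymer-free sites**, at least 40 nt
  apart, so their positions are alignment-unambiguous and the truth
  ledger can be compared at +- 3 nt. Real indels cluster in
  homopolymers; the generator deliberately avoids that regime because
  there the "true" coordinate of an indel is not well defined.
* **What is not emulated**: chromatogram-level base-calling error,
  normalization chemistry, expression-level skew beyond uniform
  sampling with replacement, reverse-strand reads (off by default for
  the directional library), and genuine repeat-family evolution (TE
  consensi are random sequences with mutated copies; lineage
  specificity is a flag, not a phylogenetic inference).

The unknown fraction (`p_unknown = 0.102`, the published 187/1835)
splits 66:60:61 among other-database transcripts, novel genome-encoded
loci and free ORF-bearing transcripts, mirroring the published triage
partition, so the cascade's branches are all exercised at their
realistic relative frequencies.

## Triage, INDELs, exonization

`triage()` applies the evidence cascade: reference hit, else
other-database hit, else genome mapping and ORF calling (forward frames
only -- the library is directional; a `both_strands` flag exists). The
ORF gate is `min_aa = 40`, slightly below the smallest published novel
ORF (44 aa) so that truth-edge cases are not missed; `find_orf()` is
checked against exhaustive ATG-to-stop enumeration. A transcript with
neither hit nor ORF stays `UNCLASSIFIED` -- the published partition
happened to be exhaustive, but the pipeline never forces a class.

`detect_indels()` turns every alignment gap shorter than `min_intron`
into one event (gaps at or above the threshold are introns; each gap
counts exactly once as indel xor intron), left-normalizes gap placement
before anchoring, and `classify_indel_region()` labels the anchor's
region, with compound labels when a deletion spans a region boundary.
`summarize_indels()` counts transcripts per region (a transcript with
indels in k regions contributes once to each), the counting that makes
the published five per-region counts sum to the published
functional-region total; raw event counts are reported alongside since
the original text is ambiguous between the two.

`screen_te_exons()` looks at intron-delimited genome blocks of a
transcript that have no counterpart in its reference-mRNA alignment
(< 20% query overlap), computes repeat coverage of the block, and calls
an exonization when coverage >= 0.5; the species-specific flag comes
from the configurable lineage-specific family list (defaults: AluYRa
subfamilies and MER11B, the families the motivating study found
exonized). At pipeline scale the screen only fires for reads that
actually span a cassette with enough flanking exon for the mRNA
alignment to bridge it; the operation itself is tested directly on
planted cassettes with full coverage, where it reaches >= 0.95
sensitivity and precision.

## Numerical and degenerate-input choices

* Percent rounding is half-away-from-zero (base R's `round()` is
  half-even and disagrees with the published table on .05 cases).
* Identity over zero aligned columns is `NA`, never 0; empty inputs
  yield empty summaries, never division errors.
* Empty sequences align with score 0 and no blocks; a 100%-vector read
  is removed, not trimmed to nothing.
* All randomness flows from the single config seed; identical configs
  reproduce byte-identical output bundles and reports.

## Known limitations

* The recursive HSP chainer assumes co-linear, same-strand loci; it
  will not model inversions or trans-splicing.
* Exact DP alignment is quadratic; the package targets desk-scale
  inputs (<= a few kb queries, <= thousands of references), not
  genome-scale read mapping.
* Consensus identity is reported per transcript with >= 2 members;
  singleton genes contribute no identity estimate, which mirrors the
  published "at least two sequences" rule but halves the usable gene
  count at low coverage.
* The published mapping of "298 consensus sequences onto 138 genes" is
  not fully explained in the source; this package reports both
  consensus-level and gene-level counts (`n_consensus`, `n_genes`)
  rather than guessing the intended granularity.
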