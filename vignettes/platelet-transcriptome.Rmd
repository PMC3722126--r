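---
title: "Characterizing a strand-specific platelet transcriptome: methods and design"
author: "plateletseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing a strand-specific platelet transcriptome: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Platelets are anucleate: they inherit megakaryocyte RNA and perform no
nuclear transcription of their own, which makes their RNA complement a
closed, unusually clean system for transcriptome analysis. A
strand-specific sequencing design — four donors, each profiled as long
RNA (≥ 40 nt) from both total and rRNA-depleted preparations, plus a
short RNA (< 40 nt) preparation — raises a series of computational
questions that this package answers with tested, reusable code:

* how to place transcripts on a common abundance scale within and
  across read sets without external spike-ins;
* whether the rRNA-depletion step distorts relative transcript
  abundances, and by how much;
* whether reads that fall in introns represent unannotated
  transcription once every known same-strand feature is excluded;
* how much transcription runs antisense to exons, UTRs, repeat
  elements and miRNA precursors;
* and what fraction of reads that fail genome mapping can be explained
  by exon–exon junctions, RNA editing, or hyperpolymorphic loci.

`plateletseq` implements each of these procedures over Bioconductor
containers (`GRanges`, `DNAStringSet`) and validates them on synthetic
data with planted ground truth, generated by the package itself.

## Reference-normalized expression

For a transcript $T$ with exonic read count $c^T$ and exonic length
$L_T$, the normalized expression is the ratio of per-nucleotide read
densities

$$ ne^T \;=\; \frac{c^T / L_T}{c^{\mathrm{ref}} / L_{\mathrm{ref}}}, $$

where the reference is an abundant, highly stable transcript: a
β-actin-like mRNA for the long preparations and a SNORD44-like snoRNA
for the short preparation. A read counts toward $c^T$ when it overlaps
at least one exon of $T$ by ≥ 1 nt **on $T$'s strand**; duplicate
reads at the same position are counted multiply (no deduplication — in
a quantitative assay identical positions carry real signal). Genes are
assigned the $ne$ of their most abundant isoform, with ties broken
toward the lexicographically smallest transcript id so the rollup is
deterministic.

Properties that follow directly from the definition — and that the test
suite verifies — are: the reference itself always scores exactly 1;
$ne = 0$ iff $c = 0$; and multiplying every count by a constant leaves
every $ne$ unchanged, which is what makes values comparable across read
sets of very different depth.

Two deliberate choices are worth stating. First, expression counting is
sense-strand only: the library preparation preserves strandedness, and
antisense reads are a biological signal in their own right, routed to
the enrichment analyses instead of being mixed into expression. Second,
a read may count toward several isoforms of one gene; since the gene
rollup takes the maximum rather than the sum, this multi-counting never
inflates gene-level values.

Presence calls use a floor of $\log_2 ne \ge -15$ (1/32 768 of the
reference, i.e. 15 PCR cycles) by default; `expression_curve()`
tabulates gene counts across the whole threshold range so the
dependence of "how many genes are expressed" on the chosen cutoff is
explicit rather than hidden.

## Depletion distortion

`depletion_impact()` compares gene-level $ne$ between the total and
rRNA-depleted preparation of one sample. A gene is *evaluated* when it
reaches $2^{-10}$ of the reference in at least one preparation (the
floor is applied one-sidedly; which side met it is recorded) and is
non-zero in both; it is *flagged* when
$|\log_2(ne_{\mathrm{total}}/ne_{\mathrm{depleted}})| \ge 1$, i.e. a
two-fold discrepancy. Genes with zero expression in exactly one
preparation are reported as dropouts rather than given infinite ratios.
The comparison is antisymmetric by construction — swapping the
preparations negates every ratio and preserves the flagged set — and
the per-gene min/max ratio across samples is summarised in a separate
range table.

The flagging rule is calibrated for genes with adequate counts: with
≥ 200 reads in both preparations the sampling noise of the log-ratio is
about 0.14 log2 units, so a 1-unit threshold yields essentially no
false flags, while planted four-fold distortions sit 7σ from it. The
test suite checks exactly this regime (< 1% false flags on nulls, ≥ 95%
sensitivity at factor ≥ 4).

## Bona fide intronic space and novel-region discovery

`derive_intronic_space()` starts from each protein-coding gene's
unspliced span (minimum exon start to maximum exon end over all
isoforms) and subtracts, **on the same strand only**, every annotated
exon of any gene, repeat element, rRNA/snoRNA locus, miRNA precursor
and lincRNA. Subtraction is global — a feature of one gene removes
intronic space from any overlapping gene — and antisense instances are
deliberately retained, since transcription antisense to an annotated
feature is itself unannotated. Pseudogene intervals are *not*
subtracted: they are not among the excluded categories, and the
pseudogene track is analysed separately.

Within that space, `coverage_islands()` finds maximal runs of
consecutive positions with read depth ≥ 1 (full read spans; a single
uncovered base breaks a run — "consecutive" is strict). A region is
reported when

* **long RNA:** the island spans ≥ 100 nt and its read density reaches
  ≥ 1/1024 of the long reference's density (within 10 PCR cycles);
* **short RNA:** only reads ≥ 30 nt contribute, the island spans
  ≥ 30 nt and reaches ≥ 1/64 of the short reference (within 6 PCR
  cycles).

Both thresholds are inclusive. Region abundance is defined as
per-nucleotide density relative to the reference's per-nucleotide
density, mirroring the $ne$ construction; a count-based variant would
confound region length with abundance. Total and rRNA-depleted read
sets are evaluated separately and a region is accepted if *any* read
set of any sample supports it; accepted islands overlapping on the same
strand are merged, accumulating their supporting samples. The final
long and short collections are intersected to count regions found by
both size classes.

## Category enrichment, sense and antisense

Enrichment is conventionally quoted as a ratio without a canonical
formula, so the package fixes one and records it in the output
metadata: the
expected fraction of signal in a category is its genomic span over a
stated background span (summed chromosome lengths by default), and two
observed fractions are formed —

* **span enrichment**: category bases covered by ≥ 1
  orientation-qualifying read, over all bases covered by any read
  (ignores read multiplicity);
* **support enrichment**: orientation-qualifying reads overlapping the
  category, over all reads (weights by multiplicity).

A read qualifies when its strand matches (sense) or opposes (antisense)
the feature and the overlap covers ≥ 50% of the read — the fraction is
configurable; requiring half the read suppresses edge artifacts at
feature boundaries. Overlapping categories (5'UTR ⊂ exons, for
instance) are scored independently; a read may legitimately count
toward several.

Antisense-miRNA detection clusters antisense short reads of
miRNA-typical length (18–25 nt) per precursor by 5′-end proximity
(≤ 3 nt shift), keeps clusters with ≥ 5 supporting reads, and reports
at most the top two per precursor — one or two products, as a mature
miRNA and its star would appear. The read-support minimum is a package
default, not a published value. Arm-level quantification assigns
sense-strand short reads to the 5p or 3p mature arm they overlap most
(equal overlap is ambiguous and assigned to neither) and normalizes by
the short reference's count.

## Junctions and orphan reads

Reads that fail genome mapping ("orphans") are examined three ways:

1. **Lenient re-mapping** against the genome with up to 6 substitutions
   instead of the default 2 (no indels), capturing heavily edited or
   error-bearing reads. Rescue is provably monotone in the allowance.
2. **Exon–exon junctions**: per gene, all ordered pairs of
   non-overlapping exons (identical exon coordinates across isoforms
   collapsed first; overlapping pairs skipped, not trimmed), with the
   junction sequence built from the donor's last *flank* nt and the
   acceptor's first *flank* nt, read 5′→3′ on the transcript strand.
   `flank = read_length − 1` guarantees any read crossing the boundary
   by ≥ 1 nt is representable. Pairing is within genes only: chimeric
   gene–gene junctions are a different phenomenon and would square the
   catalog size.
3. **An arbitrary target set** (e.g. an HLA allele collection):
   `map_reads_to_sequences()` performs ungapped Hamming alignment of
   each read, both orientations, against any named sequence set.

Matching is exact/Hamming by design, not an approximation of a gapped
aligner: the mapping contract is "up to *k* substitutions, no indels",
and a read hitting more than one distinct location is discarded as a
multi-mapper rather than assigned arbitrarily. `N` never matches. For
real data volumes an external aligner's output can be substituted at
the module boundary; the in-package matcher is authoritative for the
contract and for desk-scale data.

## The synthetic study and what it does (not) show

`simulate_platelet_dataset()` generates the full study design on one
2 Mb toy chromosome: 300 multi-exon protein-coding genes on both
strands with UTRs and occasional exon-skipping isoforms, a designated
abundant long reference and a 70-nt short reference, 150 repeats from a
RepeatMasker-style family vocabulary (intergenic and intronic, sense
and antisense), 30 miRNA precursors with 5p/3p arms, 40 pseudogenes and
30 lincRNAs. Default read budgets are 2 × 10⁵ per long read set and
10⁵ per short read set (the worked analyses and acceptance script use
10⁵/5 × 10⁴, which leaves every per-gene regime intact while keeping a
full run in minutes on one CPU).

Planted signal defines the truth manifest: transcript densities
log2-uniform over 16 units below the reference (one gene pinned at the
bottom, so the dynamic range is exactly the one the design assumes);
depletion distortion factors of magnitude ≥ 4 on ~10% of well-expressed
genes (ne ≥ 2⁻⁵ — where the ≥ 200-read evaluation regime is reachable);
long intronic regions of 150–400 nt at 2⁻⁶–2⁻⁴ of the long reference
and short regions of 35–70 nt at 2⁻³–2⁻¹ of the short reference (well
above the 1/1024 and 1/64 rules, so that islands are densely tiled at
these read budgets); antisense signal over one hundred 3'UTRs; one
repeat family carrying antisense short reads; six precursors with one
or two antisense products anchored within 1 nt at their 5′ ends; dense
sense pseudogene transcription; and *no* lincRNA signal, so the lincRNA
track acts as a built-in null. Orphans are drawn from junction
sequences (0–2 substitutions), from the genome with 3–6 substitutions
(unmappable at 2, rescuable at 6), and from random sequence.

Reads are placed multinomially over sources with weight
density × span; within a transcript, an exon is chosen proportionally
to width and the read stays inside it, so every emitted read is a
contiguous, uniquely-placed genomic interval — genome alignment is out
of scope here and reads are born "already mapped".
Junction-spanning reads appear only in the orphan FASTQ. The depleted
preparation multiplies each transcript's weight by its distortion
factor and nothing else.

What the generator does *not* emulate — and hence what green tests do
not establish about real data: sequencing error and quality scores
(orphan edits are substitutions only), colorspace chemistry,
multi-mapping ambiguity (every read is unique by construction),
fragment-level biases (GC, priming), isoform-level differential
structure beyond exon skipping, and any diffuse transcriptional
background. The last point is a deliberate default: with planted signal
only, every reported novel region traces to a manifest entry, which is
what makes exact recovery checks meaningful. Degradation-like uniform
background can be switched on through the manifest
(`background_short_density`), and the enrichment null-calibration tests
construct uniform read sets explicitly.

## Numerical and degenerate-input policy

Coordinates are held as 1-based closed `GRanges`; BED (0-based
half-open) and GTF (1-based inclusive) convert at the I/O boundary, and
round-trip tests pin the conventions. Abundance thresholds are
inclusive (`≥`), so a region at exactly 1/64 of the reference is kept.
A zero reference count is an error — the read set is unusable for that
normalization, silently returning values would be worse. Genes with
zero counts get $ne = 0$ and are excluded from log-ratio analyses; a
gene expressed in exactly one preparation is a dropout, not an infinite
ratio. Exons shorter than the junction flank truncate the junction
sequence and are flagged. Reads violating a preparation's length class
are rejected and tallied, not silently kept. All randomness flows from
explicit seeds; identical seeds give byte-identical outputs, which the
pipeline verifies by hashing its own report tables.

## Problem sizes used by the tests and acceptance script

Unit and property tests run on hand-built fixtures and on a shared
2-sample dataset (80 genes, 0.7 Mb, 4 × 10⁴ long / 2 × 10⁴ short reads
per set). The acceptance script regenerates the full 4-sample design
(300 genes, 2 Mb, 10⁵ long / 5 × 10⁴ short reads per set) from the
supplied seed and recomputes every headline quantity from scratch.
These sizes are the package's chosen desk-scale study conditions;
statistical tolerances (binomial 3σ bounds, 99% null intervals) are
derived from them, not tuned to them.

## Known limitations

At full scale — a complete genome annotation and on the order of 10⁹
reads — these procedures yield counts (thousands of novel intronic
regions, ~9,500 expressed loci, millions of junctions) that are not
reproducible on a desk-scale toy genome; the package reproduces the
*procedures* and their statistical behavior, not such numbers.
Enrichment ratios carry no significance tests; they are descriptive
observed/expected values.
The expression model performs no isoform deconvolution; with heavily
shared exons, isoform-level (not gene-level) values are upper bounds.
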