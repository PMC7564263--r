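---
title: "circleaf: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{circleaf: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Circular RNAs (circRNAs) arise when the spliceosome joins a downstream
splice donor back to an upstream acceptor (back-splicing), producing a
covalently closed transcript. In sequencing data a circRNA is visible only
through reads that span its back-splice junction: such a read aligns as two
same-chromosome, same-strand segments in *reversed* genomic order relative
to read order (chiastic geometry). Everything downstream of detection —
normalization, reproducibility filtering, differential accumulation between
genotypes, structural annotation against gene models — inherits the
peculiarities of this evidence type: counts are tiny, most junctions appear
in a single biological replicate, and the circular signal must be compared
like-for-like against the linear transcription of the same loci.

circleaf implements this analysis chain for genotype-comparison studies
(wild type versus splicing-factor knockouts in a plant-style genome with an
organelle chromosome and rRNA loci), together with a fully specified
synthetic-study generator so every stage can be tested against known ground
truth.

## Back-splice detection from split alignments

The evidence unit is a *read-end group*: all alignment segments (primary +
supplementary) of one sequenced read end, never pooled across mates. Each
segment carries its reference span and its clip-aware interval in the
original read orientation. A group supports a junction when two segments

* share chromosome and strand,
* cover complementary read intervals (overlap at most `slack = 5` bases), and
* sit in chiastic order: in transcript orientation the read prefix ends at
  the last base inside the circle and the read suffix starts at the first
  base inside it. On the plus strand the prefix segment therefore ends at
  genomic `end` and the suffix segment starts at genomic `start < end`; on
  the minus strand the genomic roles of the two arms swap.

Junction coordinates are reported 1-based and fully closed — first and last
base *inside* the circle — and the identifier `chrom:start-end` is the key
everywhere downstream. Groups with more than two usable segments contribute
the pair maximizing total aligned read length; ties are rejected as
ambiguous and counted, because picking arbitrarily would manufacture
junction evidence. A junction supported by both mates of one template is
counted once (template-level counting; read-pair counting would double the
evidence for long circles).

A call requires at least `min_reads = 2` supporting templates and, by
default, a canonical splice signal: in transcript orientation the two bases
immediately downstream of `end` must read `GT` (donor) and the two bases
immediately upstream of `start` must read `AG` (acceptor). On the minus
strand the test is applied to the reverse complement, equivalently `AC`
before `start` and `CT` after `end` on the plus-strand sequence. Junctions
within two bases of a chromosome edge fail the check by definition.
Junctions on organelle-class chromosomes are excluded from calling;
organelle reads matter only for library accounting.

## The anchor-based second detector

`call_circrnas_anchor()` is an independent cross-check that never sees the
alignments: it takes 20-mers from both ends of each raw read, finds their
exact genomic placements (each chromosome in both orientations), and keeps
reads whose two anchors land uniquely on one frame in chiastic order. Both
anchors are then extended inward over exact matches; every breakpoint
inside the extension-overlap window whose implied donor/acceptor positions
read `GT`/`AG` becomes a candidate. Because sequence immediately inside a
junction can contain spurious `AG`/`GT` pairs shared by all reads of the
same circle, candidates are resolved by voting across reads: each read
commits to its candidate with the highest global support, and reads with
tied candidates are dropped as ambiguous. Aggregation and thresholds then
mirror the split-read detector, so the two are comparable call for call.

Anchors that map to more than one genomic position drop the read. On the
synthetic scale (megabase genomes) exact 20-mer lookup is unique with
overwhelming probability; on a real genome this detector is a
cross-validation device, not a replacement for the split-read path.

## Normalization

Chloroplast and rRNA reads are technical contamination whose fraction
varies between libraries; normalization therefore divides back-spliced
read counts by an *effective* library size:

    effective = total mapped templates − organelle templates − rRNA templates

A template is organelle-mapped when its primary segment lies on an
organelle-class chromosome, and rRNA-mapped when any segment overlaps an
annotated rRNA interval by at least half the segment length (the interval
threshold is exposed; it replaces an external rRNA classifier). Categories
are disjoint with precedence organelle > rRNA. Normalized values are
counts per million effective templates; the scale factor is presentation
only — every downstream statistic is scale-free — but per-million keeps the
tables readable. Two invariances follow by construction and are tested:
scaling a sample's contamination by any factor changes no normalized value,
and jointly scaling retained reads and junction reads leaves normalized
values fixed.

## Linear counterparts

What "the abundance of the linear counterpart" means is genuinely open
(boundary reads, gene-level reads, or assembled-transcript abundance), so
both defensible counters are implemented and neither is privileged:

* **boundary**: templates with a linearly aligned segment covering a circle
  boundary base *and* at least one base outside the circle — evidence of
  linear splicing straddling the back-splice site;
* **gene**: templates overlapping the host gene's exon union — a coarser
  proxy.

Templates that support any back-splice junction are excluded from both, so
circular and linear evidence stay disjoint. Both matrices are normalized by
the same effective library size as the circular matrix, which is what makes
the circular-versus-linear replicate-correlation contrast like-for-like.

## Consensus, uniqueness, and replicate diagnostics

Most circRNAs appear in a single replicate; treating them as signal would
swamp every downstream comparison. The consensus rule keeps circRNAs
detected in at least `k` of a genotype's replicates, with `k` defaulting to
*all* replicates (taken per genotype from the sample sheet, never
hard-coded). Relaxations such as "at least 3 of 4" are just smaller `k`.

Uniqueness of a mutant's consensus set against the wild type comes in two
deliberate readings: **strict** removes a circRNA seen in even a single
wild-type replicate (a conservative "detected in none of the reference
replicates"), while **consensus** removes only members of the wild-type
consensus. Strict is always a subset of consensus-mode; both are reported.

Replicate quality is diagnosed with pairwise Pearson correlations of
normalized values, computed identically for circular and linear matrices.
For each replicate pair, features absent in both members are dropped;
features present in only one are kept as zeros, because presence/absence
variability *is* the phenomenon being measured for circRNAs. Correlations
are computed on the natural scale by default with a log2 option behind a
flag. Sporadic-dominated circRNA matrices sit far below the linear-gene
matrices from the same samples (roughly 0.5–0.7 versus 0.93–0.99 on the
demo), reproducing the field's observed contrast.

## Differential accumulation

Per-circRNA testing operates on log2(normalized + 0.5) across replicates.
The default statistic is the **variance-moderated t** (empirical-Bayes
shrinkage of per-feature variances across the matrix, via limma). The
choice is driven by power at the study's scale: with negative-binomial
dispersion 0.3 the per-observation log2 standard deviation is about 0.8
regardless of mean, so a plain Welch t at n = 4 vs 4 has a standard error
near 0.58 and about 6 degrees of freedom — its power for a 4-fold change
tops out near 0.75, while the moderated t reaches 0.85–0.95 at the same
type-I level (0.04–0.06 measured under a seeded null). `method = "welch"`
retains the ordinary test for comparison. The pseudocount (0.5) is exposed;
features all-zero in both groups are excluded and never reported
significant.

The significance flag mirrors the field's rule — raw p ≤ 0.05 *and* at
least a 2-fold change — with Benjamini–Hochberg adjusted p-values always
reported alongside but not gating the flag, so the flag stays comparable
with studies that used raw p.

The global accumulation comparison is a two-sided Mann–Whitney U on pooled
per-circRNA-per-replicate normalized counts (rank-based; no distributional
assumption at these scales), with star coding at 0.05/0.01/0.001. Which
observation universe it should use (consensus circRNAs versus everything
detected) is not determinable, so both are computed and labelled. The same
machinery applied to a linear matrix gives the linear-counterpart test, and
circular–linear coupling is a plain Pearson correlation over paired
per-feature means within a genotype — reported as a statistic, with no
independence claim beyond it.

## Structural annotation

A junction's host gene is the gene whose span contains the circle on the
junction's strand; among multiple candidates the maximal exonic overlap
wins, ties go to the smaller span, and a strand-agnostic retry (flagged)
precedes an intergenic verdict. Exon indices are counted 5′→3′ in
transcript orientation — on the minus strand exon 1 is the rightmost
genomic exon — and the circle's "start" is its transcript-5′ endpoint
(genomic start on +, genomic end on −). The annotation uses each gene's
single representative transcript model; with multi-isoform annotations the
longest transcript would stand in.

Endpoint classes are `exon_boundary` (exact match to the splice boundary
appropriate to the side: acceptor edge for starts, donor edge for ends),
`exon_internal`, `intron`, or `intergenic`. The boundary match is exact by
default; a small tolerance flag exists for noisy alignments. Intronic
endpoints are assigned the next downstream exon with a flag rather than
excluded, so distribution tables keep every consensus circRNA. Because
"started or ended in a known exon" is ambiguous between *at a boundary* and
*within an exon body*, the distribution report carries both fractions.

## The synthetic study

The generator emulates the design of a splicing-factor knockout study: a
multi-chromosome nuclear genome plus one organelle chromosome and annotated
rRNA loci; 200 multi-exon genes with canonical GT–AG introns; three
genotypes (wild type first) with four biological replicates; 40 true
circRNAs. Its defaults are the package's reference conditions and are not
adjusted per analysis.

* **CircRNA pools.** A reproducible minority (40%) is present in every
  replicate of its carrier genotypes with negative-binomial counts
  (dispersion 0.3, per-circRNA means log-normal around 20 junction
  templates); the sporadic majority (60%) is included per replicate as an
  independent Bernoulli draw (p = 0.25) with 1–3 junction templates. Half
  of the reproducible circRNAs are shared by all genotypes, the rest are
  private to single genotypes (mutants first), which is what gives the
  uniqueness analyses non-trivial truth. CircRNAs private to the first
  mutant prefer spans containing exon 1, mimicking the first-exon
  phenotype of cap-binding-complex mutants.
* **Fold changes** multiply circRNA means only; per-gene linear abundances
  are identical across genotypes by construction. Defaults spike the first
  mutant with 4 increased (4-fold) and 2 decreased (0.25-fold) circRNAs and
  the second with 3 and 2.
* **Linear transcription.** Per-gene means are log-normal with sdlog 1.5
  (a 2–3 order-of-magnitude dynamic range, mean fixed at the configured
  depth) and replicate dispersion 0.05. These two values are what place
  linear replicate correlations in the ~0.95–0.99 regime reported for
  mRNA, against which the circRNA correlations contrast.
* **Splice signals.** AG/GT flanks are planted around *every* exon boundary
  (including outer boundaries of first and last exons), so any exon-bounded
  back-splice is canonical. A 15% minority of circRNAs has one or both
  endpoints shifted into the exon body — mid-exon back-splicing — at
  positions where the random sequence already carries the canonical
  flanks, so the signal filter treats them like real mid-exon junctions.
* **Read emission.** Junction-spanning mates are written as a primary plus
  a soft-clipped supplementary record with SA tags, in exact chiastic
  geometry (spliced N-gap CIGARs when the circle spans introns); the other
  mate lies contiguously inside the circle. Junction reads carry at least
  20 bases on each side of the back-splice site, and the minimum exon
  length (80) is at least read length (100) minus anchor length (20), so
  each arm stays within one exon — both detectors face evidence they can
  in principle recover completely. Linear pairs are drawn from spliced
  transcripts; contamination reads fall uniformly inside the organelle
  chromosome and rRNA loci. Identical configuration and seed give
  byte-identical FASTA/GFF3/SAM/FASTQ/manifest outputs.

What the generator does **not** model: sequencing errors and quality
realism, adapter contamination, intron-lariat circles, multi-isoform
annotation, alignment ambiguity on repetitive sequence. Passing tests on
this data therefore demonstrate the correctness of the geometry,
accounting and statistics — not robustness to alignment noise on a real
genome.

## Numerical and degenerate-input choices

* Multi-segment tie-breaks reject rather than guess (counted).
* The anchor detector's breakpoint ambiguity is resolved by cross-read
  voting; irresolvable ties drop the read.
* Correlations with fewer than two non-degenerate features, empty test
  universes, and constant vectors return explicit not-a-values or errors
  with named reasons — never silent zeros.
* Identical groups in the fold-change test yield p = 1 (moderated path) —
  and never a significance flag.
* All coordinates are 1-based fully closed; BEDGRAPH output converts to the
  format's 0-based half-open convention at the boundary.

## Problem sizes

The reference demo (~2 Mb nuclear genome, 200 genes, 40 circRNAs, 12
samples) runs the full pipeline in about two minutes on one CPU. The
calibration studies use 2,000-feature matrices at n = 4 vs 4, and the
correlation-contrast and independence properties use 20 seeded repetitions
at the count level (the genome is fixed, counts re-drawn), sizes chosen so
the whole suite stays comfortably interactive while estimating rates with
useful precision.

## Limitations

Template-level counting assumes read names identify templates; the
detector trusts the aligner's supplementary-alignment conventions rather
than re-aligning; host-gene assignment uses a single transcript model per
gene; and the acceptance properties quantify behavior under the synthetic
model above, not under real library noise.
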