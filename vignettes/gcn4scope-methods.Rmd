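---
title: "Methods: bin-based ChIP-seq peak calling and regulon reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bin-based ChIP-seq peak calling and regulon reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`gcn4scope` reconstructs the regulon of a bZIP transcription factor — the
motivating case is yeast Gcn4, the master regulator of amino-acid
biosynthesis — from matched ChIP-seq and RNA-seq data.  It implements a
transparent bin-based peak caller with mode/MAD background normalization
and two-replicate consensus, peak annotation (targets, genomic features,
consensus-motif content), anchor-centered coverage profiles, integration
of differential-expression (DE) tables into a five-way regulon, and
arginine/lysine proteome-composition analysis.  A fully seeded synthetic
generator plants ground truth at every level so that the whole pipeline is
testable offline; this document records the model, its assumptions, and
the design decisions taken where the procedure left room.

# The peak-calling model

Aligned fragments are reduced to midpoints and counted in 100 bp
non-overlapping bins (`bin_counts()`); each fragment is counted exactly
once, in the bin containing `floor((start + end)/2)`.  The background of
the per-bin count distribution is summarized by (`background_stats()`):

* $\mu$ — the mode of the integer per-bin counts (ties resolved to the
  smallest value, deterministically);
* $x$ — the *unscaled* median absolute deviation of the bins whose count
  is below the genome-wide mean (no 1.4826 normal-consistency factor:
  the procedure names the plain MAD);
* background bins — those with counts in $[\mu - x,\ \mu + x]$;
* the divisor — the **mean count of the background bins**.

Bin counts divided by this divisor are fold-over-background, so
background bins normalize to about 1 and the default threshold of 2 reads
as "at least twice the background level".  Dividing instead by the *total*
read count in background bins (available as `divisor_mode = "total"`)
yields values far below 1, under which a threshold of 2 can never fire;
we regard the mean-count reading as the one consistent with the published
cutoff, and flag it as an interpretation.

Candidate regions are maximal runs of bins strictly above the threshold
(a bin at exactly 2 is excluded), regions separated by strictly less than
200 bp merge into one peak, and a consensus peak requires support from
both replicates with an inclusive overlap of at least 50 bp; the
consensus interval is the union of the contributing replicate peaks
(their extent is not specified by the procedure; the union is recorded in
the output provenance together with contributor IDs), and its signal the
maximum over contributors.  Each comparison is deliberately strict or
inclusive exactly as the quoted wording demands, and the whole chain is
checked bin-for-bin against an independent brute-force transcription of
the procedure in the test suite.  Normalization is genome-wide (all
chromosomes pooled); the mock sample never enters calling and is used for
QC contrast only.  The statistics are unstable below roughly 100 bins, so
`background_stats()` warns (rather than errors) under that size — the
hand-enumerable worked examples must remain computable.

# Annotation

A gene is a *possible binding target* of a peak when its ORF overlaps the
peak extended by 750 bp on each side (half-open arithmetic: a gene
starting exactly at `peak_end + 750` is not a target).  Feature
classification is a midpoint-precedence scheme: promoter (TSS −1000 to
+100 bp in transcript orientation) > near-TTS (0 to +250 bp downstream)
> exon (midpoint inside an ORF) > intergenic.  The original analysis used
HOMER's annotator here; our classifier is a transparent re-specification
— the promoter window is the published one, the TTS window is our
declared convention (HOMER's differs), so published feature-class counts
are approximated, not reproduced.  Motif content is assessed with a
consensus IUPAC scan (`TGANTCA`, both strands, overlapping hits allowed)
rather than de novo discovery.  Note that `TGANTCA` is its own reverse
complement as an IUPAC pattern, so every site is reported once per
strand, and the per-position occurrence probability on uniform random
sequence is $4 \cdot 4^{-7} = 4^{-6}$ for either-strand occupancy.

# Coverage matrices

`coverage_matrix()` computes per-gene coverage over
`[anchor − flank, anchor + flank)` (anchor TSS or ATG), aggregated into
`colbin`-bp columns.  Minus-strand rows use the same genomic window and
are reversed, which places the anchor base just left of offset 0 and
makes the strand-flip involution exact on the discrete grid (flipping
every strand exactly reverses every row) — a shifted-window alternative
breaks this by one base.  Two value semantics are provided: `"count"`
(raw fragment-midpoint counts; a genome-tiling matrix then sums to the
total fragment count) and `"normalized"` (the caller's
fold-over-background bin values expanded to bp as a step function —
constant within each 100 bp bin, keeping a single normalization semantics
pipeline-wide; we chose the step function over linear interpolation for
transparency).  Region-set signal comparison uses a two-sided
Mann–Whitney rank-sum test: exact by full enumeration of labelings when
the combined size is ≤ 20 (ties handled by enumeration over midranks),
and a tie-corrected normal approximation with continuity correction
otherwise.

# Integration with expression data

DE tables are filtered with an inclusive fold-change cutoff
(`|log2FC| ≥ log2(fc_cutoff)`) and an inclusive stringent raw p-value
cutoff (`p ≤ 1e-4`); no multiple-testing correction is applied by default,
matching the published filter (a BH mode exists but is off).  With the
contrast oriented as deletion-vs-wild-type, genes down in the deletion
are *activated* by the factor and genes up are *repressed*; intersecting
each with the ChIP target set yields the five-way partition
direct/indirect × activated/repressed plus not-regulated.  Gene-set
overlaps are tested with a one-sided Fisher exact test (hypergeometric
upper tail) over an explicitly supplied universe — the universe is never
defaulted silently because published overlap statistics are sensitive to
it.

`simple_de()` is a deliberately transparent stand-in used to exercise the
integration stage on synthetic counts: CPM normalization, log2 fold
change of mean CPM with pseudocount 0.5, and a two-sided exact binomial
test of the pooled condition counts against the pooled library-size
ratio.  The binomial model assumes Poisson sampling given totals; under
negative-binomial replicate noise with dispersion $\varphi$ its variance
is understated by the factor $1 + \varphi\mu$, so at biological-scale
dispersion (say $\varphi = 0.05$, $\mu = 100$) the stage is
anti-conservative by roughly an order of magnitude at stringent cutoffs.
Its calibration test therefore runs in the Poisson sampling limit of the
NB family ($\varphi = 10^{-4}$), the regime the test actually models.
This is precisely why real analyses should supply an external,
dispersion-aware DE table (edgeR/DESeq2) instead; the planted synthetic
effects (4-fold) are large enough that detection power is unaffected by
this choice.

# Proteome composition

`rk_fraction()` is the percentage of arginine plus lysine residues over
the full sequence (initiator methionine included, `*` stripped, `X`
counted in the length but never as R/K).  The proteome is partitioned
into three bins, by the fixed published-style cut points (bin1 < 10%,
bin3 > 13%, both boundary values assigned to the closed middle bin2 — the
boundary membership is ambiguous in prose, so it is a logged, configurable
decision) or by empirical terciles; both modes are provided because
whether the published three-way split came from the fixed cuts or from
terciles that landed there is not decidable from the text.  Enrichment of
a gene set in a bin is again the one-sided Fisher test over the binned
proteome, and group composition comparisons use the same exact/approximate
rank-sum machinery as the signal module.

# The synthetic generator

The generator's defaults are the study conditions used by all tests and
by the acceptance script: one 200 kb chromosome at GC 0.38, 80
non-overlapping genes (ORFs 500–1500 bp, 5′ UTRs 50–200 bp, 3′ UTRs
25–150 bp), two IP replicates and one mock at 2×10⁵ fragments each
(fragment length 150 bp), ChIP enrichment fold 8 over planted peaks of
200–400 bp, NB expression counts (3 replicates per condition, dispersion
0.05, planted |log2FC| = 2), and a proteome with bin fractions
(0.25, 0.50, 0.25) mirroring the roughly 25/50/25 split of the real
proteome at the 10%/13% cuts.  Fragment placement follows a midpoint-rate
model (uniform background, multiplicative enrichment inside peaks) —
simpler than shift/extension models and sufficient to exercise the
caller.  Enrichment folds in the 4–16 range are chosen for testability;
the real data's effect sizes are unknown.

Planted truth is constructed to be unambiguous: each direct-target
candidate receives one concrete `TGANTCA` instance (ambiguity resolved at
random, random strand) written into its promoter within 600 bp of the
ORF, and a peak centered on it; a candidate whose peak (extended by the
750 bp target window) would touch *another* gene's ORF is skipped and
reassigned to the corresponding indirect class.  On the crowded toy
genome this typically leaves 5–8 direct genes out of 16 candidates —
enough to exercise every downstream branch while guaranteeing that no
indirect or null gene sits within the target window of a planted peak.
All randomness flows from one seed through a documented derivation
(`(seed·101 + 7919·stream) mod (2³¹−1)`), so every stage is independently
reproducible and distinct stages never share a stream.

What the generator does *not* emulate — and hence what green tests do not
establish about real data: read-level sequencing error and mapping
ambiguity, PCR duplicates, chromatin accessibility bias, realistic yeast
sequence composition, correlated replicate structure, and edgeR's
dispersion estimation.  Recovery numbers on synthetic data certify the
*procedure* (the arithmetic and its thresholds), not performance on real
libraries.

# Numerical choices and degenerate inputs

Ties in the mode go to the smallest count; an all-identical bin vector,
an empty background window, or a zero divisor are errors with advice
rather than silent NaNs.  Empty peak sets, empty BED files and all-zero
genes in `simple_de()` (flagged, `p = 1`) are legal.  Interval merging is
idempotent and order-invariant; exact tests fall back to normal
approximations only above the enumeration limit.  Coordinates are 0-based
half-open everywhere internally; GFF3 (1-based closed) and TSS tables
(1-based positions) are converted at the boundary, and the conversion is
an involution.

# Problem sizes

The default test and acceptance workloads are sized for a laptop-class
single core: the full synthetic pipeline runs in a few seconds; the
caller-vs-oracle sweep uses 100 genomes of 3–10 kb; the motif oracle
sweep 1000 sequences of 1 kb; the DE calibration 10⁵ null genes; the
enrichment-uniformity check 200 random sets over a 2000-protein synthetic
proteome.

# Known limitations

The feature classifier approximates (does not reproduce) HOMER's
conventions; the near-TTS window is our own.  The rank-sum normal
approximation is used above n = 20 without exact mid-p refinements.
`simple_de()` is not a DE method for real data.  The literal total-reads
divisor is available but requires a user-chosen threshold.  Whether the
original normalization was genome-wide or per-chromosome is unstated; we
implement genome-wide and expose the choice structurally (per-chromosome
statistics can be obtained by calling the caller per chromosome).
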