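# gcn4scope

Reconstructing the regulon of a bZIP transcription factor from matched
ChIP-seq and RNA-seq data.

## The problem

Gcn4 (ATF4 in mammals) is the master transcriptional regulator of
amino-acid biosynthesis in budding yeast.  Mapping which genes it
*directly* drives requires combining two genome-wide measurements: where
the factor binds (ChIP-seq of an epitope-tagged factor, two biological
replicates plus a mock control) and which transcripts depend on it
(RNA-seq of a deletion mutant versus wild type).  `gcn4scope` implements
that analysis as a tested, reusable R pipeline for anyone working with a
promoter-binding factor and a deletion transcriptome:

* **Peak calling** — fragment midpoints are counted in 100 bp bins; bins
  are normalized by the background of the count distribution, summarized
  by its mode μ and the unscaled median absolute deviation *x* of
  sub-mean bins (background bins are those with counts in μ ± *x*, and
  the divisor is their mean count, so normalized values read as
  fold-over-background).  Runs of bins strictly above 2 become regions,
  regions closer than 200 bp merge, and peaks must replicate with ≥ 50 bp
  overlap to reach the consensus set.
* **Annotation** — target genes are ORFs within 750 bp of a peak;
  features are classified by peak midpoint with promoter
  (TSS −1 kb..+100 bp) precedence; peaks are scanned for the consensus
  element `TGANTCA` (IUPAC, both strands).
* **Integration** — DE tables filtered at fold change ≥ 2 and p ≤ 1e-4
  are crossed with the ChIP target set into a five-way regulon:
  direct/indirect × activated/repressed plus not-regulated.  Gene-set
  overlaps use one-sided Fisher exact tests over an explicit universe.
* **Composition** — per-protein %R+K (arginine + lysine) partitions the
  proteome into bins (<10%, 10–13%, >13%); enrichment of regulon classes
  in the high-%R+K bin and rank-sum composition comparisons connect
  amino-acid supply to the translation machinery.
* **Synthetic data** — a seeded generator plants peaks, motifs,
  expression effects and proteome composition with a machine-readable
  truth manifest, so every stage (and the whole pipeline) is testable
  without downloads.

## Worked example

Simulate an experiment at the default study scale (one 200 kb chromosome,
80 genes, two IP replicates of 2×10⁵ fragments, enrichment fold 8), call
and annotate peaks:

```r
library(gcn4scope)

sim  <- simulate_experiment(default_config(seed = 1))
repA <- call_peaks(sim$chip$ip[[1]], sim$chrom_sizes, source = "repA")
repB <- call_peaks(sim$chip$ip[[2]], sim$chrom_sizes, source = "repB")
attr(repA, "background")
#> <background_stats> mu=90 x=5 divisor=90.3436 (mean of 809 background bins)

cons <- consensus_peaks(repA, repB)
cons <- annotate_peaks(cons, sim$annotation, genome = sim$genome)
head(as.data.frame(cons)[, c("chrom", "start", "end", "signal",
                             "feature_class", "target_genes",
                             "motif_count")], 3)
#>   chrom  start    end   signal feature_class target_genes motif_count
#> 1  chrI  35800  36100 8.855079      promoter         g015           4
#> 2  chrI  62600  63000 8.866148      promoter         g026           2
#> 3  chrI 151700 152100 8.323774      promoter         g060           2
```

The background mode is ~90 fragments per 100 bp bin (2×10⁵ fragments over
2000 bins), so the planted 8-fold peaks normalize to ~8.8× background,
well above the threshold of 2; each lands in a promoter and contains the
planted `TGANTCA` instance.  The one-call pipeline runs every stage and
summarizes:

```r
run_all(default_config(seed = 1))
#> <run_report> seed 1
#>   consensus peaks: 7 (recall 1.00, precision 1.00)
#>   features: promoter 7, exon 0, near_TTS 0, intergenic 0
#>    motif fraction: 1.00
#>   DE:  14 up / 22 down; regulon accuracy 1.00
#>    bin3 enrichment p = 1.14e-05
```

All 7 planted peaks are recovered with no false positives; the DE stage
finds the 22 planted activated and 14 planted repressed genes; crossing
them with the ChIP targets reproduces the planted five-way regulon
exactly; and the repressed set is strongly enriched in the high-%R+K
bin3, the synthetic analogue of the translation machinery being
arginine/lysine-rich.  With `enrichment = 1` (a null IP) the consensus
set is empty — the replicate-consistency filter suppresses background
noise.

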