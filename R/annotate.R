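# Peak -> gene target assignment, genomic-feature classification, and
# consensus-motif scanning.
#
# Target assignment follows the ORF-window rule: a gene is a possible
# binding target of a peak when its ORF lies within `window` bp (default
# 750) of the peak on either side.  Feature classification is a
# transparent midpoint-precedence scheme over strand-aware windows
# (promoter > near_TTS > exon > intergenic) with the promoter defined as
# TSS - 1 kb .. TSS + 100 bp in transcript orientation.

#' Assign target genes to peaks
#'
#' A gene is a target of a peak iff its ORF interval overlaps the peak
#' extended by `window` bp on both sides (`[start - window, end + window)`,
#' half-open) by at least 1 bp.  A gene may be the target of several peaks
#' and a peak may have several targets (e.g. a bidirectional promoter
#' between two divergent genes).
#'
#' @param peaks A [peak_set()] (or data.frame with `chrom`, `start`,
#'   `end`, `peak_id`).
#' @param ann A [genome_annotation()].
#' @param window Extension in bp on each side of the peak (default 750).
#' @return List with `by_peak` (named list peak_id -> character vector of
#'   gene IDs) and `target_genes` (sorted unique gene IDs).
#' @export
assign_targets <- function(peaks, ann, window = 750L) {
  stopifnot(window >= 0)
  g <- ann$genes
  ids <- if (!is.null(peaks$peak_id)) peaks$peak_id
         else sprintf("peak_%d", seq_len(nrow(peaks)))
  by_peak <- lapply(seq_len(nrow(peaks)), function(i) {
    lo <- peaks$start[i] - window
    hi <- peaks$end[i] + window
    hit <- g$chrom == peaks$chrom[i] & g$start < hi & g$end > lo
    g$gene_id[hit]
  })
  names(by_peak) <- ids
  list(by_peak = by_peak,
       target_genes = sort(unique(unlist(by_peak, use.names = FALSE))))
}

#' Classify peaks by genomic feature
#'
#' Each peak is classified by the position of its midpoint against
#' strand-aware windows, with precedence promoter > near_TTS > exon >
#' intergenic.  The promoter covers transcript-oriented offsets
#' `[promoter_window[1], promoter_window[2])` around the TSS (default
#' -1000..+100); the TTS window covers `[tts_window[1], tts_window[2])`
#' downstream offsets around the TTS (default 0..+250); exon means the
#' midpoint lies within some ORF.
#'
#' @inheritParams assign_targets
#' @param promoter_window Length-2 offsets around the TSS, transcript
#'   orientation (negative = upstream).
#' @param tts_window Length-2 offsets around the TTS.
#' @return Character vector of classes (`promoter`, `near_TTS`, `exon`,
#'   `intergenic`), one per peak.
#' @export
classify_features <- function(peaks, ann,
                              promoter_window = c(-1000L, 100L),
                              tts_window = c(0L, 250L)) {
  g <- ann$genes
  plus <- g$strand == "+"
  vapply(seq_len(nrow(peaks)), function(i) {
    m <- (peaks$start[i] + peaks$end[i]) %/% 2L
    on_chr <- g$chrom == peaks$chrom[i]
    # transcript-oriented offset of the midpoint from each gene's TSS/TTS
    off_tss <- ifelse(plus, m - g$tss, g$tss - m)
    off_tts <- ifelse(plus, m - g$tts, g$tts - m)
    if (any(on_chr & off_tss >= promoter_window[1] &
              off_tss < promoter_window[2]))
      return("promoter")
    if (any(on_chr & off_tts >= tts_window[1] & off_tts < tts_window[2]))
      return("near_TTS")
    if (any(on_chr & m >= g$start & m < g$end))
      return("exon")
    "intergenic"
  }, "")
}

iupac_ok <- function(motif) {
  all(strsplit(toupper(motif), "")[[1]] %in%
        strsplit("ACGTRYSWKMBDHVN", "")[[1]])
}

#' Scan a sequence for an IUPAC consensus motif on both strands
#'
#' Reports every position (0-based) where the motif matches the forward
#' strand or where its reverse complement matches (a reverse-strand hit).
#' Overlapping matches are all reported; `N` matches any base.  For the
#' canonical bZIP element `TGANTCA` (its own reverse complement as an
#' IUPAC pattern) every site is reported once per strand.
#'
#' @param sequence DNA string (or `Biostrings::DNAString`).
#' @param motif IUPAC motif (default `"TGANTCA"`).
#' @return data.frame with `pos` (0-based start on the forward strand),
#'   `strand`, and `match` (the motif-oriented sequence of the site).
#' @export
scan_motif <- function(sequence, motif = "TGANTCA") {
  if (!iupac_ok(motif)) stop("invalid IUPAC symbol in motif: ", motif)
  subject <- Biostrings::DNAString(as.character(sequence))
  pat <- Biostrings::DNAString(toupper(motif))
  fwd <- Biostrings::matchPattern(pat, subject, fixed = "subject")
  rev <- Biostrings::matchPattern(Biostrings::reverseComplement(pat),
                                  subject, fixed = "subject")
  pos <- c(BiocGenerics::start(fwd) - 1L, BiocGenerics::start(rev) - 1L)
  strand <- rep(c("+", "-"), c(length(fwd), length(rev)))
  match <- c(as.character(fwd),
             as.character(Biostrings::reverseComplement(
               Biostrings::DNAStringSet(rev))))
  o <- order(pos, strand)
  out <- data.frame(pos = pos, strand = strand, match = match)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fraction of peaks containing a motif
#'
#' Extracts each peak's sequence `[start, end)` from the genome and counts
#' peaks with at least one [scan_motif()] hit on either strand.
#'
#' @param peaks A [peak_set()].
#' @param genome Named `Biostrings::DNAStringSet` (or FASTA path).
#' @param motif IUPAC motif (default `"TGANTCA"`).
#' @return List with `fraction`, `n_with_motif`, `n_peaks`, and
#'   `motif_counts` (per-peak hit counts, both strands).
#' @export
motif_fraction <- function(peaks, genome, motif = "TGANTCA") {
  if (is.character(genome) && length(genome) == 1L)
    genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  counts <- vapply(seq_len(nrow(peaks)), function(i) {
    chr <- peaks$chrom[i]
    if (!chr %in% names(genome)) stop("peak on unknown chromosome: ", chr)
    if (peaks$end[i] > length(genome[[chr]]) || peaks$start[i] < 0)
      stop("peak outside chromosome ", chr)
    seq <- Biostrings::subseq(genome[[chr]], peaks$start[i] + 1L,
                              peaks$end[i])
    nrow(scan_motif(seq, motif))
  }, 0L)
  list(fraction = if (nrow(peaks)) mean(counts > 0) else NA_real_,
       n_with_motif = sum(counts > 0),
       n_peaks = nrow(peaks),
       motif_counts = counts)
}

#' Annotate a peak set in place
#'
#' Fills the `feature_class`, `target_genes` and `motif_count` columns of
#' a peak set using [classify_features()], [assign_targets()] and
#' [scan_motif()].
#'
#' @inheritParams classify_features
#' @inheritParams motif_fraction
#' @param window Target-assignment window in bp (default 750).
#' @return The annotated [peak_set()].
#' @export
annotate_peaks <- function(peaks, ann, genome = NULL, motif = "TGANTCA",
                           window = 750L,
                           promoter_window = c(-1000L, 100L),
                           tts_window = c(0L, 250L)) {
  if (!nrow(peaks)) return(peaks)
  peaks$feature_class <- classify_features(peaks, ann, promoter_window,
                                           tts_window)
  tg <- assign_targets(peaks, ann, window)
  peaks$target_genes <- vapply(tg$by_peak, function(x) {
    if (length(x)) paste(x, collapse = ",") else "."
  }, "")
  if (!is.null(genome))
    peaks$motif_count <- motif_fraction(peaks, genome, motif)$motif_counts
  peaks
}
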