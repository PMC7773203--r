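# Independent oracles: deliberately plain, loop-based transcriptions of
# the published procedure and of textbook closed forms.  They share no
# code with the package implementation.

# --- brute-force reference of the bin/normalize/threshold/merge/consensus
#     procedure, single data path, plain loops -------------------------------

ref_bin <- function(frags, chrom_len, bin_size) {
  n_bins <- ceiling(chrom_len / bin_size)
  counts <- rep(0L, n_bins)
  for (i in seq_len(nrow(frags))) {
    mid <- floor((frags$start[i] + frags$end[i]) / 2)
    b <- floor(mid / bin_size) + 1
    counts[b] <- counts[b] + 1L
  }
  counts
}

ref_background <- function(counts) {
  tab <- table(counts)
  mu <- min(as.integer(names(tab)[tab == max(tab)]))
  below <- counts[counts < mean(counts)]
  x <- median(abs(below - median(below)))
  bg <- counts[counts >= mu - x & counts <= mu + x]
  list(mu = mu, x = x, divisor = mean(bg))
}

ref_regions <- function(norm, chrom_len, bin_size, threshold) {
  out <- NULL
  run_start <- NA
  for (b in seq_along(norm)) {
    if (norm[b] > threshold) {
      if (is.na(run_start)) run_start <- b
    } else if (!is.na(run_start)) {
      out <- rbind(out, c((run_start - 1) * bin_size,
                          min((b - 1) * bin_size, chrom_len)))
      run_start <- NA
    }
  }
  if (!is.na(run_start))
    out <- rbind(out, c((run_start - 1) * bin_size,
                        min(length(norm) * bin_size, chrom_len)))
  out
}

ref_merge <- function(iv, merge_gap) {
  if (is.null(iv) || nrow(iv) == 0) return(iv)
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1]) {
    last <- nrow(out)
    if (iv[i, 1] - out[last, 2] < merge_gap) {
      out[last, 2] <- max(out[last, 2], iv[i, 2])
    } else out <- rbind(out, iv[i, , drop = FALSE])
  }
  out
}

# full reference caller for a single chromosome; returns consensus
# intervals as a two-column matrix (start, end) or NULL
ref_consensus_caller <- function(fragsA, fragsB, chrom_len,
                                 bin_size = 100, threshold = 2,
                                 merge_gap = 200, min_overlap = 50) {
  one_rep <- function(frags) {
    counts <- ref_bin(frags, chrom_len, bin_size)
    bg <- ref_background(counts)
    ref_merge(ref_regions(counts / bg$divisor, chrom_len, bin_size,
                          threshold), merge_gap)
  }
  a <- one_rep(fragsA)
  b <- one_rep(fragsB)
  if (is.null(a) || is.null(b)) return(NULL)
  unions <- NULL
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    ov <- min(a[i, 2], b[j, 2]) - max(a[i, 1], b[j, 1])
    if (ov >= min_overlap)
      unions <- rbind(unions, c(min(a[i, 1], b[j, 1]),
                                max(a[i, 2], b[j, 2])))
  }
  if (is.null(unions)) return(NULL)
  # chain overlapping/adjacent unions
  unions <- unions[order(unions[, 1]), , drop = FALSE]
  out <- unions[1, , drop = FALSE]
  for (i in seq_len(nrow(unions))[-1]) {
    last <- nrow(out)
    if (unions[i, 1] <= out[last, 2]) {
      out[last, 2] <- max(out[last, 2], unions[i, 2])
    } else out <- rbind(out, unions[i, , drop = FALSE])
  }
  out
}

# --- brute-force IUPAC motif scan (both strands), character-level ----------

iupac_sets <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

ref_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

ref_scan_motif <- function(seq, motif) {
  L <- nchar(motif)
  pat <- strsplit(motif, "")[[1]]
  hits <- NULL
  for (i in 0:(nchar(seq) - L)) {
    w <- substr(seq, i + 1, i + L)
    wc <- strsplit(w, "")[[1]]
    if (all(mapply(function(a, p) a %in% iupac_sets[[p]], wc, pat)))
      hits <- rbind(hits, data.frame(pos = i, strand = "+"))
    rc <- strsplit(ref_revcomp(w), "")[[1]]
    if (all(mapply(function(a, p) a %in% iupac_sets[[p]], rc, pat)))
      hits <- rbind(hits, data.frame(pos = i, strand = "-"))
  }
  hits
}

# --- hypergeometric upper-tail enumeration (choose-based) ------------------

ref_hyper_upper <- function(k, nA, nB, N) {
  j <- k:min(nA, nB)
  sum(choose(nB, j) * choose(N - nB, nA - j)) / choose(N, nA)
}

# --- misc fixture builders -------------------------------------------------

tiny_annotation <- function() {
  genome_annotation(
    c(chrI = 20000L),
    data.frame(gene_id = c("gA", "gB", "gC"),
               chrom = "chrI",
               start = c(2000L, 6000L, 12000L),
               end = c(3000L, 7000L, 13500L),
               strand = c("+", "-", "+"),
               tss = c(1900L, 7100L, 11880L),
               tts = c(3050L, 5900L, 13600L),
               tss_default = FALSE))
}

frags_from_midpoints <- function(mids, chrom = "chrI", width = 2L,
                                 sample_id = "s") {
  fragment_set(data.frame(chrom = chrom, start = mids - width %/% 2L,
                          end = mids + width - width %/% 2L),
               sample_id = sample_id)
}
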