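# The bin-based peak caller: fixed-width binning of fragment midpoints,
# mode/MAD background normalization, strict thresholding, gap merging and
# two-replicate consensus.
#
# Normalization model: per-bin counts are divided by the mean count of the
# "background" bins, defined as those whose count lies within mu +/- x,
# where mu is the mode of the per-bin count distribution and x the
# (unscaled) median absolute deviation of the bins counting fewer reads
# than the mean.  Normalized values are therefore fold-over-background, so
# the default threshold of 2 reads as "twice the background level".

#' Bin fragment midpoints into fixed-width bins
#'
#' Each fragment is counted exactly once, in the bin containing its
#' midpoint `floor((start + end) / 2)`.  Bins are 0-based half-open and the
#' terminal bin may be shorter than `bin_size`.
#'
#' @param frags A [fragment_set()].
#' @param chrom_sizes Named integer vector of chromosome lengths.
#' @param bin_size Bin width in bp (default 100).
#' @return Object of class `binned_coverage`: list with `sample_id`,
#'   `bin_size`, and `counts` (named list of per-chromosome integer
#'   vectors).
#' @export
bin_counts <- function(frags, chrom_sizes, bin_size = 100L) {
  stopifnot(inherits(frags, "fragment_set"), bin_size >= 1)
  bin_size <- as.integer(bin_size)
  fr <- frags$fragments
  bad <- setdiff(unique(fr$chrom), names(chrom_sizes))
  if (length(bad))
    stop("fragment on unknown chromosome: ", paste(bad, collapse = ", "))
  counts <- lapply(names(chrom_sizes), function(chr) {
    n_bins <- as.integer(ceiling(chrom_sizes[[chr]] / bin_size))
    sel <- fr$chrom == chr
    mid <- (fr$start[sel] + fr$end[sel]) %/% 2L
    mid <- pmin(pmax(mid, 0L), chrom_sizes[[chr]] - 1L)
    tabulate(mid %/% bin_size + 1L, nbins = n_bins)
  })
  names(counts) <- names(chrom_sizes)
  structure(list(sample_id = frags$sample_id, bin_size = bin_size,
                 counts = counts),
            class = "binned_coverage")
}

#' @export
print.binned_coverage <- function(x, ...) {
  cat("<binned_coverage> sample:", x$sample_id, "bin:", x$bin_size,
      "bp, bins:", sum(lengths(x$counts)), "\n")
  invisible(x)
}

#' Background statistics of a binned-count distribution
#'
#' Pools all bins genome-wide and computes: `mu`, the mode of the integer
#' count distribution (smallest value on ties); `x`, the unscaled median
#' absolute deviation of the bins whose count is below the mean of all
#' bins; and the normalization `divisor`, the mean count of the background
#' bins (those with counts in `[mu - x, mu + x]`).  Dividing bin counts by
#' this divisor expresses them as fold-over-background.
#'
#' @param cov A [bin_counts()] result.
#' @param divisor_mode `"mean"` (default; mean count of background bins) or
#'   `"total"` (their summed count; a literal total-reads divisor that
#'   yields values far below 1 and needs a user-chosen threshold).
#' @param min_bins Below this many bins a warning is issued (the mode and
#'   MAD are unstable on tiny inputs); computation still proceeds so that
#'   hand-enumerable examples can be checked.
#' @return Object of class `background_stats`: list with `mu`, `x`,
#'   `divisor`, `n_background_bins`, `divisor_mode`.
#' @export
background_stats <- function(cov, divisor_mode = c("mean", "total"),
                             min_bins = 100L) {
  divisor_mode <- match.arg(divisor_mode)
  counts <- unlist(cov$counts, use.names = FALSE)
  if (length(counts) < min_bins)
    warning("only ", length(counts), " bins; background statistics are ",
            "unstable below ", min_bins, " bins")
  if (length(unique(counts)) == 1L)
    stop("all bins have identical counts; cannot estimate background")
  tab <- table(counts)
  modes <- as.integer(names(tab)[tab == max(tab)])
  mu <- min(modes)
  below <- counts[counts < mean(counts)]
  if (!length(below))
    stop("no bins below the mean count; cannot compute MAD")
  x <- stats::median(abs(below - stats::median(below)))
  bg <- counts[counts >= mu - x & counts <= mu + x]
  if (!length(bg))
    stop("no background bins in [mu - x, mu + x]; need more data")
  divisor <- if (divisor_mode == "mean") mean(bg) else sum(bg)
  if (divisor <= 0)
    stop("background divisor is zero; need more data")
  structure(list(mu = mu, x = x, divisor = divisor,
                 n_background_bins = length(bg),
                 divisor_mode = divisor_mode),
            class = "background_stats")
}

#' @export
print.background_stats <- function(x, ...) {
  cat(sprintf(
    "<background_stats> mu=%d x=%g divisor=%g (%s of %d background bins)\n",
    x$mu, x$x, x$divisor, x$divisor_mode, x$n_background_bins))
  invisible(x)
}

#' Normalize binned counts by the background divisor
#'
#' @param cov A [bin_counts()] result.
#' @param bg A [background_stats()] result for the same sample.
#' @return Named list of per-chromosome numeric vectors
#'   (fold-over-background); background bins average about 1.
#' @export
normalize_bins <- function(cov, bg) {
  stopifnot(inherits(cov, "binned_coverage"),
            inherits(bg, "background_stats"))
  lapply(cov$counts, function(v) v / bg$divisor)
}

#' Candidate binding regions from a normalized bin vector
#'
#' Maximal runs of bins whose normalized value is strictly above the
#' threshold, reported as genomic intervals.
#'
#' @param normalized Named list of per-chromosome normalized vectors (from
#'   [normalize_bins()]).
#' @param chrom_sizes Named integer vector (to truncate the last bin).
#' @param bin_size Bin width used to produce `normalized`.
#' @param threshold Strict lower cutoff (default 2; a bin at exactly the
#'   threshold is excluded).
#' @return data.frame with columns `chrom`, `start`, `end`, `signal` (max
#'   normalized value in the run).
#' @export
call_regions <- function(normalized, chrom_sizes, bin_size = 100L,
                         threshold = 2) {
  stopifnot(threshold > 0)
  out <- lapply(names(normalized), function(chr) {
    v <- normalized[[chr]]
    above <- v > threshold
    if (!any(above))
      return(NULL)
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    sel <- r$values
    first <- starts[sel]; last <- ends[sel]
    data.frame(
      chrom = chr,
      start = (first - 1L) * as.integer(bin_size),
      end = pmin(last * as.integer(bin_size), chrom_sizes[[chr]]),
      signal = vapply(seq_along(first),
                      function(i) max(v[first[i]:last[i]]), 0))
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), signal = numeric())
  out
}

#' Merge nearby intervals
#'
#' Any two intervals separated by a gap strictly smaller than `merge_gap`
#' (next start minus previous end) are merged, transitively; overlapping
#' intervals always merge.  Idempotent and order-invariant.
#'
#' @param intervals data.frame with `chrom`, `start`, `end` and optionally
#'   `signal` (max is kept over merged members).
#' @param merge_gap Strict gap threshold in bp (default 200; a gap of
#'   exactly `merge_gap` is not merged).
#' @return data.frame of merged intervals sorted by (chrom, start).
#' @export
merge_regions <- function(intervals, merge_gap = 200L) {
  if (!nrow(intervals)) return(intervals)
  has_signal <- "signal" %in% names(intervals)
  o <- order(intervals$chrom, intervals$start, intervals$end)
  iv <- intervals[o, , drop = FALSE]
  out <- vector("list", nrow(iv))
  n_out <- 0L
  cur <- iv[1, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1]) {
    row <- iv[i, , drop = FALSE]
    if (row$chrom == cur$chrom && row$start - cur$end < merge_gap) {
      cur$end <- max(cur$end, row$end)
      if (has_signal) cur$signal <- max(cur$signal, row$signal)
    } else {
      n_out <- n_out + 1L
      out[[n_out]] <- cur
      cur <- row
    }
  }
  out[[n_out + 1L]] <- cur
  res <- do.call(rbind, out[seq_len(n_out + 1L)])
  rownames(res) <- NULL
  res
}

#' Call peaks for one sample
#'
#' Convenience wrapper: binning, background statistics, normalization,
#' strict thresholding and gap merging for a single IP sample.
#'
#' @inheritParams bin_counts
#' @inheritParams call_regions
#' @inheritParams merge_regions
#' @param source Label recorded in the output (`repA`, `repB`, ...).
#' @param divisor_mode Passed to [background_stats()].
#' @param min_bins Passed to [background_stats()].
#' @return A [peak_set()]; attribute `background` holds the
#'   [background_stats()].
#' @export
call_peaks <- function(frags, chrom_sizes, bin_size = 100L, threshold = 2,
                       merge_gap = 200L, source = frags$sample_id,
                       divisor_mode = "mean", min_bins = 100L) {
  cov <- bin_counts(frags, chrom_sizes, bin_size)
  bg <- background_stats(cov, divisor_mode = divisor_mode,
                         min_bins = min_bins)
  norm <- normalize_bins(cov, bg)
  regions <- call_regions(norm, chrom_sizes, bin_size, threshold)
  merged <- merge_regions(regions, merge_gap)
  merged$source <- rep(source, nrow(merged))
  ps <- peak_set(merged,
                 parameters = list(bin_size = bin_size,
                                   threshold = threshold,
                                   merge_gap = merge_gap))
  attr(ps, "background") <- bg
  ps
}

#' Consensus peaks across two replicates
#'
#' A peak is retained only when it is supported by both replicates: every
#' pair of replicate peaks overlapping by at least `min_overlap` bp emits
#' the union of the two intervals, chained unions are merged, and the
#' consensus signal is the maximum over the contributing replicate peaks.
#'
#' @param repA,repB [peak_set()]s from the two replicates.
#' @param min_overlap Inclusive minimum overlap in bp (default 50; an
#'   overlap of exactly 50 bp qualifies).
#' @return A [peak_set()] with `source = "consensus"`; column
#'   `contributors` records the replicate peak IDs.
#' @export
consensus_peaks <- function(repA, repB, min_overlap = 50L) {
  stopifnot(inherits(repA, "peak_set"), inherits(repB, "peak_set"))
  params <- list(min_overlap = min_overlap,
                 repA = attr(repA, "parameters"),
                 repB = attr(repB, "parameters"))
  if (!nrow(repA) || !nrow(repB))
    return(peak_set(parameters = params))
  pieces <- lapply(intersect(unique(repA$chrom), unique(repB$chrom)),
                   function(chr) {
    a <- repA[repA$chrom == chr, , drop = FALSE]
    b <- repB[repB$chrom == chr, , drop = FALSE]
    ia <- IRanges::IRanges(a$start + 1L, a$end)
    ib <- IRanges::IRanges(b$start + 1L, b$end)
    ov <- IRanges::findOverlaps(ia, ib, minoverlap = as.integer(min_overlap))
    if (!length(ov)) return(NULL)
    qa <- S4Vectors::queryHits(ov); qb <- S4Vectors::subjectHits(ov)
    data.frame(chrom = chr,
               start = pmin(a$start[qa], b$start[qb]),
               end = pmax(a$end[qa], b$end[qb]),
               signal = pmax(a$signal[qa], b$signal[qb]),
               contributors = paste0(a$peak_id[qa], "|", b$peak_id[qb]))
  })
  unions <- do.call(rbind, pieces)
  if (is.null(unions)) return(peak_set(parameters = params))
  # chain overlapping/adjacent unions into single consensus peaks,
  # carrying provenance along
  o <- order(unions$chrom, unions$start, unions$end)
  unions <- unions[o, , drop = FALSE]
  merged <- list(); cur <- unions[1, , drop = FALSE]
  for (i in seq_len(nrow(unions))[-1]) {
    row <- unions[i, , drop = FALSE]
    if (row$chrom == cur$chrom && row$start <= cur$end) {
      cur$end <- max(cur$end, row$end)
      cur$signal <- max(cur$signal, row$signal)
      cur$contributors <- paste(cur$contributors, row$contributors,
                                sep = ",")
    } else {
      merged[[length(merged) + 1L]] <- cur
      cur <- row
    }
  }
  merged[[length(merged) + 1L]] <- cur
  res <- do.call(rbind, merged)
  res$source <- "consensus"
  res$peak_id <- sprintf("consensus_%d", seq_len(nrow(res)))
  contributors <- res$contributors
  res$contributors <- NULL
  ps <- peak_set(res, parameters = params)  # res is already sorted
  ps$contributors <- contributors
  ps
}

#' Pearson correlation of normalized bin counts between replicates
#'
#' Standard replicate QC: correlates fold-over-background bin values of
#' two samples over all bins, or over a seeded random subsample of bins.
#'
#' @param covA,covB [bin_counts()] results with identical binning.
#' @param subsample_n Number of bins to subsample (`NULL` = all bins).
#' @param seed Seed for the subsample draw.
#' @return Pearson correlation coefficient.
#' @export
replicate_correlation <- function(covA, covB, subsample_n = NULL,
                                  seed = 1L) {
  stopifnot(covA$bin_size == covB$bin_size,
            identical(lengths(covA$counts), lengths(covB$counts)))
  a <- unlist(normalize_bins(covA, background_stats(covA)),
              use.names = FALSE)
  b <- unlist(normalize_bins(covB, background_stats(covB)),
              use.names = FALSE)
  if (!is.null(subsample_n) && subsample_n < length(a)) {
    idx <- with_seed(seed, sample.int(length(a), subsample_n))
    a <- a[idx]; b <- b[idx]
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero variance in normalized counts; correlation undefined")
  stats::cor(a, b)
}
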