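# The bin-based caller: binning convention, the mode/MAD background
# statistics on hand-enumerable vectors, strict thresholds, merging and
# replicate consensus.

cov_from_counts <- function(counts, bin_size = 100L) {
  structure(list(sample_id = "s", bin_size = bin_size,
                 counts = list(chrI = counts)),
            class = "binned_coverage")
}

test_that("fragments are binned by midpoint with half-open bins", {
  fs <- frags_from_midpoints(c(10L, 150L, 250L))
  cov <- bin_counts(fs, c(chrI = 300L), bin_size = 100L)
  expect_equal(cov$counts$chrI, c(1L, 1L, 1L))

  # midpoint exactly 100 falls in the second bin
  fs2 <- frags_from_midpoints(100L)
  expect_equal(bin_counts(fs2, c(chrI = 300L))$counts$chrI,
               c(0L, 1L, 0L))

  # conservation: every fragment lands in exactly one bin
  set.seed(42)
  fs3 <- frags_from_midpoints(sample.int(995L, 10L))
  expect_equal(sum(bin_counts(fs3, c(chrI = 1000L))$counts$chrI), 10L)
  # truncated terminal bin exists
  expect_length(bin_counts(fs3, c(chrI = 950L))$counts$chrI, 10L)
})

test_that("background statistics match hand-enumerated examples", {
  # counts [0,0,1,1,1,2,5]: mean ~1.43, S = {0,0,1,1,1}, median(S) = 1,
  # x = median(|S-1|) = 0; mode mu = 1; background bins {1,1,1}
  bg <- suppressWarnings(background_stats(
    cov_from_counts(c(0L, 0L, 1L, 1L, 1L, 2L, 5L))))
  expect_equal(bg$mu, 1L)
  expect_equal(bg$x, 0)
  expect_equal(bg$divisor, 1)
  expect_equal(bg$n_background_bins, 3L)

  bg2 <- suppressWarnings(background_stats(
    cov_from_counts(c(2L, 2L, 2L, 2L, 9L))))
  expect_equal(bg2$mu, 2L)
  expect_equal(bg2$divisor, 2)

  # tie on the mode -> smallest value wins
  bg3 <- suppressWarnings(background_stats(
    cov_from_counts(c(1L, 1L, 4L, 4L, 9L))))
  expect_equal(bg3$mu, 1L)
  expect_equal(bg3$divisor, 1)

  # an all-zero background (divisor 0) is an error, not a division
  expect_error(suppressWarnings(background_stats(
    cov_from_counts(c(0L, 0L, 3L, 3L, 7L)))), "zero")
})

test_that("background statistics reject degenerate inputs", {
  expect_error(suppressWarnings(background_stats(
    cov_from_counts(rep(5L, 200L)))), "identical")
  expect_warning(background_stats(cov_from_counts(c(1L, 1L, 2L, 3L))),
                 "unstable")
})

test_that("divisor approximates the true background mean on null data", {
  set.seed(7)
  mids <- sample.int(100000L, 20000L) - 1L
  cov <- bin_counts(frags_from_midpoints(mids), c(chrI = 100000L))
  bg <- background_stats(cov)
  expect_lt(abs(bg$divisor - 20) / 20, 0.05)  # 20 frags/bin on average
  norm <- normalize_bins(cov, bg)
  in_bg <- cov$counts$chrI >= bg$mu - bg$x & cov$counts$chrI <= bg$mu + bg$x
  expect_gt(mean(norm$chrI[in_bg]), 0.9)
  expect_lt(mean(norm$chrI[in_bg]), 1.1)
})

test_that("normalization divides counts by the divisor", {
  bg <- suppressWarnings(background_stats(
    cov_from_counts(c(2L, 2L, 2L, 2L, 9L))))
  norm <- normalize_bins(cov_from_counts(c(6L, 0L, 2L)), bg)
  expect_equal(norm$chrI, c(3, 0, 1))
})

test_that("region calling uses a strict threshold and run boundaries", {
  norm <- list(chrI = c(0.5, 2.5, 2.1, 0.1))
  r <- call_regions(norm, c(chrI = 400L), bin_size = 100L, threshold = 2)
  expect_equal(r$start, 100L)
  expect_equal(r$end, 300L)
  expect_equal(r$signal, 2.5)

  # a bin at exactly the threshold is excluded ("above 2" is strict)
  expect_equal(nrow(call_regions(list(chrI = c(2, 2, 2)),
                                 c(chrI = 300L), 100L, 2)), 0L)
  expect_equal(nrow(call_regions(list(chrI = c(0.1, 1)),
                                 c(chrI = 200L), 100L, 2)), 0L)
  # terminal run is truncated at the chromosome end
  r2 <- call_regions(list(chrI = c(0, 3, 3)), c(chrI = 250L), 100L, 2)
  expect_equal(r2$end, 250L)
})

test_that("merging is strict on the gap, transitive and idempotent", {
  iv <- data.frame(chrom = "chrI", start = c(1000L, 1250L),
                   end = c(1100L, 1350L))
  m <- merge_regions(iv, 200L)   # gap 150 < 200 -> merged
  expect_equal(nrow(m), 1L)
  expect_equal(m$start, 1000L)
  expect_equal(m$end, 1350L)

  iv2 <- data.frame(chrom = "chrI", start = c(1000L, 1300L),
                    end = c(1100L, 1400L))
  expect_equal(nrow(merge_regions(iv2, 200L)), 2L)  # gap exactly 200

  # property: idempotent, order-invariant, equal to transitive closure
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(2:12, 1)
    start <- sample.int(5000L, n)
    iv <- data.frame(chrom = "chrI", start = start,
                     end = start + sample.int(400L, n))
    gap <- sample(c(1L, 50L, 200L), 1)
    m1 <- merge_regions(iv, gap)
    expect_equal(merge_regions(m1, gap), m1)
    shuf <- iv[sample.int(n), ]
    expect_equal(merge_regions(shuf, gap), m1)
    ref <- ref_merge(cbind(iv$start, iv$end), gap)
    expect_equal(cbind(m1$start, m1$end), unname(ref))
  }
})

test_that("consensus requires the inclusive 50 bp replicate overlap", {
  mk <- function(start, end, src)
    peak_set(data.frame(chrom = "chrI", start = start, end = end,
                        signal = seq_along(start), source = src))
  # overlap 40 < 50 -> rejected
  expect_equal(nrow(consensus_peaks(mk(100L, 300L, "repA"),
                                    mk(260L, 400L, "repB"))), 0L)
  # overlap exactly 50 -> consensus spans the union
  cons <- consensus_peaks(mk(100L, 300L, "repA"), mk(250L, 400L, "repB"))
  expect_equal(nrow(cons), 1L)
  expect_equal(cons$start, 100L)
  expect_equal(cons$end, 400L)
  expect_equal(cons$source, "consensus")
  # empty replicate -> empty consensus
  expect_equal(nrow(consensus_peaks(peak_set(), mk(1L, 200L, "b"))), 0L)
})

test_that("chained consensus unions merge and keep the max signal", {
  a <- peak_set(data.frame(chrom = "chrI",
                           start = c(100L, 420L), end = c(400L, 700L),
                           signal = c(5, 3), source = "repA"))
  b <- peak_set(data.frame(chrom = "chrI", start = 300L, end = 500L,
                           signal = 9, source = "repB"))
  cons <- consensus_peaks(a, b)
  expect_equal(nrow(cons), 1L)
  expect_equal(cons$start, 100L)
  expect_equal(cons$end, 700L)
  expect_equal(cons$signal, 9)
  expect_match(cons$contributors, "peak_1\\|")
})

test_that("replicate correlation is 1 for identical coverage and low on
           independent null data", {
  set.seed(3)
  mids <- sample.int(100000L, 20000L)
  covA <- bin_counts(frags_from_midpoints(mids), c(chrI = 100000L))
  expect_equal(replicate_correlation(covA, covA), 1)
  covB <- bin_counts(frags_from_midpoints(sample.int(100000L, 20000L)),
                     c(chrI = 100000L))
  expect_lt(abs(replicate_correlation(covA, covB)), 0.08)
})

test_that("single-sample caller output is sorted, non-overlapping and
           annotated with background stats", {
  set.seed(5)
  mids <- c(sample.int(100000L, 20000L),
            sample(4000:4300, 3000, replace = TRUE))
  ps <- call_peaks(frags_from_midpoints(mids), c(chrI = 100000L))
  expect_s3_class(ps, "peak_set")
  expect_gte(nrow(ps), 1L)
  expect_true(all(diff(ps$start) > 0))
  expect_true(all(ps$start < ps$end))
  if (nrow(ps) > 1)
    expect_true(all(ps$start[-1] >= ps$end[-nrow(ps)]))
  expect_s3_class(attr(ps, "background"), "background_stats")
  # the planted hotspot is found
  expect_true(any(ps$start <= 4300 & ps$end >= 4000))
})
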