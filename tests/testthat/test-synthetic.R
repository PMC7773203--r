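# The generator: determinism, distributional contracts, planted-truth
# invariants, and small statistical checks of each simulator.

test_that("genomes are deterministic with the stated composition", {
  g1 <- make_genome(1, 100000L, gc = 0.38, seed = 7)
  g2 <- make_genome(1, 100000L, gc = 0.38, seed = 7)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  # GC at 0.5 within 3 sd of binomial(1e5, 0.5)
  g3 <- make_genome(1, 100000L, gc = 0.5, seed = 8)
  gc_obs <- sum(Biostrings::alphabetFrequency(
    g3$genome[[1]])[c("C", "G")])
  expect_lt(abs(gc_obs - 50000), 3 * sqrt(100000 * 0.25))
  # two chromosomes
  g4 <- make_genome(2, 10000L, 0.4, seed = 1)
  expect_equal(length(g4$chrom_sizes), 2L)
  expect_equal(sum(g4$chrom_sizes), 20000L)
  expect_error(make_genome(1, 1e5, gc = 1.2), "between 0 and 1")
})

test_that("gene placement is non-overlapping, stranded and seeded", {
  cs <- c(chrI = 100000L)
  ann <- make_genes(cs, n_genes = 50L, seed = 3)
  g <- ann$genes
  expect_equal(nrow(g), 50L)
  # ORFs (indeed whole transcripts) do not overlap
  o <- order(g$start)
  expect_true(all(g$start[o][-1] >= g$end[o][-50]))
  # 5' UTR length within the requested range
  u5 <- ifelse(g$strand == "+", g$start - g$tss, g$tss - g$end + 1L)
  expect_true(all(u5 >= 50 & u5 <= 200))
  expect_identical(make_genes(cs, n_genes = 50L, seed = 3)$genes, g)
  expect_error(make_genes(c(chrI = 20000L), n_genes = 50L, seed = 1),
               "too small")
})

test_that("planted motifs sit in promoters and are found by the scanner", {
  gen <- make_genome(1, 100000L, seed = 11)
  ann <- make_genes(gen$chrom_sizes, n_genes = 30L, seed = 12)
  targets <- ann$genes$gene_id[c(3, 10, 20)]
  pl <- suppressWarnings(  # crowded toy genome: some candidates skip
    plant_motifs_and_peaks(gen$genome, ann, targets, seed = 13))
  expect_setequal(pl$truth$planted_genes,
                  setdiff(targets, pl$truth$skipped_genes))
  mp <- pl$truth$motif_positions
  for (i in seq_len(nrow(mp))) {
    gi <- ann$genes[ann$genes$gene_id == mp$gene_id[i], ]
    # within the promoter window in transcript orientation
    off <- if (gi$strand == "+") mp$pos[i] - gi$tss
           else gi$tss - (mp$pos[i] + 6L)
    expect_gte(off, -1000L)
    expect_lte(off, 100L)
    # the written instance is a concrete TGANTCA variant, found by the
    # scanner at exactly that position
    seq <- as.character(Biostrings::subseq(
      pl$genome[[mp$chrom[i]]], mp$pos[i] + 1L, mp$pos[i] + 7L))
    hits <- scan_motif(seq, "TGANTCA")
    expect_gte(nrow(hits), 1L)
    expect_true(0L %in% hits$pos)
  }
  # peaks lie within 750 bp of their own ORF and of no other ORF
  pk <- pl$truth$planted_peaks
  for (i in seq_len(nrow(pk))) {
    near <- ann$genes$start < pk$end[i] + 750L &
      ann$genes$end > pk$start[i] - 750L
    expect_equal(ann$genes$gene_id[near], pk$gene_id[i])
  }
})

test_that("ChIP simulation follows the midpoint-rate model", {
  cs <- c(chrI = 100000L)
  peaks <- data.frame(chrom = "chrI", start = 40000L, end = 40300L,
                      enrichment = 8)
  chip <- simulate_chip(cs, peaks, depth = 200000L, n_rep = 2L,
                        seed = 17)
  expect_length(chip$ip, 2L)
  expect_equal(chip$mock$sample_id, "mock")
  expect_equal(chip$ip[[1]]$total_count, 200000L)
  # expected fragments in the peak: depth * 8*300 / (99700 + 8*300)
  n_in <- function(fs) {
    mid <- (fs$fragments$start + fs$fragments$end) %/% 2L
    sum(mid >= 40000 & mid < 40300)
  }
  expected <- 200000 * (8 * 300) / (99700 + 8 * 300)
  for (k in 1:2)
    expect_lt(abs(n_in(chip$ip[[k]]) - expected), 3 * sqrt(expected))
  # mock is pure background
  exp_mock <- 200000 * 300 / 100000
  expect_lt(abs(n_in(chip$mock) - exp_mock), 4 * sqrt(exp_mock))
  # replicates differ but are seeded deterministically
  expect_false(identical(chip$ip[[1]]$fragments, chip$ip[[2]]$fragments))
  chip2 <- simulate_chip(cs, peaks, depth = 200000L, n_rep = 2L,
                         seed = 17)
  expect_identical(chip$ip[[1]]$fragments, chip2$ip[[1]]$fragments)
  expect_error(simulate_chip(cs, peaks, depth = 5000L), "too low")
})

test_that("DE counts carry the planted effects in the right direction", {
  ids <- sprintf("g%03d", 1:300)
  m <- simulate_de_counts(ids, activated = ids[1:20],
                          repressed = ids[21:40], n_cond_reps = 10L,
                          nb_dispersion = 0.01, effect_log2fc = 2,
                          seed = 19)
  expect_equal(dim(m), c(300L, 20L))
  wt <- rowMeans(m[, 1:10]); del <- rowMeans(m[, 11:20])
  lfc <- log2((del + 0.5) / (wt + 0.5))
  # planted activated genes drop ~4-fold in the deletion
  expect_lt(abs(mean(lfc[1:20]) + 2), 0.35)
  expect_lt(abs(mean(lfc[21:40]) - 2), 0.35)
  expect_lt(abs(mean(lfc[41:300])), 0.15)
  expect_identical(m, simulate_de_counts(
    ids, activated = ids[1:20], repressed = ids[21:40],
    n_cond_reps = 10L, nb_dispersion = 0.01, effect_log2fc = 2,
    seed = 19))
  expect_error(simulate_de_counts(ids, nb_dispersion = 0), "> 0")
})

test_that("simulated proteins hit their target composition and bins", {
  ids <- sprintf("g%03d", 1:200)
  pr <- simulate_proteome(ids, bin_fractions = c(0.25, 0.5, 0.25),
                          translation_gene_set = ids[1:20], seed = 23)
  bins <- bin_proteome(pr$proteome, mode = "fixed")
  # realized fixed-mode bins equal the component truth for every protein
  expect_equal(stats::setNames(bins$bin, bins$gene_id),
               pr$rk_bins_truth)
  # translation genes live almost entirely in bin3
  expect_gte(mean(pr$rk_bins_truth[ids[1:20]] == "bin3"), 0.7)
  # mixture fractions within 3 pp over the non-translation genes
  shares <- table(pr$rk_bins_truth[ids[21:200]]) / 180
  expect_lt(abs(shares[["bin1"]] - 0.25), 0.1)
  # bin_fractions = (1,0,0) -> everything is bin1
  pr2 <- simulate_proteome(ids[1:50], bin_fractions = c(1, 0, 0),
                           seed = 29)
  expect_true(all(bin_proteome(pr2$proteome)$bin == "bin1"))
})

test_that("experiment truth classes are disjoint and cover all genes", {
  sim <- simulate_experiment(default_config(seed = 2))
  t <- sim$truth
  sets <- list(t$direct_activated, t$direct_repressed,
               t$indirect_activated, t$indirect_repressed, t$null_genes)
  all_ids <- unlist(sets)
  expect_equal(sort(all_ids), sort(sim$annotation$genes$gene_id))
  expect_equal(anyDuplicated(all_ids), 0L)
  # every direct gene has a planted peak within 750 bp of its ORF,
  # and no indirect/null gene does
  tg <- assign_targets(t$planted_peaks, sim$annotation, 750L)
  expect_setequal(tg$target_genes,
                  c(t$direct_activated, t$direct_repressed))
  # truth manifest round-trips through JSON
  f <- tempfile(fileext = ".json")
  write_truth(t, f)
  back <- read_truth(f)
  expect_equal(back$direct_activated, t$direct_activated)
  expect_equal(back$rk_bins_truth, t$rk_bins_truth)
  expect_equal(back$planted_peaks$start, t$planted_peaks$start)
})
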