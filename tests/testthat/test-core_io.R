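# Format readers/writers and the coordinate conventions at the package
# boundary (BED native 0-based half-open, GFF3 converted, SAM filtered).

test_that("BED fragment reading parses intervals verbatim", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chrI\t100\t250", "chrI\t0\t150"), bed)
  fs <- read_fragments(bed, format = "bed")
  expect_s3_class(fs, "fragment_set")
  expect_equal(fs$total_count, 2L)
  expect_equal(fs$fragments$start, c(100L, 0L))
  expect_equal(fs$fragments$end, c(250L, 150L))
  expect_equal(fs$fragments$end[1] - fs$fragments$start[1], 150L)
})

test_that("empty and malformed BED inputs are handled", {
  bed <- tempfile(fileext = ".bed")
  writeLines(character(), bed)
  expect_equal(read_fragments(bed, format = "bed")$total_count, 0L)

  writeLines(c("chrI\t100\t250", "chrI\t500"), bed)
  expect_error(read_fragments(bed, format = "bed"), "line 2")
  writeLines(c("chrI\t300\t200"), bed)
  expect_error(read_fragments(bed, format = "bed"), "line 1")
})

test_that("fragments on unknown chromosomes are rejected", {
  bed <- tempfile(fileext = ".bed")
  writeLines("chrVII\t10\t60", bed)
  expect_error(
    read_fragments(bed, format = "bed", chrom_sizes = c(chrI = 1000L)),
    "unknown chromosome")
})

test_that("SAM reading keeps MAPQ >= cutoff and drops the rest", {
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chrI\tLN:10000",
    sprintf("r%d\t0\tchrI\t%d\t%d\t50M\t*\t0\t0\t%s\t*",
            1:3, c(101L, 201L, 301L), c(10L, 20L, 60L),
            strrep("A", 50)),
    # unmapped record: must be dropped regardless of MAPQ
    paste0("r4\t4\t*\t0\t0\t*\t*\t0\t0\t", strrep("A", 50), "\t*")),
    sam)
  fs <- read_fragments(sam, format = "sam", min_mapq = 20)
  expect_equal(fs$total_count, 2L)  # MAPQ 20 kept (boundary), 10 dropped
  expect_equal(fs$fragments$start, c(200L, 300L))  # 1-based -> 0-based
  expect_equal(fs$fragments$end, c(250L, 350L))
})

test_that("properly paired SAM records contribute one template span", {
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chrI\tLN:10000",
    # proper pair: leftmost mate at 101, TLEN 300 -> fragment (100, 400)
    paste0("p1\t99\tchrI\t101\t60\t50M\t=\t351\t300\t",
           strrep("A", 50), "\t*"),
    paste0("p1\t147\tchrI\t351\t60\t50M\t=\t101\t-300\t",
           strrep("A", 50), "\t*")),
    sam)
  fs <- read_fragments(sam, format = "sam")
  expect_equal(fs$total_count, 1L)
  expect_equal(fs$fragments$start, 100L)
  expect_equal(fs$fragments$end, 400L)
})

test_that("GFF3 coordinates convert to 0-based half-open and back", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chrI\tx\tgene\t101\t200\t.\t+\t.\tID=g1",
               "chrI\tx\tgene\t501\t800\t.\t-\t.\tID=g2"), gff)
  ann <- read_annotation(gff, c(chrI = 10000L))
  expect_equal(ann$genes$start, c(100L, 500L))
  expect_equal(ann$genes$end, c(200L, 800L))
  # conversion is an involution: written GFF3 reproduces the input rows
  out <- tempfile(fileext = ".gff3")
  write_gff3(ann, out)
  reread <- read_annotation(out, c(chrI = 10000L))
  expect_equal(reread$genes[, c("gene_id", "chrom", "start", "end",
                                "strand")],
               ann$genes[, c("gene_id", "chrom", "start", "end",
                             "strand")])
})

test_that("TSS table overrides flagged ORF-boundary defaults", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chrI\tx\tgene\t501\t800\t.\t-\t.\tID=g2",
               "chrI\tx\tgene\t1001\t1300\t.\t+\t.\tID=g3"), gff)
  ann <- read_annotation(gff, c(chrI = 10000L))
  expect_true(all(ann$genes$tss_default))
  # minus-strand default TSS is the 3'-most ORF base
  expect_equal(ann$genes$tss[ann$genes$gene_id == "g2"], 799L)

  tss <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ttss\ttts", "g2\t851\t451"), tss)
  ann2 <- read_annotation(gff, c(chrI = 10000L), tss_path = tss)
  g2 <- ann2$genes[ann2$genes$gene_id == "g2", ]
  expect_equal(g2$tss, 850L)   # 1-based 851 -> 0-based 850
  expect_equal(g2$tts, 450L)
  expect_false(g2$tss_default)
  expect_true(ann2$genes$tss_default[ann2$genes$gene_id == "g3"])
})

test_that("annotation validation rejects inconsistent gene records", {
  cs <- c(chrI = 1000L)
  g <- data.frame(gene_id = c("a", "a"), chrom = "chrI", start = 0L,
                  end = 10L, strand = "+")
  expect_error(genome_annotation(cs, g), "duplicate gene ID")
  g <- data.frame(gene_id = "a", chrom = "chrI", start = 0L, end = 10L,
                  strand = "*")
  expect_error(genome_annotation(cs, g), "strand")
  g <- data.frame(gene_id = "a", chrom = "chrI", start = 0L,
                  end = 2000L, strand = "+")
  expect_error(genome_annotation(cs, g), "bounds")
})

test_that("peak BED6+3 output round-trips losslessly", {
  ps <- peak_set(data.frame(
    chrom = c("chrI", "chrI"), start = c(1000L, 5000L),
    end = c(1400L, 5300L), peak_id = c("p1", "p2"),
    signal = c(3.2, 7.25), source = ".",
    feature_class = c("promoter", "intergenic"),
    target_genes = c("gA,gB", "."), motif_count = c(2L, 0L)))
  f <- tempfile(fileext = ".bed")
  write_peaks(ps, f)
  line1 <- readLines(f)[1]
  expect_match(line1, "^chrI\t1000\t1400\t")
  back <- read_peaks(f)
  expect_equal(as.data.frame(back), as.data.frame(ps))
  # write -> read -> write is byte-identical
  f2 <- tempfile(fileext = ".bed")
  write_peaks(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("empty peak sets round-trip to empty files", {
  f <- tempfile(fileext = ".bed")
  write_peaks(peak_set(), f)
  expect_equal(nrow(read_peaks(f)), 0L)
})

test_that("fragment BED round-trips through write_fragments", {
  fs <- frags_from_midpoints(c(150L, 800L, 2500L))
  f <- tempfile(fileext = ".bed")
  write_fragments(fs, f)
  back <- read_fragments(f, format = "bed", sample_id = "s")
  expect_equal(back$fragments, fs$fragments)
  expect_equal(back$total_count, fs$total_count)
})
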