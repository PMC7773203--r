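# Readers/writers for the standard formats the pipeline touches, and the
# canonical in-memory genome model.  All internal coordinates are 0-based
# half-open; GFF3 (1-based closed) is converted at the boundary, BED is
# native.  TSS/TTS are stored as 0-based positions of single bases.

#' Read a chrom.sizes table
#'
#' @param path Tab-delimited file with two columns: chromosome name, length
#'   in bp.  No header.
#' @return Named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "integer"))
  if (anyDuplicated(df$chrom))
    stop("duplicate chromosome name in ", path)
  if (any(df$length <= 0)) stop("non-positive chromosome length in ", path)
  stats::setNames(df$length, df$chrom)
}

#' Write a chrom.sizes table
#' @param chrom_sizes Named integer vector.
#' @param path Output path.
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  utils::write.table(data.frame(names(chrom_sizes), unname(chrom_sizes)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## ---------------------------------------------------------------- fragments

#' Construct a fragment set
#'
#' A fragment set holds aligned ChIP fragments as 0-based half-open
#' intervals, together with the sample they came from.
#'
#' @param fragments data.frame with columns `chrom`, `start`, `end`.
#' @param sample_id Sample label.
#' @param chrom_sizes Optional named vector; when given, every fragment must
#'   lie on a known chromosome.
#' @return Object of class `fragment_set`: list with `sample_id`,
#'   `fragments` and `total_count`.
#' @export
fragment_set <- function(fragments, sample_id = "sample",
                         chrom_sizes = NULL) {
  stopifnot(is.data.frame(fragments),
            all(c("chrom", "start", "end") %in% names(fragments)))
  fragments <- fragments[, c("chrom", "start", "end")]
  fragments$chrom <- as.character(fragments$chrom)
  if (nrow(fragments) && any(fragments$start >= fragments$end))
    stop("fragment with start >= end")
  if (!is.null(chrom_sizes)) {
    bad <- setdiff(unique(fragments$chrom), names(chrom_sizes))
    if (length(bad))
      stop("fragment on unknown chromosome: ", paste(bad, collapse = ", "))
  }
  structure(list(sample_id = sample_id,
                 fragments = fragments,
                 total_count = nrow(fragments)),
            class = "fragment_set")
}

#' @export
print.fragment_set <- function(x, ...) {
  cat("<fragment_set> sample:", x$sample_id,
      "fragments:", x$total_count, "\n")
  invisible(x)
}

#' Read aligned fragments from BED or SAM
#'
#' SAM records with mapping quality below `min_mapq` are discarded (the
#' boundary value itself is kept), as are unmapped, secondary and
#' supplementary alignments.  Properly paired records contribute one
#' fragment per template (the template span, taken from the
#' leftmost-of-pair record); all other records contribute their own
#' reference span.  BED input is taken as-is and `min_mapq` is ignored
#' (with a message).
#'
#' @param path Input file.
#' @param format `"bed"` or `"sam"`.
#' @param min_mapq Minimum mapping quality for SAM input (default 20).
#' @param sample_id Sample label (default: file base name).
#' @param chrom_sizes Optional named vector for chromosome validation.
#' @return A [fragment_set()].
#' @export
read_fragments <- function(path, format = c("bed", "sam"), min_mapq = 20L,
                           sample_id = NULL, chrom_sizes = NULL) {
  format <- match.arg(format)
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  if (format == "bed") {
    if (!missing(min_mapq) && !is.null(min_mapq))
      message("BED input: min_mapq is ignored")
    df <- read_bed3(path)
  } else {
    df <- read_sam_fragments(path, min_mapq)
  }
  fragment_set(df, sample_id = sample_id, chrom_sizes = chrom_sizes)
}

# Minimal BED3 reader with per-line validation so malformed records are
# reported by line number (rtracklayer's importer does not).
read_bed3 <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  if (!any(keep))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  idx <- which(keep)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("malformed BED record at line ", idx[which(nf < 3)[1]],
         ": fewer than 3 fields")
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad))
    stop("malformed BED record at line ", idx[bad[1]],
         ": invalid interval")
  data.frame(chrom = chrom, start = start, end = end)
}

# SAM reading goes through Rsamtools (samtools' own parser); fragment model:
# properly-paired leftmost records give the template span, everything else
# its reference span from POS and read width.
read_sam_fragments <- function(path, min_mapq) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam))
  p <- Rsamtools::ScanBamParam(
    what = c("rname", "pos", "mapq", "flag", "qwidth", "isize"))
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  flag <- b$flag
  unmapped <- bitwAnd(flag, 0x4L) != 0L
  secondary <- bitwAnd(flag, 0x100L) != 0L
  supplementary <- bitwAnd(flag, 0x800L) != 0L
  keep <- !unmapped & !secondary & !supplementary &
    !is.na(b$mapq) & b$mapq >= min_mapq
  flag <- flag[keep]
  rname <- as.character(b$rname)[keep]
  pos <- b$pos[keep]
  qwidth <- b$qwidth[keep]
  isize <- b$isize[keep]
  paired_proper <- bitwAnd(flag, 0x1L) != 0L & bitwAnd(flag, 0x2L) != 0L
  # template span once per properly-paired template (leftmost mate only)
  tmpl <- paired_proper & !is.na(isize) & isize > 0L
  single <- !paired_proper
  chrom <- c(rname[tmpl], rname[single])
  start <- c(pos[tmpl] - 1L, pos[single] - 1L)
  end <- c(pos[tmpl] - 1L + isize[tmpl],
           pos[single] - 1L + qwidth[single])
  data.frame(chrom = chrom, start = start, end = end)
}

#' Write a fragment set as BED3
#' @param frags A [fragment_set()].
#' @param path Output path.
#' @export
write_fragments <- function(frags, path) {
  stopifnot(inherits(frags, "fragment_set"))
  utils::write.table(frags$fragments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## --------------------------------------------------------------- annotation

#' Construct a genome annotation
#'
#' The canonical in-memory genome model: chromosome sizes plus one record
#' per gene with ORF span, strand, TSS and TTS.  Coordinates are 0-based
#' half-open for the ORF; `tss`/`tts` are 0-based single-base positions.
#' For a + strand gene `tss <= start` and `tts >= end - 1`; mirrored on -.
#'
#' @param chrom_sizes Named integer vector.
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, and optionally `tss`, `tts`, `tss_default`.  Missing TSS/TTS
#'   default to the ORF boundaries and are flagged in `tss_default`.
#' @return Object of class `genome_annotation`.
#' @export
genome_annotation <- function(chrom_sizes, genes) {
  stopifnot(is.data.frame(genes),
            all(c("gene_id", "chrom", "start", "end", "strand") %in%
                  names(genes)))
  genes$gene_id <- as.character(genes$gene_id)
  genes$chrom <- as.character(genes$chrom)
  genes$strand <- as.character(genes$strand)
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene ID: ",
         genes$gene_id[anyDuplicated(genes$gene_id)])
  if (!all(genes$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  bad <- setdiff(unique(genes$chrom), names(chrom_sizes))
  if (length(bad))
    stop("gene on unknown chromosome: ", paste(bad, collapse = ", "))
  len <- unname(chrom_sizes[genes$chrom])
  if (nrow(genes) &&
      any(genes$start < 0 | genes$start >= genes$end | genes$end > len))
    stop("gene outside its chromosome bounds")
  if (is.null(genes$tss) || is.null(genes$tts)) {
    genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
    genes$tts <- ifelse(genes$strand == "+", genes$end - 1L, genes$start)
    genes$tss_default <- rep(TRUE, nrow(genes))
  }
  if (is.null(genes$tss_default)) genes$tss_default <- FALSE
  plus <- genes$strand == "+"
  ok <- ifelse(plus,
               genes$tss <= genes$start & genes$tts >= genes$end - 1L,
               genes$tss >= genes$end - 1L & genes$tts <= genes$start)
  if (nrow(genes) && !all(ok))
    stop("TSS/TTS not oriented consistently with the ORF for gene(s): ",
         paste(utils::head(genes$gene_id[!ok], 5), collapse = ", "))
  rownames(genes) <- NULL
  structure(list(chrom_sizes = chrom_sizes,
                 genes = genes[, c("gene_id", "chrom", "start", "end",
                                   "strand", "tss", "tts", "tss_default")]),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("<genome_annotation>", length(x$chrom_sizes), "chromosome(s),",
      nrow(x$genes), "gene(s)\n")
  invisible(x)
}

#' Read gene annotation (GFF3 or BED6), optionally with a TSS table
#'
#' GFF3 1-based closed coordinates are converted to internal 0-based
#' half-open.  When a TSS table is supplied, its `tss`/`tts` columns
#' (1-based positions) override the ORF-boundary defaults; genes missing
#' from the table keep the flagged defaults.
#'
#' @param genes_path GFF3 (`.gff`/`.gff3`) or BED6 (`.bed`) gene file.  For
#'   GFF3, records of type `gene` are used (all records when no `gene`
#'   type is present) and the gene ID is taken from `ID` (fallback `Name`).
#' @param chrom_sizes Named vector or path to a chrom.sizes file.
#' @param tss_path Optional TSV with header columns `gene_id`, `tss` and
#'   optionally `tts` (1-based positions, YeasTSS-style).
#' @return A [genome_annotation()].
#' @export
read_annotation <- function(genes_path, chrom_sizes, tss_path = NULL) {
  if (is.character(chrom_sizes) && length(chrom_sizes) == 1L)
    chrom_sizes <- read_chrom_sizes(chrom_sizes)
  if (grepl("\\.bed$", genes_path, ignore.case = TRUE)) {
    df <- utils::read.table(genes_path, sep = "\t", header = FALSE)
    if (ncol(df) < 6) stop("BED6 gene file needs 6 columns")
    genes <- data.frame(gene_id = as.character(df[[4]]),
                        chrom = as.character(df[[1]]),
                        start = as.integer(df[[2]]),
                        end = as.integer(df[[3]]),
                        strand = as.character(df[[6]]))
  } else {
    gr <- rtracklayer::import(genes_path)
    if ("type" %in% names(S4Vectors::mcols(gr)) &&
        any(S4Vectors::mcols(gr)$type == "gene"))
      gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
    id <- S4Vectors::mcols(gr)$ID
    if (is.null(id)) id <- S4Vectors::mcols(gr)$Name
    if (is.null(id) || anyNA(id))
      stop("GFF3 gene records need an ID (or Name) attribute")
    genes <- data.frame(gene_id = as.character(id),
                        chrom = as.character(GenomeInfoDb::seqnames(gr)),
                        start = BiocGenerics::start(gr) - 1L,
                        end = BiocGenerics::end(gr),
                        strand = as.character(BiocGenerics::strand(gr)))
  }
  ann <- genome_annotation(chrom_sizes, genes)
  if (!is.null(tss_path)) ann <- apply_tss_table(ann, tss_path)
  ann
}

apply_tss_table <- function(ann, tss_path) {
  tab <- utils::read.table(tss_path, sep = "\t", header = TRUE)
  if (!all(c("gene_id", "tss") %in% names(tab)))
    stop("TSS table needs header columns gene_id, tss")
  unknown <- setdiff(tab$gene_id, ann$genes$gene_id)
  if (length(unknown))
    warning("TSS table has ", length(unknown),
            " gene ID(s) absent from the annotation; ignored")
  g <- ann$genes
  m <- match(g$gene_id, tab$gene_id)
  hit <- !is.na(m)
  g$tss[hit] <- as.integer(tab$tss[m[hit]]) - 1L
  if ("tts" %in% names(tab) && !all(is.na(tab$tts)))
    g$tts[hit] <- as.integer(tab$tts[m[hit]]) - 1L
  g$tss_default[hit] <- FALSE
  genome_annotation(ann$chrom_sizes, g)
}

#' Write a genome annotation as GFF3
#'
#' Inverse of the GFF3 branch of [read_annotation()]: internal 0-based
#' half-open ORF spans become 1-based closed GFF3 `gene` records.
#'
#' @param ann A [genome_annotation()].
#' @param path Output path.
#' @export
write_gff3 <- function(ann, path) {
  g <- ann$genes
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(g))
    writeLines(sprintf("%s\tgcn4scope\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$chrom, g$start + 1L, g$end, g$strand, g$gene_id),
               con)
  invisible(path)
}

#' Write a TSS table (TSV, 1-based positions)
#' @param ann A [genome_annotation()].
#' @param path Output path.
#' @export
write_tss_table <- function(ann, path) {
  g <- ann$genes
  utils::write.table(
    data.frame(gene_id = g$gene_id, tss = g$tss + 1L, tts = g$tts + 1L),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## -------------------------------------------------------------------- peaks

#' Construct a peak set
#'
#' @param peaks data.frame with columns `chrom`, `start`, `end`, and
#'   optionally `peak_id`, `signal` (max normalized bin value), `source`
#'   (`repA`/`repB`/`consensus`), `feature_class`, `target_genes`
#'   (comma-separated), `motif_count`.
#' @param parameters Named list of calling parameters (threshold,
#'   merge_gap, min_overlap, ...), kept as an attribute.
#' @return Object of class `peak_set` (a data.frame).
#' @export
peak_set <- function(peaks = NULL, parameters = list()) {
  cols <- c("chrom", "start", "end", "peak_id", "signal", "source",
            "feature_class", "target_genes", "motif_count")
  if (is.null(peaks) || nrow(peaks) == 0) {
    peaks <- data.frame(chrom = character(), start = integer(),
                        end = integer(), peak_id = character(),
                        signal = numeric(), source = character(),
                        feature_class = character(),
                        target_genes = character(),
                        motif_count = integer())
  } else {
    if (is.null(peaks$peak_id))
      peaks$peak_id <- sprintf("peak_%d", seq_len(nrow(peaks)))
    if (is.null(peaks$signal)) peaks$signal <- NA_real_
    if (is.null(peaks$source)) peaks$source <- "."
    if (is.null(peaks$feature_class)) peaks$feature_class <- "."
    if (is.null(peaks$target_genes)) peaks$target_genes <- "."
    if (is.null(peaks$motif_count)) peaks$motif_count <- NA_integer_
    peaks <- peaks[order(peaks$chrom, peaks$start), cols]
    if (any(peaks$start >= peaks$end)) stop("peak with start >= end")
  }
  rownames(peaks) <- NULL
  structure(peaks, class = c("peak_set", "data.frame"),
            parameters = parameters)
}

#' Write peaks as BED6+3
#'
#' Columns: chrom, start, end, peak_id, normalized signal, ".",
#' feature_class, target_genes (comma-separated), motif_count.
#' Round-trips losslessly through [read_peaks()].
#'
#' @param peaks A [peak_set()].
#' @param path Output path.
#' @export
write_peaks <- function(peaks, path) {
  stopifnot(inherits(peaks, "peak_set"))
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t.\t%s\t%s\t%s",
                   peaks$chrom, peaks$start, peaks$end, peaks$peak_id,
                   format_num(peaks$signal), peaks$feature_class,
                   peaks$target_genes, format_num(peaks$motif_count))
  writeLines(lines, path)
  invisible(path)
}

format_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "." else format(v, digits = 15, scientific = FALSE)
  }, "")
  out
}

#' Read peaks written by [write_peaks()]
#' @param path BED6+3 peak file.
#' @return A [peak_set()].
#' @export
read_peaks <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(#|track)", lines)]
  if (!length(lines)) return(peak_set())
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) != 9))
    stop("malformed peak record at line ",
         which(lengths(f) != 9)[1], ": expected 9 fields")
  num <- function(i) {
    v <- vapply(f, `[[`, "", i)
    ifelse(v == ".", NA, v)
  }
  peak_set(data.frame(
    chrom = vapply(f, `[[`, "", 1L),
    start = as.integer(vapply(f, `[[`, "", 2L)),
    end = as.integer(vapply(f, `[[`, "", 3L)),
    peak_id = vapply(f, `[[`, "", 4L),
    signal = as.numeric(num(5L)),
    source = ".",
    feature_class = vapply(f, `[[`, "", 7L),
    target_genes = vapply(f, `[[`, "", 8L),
    motif_count = as.integer(num(9L))))
}
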