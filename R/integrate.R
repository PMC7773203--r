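# DE-table filtering, direct/indirect regulon classification, and
# gene-set overlap enrichment.
#
# Orientation convention: the DE contrast is mutant (regulator deletion)
# vs wild type, so a gene *down* in the deletion is *activated* by the
# factor and a gene *up* is *repressed* by it.

#' Filter a differential-expression table
#'
#' @param table data.frame with columns `gene_id`, `log2fc`, `p` (raw
#'   p-values; the published-style stringent raw-p cutoff is used, no
#'   multiple-testing correction by default).
#' @param fc_cutoff Fold-change cutoff on the natural scale (>= 1); a gene
#'   passes when `|log2fc| >= log2(fc_cutoff)` (inclusive).
#' @param p_cutoff Inclusive p-value cutoff (default 1e-4, i.e.
#'   `p <= p_cutoff`).
#' @param adjust `"none"` (default) or `"BH"` to filter on
#'   Benjamini-Hochberg adjusted p-values instead.
#' @return List with `up` and `down` gene-ID character vectors.
#' @export
de_filter <- function(table, fc_cutoff = 2, p_cutoff = 1e-4,
                      adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(fc_cutoff >= 1, p_cutoff >= 0, p_cutoff <= 1,
            all(c("gene_id", "log2fc", "p") %in% names(table)))
  if (any(table$p < 0 | table$p > 1, na.rm = TRUE))
    stop("p-values outside [0, 1]")
  if (anyDuplicated(table$gene_id)) stop("duplicate gene IDs in DE table")
  p <- if (adjust == "BH") stats::p.adjust(table$p, "BH") else table$p
  lfc <- log2(fc_cutoff)
  pass <- !is.na(p) & p <= p_cutoff
  list(up = table$gene_id[pass & table$log2fc >= lfc],
       down = table$gene_id[pass & table$log2fc <= -lfc])
}

#' Classify the regulon: direct/indirect x activated/repressed
#'
#' Genes down in the deletion mutant are activated by the factor; those
#' bound within the target window (members of `chip_targets`) are direct,
#' the rest indirect.  Mirrored for up/repressed.  Remaining genes in the
#' universe are `not_regulated`.
#'
#' @param up,down Gene sets from [de_filter()] (up/down in the deletion).
#' @param chip_targets ChIP target gene set (from [assign_targets()]).
#' @param universe All annotated gene IDs.
#' @return data.frame (`gene_id`, `class`) partitioning `universe` into
#'   `direct_activated`, `indirect_activated`, `direct_repressed`,
#'   `indirect_repressed`, `not_regulated`.
#' @export
classify_regulon <- function(up, down, chip_targets, universe) {
  if (length(intersect(up, down)))
    stop("genes in both up and down sets: contradictory DE table")
  out <- setdiff(c(up, down, chip_targets), universe)
  if (length(out))
    stop("gene(s) outside the universe: ",
         paste(utils::head(out, 5), collapse = ", "))
  cls <- rep("not_regulated", length(universe))
  names(cls) <- universe
  cls[intersect(down, chip_targets)] <- "direct_activated"
  cls[setdiff(down, chip_targets)] <- "indirect_activated"
  cls[intersect(up, chip_targets)] <- "direct_repressed"
  cls[setdiff(up, chip_targets)] <- "indirect_repressed"
  data.frame(gene_id = universe, class = unname(cls))
}

#' Gene-set overlap enrichment (one-sided Fisher exact test)
#'
#' Tests whether two gene sets overlap more than expected by chance in a
#' universe of size `n_universe` (hypergeometric upper tail).  The odds
#' ratio is the sample odds ratio of the 2x2 table (reported as `Inf` when
#' a zero cell makes it degenerate).
#'
#' @param setA,setB Gene-ID vectors.
#' @param n_universe Universe size (must be supplied explicitly; there is
#'   no default).
#' @param alternative `"greater"` (enrichment, default) or `"two.sided"`.
#' @return List with `table` (2x2 counts), `odds_ratio`, `p`,
#'   `n_universe`, `overlap`, and the overlap fractions of each set.
#' @export
set_enrichment <- function(setA, setB, n_universe,
                           alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  setA <- unique(setA); setB <- unique(setB)
  if (length(union(setA, setB)) > n_universe)
    stop("universe smaller than the union of the two sets")
  k <- length(intersect(setA, setB))
  a_only <- length(setA) - k
  b_only <- length(setB) - k
  rest <- n_universe - k - a_only - b_only
  tab <- matrix(c(k, a_only, b_only, rest), 2, 2,
                dimnames = list(c("inA", "notA"), c("inB", "notB")))
  p <- stats::fisher.test(tab, alternative = alternative)$p.value
  or <- if (a_only == 0 || b_only == 0) {
    if (k == 0) NaN else Inf
  } else k * rest / (a_only * b_only)
  list(table = tab, odds_ratio = or, p = p, n_universe = n_universe,
       overlap = k,
       fracA = if (length(setA)) k / length(setA) else NA_real_,
       fracB = if (length(setB)) k / length(setB) else NA_real_)
}

#' Simplified differential-expression stage for synthetic runs
#'
#' A deliberately transparent stand-in used to exercise the integration
#' stage on simulated counts; it is *not* a substitute for a dispersion-
#' aware NB model (edgeR/DESeq2) on real data, and assumes near-Poisson
#' replicate noise.  Per-gene: CPM normalization by total library size,
#' log2 fold change of mean CPM with pseudocount 0.5, and a two-sided
#' exact binomial test of the pooled condition-B count against the pooled
#' library-size ratio.
#'
#' @param counts Integer matrix, genes x samples.
#' @param condition Factor/character of length `ncol(counts)` with exactly
#'   two levels; the second level is the test condition (log2fc is second
#'   vs first).
#' @return data.frame `gene_id`, `log2fc`, `p` (class `de_table`); all-zero
#'   genes get `log2fc = 0`, `p = 1` and are flagged in the `flat` column.
#' @export
simple_de <- function(counts, condition) {
  stopifnot(is.matrix(counts), ncol(counts) == length(condition))
  if (!is.factor(condition))  # preserve first-appearance order
    condition <- factor(condition, levels = unique(as.character(condition)))
  stopifnot(nlevels(condition) == 2)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("gene_%d", seq_len(nrow(counts)))
  lib <- colSums(counts)
  if (any(lib == 0)) stop("sample with zero library size")
  cpm <- sweep(counts, 2, lib / 1e6, "/")
  a <- condition == levels(condition)[1]
  b <- !a
  mean_a <- rowMeans(cpm[, a, drop = FALSE])
  mean_b <- rowMeans(cpm[, b, drop = FALSE])
  log2fc <- log2((mean_b + 0.5) / (mean_a + 0.5))
  tot_a <- rowSums(counts[, a, drop = FALSE])
  tot_b <- rowSums(counts[, b, drop = FALSE])
  ratio_b <- sum(lib[b]) / sum(lib)
  n <- tot_a + tot_b
  p <- vapply(seq_len(nrow(counts)), function(i) {
    if (n[i] == 0) return(1)
    stats::binom.test(tot_b[i], n[i], ratio_b)$p.value
  }, 0)
  flat <- n == 0
  log2fc[flat] <- 0
  structure(data.frame(gene_id = rownames(counts), log2fc = log2fc,
                       p = p, flat = flat),
            class = c("de_table", "data.frame"))
}
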