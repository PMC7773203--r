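# Arginine/lysine proteome composition: %R+K per protein, three-bin
# partition of the proteome, bin enrichment of gene sets, and group
# composition comparison.  The biological motivation: translation-related
# proteins are strongly enriched for R and K, so a factor that both
# supplies Arg/Lys and represses translation genes couples amino-acid
# supply to translation capacity.

#' Percent arginine + lysine of a protein sequence
#'
#' Stop symbols (`*`) are stripped; `X` is tolerated and counted in the
#' length but never as R/K.  The initiator methionine is included.
#'
#' @param sequence Amino-acid string (or `Biostrings::AAString`).
#' @return Percent (0..100).
#' @export
rk_fraction <- function(sequence) {
  s <- gsub("*", "", toupper(as.character(sequence)), fixed = TRUE)
  if (!nchar(s)) stop("empty protein sequence")
  aa <- strsplit(s, "")[[1]]
  valid <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
             "P","S","T","W","Y","V","X")
  if (!all(aa %in% valid))
    stop("invalid amino-acid symbol: ",
         paste(unique(aa[!aa %in% valid]), collapse = ","))
  100 * sum(aa == "R" | aa == "K") / length(aa)
}

#' Bin a proteome by %R+K
#'
#' Fixed mode uses the published-style cut points: bin1 below `low` %R+K,
#' bin3 above `high`, bin2 the closed middle interval (both boundary
#' values fall in bin2).  Tercile mode cuts at the empirical 1/3 and 2/3
#' quantiles instead.
#'
#' @param proteome Named `Biostrings::AAStringSet`, FASTA path, or named
#'   character vector of protein sequences (names are gene IDs).
#' @param mode `"fixed"` or `"tercile"`.
#' @param low,high Fixed-mode cut points in percent (defaults 10 and 13).
#' @return Object of class `proteome_bins`: data.frame `gene_id`,
#'   `length`, `rk_count`, `rk_percent`, `bin`; attributes `mode` and
#'   `boundaries`.
#' @export
bin_proteome <- function(proteome, mode = c("fixed", "tercile"),
                         low = 10, high = 13) {
  mode <- match.arg(mode)
  if (is.character(proteome) && length(proteome) == 1L &&
      file.exists(proteome))
    proteome <- Biostrings::readAAStringSet(proteome)
  seqs <- as.character(proteome)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (length(seqs) < 3) stop("need at least 3 proteins")
  seqs <- gsub("*", "", seqs, fixed = TRUE)
  pct <- vapply(seqs, rk_fraction, 0, USE.NAMES = FALSE)
  len <- nchar(seqs)
  rk <- as.integer(round(pct * len / 100))
  if (mode == "tercile") {
    cuts <- stats::quantile(pct, c(1/3, 2/3), type = 1, names = FALSE)
    low <- cuts[1]; high <- cuts[2]
    bin <- ifelse(pct <= low, "bin1", ifelse(pct <= high, "bin2", "bin3"))
  } else {
    bin <- ifelse(pct < low, "bin1", ifelse(pct <= high, "bin2", "bin3"))
  }
  structure(data.frame(gene_id = names(seqs), length = len,
                       rk_count = rk, rk_percent = pct, bin = bin),
            class = c("proteome_bins", "data.frame"),
            mode = mode, boundaries = c(low = low, high = high))
}

#' Enrichment of a gene set in one composition bin
#'
#' One-sided Fisher exact test of set membership against focus-bin
#' membership over the binned proteome as the universe.
#'
#' @param gene_set Gene IDs; IDs absent from the binned proteome are
#'   dropped with a warning.
#' @param bins A [bin_proteome()] result.
#' @param focus_bin Bin tested for enrichment (default `"bin3"`).
#' @return A [set_enrichment()] result, plus `bin_fractions` (fraction of
#'   the set in each bin).
#' @export
bin_enrichment <- function(gene_set, bins, focus_bin = "bin3") {
  stopifnot(inherits(bins, "proteome_bins"),
            focus_bin %in% c("bin1", "bin2", "bin3"))
  gene_set <- unique(gene_set)
  missing <- setdiff(gene_set, bins$gene_id)
  if (length(missing)) {
    warning(length(missing), " gene ID(s) not in the binned proteome; ",
            "dropped")
    gene_set <- setdiff(gene_set, missing)
  }
  if (!length(gene_set)) stop("empty gene set after ID matching")
  res <- set_enrichment(gene_set, bins$gene_id[bins$bin == focus_bin],
                        n_universe = nrow(bins))
  in_set <- bins$gene_id %in% gene_set
  res$bin_fractions <- vapply(c("bin1", "bin2", "bin3"), function(b)
    mean(bins$bin[in_set] == b), 0)
  res$focus_bin <- focus_bin
  res
}

#' Compare %R+K between a protein set and the rest of the proteome
#'
#' Two-sided Mann-Whitney rank-sum test on `rk_percent`; the comparison
#' group is the proteome *excluding* the set (overlap is removed
#' internally).
#'
#' @param gene_set Protein/gene IDs of the focal group (e.g. translation-
#'   related genes).
#' @param bins A [bin_proteome()] result.
#' @return List with `median_set`, `median_rest`, `U`, `p`, `n_set`,
#'   `n_rest`.
#' @export
composition_compare <- function(gene_set, bins) {
  stopifnot(inherits(bins, "proteome_bins"))
  in_set <- bins$gene_id %in% gene_set
  if (!any(in_set) || all(in_set))
    stop("both groups must be non-empty")
  a <- bins$rk_percent[in_set]
  b <- bins$rk_percent[!in_set]
  rs <- rank_sum_test(a, b)
  list(median_set = stats::median(a), median_rest = stats::median(b),
       U = rs$U, p = rs$p, n_set = length(a), n_rest = length(b))
}
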