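# Synthetic-data generator: a toy genome with non-overlapping genes,
# planted consensus motifs and binding peaks in promoters, ChIP fragments
# (IP replicates + mock) from a midpoint-rate model, NB expression counts
# with planted activation/repression, and a proteome whose "translation"
# genes are enriched for high %R+K.  Everything is deterministic given a
# seed; sub-stages draw from seeds derived with `derive_seed()` so stages
# can be re-run independently.

#' Generate a random genome
#'
#' I.i.d. bases at the stated GC content, one sequence per chromosome
#' (named chrI, chrII, ...).
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_len Length of each chromosome in bp (>= 10000).
#' @param gc GC fraction in (0, 1).
#' @param seed Integer seed.
#' @return List with `genome` (`Biostrings::DNAStringSet`) and
#'   `chrom_sizes` (named integer vector).
#' @export
make_genome <- function(n_chrom = 1L, chrom_len = 200000L, gc = 0.38,
                        seed = 1L) {
  if (!(gc > 0 && gc < 1)) stop("gc must be strictly between 0 and 1")
  if (chrom_len < 10000) stop("chrom_len must be at least 10000")
  prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- with_seed(seed, lapply(seq_len(n_chrom), function(i)
    paste(sample(names(prob), chrom_len, replace = TRUE, prob = prob),
          collapse = "")))
  names(seqs) <- paste0("chr", as.character(utils::as.roman(
    seq_len(n_chrom))))
  genome <- Biostrings::DNAStringSet(unlist(seqs))
  list(genome = genome,
       chrom_sizes = stats::setNames(rep(as.integer(chrom_len), n_chrom),
                                     names(seqs)))
}

#' Place random non-overlapping genes on a genome
#'
#' Transcript spans (TSS..TTS, i.e. ORF plus UTRs) are rejection-sampled
#' to be non-overlapping.  Strands are Bernoulli(0.5); the TSS offset
#' upstream of the ORF is uniform in `utr5_range` and the TTS offset
#' downstream uniform in `utr3_range`.
#'
#' @param chrom_sizes Named integer vector (or a [make_genome()] result).
#' @param n_genes Number of genes.
#' @param orf_len_range ORF length range in bp.
#' @param utr5_range TSS-to-ORF offset range in bp.
#' @param utr3_range ORF-to-TTS offset range in bp.
#' @param seed Integer seed.
#' @param max_attempts Rejection-sampling budget per gene.
#' @return A [genome_annotation()] with genes `g001`, `g002`, ... sorted
#'   by position.
#' @export
make_genes <- function(chrom_sizes, n_genes = 80L,
                       orf_len_range = c(500L, 1500L),
                       utr5_range = c(50L, 200L),
                       utr3_range = c(25L, 150L),
                       seed = 1L, max_attempts = 200L) {
  if (is.list(chrom_sizes)) chrom_sizes <- chrom_sizes$chrom_sizes
  need <- n_genes * (max(orf_len_range) + max(utr5_range) +
                       max(utr3_range))
  if (need > sum(chrom_sizes))
    stop("genome too small for ", n_genes, " genes: needs about ", need,
         " bp, has ", sum(chrom_sizes))
  rows <- with_seed(seed, {
    taken <- lapply(chrom_sizes, function(...) NULL)  # spans per chrom
    out <- vector("list", n_genes)
    for (i in seq_len(n_genes)) {
      placed <- FALSE
      for (att in seq_len(max_attempts)) {
        chr <- sample(names(chrom_sizes), 1, prob = chrom_sizes)
        len <- chrom_sizes[[chr]]
        orf_len <- sample(orf_len_range[1]:orf_len_range[2], 1)
        u5 <- sample(utr5_range[1]:utr5_range[2], 1)
        u3 <- sample(utr3_range[1]:utr3_range[2], 1)
        strand <- sample(c("+", "-"), 1)
        span <- orf_len + u5 + u3
        if (span > len) next
        span_start <- sample.int(len - span + 1L, 1) - 1L
        span_end <- span_start + span
        tk <- taken[[chr]]
        if (!is.null(tk) &&
            any(tk$start < span_end & tk$end > span_start)) next
        if (strand == "+") {
          start <- span_start + u5; end <- start + orf_len
          tss <- span_start; tts <- span_end - 1L
        } else {
          end <- span_end - u5; start <- end - orf_len
          tss <- span_end - 1L; tts <- span_start
        }
        taken[[chr]] <- rbind(tk, data.frame(start = span_start,
                                             end = span_end))
        out[[i]] <- data.frame(chrom = chr, start = start, end = end,
                               strand = strand, tss = tss, tts = tts)
        placed <- TRUE
        break
      }
      if (!placed)
        stop("could not place gene ", i, " after ", max_attempts,
             " attempts; genome too crowded (", sum(chrom_sizes),
             " bp for ", n_genes, " genes)")
    }
    do.call(rbind, out)
  })
  rows <- rows[order(rows$chrom, rows$start), ]
  rows$gene_id <- sprintf("g%03d", seq_len(n_genes))
  rows$tss_default <- FALSE
  genome_annotation(chrom_sizes, rows)
}

resolve_iupac <- function(motif) {
  codes <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
                Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
                K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
                D = c("A", "G", "T"), H = c("A", "C", "T"),
                V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
  paste(vapply(strsplit(toupper(motif), "")[[1]], function(ch) {
    opts <- codes[[ch]]
    if (length(opts) == 1) opts else sample(opts, 1)
  }, ""), collapse = "")
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Plant consensus motifs and binding peaks in gene promoters
#'
#' For each target gene, one concrete motif instance (ambiguity codes
#' resolved at random, random strand) is written into the promoter window
#' (TSS - 1 kb .. TSS + 100 bp in transcript orientation, clipped to the
#' chromosome) at a position within `proximal_margin` bp of the ORF, and a
#' planted peak of width drawn from `peak_width_range` is centered on it.
#' A candidate is skipped (with a warning) when no valid motif position
#' exists or when its peak extended by `exclusion_window` bp would touch
#' another gene's ORF — this keeps the planted truth unambiguous: every
#' planted gene has a peak within the target window of its ORF, and no
#' other gene does.
#'
#' @param genome `Biostrings::DNAStringSet` (or a [make_genome()] result).
#' @param ann A [genome_annotation()].
#' @param target_genes Candidate gene IDs, in priority order.
#' @param motif IUPAC motif to plant (default `"TGANTCA"`).
#' @param enrichment ChIP enrichment fold recorded for each planted peak.
#' @param peak_width_range Planted peak width range in bp.
#' @param seed Integer seed.
#' @param proximal_margin Maximum motif-to-ORF distance in bp; keeps the
#'   peak within the target-assignment window of its gene.
#' @param exclusion_window Half-width of the clash check (default 750,
#'   the target-assignment window).
#' @return List with `genome` (modified sequences) and `truth`: a list
#'   with `planted_peaks` (chrom, start, end, enrichment, gene_id),
#'   `motif_positions` (chrom, pos, strand, instance, gene_id),
#'   `planted_genes`, `skipped_genes`, `seed`.
#' @export
plant_motifs_and_peaks <- function(genome, ann, target_genes,
                                   motif = "TGANTCA", enrichment = 8,
                                   peak_width_range = c(200L, 400L),
                                   seed = 1L, proximal_margin = 600L,
                                   exclusion_window = 750L) {
  if (is.list(genome) && !is.null(genome$genome)) genome <- genome$genome
  if (!iupac_ok(motif)) stop("invalid IUPAC symbol in motif: ", motif)
  g <- ann$genes
  miss <- setdiff(target_genes, g$gene_id)
  if (length(miss))
    stop("unknown target gene(s): ", paste(miss, collapse = ", "))
  L <- nchar(motif)
  peaks <- list(); motifs <- list(); skipped <- character()
  with_seed(seed, {
    for (id in target_genes) {
      gi <- g[g$gene_id == id, ]
      len <- ann$chrom_sizes[[gi$chrom]]
      if (gi$strand == "+") {
        p_lo <- gi$tss - 1000L; p_hi <- gi$tss + 100L
      } else {
        p_lo <- gi$tss - 99L; p_hi <- gi$tss + 1001L
      }
      lo <- max(p_lo, gi$start - proximal_margin, 0L)
      hi <- min(p_hi, gi$end + proximal_margin, len) - L
      if (hi < lo) {
        warning("no valid motif position for gene ", id, "; skipped")
        skipped <- c(skipped, id)
        next
      }
      m <- sample(lo:hi, 1)
      w <- sample(peak_width_range[1]:peak_width_range[2], 1)
      centre <- m + L %/% 2L
      pk_start <- max(0L, centre - w %/% 2L)
      pk_end <- min(len, pk_start + w)
      other <- g[g$gene_id != id & g$chrom == gi$chrom, ]
      if (nrow(other) && any(other$start < pk_end + exclusion_window &
                             other$end > pk_start - exclusion_window)) {
        warning("peak for gene ", id,
                " would fall near another ORF; skipped")
        skipped <- c(skipped, id)
        next
      }
      instance <- resolve_iupac(motif)
      strand <- sample(c("+", "-"), 1)
      written <- if (strand == "+") instance else revcomp_chr(instance)
      Biostrings::subseq(genome[[gi$chrom]], m + 1L, m + L) <-
        Biostrings::DNAString(written)
      peaks[[id]] <- data.frame(chrom = gi$chrom, start = pk_start,
                                end = pk_end, enrichment = enrichment,
                                gene_id = id)
      motifs[[id]] <- data.frame(chrom = gi$chrom, pos = m,
                                 strand = strand, instance = instance,
                                 gene_id = id)
    }
  })
  empty_peaks <- data.frame(chrom = character(), start = integer(),
                            end = integer(), enrichment = numeric(),
                            gene_id = character())
  truth <- list(
    planted_peaks = if (length(peaks)) {
      z <- do.call(rbind, peaks); rownames(z) <- NULL; z
    } else empty_peaks,
    motif_positions = if (length(motifs)) {
      z <- do.call(rbind, motifs); rownames(z) <- NULL; z
    } else NULL,
    planted_genes = setdiff(target_genes, skipped),
    skipped_genes = skipped,
    seed = seed)
  list(genome = genome, truth = truth)
}

#' Simulate ChIP fragments: IP replicates plus a mock control
#'
#' Fragment midpoints follow a midpoint-rate model: uniform over the
#' genome, with the local rate multiplied by each planted peak's
#' enrichment fold inside the peak — for IP samples only; the mock is pure
#' background.  Replicates are i.i.d. under distinct derived seeds.
#'
#' @param chrom_sizes Named integer vector (or a [make_genome()] result).
#' @param planted_peaks data.frame `chrom`, `start`, `end`, `enrichment`
#'   (may have zero rows for a null simulation).
#' @param depth Fragments per sample; must be at least `10 *` the number
#'   of 100 bp bins so the background mode is non-degenerate.
#' @param frag_len Fragment length in bp.
#' @param n_rep Number of IP replicates.
#' @param seed Integer seed.
#' @return List with `ip` (list of `n_rep` [fragment_set()]s, samples
#'   `ip_rep1`, ...) and `mock` (one [fragment_set()]).
#' @export
simulate_chip <- function(chrom_sizes, planted_peaks, depth = 200000L,
                          frag_len = 150L, n_rep = 2L, seed = 1L) {
  if (is.list(chrom_sizes) && !is.null(chrom_sizes$chrom_sizes))
    chrom_sizes <- chrom_sizes$chrom_sizes
  n_bins <- sum(ceiling(chrom_sizes / 100))
  if (depth < 10 * n_bins)
    stop("depth ", depth, " too low: need at least ", 10 * n_bins,
         " fragments (10 per 100 bp bin) for a stable background mode")
  weights_for <- function(enriched) {
    lapply(names(chrom_sizes), function(chr) {
      w <- rep(1, chrom_sizes[[chr]])
      if (enriched && nrow(planted_peaks)) {
        pk <- planted_peaks[planted_peaks$chrom == chr, , drop = FALSE]
        for (j in seq_len(nrow(pk)))
          w[(pk$start[j] + 1L):pk$end[j]] <- pk$enrichment[j]
      }
      w
    })
  }
  draw_sample <- function(w, sample_id, sub_seed) {
    tot <- vapply(w, sum, 0)
    with_seed(sub_seed, {
      n_chr <- as.vector(stats::rmultinom(1, depth, tot))
      dfs <- lapply(seq_along(w), function(ci) {
        if (n_chr[ci] == 0)
          return(data.frame(chrom = character(), start = integer(),
                            end = integer()))
        mid <- sample.int(length(w[[ci]]), n_chr[ci], replace = TRUE,
                          prob = w[[ci]]) - 1L
        start <- pmax(0L, mid - frag_len %/% 2L)
        end <- pmin(length(w[[ci]]), start + frag_len)
        start <- pmin(start, end - 1L)
        data.frame(chrom = names(chrom_sizes)[ci], start = start,
                   end = end)
      })
      fragment_set(do.call(rbind, dfs), sample_id = sample_id,
                   chrom_sizes = chrom_sizes)
    })
  }
  w_ip <- weights_for(TRUE)
  w_bg <- weights_for(FALSE)
  ip <- lapply(seq_len(n_rep), function(k)
    draw_sample(w_ip, paste0("ip_rep", k), derive_seed(seed, k)))
  mock <- draw_sample(w_bg, "mock", derive_seed(seed, 0L))
  list(ip = ip, mock = mock)
}

#' Simulate negative-binomial expression counts with planted effects
#'
#' Baseline means are log-normal around `base_mean`; in the deletion
#' condition, activated genes (which require the factor) have their mean
#' divided by `2^effect_log2fc` and repressed genes multiplied by it;
#' null genes are unchanged.  Counts are NB with shared dispersion.
#'
#' @param gene_ids Character vector of genes.
#' @param activated,repressed Gene-ID sets carrying the planted effects.
#' @param n_cond_reps Replicates per condition.
#' @param nb_dispersion NB dispersion (variance = mu + dispersion * mu^2);
#'   must be > 0.
#' @param effect_log2fc Planted |log2 fold change|.
#' @param base_mean Median baseline mean count.
#' @param base_log_sd SD of log-normal baseline spread.
#' @param seed Integer seed.
#' @return Integer matrix genes x samples (`WT_1..`, `del_1..`) with
#'   attribute `condition`.
#' @export
simulate_de_counts <- function(gene_ids, activated = character(),
                               repressed = character(), n_cond_reps = 3L,
                               nb_dispersion = 0.05, effect_log2fc = 2,
                               base_mean = 100, base_log_sd = 1,
                               seed = 1L) {
  if (nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  if (base_mean <= 0) stop("base_mean must be > 0")
  n <- length(gene_ids)
  with_seed(seed, {
    mu_wt <- stats::rlnorm(n, log(base_mean), base_log_sd)
    mu_del <- mu_wt
    mu_del[gene_ids %in% activated] <-
      mu_wt[gene_ids %in% activated] / 2^effect_log2fc
    mu_del[gene_ids %in% repressed] <-
      mu_wt[gene_ids %in% repressed] * 2^effect_log2fc
    size <- 1 / nb_dispersion
    draw <- function(mu) as.integer(stats::rnbinom(n, mu = mu,
                                                   size = size))
    m <- cbind(
      vapply(seq_len(n_cond_reps), function(r) draw(mu_wt), integer(n)),
      vapply(seq_len(n_cond_reps), function(r) draw(mu_del), integer(n)))
    dimnames(m) <- list(gene_ids,
                        c(paste0("WT_", seq_len(n_cond_reps)),
                          paste0("del_", seq_len(n_cond_reps))))
    attr(m, "condition") <- rep(c("WT", "del"), each = n_cond_reps)
    m
  })
}

#' Simulate a proteome with composition structure
#'
#' Each protein's target %R+K is drawn from one of three component
#' distributions straddling the 10%/13% cut points (components stay 0.6
#' percentage points clear of the cuts so the realized composition, within
#' 0.5 points of target by construction, always lands in its component's
#' bin).  Proteins in `translation_gene_set` are drawn predominantly from
#' the high-%R+K bin3 component.
#'
#' @param gene_ids Protein/gene IDs.
#' @param bin_fractions Length-3 mixture fractions (must sum to 1).
#' @param translation_gene_set IDs drawn from the bin3 component with
#'   probability `p_translation_bin3`.
#' @param seed Integer seed.
#' @param len_range Protein length range (>= 100 residues so the rounding
#'   error stays within 0.5 points).
#' @param p_translation_bin3 See above (default 0.9; the rest from bin2).
#' @return List with `proteome` (`Biostrings::AAStringSet`) and
#'   `rk_bins_truth` (named character vector gene_id -> bin).
#' @export
simulate_proteome <- function(gene_ids, bin_fractions = c(0.25, 0.5, 0.25),
                              translation_gene_set = character(),
                              seed = 1L, len_range = c(150L, 600L),
                              p_translation_bin3 = 0.9) {
  if (abs(sum(bin_fractions) - 1) > 1e-8)
    stop("bin_fractions must sum to 1")
  if (len_range[1] < 100) stop("minimum protein length is 100 residues")
  comp_range <- list(bin1 = c(5, 9.4), bin2 = c(10.6, 12.4),
                     bin3 = c(13.6, 20))
  if (max(comp_range$bin3) > 100) stop("infeasible composition")
  other_aa <- c("A","N","D","C","Q","E","G","H","I","L","M","F","P","S",
                "T","W","Y","V")
  with_seed(seed, {
    n <- length(gene_ids)
    comp <- character(n)
    is_tr <- gene_ids %in% translation_gene_set
    comp[is_tr] <- ifelse(stats::runif(sum(is_tr)) < p_translation_bin3,
                          "bin3", "bin2")
    comp[!is_tr] <- sample(c("bin1", "bin2", "bin3"), sum(!is_tr),
                           replace = TRUE, prob = bin_fractions)
    seqs <- vapply(seq_len(n), function(i) {
      rng <- comp_range[[comp[i]]]
      target <- stats::runif(1, rng[1], rng[2])
      len <- sample(len_range[1]:len_range[2], 1)
      rk <- as.integer(round(len * target / 100))
      aa <- c("M", sample(other_aa, len - 1L, replace = TRUE))
      pos <- sample(2:len, rk)
      aa[pos] <- sample(c("R", "K"), rk, replace = TRUE)
      paste(aa, collapse = "")
    }, "")
    names(seqs) <- gene_ids
    list(proteome = Biostrings::AAStringSet(seqs),
         rk_bins_truth = stats::setNames(comp, gene_ids))
  })
}
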