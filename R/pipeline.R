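# Orchestration: one config object, a full synthetic experiment with
# planted truth, and the end-to-end pipeline
# simulate -> call peaks -> annotate -> integrate -> composition,
# summarized in a deterministic report.

#' Default pipeline configuration
#'
#' All tunables in one list.  Analysis defaults are the published values
#' of the bin-based caller and its downstream stages: 100 bp bins,
#' fold-over-background threshold 2, merge gap 200 bp, replicate overlap
#' 50 bp, target window 750 bp, promoter window -1 kb..+100 bp, DE cutoffs
#' fold change 2 and p <= 1e-4, motif TGANTCA, %R+K bins cut at 10/13.
#' Simulation defaults define the toy scale: one 200 kb chromosome, 80
#' genes, 2e5 fragments per sample, enrichment fold 8.
#'
#' @param ... Named overrides of any default.
#' @return Named list of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    # genome / annotation
    n_chrom = 1L, chrom_len = 200000L, gc = 0.38, n_genes = 80L,
    orf_len_range = c(500L, 1500L), utr5_range = c(50L, 200L),
    utr3_range = c(25L, 150L),
    # planted truth
    n_direct_activated = 12L, n_direct_repressed = 4L,
    n_indirect_activated = 10L, n_indirect_repressed = 10L,
    motif = "TGANTCA", enrichment = 8, peak_width_range = c(200L, 400L),
    # ChIP simulation
    depth = 200000L, frag_len = 150L, n_rep = 2L,
    # peak calling
    bin_size = 100L, threshold = 2, merge_gap = 200L, min_overlap = 50L,
    # annotation
    target_window = 750L, promoter_window = c(-1000L, 100L),
    tts_window = c(0L, 250L),
    # expression
    n_cond_reps = 3L, nb_dispersion = 0.05, effect_log2fc = 2,
    base_mean = 100, fc_cutoff = 2, p_cutoff = 1e-4,
    # proteome
    bin_fractions = c(0.25, 0.5, 0.25), rk_bin_mode = "fixed",
    n_translation_extra = 4L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad))
    stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' Simulate a complete experiment with planted ground truth
#'
#' Builds the toy genome and annotation, partitions the genes into the
#' five truth classes (direct/indirect x activated/repressed plus null),
#' plants motifs and peaks at the direct genes, and simulates ChIP
#' fragments, NB expression counts and a proteome.  Direct candidates that
#' cannot host an unambiguous peak (see [plant_motifs_and_peaks()]) are
#' reassigned to the corresponding indirect class.  The "translation" gene
#' set — high-%R+K by construction — is the repressed classes plus a few
#' null genes.
#'
#' @param config A [default_config()] (or overrides via that function).
#' @return List of class `synthetic_experiment`: `genome`, `chrom_sizes`,
#'   `annotation`, `truth` (see below), `chip` (`ip` list + `mock`),
#'   `counts`, `proteome`, `config`.  `truth` holds the five gene-ID sets,
#'   `planted_peaks`, `motif_positions`, `translation_genes`,
#'   `rk_bins_truth`, `schema` and `seed`.
#' @export
simulate_experiment <- function(config = default_config()) {
  cfg <- config
  gen <- make_genome(cfg$n_chrom, cfg$chrom_len, cfg$gc,
                     seed = derive_seed(cfg$seed, 1L))
  ann <- make_genes(gen$chrom_sizes, cfg$n_genes, cfg$orf_len_range,
                    cfg$utr5_range, cfg$utr3_range,
                    seed = derive_seed(cfg$seed, 2L))
  ids <- with_seed(derive_seed(cfg$seed, 3L), sample(ann$genes$gene_id))
  n_da <- cfg$n_direct_activated; n_dr <- cfg$n_direct_repressed
  cand_da <- ids[seq_len(n_da)]
  cand_dr <- ids[n_da + seq_len(n_dr)]
  plant <- suppressWarnings(plant_motifs_and_peaks(
    gen$genome, ann, c(cand_da, cand_dr), motif = cfg$motif,
    enrichment = cfg$enrichment, peak_width_range = cfg$peak_width_range,
    seed = derive_seed(cfg$seed, 4L),
    exclusion_window = cfg$target_window))
  direct_activated <- intersect(cand_da, plant$truth$planted_genes)
  direct_repressed <- intersect(cand_dr, plant$truth$planted_genes)
  rest <- ids[-seq_len(n_da + n_dr)]
  indirect_activated <- c(intersect(cand_da, plant$truth$skipped_genes),
                          rest[seq_len(cfg$n_indirect_activated)])
  rest <- rest[-seq_len(cfg$n_indirect_activated)]
  indirect_repressed <- c(intersect(cand_dr, plant$truth$skipped_genes),
                          rest[seq_len(cfg$n_indirect_repressed)])
  null_genes <- rest[-seq_len(cfg$n_indirect_repressed)]
  chip <- simulate_chip(gen$chrom_sizes, plant$truth$planted_peaks,
                        depth = cfg$depth, frag_len = cfg$frag_len,
                        n_rep = cfg$n_rep,
                        seed = derive_seed(cfg$seed, 5L))
  counts <- simulate_de_counts(
    ann$genes$gene_id,
    activated = c(direct_activated, indirect_activated),
    repressed = c(direct_repressed, indirect_repressed),
    n_cond_reps = cfg$n_cond_reps, nb_dispersion = cfg$nb_dispersion,
    effect_log2fc = cfg$effect_log2fc, base_mean = cfg$base_mean,
    seed = derive_seed(cfg$seed, 6L))
  translation_genes <- c(direct_repressed, indirect_repressed,
                         null_genes[seq_len(min(cfg$n_translation_extra,
                                                length(null_genes)))])
  prot <- simulate_proteome(ann$genes$gene_id,
                            bin_fractions = cfg$bin_fractions,
                            translation_gene_set = translation_genes,
                            seed = derive_seed(cfg$seed, 7L))
  truth <- list(schema = "gcn4scope-truth-1",
                seed = cfg$seed,
                direct_activated = direct_activated,
                direct_repressed = direct_repressed,
                indirect_activated = indirect_activated,
                indirect_repressed = indirect_repressed,
                null_genes = null_genes,
                planted_peaks = plant$truth$planted_peaks,
                motif_positions = plant$truth$motif_positions,
                translation_genes = translation_genes,
                rk_bins_truth = prot$rk_bins_truth)
  structure(list(genome = plant$genome, chrom_sizes = gen$chrom_sizes,
                 annotation = ann, truth = truth, chip = chip,
                 counts = counts, proteome = prot$proteome,
                 config = cfg),
            class = "synthetic_experiment")
}

#' Write a truth manifest as JSON
#' @param truth The `truth` element of a [simulate_experiment()] result.
#' @param path Output path.
#' @export
write_truth <- function(truth, path) {
  truth$rk_bins_truth <- as.list(truth$rk_bins_truth)  # keep names
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Read a truth manifest written by [write_truth()]
#' @param path JSON truth manifest.
#' @return Truth list; errors if the schema tag is missing/unknown.
#' @export
read_truth <- function(path) {
  truth <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(truth$schema, "gcn4scope-truth-1"))
    stop("unknown truth schema: ", truth$schema)
  truth$rk_bins_truth <- unlist(truth$rk_bins_truth)
  truth
}

# recall/precision of called peaks against planted truth (>= 1 bp overlap)
peak_recovery <- function(consensus, truth_peaks) {
  if (!nrow(truth_peaks))
    return(list(recall = NA_real_, precision = NA_real_,
                n_called = nrow(consensus)))
  hit_truth <- vapply(seq_len(nrow(truth_peaks)), function(i)
    any(consensus$chrom == truth_peaks$chrom[i] &
          consensus$start < truth_peaks$end[i] &
          consensus$end > truth_peaks$start[i]), TRUE)
  hit_called <- if (nrow(consensus))
    vapply(seq_len(nrow(consensus)), function(i)
      any(truth_peaks$chrom == consensus$chrom[i] &
            truth_peaks$start < consensus$end[i] &
            truth_peaks$end > consensus$start[i]), TRUE)
  else logical()
  list(recall = mean(hit_truth),
       precision = if (nrow(consensus)) mean(hit_called) else NA_real_,
       n_called = nrow(consensus))
}

#' Run the full pipeline on a synthetic experiment
#'
#' Executes every stage in dependency order on data from
#' [simulate_experiment()]: per-replicate peak calling, two-replicate
#' consensus, annotation (features, targets, motifs), the simplified DE
#' stage plus regulon classification, and proteome-composition analysis.
#' The mock sample is never used in calling (it is compared against the
#' IP profile in QC only).
#'
#' @param config A [default_config()]; or pass a ready-made
#'   `synthetic_experiment` via `experiment` to skip re-simulation.
#' @param experiment Optional [simulate_experiment()] result.
#' @return List of class `run_report` with per-stage summaries (peak
#'   counts, feature-class counts, motif fraction, DE counts, regulon
#'   class counts, recovery vs truth, composition enrichment) plus the
#'   full intermediate objects under `$objects`.
#' @export
run_all <- function(config = default_config(), experiment = NULL) {
  sim <- if (is.null(experiment)) simulate_experiment(config)
         else experiment
  cfg <- sim$config
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  # --- peak calling (IP replicates only; mock is QC)
  reps <- stage("callpeaks", lapply(seq_along(sim$chip$ip), function(k)
    call_peaks(sim$chip$ip[[k]], sim$chrom_sizes,
               bin_size = cfg$bin_size, threshold = cfg$threshold,
               merge_gap = cfg$merge_gap, source = paste0("rep", k))))
  consensus <- stage("consensus",
                     consensus_peaks(reps[[1]], reps[[2]],
                                     min_overlap = cfg$min_overlap))
  covs <- lapply(sim$chip$ip, bin_counts, chrom_sizes = sim$chrom_sizes,
                 bin_size = cfg$bin_size)
  rep_cor <- stage("qc", replicate_correlation(covs[[1]], covs[[2]]))
  # --- annotation
  consensus <- stage("annotate", annotate_peaks(
    consensus, sim$annotation, genome = sim$genome, motif = cfg$motif,
    window = cfg$target_window, promoter_window = cfg$promoter_window,
    tts_window = cfg$tts_window))
  targets <- assign_targets(consensus, sim$annotation,
                            window = cfg$target_window)
  mf <- stage("motif", motif_fraction(consensus, sim$genome, cfg$motif))
  # --- integration
  de <- stage("de", simple_de(sim$counts, attr(sim$counts, "condition")))
  sets <- de_filter(de, fc_cutoff = cfg$fc_cutoff,
                    p_cutoff = cfg$p_cutoff)
  regulon <- stage("regulon", classify_regulon(
    sets$up, sets$down, targets$target_genes,
    sim$annotation$genes$gene_id))
  # --- composition
  bins <- stage("composition", bin_proteome(sim$proteome,
                                            mode = cfg$rk_bin_mode))
  repressed_called <- regulon$gene_id[
    regulon$class %in% c("direct_repressed", "indirect_repressed")]
  bin3 <- if (length(repressed_called))
    bin_enrichment(repressed_called, bins) else NULL
  comp <- composition_compare(sim$truth$translation_genes, bins)
  # --- recovery vs planted truth
  recovery <- peak_recovery(consensus, sim$truth$planted_peaks)
  truth_classes <- c(
    stats::setNames(rep("direct_activated",
                        length(sim$truth$direct_activated)),
                    sim$truth$direct_activated),
    stats::setNames(rep("direct_repressed",
                        length(sim$truth$direct_repressed)),
                    sim$truth$direct_repressed),
    stats::setNames(rep("indirect_activated",
                        length(sim$truth$indirect_activated)),
                    sim$truth$indirect_activated),
    stats::setNames(rep("indirect_repressed",
                        length(sim$truth$indirect_repressed)),
                    sim$truth$indirect_repressed),
    stats::setNames(rep("not_regulated", length(sim$truth$null_genes)),
                    sim$truth$null_genes))
  regulon_acc <- mean(regulon$class ==
                        unname(truth_classes[regulon$gene_id]))
  class_counts <- table(factor(regulon$class, levels = c(
    "direct_activated", "indirect_activated", "direct_repressed",
    "indirect_repressed", "not_regulated")))
  report <- list(
    seed = cfg$seed,
    qc = list(replicate_pearson_r = rep_cor),
    peaks = list(n_rep = vapply(reps, nrow, 0L),
                 n_consensus = nrow(consensus),
                 background = lapply(reps, function(r)
                   unclass(attr(r, "background"))[c("mu", "x",
                                                    "divisor")])),
    features = as.list(table(factor(consensus$feature_class, levels = c(
      "promoter", "exon", "near_TTS", "intergenic")))),
    motif = list(fraction = mf$fraction, n_with_motif = mf$n_with_motif,
                 n_peaks = mf$n_peaks),
    de = list(n_up = length(sets$up), n_down = length(sets$down)),
    regulon = as.list(class_counts),
    recovery = c(recovery, list(regulon_accuracy = regulon_acc)),
    composition = list(
      bin_sizes = as.list(table(factor(bins$bin, levels = c(
        "bin1", "bin2", "bin3")))),
      bin3_enrichment_p = if (is.null(bin3)) NA_real_ else bin3$p,
      bin3_fraction_of_repressed = if (is.null(bin3)) NA_real_
        else unname(bin3$bin_fractions["bin3"]),
      translation_median_rk = comp$median_set,
      rest_median_rk = comp$median_rest,
      translation_vs_rest_p = comp$p))
  structure(c(report,
              list(objects = list(experiment = sim, replicates = reps,
                                  consensus = consensus, de = de,
                                  regulon = regulon, bins = bins))),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> seed", x$seed, "\n",
      " consensus peaks:", x$peaks$n_consensus,
      sprintf("(recall %.2f, precision %.2f)", x$recovery$recall,
              x$recovery$precision), "\n",
      " features:", paste(names(x$features), unlist(x$features),
                          collapse = ", "), "\n",
      sprintf("  motif fraction: %.2f", x$motif$fraction), "\n",
      " DE: ", x$de$n_up, "up /", x$de$n_down, "down;",
      "regulon accuracy", sprintf("%.2f", x$recovery$regulon_accuracy),
      "\n",
      sprintf("  bin3 enrichment p = %.3g",
              x$composition$bin3_enrichment_p), "\n")
  invisible(x)
}

#' Serialize a run report (without objects) to JSON
#' @param report A [run_all()] result.
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  report$objects <- NULL
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
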