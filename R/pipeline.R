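# End-to-end driver reproducing the analysis shapes on a synthetic fixture:
# simulate -> cross-reactivity screen -> classification -> motif enrichment
# -> anchor enrichment -> calibration + GC QC -> gene assignment ->
# conservation -> deconvolution.

#' Pipeline configuration
#'
#' One object holding the simulation config and every stage parameter, each
#' defaulting to the analysis' standard values (100 permutations, ICA k =
#' number of simulated cell types, 100 iterations, 2 kb / 1 kb TSS window,
#' 2 kb centre distance). All stage randomness derives from the global seed
#' through named substreams.
#'
#' @param seed Global integer seed.
#' @param sim A \code{\link{sim_config}} (defaults to one built from
#'   \code{seed}).
#' @param n_perm Permutations for every enrichment test.
#' @param n_compendium Reference sets in the synthetic compendium.
#' @param ica_max_iter Maximum FastICA iterations.
#' @param upstream,downstream,max_center_distance TSS-window parameters (bp).
#' @param gc_reads Reads drawn for the GC-bias diagnostic.
#' @return List of class \code{pipeline_config}.
#' @export
pipeline_config <- function(seed = 1L, sim = sim_config(seed = seed),
                            n_perm = 100L, n_compendium = 8L,
                            ica_max_iter = 100L,
                            upstream = 2000L, downstream = 1000L,
                            max_center_distance = 2000L,
                            gc_reads = 20000L) {
  structure(as.list(environment()), class = "pipeline_config")
}

# split a peak set into jittered subsampled reference sets
synthetic_compendium <- function(b_sites, n_sets, seed, cell_types = NULL) {
  set.seed(seed)
  if (is.null(cell_types))
    cell_types <- paste0("ct", seq_len(max(1L, ceiling(n_sets / 2))))
  lapply(seq_len(n_sets), function(i) {
    keep <- sort(sample(length(b_sites), round(0.7 * length(b_sites))))
    gr <- GenomicRanges::shift(b_sites[keep],
                               sample(-30:30, length(keep), replace = TRUE))
    peak_set(gr, genome_id = genome_id(b_sites),
             cell_type = cell_types[(i - 1L) %% length(cell_types) + 1L],
             dataset_id = sprintf("ref%02d", i))
  })
}

#' Run the full synthetic analysis pipeline
#'
#' Executes all stages on data generated from the configuration and returns
#' a machine-readable report. Writes \code{report.json} plus per-stage TSV /
#' BED outputs when \code{outdir} is given. Rerunning with the same
#' configuration reproduces the report exactly.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @param outdir Optional output directory.
#' @return Nested list of class \code{pipeline_report} with one block per
#'   stage.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL) {
  sim <- config$sim
  seed <- config$seed
  report <- list(parameters = list(
    seed = seed, n_perm = config$n_perm,
    k_cell_types = sim$k_cell_types,
    cross_reactive_fraction = sim$cross_reactive_fraction,
    upstream = config$upstream, downstream = config$downstream,
    max_center_distance = config$max_center_distance))

  ## 1. simulate
  genome_seq <- simulate_genome(sim)
  ab <- simulate_antibody_peaksets(sim)
  pwm_a <- example_pwm("A"); pwm_b <- example_pwm("B")
  genome_seq <- plant_motifs(genome_seq, ab$a_sites, pwm_a,
                             seed = substream_seed(seed, "plant_a"))
  genome_seq <- plant_motifs(genome_seq, ab$b_sites, pwm_b,
                             seed = substream_seed(seed, "plant_b"))
  report$simulate <- list(
    n_clean_a = length(ab$clean_a), n_dirty_a = length(ab$dirty_a),
    n_b = length(ab$b), n_crossreactive = length(ab$crossreactive_idx))

  ## 2. cross-reactivity screen against a factor-B compendium
  compendium <- synthetic_compendium(ab$b_sites, config$n_compendium,
                                     substream_seed(seed, "compendium"))
  prof_clean <- compendium_overlap(ab$clean_a, compendium)
  prof_dirty <- compendium_overlap(ab$dirty_a, compendium)
  report$crossreactivity_screen <- list(
    median_fraction_clean = prof_clean$median_fraction,
    median_fraction_dirty = prof_dirty$median_fraction)

  ## 3. classification
  cls <- classify_peaks(ab$dirty_a, ab$clean_a)
  planted <- ab$b_sites[ab$crossreactive_idx]
  recovery <- if (length(planted))
    count_overlapping(planted, cls$a_specific) / length(planted) else NA_real_
  report$classification <- list(
    counts = as.list(cls$counts),
    crossreactive_recovery = recovery)

  ## 4. motif enrichment in the peak categories
  hits_a <- scan_pwm(genome_seq, pwm_a)
  hits_b <- scan_pwm(genome_seq, pwm_b)
  enr <- function(regions, hits, name)
    permutation_enrichment(regions, hits, sim$genome,
                           n_perm = config$n_perm,
                           seed = substream_seed(seed, name))
  e_common_a <- enr(cls$common, hits_a, "common_vs_A")
  e_common_b <- enr(cls$common, hits_b, "common_vs_B")
  e_spec_a <- enr(cls$a_specific, hits_a, "dirtyspecific_vs_A")
  e_spec_b <- enr(cls$a_specific, hits_b, "dirtyspecific_vs_B")
  report$motif_enrichment <- list(
    common_factor_a_z = e_common_a$z, common_factor_b_z = e_common_b$z,
    dirty_specific_factor_a_z = e_spec_a$z,
    dirty_specific_factor_b_z = e_spec_b$z)

  ## 5. anchor enrichment: planted set vs random references
  set.seed(substream_seed(seed, "anchors"))
  # anchors centred on planted factor-B sites, clamped to the genome
  L <- sim$genome[as.character(GenomicRanges::seqnames(ab$b_sites))]
  anchors <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(ab$b_sites),
    IRanges::IRanges(pmax(GenomicRanges::start(ab$b_sites) - 300, 1),
                     pmin(GenomicRanges::end(ab$b_sites) + 300, L)))
  refsets <- lapply(seq_len(10), function(i)
    circular_permute(ab$b_sites, sim$genome))
  names(refsets) <- sprintf("random%02d", seq_len(10))
  sets <- c(list(planted = ab$b), refsets)
  anchor_tab <- anchor_enrichment_table(
    anchors, sets, reference_flags = c(FALSE, rep(TRUE, 10)),
    genome = sim$genome, n_perm = config$n_perm,
    seed = substream_seed(seed, "anchor_enrichment"))
  report$anchor_enrichment <- list(
    planted_relative_fold = anchor_tab$relative_fold[1],
    max_reference_relative_fold =
      max(anchor_tab$relative_fold[anchor_tab$is_reference]),
    planted_anchor_fraction = anchor_tab$anchor_fraction[1])

  ## 6. spike-in calibration on a synthetic sample table
  calib <- data.frame(
    sample_id = c("ctrl", "depleted", "rescue"),
    spike_pct = c(10, 10, 10),
    reads_target_total = c(2e7, 2e7, 1.5e7),
    reads_target_in_peaks = c(4e6, 1e6, 2.4e6),
    reads_spike_total = c(2e6, 2.2e6, 1.6e6),
    reads_spike_in_peaks = c(2e5, 2.4e5, 1.5e5))
  sf <- scaling_factors(calib)
  report$calibration <- list(sample_id = sf$sample_id,
                             absolute = sf$absolute, relative = sf$relative)

  ## 7. GC-bias diagnostic
  reads <- simulate_reads_gc(genome_seq, config$gc_reads,
                             bias = sim$gc_bias_strength,
                             seed = substream_seed(seed, "reads"))
  gcp <- gc_bias_profile(reads, genome_seq,
                         seed = substream_seed(seed, "gc_expected"))
  defined <- !is.na(gcp$table$ratio) & gcp$table$observed > 0
  mid <- (gcp$table$bin_lo + gcp$table$bin_hi) / 2
  gc_rho <- if (sum(defined) >= 3)
    suppressWarnings(stats::cor(mid[defined], gcp$table$ratio[defined],
                                method = "spearman")) else NA_real_
  report$gc_bias <- list(bias = sim$gc_bias_strength,
                         spearman_rho = gc_rho,
                         max_ratio = max(gcp$table$ratio[defined]),
                         min_ratio = min(gcp$table$ratio[defined]))

  ## 8. gene assignment on the planted annotation fixture
  annfix <- simulate_annotation(sim)
  ga <- assign_peaks_to_genes(annfix$peaks, annfix$annotation,
                              upstream = config$upstream,
                              downstream = config$downstream,
                              max_center_distance =
                                config$max_center_distance)
  report$gene_assignment <- list(
    n_bound_genes = nrow(ga$bound_genes),
    n_assigned_peaks = nrow(ga$assigned_peaks),
    n_bidirectional = sum(ga$assigned_peaks$bidirectional),
    n_discard_records = nrow(ga$discarded),
    matches_expected = identical(
      ga$bound_genes[order(ga$bound_genes$gene_id), ],
      annfix$expected$bound_genes[
        order(annfix$expected$bound_genes$gene_id), ]))

  ## 9. conserved sites across cell types
  datasets <- synthetic_compendium(ab$b_sites, 5L,
                                   substream_seed(seed, "conservation"),
                                   cell_types = paste0("ct", 1:3))
  names(datasets) <- sprintf("ds%02d", seq_along(datasets))
  ct_map <- setNames(vapply(datasets, function(d)
    S4Vectors::metadata(d)$cell_type, ""), names(datasets))
  cons <- conserved_sites(datasets, ct_map)
  report$conservation <- list(n_consensus = length(merge_union(datasets)),
                              n_conserved = length(cons))

  ## 10. deconvolution
  scfix <- simulate_sc_accessibility(sim)
  pb <- pseudobulk(scfix$sc_counts, scfix$cell_types)
  model <- fit_deconv(pb, k = sim$k_cell_types,
                      max_iter = config$ica_max_iter,
                      seed = substream_seed(seed, "ica"))
  prop <- estimate_proportions(model, scfix$bulk_counts)
  truth <- scfix$true_proportions[rownames(prop), colnames(prop)]
  mae <- mean(abs(prop - truth))
  per_type_cor <- vapply(colnames(prop), function(ct)
    stats::cor(prop[, ct], truth[, ct]), 0)
  report$deconvolution <- list(
    k = model$k, converged = model$converged,
    map_bijective = !anyDuplicated(model$component_cluster),
    mean_absolute_error = mae,
    mean_per_type_correlation = mean(per_type_cor))

  class(report) <- "pipeline_report"
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(unclass(report),
                         file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_bed(cls$common, file.path(outdir, "common.bed"))
    write_bed(cls$a_specific, file.path(outdir, "dirty_specific.bed"))
    write_bed(cls$b_specific, file.path(outdir, "clean_specific.bed"))
    write.table(anchor_tab, file.path(outdir, "anchor_enrichment.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(sf, file.path(outdir, "scaling_factors.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(gcp$table, file.path(outdir, "gc_bias.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(ga$bound_genes, file.path(outdir, "bound_genes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(as.data.frame(prop),
                file.path(outdir, "proportions.tsv"),
                sep = "\t", quote = FALSE)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report (seed", x$parameters$seed, ")\n")
  cat(sprintf("  cross-reactivity screen: median overlap clean %.3f, dirty %.3f\n",
              x$crossreactivity_screen$median_fraction_clean,
              x$crossreactivity_screen$median_fraction_dirty))
  cat(sprintf("  classification: common %d, dirty-specific %d (recovery %.3f)\n",
              x$classification$counts$common,
              x$classification$counts$a_specific,
              x$classification$crossreactive_recovery))
  cat(sprintf("  motif z: common~A %.1f, dirty-specific~B %.1f\n",
              x$motif_enrichment$common_factor_a_z,
              x$motif_enrichment$dirty_specific_factor_b_z))
  cat(sprintf("  anchors: planted relative fold %.2f (max reference %.2f)\n",
              x$anchor_enrichment$planted_relative_fold,
              x$anchor_enrichment$max_reference_relative_fold))
  cat(sprintf("  deconvolution: MAE %.3f, mean per-type r %.3f\n",
              x$deconvolution$mean_absolute_error,
              x$deconvolution$mean_per_type_correlation))
  invisible(x)
}
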