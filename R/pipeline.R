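#' Default pipeline configuration
#'
#' All numeric parameters of every stage, with the analysis defaults:
#' pseudocount 0.5 RPM, occupancy threshold 0 log2 units, minimum run of
#' 2 fragments, 100 shuffles, FDR threshold 1e-4 (0.01 %), gene-mapping
#' distance 5 kb, metaprofile flanks 10 kb (CRM-style) and 2 kb
#' (open-chromatin-style), accessibility quantile 0.95, DE thresholds
#' padj < 0.05 and |log2FC| > 1, FPKM threshold 2.
#'
#' @param ... Name = value overrides of any default.
#' @return A named list of class `PipelineConfig`.
#' @export
default_config <- function(...) {
  cfg <- list(pseudocount = 0.5, occupancy_threshold = 0, min_fragments = 2L,
              n_shuffles = 100L, fdr_threshold = 1e-4, max_distance = 5000,
              flank_crm = 10000L, flank_open = 2000L, bin_width = 200L,
              threshold_quantile = 0.95, padj_cutoff = 0.05, lfc_cutoff = 1.0,
              fpkm_threshold = 2.0, seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  .assert(length(unknown) == 0, "unknown config key: %s", unknown[1L])
  cfg[names(over)] <- over
  structure(cfg, class = "PipelineConfig")
}

#' Read a key = value configuration file
#'
#' Plain text, one `key = value` per line, `#` comments; unknown keys are
#' rejected.
#'
#' @param path Path to the file.
#' @return A `PipelineConfig`.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  .assert(all(lengths(kv) == 2L), "malformed config line: %s",
          lines[lengths(kv) != 2L][1L])
  vals <- lapply(kv, function(p) {
    v <- suppressWarnings(as.numeric(p[2L]))
    if (is.na(v)) p[2L] else v
  })
  do.call(default_config, stats::setNames(vals, vapply(kv, `[`, "", 1L)))
}

.header_lines <- function(cfg, stage) {
  c(sprintf("tadakit %s", as.character(utils::packageVersion("tadakit"))),
    sprintf("stage: %s", stage),
    sprintf("seed: %d", as.integer(cfg$seed)),
    sprintf("params: pseudocount=%g occupancy_threshold=%g min_fragments=%d n_shuffles=%d fdr_threshold=%g max_distance=%g",
            cfg$pseudocount, cfg$occupancy_threshold, cfg$min_fragments,
            cfg$n_shuffles, cfg$fdr_threshold, cfg$max_distance))
}

#' Run the full analysis pipeline on synthetic data
#'
#' Generates a genome, annotation, planted truth and replicate DamID
#' counts from `sim`, then chains every stage: occupancy-ratio tracks per
#' replicate, candidate peaks, shuffle-null FDR, significance filtering,
#' replicate intersection, gene assignment, feature classification,
#' CATaDa accessible regions, the open-chromatin metaprofile,
#' chromatin-state enrichment, binding--accessibility correlation, and a
#' DE/bound overlap report on a simulated DE table.  Every output file
#' carries a `#` header recording version, parameters and seed; re-running
#' with the same configuration and seed reproduces the files byte for
#' byte.
#'
#' @param config A [default_config()].
#' @param outdir Output directory (created if needed).
#' @param sim A [sim_config()] describing the synthetic inputs.
#' @return Invisibly, a list with the main in-memory results (`final`,
#'   `assignments`, `features`, `accessible`, `correlation`, `report`,
#'   `truth`) and the output paths.
#' @export
run_pipeline <- function(config = default_config(), outdir, sim = sim_config()) {
  .assert(inherits(config, "PipelineConfig"), "config must be a PipelineConfig")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  message(sprintf("[tadakit] simulate: seed=%d", seed))
  gen <- simulate_genome(sim, seed)
  fragments <- gen$fragments
  genes <- simulate_annotation(sim, fragments, seed)
  truth <- simulate_truth(sim, fragments, seed)
  reps <- simulate_damid(truth, fragments)
  message(sprintf("[tadakit] fragments: %d; genes: %d; replicates: %d",
                  length(fragments), length(genes), length(reps)))

  sig_sets <- vector("list", length(reps))
  tracks <- vector("list", length(reps))
  for (r in seq_along(reps)) {
    tr <- occupancy_ratio(reps[[r]]$fusion, reps[[r]]$control,
                          pseudocount = config$pseudocount)
    tracks[[r]] <- tr
    cand <- call_candidate_peaks(tr, config$occupancy_threshold, config$min_fragments)
    cand <- estimate_fdr(cand, tr, n_shuffles = config$n_shuffles,
                         seed = sub_seed(seed, paste0("fdr:rep", r)))
    sig_sets[[r]] <- filter_significant(cand, config$fdr_threshold)
    message(sprintf("[tadakit] rep%d: candidates=%d significant=%d",
                    r, length(cand), length(sig_sets[[r]])))
    write_bedgraph(tr, file.path(outdir, sprintf("occupancy_rep%d.bedgraph", r)),
                   header = .header_lines(config, sprintf("occupancy rep%d", r)))
  }
  final <- Reduce(intersect_replicates, sig_sets)
  message(sprintf("[tadakit] final peaks: %d", length(final)))
  write_peaks_bed(final, file.path(outdir, "final_peaks.bed"),
                  header = .header_lines(config, "final peaks"))
  for (r in seq_along(sig_sets))
    write_peak_table(sig_sets[[r]],
                     file.path(outdir, sprintf("significant_rep%d.tsv", r)),
                     header = .header_lines(config, sprintf("significant rep%d", r)))

  assignments <- assign_genes(final, genes, config$max_distance)
  write_assignments(assignments, file.path(outdir, "gene_assignments.tsv"),
                    header = .header_lines(config, "gene assignment"))
  features <- classify_features(final, genes)
  fcon <- file(file.path(outdir, "feature_breakdown.tsv"), "w")
  writeLines(paste0("# ", .header_lines(config, "feature breakdown")), fcon)
  writeLines("feature\tcount\tfraction", fcon)
  writeLines(paste(features$levels, features$counts,
                   sprintf("%.6g", features$fractions), sep = "\t"), fcon)
  close(fcon)

  access_rpm <- rpm_normalize(reps[[1L]]$control)
  accessible <- call_accessible_regions(access_rpm, config$threshold_quantile,
                                        config$min_fragments)
  write_bed(GenomicRanges::granges(accessible),
            file.path(outdir, "accessible_regions.bed"),
            header = .header_lines(config, "accessible regions"))
  profile <- metaprofile(tracks[[1L]], accessible, flank = config$flank_open,
                         bin_width = config$bin_width)
  write_metaprofile(profile, file.path(outdir, "open_chromatin_matrix.tsv"),
                    file.path(outdir, "open_chromatin_profile.tsv"),
                    header = .header_lines(config, "open-chromatin metaprofile"))
  states <- simulate_states(fragments, seed)
  enr <- state_enrichment(tracks[[1L]], states)
  utils::write.table(format(enr, digits = 7),
                     file.path(outdir, "state_enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  correlation <- binding_accessibility_correlation(tracks[[1L]], access_rpm)
  message(sprintf("[tadakit] binding-accessibility Spearman r = %.3f", correlation))

  universe <- S4Vectors::mcols(genes)$gene_id
  bound <- unique(assignments$gene_id)
  # size the simulated DE set so the 75 % bound target stays feasible
  n_de <- min(20L, floor(length(bound) / 2), floor(length(universe) / 4))
  if (n_de >= 2L) {
    de_tab <- simulate_de_table(bound, universe, target_bound_fraction = 0.75,
                                n_up = n_de, n_down = n_de, seed = seed)
    de <- classify_de(de_tab, config$padj_cutoff, config$lfc_cutoff)
    report <- bound_de_overlap_report(bound, de$up, de$down, universe)
  } else {
    message("[tadakit] too few bound genes for a DE overlap report")
    report <- list(up_bound_fraction = NA_real_, down_bound_fraction = NA_real_)
  }

  scon <- file(file.path(outdir, "summary.txt"), "w")
  writeLines(paste0("# ", .header_lines(config, "summary")), scon)
  writeLines(sprintf("fragments\t%d", length(fragments)), scon)
  writeLines(sprintf("genes\t%d", length(genes)), scon)
  writeLines(sprintf("final_peaks\t%d", length(final)), scon)
  writeLines(sprintf("assigned_genes\t%d", length(bound)), scon)
  writeLines(sprintf("accessible_regions\t%d", length(accessible)), scon)
  writeLines(sprintf("binding_accessibility_spearman\t%.6g", correlation), scon)
  writeLines(sprintf("up_bound_fraction\t%.6g", report$up_bound_fraction), scon)
  writeLines(sprintf("down_bound_fraction\t%.6g", report$down_bound_fraction), scon)
  close(scon)

  invisible(list(fragments = fragments, genes = genes, truth = truth,
                 tracks = tracks, significant = sig_sets, final = final,
                 assignments = assignments, features = features,
                 accessible = accessible, correlation = correlation,
                 report = report, outdir = outdir))
}
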