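#' Call accessible chromatin regions from a Dam-only RPM track
#'
#' CATaDa: untethered Dam methylation marks open chromatin, so the
#' Dam-only control doubles as an accessibility assay.  Accessible regions
#' are maximal runs of at least `min_fragments` fragments whose RPM
#' strictly exceeds the genome-wide `threshold_quantile` quantile
#' (computed over non-missing fragments).
#'
#' @param dam_only_rpm An RPM [fragment_track()].
#' @param threshold_quantile Quantile in (0, 1) defining the threshold
#'   (default 0.95).
#' @param min_fragments Minimum run length (default 2).
#' @return A `GRanges` of accessible regions snapped to fragment
#'   boundaries, with the threshold recorded in `metadata()`.
#' @export
call_accessible_regions <- function(dam_only_rpm, threshold_quantile = 0.95,
                                    min_fragments = 2L) {
  .assert(inherits(dam_only_rpm, "FragmentTrack"), "input must be a FragmentTrack")
  .assert(threshold_quantile > 0 && threshold_quantile < 1,
          "threshold_quantile must be in (0, 1)")
  v <- dam_only_rpm$values
  nz <- v[!is.na(v)]
  .assert(length(unique(nz)) > 1,
          "all fragment values are equal; the quantile threshold cannot separate runs")
  thr <- unname(quantile(nz, threshold_quantile))
  fr <- dam_only_rpm$fragments
  chrom <- as.character(GenomeInfoDb::seqnames(fr))
  ok <- !is.na(v) & v > thr
  runs <- .scan_runs(chrom, ok, as.integer(min_fragments), v)
  out <- GenomicRanges::GRanges(chrom[runs$first],
    IRanges::IRanges(BiocGenerics::start(fr)[runs$first],
                     BiocGenerics::end(fr)[runs$last]))
  S4Vectors::mcols(out)$n_fragments <- runs$len
  S4Vectors::mcols(out)$mean_rpm <- runs$mean
  S4Vectors::metadata(out) <- list(threshold_quantile = threshold_quantile,
                                   threshold_rpm = thr,
                                   min_fragments = as.integer(min_fragments))
  out
}

#' Average signal profile around region centres
#'
#' Projects a fragment track onto fixed-width bins centred on each
#' region's midpoint (floor of the coordinate mean), out to `flank` bp on
#' either side.  Each bin's value is the length-weighted mean of the
#' non-missing fragment values it overlaps; bins entirely off-chromosome
#' or without any covered non-missing base are missing.  The mean profile
#' is the column-wise mean ignoring missing entries.  Typical flanks:
#' 10 kb around cis-regulatory modules, 2 kb around open-chromatin
#' regions.
#'
#' @param track A [fragment_track()].
#' @param regions A `GRanges` of regions.
#' @param flank Flank size in bp on each side of the centre.
#' @param bin_width Bin width in bp; `flank` must be a multiple of it.
#' @return A list of class `MetaProfile`: `matrix` (regions x bins),
#'   `bin_centres` (bp relative to the region centre), `mean_profile`,
#'   `flank`, `bin_width`.
#' @export
metaprofile <- function(track, regions, flank = 10000L, bin_width = 200L) {
  .assert(inherits(track, "FragmentTrack"), "track must be a FragmentTrack")
  .assert(length(regions) > 0, "region set is empty")
  .assert(flank %% bin_width == 0, "flank must be a multiple of bin_width")
  n_bins <- as.integer(2 * flank / bin_width)
  fr <- track$fragments
  fchrom <- as.character(GenomeInfoDb::seqnames(fr))
  fs0 <- BiocGenerics::start(fr) - 1L; fe0 <- BiocGenerics::end(fr)
  sl <- GenomeInfoDb::seqlengths(fr)
  rchrom <- as.character(GenomeInfoDb::seqnames(regions))
  centre0 <- floor((BiocGenerics::start(regions) - 1 + BiocGenerics::end(regions)) / 2)
  mat <- matrix(NA_real_, nrow = length(regions), ncol = n_bins)
  for (r in seq_along(regions)) {
    w_lo <- centre0[r] - flank            # 0-based window [w_lo, w_hi)
    w_hi <- centre0[r] + flank
    on_chrom <- which(fchrom == rchrom[r] & fe0 > w_lo & fs0 < w_hi &
                        !is.na(track$values))
    if (length(on_chrom) == 0L) next
    chrom_len <- if (rchrom[r] %in% names(sl) && !is.na(sl[[rchrom[r]]]))
      sl[[rchrom[r]]] else Inf
    for (b in seq_len(n_bins)) {
      b_lo <- w_lo + (b - 1L) * bin_width
      b_hi <- b_lo + bin_width
      if (b_hi <= 0 || b_lo >= chrom_len) next   # bin entirely off-chromosome
      lo <- pmax(fs0[on_chrom], max(b_lo, 0))
      hi <- pmin(fe0[on_chrom], min(b_hi, chrom_len))
      w <- pmax(hi - lo, 0)
      mat[r, b] <- .wmean(track$values[on_chrom], w)
    }
  }
  structure(list(matrix = mat,
                 bin_centres = seq(-flank + bin_width / 2, flank - bin_width / 2,
                                   by = bin_width),
                 mean_profile = colMeans(mat, na.rm = TRUE),
                 flank = flank, bin_width = bin_width),
            class = "MetaProfile")
}

#' @export
print.MetaProfile <- function(x, ...) {
  cat(sprintf("MetaProfile: %d regions x %d bins (flank %d bp, bin %d bp)\n",
              nrow(x$matrix), ncol(x$matrix), x$flank, x$bin_width))
  invisible(x)
}

#' Write a metaprofile matrix and mean profile
#'
#' @param profile A [metaprofile()] result.
#' @param matrix_path,mean_path Output paths (tab-delimited).
#' @param header Optional comment lines.
#' @export
write_metaprofile <- function(profile, matrix_path, mean_path, header = NULL) {
  con <- file(matrix_path, "w")
  if (length(header)) writeLines(paste0("# ", header), con)
  writeLines(paste(c("region", profile$bin_centres), collapse = "\t"), con)
  for (r in seq_len(nrow(profile$matrix)))
    writeLines(paste(c(r, ifelse(is.na(profile$matrix[r, ]), "NA",
                                 sprintf("%.6g", profile$matrix[r, ]))),
                     collapse = "\t"), con)
  close(con)
  con <- file(mean_path, "w")
  if (length(header)) writeLines(paste0("# ", header), con)
  writeLines("bin_centre\tmean_signal", con)
  writeLines(paste(profile$bin_centres,
                   ifelse(is.na(profile$mean_profile), "NA",
                          sprintf("%.6g", profile$mean_profile)), sep = "\t"), con)
  close(con)
  invisible(matrix_path)
}

#' Order metaprofile rows for heatmap display
#'
#' Rows sorted by descending mean row signal (missing-last); a
#' deterministic display order.
#'
#' @param profile A [metaprofile()] result.
#' @return The row order (integer vector).
#' @export
heatmap_order <- function(profile) {
  rm <- rowMeans(profile$matrix, na.rm = TRUE)
  order(-rm, seq_along(rm))
}

#' Mean signal per chromatin state
#'
#' Computes the length-weighted mean of fragment values within each
#' labelled state (e.g. the published colour scheme including "black"
#' chromatin), and each state's enrichment relative to the genome-wide
#' (length-weighted) mean.  On a log2 occupancy track a positive
#' enrichment marks states where binding is concentrated.
#'
#' @param track A [fragment_track()].
#' @param states A `GRanges` with a `label` metadata column; intervals may
#'   abut but not overlap.
#' @return A data.frame with columns `state`, `mean_signal`, `enrichment`
#'   (state mean minus genome-wide mean); states covering no non-missing
#'   fragment get `NA`.
#' @export
state_enrichment <- function(track, states) {
  .assert(inherits(track, "FragmentTrack"), "track must be a FragmentTrack")
  labels <- S4Vectors::mcols(states)$label
  .assert(!is.null(labels) && all(nzchar(labels)), "states must carry non-empty labels")
  cov <- GenomicRanges::coverage(states)
  if (any(vapply(cov, function(x) any(S4Vectors::runValue(x) > 1), logical(1))))
    .fail("state intervals overlap")
  fr <- track$fragments
  genome_mean <- .wmean(track$values, BiocGenerics::width(fr))
  hits <- GenomicRanges::findOverlaps(states, fr, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::pintersect(GenomicRanges::granges(states)[qi],
                                  GenomicRanges::granges(fr)[si])
  w <- BiocGenerics::width(ov)
  v <- track$values[si]
  out <- data.frame(state = sort(unique(labels)), mean_signal = NA_real_,
                    enrichment = NA_real_)
  for (i in seq_len(nrow(out))) {
    sel <- labels[qi] == out$state[i]
    out$mean_signal[i] <- .wmean(v[sel], w[sel])
  }
  out$enrichment <- out$mean_signal - genome_mean
  attr(out, "genome_mean") <- genome_mean
  out
}
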