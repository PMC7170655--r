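#' Per-fragment read counts
#'
#' Container for raw DamID counts on a GATC fragment map.  `total_reads`
#' defaults to the column sum but may exceed it when the sequencing run
#' contained reads not assigned to any fragment.
#'
#' @param fragments Fragment map `GRanges`.
#' @param counts Non-negative integer counts, one per fragment.
#' @param total_reads Library size used for RPM normalisation.
#' @return An object of class `CountTrack`.
#' @export
count_track <- function(fragments, counts, total_reads = sum(counts)) {
  .assert(length(counts) == length(fragments),
          "counts length (%d) != fragment count (%d)", length(counts), length(fragments))
  .assert(all(counts >= 0) && !anyNA(counts), "counts must be non-negative and complete")
  structure(list(fragments = fragments, counts = as.numeric(counts),
                 total_reads = as.numeric(total_reads)),
            class = "CountTrack")
}

#' Per-fragment real-valued signal
#'
#' Container for RPM or log2 occupancy-ratio values on a fragment map.
#' `NA` marks missing fragments (no data in any contributing sample);
#' missing fragments are excluded from peak calling, correlations and
#' profiles.
#'
#' @param fragments Fragment map `GRanges`.
#' @param values Numeric values, `NA` = missing.
#' @param units `"log2_ratio"`, `"rpm"`, or another unit string.
#' @param params Optional named list of provenance parameters.
#' @return An object of class `FragmentTrack`.
#' @export
fragment_track <- function(fragments, values, units = "value", params = list()) {
  .assert(length(values) == length(fragments),
          "values length (%d) != fragment count (%d)", length(values), length(fragments))
  .assert(all(is.finite(values) | is.na(values)), "non-missing values must be finite")
  structure(list(fragments = fragments, values = as.numeric(values),
                 units = units, params = params),
            class = "FragmentTrack")
}

#' @export
print.FragmentTrack <- function(x, ...) {
  cat(sprintf("FragmentTrack: %d fragments, units=%s, %d missing\n",
              length(x$values), x$units, sum(is.na(x$values))))
  invisible(x)
}

#' @export
print.CountTrack <- function(x, ...) {
  cat(sprintf("CountTrack: %d fragments, total_reads=%g\n",
              length(x$counts), x$total_reads))
  invisible(x)
}

.same_map <- function(a, b) {
  la <- if (inherits(a, "CountTrack")) length(a$counts) else length(a$values)
  lb <- if (inherits(b, "CountTrack")) length(b$counts) else length(b$values)
  .assert(la == lb, "tracks are on different fragment maps (%d vs %d fragments)", la, lb)
}

#' Reads-per-million normalisation
#'
#' Scales counts to reads per million: `value_i = count_i * 1e6 /
#' total_reads`.  This is the normalisation applied to Dam-only (CATaDa)
#' accessibility data before comparison across samples.
#'
#' @param counts A [count_track()].
#' @return A [fragment_track()] in RPM units (no missing values).
#' @export
rpm_normalize <- function(counts) {
  .assert(inherits(counts, "CountTrack"), "counts must be a CountTrack")
  .assert(counts$total_reads > 0, "total_reads must be positive")
  fragment_track(counts$fragments, counts$counts * 1e6 / counts$total_reads,
                 units = "rpm",
                 params = list(total_reads = counts$total_reads))
}

#' Log2 occupancy ratio of a Dam-fusion sample over the Dam-only control
#'
#' The binding signal of Targeted DamID: each fragment's value is
#' `log2((rpm_fusion + pseudocount) / (rpm_control + pseudocount))`.
#' Fragments with zero counts in both samples carry no information and are
#' flagged missing.  Because the fusion signal is normalised against the
#' Dam-only control, negative values ("negative peaks") are expected where
#' background Dam methylation exceeds the fusion signal.
#'
#' @param fusion,control [count_track()] objects on the same fragment map.
#' @param pseudocount Pseudocount in RPM units added to both terms
#'   (default 0.5); recorded in the track's `params`.
#' @return A [fragment_track()] in log2-ratio units.
#' @export
occupancy_ratio <- function(fusion, control, pseudocount = 0.5) {
  .assert(inherits(fusion, "CountTrack") && inherits(control, "CountTrack"),
          "fusion and control must be CountTracks")
  .same_map(fusion, control)
  .assert(pseudocount > 0, "pseudocount must be positive")
  rf <- rpm_normalize(fusion)$values
  rc <- rpm_normalize(control)$values
  v <- log2((rf + pseudocount) / (rc + pseudocount))
  v[fusion$counts == 0 & control$counts == 0] <- NA_real_
  fragment_track(fusion$fragments, v, units = "log2_ratio",
                 params = list(pseudocount = pseudocount))
}

#' Spearman concordance of two fragment tracks
#'
#' Rank correlation over the jointly non-missing fragments, with average
#' ranks for ties -- the replicate-concordance statistic (biological
#' replicates of the same cell stage are expected around r = 0.9).
#'
#' @param track_a,track_b [fragment_track()] objects on the same map.
#' @return Spearman's rank correlation coefficient in `[-1, 1]`.
#' @export
replicate_concordance <- function(track_a, track_b) {
  .assert(inherits(track_a, "FragmentTrack") && inherits(track_b, "FragmentTrack"),
          "inputs must be FragmentTracks")
  .same_map(track_a, track_b)
  keep <- !is.na(track_a$values) & !is.na(track_b$values)
  .assert(sum(keep) >= 3L, "need at least 3 jointly non-missing fragments (have %d)",
          sum(keep))
  cor(track_a$values[keep], track_b$values[keep], method = "spearman")
}

#' Spearman correlation of binding with chromatin accessibility
#'
#' Correlates a log2 occupancy track with a Dam-only RPM accessibility
#' track per GATC fragment.  A negative value indicates that binding is
#' preferentially found in inaccessible chromatin.
#'
#' @param binding Log2 occupancy [fragment_track()].
#' @param accessibility RPM accessibility [fragment_track()].
#' @return Spearman's rank correlation coefficient in `[-1, 1]`.
#' @export
binding_accessibility_correlation <- function(binding, accessibility) {
  replicate_concordance(binding, accessibility)
}
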