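#' Detect candidate broadly bound regions
#'
#' A candidate peak is a maximal run of at least `min_fragments` consecutive
#' non-missing GATC fragments whose occupancy exceeds `occupancy_threshold`.
#' Missing fragments and chromosome boundaries break runs.  Peak coordinates
#' span the first member fragment's start to the last member's end;
#' `mean_occupancy` is the unweighted mean of member fragment values.
#' A single enriched fragment never forms a peak when `min_fragments >= 2`.
#'
#' @param track A log2 occupancy [fragment_track()].
#' @param occupancy_threshold Log2 threshold a fragment must exceed
#'   (strictly) to join a run; default 0 (any enrichment of fusion over
#'   control).
#' @param min_fragments Minimum run length; default 2 (a peak is formed of
#'   two or more consecutive GATC fragments).
#' @return A `GRanges` with metadata columns `n_fragments`,
#'   `mean_occupancy`, and `fdr` (unset, `NA`); calling parameters are kept
#'   in `metadata()`.
#' @export
call_candidate_peaks <- function(track, occupancy_threshold = 0, min_fragments = 2L) {
  .assert(inherits(track, "FragmentTrack"), "track must be a FragmentTrack")
  .assert(min_fragments >= 1, "min_fragments must be >= 1")
  fr <- track$fragments
  .assert(length(fr) == length(track$values), "track/fragment map mismatch")
  chrom <- as.character(GenomeInfoDb::seqnames(fr))
  ok <- !is.na(track$values) & track$values > occupancy_threshold
  runs <- .scan_runs(chrom, ok, as.integer(min_fragments), track$values)
  pk <- GenomicRanges::GRanges(
    chrom[runs$first],
    IRanges::IRanges(start = BiocGenerics::start(fr)[runs$first],
                     end = BiocGenerics::end(fr)[runs$last]))
  S4Vectors::mcols(pk)$n_fragments <- runs$len
  S4Vectors::mcols(pk)$mean_occupancy <- runs$mean
  S4Vectors::mcols(pk)$fdr <- rep(NA_real_, length(pk))
  S4Vectors::metadata(pk) <- list(occupancy_threshold = occupancy_threshold,
                                  min_fragments = as.integer(min_fragments))
  pk
}

# Pooled (length, mean) statistics of peaks re-detected in shuffled tracks.
.null_peak_stats <- function(chrom, values, nm_idx, occupancy_threshold,
                             min_fragments, n_shuffles) {
  pool_n <- vector("list", n_shuffles)
  pool_m <- vector("list", n_shuffles)
  vals <- values[nm_idx]
  shuffled <- values
  for (s in seq_len(n_shuffles)) {
    shuffled[nm_idx] <- sample(vals)
    ok <- !is.na(shuffled) & shuffled > occupancy_threshold
    runs <- .scan_runs(chrom, ok, min_fragments, shuffled)
    pool_n[[s]] <- runs$len
    pool_m[[s]] <- runs$mean
  }
  list(n = unlist(pool_n), m = unlist(pool_m))
}

#' Assign permutation-null false discovery rates to candidate peaks
#'
#' The null model permutes the non-missing fragment values uniformly at
#' random across the non-missing fragment positions, `n_shuffles` times,
#' and re-detects peaks in each permutation with the same threshold and
#' minimum run length.  For an observed peak with `n` fragments and mean
#' occupancy `m`, the FDR is the expected number of null peaks at least as
#' extreme in both statistics (run length >= n AND mean >= m, ties
#' inclusive) divided by the number of observed peaks at least as extreme,
#' clipped to `[0, 1]`.  Deterministic given `seed`.
#'
#' @param candidates Candidate peaks from [call_candidate_peaks()] on this
#'   track.
#' @param track The [fragment_track()] the candidates came from.
#' @param n_shuffles Number of permutations (default 100; use >= 10 for
#'   production).
#' @param seed Integer seed for the permutation stream (mandatory).
#' @param occupancy_threshold,min_fragments Detection parameters; default
#'   to those recorded on `candidates`.
#' @return `candidates` with the `fdr` column filled in.
#' @export
estimate_fdr <- function(candidates, track, n_shuffles = 100L, seed,
                         occupancy_threshold = NULL, min_fragments = NULL) {
  .assert(inherits(track, "FragmentTrack"), "track must be a FragmentTrack")
  .assert(n_shuffles >= 1, "n_shuffles must be >= 1")
  .assert(!missing(seed), "seed is mandatory")
  meta <- S4Vectors::metadata(candidates)
  if (is.null(occupancy_threshold)) occupancy_threshold <- meta$occupancy_threshold
  if (is.null(min_fragments)) min_fragments <- meta$min_fragments
  .assert(!is.null(occupancy_threshold) && !is.null(min_fragments),
          "detection parameters not found on candidates; pass them explicitly")
  if (length(candidates) == 0L) return(candidates)
  chrom <- as.character(GenomeInfoDb::seqnames(track$fragments))
  nm_idx <- which(!is.na(track$values))
  obs_n <- S4Vectors::mcols(candidates)$n_fragments
  obs_m <- S4Vectors::mcols(candidates)$mean_occupancy
  set.seed(as.integer(seed))
  null_stats <- .null_peak_stats(chrom, track$values, nm_idx,
                                 occupancy_threshold, as.integer(min_fragments),
                                 as.integer(n_shuffles))
  null_tail <- .tail_counts(obs_n, obs_m, null_stats$n, null_stats$m)
  obs_tail <- .tail_counts(obs_n, obs_m, obs_n, obs_m)
  fdr <- pmin(pmax((null_tail / n_shuffles) / obs_tail, 0), 1)
  S4Vectors::mcols(candidates)$fdr <- fdr
  md <- S4Vectors::metadata(candidates)
  md$n_shuffles <- as.integer(n_shuffles)
  md$seed <- as.integer(seed)
  S4Vectors::metadata(candidates) <- md
  candidates
}

#' Filter peaks at an FDR threshold
#'
#' Retains peaks with `fdr` strictly below the threshold (the printed rule
#' "less than a 0.01% FDR" -- an FDR exactly equal to the threshold is not
#' significant), sorts them, and merges book-ended peaks that share a
#' fragment boundary.  A merged peak's `n_fragments` is the member sum, its
#' `mean_occupancy` the fragment-count-weighted mean, and its `fdr` the
#' member minimum.
#'
#' @param peaks Peaks with `fdr` set (see [estimate_fdr()]).
#' @param fdr_threshold Significance threshold as a fraction; default
#'   `1e-4` (= 0.01 %).
#' @return A sorted, non-overlapping significant `PeakSet` (`GRanges`).
#' @export
filter_significant <- function(peaks, fdr_threshold = 1e-4) {
  fdr <- S4Vectors::mcols(peaks)$fdr
  .assert(!is.null(fdr) && !anyNA(fdr), "all peaks must have fdr set")
  keep <- peaks[fdr < fdr_threshold]
  if (length(keep) == 0L) return(keep)
  o <- order(as.character(GenomeInfoDb::seqnames(keep)), BiocGenerics::start(keep))
  keep <- keep[o]
  chrom <- as.character(GenomeInfoDb::seqnames(keep))
  n <- length(keep)
  # merge chains of book-ended peaks: next start == this end + 1, same chrom
  joined <- c(FALSE, chrom[-1L] == chrom[-n] &
                BiocGenerics::start(keep)[-1L] == BiocGenerics::end(keep)[-n] + 1L)
  grp <- cumsum(!joined)
  mc <- S4Vectors::mcols(keep)
  nf <- as.vector(rowsum(mc$n_fragments, grp))
  mo <- as.vector(rowsum(mc$mean_occupancy * mc$n_fragments, grp)) / nf
  fd <- vapply(split(mc$fdr, grp), min, numeric(1))
  first <- !duplicated(grp)
  last <- rev(!duplicated(rev(grp)))
  out <- GenomicRanges::GRanges(chrom[first],
    IRanges::IRanges(BiocGenerics::start(keep)[first], BiocGenerics::end(keep)[last]))
  S4Vectors::mcols(out)$n_fragments <- nf
  S4Vectors::mcols(out)$mean_occupancy <- mo
  S4Vectors::mcols(out)$fdr <- unname(fd)
  md <- S4Vectors::metadata(peaks)
  md$fdr_threshold <- fdr_threshold
  S4Vectors::metadata(out) <- md
  out
}

#' Final peaks present in both replicates
#'
#' Builds the overlap graph between the significant peaks of two
#' replicates (an edge is >= 1 bp of overlap) and emits one final peak per
#' connected component that contains at least one peak from each
#' replicate; the final interval is the union span of the component.
#' Final peaks carry no FDR.
#'
#' @param rep1,rep2 Significant `PeakSet`s from [filter_significant()].
#' @return A sorted `GRanges` of final peaks with a `n_fragments` column
#'   (member sum across the component).
#' @export
intersect_replicates <- function(rep1, rep2) {
  n1 <- length(rep1); n2 <- length(rep2)
  if (n1 == 0L || n2 == 0L) return(GenomicRanges::GRanges())
  combined <- c(GenomicRanges::granges(rep1), GenomicRanges::granges(rep2))
  src <- rep(1:2, c(n1, n2))
  hits <- GenomicRanges::findOverlaps(combined, combined, minoverlap = 1L)
  # union-find over overlap edges
  parent <- seq_len(n1 + n2)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_along(hits)) {
    a <- find(S4Vectors::queryHits(hits)[k]); b <- find(S4Vectors::subjectHits(hits)[k])
    if (a != b) parent[b] <- a
  }
  comp <- vapply(seq_len(n1 + n2), find, integer(1))
  both <- intersect(unique(comp[src == 1]), unique(comp[src == 2]))
  if (length(both) == 0L) return(GenomicRanges::GRanges())
  chrom <- as.character(GenomeInfoDb::seqnames(combined))
  spans <- lapply(both, function(cc) {
    i <- which(comp == cc)
    c(min(BiocGenerics::start(combined)[i]), max(BiocGenerics::end(combined)[i]))
  })
  out <- GenomicRanges::GRanges(chrom[match(both, comp)],
    IRanges::IRanges(vapply(spans, `[`, numeric(1), 1L),
                     vapply(spans, `[`, numeric(1), 2L)))
  o <- order(as.character(GenomeInfoDb::seqnames(out)), BiocGenerics::start(out))
  out <- out[o]
  S4Vectors::metadata(out) <- list(replicates = 2L)
  out
}

#' Write peaks as BED6
#'
#' The BED score is `-10 * log10(max(fdr, 1e-10))` capped at 1000; final
#' peaks without an FDR get score 0.  Peak names are `peak_1`, `peak_2`,
#' ... in sorted order.
#'
#' @param peaks A `GRanges` of peaks.
#' @param path Output path.
#' @param header Optional comment lines.
#' @export
write_peaks_bed <- function(peaks, path, header = NULL) {
  fdr <- S4Vectors::mcols(peaks)$fdr
  score <- if (is.null(fdr) || all(is.na(fdr))) rep(0, length(peaks)) else
    pmin(round(-10 * log10(pmax(fdr, 1e-10)), 1), 1000)
  o <- order(as.character(GenomeInfoDb::seqnames(peaks)), BiocGenerics::start(peaks))
  gr <- GenomicRanges::granges(peaks)[o]
  S4Vectors::mcols(gr)$label <- paste0("peak_", seq_along(gr))
  S4Vectors::mcols(gr)$score <- score[o]
  BiocGenerics::strand(gr) <- "*"
  write_bed(gr, path, header = header)
}

#' Write a peak table
#'
#' Tab-delimited with 0-based half-open coordinates, `n_fragments`,
#' `mean_occupancy` and `fdr`.
#'
#' @param peaks A `GRanges` of peaks.
#' @param path Output path.
#' @param header Optional comment lines.
#' @export
write_peak_table <- function(peaks, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  writeLines("chrom\tstart\tend\tn_fragments\tmean_occupancy\tfdr", con)
  mc <- S4Vectors::mcols(peaks)
  fdr <- if ("fdr" %in% colnames(mc)) mc$fdr else rep(NA_real_, length(peaks))
  mo <- if ("mean_occupancy" %in% colnames(mc)) mc$mean_occupancy else rep(NA_real_, length(peaks))
  writeLines(paste(as.character(GenomeInfoDb::seqnames(peaks)),
                   BiocGenerics::start(peaks) - 1L, BiocGenerics::end(peaks),
                   mc$n_fragments, sprintf("%.6g", mo),
                   ifelse(is.na(fdr), "NA", sprintf("%.6g", fdr)), sep = "\t"), con)
  invisible(path)
}
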