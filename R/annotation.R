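#' Assign peaks to putatively regulated genes
#'
#' A gene is assigned to a peak when (a) its span overlaps the peak
#' (distance 0), or (b) the edge-to-edge gap between peak and gene is at
#' most `max_distance` (default 5 kb) AND no other gene's span lies
#' entirely within that gap -- the "no intervening genes" rule.  A gene
#' partially overlapping the gap does not block the assignment.  One peak
#' may yield several genes and one gene several peaks; pairs are
#' deduplicated.
#'
#' @param peaks A `GRanges` of (final) peaks.
#' @param genes Gene models from [gene_models()] / [read_annotation()].
#' @param max_distance Maximum edge-to-edge gap in bp (default 5000).
#' @return A data.frame with columns `peak_id` (index into the sorted
#'   peaks), `gene_id`, `distance` (bp, 0 for overlap).
#' @export
assign_genes <- function(peaks, genes, max_distance = 5000) {
  .assert(max_distance >= 0, "max_distance must be non-negative")
  if (length(peaks) == 0L || length(genes) == 0L)
    return(data.frame(peak_id = integer(0), gene_id = character(0),
                      distance = numeric(0)))
  o <- order(as.character(GenomeInfoDb::seqnames(peaks)), BiocGenerics::start(peaks))
  peaks <- peaks[o]
  hits <- GenomicRanges::findOverlaps(GenomicRanges::granges(peaks),
                                      GenomicRanges::granges(genes),
                                      maxgap = max_distance, ignore.strand = TRUE)
  if (length(hits) == 0L)
    return(data.frame(peak_id = integer(0), gene_id = character(0),
                      distance = numeric(0)))
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  gs <- BiocGenerics::start(genes); ge <- BiocGenerics::end(genes)
  gchrom <- as.character(GenomeInfoDb::seqnames(genes))
  ps <- BiocGenerics::start(peaks)[qi]; pe <- BiocGenerics::end(peaks)[qi]
  d <- GenomicRanges::distance(GenomicRanges::granges(peaks)[qi],
                               GenomicRanges::granges(genes)[si],
                               ignore.strand = TRUE)
  ok <- vapply(seq_along(qi), function(k) {
    if (d[k] == 0) return(TRUE)
    # open gap between nearest edges, 1-based closed
    if (gs[si[k]] > pe[k]) { lo <- pe[k] + 1L; hi <- gs[si[k]] - 1L }
    else { lo <- ge[si[k]] + 1L; hi <- ps[k] - 1L }
    blockers <- gchrom == gchrom[si[k]] & gs >= lo & ge <= hi
    blockers[si[k]] <- FALSE
    !any(blockers)
  }, logical(1))
  out <- data.frame(peak_id = qi[ok],
                    gene_id = S4Vectors::mcols(genes)$gene_id[si[ok]],
                    distance = as.numeric(d[ok]))
  out <- unique(out)
  out[order(out$peak_id, out$gene_id), , drop = FALSE]
}

#' Classify peaks by genomic feature
#'
#' Each peak is classified by its midpoint with priority
#' promoter-TSS > TTS > exon > intron > intergenic.  The promoter window is
#' strand-aware around the transcription start site (default 1 kb upstream
#' to 100 bp downstream); the TTS window is symmetric (default +/- 100 bp).
#' Genes without exon annotation count as single-exon.
#'
#' @param peaks A `GRanges` of peaks.
#' @param genes Gene models.
#' @param promoter_window `c(upstream_bp, downstream_bp)` around the TSS.
#' @param tts_window Half-width in bp around the TTS.
#' @return A list with `categories` (per-peak factor), `counts` and
#'   `fractions` over promoter-TSS, TTS, exon, intron, intergenic.
#' @export
classify_features <- function(peaks, genes,
                              promoter_window = c(1000, 100), tts_window = 100) {
  cats <- c("promoter-TSS", "TTS", "exon", "intron", "intergenic")
  mid <- floor((BiocGenerics::start(peaks) - 1 + BiocGenerics::end(peaks)) / 2) + 1L
  pchrom <- as.character(GenomeInfoDb::seqnames(peaks))
  gchrom <- as.character(GenomeInfoDb::seqnames(genes))
  tss <- .tss(genes); tts <- .tts(genes)
  sgn <- ifelse(as.character(BiocGenerics::strand(genes)) == "+", 1, -1)
  gs <- BiocGenerics::start(genes); ge <- BiocGenerics::end(genes)
  exons <- S4Vectors::mcols(genes)$exons
  category <- vapply(seq_along(peaks), function(i) {
    same <- which(gchrom == pchrom[i])
    if (length(same) == 0L) return("intergenic")
    p <- mid[i]
    off <- (p - tss[same]) * sgn[same]     # strand-aware offset from TSS
    if (any(off >= -promoter_window[1] & off <= promoter_window[2]))
      return("promoter-TSS")
    if (any(abs(p - tts[same]) <= tts_window)) return("TTS")
    inside <- same[gs[same] <= p & ge[same] >= p]
    if (length(inside) > 0L) {
      in_exon <- any(vapply(inside, function(g) {
        ex <- exons[[g]]
        any(BiocGenerics::start(ex) <= p & BiocGenerics::end(ex) >= p)
      }, logical(1)))
      return(if (in_exon) "exon" else "intron")
    }
    "intergenic"
  }, character(1))
  category <- factor(category, levels = cats)
  counts <- table(category)
  n <- length(peaks)
  list(categories = category,
       counts = as.vector(counts),
       fractions = if (n > 0) as.vector(counts) / n else rep(NA_real_, 5L),
       levels = cats)
}

#' Counts of every intersection region of named gene sets
#'
#' For `k` named sets, counts the elements falling in each of the
#' `2^k - 1` non-empty membership patterns (the regions of a Venn
#' diagram).  The pattern names join member set names with `&`.
#'
#' @param sets A named list of >= 2 character vectors (gene ids).
#' @return A named integer vector of region counts; the counts sum to the
#'   size of the union.
#' @export
venn_counts <- function(sets) {
  .assert(is.list(sets) && length(sets) >= 2, "need at least 2 named sets")
  .assert(!is.null(names(sets)) && all(nzchar(names(sets))), "sets must be named")
  .assert(length(sets) <= 6, "more than 6 sets cannot be displayed as a Venn diagram")
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets))
  k <- length(sets)
  membership <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) membership <- matrix(membership, nrow = 1L)
  patterns <- apply(membership, 1L, function(row) paste(names(sets)[row], collapse = "&"))
  all_patterns <- unlist(lapply(seq_len(k), function(r)
    apply(utils::combn(names(sets), r), 2L, paste, collapse = "&")))
  out <- stats::setNames(integer(length(all_patterns)), all_patterns)
  tab <- table(patterns)
  out[names(tab)] <- as.integer(tab)
  out
}

#' Write gene assignments as a tab-delimited table
#'
#' @param assignments A data.frame from [assign_genes()].
#' @param path Output path.
#' @param header Optional comment lines.
#' @export
write_assignments <- function(assignments, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  writeLines("peak_id\tgene_id\tdistance", con)
  if (nrow(assignments))
    writeLines(paste(assignments$peak_id, assignments$gene_id,
                     assignments$distance, sep = "\t"), con)
  invisible(path)
}
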