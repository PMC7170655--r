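#' Build the GATC fragment map of a genome
#'
#' DamID signals have a native resolution of one GATC fragment: the interval
#' between consecutive GATC motifs.  This function cuts each chromosome at
#' the first base of every literal `GATC` occurrence (case-insensitive), so
#' the four motif bases belong to the downstream fragment.  Fragments tile
#' each chromosome exactly; a chromosome without any motif yields a single
#' fragment covering it.  Ambiguity codes (`N` etc.) never match.
#'
#' @param genome A named character vector of chromosome sequences, or a
#'   [Biostrings::DNAStringSet].
#' @return A [GenomicRanges::GRanges] of fragments, sorted, with
#'   `seqlengths` set to the chromosome lengths.
#' @examples
#' build_fragment_map(c(chrA = "AAAAGATCAAAA"))
#' @export
build_fragment_map <- function(genome) {
  if (is(genome, "DNAStringSet")) genome <- as.character(genome)
  .assert(is.character(genome) && length(genome) > 0, "genome must have at least one sequence")
  .assert(!is.null(names(genome)) && !anyNA(names(genome)) && all(nzchar(names(genome))),
          "chromosome sequences must be named")
  .assert(!anyDuplicated(names(genome)), "duplicate chromosome name: %s",
          names(genome)[duplicated(names(genome))][1L])
  seqs <- toupper(genome)
  .assert(all(nchar(seqs) > 0), "empty sequence for chromosome %s",
          names(seqs)[nchar(seqs) == 0][1L])
  bad <- gsub("[ACGTURYSWKMBDHVN]", "", seqs)
  if (any(nchar(bad) > 0)) {
    offender <- substr(bad[nchar(bad) > 0][1L], 1L, 1L)
    .fail("non-nucleotide character '%s' in chromosome %s", offender,
          names(seqs)[nchar(bad) > 0][1L])
  }
  per_chrom <- lapply(names(seqs), function(nm) {
    s <- seqs[[nm]]
    len <- nchar(s)
    hits <- Biostrings::matchPattern("GATC", Biostrings::DNAString(s), fixed = TRUE)
    cuts <- BiocGenerics::start(hits)          # 1-based first motif base
    bounds0 <- sort(unique(c(0L, cuts - 1L, len)))  # 0-based boundaries
    bounds0 <- bounds0[bounds0 >= 0L & bounds0 <= len]
    starts0 <- bounds0[-length(bounds0)]
    ends0 <- bounds0[-1L]
    GenomicRanges::GRanges(nm, IRanges::IRanges(start = starts0 + 1L, end = ends0))
  })
  gr <- do.call(c, per_chrom)
  GenomeInfoDb::seqlevels(gr) <- names(seqs)
  GenomeInfoDb::seqlengths(gr) <- nchar(seqs)
  gr
}

#' Validate a fragment map
#'
#' Checks the tiling invariant: within each chromosome fragments are sorted,
#' non-overlapping, start at base 1, end at the chromosome length, and each
#' fragment starts where the previous one ends.
#'
#' @param fragments A `GRanges` fragment map with `seqlengths` set.
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validate_fragment_map <- function(fragments) {
  .assert(is(fragments, "GRanges"), "fragments must be a GRanges")
  sl <- GenomeInfoDb::seqlengths(fragments)
  .assert(!anyNA(sl), "fragment map must carry seqlengths")
  chrom <- as.character(GenomeInfoDb::seqnames(fragments))
  for (nm in unique(chrom)) {
    s <- BiocGenerics::start(fragments)[chrom == nm]
    e <- BiocGenerics::end(fragments)[chrom == nm]
    .assert(s[1L] == 1L, "chromosome %s does not start at base 1", nm)
    .assert(e[length(e)] == sl[[nm]], "chromosome %s does not end at its length", nm)
    if (length(s) > 1L)
      .assert(all(s[-1L] == e[-length(e)] + 1L),
              "fragments on chromosome %s do not tile contiguously", nm)
  }
  invisible(TRUE)
}

#' Construct a uniform-width fragment map
#'
#' Convenience constructor for simulations and examples: one chromosome
#' tiled by `n` fragments of equal width (no sequence attached).
#'
#' @param n Number of fragments.
#' @param width Fragment width in bp.
#' @param chrom Chromosome name.
#' @return A `GRanges` fragment map.
#' @export
uniform_fragments <- function(n, width = 200L, chrom = "chrSim") {
  .assert(n >= 1 && width >= 1, "n and width must be positive")
  starts <- seq.int(1L, by = as.integer(width), length.out = n)
  gr <- GenomicRanges::GRanges(chrom,
    IRanges::IRanges(start = starts, width = as.integer(width)))
  GenomeInfoDb::seqlengths(gr) <- stats::setNames(as.integer(n * width), chrom)
  gr
}

#' Gene models as a GRanges
#'
#' Internal constructor used by [read_annotation()] and the simulator.
#' Genes carry `gene_id`, strand, and an exon list; the transcription start
#' site is the strand-aware 5' end of the span.
#'
#' @param chrom,start,end,strand,gene_id Per-gene vectors (1-based closed
#'   coordinates).
#' @param exons A list of 2-column matrices (start, end) per gene, or NULL
#'   for single-exon genes spanning the whole model.
#' @return A `GRanges` with metadata columns `gene_id` and `exons`
#'   (an [IRanges::IRangesList]).
#' @export
gene_models <- function(chrom, start, end, strand, gene_id, exons = NULL) {
  .assert(!anyDuplicated(gene_id), "duplicate gene_id: %s",
          gene_id[duplicated(gene_id)][1L])
  .assert(all(end >= start), "gene end < start for %s", gene_id[end < start][1L])
  .assert(all(strand %in% c("+", "-")), "strand must be + or -")
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end), strand = strand)
  if (is.null(exons)) {
    ex <- IRanges::IRangesList(lapply(seq_along(start), function(i)
      IRanges::IRanges(start[i], end[i])))
  } else {
    ex <- IRanges::IRangesList(lapply(exons, function(m)
      IRanges::IRanges(m[, 1L], m[, 2L])))
    for (i in seq_along(ex)) {
      .assert(all(BiocGenerics::start(ex[[i]]) >= start[i]) &&
              all(BiocGenerics::end(ex[[i]]) <= end[i]),
              "exons outside gene span for %s", gene_id[i])
    }
  }
  S4Vectors::mcols(gr)$gene_id <- as.character(gene_id)
  S4Vectors::mcols(gr)$exons <- ex
  o <- order(as.character(GenomeInfoDb::seqnames(gr)), BiocGenerics::start(gr))
  gr[o]
}

# Strand-aware TSS / TTS positions (1-based single bases).
.tss <- function(genes) {
  ifelse(as.character(BiocGenerics::strand(genes)) == "+",
         BiocGenerics::start(genes), BiocGenerics::end(genes))
}
.tts <- function(genes) {
  ifelse(as.character(BiocGenerics::strand(genes)) == "+",
         BiocGenerics::end(genes), BiocGenerics::start(genes))
}
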