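#' Read a multi-record FASTA genome
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of upper-case chromosome sequences.
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(seqs))
  # FASTA description lines may carry free text after the record name
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Write a genome as FASTA
#'
#' @param genome Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @export
write_genome_fasta <- function(genome, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(genome)) {
    writeLines(paste0(">", nm), con)
    s <- genome[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

.read_lines_nocomment <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  list(lines = lines[keep], lineno = which(keep))
}

#' Read gene models from GFF3
#'
#' Accepts `gene` features (attributes must contain `ID=` or `gene_id=`)
#' plus optional `exon` children linked by `Parent=`.  GFF3 coordinates are
#' 1-based closed and are kept as such in the returned `GRanges`.
#' Genes are sorted by (chromosome, start); duplicate gene ids are an error.
#'
#' @param path Path to a GFF3 file.
#' @return A `GRanges` of gene models (see [gene_models()]).
#' @export
read_annotation <- function(path) {
  parsed <- .read_lines_nocomment(path)
  fields <- strsplit(parsed$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L))
    .fail("malformed GFF3: line %d has %d columns (9 expected)",
          parsed$lineno[nf != 9L][1L], nf[nf != 9L][1L])
  m <- do.call(rbind, fields)
  start <- as.integer(m[, 4L]); end <- as.integer(m[, 5L])
  if (any(end < start))
    .fail("malformed GFF3: end < start at line %d", parsed$lineno[end < start][1L])
  type <- m[, 3L]
  attr_get <- function(attrs, key) {
    hit <- regexpr(paste0("(?:^|;)", key, "=[^;]*"), attrs, perl = TRUE)
    out <- rep(NA_character_, length(attrs))
    out[hit != -1L] <- sub(paste0("^;?", key, "="), "", regmatches(attrs, hit))
    out
  }
  is_gene <- type == "gene"
  .assert(any(is_gene), "no gene features found in %s", path)
  attrs <- m[, 9L]
  ids <- attr_get(attrs[is_gene], "ID")
  alt <- attr_get(attrs[is_gene], "gene_id")
  ids[is.na(ids)] <- alt[is.na(ids)]
  .assert(!anyNA(ids), "gene feature without ID or gene_id at line %d",
          parsed$lineno[is_gene][is.na(ids)][1L])
  is_exon <- type == "exon"
  parents <- if (any(is_exon)) attr_get(attrs[is_exon], "Parent") else character(0)
  exon_tab <- if (any(is_exon))
    data.frame(parent = parents, start = start[is_exon], end = end[is_exon]) else NULL
  exons <- lapply(seq_along(ids), function(i) {
    if (is.null(exon_tab)) return(cbind(start[is_gene][i], end[is_gene][i]))
    ex <- exon_tab[exon_tab$parent == ids[i], , drop = FALSE]
    if (nrow(ex) == 0L) return(cbind(start[is_gene][i], end[is_gene][i]))
    ex <- ex[order(ex$start), , drop = FALSE]
    cbind(ex$start, ex$end)
  })
  gene_models(chrom = m[is_gene, 1L], start = start[is_gene], end = end[is_gene],
              strand = m[is_gene, 7L], gene_id = ids, exons = exons)
}

#' Write gene models as GFF3
#'
#' Emits one `gene` line per model plus `exon` children; output is sorted
#' by (chromosome, start).  Round-trips with [read_annotation()].
#'
#' @param genes A `GRanges` from [gene_models()] / [read_annotation()].
#' @param path Output path.
#' @param header Optional extra comment lines (written with a leading `#`).
#' @export
write_gff3 <- function(genes, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (length(header)) writeLines(paste0("# ", header), con)
  chrom <- as.character(GenomeInfoDb::seqnames(genes))
  o <- order(chrom, BiocGenerics::start(genes))
  for (i in o) {
    gid <- S4Vectors::mcols(genes)$gene_id[i]
    writeLines(sprintf("%s\ttadakit\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       chrom[i], BiocGenerics::start(genes)[i],
                       BiocGenerics::end(genes)[i],
                       as.character(BiocGenerics::strand(genes))[i], gid), con)
    ex <- S4Vectors::mcols(genes)$exons[[i]]
    writeLines(sprintf("%s\ttadakit\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                       chrom[i], BiocGenerics::start(ex), BiocGenerics::end(ex),
                       as.character(BiocGenerics::strand(genes))[i], gid), con)
  }
  invisible(path)
}

#' Read a BED region set
#'
#' BED is 0-based half-open; coordinates are converted to the 1-based closed
#' convention of `GRanges`.  Optional columns 4-6 are preserved as `label`,
#' `score`, strand.
#'
#' @param path Path to a BED file.
#' @param genome Optional named vector of chromosome lengths; when given,
#'   records on unknown chromosomes are an error.
#' @return A `GRanges`; metadata columns `label` and `score` when present.
#' @export
read_region_bed <- function(path, genome = NULL) {
  parsed <- .read_lines_nocomment(path)
  if (length(parsed$lines) == 0L) {
    gr <- GenomicRanges::GRanges()
    return(gr)
  }
  fields <- strsplit(parsed$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  .assert(all(nf >= 3L), "malformed BED: line %d has fewer than 3 columns",
          parsed$lineno[nf < 3L][1L])
  ncol_use <- min(nf)
  m <- do.call(rbind, lapply(fields, function(f) f[seq_len(ncol_use)]))
  chrom <- m[, 1L]
  start0 <- as.numeric(m[, 2L]); end0 <- as.numeric(m[, 3L])
  if (any(start0 >= end0))
    .fail("malformed BED: start >= end at line %d", parsed$lineno[start0 >= end0][1L])
  if (!is.null(genome)) {
    unk <- !(chrom %in% names(genome))
    if (any(unk))
      .fail("unknown chromosome '%s' at line %d", chrom[unk][1L], parsed$lineno[unk][1L])
  }
  strand <- if (ncol_use >= 6L) m[, 6L] else "*"
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1L, end0),
                               strand = strand)
  if (ncol_use >= 4L) S4Vectors::mcols(gr)$label <- m[, 4L]
  if (ncol_use >= 5L) S4Vectors::mcols(gr)$score <- m[, 5L]
  if (!is.null(genome)) GenomeInfoDb::seqlengths(gr) <-
    genome[GenomeInfoDb::seqlevels(gr)]
  gr
}

#' Write a region set as BED
#'
#' Emits BED3 plus `label`, `score` and strand columns when present in the
#' metadata; output sorted by (chromosome, start).  `write_bed` composed
#' with [read_region_bed()] is the identity on (chrom, start, end, label,
#' score).
#'
#' @param regions A `GRanges`.
#' @param path Output path.
#' @param header Optional comment lines, written with a leading `#`.
#' @export
write_bed <- function(regions, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  chrom <- as.character(GenomeInfoDb::seqnames(regions))
  o <- order(chrom, BiocGenerics::start(regions))
  mc <- S4Vectors::mcols(regions)
  has_label <- "label" %in% colnames(mc)
  has_score <- "score" %in% colnames(mc)
  strand <- as.character(BiocGenerics::strand(regions))
  has_strand <- any(strand != "*")
  cols <- list(chrom[o],
               format(BiocGenerics::start(regions)[o] - 1L, scientific = FALSE, trim = TRUE),
               format(BiocGenerics::end(regions)[o], scientific = FALSE, trim = TRUE))
  if (has_label || has_score || has_strand)
    cols <- c(cols, list(if (has_label) as.character(mc$label)[o] else rep(".", length(o))))
  if (has_score || has_strand)
    cols <- c(cols, list(if (has_score) as.character(mc$score)[o] else rep("0", length(o))))
  if (has_strand) cols <- c(cols, list(strand[o]))
  writeLines(do.call(paste, c(cols, sep = "\t")), con)
  invisible(path)
}

#' Write a fragment track as bedGraph
#'
#' One record per non-missing fragment (0-based half-open coordinates);
#' missing fragments are omitted and read back as missing.
#'
#' @param track A [fragment_track()].
#' @param path Output path.
#' @param header Optional comment lines (parameters, seed), written with a
#'   leading `#`.
#' @export
write_bedgraph <- function(track, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  fr <- track$fragments
  keep <- !is.na(track$values)
  writeLines(sprintf("%s\t%d\t%d\t%s",
                     as.character(GenomeInfoDb::seqnames(fr))[keep],
                     BiocGenerics::start(fr)[keep] - 1L,
                     BiocGenerics::end(fr)[keep],
                     sprintf("%.6g", track$values[keep])), con)
  invisible(path)
}

#' Read a bedGraph onto a fragment map
#'
#' When every record matches a fragment's boundaries exactly, values attach
#' directly; otherwise each fragment receives the length-weighted mean of
#' the records overlapping it.  Fragments with no coverage are missing.
#'
#' @param path Path to a bedGraph file.
#' @param fragments A fragment map `GRanges`.
#' @param units Unit string stored on the returned track.
#' @return A [fragment_track()].
#' @export
read_bedgraph <- function(path, fragments, units = "value") {
  parsed <- .read_lines_nocomment(path)
  n <- length(fragments)
  if (length(parsed$lines) == 0L)
    return(fragment_track(fragments, rep(NA_real_, n), units = units))
  fields <- strsplit(parsed$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  .assert(all(nf >= 4L), "malformed bedGraph: line %d has fewer than 4 columns",
          parsed$lineno[nf < 4L][1L])
  m <- do.call(rbind, lapply(fields, function(f) f[1:4]))
  start0 <- as.numeric(m[, 2L]); end0 <- as.numeric(m[, 3L])
  if (any(start0 >= end0))
    .fail("malformed bedGraph: start >= end at line %d", parsed$lineno[start0 >= end0][1L])
  gr <- GenomicRanges::GRanges(m[, 1L], IRanges::IRanges(start0 + 1L, end0))
  vals <- as.numeric(m[, 4L])
  hit <- GenomicRanges::findOverlaps(gr, fragments)
  exact <- length(gr) > 0 &&
    length(hit) == length(gr) &&
    all(BiocGenerics::start(gr)[S4Vectors::queryHits(hit)] ==
          BiocGenerics::start(fragments)[S4Vectors::subjectHits(hit)]) &&
    all(BiocGenerics::end(gr)[S4Vectors::queryHits(hit)] ==
          BiocGenerics::end(fragments)[S4Vectors::subjectHits(hit)])
  out <- rep(NA_real_, n)
  if (exact) {
    out[S4Vectors::subjectHits(hit)] <- vals[S4Vectors::queryHits(hit)]
  } else if (length(hit) > 0) {
    ov <- GenomicRanges::pintersect(gr[S4Vectors::queryHits(hit)],
                                    fragments[S4Vectors::subjectHits(hit)])
    w <- BiocGenerics::width(ov)
    num <- rowsum(vals[S4Vectors::queryHits(hit)] * w, S4Vectors::subjectHits(hit))
    den <- rowsum(w, S4Vectors::subjectHits(hit))
    out[as.integer(rownames(num))] <- num / den
  }
  fragment_track(fragments, out, units = units)
}

#' Write a per-fragment value table
#'
#' Tab-delimited with columns chrom, start, end (0-based half-open), value,
#' missing_flag.
#'
#' @param track A [fragment_track()].
#' @param path Output path.
#' @param header Optional comment lines.
#' @export
write_track_table <- function(track, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  fr <- track$fragments
  writeLines("chrom\tstart\tend\tvalue\tmissing_flag", con)
  v <- ifelse(is.na(track$values), "NA", sprintf("%.6g", track$values))
  writeLines(paste(as.character(GenomeInfoDb::seqnames(fr)),
                   BiocGenerics::start(fr) - 1L, BiocGenerics::end(fr),
                   v, as.integer(is.na(track$values)), sep = "\t"), con)
  invisible(path)
}
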