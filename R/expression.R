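#' Read a differential-expression results table
#'
#' Tab-delimited with a header containing `gene_id`, `log2FC` (or
#' `log2_fold_change`) and `padj` (or `adjusted_p`) columns.
#'
#' @param path Path to the table.
#' @return A data.frame with columns `gene_id`, `log2_fold_change`,
#'   `adjusted_p`.
#' @export
read_de_table <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
  pick <- function(choices) {
    hit <- intersect(choices, colnames(tab))
    .assert(length(hit) >= 1, "DE table lacks a column among: %s",
            paste(choices, collapse = ", "))
    tab[[hit[1L]]]
  }
  data.frame(gene_id = as.character(pick(c("gene_id", "gene"))),
             log2_fold_change = as.numeric(pick(c("log2FC", "log2_fold_change", "log2FoldChange"))),
             adjusted_p = as.numeric(pick(c("padj", "adjusted_p", "adj_p"))))
}

#' Classify differentially expressed genes at the printed thresholds
#'
#' Upregulated: adjusted p strictly below `padj_cutoff` AND log2 fold
#' change strictly greater than `lfc_cutoff`.  Downregulated: adjusted p
#' strictly below `padj_cutoff` AND log2 fold change strictly less than
#' `-lfc_cutoff`.  A fold change of exactly `lfc_cutoff` is not
#' significant; rows with a missing adjusted p are excluded.
#'
#' @param table A DE table (see [read_de_table()]).
#' @param padj_cutoff Adjusted-p threshold (default 0.05).
#' @param lfc_cutoff Absolute log2 fold-change threshold (default 1).
#' @return A list with character vectors `up` and `down` (disjoint).
#' @export
classify_de <- function(table, padj_cutoff = 0.05, lfc_cutoff = 1.0) {
  .assert(padj_cutoff > 0 && lfc_cutoff > 0, "thresholds must be positive")
  .assert(!anyDuplicated(table$gene_id), "duplicate gene_id: %s",
          table$gene_id[duplicated(table$gene_id)][1L])
  usable <- !is.na(table$adjusted_p)
  sig <- usable & table$adjusted_p < padj_cutoff
  list(up = table$gene_id[sig & table$log2_fold_change > lfc_cutoff],
       down = table$gene_id[sig & table$log2_fold_change < -lfc_cutoff])
}

#' One-sided gene-set overlap enrichment test
#'
#' Fisher's exact test for enrichment: the p-value is the hypergeometric
#' upper tail `P(X >= |A intersect B|)` of drawing `|B|` genes from the
#' universe of which `|A|` are in A.  The odds ratio is computed from the
#' 2x2 table; a zero cell yields an infinite ratio (not adjusted).
#'
#' @param set_a,set_b Character vectors of gene ids, subsets of `universe`.
#' @param universe Character vector of all genes considered.
#' @return A list of class `OverlapResult`: `table` (2x2 counts),
#'   `odds_ratio`, `p_value`, `n_overlap`.
#' @export
overlap_test <- function(set_a, set_b, universe) {
  universe <- unique(universe)
  set_a <- unique(set_a); set_b <- unique(set_b)
  .assert(length(universe) >= 1, "universe must be non-empty")
  .assert(all(set_a %in% universe), "set_a contains genes outside the universe")
  .assert(all(set_b %in% universe), "set_b contains genes outside the universe")
  n11 <- length(intersect(set_a, set_b))
  n10 <- length(set_a) - n11
  n01 <- length(set_b) - n11
  n00 <- length(universe) - n11 - n10 - n01
  # hypergeometric upper tail P(X >= n11): white balls = |A|, draws = |B|
  p <- phyper(n11 - 1L, length(set_a), length(universe) - length(set_a),
              length(set_b), lower.tail = FALSE)
  or <- (n11 * n00) / (n10 * n01)   # 0 denominator -> Inf (or NaN when 0/0)
  structure(list(table = matrix(c(n11, n10, n01, n00), nrow = 2,
                                dimnames = list(c("in_A", "not_A"),
                                                c("in_B", "not_B"))),
                 odds_ratio = or, p_value = p, n_overlap = n11),
            class = "OverlapResult")
}

#' @export
print.OverlapResult <- function(x, ...) {
  cat(sprintf("OverlapResult: overlap=%d, odds ratio=%.3g, one-sided p=%.3g\n",
              x$n_overlap, x$odds_ratio, x$p_value))
  invisible(x)
}

#' Read a gene x tissue FPKM matrix
#'
#' Tab-delimited with a header; first column `gene_id`, remaining columns
#' one tissue each.
#'
#' @param path Path to the matrix.
#' @return A numeric matrix, rownames = gene ids, colnames = tissues.
#' @export
read_fpkm_matrix <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
  .assert(ncol(tab) >= 2, "FPKM matrix needs a gene_id column plus tissues")
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- as.character(tab[[1L]])
  storage.mode(m) <- "double"
  .assert(all(m >= 0, na.rm = TRUE), "FPKM values must be non-negative")
  m
}

#' Tissue of origin of a gene set from an FPKM matrix
#'
#' FPKM values strictly above `fpkm_threshold` (default 2, the
#' non-background rule) count as expression.  A gene is labelled
#' `focal-tissue` when the focal tissue (e.g. CNS) expresses it;
#' otherwise `non-focal:<tissue>` for the highest-expressing other tissue
#' (lexicographic tie-break); otherwise `not-detected`.  Genes absent from
#' the matrix are reported separately, never silently dropped.
#'
#' @param genes Character vector of gene ids.
#' @param matrix FPKM matrix from [read_fpkm_matrix()].
#' @param focal_tissue Column name of the focal tissue.
#' @param fpkm_threshold Expression threshold (default 2; FPKM exactly 2
#'   is background).
#' @return A list with `labels` (named character vector over the genes
#'   found), `fractions` (per label over the labelled genes), `missing`
#'   (ids absent from the matrix).
#' @export
tissue_of_origin <- function(genes, matrix, focal_tissue, fpkm_threshold = 2.0) {
  .assert(ncol(matrix) >= 1, "no tissues in matrix")
  .assert(focal_tissue %in% colnames(matrix),
          "focal tissue '%s' not in matrix", focal_tissue)
  genes <- unique(genes)
  found <- genes[genes %in% rownames(matrix)]
  missing <- setdiff(genes, found)
  others <- setdiff(colnames(matrix), focal_tissue)
  labels <- vapply(found, function(g) {
    row <- matrix[g, ]
    if (!is.na(row[[focal_tissue]]) && row[[focal_tissue]] > fpkm_threshold)
      return("focal-tissue")
    ov <- row[others]
    ov[is.na(ov)] <- 0
    if (length(ov) && any(ov > fpkm_threshold)) {
      best <- sort(others[ov == max(ov)])[1L]   # lexicographic tie-break
      return(paste0("non-focal:", best))
    }
    "not-detected"
  }, character(1))
  fractions <- if (length(labels)) table(labels) / length(labels) else table(character(0))
  list(labels = labels, fractions = c(fractions), missing = missing)
}

#' Bound-gene / differentially-expressed-gene overlap report
#'
#' Runs [overlap_test()] for upregulated-vs-bound and downregulated-vs-
#' bound and reports the fraction of DE genes in each direction that are
#' directly bound.
#'
#' @param bound Character vector of genes assigned to final peaks.
#' @param up,down DE gene sets from [classify_de()].
#' @param universe All genes considered.
#' @return A list with `up_test`, `down_test` ([overlap_test()] results),
#'   `up_bound_fraction`, `down_bound_fraction`.
#' @export
bound_de_overlap_report <- function(bound, up, down, universe) {
  up <- unique(up); down <- unique(down); bound <- unique(bound)
  list(up_test = overlap_test(up, bound, universe),
       down_test = overlap_test(down, bound, universe),
       up_bound_fraction = if (length(up)) length(intersect(up, bound)) / length(up) else NA_real_,
       down_bound_fraction = if (length(down)) length(intersect(down, bound)) / length(down) else NA_real_)
}
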