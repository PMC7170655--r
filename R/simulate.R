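#' Simulation configuration
#'
#' Defaults describe the conditions the rest of the package is validated
#' under: a 4 Mb chromosome with one GATC motif every ~200 bp (about
#' 20,000 fragments, so RPM values coincide numerically with raw counts at
#' the default coverage), 50x mean fragment coverage, negative-binomial
#' dispersion 0.015 (calibrated so replicate samples show the Spearman
#' r ~ 0.9 concordance the assay reports), log-normal per-fragment
#' accessibility (sdlog 0.5), two biological replicates, 40 planted bound
#' regions of 5 consecutive fragments at a log2 effect of 2, and binding
#' placed in low-accessibility fragments 80 % of the time (binding of
#' this condensin subunit is concentrated in inaccessible chromatin).
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chromosome_length Length of each chromosome in bp.
#' @param mean_gatc_spacing Mean distance between GATC motif starts (bp,
#'   >= 50).
#' @param n_genes Genes to simulate.
#' @param coverage Mean reads per fragment in the Dam-only control.
#' @param dispersion Negative-binomial dispersion (variance = mu +
#'   dispersion * mu^2).
#' @param accessibility_sdlog Log-sd of the per-fragment accessibility
#'   multiplier.
#' @param n_bound_regions Planted bound regions.
#' @param region_fragments Fragments per planted region.
#' @param effect_size Planted log2 enrichment of fusion over control.
#' @param n_replicates Biological replicates (>= 2; replicate
#'   intersection needs two).
#' @param low_access_bias Probability that a planted region is placed in
#'   the low-accessibility half of fragments.
#' @return A named list of class `SimConfig`.
#' @export
sim_config <- function(n_chromosomes = 1L, chromosome_length = 4000000L,
                       mean_gatc_spacing = 200L, n_genes = 400L,
                       coverage = 50, dispersion = 0.015,
                       accessibility_sdlog = 0.5,
                       n_bound_regions = 40L, region_fragments = 5L,
                       effect_size = 2.0, n_replicates = 2L,
                       low_access_bias = 0.8) {
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              chromosome_length = as.integer(chromosome_length),
              mean_gatc_spacing = as.integer(mean_gatc_spacing),
              n_genes = as.integer(n_genes), coverage = coverage,
              dispersion = dispersion,
              accessibility_sdlog = accessibility_sdlog,
              n_bound_regions = as.integer(n_bound_regions),
              region_fragments = as.integer(region_fragments),
              effect_size = effect_size, n_replicates = as.integer(n_replicates),
              low_access_bias = low_access_bias)
  .assert(cfg$n_chromosomes >= 1 && cfg$chromosome_length >= 1,
          "chromosome count and length must be positive")
  .assert(cfg$mean_gatc_spacing >= 50, "mean GATC spacing must be >= 50 bp")
  .assert(cfg$coverage >= 0 && cfg$dispersion > 0, "coverage >= 0, dispersion > 0")
  .assert(cfg$n_replicates >= 1, "need at least one replicate")
  .assert(cfg$low_access_bias >= 0 && cfg$low_access_bias <= 1,
          "low_access_bias must be a probability")
  structure(cfg, class = "SimConfig")
}

# Random filler sequence guaranteed free of GATC: accidental motifs are
# mutated (A -> C at the second motif base) until none remain.
.filler <- function(n) {
  if (n <= 0L) return("")
  s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  repeat {
    hit <- regexpr("GATC", s, fixed = TRUE)
    if (hit == -1L) break
    substr(s, hit + 1L, hit + 1L) <- "C"
  }
  s
}

#' Simulate a genome with renewal-process GATC spacing
#'
#' Motif start positions form a renewal process whose inter-start gaps are
#' `4 + Geometric` with the configured mean spacing; the filler sequence
#' between motifs never contains an accidental GATC, so the fragment
#' structure is exactly the planted one.
#'
#' @param config A [sim_config()].
#' @param seed Master seed.
#' @return A list: `genome` (named character vector) and `fragments`
#'   (the [build_fragment_map()] of the genome).
#' @export
simulate_genome <- function(config, seed) {
  .assert(inherits(config, "SimConfig"), "config must be a SimConfig")
  genome <- character(config$n_chromosomes)
  names(genome) <- paste0("chrS", seq_len(config$n_chromosomes))
  p_gap <- 1 / (config$mean_gatc_spacing - 3)
  for (i in seq_len(config$n_chromosomes)) {
    set.seed(sub_seed(seed, paste0("genome:", i)))
    len <- config$chromosome_length
    n_draw <- ceiling(len / config$mean_gatc_spacing * 1.5) + 10L
    gaps <- 4L + stats::rgeom(n_draw, p_gap)
    while (sum(gaps) < len) gaps <- c(gaps, 4L + stats::rgeom(n_draw, p_gap))
    pieces <- character(0)
    pos <- 0L
    first <- TRUE
    for (g in gaps) {
      fill_len <- g - 4L
      chunk <- if (first) .filler(g) else paste0("GATC", .filler(fill_len))
      first <- FALSE
      pieces <- c(pieces, chunk)
      pos <- pos + nchar(chunk)
      if (pos >= len) break
    }
    s <- substr(paste(pieces, collapse = ""), 1L, len)
    genome[i] <- s
  }
  list(genome = genome, fragments = build_fragment_map(genome))
}

#' Simulate a gene annotation
#'
#' Non-overlapping gene spans with log-normal lengths placed uniformly,
#' random strands, 1-5 exons each (alternating exon/intron segments within
#' the span).
#'
#' @param config A [sim_config()].
#' @param fragments Fragment map (supplies chromosome names and lengths).
#' @param seed Master seed.
#' @return A `GRanges` of gene models (see [gene_models()]).
#' @export
simulate_annotation <- function(config, fragments, seed) {
  set.seed(sub_seed(seed, "annotation"))
  sl <- GenomeInfoDb::seqlengths(fragments)
  n <- config$n_genes
  if (n == 0L)
    return(gene_models(character(0), integer(0), integer(0), character(0), character(0)))
  chrom <- character(0); start <- integer(0); end <- integer(0)
  tries <- 0L
  while (length(start) < n) {
    tries <- tries + 1L
    .assert(tries <= 50L * n, "gene density infeasible after %d placement attempts", tries)
    len <- max(200L, round(rlnorm(1, log(3000), 0.5)))
    cn <- sample(names(sl), 1L)
    if (len >= sl[[cn]]) next
    s <- sample.int(sl[[cn]] - len, 1L)
    e <- s + len - 1L
    clash <- chrom == cn & start <= e & end >= s
    if (any(clash)) next
    chrom <- c(chrom, cn); start <- c(start, s); end <- c(end, e)
  }
  o <- order(chrom, start)
  chrom <- chrom[o]; start <- start[o]; end <- end[o]
  strand <- sample(c("+", "-"), n, replace = TRUE)
  exons <- lapply(seq_len(n), function(i) {
    k <- sample(1:5, 1L)
    if (k == 1L) return(cbind(start[i], end[i]))
    span <- end[i] - start[i] + 1L
    if (span < 2L * (2L * k - 1L)) return(cbind(start[i], end[i]))
    cuts <- sort(sample.int(span - 1L, 2L * k - 2L))
    bounds <- c(0L, cuts, span)
    seg_start <- start[i] + bounds[-length(bounds)]
    seg_end <- start[i] + bounds[-1L] - 1L
    odd <- seq(1L, 2L * k - 1L, by = 2L)
    cbind(seg_start[odd], seg_end[odd])
  })
  gene_models(chrom, start, end, strand, sprintf("gene%04d", seq_len(n)), exons)
}

#' Plant ground-truth bound regions and accessibility structure
#'
#' Per-fragment accessibility multipliers are log-normal (mean 1); bound
#' regions are runs of `region_fragments` consecutive fragments, placed in
#' the low-accessibility half of fragments with probability
#' `low_access_bias`, never overlapping each other, each carrying the
#' configured log2 effect.
#'
#' @param config A [sim_config()].
#' @param fragments Fragment map.
#' @param seed Master seed (stored; fully determines all downstream
#'   simulated data).
#' @return A list of class `SimTruth`: `regions` (`GRanges` with `effect`
#'   column), `effect` and `accessibility` per-fragment vectors, `seed`,
#'   `config`.
#' @export
simulate_truth <- function(config, fragments, seed) {
  set.seed(sub_seed(seed, "truth"))
  nf <- length(fragments)
  accessibility <- rlnorm(nf, meanlog = 0, sdlog = config$accessibility_sdlog)
  accessibility <- accessibility / mean(accessibility)
  chrom <- as.character(GenomeInfoDb::seqnames(fragments))
  effect <- numeric(nf)
  in_region <- logical(nf)
  low_pool <- which(accessibility < stats::median(accessibility))
  k <- config$region_fragments
  picked <- 0L
  tries <- 0L
  region_first <- integer(0)
  while (picked < config$n_bound_regions) {
    tries <- tries + 1L
    .assert(tries <= 1000L * max(1L, config$n_bound_regions),
            "could not place bound regions (genome too small?)")
    use_low <- runif(1) < config$low_access_bias
    s <- if (use_low && length(low_pool)) sample(low_pool, 1L) else sample.int(nf, 1L)
    idx <- s:(s + k - 1L)
    if (max(idx) > nf) next
    if (length(unique(chrom[idx])) > 1L) next
    if (any(in_region[idx])) next
    in_region[idx] <- TRUE
    effect[idx] <- config$effect_size
    region_first <- c(region_first, s)
    picked <- picked + 1L
  }
  region_first <- sort(region_first)
  regions <- GenomicRanges::GRanges(chrom[region_first],
    IRanges::IRanges(BiocGenerics::start(fragments)[region_first],
                     BiocGenerics::end(fragments)[region_first + k - 1L]))
  S4Vectors::mcols(regions)$effect <- rep(config$effect_size, length(regions))
  structure(list(regions = regions, effect = effect,
                 accessibility = accessibility, seed = as.integer(seed),
                 config = config),
            class = "SimTruth")
}

#' Simulate replicate DamID count tracks
#'
#' Control (Dam-only) counts are negative binomial with mean
#' `coverage x sqrt(fragment length / mean length) x accessibility`;
#' the square-root length factor reflects that short GATC fragments still
#' collect reads from library inserts spanning their boundaries.  Fusion
#' counts have mean `control mean x 2^effect` with the planted effect
#' inside bound regions and 0 elsewhere.  Replicates draw from
#' independent labelled seed streams.
#'
#' @param truth A [simulate_truth()] result.
#' @param fragments Fragment map the truth was planted on.
#' @return A list of `n_replicates` elements, each
#'   `list(fusion = CountTrack, control = CountTrack)`.
#' @export
simulate_damid <- function(truth, fragments) {
  .assert(inherits(truth, "SimTruth"), "truth must be a SimTruth")
  cfg <- truth$config
  nf <- length(fragments)
  .assert(length(truth$effect) == nf, "truth/fragment map mismatch")
  w <- BiocGenerics::width(fragments)
  # sub-linear length factor: short GATC fragments still collect reads from
  # library inserts spanning their boundaries, so counts do not fall
  # linearly with fragment length
  len_factor <- sqrt(w / mean(w))
  mu_control <- cfg$coverage * len_factor * truth$accessibility
  mu_fusion <- mu_control * 2^truth$effect
  size <- 1 / cfg$dispersion
  lapply(seq_len(cfg$n_replicates), function(r) {
    set.seed(sub_seed(truth$seed, paste0("damid:rep", r)))
    ctrl <- rnbinom(nf, mu = mu_control, size = size)
    fus <- rnbinom(nf, mu = mu_fusion, size = size)
    list(fusion = count_track(fragments, fus),
         control = count_track(fragments, ctrl))
  })
}

#' Simulate a DE results table with controlled bound-gene overlap
#'
#' Each DE gene is drawn from the bound pool with probability
#' `target_bound_fraction` (else from the unbound pool), so the expected
#' bound fraction among DE genes equals the target.  Significant rows get
#' `padj < 0.05` and `|log2FC| > 1`; all other universe genes get
#' non-significant rows.
#'
#' @param bound Character vector of bound gene ids.
#' @param universe All gene ids.
#' @param target_bound_fraction Target probability that a DE gene is
#'   bound.
#' @param n_up,n_down Numbers of up/downregulated genes.
#' @param seed Master seed.
#' @return A data.frame DE table (`gene_id`, `log2_fold_change`,
#'   `adjusted_p`).
#' @export
simulate_de_table <- function(bound, universe, target_bound_fraction,
                              n_up, n_down, seed) {
  set.seed(sub_seed(seed, "de_table"))
  universe <- unique(universe)
  bound <- intersect(unique(bound), universe)
  unbound <- setdiff(universe, bound)
  n_de <- n_up + n_down
  .assert(n_de <= length(universe), "more DE genes than universe genes")
  .assert(target_bound_fraction >= 0 && target_bound_fraction <= 1,
          "target_bound_fraction must be a probability")
  pool_b <- sample(bound); pool_u <- sample(unbound)
  de <- character(n_de)
  for (i in seq_len(n_de)) {
    want_bound <- runif(1) < target_bound_fraction
    if (want_bound) {
      .assert(length(pool_b) > 0,
              "bound pool exhausted: target bound fraction infeasible")
      de[i] <- pool_b[1L]; pool_b <- pool_b[-1L]
    } else {
      .assert(length(pool_u) > 0,
              "unbound pool exhausted: target bound fraction infeasible")
      de[i] <- pool_u[1L]; pool_u <- pool_u[-1L]
    }
  }
  up <- de[seq_len(n_up)]
  down <- if (n_down > 0) de[n_up + seq_len(n_down)] else character(0)
  rest <- setdiff(universe, de)
  lfc <- c(1 + rexp(n_up, 1), -(1 + rexp(n_down, 1)), runif(length(rest), -0.8, 0.8))
  padj <- c(runif(n_de, 0, 0.049), runif(length(rest), 0.05, 1))
  data.frame(gene_id = c(up, down, rest), log2_fold_change = lfc,
             adjusted_p = padj)
}

#' Simulate a labelled chromatin-state map
#'
#' Partitions each chromosome into consecutive intervals with
#' exponential-ish lengths, labelled by a recycled state palette
#' (including the prevalent repressive "black" state).
#'
#' @param fragments Fragment map (chromosome lengths).
#' @param seed Master seed.
#' @param states State labels to draw from.
#' @param mean_length Mean state-interval length in bp.
#' @return A `GRanges` with a `label` column; intervals abut, never
#'   overlap.
#' @export
simulate_states <- function(fragments, seed,
                            states = c("black", "HP1", "PcG", "TrxG", "red", "yellow"),
                            mean_length = 20000) {
  set.seed(sub_seed(seed, "states"))
  sl <- GenomeInfoDb::seqlengths(fragments)
  out <- NULL
  for (nm in names(sl)) {
    pos <- 0L
    starts <- integer(0); ends <- integer(0)
    while (pos < sl[[nm]]) {
      len <- max(1000L, round(rexp(1, 1 / mean_length)))
      starts <- c(starts, pos + 1L)
      ends <- c(ends, min(pos + len, sl[[nm]]))
      pos <- pos + len
    }
    gr <- GenomicRanges::GRanges(nm, IRanges::IRanges(starts, ends))
    S4Vectors::mcols(gr)$label <- sample(states, length(gr), replace = TRUE)
    out <- if (is.null(out)) gr else c(out, gr)
  }
  out
}

#' Simulate a gene x tissue FPKM matrix
#'
#' Each gene is expressed (log-normal FPKM above background) in a random
#' subset of tissues; `focal_fraction` of genes include the focal tissue.
#'
#' @param gene_ids Character vector of genes.
#' @param tissues Tissue names; the first is the focal tissue.
#' @param focal_fraction Probability a gene is expressed in the focal
#'   tissue.
#' @param seed Master seed.
#' @return A numeric FPKM matrix.
#' @export
simulate_fpkm_matrix <- function(gene_ids,
                                 tissues = c("CNS", "Fat_body", "Gut", "Salivary_gland"),
                                 focal_fraction = 0.4, seed = 1L) {
  set.seed(sub_seed(seed, "fpkm"))
  m <- matrix(runif(length(gene_ids) * length(tissues), 0, 1.5),
              nrow = length(gene_ids),
              dimnames = list(gene_ids, tissues))
  for (i in seq_along(gene_ids)) {
    expressed <- sample(tissues[-1L], sample(1:2, 1L))
    if (runif(1) < focal_fraction) expressed <- c(tissues[1L], expressed)
    m[i, expressed] <- rlnorm(length(expressed), log(20), 1)
  }
  m
}
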