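# Independent brute-force reference implementations.  These are written as
# plain loops over positions/pairs, deliberately sharing no code with the
# package internals they check.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(S4Vectors)
})

# maximal runs of values > thr (NA breaks), as a matrix [n, mean, first, last]
oracle_runs <- function(values, thr, min_len) {
  out <- NULL
  i <- 1L; n <- length(values)
  while (i <= n) {
    if (!is.na(values[i]) && values[i] > thr) {
      j <- i
      while (j < n && !is.na(values[j + 1L]) && values[j + 1L] > thr) j <- j + 1L
      if (j - i + 1L >= min_len)
        out <- rbind(out, c(j - i + 1L, mean(values[i:j]), i, j))
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

# shuffle-null FDR recomputation consuming the identical permutation stream
oracle_fdr <- function(values, thr, min_len, n_shuffles, seed) {
  obs <- oracle_runs(values, thr, min_len)
  if (is.null(obs)) return(numeric(0))
  nm <- which(!is.na(values))
  set.seed(as.integer(seed))
  null <- NULL
  for (s in seq_len(n_shuffles)) {
    x <- values
    x[nm] <- sample(values[nm])
    null <- rbind(null, oracle_runs(x, thr, min_len))
  }
  vapply(seq_len(nrow(obs)), function(k) {
    nt <- if (is.null(null)) 0 else
      sum(null[, 1L] >= obs[k, 1L] & null[, 2L] >= obs[k, 2L])
    ot <- sum(obs[, 1L] >= obs[k, 1L] & obs[, 2L] >= obs[k, 2L])
    max(0, min(1, (nt / n_shuffles) / ot))
  }, numeric(1))
}

# Spearman rank correlation with average ranks, from first principles
oracle_spearman <- function(a, b) {
  avg_rank <- function(x) {
    r <- numeric(length(x))
    for (i in seq_along(x)) r[i] <- (sum(x < x[i]) + 1 + sum(x <= x[i])) / 2
    r
  }
  ra <- avg_rank(a); rb <- avg_rank(b)
  sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
}

# replicate-intersection final peaks by all-pairs overlap + component closure
oracle_intersect <- function(rep1, rep2) {
  peaks <- rbind(rep1, rep2)   # columns: start, end (1-based closed), src
  n <- nrow(peaks)
  if (nrow(rep1) == 0L || nrow(rep2) == 0L) return(NULL)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (comp[i] != comp[j] &&
          peaks$start[i] <= peaks$end[j] && peaks$start[j] <= peaks$end[i]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- NULL
  for (cc in unique(comp)) {
    sel <- comp == cc
    if (length(unique(peaks$src[sel])) == 2L)
      out <- rbind(out, c(min(peaks$start[sel]), max(peaks$end[sel])))
  }
  if (is.null(out)) return(NULL)
  out[order(out[, 1L]), , drop = FALSE]
}

# gene assignment with explicit intervening-gene scan (all 1-based closed)
oracle_assign <- function(peaks, genes, max_distance) {
  out <- NULL
  for (p in seq_len(nrow(peaks))) for (g in seq_len(nrow(genes))) {
    if (peaks$chrom[p] != genes$chrom[g]) next
    overlap <- peaks$start[p] <= genes$end[g] && genes$start[g] <= peaks$end[p]
    if (overlap) {
      out <- rbind(out, data.frame(peak_id = p, gene_id = genes$gene_id[g],
                                   distance = 0))
      next
    }
    if (genes$start[g] > peaks$end[p]) {
      gap <- genes$start[g] - peaks$end[p] - 1L
      lo <- peaks$end[p] + 1L; hi <- genes$start[g] - 1L
    } else {
      gap <- peaks$start[p] - genes$end[g] - 1L
      lo <- genes$end[g] + 1L; hi <- peaks$start[p] - 1L
    }
    if (gap > max_distance) next
    blocked <- FALSE
    for (h in seq_len(nrow(genes))) {
      if (h == g || genes$chrom[h] != genes$chrom[g]) next
      if (genes$start[h] >= lo && genes$end[h] <= hi) { blocked <- TRUE; break }
    }
    if (!blocked)
      out <- rbind(out, data.frame(peak_id = p, gene_id = genes$gene_id[g],
                                   distance = gap))
  }
  if (is.null(out)) return(out)
  unique(out[order(out$peak_id, out$gene_id), ])
}

# per-peak feature category by explicit window arithmetic
oracle_classify <- function(peaks, genes, exons, prom_up = 1000, prom_down = 100,
                            tts_win = 100) {
  vapply(seq_len(nrow(peaks)), function(p) {
    pos <- floor((peaks$start[p] - 1 + peaks$end[p]) / 2) + 1
    same <- which(genes$chrom == peaks$chrom[p])
    for (g in same) {
      tss <- if (genes$strand[g] == "+") genes$start[g] else genes$end[g]
      d <- if (genes$strand[g] == "+") pos - tss else tss - pos
      if (d >= -prom_up && d <= prom_down) return("promoter-TSS")
    }
    for (g in same) {
      tts <- if (genes$strand[g] == "+") genes$end[g] else genes$start[g]
      if (abs(pos - tts) <= tts_win) return("TTS")
    }
    inside <- FALSE; inexon <- FALSE
    for (g in same) {
      if (genes$start[g] <= pos && genes$end[g] >= pos) {
        inside <- TRUE
        ex <- exons[[g]]
        for (r in seq_len(nrow(ex)))
          if (ex[r, 1L] <= pos && ex[r, 2L] >= pos) inexon <- TRUE
      }
    }
    if (inexon) return("exon")
    if (inside) return("intron")
    "intergenic"
  }, character(1))
}

# hypergeometric upper tail by explicit enumeration over choose()
oracle_hyper_p <- function(n_overlap, size_a, size_b, n_universe) {
  xs <- n_overlap:min(size_a, size_b)
  sum(choose(size_a, xs) * choose(n_universe - size_a, size_b - xs)) /
    choose(n_universe, size_b)
}

# small helpers for building fixtures
random_regions <- function(n, chrom_len, min_w = 50, max_w = 2000, chrom = "c1") {
  w <- sample(min_w:max_w, n, replace = TRUE)
  s <- sample.int(chrom_len - max_w, n, replace = TRUE)
  GRanges(chrom, IRanges(s, s + w - 1L))
}

default_test_sim <- function(...) sim_config(...)
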