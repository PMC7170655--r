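#' @importFrom methods is
#' @importFrom stats cor quantile rnorm rnbinom runif rexp rlnorm phyper
#' @importFrom utils read.table write.table
NULL

# Stop with a message assembled sprintf-style.
.fail <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.assert <- function(cond, fmt, ...) if (!isTRUE(cond)) .fail(fmt, ...)

#' Derive a labelled sub-seed from a master seed
#'
#' Stages of the pipeline and of the synthetic-data generator draw their
#' random numbers from independent streams keyed by a text label, so that
#' adding one generator never perturbs the draws of another.  The sub-seed
#' is a deterministic 31-bit hash of `(seed, label)`.
#'
#' @param seed Master seed (single integer).
#' @param label Stage label (single character string).
#' @return A single integer in `[0, 2^31 - 1)` usable with [set.seed()].
#' @export
sub_seed <- function(seed, label) {
  .assert(is.numeric(seed) && length(seed) == 1L, "seed must be a single number")
  .assert(is.character(label) && length(label) == 1L, "label must be a single string")
  h <- as.double(seed) %% 2147483647
  for (k in utf8ToInt(label)) h <- (h * 131 + k) %% 2147483647
  as.integer(h)
}

# Maximal runs of TRUE in `ok`, never crossing a change in `chrom`.
# Returns a list of integer vectors first/last (fragment indices) and the
# per-run length, filtered to runs of at least `min_len`.  `values` supplies
# per-run means when given.  Vectorised: O(n) in the number of fragments.
.scan_runs <- function(chrom, ok, min_len, values = NULL) {
  n <- length(ok)
  if (n == 0L || !any(ok)) {
    return(list(first = integer(0), last = integer(0),
                len = integer(0), mean = numeric(0)))
  }
  new_chrom <- c(TRUE, chrom[-1L] != chrom[-n])
  starts <- ok & (c(TRUE, !ok[-n]) | new_chrom)
  run_id <- cumsum(starts)
  run_id[!ok] <- 0L
  keep <- ok
  ids <- run_id[keep]
  idx <- which(keep)
  len <- tabulate(ids)
  first <- idx[!duplicated(ids)]
  last <- rev(rev(idx)[!duplicated(rev(ids))])
  m <- if (is.null(values)) rep.int(NA_real_, length(len)) else
    as.vector(rowsum(values[keep], ids)) / len
  sel <- len >= min_len
  list(first = first[sel], last = last[sel], len = len[sel], mean = m[sel])
}

# For each observed pair (obs_n[i], obs_m[i]) count reference peaks with
# ref_n >= obs_n[i] AND ref_m >= obs_m[i] (ties inclusive).  Grouped by the
# (few) distinct obs_n values; each group is one sort plus one findInterval.
.tail_counts <- function(obs_n, obs_m, ref_n, ref_m) {
  out <- numeric(length(obs_n))
  if (length(obs_n) == 0L) return(out)
  for (v in unique(obs_n)) {
    sel <- obs_n == v
    ms <- sort(ref_m[ref_n >= v])
    # findInterval(x, ms, left.open = TRUE) counts ms[j] < x, so the
    # remainder counts ms[j] >= x.
    out[sel] <- length(ms) - findInterval(obs_m[sel], ms, left.open = TRUE)
  }
  out
}

# Length-weighted mean of `values` with weights `w`, NA values dropped
# together with their weights; NA when nothing remains.
.wmean <- function(values, w) {
  keep <- !is.na(values) & w > 0
  if (!any(keep)) return(NA_real_)
  sum(values[keep] * w[keep]) / sum(w[keep])
}
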