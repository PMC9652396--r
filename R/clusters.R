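## Megabase-scale clusters of age-differential cCREs: count strongly
## differential cCREs (p < 0.001) in 100-kb bins, smooth with a Gaussian
## kernel, and call contiguous runs above a permutation-null threshold.

bin_index <- function(pos, bin_size) floor(pos / bin_size) + 1L

n_bins <- function(genome, bin_size) ceiling(genome$length / bin_size)

#' Bin differential cCRE counts along the genome
#'
#' Counts, per non-overlapping bin (default 100 kb; last partial bin kept),
#' the cCREs that are differential at `p < p_thresh` in the given direction.
#' A cCRE is assigned to the bin containing its midpoint.
#'
#' @param records Differential records from [nb_lrt()].
#' @param ccres `genomic_intervals` of all tested cCREs.
#' @param genome A `genome_layout`.
#' @param direction `"up"` or `"down"` (sign of log2fc).
#' @param p_thresh Inclusion threshold on the raw p-value (default 0.001).
#' @param bin_size Bin width in bp (default 1e5).
#' @return A `bin_track`: per-chromosome integer count vectors plus the
#'   member cCRE ids.
#' @export
bin_differential_counts <- function(records, ccres, genome,
                                    direction = c("up", "down"),
                                    p_thresh = 0.001, bin_size = 1e5) {
  direction <- match.arg(direction)
  m <- match(records$feature_id, ccres$id)
  if (anyNA(m)) {
    stop("differential record for unknown cCRE: ",
         records$feature_id[which(is.na(m))[1]])
  }
  sgn <- if (direction == "up") 1 else -1
  sel <- records$p_value < p_thresh & sign(records$log2fc) == sgn
  ids <- records$feature_id[sel]
  sub <- ccres[match(ids, ccres$id), , drop = FALSE]
  nb <- n_bins(genome, bin_size)
  counts <- lapply(seq_len(nrow(genome)), function(ci) {
    on <- sub$chrom == genome$chrom[ci]
    tabulate(bin_index((sub$start[on] + sub$end[on]) / 2, bin_size),
             nbins = nb[ci])
  })
  names(counts) <- genome$chrom
  structure(list(counts = counts, bin_size = bin_size, genome = genome,
                 direction = direction, p_thresh = p_thresh,
                 member_ids = ids),
            class = "bin_track")
}

## truncated, normalized Gaussian kernel of `window`+1 taps
gaussian_kernel <- function(window, sigma) {
  h <- floor(window / 2)
  k <- stats::dnorm(seq(-h, h), sd = sigma)
  k / sum(k)
}

## mass-conserving smoothing of one vector: each source bin distributes its
## count over the in-bounds kernel taps, renormalized at the edges
smooth_vec <- function(v, k) {
  n <- length(v)
  h <- (length(k) - 1L) / 2L
  kc <- cumsum(k)
  i <- seq_len(n)
  lo <- pmax(-h, 1L - i); hi <- pmin(h, n - i)
  S <- kc[hi + h + 1L] - c(0, kc)[lo + h + 1L]
  src <- v / S
  out <- numeric(n)
  for (t in seq(-h, h)) {
    ii <- i + t
    ok <- ii >= 1L & ii <= n
    out[ii[ok]] <- out[ii[ok]] + src[ok] * k[t + h + 1L]
  }
  out
}

#' Gaussian-smooth a binned count track
#'
#' Per-chromosome discrete convolution with a truncated Gaussian kernel
#' (window + 1 taps, normalized to sum 1; default sigma = window/4 bins).
#' Edges are renormalized over the in-bounds kernel mass so the per-
#' chromosome score total equals the count total, and no mass bleeds across
#' chromosomes.
#'
#' @param track A `bin_track`.
#' @param window Kernel window length in bins (default 20).
#' @param sigma Kernel standard deviation in bins (default window/4).
#' @return A `smoothed_track`: per-chromosome numeric score vectors.
#' @export
gaussian_smooth <- function(track, window = 20, sigma = window / 4) {
  if (window <= 0) stop("window must be positive")
  k <- gaussian_kernel(window, sigma)
  scores <- lapply(track$counts, smooth_vec, k = k)
  structure(list(scores = scores, bin_size = track$bin_size,
                 genome = track$genome, window = window, sigma = sigma),
            class = "smoothed_track")
}

#' Call clusters of age-differential cCREs
#'
#' Bins and smooths the differential cCREs, then builds a null by permuting
#' which of the tested cCREs carry the differential label (count preserved),
#' re-binning and re-smoothing `n_perm` times. The calling threshold is the
#' (1 - fdr_level) quantile of all null bin scores; contiguous observed bins
#' at or above it merge into clusters, and clusters holding fewer than
#' `min_members` differential cCREs are discarded. Deterministic given
#' `seed`.
#'
#' @inheritParams bin_differential_counts
#' @param window,sigma Smoothing kernel parameters (bins).
#' @param n_perm Number of label permutations (default 1000).
#' @param fdr_level Null-quantile level for the threshold (default 0.001).
#' @param min_members Minimum differential cCREs per cluster (default 5).
#' @param seed Integer RNG seed.
#' @param cell_type Optional label stored on the calls.
#' @return `genomic_intervals` of cluster calls with columns `direction`,
#'   `peak_score`, `n_members`; attributes `threshold` and `smoothed`.
#' @export
call_ccre_clusters <- function(records, ccres, genome,
                               direction = c("up", "down"),
                               p_thresh = 0.001, bin_size = 1e5,
                               window = 20, sigma = window / 4,
                               n_perm = 1000, fdr_level = 0.001,
                               min_members = 5, seed = 1,
                               cell_type = NA_character_) {
  direction <- match.arg(direction)
  ## canonical record order so the seeded permutation null (and hence the
  ## calls) cannot depend on input row order
  records <- records[order(records$feature_id), , drop = FALSE]
  track <- bin_differential_counts(records, ccres, genome, direction,
                                   p_thresh, bin_size)
  sm <- gaussian_smooth(track, window, sigma)
  n_diff <- length(track$member_ids)
  empty <- genomic_intervals(character(0), numeric(0), numeric(0))
  empty$direction <- character(0)
  empty$peak_score <- numeric(0)
  empty$n_members <- integer(0)
  if (n_diff == 0) return(empty)

  ## permutation null over label assignments among all tested cCREs
  set.seed(seed)
  tested <- ccres[match(records$feature_id, ccres$id), , drop = FALSE]
  ci <- match(tested$chrom, genome$chrom)
  bi <- bin_index((tested$start + tested$end) / 2, bin_size)
  nb <- n_bins(genome, bin_size)
  k <- gaussian_kernel(window, sigma)
  null_scores <- vector("list", n_perm)
  for (p in seq_len(n_perm)) {
    lab <- sample.int(nrow(tested), n_diff)
    null_scores[[p]] <- unlist(lapply(seq_len(nrow(genome)), function(cc) {
      on <- lab[ci[lab] == cc]
      smooth_vec(tabulate(bi[on], nbins = nb[cc]), k)
    }), use.names = FALSE)
  }
  theta <- stats::quantile(unlist(null_scores, use.names = FALSE),
                           1 - fdr_level, names = FALSE)

  calls <- list()
  mid_diff <- ccres[match(track$member_ids, ccres$id), , drop = FALSE]
  for (cc in seq_len(nrow(genome))) {
    sc <- sm$scores[[genome$chrom[cc]]]
    above <- sc >= theta
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      b0 <- starts[j]; b1 <- ends[j]
      iv_start <- (b0 - 1) * bin_size
      iv_end <- min(b1 * bin_size, genome$length[cc])
      on <- mid_diff$chrom == genome$chrom[cc]
      mids <- (mid_diff$start[on] + mid_diff$end[on]) / 2
      n_mem <- sum(mids >= iv_start & mids < iv_end)
      if (n_mem < min_members) next
      calls[[length(calls) + 1L]] <- data.frame(
        chrom = genome$chrom[cc], start = iv_start, end = iv_end,
        peak_score = max(sc[b0:b1]), n_members = n_mem,
        stringsAsFactors = FALSE)
    }
  }
  if (length(calls) == 0) {
    out <- empty
  } else {
    df <- do.call(rbind, calls)
    out <- genomic_intervals(df$chrom, df$start, df$end,
                             id = sprintf("cluster_%s_%02d", direction,
                                          seq_len(nrow(df))),
                             score = df$peak_score, genome = genome)
    out$direction <- direction
    out$peak_score <- df$peak_score
    out$n_members <- df$n_members
    out$cell_type <- cell_type
  }
  attr(out, "threshold") <- theta
  attr(out, "smoothed") <- sm
  out
}
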