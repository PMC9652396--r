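## ATAC quality control: TSS enrichment with Tn5-corrected insertion sites,
## nucleus filtering, and exact-depth down-sampling of pseudo-bulk samples.

## Tn5-corrected insertion sites of a fragment table. Each fragment yields
## two cut sites: the start (+ strand cut, shifted +4) and end-1 (- strand
## cut, shifted -5), the standard ATAC correction for the 9-bp Tn5 duplication.
insertion_sites <- function(fragments) {
  data.frame(
    chrom = rep(fragments$chrom, 2),
    pos = c(fragments$start + 4, fragments$end - 1 - 5),
    barcode = rep(fragments$barcode, 2),
    stringsAsFactors = FALSE
  )
}

## strand-corrected insertion offsets relative to each TSS, within +/- flank
tss_relative_positions <- function(ins, tss, flank) {
  ins_gr <- GenomicRanges::GRanges(ins$chrom,
                                   IRanges::IRanges(ins$pos + 1, width = 1))
  win <- GenomicRanges::GRanges(
    tss$chrom, IRanges::IRanges(pmax(tss$start - flank, 0) + 1,
                                tss$start + flank + 1))
  hits <- GenomicRanges::findOverlaps(ins_gr, win, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  rel <- ins$pos[qi] - tss$start[si]
  neg <- tss$strand[si] == "-"
  rel[neg] <- -rel[neg]
  keep <- abs(rel) <= flank
  list(rel = rel[keep], barcode = ins$barcode[qi][keep])
}

profile_from_rel <- function(rel, flank, n_events_total = length(rel)) {
  raw <- tabulate(rel + flank + 1, nbins = 2 * flank + 1)
  flank_idx <- c(seq_len(101), (2 * flank + 1 - 100):(2 * flank + 1))
  fm <- mean(raw[flank_idx])
  floored <- FALSE
  if (fm <= 0) {
    fm <- n_events_total / ((2 * flank + 1) * 50)
    floored <- TRUE
  }
  norm <- raw / fm
  n <- length(norm)
  cs <- cumsum(c(0, norm))
  lo <- pmax(seq_len(n) - 5, 1); hi <- pmin(seq_len(n) + 5, n)
  smoothed <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  list(position = seq(-flank, flank), raw = raw, norm = norm,
       smoothed = smoothed, score = max(smoothed), flank_floored = floored)
}

#' TSS enrichment profile and score
#'
#' Aggregates Tn5-corrected insertion events (fragment start shifted +4,
#' fragment end-1 shifted -5) at strand-corrected positions within
#' `flank` bp of every TSS, normalizes the per-bp profile by the mean of the
#' distal flanks (positions 1900-2000 bp away on both sides, 202 positions),
#' smooths with a centered 11-bp moving average (windows shrink at the
#' array edges), and reports the maximum of the smoothed profile as the
#' enrichment score. A uniform insertion profile scores ~1. If the flank
#' signal is exactly zero, the flank mean is floored at
#' `total events / (4001 * 50)` with a warning rather than dividing by zero.
#'
#' @param fragments Fragment table (chrom, start, end, barcode).
#' @param tss `genomic_intervals` of 1-bp TSS positions with strand.
#' @param flank Half-window in bp (default 2000).
#' @return A `tss_profile` list: `position`, `raw`, `norm`, `smoothed`,
#'   `score`.
#' @export
tss_enrichment <- function(fragments, tss, flank = 2000) {
  if (nrow(tss) == 0) stop("tss list is empty")
  if (nrow(fragments) == 0) stop("no insertions")
  ins <- insertion_sites(fragments)
  rp <- tss_relative_positions(ins, tss, flank)
  if (length(rp$rel) == 0) stop("no insertions within the TSS windows")
  out <- profile_from_rel(rp$rel, flank)
  if (out$flank_floored) warning("zero flank signal; flank mean floored")
  class(out) <- "tss_profile"
  out
}

#' Per-nucleus fragment counts and TSS enrichment
#'
#' Computes, for every barcode in the fragment table, its fragment count and
#' a TSS enrichment score from that barcode's own insertions.
#'
#' @inheritParams tss_enrichment
#' @return data.frame: `barcode`, `n_fragments`, `tss_enrichment`.
#' @export
nucleus_stats <- function(fragments, tss, flank = 2000) {
  nf <- table(fragments$barcode)
  ins <- insertion_sites(fragments)
  rp <- tss_relative_positions(ins, tss, flank)
  barcodes <- names(nf)
  rel_by_bc <- split(rp$rel, factor(rp$barcode, levels = barcodes))
  score <- vapply(barcodes, function(b) {
    r <- rel_by_bc[[b]]
    if (length(r) == 0) return(0)
    suppressWarnings(profile_from_rel(r, flank)$score)
  }, numeric(1))
  data.frame(barcode = barcodes, n_fragments = as.integer(nf),
             tss_enrichment = unname(score), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Filter nuclei on fragment count and TSS enrichment
#'
#' A nucleus is kept iff it has at least `min_fragments` fragments AND a TSS
#' enrichment of at least `min_tss` (the default 500/10; some tissues with
#' lower overall signal use a TSS cutoff of 7).
#'
#' @param stats data.frame from [nucleus_stats()].
#' @param min_fragments,min_tss Thresholds (both must be positive).
#' @return Character vector of kept barcodes.
#' @export
filter_nuclei <- function(stats, min_fragments = 500, min_tss = 10) {
  stopifnot(min_fragments > 0, min_tss > 0)
  keep <- stats$n_fragments >= min_fragments & stats$tss_enrichment >= min_tss
  stats$barcode[keep]
}

#' Down-sample a count vector to an exact read total
#'
#' Samples exactly `target` reads without replacement from the observed
#' counts (a multivariate hypergeometric draw), so the output column sums to
#' `target` exactly; samples with fewer than `target` reads are flagged as
#' removed, mirroring the fair-comparison rule of down-sampling every
#' pseudo-bulk sample to 1 million reads.
#'
#' @param x Non-negative integer vector of per-feature counts.
#' @param target Reads to keep (default 1e6).
#' @param seed Optional integer seed for a deterministic draw.
#' @return List with `removed` (logical) and `counts` (NULL when removed).
#' @export
downsample_sample <- function(x, target = 1e6, seed = NULL) {
  stopifnot(target > 0, all(x >= 0))
  total <- sum(x)
  if (total < target) return(list(removed = TRUE, counts = NULL))
  if (!is.null(seed)) set.seed(seed)
  out <- numeric(length(x))
  rem_total <- total
  rem_target <- target
  for (i in seq_along(x)) {
    if (rem_target == 0) break
    rem_other <- rem_total - x[i]
    k <- stats::rhyper(1, m = x[i], n = rem_other, k = rem_target)
    out[i] <- k
    rem_target <- rem_target - k
    rem_total <- rem_other
  }
  names(out) <- names(x)
  list(removed = FALSE, counts = out)
}

#' Down-sample every column of a count matrix
#'
#' Applies [downsample_sample()] per sample; under-depth samples are dropped
#' from the returned matrix.
#'
#' @param mat Raw `count_matrix`.
#' @param target Reads per sample.
#' @param seed Integer seed; column s uses sub-seed `seed + s`.
#' @return List: `matrix` (downsampled `count_matrix`, NULL if no sample
#'   survives), `removed` (character vector of removed sample ids).
#' @export
downsample_matrix <- function(mat, target = 1e6, seed = 1) {
  stopifnot(inherits(mat, "count_matrix"), mat$normalization == "raw")
  ids <- sample_id(mat$samples)
  res <- lapply(seq_len(ncol(mat$counts)), function(s) {
    downsample_sample(mat$counts[, s], target, seed = seed + s)
  })
  removed <- vapply(res, `[[`, logical(1), "removed")
  if (all(removed)) return(list(matrix = NULL, removed = ids))
  kept <- which(!removed)
  counts <- do.call(cbind, lapply(res[kept], `[[`, "counts"))
  rownames(counts) <- rownames(mat$counts)
  list(matrix = count_matrix(counts, mat$samples[kept, , drop = FALSE]),
       removed = ids[removed])
}
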