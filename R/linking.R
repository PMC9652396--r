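## Gene-cCRE linking by weighted Pearson correlation of CPM values across
## pseudo-bulk (cell type x age) data points, weighted by the number of
## cells behind each data point, plus the rank-sum concordance test between
## linked differential cCREs and gene expression changes.

#' Weighted Pearson correlation with a t-approximation p-value
#'
#' r is the weighted correlation (weighted means/variances with the given
#' positive weights); the p-value comes from the t statistic
#' `r * sqrt((n_eff - 2) / (1 - r^2))` with the Kish effective sample size
#' `n_eff = (sum w)^2 / sum(w^2)`, two-sided. The weighted correlation is
#' invariant to rescaling the weights; with equal weights it reduces exactly
#' to the ordinary Pearson correlation. The t/Kish p-value is an
#' approximation chosen here: no exact small-sample distribution exists for
#' a weighted correlation.
#'
#' @param x,y Numeric vectors (length >= 3).
#' @param w Positive weights, same length.
#' @return List: `r`, `p`, `n_eff`, `flagged` (TRUE when x or y has zero
#'   weighted variance, in which case r is NA and p = 1).
#' @export
weighted_pearson <- function(x, y, w) {
  stopifnot(length(x) == length(y), length(x) == length(w), length(x) >= 3)
  if (any(w <= 0)) stop("weights must be positive")
  sw <- sum(w)
  mx <- sum(w * x) / sw
  my <- sum(w * y) / sw
  vx <- sum(w * (x - mx)^2) / sw
  vy <- sum(w * (y - my)^2) / sw
  n_eff <- sw^2 / sum(w^2)
  if (vx <= 0 || vy <= 0) {
    return(list(r = NA_real_, p = 1, n_eff = n_eff, flagged = TRUE))
  }
  r <- sum(w * (x - mx) * (y - my)) / sw / sqrt(vx * vy)
  r <- min(1, max(-1, r))
  p <- wpcc_pvalue(r, n_eff)
  list(r = r, p = p, n_eff = n_eff, flagged = FALSE)
}

wpcc_pvalue <- function(r, n_eff) {
  df <- n_eff - 2
  if (df <= 0) return(rep(1, length(r)))
  denom <- pmax(1 - r^2, 1e-15)
  t <- r * sqrt(df / denom)
  2 * stats::pt(-abs(t), df = df)
}

#' Merge replicate columns of a count matrix into (cell type, age) points
#'
#' Sums counts and cell numbers over replicates; the result carries one
#' column per (cell type, age) combination, the data-point granularity at
#' which gene-cCRE correlations are computed.
#'
#' @param mat Raw `count_matrix`.
#' @return Raw `count_matrix` with one column per cell type x age.
#' @export
merge_replicates <- function(mat) {
  stopifnot(inherits(mat, "count_matrix"), mat$normalization == "raw")
  key <- paste(mat$samples$cell_type, mat$samples$age_months, sep = ".")
  uk <- unique(key)
  counts <- vapply(uk, function(k) {
    rowSums(mat$counts[, key == k, drop = FALSE])
  }, numeric(nrow(mat$counts)))
  rownames(counts) <- rownames(mat$counts)
  first <- match(uk, key)
  samples <- data.frame(
    cell_type = mat$samples$cell_type[first],
    age_months = mat$samples$age_months[first],
    replicate = 1L,
    n_cells = as.integer(tapply(mat$samples$n_cells, key, sum)[uk]),
    stringsAsFactors = FALSE
  )
  count_matrix(counts, samples)
}

#' Link genes to cCREs by weighted Pearson correlation
#'
#' For every (gene, cCRE) pair whose cCRE midpoint lies within `window` bp of
#' the gene's TSS, correlates the cCRE's ATAC CPM with the gene's RNA CPM
#' across the shared pseudo-bulk data points, weighting each point by its
#' cell number. P-values are BH-adjusted across ALL tested pairs; a pair is
#' a significant link when adjusted p < `alpha` and the correlation is
#' positive (enhancer-like coupling).
#'
#' @param atac CPM `count_matrix` of cCREs over merged data points.
#' @param rna CPM `count_matrix` of genes over the same data points.
#' @param ccres `genomic_intervals` of the cCREs (ids matching `atac` rows).
#' @param tss `genomic_intervals` of 1-bp TSS positions (ids matching `rna`
#'   rows; one TSS per gene).
#' @param window Maximum TSS-to-midpoint distance in bp (default 500000).
#' @param alpha BH-adjusted significance cutoff (default 0.05).
#' @return data.frame of link records: `gene_id`, `ccre_id`, `distance`,
#'   `wpcc`, `p_value`, `p_adj`, `n_points`, `n_eff`, `significant`.
#' @export
link_gene_ccres <- function(atac, rna, ccres, tss, window = 5e5,
                            alpha = 0.05) {
  stopifnot(inherits(atac, "count_matrix"), inherits(rna, "count_matrix"))
  ida <- sample_id(atac$samples); idr <- sample_id(rna$samples)
  if (!identical(sort(ida), sort(idr))) {
    stop("sample-key mismatch between ATAC and RNA matrices: ",
         paste(c(setdiff(ida, idr), setdiff(idr, ida)), collapse = ", "))
  }
  ord <- match(ida, idr)
  R <- rna$counts[, ord, drop = FALSE]
  A <- atac$counts
  w <- atac$samples$n_cells
  sw <- sum(w)
  n_eff <- sw^2 / sum(w^2)

  mid <- (ccres$start + ccres$end) / 2
  ccre_idx <- match(ccres$id, rownames(A))
  if (anyNA(ccre_idx)) stop("cCRE ids absent from the ATAC matrix")

  ## weighted-center the ATAC rows once
  Aw <- A - rowSums(sweep(A, 2, w, "*")) / sw
  Asd <- sqrt(rowSums(sweep(Aw^2, 2, w, "*")) / sw)

  res <- vector("list", nrow(tss))
  for (gi in seq_len(nrow(tss))) {
    g <- tss$id[gi]
    ri <- match(g, rownames(R))
    if (is.na(ri)) next
    cand <- which(ccres$chrom == tss$chrom[gi] &
                    abs(mid - tss$start[gi]) <= window)
    if (length(cand) == 0) next
    y <- R[ri, ]
    my <- sum(w * y) / sw
    yc <- y - my
    ysd <- sqrt(sum(w * yc^2) / sw)
    Ac <- Aw[cand, , drop = FALSE]
    covv <- as.vector(Ac %*% (w * yc)) / sw
    den <- Asd[cand] * ysd
    r <- ifelse(den > 0, covv / den, NA_real_)
    r <- pmin(1, pmax(-1, r))
    p <- ifelse(is.na(r), 1, wpcc_pvalue(r, n_eff))
    res[[gi]] <- data.frame(
      gene_id = g, ccre_id = ccres$id[cand],
      distance = as.integer(abs(mid[cand] - tss$start[gi])),
      wpcc = r, p_value = p, n_points = ncol(A), n_eff = n_eff,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res)
  if (is.null(out) || nrow(out) == 0) {
    stop("no candidate gene-cCRE pairs within the window")
  }
  out$p_adj <- stats::p.adjust(out$p_value, "BH")
  out$significant <- !is.na(out$wpcc) & out$p_adj < alpha & out$wpcc > 0
  rownames(out) <- NULL
  out
}

#' Concordance of linked cCRE and gene expression changes
#'
#' Collects, at the pair level, the RNA log2 fold changes (old over young) of
#' genes linked to age-up cCREs and of genes linked to age-down cCREs, and
#' compares the two sets with a two-sided Wilcoxon rank-sum test (normal
#' approximation with tie correction). Also counts concordant pairs: up-linked
#' genes with positive fold change plus down-linked genes with negative fold
#' change.
#'
#' @param links Link records (typically the significant subset from
#'   [link_gene_ccres()]).
#' @param age_up,age_down Character vectors of age-up / age-down cCRE ids.
#' @param gene_log2fc Named numeric vector of per-gene RNA log2 fold changes.
#' @return List: `up_log2fc`, `down_log2fc`, `statistic`, `p_value`,
#'   `n_concordant`, `flagged` (TRUE when either group is empty).
#' @export
concordance_test <- function(links, age_up, age_down, gene_log2fc) {
  up <- gene_log2fc[links$gene_id[links$ccre_id %in% age_up]]
  dn <- gene_log2fc[links$gene_id[links$ccre_id %in% age_down]]
  up <- up[!is.na(up)]; dn <- dn[!is.na(dn)]
  n_conc <- sum(up > 0) + sum(dn < 0)
  if (length(up) == 0 || length(dn) == 0) {
    return(list(up_log2fc = up, down_log2fc = dn, statistic = NA_real_,
                p_value = NA_real_, n_concordant = n_conc, flagged = TRUE))
  }
  wt <- suppressWarnings(stats::wilcox.test(up, dn, exact = FALSE,
                                            correct = TRUE))
  list(up_log2fc = up, down_log2fc = dn,
       statistic = unname(wt$statistic), p_value = wt$p.value,
       n_concordant = n_conc, flagged = FALSE)
}
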