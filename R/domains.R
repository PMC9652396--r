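## Broad heterochromatin (H3K9me3) domain calling and the statistics built
## on domains: per-domain tri-modal differential tests, per-cell fraction of
## reads in a domain set, interval overlap enrichment (Fisher and shuffle
## nulls), and aggregate signal profiles over repeat instances.

#' Call broad signal domains by window chaining
#'
#' Tiles the genome into `window`-bp bins, marks bins whose count clears the
#' Poisson upper tail at `bin_p` (lambda = genome-mean count per bin), chains
#' eligible bins separated by at most `gap` bp into candidate domains
#' (sub-threshold intervening bins included), and keeps candidates longer
#' than `min_size`. This is a window/gap island scheme in the SICER spirit
#' (no input-library correction), with a plain Poisson bin test.
#'
#' @param signal Either a fragment table (chrom, start, end; counted by
#'   midpoint) or a named per-chromosome list of bin-count vectors.
#' @param genome A `genome_layout`.
#' @param window Bin width in bp (default 5000).
#' @param gap Maximum chained gap in bp (default 10000).
#' @param min_size Minimum domain length in bp, exclusive (default 1e5).
#' @param bin_p Poisson upper-tail threshold for bin eligibility (0.01).
#' @return `genomic_intervals` of domains with columns `mean_density` and
#'   `background_density` (reads per bp).
#' @export
call_broad_domains <- function(signal, genome, window = 5000, gap = 10000,
                               min_size = 1e5, bin_p = 0.01) {
  nb <- ceiling(genome$length / window)
  if (is.data.frame(signal)) {
    counts <- lapply(seq_len(nrow(genome)), function(ci) {
      on <- signal$chrom == genome$chrom[ci]
      mid <- (signal$start[on] + signal$end[on]) / 2
      tabulate(floor(mid / window) + 1L, nbins = nb[ci])
    })
  } else {
    counts <- signal[genome$chrom]
  }
  allc <- unlist(counts, use.names = FALSE)
  if (length(allc) == 0 || sum(allc) == 0) {
    return(genomic_intervals(character(0), numeric(0), numeric(0)))
  }
  lambda <- mean(allc)
  out <- list()
  max_skip <- floor(gap / window)
  for (ci in seq_len(nrow(genome))) {
    v <- counts[[ci]]
    elig <- which(stats::ppois(v - 1, lambda, lower.tail = FALSE) < bin_p)
    if (length(elig) == 0) next
    brk <- c(0, which(diff(elig) - 1 > max_skip), length(elig))
    for (j in seq_len(length(brk) - 1)) {
      b <- elig[(brk[j] + 1):brk[j + 1]]
      s <- (b[1] - 1) * window
      e <- min(b[length(b)] * window, genome$length[ci])
      if (e - s <= min_size) next
      dens <- sum(v[b[1]:b[length(b)]]) / (e - s)
      out[[length(out) + 1L]] <- data.frame(
        chrom = genome$chrom[ci], start = s, end = e,
        mean_density = dens, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(genomic_intervals(character(0), numeric(0), numeric(0)))
  }
  df <- do.call(rbind, out)
  iv <- genomic_intervals(df$chrom, df$start, df$end,
                          id = sprintf("domain_%03d", seq_len(nrow(df))),
                          genome = genome)
  iv$mean_density <- df$mean_density
  iv$background_density <- lambda / window
  iv
}

#' Per-domain differential statistics across modalities
#'
#' For each modality (e.g. H3K9me3, ATAC, RNA aggregated over the same
#' domain intervals) and each cell type, runs the two-group NB LRT between
#' the reference and alternative age, with dispersions estimated once per
#' modality from the full matrix (groups = cell type x age). BH adjustment
#' is applied within each (cell type, modality) stratum by default;
#' `stratify_by_cell_type = FALSE` adjusts jointly across all cell types of
#' a modality instead (fewer false strata at the cost of power for
#' borderline domains).
#'
#' @param mats Named list of raw `count_matrix` objects (one per modality),
#'   all sharing identical domain ids.
#' @param ref_age,alt_age Ages (months) to contrast (default 3 vs 18).
#' @param prior_df Dispersion shrinkage prior (see [estimate_dispersions()]).
#' @param stratify_by_cell_type BH stratification switch.
#' @return data.frame: `domain_id`, `cell_type`, `modality`, `log2fc`,
#'   `p_value`, `p_adj`.
#' @export
domain_differential <- function(mats, ref_age = 3, alt_age = 18,
                                prior_df = 10,
                                stratify_by_cell_type = TRUE) {
  stopifnot(is.list(mats), length(mats) >= 1, !is.null(names(mats)))
  ids <- rownames(mats[[1]]$counts)
  for (m in mats) {
    if (!identical(rownames(m$counts), ids)) {
      stop("modality matrices have mismatched domain ids")
    }
  }
  res <- list()
  for (mod in names(mats)) {
    mat <- mats[[mod]]
    grp_all <- interaction(mat$samples$cell_type, mat$samples$age_months,
                           drop = TRUE)
    disp <- estimate_dispersions(mat, grp_all, prior_df = prior_df)
    for (ct in unique(mat$samples$cell_type)) {
      sel <- mat$samples$cell_type == ct &
        mat$samples$age_months %in% c(ref_age, alt_age)
      sub <- count_matrix(mat$counts[, sel, drop = FALSE],
                          mat$samples[sel, , drop = FALSE],
                          library_size = mat$samples$library_size[sel])
      grp <- factor(sub$samples$age_months, levels = c(ref_age, alt_age))
      rec <- nb_lrt(sub, grp, disp)
      res[[length(res) + 1L]] <- data.frame(
        domain_id = rec$feature_id, cell_type = ct, modality = mod,
        log2fc = rec$log2fc, p_value = rec$p_value,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  stratum <- if (stratify_by_cell_type) {
    paste(out$cell_type, out$modality)
  } else {
    out$modality
  }
  out$p_adj <- stats::ave(out$p_value, stratum,
                          FUN = function(p) stats::p.adjust(p, "BH"))
  rownames(out) <- NULL
  out
}

#' Per-cell fraction of reads in a domain set
#'
#' Computes, for every cell with at least one read, the fraction of its
#' reads falling in the given domain subset, and compares the per-cell
#' distributions between two ages with a two-sided Wilcoxon rank-sum test.
#' Cells with zero total reads are excluded and counted.
#'
#' @param cells data.frame: `barcode`, `cell_type`, `age_months`,
#'   `total_reads`.
#' @param domain_reads Matrix cells x domains of per-cell in-domain read
#'   counts (rows aligned with `cells`).
#' @param domain_subset Character vector of domain ids (columns) to score.
#' @param ref_age,alt_age Ages compared by the rank-sum test.
#' @return List: `frip` (per-cell records), `p_value`, `median_ref`,
#'   `median_alt`, `n_excluded`.
#' @export
fraction_reads_in_domains <- function(cells, domain_reads, domain_subset,
                                      ref_age = 3, alt_age = 18) {
  stopifnot(nrow(cells) == nrow(domain_reads))
  keep <- cells$total_reads > 0
  n_excluded <- sum(!keep)
  cells <- cells[keep, , drop = FALSE]
  dr <- domain_reads[keep, domain_subset, drop = FALSE]
  frac <- rowSums(dr) / cells$total_reads
  if (any(frac > 1 + 1e-9)) stop("in-domain reads exceed per-cell totals")
  frip <- data.frame(barcode = cells$barcode, cell_type = cells$cell_type,
                     age_months = cells$age_months,
                     fraction = pmin(frac, 1), stringsAsFactors = FALSE)
  a <- frip$fraction[frip$age_months == ref_age]
  b <- frip$fraction[frip$age_months == alt_age]
  p <- if (length(a) && length(b)) {
    suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
  } else NA_real_
  list(frip = frip, p_value = p,
       median_ref = stats::median(a), median_alt = stats::median(b),
       n_excluded = n_excluded)
}

## two-sided Fisher p by summing hypergeometric point masses no larger than
## that of the observed table
fisher_p_twosided <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  kmin <- max(0, r1 + c1 - n); kmax <- min(r1, c1)
  k <- kmin:kmax
  dk <- stats::dhyper(k, c1, n - c1, r1)
  d0 <- stats::dhyper(a, c1, n - c1, r1)
  sum(dk[dk <= d0 * (1 + 1e-7)])
}

#' Overlap enrichment of top differential cCREs in a region set
#'
#' Ranks cCREs by p-value (ties broken by |log2fc| descending, then feature
#' id), splits them into the top `top_fraction` vs the rest, crosses that
#' with >= 1 bp overlap against the region set, and tests the 2x2 table with
#' a two-sided Fisher exact test. The odds ratio is the sample OR, with the
#' Haldane +0.5 correction when any cell is zero.
#'
#' @param records Differential records ([nb_lrt()] output).
#' @param ccres `genomic_intervals` of the tested cCREs.
#' @param regions `genomic_intervals`, e.g. histone-mark domains.
#' @param top_fraction Fraction of cCREs in the "top" group (default 0.01).
#' @return List: `table` (2x2), `odds_ratio`, `p_value`, `flagged`.
#' @export
fisher_overlap_enrichment <- function(records, ccres, regions,
                                      top_fraction = 0.01) {
  if (top_fraction <= 0 || top_fraction >= 1) {
    stop("top_fraction must be in (0, 1): the rest group would be empty")
  }
  if (nrow(regions) == 0) {
    return(list(table = NULL, odds_ratio = NA_real_, p_value = NA_real_,
                flagged = TRUE))
  }
  ord <- order(records$p_value, -abs(records$log2fc), records$feature_id)
  n_top <- max(1L, round(top_fraction * nrow(records)))
  top_ids <- records$feature_id[ord][seq_len(n_top)]
  ov_ids <- ccres$id[IRanges::overlapsAny(gi_to_gr(ccres), gi_to_gr(regions),
                                          ignore.strand = TRUE)]
  is_top <- records$feature_id %in% top_ids
  is_ov <- records$feature_id %in% ov_ids
  a <- sum(is_top & is_ov); b <- sum(is_top & !is_ov)
  c_ <- sum(!is_top & is_ov); d <- sum(!is_top & !is_ov)
  tab <- matrix(c(a, b, c_, d), 2, byrow = TRUE,
                dimnames = list(c("top", "rest"), c("overlap", "no_overlap")))
  cells <- c(a, b, c_, d)
  if (any(cells == 0)) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  list(table = tab, odds_ratio = or,
       p_value = fisher_p_twosided(a, b, c_, d), flagged = FALSE)
}

#' Enrichment of domain overlap with cCRE clusters
#'
#' Observed value: the fraction of domains overlapping at least one cluster
#' by >= 1 bp (optionally a minimum fraction of the domain). The expected
#' value is computed two ways: an analytic baseline (fraction of the genome
#' covered by the merged clusters) and a shuffle null, the mean observed
#' fraction over `n_shuffles` uniform re-placements of the domain set (sizes
#' preserved, same chromosome, mutually non-overlapping). The headline fold
#' is observed over the shuffle mean, with an empirical shuffle p-value
#' `(1 + #{null >= observed}) / (n_shuffles + 1)`.
#'
#' @param domains,clusters `genomic_intervals`.
#' @param genome A `genome_layout`.
#' @param n_shuffles Number of domain-set shuffles (default 1000).
#' @param seed Integer RNG seed.
#' @param min_overlap_frac Minimum overlapped fraction of a domain for it to
#'   count as hit (default 0 = any 1-bp overlap).
#' @return List: `observed`, `expected_analytic`, `expected_shuffle`,
#'   `fold`, `p_value`, `flagged`.
#' @export
cluster_domain_overlap_enrichment <- function(domains, clusters, genome,
                                              n_shuffles = 1000, seed = 1,
                                              min_overlap_frac = 0) {
  if (nrow(clusters) == 0) {
    return(list(observed = 0, expected_analytic = NA_real_,
                expected_shuffle = NA_real_, fold = NA_real_,
                p_value = NA_real_, flagged = TRUE))
  }
  cl <- merge_overlapping(clusters, genome)
  hit_frac <- function(d_start, d_end, d_chrom) {
    vapply(seq_along(d_start), function(i) {
      on <- cl$chrom == d_chrom[i]
      ov <- pmin(cl$end[on], d_end[i]) - pmax(cl$start[on], d_start[i])
      ov_tot <- sum(ov[ov > 0])
      if (min_overlap_frac <= 0) as.numeric(ov_tot > 0)
      else as.numeric(ov_tot / (d_end[i] - d_start[i]) >= min_overlap_frac)
    }, numeric(1))
  }
  observed <- mean(hit_frac(domains$start, domains$end, domains$chrom))
  expected_analytic <- sum(cl$end - cl$start) / sum(genome$length)

  set.seed(seed)
  sizes <- domains$end - domains$start
  chroms <- domains$chrom
  clen <- genome$length[match(chroms, genome$chrom)]
  null_frac <- numeric(n_shuffles)
  for (s in seq_len(n_shuffles)) {
    placed_s <- numeric(0); placed_e <- numeric(0); placed_c <- character(0)
    ord <- order(sizes, decreasing = TRUE)
    for (i in ord) {
      for (try in 1:1000) {
        st <- floor(stats::runif(1, 0, clen[i] - sizes[i]))
        en <- st + sizes[i]
        same <- placed_c == chroms[i]
        if (!any(same & placed_s < en & placed_e > st)) break
        if (try == 1000) stop("could not place shuffled domains without overlap")
      }
      placed_s <- c(placed_s, st); placed_e <- c(placed_e, en)
      placed_c <- c(placed_c, chroms[i])
    }
    null_frac[s] <- mean(hit_frac(placed_s, placed_e, placed_c))
  }
  expected_shuffle <- mean(null_frac)
  list(observed = observed,
       expected_analytic = expected_analytic,
       expected_shuffle = expected_shuffle,
       fold = if (expected_shuffle > 0) observed / expected_shuffle else NA_real_,
       p_value = (1 + sum(null_frac >= observed)) / (n_shuffles + 1),
       flagged = FALSE)
}

#' Aggregate signal profile over stranded element instances
#'
#' Builds a meta-profile over a set of elements: each instance's body is
#' rescaled to `body_points` grid points, flanked by `flank` bp at 1-bp
#' resolution on each side; per-position fragment coverage is averaged over
#' instances (minus-strand instances are reversed), then the profile is
#' down-sampled by block means of `downsample` positions. With
#' `normalize = TRUE` the profile is divided by its mean flank level.
#'
#' @param fragments Fragment table (chrom, start, end).
#' @param instances Stranded `genomic_intervals` of element copies.
#' @param flank Flank width in bp (default 500).
#' @param body_points Grid points across the element body (default 100).
#' @param downsample Block size for the final down-sampling (default 10).
#' @param normalize Divide by mean flank coverage.
#' @return List: `profile` (numeric), `n_instances`, `flank_bins`,
#'   `body_bins`.
#' @export
aggregate_profile <- function(fragments, instances, flank = 500,
                              body_points = 100, downsample = 10,
                              normalize = FALSE) {
  if (nrow(instances) == 0) stop("no instances to aggregate over")
  grid_len <- 2 * flank + body_points
  acc <- numeric(grid_len)
  for (i in seq_len(nrow(instances))) {
    s <- instances$start[i]; e <- instances$end[i]
    w0 <- s - flank; w1 <- e + flank
    on <- fragments$chrom == instances$chrom[i] &
      fragments$start < w1 & fragments$end > w0
    cov <- numeric(w1 - w0)
    if (any(on)) {
      fs <- pmax(fragments$start[on], w0) - w0
      fe <- pmin(fragments$end[on], w1) - w0
      delta <- numeric(w1 - w0 + 1)
      for (j in seq_along(fs)) {
        delta[fs[j] + 1] <- delta[fs[j] + 1] + 1
        delta[fe[j] + 1] <- delta[fe[j] + 1] - 1
      }
      cov <- cumsum(delta[seq_len(w1 - w0)])
    }
    body_pos <- flank + floor((e - s) * (seq_len(body_points) - 0.5) /
                                body_points) + 1
    prof <- c(cov[seq_len(flank)], cov[body_pos],
              cov[(w1 - w0 - flank + 1):(w1 - w0)])
    if (instances$strand[i] == "-") prof <- rev(prof)
    acc <- acc + prof
  }
  prof <- acc / nrow(instances)
  nblk <- grid_len %/% downsample
  prof_ds <- colMeans(matrix(prof[seq_len(nblk * downsample)],
                             nrow = downsample))
  flank_bins <- flank %/% downsample
  if (normalize) {
    fl <- mean(prof_ds[c(seq_len(flank_bins),
                         (nblk - flank_bins + 1):nblk)])
    if (fl > 0) prof_ds <- prof_ds / fl
  }
  list(profile = prof_ds, n_instances = nrow(instances),
       flank_bins = flank_bins, body_bins = body_points %/% downsample)
}
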