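## Seeded synthetic-data generator: genome annotation with planted
## age-differential cCREs (a minority, cell-type specific), clustered age-up
## cCREs confined to decaying heterochromatin domains of one excitatory-
## neuron-like cell type, NB pseudo-bulk counts for ATAC / RNA / H3K9me3,
## latently coupled RNA for truth gene-cCRE links, per-cell H3K9me3 read
## assignments, and a TSS-enriched fragment file. Every stage draws from a
## sub-seed derived from the global seed by a fixed offset, so outputs are
## byte-identical across runs.

#' Simulation configuration
#'
#' Collects every tunable of the synthetic-data generator with defaults that
#' emulate the study design: 3 age groups (3, 10, 18 months) x 2 replicates
#' x 12 cell types (one excitatory-neuron-like, where all clustered effects
#' and domain decay are planted; 12 cell types x 3 ages gives the 36
#' correlation data points used for gene-cCRE linking), NB counts with
#' dispersion 0.1, 1.5-fold accessibility change per age step for the 5% of
#' cCREs planted in each direction, three ~1-Mb clusters of age-up cCREs
#' inside decaying H3K9me3 domains, 30% H3K9me3 domain decay by 18 months,
#' and 15-fold TSS insertion enrichment.
#'
#' @param seed Integer master seed.
#' @param ... Overrides for any default listed below.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    chromosomes = list(chrom = c("chr1", "chr2"), length = c(2e7, 2e7)),
    n_cell_types = 12, exn_label = "ExN",
    ages = c(3, 10, 18), replicates = 2,
    n_ccres = 4000, ccre_width = c(200, 1000),
    n_genes = 600, fraction_linked_genes = 0.2,
    n_domains = 10, domain_size = c(5e5, 1.5e6), domain_min_gap = 1.5e6,
    fraction_decaying_domains = 0.4,
    n_clusters = 3, ccres_per_cluster = 50, cluster_span = 1e6,
    ccre_baseline_meanlog = 0, ccre_baseline_sdlog = 1,
    dispersion = 0.1, k9_dispersion = 0.005,
    age_fold = 1.5,
    fraction_age_up = 0.05, fraction_age_down = 0.05,
    library_size = 2e6, rna_library_size = 1e6, k9_library_size = 1e6,
    cells_per_sample = 500,
    rna_link_r = 0.8, latent_sdlog = 1,
    domain_decay = 0.3,
    tss_enrichment_fold = 15,
    n_barcodes = 300, median_fragments = 2000, fragments_sdlog = 0.4,
    low_quality_fraction = 0.1, fragment_tss_sd = 75,
    k9_domain_fold = 5, k9_bin_lambda = 20, k9_reads_per_cell = 2500,
    n_repeat_instances = 100, repeat_width = 300
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown sim_config fields: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  fr <- c("fraction_decaying_domains", "fraction_age_up", "fraction_age_down",
          "fraction_linked_genes", "low_quality_fraction")
  for (f in fr) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must be in [0, 1]")
  }
  if (cfg$n_cell_types < 1) stop("need at least one cell type")
  if (cfg$rna_link_r < 0 || cfg$rna_link_r >= 1) {
    stop("rna_link_r must be in [0, 1)")
  }
  if (cfg$n_domains > 0 && cfg$n_clusters > 0) {
    n_dec <- round(cfg$fraction_decaying_domains * cfg$n_domains)
    if (n_dec < cfg$n_clusters) {
      stop("not enough decaying domains to host the planted clusters")
    }
  }
  class(cfg) <- "sim_config"
  cfg
}

sim_cell_types <- function(cfg) {
  if (cfg$n_cell_types == 1) return(cfg$exn_label)
  c(cfg$exn_label, sprintf("CT%02d", seq_len(cfg$n_cell_types - 1)))
}

sim_genome <- function(cfg) {
  genome_layout(cfg$chromosomes$chrom, cfg$chromosomes$length)
}

age_step <- function(age, ages) match(age, sort(ages)) - 1L

## place n disjoint intervals of the given widths uniformly on the genome,
## avoiding `existing` (data.frame chrom/start/end) and keeping at least
## `gap` bp between placed intervals; greedy with retries
place_disjoint <- function(n, widths, genome, existing = NULL,
                           max_rounds = 200, gap = 0) {
  if (n > 0 && min(widths) >= max(genome$length)) {
    stop("configuration error: requested features exceed genome capacity")
  }
  placed <- existing
  got <- NULL
  need <- n
  probs <- genome$length / sum(genome$length)
  for (round in seq_len(max_rounds)) {
    if (need <= 0) break
    m <- max(need * 2L, 10L)
    w <- widths[seq_len(need)]
    w <- rep_len(w, m)
    ci <- sample.int(nrow(genome), m, replace = TRUE, prob = probs)
    ok <- genome$length[ci] > w
    ci <- ci[ok]; w <- w[ok]; m <- sum(ok)
    if (m == 0) next
    st <- floor(stats::runif(m, 0, genome$length[ci] - w))
    cand <- data.frame(chrom = genome$chrom[ci], start = st, end = st + w)
    for (i in seq_len(m)) {
      if (need <= 0) break
      clash <- !is.null(placed) &&
        any(placed$chrom == cand$chrom[i] &
              placed$start < cand$end[i] + gap &
              placed$end > cand$start[i] - gap)
      if (!clash) {
        got <- rbind(got, cand[i, ])
        placed <- rbind(placed, cand[i, ])
        need <- need - 1L
      }
    }
  }
  if (need > 0) {
    stop("configuration error: requested features exceed genome capacity")
  }
  got
}

#' Generate the synthetic annotation and truth tables
#'
#' Lays out heterochromatin domains (a configurable fraction flagged as
#' decaying), plants clusters of age-up cCREs fully inside the largest
#' decaying domains, scatters the remaining cCREs (disjoint, 200-1000 bp),
#' assigns cell-type-specific age directions to a minority of cCREs, places
#' one stranded TSS per gene (truth-linked genes near their partner cCRE),
#' and drops repeat-element instances inside decaying domains. Deterministic
#' given the config seed.
#'
#' @param cfg A `sim_config`.
#' @return A `chromage_annotation` list: `genome`, `ccres`, `tss`,
#'   `domains`, `clusters`, `repeats`, and `truth` (per-cCRE, link, domain
#'   and cluster tables).
#' @export
generate_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 101)
  genome <- sim_genome(cfg)
  cell_types <- sim_cell_types(cfg)

  ## --- domains ---
  if (cfg$n_domains > 0) {
    dw <- round(stats::runif(cfg$n_domains, cfg$domain_size[1],
                             cfg$domain_size[2]))
    ## domains stay at least domain_min_gap apart: planted structures closer
    ## than the cluster-caller kernel support (2 Mb at default settings)
    ## would be unresolvable by construction
    dpl <- place_disjoint(cfg$n_domains, dw, genome,
                          gap = cfg$domain_min_gap)
    dpl <- dpl[order(dpl$chrom, dpl$start), ]
    domains <- genomic_intervals(dpl$chrom, dpl$start, dpl$end,
                                 id = sprintf("domain_%03d",
                                              seq_len(nrow(dpl))),
                                 genome = genome)
    n_dec <- round(cfg$fraction_decaying_domains * cfg$n_domains)
    sizes <- domains$end - domains$start
    ## decay flags: the cluster hosts must be large enough, so the largest
    ## n_clusters decaying domains are picked among the biggest domains
    hosts <- order(sizes, decreasing = TRUE)[seq_len(min(cfg$n_clusters,
                                                         cfg$n_domains))]
    rest <- setdiff(seq_len(cfg$n_domains), hosts)
    extra <- if (n_dec > length(hosts)) {
      sample(rest, n_dec - length(hosts))
    } else integer(0)
    decaying <- sort(c(hosts[seq_len(min(length(hosts), n_dec))], extra))
  } else {
    domains <- genomic_intervals(character(0), numeric(0), numeric(0))
    decaying <- integer(0)
    hosts <- integer(0)
  }

  ## --- planted clusters inside decaying host domains ---
  clusters <- NULL
  cluster_ccres <- NULL
  if (cfg$n_clusters > 0 && cfg$n_domains > 0) {
    cl <- list()
    for (k in seq_len(cfg$n_clusters)) {
      h <- hosts[k]
      hl <- domains$end[h] - domains$start[h]
      span <- min(cfg$cluster_span, floor(0.9 * hl))
      off <- floor(stats::runif(1, 0, hl - span))
      cl[[k]] <- data.frame(chrom = domains$chrom[h],
                            start = domains$start[h] + off,
                            end = domains$start[h] + off + span,
                            host = domains$id[h], stringsAsFactors = FALSE)
    }
    cl <- do.call(rbind, cl)
    clusters <- genomic_intervals(cl$chrom, cl$start, cl$end,
                                  id = sprintf("planted_cluster_%02d",
                                               seq_len(nrow(cl))),
                                  genome = genome)
    clusters$host_domain <- cl$host
    clusters$cell_type <- cfg$exn_label
    ## cluster member cCREs, disjoint within each span
    for (k in seq_len(nrow(clusters))) {
      w <- round(stats::runif(cfg$ccres_per_cluster, cfg$ccre_width[1],
                              cfg$ccre_width[2]))
      sub_genome <- genome_layout(clusters$chrom[k],
                                  genome$length[genome$chrom ==
                                                  clusters$chrom[k]])
      ## restrict placement to the cluster span by rejection
      got <- NULL
      tries <- 0
      while (is.null(got) || nrow(got) < cfg$ccres_per_cluster) {
        tries <- tries + 1
        if (tries > 500) stop("configuration error: cluster span too dense")
        st <- floor(stats::runif(1, clusters$start[k],
                                 clusters$end[k] - max(w)))
        wi <- w[(if (is.null(got)) 0 else nrow(got)) + 1]
        cand <- data.frame(chrom = clusters$chrom[k], start = st,
                           end = st + wi)
        pool <- rbind(got, if (is.null(cluster_ccres)) NULL else
          cluster_ccres[, c("chrom", "start", "end")])
        clash <- !is.null(pool) &&
          any(pool$chrom == cand$chrom & pool$start < cand$end &
                pool$end > cand$start)
        if (!clash) got <- rbind(got, cand)
      }
      got$cluster_id <- clusters$id[k]
      cluster_ccres <- rbind(cluster_ccres, got)
    }
  }

  ## --- background cCREs ---
  n_in_cluster <- if (is.null(cluster_ccres)) 0L else nrow(cluster_ccres)
  n_bg <- cfg$n_ccres - n_in_cluster
  if (n_bg < 0) stop("configuration error: more cluster cCREs than n_ccres")
  bgw <- round(stats::runif(n_bg, cfg$ccre_width[1], cfg$ccre_width[2]))
  bg <- place_disjoint(n_bg, bgw, genome,
                       existing = if (is.null(cluster_ccres)) NULL else
                         cluster_ccres[, c("chrom", "start", "end")])
  bg$cluster_id <- NA_character_
  all_ccres <- rbind(cluster_ccres, bg)
  ord <- order(all_ccres$chrom, all_ccres$start)
  all_ccres <- all_ccres[ord, ]
  ccres <- genomic_intervals(all_ccres$chrom, all_ccres$start, all_ccres$end,
                             id = sprintf("ccre_%06d",
                                          seq_len(nrow(all_ccres))),
                             genome = genome)

  ## --- per-cCRE truth: direction, affected cell type, fold per step ---
  truth_ccre <- data.frame(
    ccre_id = ccres$id,
    direction = "null", cell_type = NA_character_,
    fold_per_step = 1, cluster_id = all_ccres$cluster_id,
    stringsAsFactors = FALSE
  )
  in_cluster <- !is.na(truth_ccre$cluster_id)
  truth_ccre$direction[in_cluster] <- "up"
  truth_ccre$cell_type[in_cluster] <- cfg$exn_label
  truth_ccre$fold_per_step[in_cluster] <- cfg$age_fold
  n_up_extra <- max(0L, round(cfg$fraction_age_up * cfg$n_ccres) -
                      sum(in_cluster))
  n_down <- round(cfg$fraction_age_down * cfg$n_ccres)
  free <- which(!in_cluster)
  pick <- sample(free, n_up_extra + n_down)
  up_pick <- pick[seq_len(n_up_extra)]
  down_pick <- setdiff(pick, up_pick)
  truth_ccre$direction[up_pick] <- "up"
  truth_ccre$fold_per_step[up_pick] <- cfg$age_fold
  truth_ccre$direction[down_pick] <- "down"
  truth_ccre$fold_per_step[down_pick] <- 1 / cfg$age_fold
  affected <- c(up_pick, down_pick)
  truth_ccre$cell_type[affected] <- sample(cell_types, length(affected),
                                           replace = TRUE)

  ## --- genes: truth-linked genes sit near their partner cCRE ---
  n_linked <- round(cfg$fraction_linked_genes * cfg$n_genes)
  by_dir <- split(seq_len(nrow(truth_ccre)), truth_ccre$direction)
  n_per <- c(up = floor(n_linked / 3), down = floor(n_linked / 3))
  n_per <- c(n_per, null = n_linked - sum(n_per))
  link_ccre_idx <- integer(0)
  for (d in names(n_per)) {
    pool <- by_dir[[d]]
    take <- min(n_per[[d]], length(pool))
    link_ccre_idx <- c(link_ccre_idx, sample(pool, take))
  }
  n_linked <- length(link_ccre_idx)
  mid <- (ccres$start + ccres$end) / 2
  lchr <- ccres$chrom[link_ccre_idx]
  lpos <- round(mid[link_ccre_idx] +
                  stats::runif(n_linked, -4e5, 4e5))
  lpos <- pmax(0, pmin(lpos, genome$length[match(lchr, genome$chrom)] - 1))
  n_other <- cfg$n_genes - n_linked
  oci <- sample.int(nrow(genome), n_other, replace = TRUE,
                    prob = genome$length / sum(genome$length))
  opos <- floor(stats::runif(n_other, 0, genome$length[oci] - 1))
  gdf <- data.frame(
    chrom = c(lchr, genome$chrom[oci]),
    pos = c(lpos, opos),
    strand = sample(c("+", "-"), cfg$n_genes, replace = TRUE),
    linked_ccre = c(ccres$id[link_ccre_idx], rep(NA_character_, n_other)),
    stringsAsFactors = FALSE
  )
  gdf <- gdf[order(gdf$chrom, gdf$pos), ]
  gdf$gene_id <- sprintf("gene_%04d", seq_len(nrow(gdf)))
  tss <- genomic_intervals(gdf$chrom, gdf$pos, gdf$pos + 1,
                           id = gdf$gene_id, strand = gdf$strand,
                           genome = genome)
  linked_rows <- which(!is.na(gdf$linked_ccre))
  truth_links <- data.frame(
    gene_id = gdf$gene_id[linked_rows],
    ccre_id = gdf$linked_ccre[linked_rows],
    target_r = rep(cfg$rna_link_r, length(linked_rows)),
    stringsAsFactors = FALSE)

  ## --- repeat-element instances inside decaying domains ---
  repeats <- genomic_intervals(character(0), numeric(0), numeric(0))
  if (cfg$n_repeat_instances > 0 && length(decaying) > 0) {
    dd <- domains[decaying, , drop = FALSE]
    ri <- sample(seq_len(nrow(dd)), cfg$n_repeat_instances, replace = TRUE,
                 prob = dd$end - dd$start)
    rst <- floor(stats::runif(cfg$n_repeat_instances, dd$start[ri],
                              dd$end[ri] - cfg$repeat_width))
    repeats <- genomic_intervals(dd$chrom[ri], rst, rst + cfg$repeat_width,
                                 id = sprintf("rep_%04d",
                                              seq_len(cfg$n_repeat_instances)),
                                 strand = sample(c("+", "-"),
                                                 cfg$n_repeat_instances,
                                                 replace = TRUE),
                                 genome = genome)
    repeats <- repeats[order(repeats$chrom, repeats$start), ]
  }

  truth_domains <- data.frame(
    domain_id = domains$id,
    decaying = seq_len(nrow(domains)) %in% decaying,
    delta = ifelse(seq_len(nrow(domains)) %in% decaying,
                   cfg$domain_decay, 0),
    stringsAsFactors = FALSE)

  structure(list(
    genome = genome, cell_types = cell_types,
    ccres = ccres, tss = tss, domains = domains,
    clusters = if (is.null(clusters)) {
      genomic_intervals(character(0), numeric(0), numeric(0))
    } else clusters,
    repeats = repeats,
    truth = list(ccre = truth_ccre, links = truth_links,
                 domains = truth_domains)
  ), class = "chromage_annotation")
}

sim_samples <- function(cfg) {
  g <- expand.grid(replicate = seq_len(cfg$replicates),
                   age_months = sort(cfg$ages),
                   cell_type = sim_cell_types(cfg),
                   stringsAsFactors = FALSE)
  g <- g[, c("cell_type", "age_months", "replicate")]
  g$n_cells <- cfg$cells_per_sample
  g
}

#' Generate pseudo-bulk count matrices with planted effects
#'
#' ATAC counts are NB draws around log-normal baselines scaled per sample;
#' age-affected cCREs multiply their mean by `age_fold` per age step (3 ->
#' 10 -> 18 months) in their affected cell type only. RNA counts for
#' truth-linked genes share a latent per-(cell type, age) activity with
#' their partner cCRE (correlation calibrated to the configured target);
#' other genes are age-flat. H3K9me3 domain counts decay by
#' `1 - delta * step/2` in decaying domains of the excitatory-neuron-like
#' cell type only; per-cell read-to-domain assignments for that cell type
#' are recorded for the fraction-of-reads-in-domain statistic, and a binned
#' genome-wide H3K9me3 signal is emitted for the domain caller.
#'
#' @param ann A `chromage_annotation`.
#' @param cfg The same `sim_config` that produced it.
#' @return List: `atac`, `rna`, `k9_domains` (all `count_matrix`),
#'   `k9_cells` (list `cells`, `domain_reads`), `k9_bins` (per-chromosome
#'   bin counts, 5-kb bins), `samples`.
#' @export
generate_counts <- function(ann, cfg) {
  stopifnot(inherits(ann, "chromage_annotation"))
  set.seed(cfg$seed + 202)
  samples <- sim_samples(cfg)
  n_s <- nrow(samples)
  steps <- age_step(samples$age_months, cfg$ages)
  ct <- samples$cell_type
  ages_sorted <- sort(cfg$ages)
  point_key <- paste(samples$cell_type, samples$age_months, sep = ".")

  ## --- ATAC ---
  n_c <- nrow(ann$ccres)
  base <- stats::rlnorm(n_c, cfg$ccre_baseline_meanlog,
                        cfg$ccre_baseline_sdlog)
  base <- base / sum(base)
  tc <- ann$truth$ccre
  foldmat <- matrix(1, n_c, n_s)
  aff <- which(tc$direction != "null")
  for (i in aff) {
    on <- ct == tc$cell_type[i]
    foldmat[i, on] <- tc$fold_per_step[i]^steps[on]
  }
  ## latent activity shared between linked cCRE and gene, per (ct, age)
  links <- ann$truth$links
  cell_types <- ann$cell_types
  pt_grid <- expand.grid(age_months = ages_sorted, cell_type = cell_types,
                         stringsAsFactors = FALSE)
  pt_id <- paste(pt_grid$cell_type, pt_grid$age_months, sep = ".")
  s2pt <- match(point_key, pt_id)
  latmat <- matrix(1, n_c, n_s)
  U <- NULL
  if (nrow(links) > 0) {
    U <- matrix(stats::rnorm(nrow(links) * length(pt_id), 0,
                             cfg$latent_sdlog),
                nrow = nrow(links), dimnames = list(links$gene_id, pt_id))
    li <- match(links$ccre_id, ann$ccres$id)
    latmat[li, ] <- exp(U[, s2pt, drop = FALSE] - cfg$latent_sdlog^2 / 2)
  }
  mu_atac <- (base %o% rep(cfg$library_size, n_s)) * foldmat * latmat
  atac_counts <- matrix(stats::rnbinom(n_c * n_s, mu = mu_atac,
                                       size = 1 / cfg$dispersion),
                        n_c, n_s, dimnames = list(ann$ccres$id, NULL))
  atac <- count_matrix(atac_counts, samples)

  ## --- RNA ---
  n_g <- nrow(ann$tss)
  gbase <- stats::rlnorm(n_g, 0, 1)
  gbase <- gbase / sum(gbase)
  gmul <- matrix(1, n_g, length(pt_id), dimnames = list(ann$tss$id, pt_id))
  if (nrow(links) > 0) {
    ## latent correlation inflated so the realized count-level correlation
    ## lands near the target despite NB measurement noise
    rho <- min(0.99, cfg$rna_link_r *
                 (1 + cfg$dispersion / cfg$latent_sdlog^2))
    li <- match(links$ccre_id, ann$ccres$id)
    lg <- match(links$gene_id, ann$tss$id)
    pt_steps <- age_step(pt_grid$age_months, cfg$ages)
    for (k in seq_len(nrow(links))) {
      f_pt <- rep(1, length(pt_id))
      if (tc$direction[li[k]] != "null") {
        on <- pt_grid$cell_type == tc$cell_type[li[k]]
        f_pt[on] <- tc$fold_per_step[li[k]]^pt_steps[on]
      }
      s_act <- log(f_pt) + U[k, ]
      sc <- s_act - mean(s_act)
      sds <- stats::sd(sc)
      z <- stats::rnorm(length(pt_id))
      v <- rho * sc + sqrt(1 - rho^2) * sds * z
      gmul[lg[k], ] <- exp(v - stats::var(v) / 2)
    }
  }
  mu_rna <- (gbase %o% rep(cfg$rna_library_size, n_s)) *
    gmul[, s2pt, drop = FALSE]
  rna_counts <- matrix(stats::rnbinom(n_g * n_s, mu = mu_rna,
                                      size = 1 / cfg$dispersion),
                       n_g, n_s, dimnames = list(ann$tss$id, NULL))
  rna <- count_matrix(rna_counts, samples)

  ## --- H3K9me3 domain counts ---
  n_d <- nrow(ann$domains)
  k9 <- NULL; k9_cells <- NULL; k9_bins <- NULL
  if (n_d > 0) {
    dlen <- ann$domains$end - ann$domains$start
    dshare <- dlen / sum(dlen)
    decayf <- matrix(1, n_d, n_s)
    dec <- which(ann$truth$domains$decaying)
    exn_s <- ct == cfg$exn_label
    for (d in dec) {
      decayf[d, exn_s] <- 1 - cfg$domain_decay * steps[exn_s] / 2
    }
    mu_k9 <- (dshare %o% rep(cfg$k9_library_size, n_s)) * decayf
    k9_counts <- matrix(stats::rnbinom(n_d * n_s, mu = mu_k9,
                                       size = 1 / cfg$k9_dispersion),
                        n_d, n_s, dimnames = list(ann$domains$id, NULL))
    ## library size is the per-sample sequencing depth, not the in-domain
    ## total: domain decay lowers FRiP, not the library
    k9 <- count_matrix(k9_counts, samples,
                       library_size = rep(cfg$k9_library_size, n_s))

    ## per-cell read-domain assignments for the ExN-like cell type
    exn_samples <- which(exn_s)
    cells <- list(); dr <- list()
    bg_len <- sum(ann$genome$length) - sum(dlen)
    for (s in exn_samples) {
      wts <- c(bg_len, dlen * cfg$k9_domain_fold * decayf[, s])
      pr <- wts / sum(wts)
      tot <- pmax(1, round(stats::rlnorm(cfg$cells_per_sample,
                                         log(cfg$k9_reads_per_cell), 0.3)))
      draw <- vapply(tot, function(n) {
        stats::rmultinom(1, n, pr)[, 1]
      }, numeric(length(pr)))
      cells[[length(cells) + 1L]] <- data.frame(
        barcode = sprintf("%s.%d.%d.c%04d", samples$cell_type[s],
                          samples$age_months[s], samples$replicate[s],
                          seq_len(cfg$cells_per_sample)),
        cell_type = samples$cell_type[s],
        age_months = samples$age_months[s],
        total_reads = tot, stringsAsFactors = FALSE)
      dr[[length(dr) + 1L]] <- t(draw[-1, , drop = FALSE])
    }
    cells <- do.call(rbind, cells)
    domain_reads <- do.call(rbind, dr)
    colnames(domain_reads) <- ann$domains$id
    k9_cells <- list(cells = cells, domain_reads = domain_reads)

    ## binned genome-wide H3K9me3 signal (young ExN pooled) for the caller
    bin <- 5000
    k9_bins <- lapply(seq_len(nrow(ann$genome)), function(ci) {
      nb <- ceiling(ann$genome$length[ci] / bin)
      lam <- rep(cfg$k9_bin_lambda, nb)
      on <- which(ann$domains$chrom == ann$genome$chrom[ci])
      for (d in on) {
        b0 <- floor(ann$domains$start[d] / bin) + 1
        b1 <- ceiling(ann$domains$end[d] / bin)
        lam[b0:b1] <- cfg$k9_bin_lambda * cfg$k9_domain_fold
      }
      stats::rpois(nb, lam)
    })
    names(k9_bins) <- ann$genome$chrom
  }

  list(atac = atac, rna = rna, k9_domains = k9, k9_cells = k9_cells,
       k9_bins = k9_bins, samples = samples)
}

## expected TSS profile math for calibrating the targeted-fragment fraction
frag_len_probs <- function(max_len = 1470) {
  l <- 0:max_len
  p <- stats::dgamma(l, shape = 2, scale = 75)
  p / sum(p)
}

## combined density of the two cut sites of a TSS-targeted fragment at
## TSS-relative positions: first cut ~ N(0, sd), second cut one fragment
## length downstream
tss_cut_kernel <- function(flank, tss_sd) {
  r <- seq(-flank, flank)
  k1 <- stats::dnorm(r, 0, tss_sd)
  lp <- frag_len_probs()
  k2 <- numeric(length(r))
  for (li in seq_along(lp)) {
    if (lp[li] < 1e-7) next
    shift <- (li - 1) + 30
    idx <- which(r - shift >= -flank)
    k2[idx] <- k2[idx] + lp[li] * k1[idx - shift]
  }
  k1 + k2
}

expected_tss_score <- function(pi_t, kern, flank, n_tss, genome_len) {
  flat <- (1 - pi_t) * 2 * n_tss / genome_len
  prof <- flat + pi_t * kern
  n <- length(prof)
  fm <- mean(prof[c(seq_len(101), (n - 100):n)])
  norm <- prof / fm
  cs <- cumsum(c(0, norm))
  lo <- pmax(seq_len(n) - 5, 1); hi <- pmin(seq_len(n) + 5, n)
  max((cs[hi + 1] - cs[lo]) / (hi - lo + 1))
}

#' Generate a barcoded fragment file with TSS enrichment
#'
#' Fragment counts per barcode are log-normal around the configured median.
#' Each fragment's first Tn5 cut is either background (uniform on the
#' genome) or TSS-targeted (normal around a random TSS); the targeted
#' fraction is calibrated numerically so the expected aggregate TSS
#' enrichment score equals the configured fold. A configurable fraction of
#' barcodes is low quality: half with fewer than 500 fragments, half with
#' background-only insertions. Fragment coordinates are built so that the
#' +4/-5 Tn5 correction recovers the simulated cut sites exactly.
#'
#' @param ann A `chromage_annotation`.
#' @param cfg The `sim_config`.
#' @return List: `fragments` (chrom, start, end, barcode), `barcodes`
#'   (truth: barcode, low_quality, type), `targeted_fraction`.
#' @export
generate_fragments <- function(ann, cfg) {
  set.seed(cfg$seed + 303)
  genome <- ann$genome
  glen <- sum(genome$length)
  n_tss <- nrow(ann$tss)
  fold <- cfg$tss_enrichment_fold
  pi_t <- 0
  if (fold > 1) {
    kern <- tss_cut_kernel(2000, cfg$fragment_tss_sd)
    pi_t <- stats::uniroot(function(p) {
      expected_tss_score(p, kern, 2000, n_tss, glen) - fold
    }, c(1e-6, 0.999), tol = 1e-6)$root
  }

  n_bc <- cfg$n_barcodes
  n_lq <- round(cfg$low_quality_fraction * n_bc)
  type <- rep("good", n_bc)
  if (n_lq > 0) {
    lq <- sample.int(n_bc, n_lq)
    half <- lq[seq_len(ceiling(n_lq / 2))]
    type[half] <- "low_count"
    type[setdiff(lq, half)] <- "background_only"
  }
  counts <- round(stats::rlnorm(n_bc, log(cfg$median_fragments),
                                cfg$fragments_sdlog))
  counts[type == "low_count"] <- round(stats::runif(sum(type == "low_count"),
                                                    50, 450))
  barcodes <- sprintf("BC%04d", seq_len(n_bc))

  bc_col <- rep(barcodes, counts)
  n_frag <- length(bc_col)
  targeted <- stats::runif(n_frag) < pi_t
  targeted[rep(type, counts) == "background_only"] <- FALSE

  lens <- 30 + round(stats::rgamma(n_frag, shape = 2, scale = 75))
  lens <- pmin(lens, 1900)
  cut <- numeric(n_frag)
  chrom <- character(n_frag)
  nt <- sum(targeted)
  if (nt > 0) {
    ti <- sample.int(n_tss, nt, replace = TRUE)
    cut[targeted] <- ann$tss$start[ti] +
      round(stats::rnorm(nt, 0, cfg$fragment_tss_sd))
    chrom[targeted] <- ann$tss$chrom[ti]
  }
  nb <- sum(!targeted)
  if (nb > 0) {
    ci <- sample.int(nrow(genome), nb, replace = TRUE,
                     prob = genome$length / sum(genome$length))
    cut[!targeted] <- floor(stats::runif(nb, 0, genome$length[ci]))
    chrom[!targeted] <- genome$chrom[ci]
  }
  clen <- genome$length[match(chrom, genome$chrom)]
  cut <- pmax(4, pmin(cut, clen - lens - 10))
  frag <- data.frame(chrom = chrom, start = cut - 4, end = cut + lens + 6,
                     barcode = bc_col, stringsAsFactors = FALSE)
  frag <- frag[sample.int(n_frag), ]
  rownames(frag) <- NULL
  list(fragments = frag,
       barcodes = data.frame(barcode = barcodes, type = type,
                             low_quality = type != "good",
                             stringsAsFactors = FALSE),
       targeted_fraction = pi_t)
}

#' Write a simulation to disk
#'
#' Emits BED files for cCREs, domains, TSSs, planted clusters and repeats,
#' TSV count matrices, the fragments file, truth tables, and a YAML dump of
#' the resolved configuration.
#'
#' @param ann Annotation from [generate_annotation()].
#' @param counts Output of [generate_counts()].
#' @param frag Output of [generate_fragments()] (optional).
#' @param cfg The `sim_config`.
#' @param dir Output directory (created if missing).
#' @export
write_simulation <- function(ann, counts, frag = NULL, cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_bed(ann$ccres, file.path(dir, "ccres.bed"))
  write_bed(ann$tss, file.path(dir, "tss.bed"))
  if (nrow(ann$domains) > 0) {
    write_bed(ann$domains, file.path(dir, "domains.bed"))
  }
  if (nrow(ann$clusters) > 0) {
    write_bed(ann$clusters, file.path(dir, "clusters_truth.bed"))
  }
  if (nrow(ann$repeats) > 0) {
    write_bed(ann$repeats, file.path(dir, "repeats.bed"))
  }
  write_count_matrix(counts$atac, file.path(dir, "counts_atac.tsv"))
  write_count_matrix(counts$rna, file.path(dir, "counts_rna.tsv"))
  if (!is.null(counts$k9_domains)) {
    write_count_matrix(counts$k9_domains,
                       file.path(dir, "counts_k9_domains.tsv"))
  }
  tdir <- file.path(dir, "truth")
  dir.create(tdir, showWarnings = FALSE)
  for (nm in names(ann$truth)) {
    utils::write.table(ann$truth[[nm]],
                       file.path(tdir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(frag)) {
    utils::write.table(frag$fragments, file.path(dir, "fragments.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    utils::write.table(frag$barcodes, file.path(dir, "barcodes_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  cfg_plain <- unclass(cfg)
  yaml::write_yaml(cfg_plain, file.path(dir, "sim_config.yaml"))
  invisible(dir)
}
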