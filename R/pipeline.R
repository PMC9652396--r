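## End-to-end pipeline on synthetic data: generate -> QC -> differential ->
## linking -> cluster calling -> domain analysis, with every stage seeded
## from the master seed so two runs produce byte-identical outputs.

#' Per-cell-type differential accessibility between two ages
#'
#' Runs dispersion estimation and the NB LRT (alt age vs ref age) within
#' each cell type of a pseudo-bulk count matrix.
#'
#' @param mat Raw `count_matrix`.
#' @param ref_age,alt_age Ages (months) to contrast.
#' @param alpha Direction-label cutoff passed to [nb_lrt()].
#' @param prior_df Dispersion shrinkage prior.
#' @return Named list (by cell type) of differential record data.frames.
#' @export
differential_by_celltype <- function(mat, ref_age = 3, alt_age = 18,
                                     alpha = 0.01, prior_df = 10) {
  out <- list()
  for (ct in unique(mat$samples$cell_type)) {
    sel <- mat$samples$cell_type == ct &
      mat$samples$age_months %in% c(ref_age, alt_age)
    sub <- count_matrix(mat$counts[, sel, drop = FALSE],
                        mat$samples[sel, , drop = FALSE],
                        library_size = mat$samples$library_size[sel])
    grp <- factor(sub$samples$age_months, levels = c(ref_age, alt_age))
    disp <- estimate_dispersions(sub, grp, prior_df = prior_df)
    out[[ct]] <- nb_lrt(sub, grp, disp, alpha = alpha)
  }
  out
}

#' Pairwise Jaccard matrix of age-differential cCRE sets
#'
#' @param diff_by_ct Output of [differential_by_celltype()].
#' @param alpha Cutoff defining the age-differential set of each cell type.
#' @return Symmetric matrix of Jaccard indices between cell types.
#' @export
jaccard_matrix <- function(diff_by_ct, alpha = 0.01) {
  sets <- lapply(diff_by_ct, function(r) {
    cl <- classify_age_ccres(r, alpha)
    c(cl$age_up, cl$age_down)
  })
  n <- length(sets)
  m <- matrix(1, n, n, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    m[i, j] <- jaccard_index(sets[[i]], sets[[j]])
  }
  m
}

#' Pooled concordance test across cell types
#'
#' For each cell type, collects the RNA log2 fold changes of genes linked
#' (through significant links) to that cell type's age-up and age-down
#' cCREs, pools the pair-level values over cell types, and runs the
#' two-sided rank-sum test between the up-linked and down-linked groups.
#'
#' @param links Significant link records.
#' @param atac_diff,rna_diff Outputs of [differential_by_celltype()] for
#'   ATAC (cCREs) and RNA (genes).
#' @param alpha Cutoff for the cCRE age sets (raw p).
#' @param rna_alpha BH-adjusted cutoff defining concordant differential
#'   genes for the pair count.
#' @return As [concordance_test()], plus `n_pairs_up`, `n_pairs_down`.
#' @export
concordance_by_celltype <- function(links, atac_diff, rna_diff,
                                    alpha = 0.01, rna_alpha = 0.1) {
  up <- numeric(0); dn <- numeric(0); n_conc <- 0L
  for (ct in names(atac_diff)) {
    cl <- classify_age_ccres(atac_diff[[ct]], alpha)
    fc <- stats::setNames(rna_diff[[ct]]$log2fc, rna_diff[[ct]]$feature_id)
    sig_gene <- rna_diff[[ct]]$feature_id[rna_diff[[ct]]$p_adj < rna_alpha]
    u <- fc[links$gene_id[links$ccre_id %in% cl$age_up]]
    d <- fc[links$gene_id[links$ccre_id %in% cl$age_down]]
    gu <- links$gene_id[links$ccre_id %in% cl$age_up]
    gd <- links$gene_id[links$ccre_id %in% cl$age_down]
    n_conc <- n_conc + sum(u > 0 & gu %in% sig_gene, na.rm = TRUE) +
      sum(d < 0 & gd %in% sig_gene, na.rm = TRUE)
    up <- c(up, u[!is.na(u)]); dn <- c(dn, d[!is.na(d)])
  }
  if (length(up) == 0 || length(dn) == 0) {
    return(list(up_log2fc = up, down_log2fc = dn, statistic = NA_real_,
                p_value = NA_real_, n_concordant = n_conc, flagged = TRUE,
                n_pairs_up = length(up), n_pairs_down = length(dn)))
  }
  wt <- suppressWarnings(stats::wilcox.test(up, dn, exact = FALSE))
  list(up_log2fc = up, down_log2fc = dn, statistic = unname(wt$statistic),
       p_value = wt$p.value, n_concordant = n_conc, flagged = FALSE,
       n_pairs_up = length(up), n_pairs_down = length(dn))
}

#' Run the full synthetic-data pipeline
#'
#' Generates annotation, counts and fragments from the configuration, then
#' runs nucleus QC, per-sample down-sampling, per-cell-type differential
#' testing, gene-cCRE linking with the concordance test, cluster calling in
#' the excitatory-neuron-like cell type, broad-domain calling on the binned
#' H3K9me3 signal, per-domain differential statistics, the per-cell
#' fraction-of-reads-in-domain comparison, overlap enrichment tests, and an
#' aggregate profile over the planted repeat instances. All stages derive
#' their seeds from `cfg$seed`; when `outdir` is given, inputs and results
#' are written as plain-text files.
#'
#' @param cfg A `sim_config`.
#' @param outdir Optional output directory.
#' @param n_perm Permutations for cluster calling (default 1000).
#' @param n_shuffles Shuffles for the domain-cluster enrichment (default
#'   1000).
#' @return List with all intermediate results and a `summary` list of key
#'   numbers.
#' @export
run_pipeline <- function(cfg = sim_config(), outdir = NULL, n_perm = 1000,
                         n_shuffles = 1000) {
  ann <- generate_annotation(cfg)
  counts <- generate_counts(ann, cfg)
  frag <- generate_fragments(ann, cfg)
  exn <- cfg$exn_label

  ## --- QC ---
  qc_stats <- nucleus_stats(frag$fragments, ann$tss)
  kept <- filter_nuclei(qc_stats)
  pooled_tss <- tss_enrichment(frag$fragments[
    frag$fragments$barcode %in%
      frag$barcodes$barcode[!frag$barcodes$low_quality], ], ann$tss)
  ds <- downsample_matrix(counts$atac, target = 1e6, seed = cfg$seed + 404)

  ## --- differential accessibility and expression, per cell type ---
  atac_diff <- differential_by_celltype(counts$atac)
  rna_diff <- differential_by_celltype(counts$rna)
  jac <- jaccard_matrix(atac_diff)

  ## --- gene-cCRE linking ---
  atac_cpm <- cpm_normalize(merge_replicates(counts$atac))
  rna_cpm <- cpm_normalize(merge_replicates(counts$rna))
  links <- link_gene_ccres(atac_cpm, rna_cpm, ann$ccres, ann$tss)
  sig_links <- links[links$significant, , drop = FALSE]
  conc <- concordance_by_celltype(sig_links, atac_diff, rna_diff)

  ## --- cCRE clusters in the ExN-like cell type ---
  cl_up <- call_ccre_clusters(atac_diff[[exn]], ann$ccres, ann$genome,
                              direction = "up", n_perm = n_perm,
                              seed = cfg$seed + 505, cell_type = exn)
  cl_down <- call_ccre_clusters(atac_diff[[exn]], ann$ccres, ann$genome,
                                direction = "down", n_perm = n_perm,
                                seed = cfg$seed + 506, cell_type = exn)

  ## --- H3K9me3 domains ---
  called_domains <- NULL; dom_diff <- NULL; frip <- NULL
  overlap_enr <- NULL; fisher_enr <- NULL
  if (!is.null(counts$k9_domains)) {
    called_domains <- call_broad_domains(counts$k9_bins, ann$genome)
    dom_diff <- domain_differential(list(H3K9me3 = counts$k9_domains))
    reduced <- dom_diff$domain_id[dom_diff$cell_type == exn &
                                    dom_diff$log2fc < 0 &
                                    dom_diff$p_adj < 0.05]
    if (length(reduced) > 0) {
      frip <- fraction_reads_in_domains(counts$k9_cells$cells,
                                        counts$k9_cells$domain_reads,
                                        reduced)
    }
    if (nrow(cl_up) > 0) {
      overlap_enr <- cluster_domain_overlap_enrichment(
        ann$domains, cl_up, ann$genome, n_shuffles = n_shuffles,
        seed = cfg$seed + 607)
    }
    fisher_enr <- fisher_overlap_enrichment(atac_diff[[exn]], ann$ccres,
                                            ann$domains)
  }

  ## --- aggregate profile over repeat instances ---
  repeat_profile <- if (nrow(ann$repeats) > 0) {
    aggregate_profile(frag$fragments, ann$repeats, flank = 500,
                      normalize = TRUE)
  } else NULL

  summary <- list(
    seed = cfg$seed,
    n_barcodes = nrow(qc_stats), n_kept_barcodes = length(kept),
    pooled_tss_score = pooled_tss$score,
    n_samples_downsampled = if (is.null(ds$matrix)) 0 else
      ncol(ds$matrix$counts),
    n_age_up_exn = length(classify_age_ccres(atac_diff[[exn]])$age_up),
    n_age_down_exn = length(classify_age_ccres(atac_diff[[exn]])$age_down),
    n_sig_links = nrow(sig_links),
    concordance_p = conc$p_value,
    n_clusters_up = nrow(cl_up), n_clusters_down = nrow(cl_down),
    n_called_domains = if (is.null(called_domains)) 0 else
      nrow(called_domains),
    n_decayed_domains_exn = if (is.null(dom_diff)) 0 else
      sum(dom_diff$cell_type == exn & dom_diff$log2fc < 0 &
            dom_diff$p_adj < 0.05),
    frip_p = if (is.null(frip)) NA else frip$p_value,
    cluster_domain_fold = if (is.null(overlap_enr)) NA else
      overlap_enr$fold
  )

  res <- list(config = cfg, annotation = ann, counts = counts,
              fragments = frag, qc_stats = qc_stats, kept_barcodes = kept,
              downsampled = ds, atac_diff = atac_diff, rna_diff = rna_diff,
              jaccard = jac, links = links, concordance = conc,
              clusters_up = cl_up, clusters_down = cl_down,
              called_domains = called_domains, domain_diff = dom_diff,
              frip = frip, overlap_enrichment = overlap_enr,
              fisher_enrichment = fisher_enr,
              repeat_profile = repeat_profile, summary = summary)

  if (!is.null(outdir)) write_pipeline(res, outdir)
  invisible(res)
}

#' @keywords internal
write_pipeline <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_simulation(res$annotation, res$counts, res$fragments, res$config,
                   file.path(outdir, "sim"))
  wt <- function(x, f) utils::write.table(
    x, file.path(outdir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(res$qc_stats, "qc_barcode_stats.tsv")
  writeLines(res$kept_barcodes, file.path(outdir, "kept_barcodes.txt"))
  for (ct in names(res$atac_diff)) {
    wt(res$atac_diff[[ct]], sprintf("diff_atac_%s.tsv", ct))
  }
  wt(res$links, "links.tsv")
  if (nrow(res$clusters_up) > 0) {
    write_bed(res$clusters_up, file.path(outdir, "clusters_up.bed"))
  }
  if (nrow(res$clusters_down) > 0) {
    write_bed(res$clusters_down, file.path(outdir, "clusters_down.bed"))
  }
  if (!is.null(res$called_domains) && nrow(res$called_domains) > 0) {
    write_bed(res$called_domains, file.path(outdir, "called_domains.bed"))
  }
  if (!is.null(res$domain_diff)) wt(res$domain_diff, "domain_differential.tsv")
  if (!is.null(res$frip)) wt(res$frip$frip, "frip_per_cell.tsv")
  jsonlite::write_json(res$summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
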