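test_that("generation is deterministic given the seed", {
  cfg <- sim_config(seed = 3, n_ccres = 500, n_genes = 80,
                    n_cell_types = 3, cells_per_sample = 50,
                    library_size = 2e5, rna_library_size = 1e5,
                    n_barcodes = 40, median_fragments = 300)
  a1 <- generate_annotation(cfg)
  a2 <- generate_annotation(cfg)
  expect_identical(a1, a2)
  c1 <- generate_counts(a1, cfg)
  c2 <- generate_counts(a2, cfg)
  expect_identical(c1$atac$counts, c2$atac$counts)
  expect_identical(c1$rna$counts, c2$rna$counts)
  expect_identical(c1$k9_domains$counts, c2$k9_domains$counts)
  f1 <- generate_fragments(a1, cfg)
  f2 <- generate_fragments(a2, cfg)
  expect_identical(f1$fragments, f2$fragments)
})

test_that("planted cluster cCREs are contained in decaying domains", {
  sim <- default_sim()
  ann <- sim$ann
  tc <- ann$truth$ccre
  cl_ids <- tc$ccre_id[!is.na(tc$cluster_id)]
  expect_gte(length(cl_ids), 3 * 20)
  expect_true(all(tc$direction[!is.na(tc$cluster_id)] == "up"))
  expect_true(all(tc$cell_type[!is.na(tc$cluster_id)] == "ExN"))
  dec <- ann$domains[ann$truth$domains$decaying, ]
  sub <- ann$ccres[match(cl_ids, ann$ccres$id), ]
  inside <- vapply(seq_len(nrow(sub)), function(i) {
    any(dec$chrom == sub$chrom[i] & dec$start <= sub$start[i] &
          dec$end >= sub$end[i])
  }, logical(1))
  expect_true(all(inside))
  ## clusters themselves sit inside their host domains and span <= 1.5 Mb
  expect_true(all(ann$clusters$end - ann$clusters$start <= 1.5e6))
  host <- match(ann$clusters$host_domain, ann$domains$id)
  expect_true(all(ann$domains$start[host] <= ann$clusters$start &
                    ann$domains$end[host] >= ann$clusters$end))
})

test_that("annotation respects geometry and capacity limits", {
  sim <- default_sim()
  ann <- sim$ann
  w <- ann$ccres$end - ann$ccres$start
  expect_true(all(w >= 200 & w <= 1000))
  ## cCREs disjoint
  m <- merge_overlapping(ann$ccres, ann$genome)
  expect_equal(sum(m$end - m$start), sum(w))
  ## domains disjoint and within bounds
  dm <- merge_overlapping(ann$domains, ann$genome)
  expect_equal(nrow(dm), nrow(ann$domains))
  ## infeasible packing errors out
  cfg_bad <- sim_config(seed = 1, n_ccres = 4000,
                        chromosomes = list(chrom = "chr1", length = 3e5))
  expect_error(generate_annotation(cfg_bad), "configuration error")
  ## no domains: no clusters, but generation still works
  cfg0 <- sim_config(seed = 2, n_domains = 0, n_clusters = 0,
                     n_repeat_instances = 0, n_ccres = 300, n_genes = 50,
                     n_cell_types = 3, cells_per_sample = 50,
                     library_size = 1e5, rna_library_size = 1e5)
  ann0 <- generate_annotation(cfg0)
  expect_equal(nrow(ann0$domains), 0)
  expect_equal(nrow(ann0$clusters), 0)
  cc0 <- generate_counts(ann0, cfg0)
  expect_null(cc0$k9_domains)
})

test_that("counts are integer, non-negative, with exact library metadata", {
  sim <- default_sim()
  for (m in list(sim$counts$atac, sim$counts$rna)) {
    expect_true(all(m$counts >= 0))
    expect_true(all(m$counts == round(m$counts)))
    expect_equal(m$samples$library_size, unname(colSums(m$counts)))
  }
  ## per-cell domain reads never exceed totals
  k9c <- sim$counts$k9_cells
  expect_true(all(rowSums(k9c$domain_reads) <= k9c$cells$total_reads))
})

test_that("planted fold reproduces the 18-vs-3-month mean ratio", {
  cfg <- sim_config(seed = 6, n_cell_types = 3, n_ccres = 2500,
                    fraction_age_up = 0.1, fraction_age_down = 0,
                    n_clusters = 0, n_genes = 60,
                    fraction_linked_genes = 0, cells_per_sample = 50)
  ann <- generate_annotation(cfg)
  cc <- generate_counts(ann, cfg)
  tc <- ann$truth$ccre
  ratios <- numeric(0)
  for (ct in unique(tc$cell_type[tc$direction == "up"])) {
    ids <- tc$ccre_id[tc$direction == "up" & tc$cell_type == ct]
    if (length(ids) < 5) next
    sel3 <- cc$samples$cell_type == ct & cc$samples$age_months == 3
    sel18 <- cc$samples$cell_type == ct & cc$samples$age_months == 18
    i <- match(ids, rownames(cc$atac$counts))
    ratios <- c(ratios, rowSums(cc$atac$counts[i, sel18, drop = FALSE]) /
                  pmax(1, rowSums(cc$atac$counts[i, sel3, drop = FALSE])))
  }
  expect_gte(length(ratios), 200)
  expect_lt(abs(mean(ratios) - 2.25) / 2.25, 0.1)
})

test_that("null configuration yields nominal differential call rates", {
  cfg <- sim_config(seed = 7, n_cell_types = 3, n_ccres = 3000,
                    fraction_age_up = 0, fraction_age_down = 0,
                    n_clusters = 0, domain_decay = 0,
                    fraction_linked_genes = 0, n_genes = 60,
                    cells_per_sample = 50)
  ann <- generate_annotation(cfg)
  cc <- generate_counts(ann, cfg)
  d <- differential_by_celltype(cc$atac)
  rate <- mean(unlist(lapply(d, function(r) r$p_value)) < 0.01)
  expect_gt(rate, 0.003)
  expect_lt(rate, 0.02)
  ## and domain decay is absent by construction (BH keeps false
  ## discoveries near zero on an all-null matrix)
  dd <- domain_differential(list(H3K9me3 = cc$k9_domains))
  expect_lte(sum(dd$p_adj < 0.05), 1)
})

test_that("fragment barcodes split into good and low-quality classes", {
  cfg <- sim_config(seed = 8, n_barcodes = 150, low_quality_fraction = 0.2,
                    median_fragments = 1500, n_ccres = 400, n_genes = 300,
                    n_cell_types = 3)
  ann <- generate_annotation(cfg)
  fr <- generate_fragments(ann, cfg)
  expect_equal(sum(fr$barcodes$low_quality), 30)
  tab <- table(fr$fragments$barcode)
  low_count <- fr$barcodes$barcode[fr$barcodes$type == "low_count"]
  expect_true(all(tab[low_count] < 500))
  expect_true(all(fr$fragments$end - fr$fragments$start < 2000))
  expect_true(all(fr$fragments$start >= 0))
})

test_that("simulation files round-trip through disk", {
  cfg <- sim_config(seed = 9, n_ccres = 300, n_genes = 50, n_cell_types = 3,
                    cells_per_sample = 40, library_size = 1e5,
                    rna_library_size = 5e4, n_barcodes = 30,
                    median_fragments = 200)
  ann <- generate_annotation(cfg)
  cc <- generate_counts(ann, cfg)
  fr <- generate_fragments(ann, cfg)
  dir <- file.path(tempdir(), "simout")
  write_simulation(ann, cc, fr, cfg, dir)
  expect_true(file.exists(file.path(dir, "ccres.bed")))
  expect_true(file.exists(file.path(dir, "sim_config.yaml")))
  back <- read_count_matrix(file.path(dir, "counts_atac.tsv"))
  expect_equal(back$counts, cc$atac$counts)
  beds <- read_bed(file.path(dir, "ccres.bed"), ann$genome)
  expect_equal(beds$start, ann$ccres$start)
})
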