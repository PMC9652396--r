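test_that("broad-domain calling recovers planted blocks and rejects short ones", {
  g <- genome_layout("chr1", 1e7)
  nb <- 2000  # 5-kb bins
  set.seed(9)
  ## uniform signal: no domains
  expect_equal(nrow(call_broad_domains(list(chr1 = rpois(nb, 20)), g)), 0)
  ## planted 300-kb block at 5x background
  lam <- rep(20, nb)
  lam[401:460] <- 100
  dom <- call_broad_domains(list(chr1 = rpois(nb, lam)), g)
  expect_equal(nrow(dom), 1)
  ro <- best_reciprocal_overlap(
    data.frame(chrom = "chr1", start = 400 * 5000, end = 460 * 5000), dom)
  expect_gte(ro, 0.95)
  expect_gt(dom$mean_density, dom$background_density)
  ## 50-kb block at 10x background: rejected by the >100 kb rule
  lam2 <- rep(20, nb)
  lam2[1001:1010] <- 200
  expect_equal(nrow(call_broad_domains(list(chr1 = rpois(nb, lam2)), g)), 0)
  ## gap chaining: two eligible stretches 10 kb apart become one domain
  lam3 <- rep(20, nb)
  lam3[c(301:330, 333:362)] <- 100
  dom3 <- call_broad_domains(list(chr1 = rpois(nb, lam3)), g)
  expect_equal(nrow(dom3), 1)
  expect_gt(dom3$end - dom3$start, 290e3)
})

test_that("domain caller output is disjoint and above the size floor", {
  set.seed(10)
  g <- genome_layout(c("chr1", "chr2"), c(8e6, 8e6))
  mk <- function(n) {
    lam <- rep(15, n)
    for (k in 1:3) {
      s <- sample(100:(n - 120), 1)
      lam[s:(s + sample(25:60, 1))] <- 15 * 5
    }
    rpois(n, lam)
  }
  dom <- call_broad_domains(list(chr1 = mk(1600), chr2 = mk(1600)), g)
  expect_true(all(dom$end - dom$start > 1e5))
  for (ch in unique(dom$chrom)) {
    d <- dom[dom$chrom == ch, ]
    if (nrow(d) > 1) expect_true(all(d$start[-1] >= d$end[-nrow(d)]))
  }
})

test_that("fisher enrichment matches the exact-enumeration and fisher.test", {
  ## published-style table: sample OR with two-sided exact p
  g <- genome_layout("chr1", 1e8)
  set.seed(11)
  n <- 1000
  st <- seq(1000, by = 90000, length.out = n)
  ccres <- genomic_intervals("chr1", st, st + 500,
                             id = sprintf("c%04d", 1:n))
  ## regions overlap the first 10 of the top 100 and 10 of the rest
  ov_idx <- c(1:10, 101:110)
  regions <- genomic_intervals("chr1", st[ov_idx], st[ov_idx] + 100)
  rec <- data.frame(feature_id = ccres$id, log2fc = 1,
                    p_value = seq_len(n) / n / 10)
  res <- fisher_overlap_enrichment(rec, ccres, regions, top_fraction = 0.1)
  expect_equal(unname(res$table["top", ]), c(10, 90))
  expect_equal(unname(res$table["rest", ]), c(10, 890))
  expect_equal(round(res$odds_ratio, 2), 9.89)
  ft <- fisher.test(matrix(c(10, 90, 10, 890), 2, byrow = TRUE))
  expect_equal(res$p_value, ft$p.value, tolerance = 1e-12)
  ## degenerate guards
  expect_error(fisher_overlap_enrichment(rec, ccres, regions,
                                         top_fraction = 1), "top_fraction")
  expect_true(fisher_overlap_enrichment(
    rec, ccres, genomic_intervals(character(0), numeric(0), numeric(0)),
    top_fraction = 0.1)$flagged)
})

test_that("two-sided exact p equals fisher.test over random small tables", {
  set.seed(12)
  fp <- getFromNamespace("fisher_p_twosided", "chromage")
  for (i in 1:300) {
    tab <- matrix(rpois(4, sample(c(1, 3, 10), 1)), 2)
    if (sum(tab) == 0 || any(rowSums(tab) > 50) || any(colSums(tab) > 50)) next
    expect_equal(fp(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
                 fisher.test(tab)$p.value, tolerance = 1e-12)
  }
  ## symmetric margins with equal proportions: p = 1
  expect_equal(fp(5, 5, 5, 5), 1)
})

test_that("per-cell FRiP fractions are exact and compared across ages", {
  cells <- data.frame(barcode = c("a", "b", "c"),
                      cell_type = "ExN", age_months = c(3, 18, 3),
                      total_reads = c(8, 12, 0))
  dr <- matrix(c(8, 3, 0, 0, 0, 0), 3, 2,
               dimnames = list(NULL, c("d1", "d2")))
  res <- fraction_reads_in_domains(cells, dr, c("d1", "d2"))
  expect_equal(res$frip$fraction, c(1, 0.25))
  expect_equal(res$n_excluded, 1)
  expect_false(is.na(res$p_value))
})

test_that("cluster-domain enrichment saturates and shuffles sensibly", {
  g <- genome_layout(c("chr1", "chr2"), c(2e7, 2e7))
  dom <- genomic_intervals(c("chr1", "chr2"), c(1e6, 5e6),
                           c(2e6, 6.2e6), id = c("d1", "d2"))
  ## clusters covering the whole genome: observed = 1, fold = 1
  cl_all <- genomic_intervals(c("chr1", "chr2"), c(0, 0), c(2e7, 2e7))
  res <- cluster_domain_overlap_enrichment(dom, cl_all, g,
                                           n_shuffles = 50, seed = 1)
  expect_equal(res$observed, 1)
  expect_equal(res$fold, 1)
  expect_equal(res$expected_analytic, 1)
  ## empty cluster set flagged
  res0 <- cluster_domain_overlap_enrichment(
    dom, genomic_intervals(character(0), numeric(0), numeric(0)), g)
  expect_true(res0$flagged)
  expect_equal(res0$observed, 0)
})

test_that("domain differential is null on identical groups and checks ids", {
  set.seed(13)
  Y <- matrix(rep(rpois(6, 5000), 8), 6, 8)
  rownames(Y) <- sprintf("d%d", 1:6)
  smp <- data.frame(cell_type = rep(c("A", "B"), each = 4),
                    age_months = rep(c(3, 3, 18, 18), 2),
                    replicate = rep(c(1, 2), 4), n_cells = 100)
  cm <- count_matrix(Y, smp, library_size = rep(1e5, 8))
  dd <- domain_differential(list(H3K9me3 = cm))
  expect_true(all(abs(dd$log2fc) < 1e-10))
  expect_true(all(dd$p_adj > 0.99))
  cm2 <- cm
  rownames(cm2$counts) <- sprintf("x%d", 1:6)
  expect_error(domain_differential(list(A = cm, B = cm2)), "mismatched")
})

test_that("aggregate profiles are flat on uniform signal and strand-aware", {
  ## tiled fragments give exactly uniform coverage 2x
  frag <- data.frame(chrom = "chr1",
                     start = rep(seq(0, 19800, by = 100), each = 2),
                     end = rep(seq(200, 20000, by = 100), each = 2),
                     barcode = "b")
  inst <- genomic_intervals("chr1", c(5000, 9000), c(5500, 9600),
                            id = c("i1", "i2"), strand = c("+", "-"))
  prof <- aggregate_profile(frag, inst, flank = 500)
  expect_equal(var(prof$profile), 0, tolerance = 1e-12)
  ## tiles of length 200 at step 100, duplicated: uniform 4x coverage
  expect_equal(prof$profile[1], 4, tolerance = 1e-9)
  ## left-skewed signal on a minus-strand instance appears right-skewed
  frag2 <- data.frame(chrom = "chr1", start = rep(4000, 50),
                      end = rep(4400, 50), barcode = "b")
  inst_m <- genomic_intervals("chr1", 4000, 5000, id = "m", strand = "-")
  inst_p <- genomic_intervals("chr1", 4000, 5000, id = "p", strand = "+")
  pm <- aggregate_profile(frag2, inst_m, flank = 200)$profile
  pp <- aggregate_profile(frag2, inst_p, flank = 200)$profile
  expect_equal(pm, rev(pp), tolerance = 1e-9)
  expect_gt(which.max(pm), length(pm) / 2)
  expect_error(aggregate_profile(
    frag2, genomic_intervals(character(0), numeric(0), numeric(0))),
    "no instances")
})

test_that("body enrichment shows up as the plateau-to-flank ratio", {
  set.seed(14)
  ## 3x more fragments over bodies than flanks
  body_start <- seq(2000, by = 20000, length.out = 10)
  inst <- genomic_intervals("chr1", body_start, body_start + 1000,
                            id = sprintf("e%02d", 1:10), strand = "+")
  bg <- floor(runif(4000, 0, 2.2e5))
  extra <- unlist(lapply(body_start, function(s) floor(runif(40, s, s + 850))))
  st <- c(bg, extra)
  frag <- data.frame(chrom = "chr1", start = st, end = st + 150, barcode = "b")
  prof <- aggregate_profile(frag, inst, flank = 500, normalize = TRUE)
  fb <- prof$flank_bins
  body <- prof$profile[(fb + 1):(fb + prof$body_bins)]
  expect_gt(mean(body[2:9]), 2.2)
  expect_lt(mean(body[2:9]), 4.5)
})
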