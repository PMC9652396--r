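test_that("cpm_normalize scales columns by library size", {
  Y <- matrix(c(2, 3, 5), 3, 1, dimnames = list(c("a", "b", "c"), NULL))
  cm <- count_matrix(Y, data.frame(cell_type = "A", age_months = 3,
                                   replicate = 1, n_cells = 1))
  cpm <- cpm_normalize(cm)
  expect_equal(unname(cpm$counts[, 1]), c(200000, 300000, 500000))
  expect_equal(cpm$normalization, "CPM")

  cm2 <- nb_matrix(100, 80, 0.1, seed = 2)
  cm2$counts[1, ] <- 0
  cm2 <- count_matrix(cm2$counts, cm2$samples[, 1:4])
  cpm2 <- cpm_normalize(cm2)
  expect_true(all(cpm2$counts[1, ] == 0))
  expect_equal(unname(colSums(cpm2$counts)), rep(1e6, 4))

  bad <- cm2
  bad$samples$library_size[2] <- 0
  expect_error(cpm_normalize(bad), "zero library size")
})

test_that("nb_lrt is null on identical counts and flags all-zero features", {
  Y <- matrix(10, 3, 4, dimnames = list(c("a", "b", "c"), NULL))
  Y[3, ] <- 0
  cm <- count_matrix(Y, data.frame(cell_type = "A", age_months = c(3, 3, 18, 18),
                                   replicate = c(1, 2, 1, 2), n_cells = 5),
                     library_size = rep(1000, 4))
  rec <- nb_lrt(cm, age_groups_2v2, 0.2)
  expect_equal(rec$lrt[1:2], c(0, 0), tolerance = 1e-8)
  expect_equal(rec$p_value[1:2], c(1, 1), tolerance = 1e-6)
  expect_equal(rec$log2fc[1:2], c(0, 0), tolerance = 1e-10)
  expect_equal(rec$direction, rep("ns", 3))
  expect_true(rec$all_zero[3])
  expect_equal(rec$p_value[3], 1)
})

test_that("nb_lrt matches the brute-force likelihood-maximization oracle", {
  set.seed(31)
  G <- 100
  Y <- matrix(rnbinom(G * 4, mu = runif(G * 4, 2, 60), size = 5), G, 4)
  rownames(Y) <- sprintf("f%03d", seq_len(G))
  lib <- c(900, 1100, 1000, 1050)
  cm <- count_matrix(Y, data.frame(cell_type = "A",
                                   age_months = c(3, 3, 18, 18),
                                   replicate = c(1, 2, 1, 2), n_cells = 5),
                     library_size = lib)
  phi <- 0.2
  rec <- nb_lrt(cm, age_groups_2v2, phi)
  oracle <- vapply(seq_len(G), function(i) {
    nb_lrt_oracle(Y[i, ], lib, c(1, 1, 2, 2), phi)
  }, numeric(1))
  expect_equal(rec$lrt, oracle, tolerance = 1e-4)
})

test_that("dispersion estimation recovers the truth", {
  ## Poisson data: common dispersion collapses toward zero
  cmp <- nb_matrix(2000, 60, 0, seed = 8)
  dp <- estimate_dispersions(cmp, age_groups_2v2)
  expect_lte(dp$common, 0.02)
  ## NB data at phi = 0.2
  cmn <- nb_matrix(2000, 60, 0.2, seed = 9)
  dn <- estimate_dispersions(cmn, age_groups_2v2)
  expect_gte(dn$common, 0.15)
  expect_lte(dn$common, 0.25)
  ## infinite prior collapses tagwise onto the common value
  dinf <- estimate_dispersions(cmn, age_groups_2v2, prior_df = Inf)
  expect_true(all(dinf$tagwise == dinf$common))
  ## larger priors pull tagwise closer to the common value
  d10 <- estimate_dispersions(cmn, age_groups_2v2, prior_df = 10)
  d40 <- estimate_dispersions(cmn, age_groups_2v2, prior_df = 40)
  expect_lte(mean(abs(log(d40$tagwise) - log(d40$common))),
             mean(abs(log(d10$tagwise) - log(d10$common))))
  expect_error(estimate_dispersions(
    count_matrix(matrix(0, 2, 2),
                 data.frame(cell_type = "A", age_months = c(3, 18),
                            replicate = 1, n_cells = 1),
                 library_size = c(1, 1)), factor(c(3, 18))), "all-zero")
})

test_that("classification splits by cutoff and fold-change sign", {
  rec <- data.frame(feature_id = c("a", "b", "c", "d"),
                    log2fc = c(1, -1, 2, 0.5),
                    p_value = c(0.005, 0.005, 0.05, 0.2),
                    p_adj = c(0.05, 0.05, 0.2, 0.5))
  cl <- classify_age_ccres(rec, alpha = 0.01)
  expect_equal(cl$age_up, "a")
  expect_equal(cl$age_down, "b")
  cl2 <- classify_age_ccres(rec, alpha = 0.1, use_adjusted = TRUE)
  expect_setequal(cl2$age_up, "a")
})

test_that("detection rate grows with the planted fold change", {
  rates <- vapply(c(1.5, 2.5, 4), function(f) {
    ## fixed library sizes: the planted fold must not leak into the offsets
    cm <- nb_matrix(600, 100, 0.1, fold = f, seed = 17,
                    lib = rep(600 * 100, 4))
    disp <- estimate_dispersions(cm, age_groups_2v2)
    rec <- nb_lrt(cm, age_groups_2v2, disp)
    mean(rec$p_value < 0.01 & rec$log2fc > 0)
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_gt(rates[3], 0.5)
})

test_that("LRT statistics track edgeR's on shared data", {
  set.seed(19)
  cm <- nb_matrix(400, 80, 0.15, fold = rep(c(1, 2), each = 200), seed = 19)
  disp <- estimate_dispersions(cm, age_groups_2v2)
  rec <- nb_lrt(cm, age_groups_2v2, disp)
  dge <- edgeR::DGEList(counts = cm$counts,
                        group = age_groups_2v2)
  design <- stats::model.matrix(~age_groups_2v2)
  dge <- edgeR::estimateDisp(dge, design)
  tab <- edgeR::glmLRT(edgeR::glmFit(dge, design))$table
  expect_gt(cor(rec$lrt, tab$LR), 0.98)
  expect_gt(cor(rec$log2fc, tab$logFC), 0.99)
})
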