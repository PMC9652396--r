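test_that("merge_overlapping unions overlapping and touching intervals", {
  g <- genome_layout(c("chr1", "chr2"), c(1e6, 1e6))
  iv <- genomic_intervals(c("chr1", "chr1"), c(0, 50), c(100, 150))
  m <- merge_overlapping(iv, g)
  expect_equal(m$start, 0)
  expect_equal(m$end, 150)

  iv2 <- genomic_intervals(c("chr2", "chr1"), c(0, 0), c(100, 100))
  m2 <- merge_overlapping(iv2, g)
  expect_equal(m2$chrom, c("chr1", "chr2"))
  expect_equal(m2$start, c(0, 0))

  ## touching intervals merge under the half-open convention
  iv3 <- genomic_intervals(c("chr1", "chr1"), c(0, 100), c(100, 200))
  expect_equal(nrow(merge_overlapping(iv3, g)), 1)
})

test_that("merge_overlapping matches the per-bp mask oracle and is idempotent", {
  set.seed(41)
  g <- genome_layout(c("chr1", "chr2"), c(5e4, 3e4))
  iv <- random_intervals(1000, g, 10, 400)
  m <- merge_overlapping(iv, g)
  oracle <- mask_merge_oracle(iv, g)
  expect_equal(m$chrom, oracle$chrom)
  expect_equal(m$start, oracle$start)
  expect_equal(m$end, oracle$end)
  m2 <- merge_overlapping(m, g)
  expect_equal(m2$start, m$start)
  expect_equal(m2$end, m$end)
})

test_that("interval validation rejects bad coordinates", {
  g <- genome_layout("chr1", 1000)
  expect_error(genomic_intervals("chr1", 10, 10), "0 <= start < end")
  expect_error(genomic_intervals("chr1", 900, 1100, genome = g),
               "past chromosome end")
  expect_error(genomic_intervals("chrX", 0, 10, genome = g),
               "unknown chromosome")
})

test_that("filter_by_overlap uses half-open >=1bp overlap semantics", {
  iv <- genomic_intervals("chr1", 10, 20, id = "a")
  res1 <- filter_by_overlap(iv, genomic_intervals("chr1", 19, 30))
  expect_equal(nrow(res1$removed), 1)
  res2 <- filter_by_overlap(iv, genomic_intervals("chr1", 20, 30))
  expect_equal(nrow(res2$kept), 1)
  expect_equal(nrow(res2$removed), 0)
})

test_that("filter_by_overlap matches the mask oracle on random sets", {
  set.seed(42)
  g <- genome_layout(c("chr1", "chr2"), c(4e4, 4e4))
  iv <- random_intervals(400, g, 20, 500)
  excl <- random_intervals(60, g, 100, 2000)
  res <- filter_by_overlap(iv, excl)
  hit <- mask_overlap_oracle(iv, excl, g)
  expect_setequal(res$removed$id, iv$id[hit])
  expect_setequal(res$kept$id, iv$id[!hit])
  ## order preserved, partition complete
  expect_equal(c(res$kept$id, res$removed$id)[order(match(
    c(res$kept$id, res$removed$id), iv$id))], iv$id)
})

test_that("fragment counting follows whole-fragment multi-overlap semantics", {
  iv <- genomic_intervals("chr1", c(0, 40), c(20, 100), id = c("p1", "p2"))
  smp <- data.frame(cell_type = "A", age_months = 3, replicate = 1,
                    n_cells = 10)
  frag <- data.frame(chrom = "chr1", start = 10, end = 50, barcode = "bc1")
  cm <- count_fragments_in_intervals(frag, iv, c(bc1 = "A.3.1"), smp)
  expect_equal(unname(cm$counts[, 1]), c(1, 1))

  frag2 <- data.frame(chrom = "chr1", start = 10, end = 50, barcode = "bcX")
  expect_warning(
    cm2 <- count_fragments_in_intervals(frag2, iv, c(bc1 = "A.3.1"), smp),
    "unmapped")
  expect_equal(sum(cm2$counts), 0)
  expect_equal(attr(cm2, "n_unmapped"), 1)
})

test_that("fragment counting matches brute force and ignores stream order", {
  set.seed(43)
  g <- genome_layout("chr1", 2e5)
  iv <- merge_overlapping(random_intervals(80, g, 100, 1500), g)
  n <- 10000
  st <- floor(runif(n, 0, 2e5 - 600))
  frag <- data.frame(chrom = "chr1", start = st,
                     end = st + sample(50:500, n, TRUE),
                     barcode = sample(c("b1", "b2", "b3"), n, TRUE))
  map <- c(b1 = "A.3.1", b2 = "A.18.1", b3 = "A.18.2")
  smp <- data.frame(cell_type = "A", age_months = c(3, 18, 18),
                    replicate = c(1, 1, 2), n_cells = 5)
  cm <- count_fragments_in_intervals(frag, iv, map, smp)
  ## brute-force double loop
  bf <- matrix(0, nrow(iv), 3, dimnames = list(iv$id, sample_id(smp)))
  for (i in seq_len(n)) {
    hits <- which(iv$start < frag$end[i] & iv$end > frag$start[i])
    s <- map[frag$barcode[i]]
    bf[hits, s] <- bf[hits, s] + 1
  }
  expect_equal(cm$counts, bf)
  ## column sums invariant under reordering of the fragment stream
  cm_r <- count_fragments_in_intervals(frag[sample.int(n), ], iv, map, smp)
  expect_equal(colSums(cm_r$counts), colSums(cm$counts))
})

test_that("jaccard_index handles identity, disjoint and partial overlap", {
  expect_equal(jaccard_index(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard_index(c("a"), c("b")), 0)
  expect_equal(jaccard_index(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_equal(jaccard_index(character(0), character(0)), 0)
  expect_equal(jaccard_index(c("a", "b"), c("b", "a")), 1)
})

test_that("BED and count-matrix files round-trip", {
  g <- genome_layout("chr1", 1e5)
  iv <- genomic_intervals("chr1", c(100, 5000), c(600, 5400),
                          id = c("x1", "x2"), strand = c("+", "-"),
                          score = c(1.5, 2))
  bed <- tempfile(fileext = ".bed")
  write_bed(iv, bed)
  back <- read_bed(bed, g)
  expect_equal(back$start, iv$start)
  expect_equal(back$end, iv$end)
  expect_equal(back$strand, iv$strand)

  cm <- nb_matrix(20, 50, 0.1, seed = 7)
  tsv <- tempfile(fileext = ".tsv")
  write_count_matrix(cm, tsv)
  back2 <- read_count_matrix(tsv)
  expect_equal(back2$counts, cm$counts)
  expect_equal(back2$samples$library_size, cm$samples$library_size)
})

test_that("fragment reader drops over-long inserts and flags bad lines", {
  f <- tempfile()
  writeLines(c("chr1\t0\t100\tb1", "chr1\t0\t2500\tb2",
               "chr1\t10\t500\tb3"), f)
  fr <- read_fragments(f)
  expect_equal(nrow(fr), 2)
  writeLines(c("chr1\t100\t50\tb1"), f)
  expect_error(read_fragments(f), "line 1")
})
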