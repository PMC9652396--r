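## Independent brute-force oracles used to verify the fast implementations.

## per-bp boolean-mask union of intervals on one genome
mask_merge_oracle <- function(iv, genome) {
  out <- NULL
  for (ci in seq_len(nrow(genome))) {
    mask <- logical(genome$length[ci])
    on <- which(iv$chrom == genome$chrom[ci])
    for (i in on) mask[(iv$start[i] + 1):iv$end[i]] <- TRUE
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    if (length(keep)) {
      out <- rbind(out, data.frame(chrom = genome$chrom[ci],
                                   start = starts[keep] - 1L,
                                   end = ends[keep]))
    }
  }
  out
}

## per-bp mask overlap test of each interval against an excluded set
mask_overlap_oracle <- function(iv, excl, genome) {
  masks <- lapply(seq_len(nrow(genome)), function(ci) {
    m <- logical(genome$length[ci])
    on <- which(excl$chrom == genome$chrom[ci])
    for (i in on) m[(excl$start[i] + 1):excl$end[i]] <- TRUE
    m
  })
  names(masks) <- genome$chrom
  vapply(seq_len(nrow(iv)), function(i) {
    any(masks[[iv$chrom[i]]][(iv$start[i] + 1):iv$end[i]])
  }, logical(1))
}

## Benjamini-Hochberg step-up, written straight from the definition
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

## brute-force NB LRT for one feature: 1-d likelihood maximizations over the
## log-rate, independent of the package's Newton fit
nb_lrt_oracle <- function(y, lib, groups, phi) {
  ll <- function(idx, r) {
    sum(stats::dnbinom(y[idx], size = 1 / phi, mu = r * lib[idx], log = TRUE))
  }
  opt <- function(idx) {
    r0 <- (sum(y[idx]) + 0.5) / sum(lib[idx])
    stats::optimize(function(lr) ll(idx, exp(lr)),
                    log(r0) + c(-8, 8), maximum = TRUE, tol = 1e-10)$objective
  }
  g <- unique(groups)
  full <- opt(groups == g[1]) + opt(groups == g[2])
  null <- opt(rep(TRUE, length(y)))
  max(0, 2 * (full - null))
}

random_intervals <- function(n, genome, min_w = 50, max_w = 2000) {
  ci <- sample.int(nrow(genome), n, replace = TRUE)
  w <- sample(min_w:max_w, n, replace = TRUE)
  st <- floor(runif(n, 0, genome$length[ci] - w))
  genomic_intervals(genome$chrom[ci], st, st + w,
                    id = sprintf("r%05d", seq_len(n)))
}

## small NB count_matrix for differential tests; `lib` fixes the library
## sizes (offsets) explicitly, so planted folds are not absorbed into them
nb_matrix <- function(G, mu, phi, fold = 1, seed = 1, lib = NULL) {
  set.seed(seed)
  if (length(mu) == 1) mu <- rep(mu, G)
  if (length(fold) == 1) fold <- rep(fold, G)
  size <- if (phi > 0) 1 / phi else Inf
  draw <- function(m) {
    if (is.infinite(size)) rpois(G, m) else rnbinom(G, mu = m, size = size)
  }
  Y <- cbind(draw(mu), draw(mu), draw(mu * fold), draw(mu * fold))
  rownames(Y) <- sprintf("f%05d", seq_len(G))
  count_matrix(Y, data.frame(cell_type = "A", age_months = c(3, 3, 18, 18),
                             replicate = c(1, 2, 1, 2), n_cells = 500),
               library_size = lib)
}

age_groups_2v2 <- factor(c(3, 3, 18, 18), levels = c(3, 18))
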