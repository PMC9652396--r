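## Negative-binomial two-group testing on pseudo-bulk counts.
##
## The model: y_ij ~ NB(mu_ij, phi_i) with log mu_ij = beta_{i,g(j)} + o_j,
## o_j = log library size. Differential features are found by a likelihood
## ratio test of group-specific means vs a shared mean, with the dispersion
## phi_i held fixed at a tagwise estimate shrunk toward a common value.

## NB log-likelihood; phi ~ 0 falls back to Poisson
nb_ll <- function(y, mu, phi) {
  mu <- pmax(mu, 1e-12)
  if (length(phi) == 1) phi <- rep(phi, length(y))
  pois <- phi < 1e-8
  out <- numeric(length(y))
  if (any(pois)) out[pois] <- stats::dpois(y[pois], mu[pois], log = TRUE)
  if (any(!pois)) {
    out[!pois] <- stats::dnbinom(y[!pois], size = 1 / phi[!pois],
                                 mu = mu[!pois], log = TRUE)
  }
  out
}

## Fit per-feature group means by Newton scoring, vectorized across features.
## Returns per-feature log-likelihood and the Cox-Reid adjustment
## 0.5 * sum_g log(X'WX)_g needed for dispersion estimation.
fit_nb_means <- function(Y, offsets, groups, phi, n_iter = 30L) {
  groups <- as.factor(groups)
  G <- nrow(Y)
  if (length(phi) == 1) phi <- rep(phi, G)
  ll <- numeric(G)
  cr <- numeric(G)
  beta <- matrix(NA_real_, G, nlevels(groups),
                 dimnames = list(rownames(Y), levels(groups)))
  for (g in levels(groups)) {
    idx <- which(groups == g)
    Yg <- Y[, idx, drop = FALSE]
    eo <- exp(offsets[idx])
    b <- log((rowSums(Yg) + 0.5) / sum(eo))
    for (it in seq_len(n_iter)) {
      mu <- exp(b) %o% eo
      denom <- 1 + phi * mu
      score <- rowSums((Yg - mu) / denom)
      info <- rowSums(mu / denom)
      step <- score / pmax(info, 1e-10)
      step <- pmin(pmax(step, -3), 3)
      b <- b + step
      if (max(abs(step)) < 1e-10) break
    }
    mu <- exp(b) %o% eo
    ll <- ll + rowSums(matrix(nb_ll(as.vector(Yg), as.vector(mu),
                                    rep(phi, ncol(Yg))), nrow = G))
    cr <- cr + 0.5 * log(pmax(rowSums(mu / (1 + phi * mu)), 1e-300))
    beta[, g] <- b
  }
  list(beta = beta, loglik = ll, cr = cr)
}

#' Estimate common and tagwise NB dispersions
#'
#' The common dispersion maximizes the summed adjusted profile log-likelihood
#' over features (group means profiled out at fixed log-library offsets, with
#' the Cox-Reid degrees-of-freedom correction, which removes the downward
#' bias of the plain profile MLE at small replicate numbers). Tagwise values
#' combine the per-feature maximizer with the common value on the log scale,
#' with `prior_df` pseudo-residual-df of weight on the common value:
#' `log phi_i = d/(d+prior_df) * log phihat_i + prior_df/(d+prior_df) * log phic`
#' where d is the per-feature residual df.
#'
#' @param mat A raw `count_matrix`.
#' @param groups Factor/character of length `ncol`, the group of each sample.
#' @param prior_df Shrinkage weight in residual-df units (default 10);
#'   `Inf` forces all tagwise values to the common dispersion.
#' @param phi_range Search range for the dispersion.
#' @return List with `common`, `tagwise` (per feature), `prior_df`.
#' @export
estimate_dispersions <- function(mat, groups, prior_df = 10,
                                 phi_range = c(1e-4, 4)) {
  stopifnot(inherits(mat, "count_matrix"), mat$normalization == "raw")
  Y <- mat$counts
  if (all(Y == 0)) stop("all-zero count matrix")
  offsets <- log(mat$samples$library_size)
  groups <- as.factor(groups)
  grid <- exp(seq(log(phi_range[1]), log(phi_range[2]), length.out = 25))
  apl <- sapply(grid, function(phi) {
    f <- fit_nb_means(Y, offsets, groups, phi)
    f$loglik - f$cr
  })
  tot <- colSums(apl)
  i0 <- which.max(tot)
  lo <- grid[max(1, i0 - 1)]; hi <- grid[min(length(grid), i0 + 1)]
  opt <- stats::optimize(function(lphi) {
    f <- fit_nb_means(Y, offsets, groups, exp(lphi))
    sum(f$loglik - f$cr)
  }, interval = log(c(lo, hi)), maximum = TRUE, tol = 1e-4)
  common <- exp(opt$maximum)

  ## tagwise: maximize the per-feature adjusted profile likelihood plus
  ## prior_df/d shares of the feature-averaged likelihood (empirical-Bayes
  ## weighting; prior_df = Inf collapses every feature onto the common value)
  d <- max(1, ncol(Y) - nlevels(groups))
  lg <- log(grid)
  if (is.infinite(prior_df)) {
    tagwise <- rep(common, nrow(Y))
  } else {
    obj <- apl + matrix(rep((prior_df / d) * colMeans(apl), each = nrow(Y)),
                        nrow = nrow(Y))
    imax <- max.col(obj, ties.method = "first")
    tagwise <- vapply(seq_len(nrow(Y)), function(i) {
      k <- imax[i]
      if (k == 1 || k == length(grid)) return(grid[k])
      y3 <- obj[i, (k - 1):(k + 1)]
      x3 <- lg[(k - 1):(k + 1)]
      den <- (y3[1] - 2 * y3[2] + y3[3])
      if (!is.finite(den) || den >= 0) return(grid[k])
      exp(x3[2] - 0.5 * (x3[2] - x3[1]) * (y3[3] - y3[1]) / den)
    }, numeric(1))
  }
  names(tagwise) <- rownames(Y)
  list(common = common, tagwise = tagwise, prior_df = prior_df)
}

#' Two-group NB likelihood-ratio test
#'
#' Tests, per feature, group-specific means against a shared mean (both with
#' log-library offsets and fixed tagwise dispersions); the statistic
#' 2(l_full - l_null) is referred to chi-square with 1 df. The fold change
#' (reported as log2, alt over ref) comes from offset-adjusted group totals
#' with a half-count continuity adjustment so zero groups stay finite.
#'
#' @param mat Raw `count_matrix`.
#' @param groups Two-level factor (ref level first, e.g. 3 then 18 months).
#' @param dispersions Result of [estimate_dispersions()] (or a single phi).
#' @param alpha P-value cutoff used to label direction (default 0.01).
#' @return data.frame of per-feature records: `feature_id`, `log2fc`, `lrt`,
#'   `p_value`, `p_adj` (BH), `direction` in `{up, down, ns}`, `all_zero`.
#' @export
nb_lrt <- function(mat, groups, dispersions, alpha = 0.01) {
  stopifnot(inherits(mat, "count_matrix"), mat$normalization == "raw")
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("nb_lrt needs exactly two groups")
  Y <- mat$counts
  offsets <- log(mat$samples$library_size)
  phi <- if (is.list(dispersions)) dispersions$tagwise else
    rep(dispersions, nrow(Y))

  full <- fit_nb_means(Y, offsets, groups, phi)
  null <- fit_nb_means(Y, offsets, rep("all", ncol(Y)), phi)
  lrt <- pmax(0, 2 * (full$loglik - null$loglik))
  p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)

  ref <- levels(groups)[1]; alt <- levels(groups)[2]
  lib <- exp(offsets)
  ref_idx <- groups == ref
  rate_ref <- (rowSums(Y[, ref_idx, drop = FALSE]) + 0.5) / sum(lib[ref_idx])
  rate_alt <- (rowSums(Y[, !ref_idx, drop = FALSE]) + 0.5) / sum(lib[!ref_idx])
  log2fc <- log2(rate_alt / rate_ref)

  all_zero <- rowSums(Y) == 0
  p[all_zero] <- 1
  lrt[all_zero] <- 0
  log2fc[all_zero] <- 0

  direction <- rep("ns", nrow(Y))
  direction[p < alpha & log2fc > 0] <- "up"
  direction[p < alpha & log2fc < 0] <- "down"
  data.frame(feature_id = rownames(Y), log2fc = log2fc, lrt = lrt,
             p_value = p, p_adj = stats::p.adjust(p, "BH"),
             direction = direction, all_zero = all_zero,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' CPM-normalize a count matrix
#'
#' Scales each column to counts per million using its library size.
#'
#' @param mat Raw `count_matrix`.
#' @return A `count_matrix` in CPM mode (columns sum to 1e6 when the library
#'   size equals the column total).
#' @export
cpm_normalize <- function(mat) {
  stopifnot(inherits(mat, "count_matrix"))
  if (mat$normalization == "CPM") return(mat)
  ls <- mat$samples$library_size
  if (any(ls <= 0)) {
    stop("zero library size for sample ", sample_id(mat$samples)[which(ls <= 0)[1]])
  }
  cpm <- sweep(mat$counts, 2, ls, "/") * 1e6
  count_matrix(cpm, mat$samples, normalization = "CPM", library_size = ls)
}

#' Classify age-differential features
#'
#' Splits differential records into age-up and age-down sets at the given
#' cutoff: raw p < alpha for accessibility (the default, alpha = 0.01), or
#' BH-adjusted p < alpha for transcript-level calls (`use_adjusted = TRUE`,
#' typically alpha = 0.1).
#'
#' @param records Output of [nb_lrt()].
#' @param alpha Significance cutoff.
#' @param use_adjusted Test the BH-adjusted p instead of the raw p.
#' @return List with character vectors `age_up` and `age_down`.
#' @export
classify_age_ccres <- function(records, alpha = 0.01, use_adjusted = FALSE) {
  p <- if (use_adjusted) records$p_adj else records$p_value
  list(age_up = records$feature_id[p < alpha & records$log2fc > 0],
       age_down = records$feature_id[p < alpha & records$log2fc < 0])
}
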