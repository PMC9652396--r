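## One default-configuration simulation shared (memoized) across tests, so
## the expensive generation + per-cell-type differential run happens once.

.sim_cache <- new.env(parent = emptyenv())

default_sim <- function() {
  if (!is.null(.sim_cache$sim)) return(.sim_cache$sim)
  cfg <- sim_config(seed = 1)
  ann <- generate_annotation(cfg)
  counts <- generate_counts(ann, cfg)
  atac_diff <- differential_by_celltype(counts$atac)
  rna_diff <- differential_by_celltype(counts$rna)
  .sim_cache$sim <- list(cfg = cfg, ann = ann, counts = counts,
                         atac_diff = atac_diff, rna_diff = rna_diff)
  .sim_cache$sim
}

## reciprocal overlap of one truth interval with its best-matching call
best_reciprocal_overlap <- function(truth_row, calls) {
  if (nrow(calls) == 0) return(0)
  ov <- pmin(calls$end, truth_row$end) - pmax(calls$start, truth_row$start)
  ov[calls$chrom != truth_row$chrom] <- 0
  j <- which.max(ov)
  if (ov[j] <= 0) return(0)
  min(ov[j] / (truth_row$end - truth_row$start),
      ov[j] / (calls$end[j] - calls$start[j]))
}
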