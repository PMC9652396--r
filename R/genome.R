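#' Define a genome layout
#'
#' A genome layout is the coordinate universe for every interval handled by
#' the package: an ordered set of chromosome names with their lengths in bp.
#' All intervals are 0-based half-open (BED convention).
#'
#' @param chrom Character vector of unique chromosome names.
#' @param length Integer vector of chromosome lengths (bp), all positive.
#' @return A `genome_layout` data.frame with columns `chrom` and `length`.
#' @export
#' @examples
#' genome_layout(c("chr1", "chr2"), c(2e7, 2e7))
genome_layout <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  if (any(!is.finite(length)) || any(length <= 0)) {
    stop("chromosome lengths must be positive")
  }
  out <- data.frame(chrom = chrom, length = length, stringsAsFactors = FALSE)
  class(out) <- c("genome_layout", "data.frame")
  out
}

#' Construct a genomic interval table
#'
#' Intervals are 0-based half-open spans `[start, end)`. This is the carrier
#' type for cCREs, heterochromatin domains, TSSs, blacklist entries and
#' cluster calls.
#'
#' @param chrom,start,end Coordinates (half-open, 0-based).
#' @param id Optional feature identifiers (auto-generated when `NULL`).
#' @param strand Optional strand, one of `"+"`, `"-"`, `"."`.
#' @param score Optional numeric score.
#' @param genome Optional `genome_layout`; when given, coordinates are
#'   validated against chromosome bounds.
#' @return A `genomic_intervals` data.frame.
#' @export
genomic_intervals <- function(chrom, start, end, id = NULL, strand = NULL,
                              score = NULL, genome = NULL) {
  n <- length(chrom)
  if (is.null(id)) id <- sprintf("iv_%06d", seq_len(max(n, 0L)))
  if (is.null(strand)) strand <- rep(".", n)
  if (is.null(score)) score <- rep(NA_real_, n)
  out <- data.frame(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    id = as.character(id),
    strand = as.character(strand),
    score = as.numeric(score),
    stringsAsFactors = FALSE
  )
  class(out) <- c("genomic_intervals", "data.frame")
  validate_intervals(out, genome)
  out
}

#' @keywords internal
validate_intervals <- function(x, genome = NULL) {
  if (nrow(x) == 0) return(invisible(x))
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad)) {
    stop(sprintf("invalid coordinates (need 0 <= start < end) for record '%s' (%s:%s-%s)",
                 x$id[bad[1]], x$chrom[bad[1]], x$start[bad[1]], x$end[bad[1]]))
  }
  if (!is.null(genome)) {
    m <- match(x$chrom, genome$chrom)
    if (anyNA(m)) {
      bad <- which(is.na(m))[1]
      stop(sprintf("record '%s' on unknown chromosome '%s'", x$id[bad], x$chrom[bad]))
    }
    over <- which(x$end > genome$length[m])
    if (length(over)) {
      stop(sprintf("record '%s' (%s:%s-%s) extends past chromosome end (%s bp)",
                   x$id[over[1]], x$chrom[over[1]], x$start[over[1]],
                   x$end[over[1]], genome$length[m[over[1]]]))
    }
  }
  invisible(x)
}

## internal bridge to GenomicRanges: BED half-open -> 1-based closed
#' @keywords internal
gi_to_gr <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end),
    strand = ifelse(x$strand %in% c("+", "-"), x$strand, "*")
  )
}

#' @keywords internal
gr_to_gi <- function(gr, id = NULL) {
  st <- as.character(GenomicRanges::strand(gr))
  st[st == "*"] <- "."
  genomic_intervals(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    id = id,
    strand = st
  )
}

#' Merge overlapping or touching intervals
#'
#' Collapses a set of intervals to the disjoint union of their footprint,
#' sorted by (chrom, start). Touching intervals (`end == start` of the next)
#' are merged, per the half-open convention.
#'
#' @param intervals A `genomic_intervals` table.
#' @param genome Optional `genome_layout` for bounds validation.
#' @return A sorted, disjoint `genomic_intervals` table.
#' @export
merge_overlapping <- function(intervals, genome = NULL) {
  validate_intervals(intervals, genome)
  if (nrow(intervals) == 0) return(intervals)
  gr <- GenomicRanges::reduce(gi_to_gr(intervals), min.gapwidth = 1L,
                              ignore.strand = TRUE)
  out <- gr_to_gi(gr)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out$id <- sprintf("merged_%05d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

#' Partition intervals by overlap with excluded regions
#'
#' Implements blacklist/high-signal-repeat filtering: an interval is removed
#' iff it overlaps any excluded region by at least 1 bp (half-open
#' semantics, so an interval ending where an excluded region starts is kept).
#'
#' @param intervals,excluded `genomic_intervals` tables.
#' @return List with elements `kept` and `removed`, input order preserved.
#' @export
filter_by_overlap <- function(intervals, excluded) {
  validate_intervals(intervals)
  validate_intervals(excluded)
  if (nrow(intervals) == 0 || nrow(excluded) == 0) {
    return(list(kept = intervals, removed = intervals[0, ]))
  }
  hit <- IRanges::overlapsAny(gi_to_gr(intervals), gi_to_gr(excluded),
                              ignore.strand = TRUE)
  list(kept = intervals[!hit, , drop = FALSE],
       removed = intervals[hit, , drop = FALSE])
}

#' Jaccard index between two feature-id sets
#'
#' Intersection over union; defined as 0 when both sets are empty. Used to
#' compare age-differential cCRE sets between cell types.
#'
#' @param a,b Character vectors of feature ids.
#' @return A number in \[0, 1\].
#' @export
jaccard_index <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Read a BED3/BED6 file
#'
#' Tab-separated, no header; columns beyond the sixth are ignored.
#'
#' @param path File path.
#' @param genome Optional `genome_layout` for validation.
#' @return A `genomic_intervals` table.
#' @export
read_bed <- function(path, genome = NULL) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t", data.table = FALSE)
  if (ncol(dt) < 3) stop("BED file needs at least 3 columns: ", path)
  genomic_intervals(
    chrom = dt[[1]], start = dt[[2]], end = dt[[3]],
    id = if (ncol(dt) >= 4) as.character(dt[[4]]) else NULL,
    score = if (ncol(dt) >= 5) suppressWarnings(as.numeric(dt[[5]])) else NULL,
    strand = if (ncol(dt) >= 6) as.character(dt[[6]]) else NULL,
    genome = genome
  )
}

#' Write intervals as BED6
#'
#' @param intervals A `genomic_intervals` table.
#' @param path Output path.
#' @export
write_bed <- function(intervals, path) {
  sc <- ifelse(is.na(intervals$score), 0, intervals$score)
  out <- data.frame(intervals$chrom,
                    format(intervals$start, scientific = FALSE,
                           trim = TRUE, digits = 15),
                    format(intervals$end, scientific = FALSE,
                           trim = TRUE, digits = 15),
                    intervals$id, sc, intervals$strand)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a barcoded fragments file
#'
#' 4-column TSV (chrom, start, end, barcode), optionally gzip-compressed.
#' Fragments are proper-pair spans; records with non-positive width or an
#' insert size of 2000 bp or more are rejected.
#'
#' @param path File path (`.gz` allowed).
#' @param max_insert Maximum allowed fragment length, exclusive (default 2000).
#' @return data.frame with columns chrom, start, end, barcode.
#' @export
read_fragments <- function(path, max_insert = 2000) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t", data.table = FALSE)
  if (ncol(dt) < 4) stop("fragments file needs 4 columns (chrom, start, end, barcode)")
  names(dt)[1:4] <- c("chrom", "start", "end", "barcode")
  bad <- which(!(dt$start < dt$end))
  if (length(bad)) stop("malformed fragment at line ", bad[1], ": start >= end")
  dt[dt$end - dt$start < max_insert, 1:4]
}

#' Construct a pseudo-bulk count matrix
#'
#' Couples an integer feature-by-sample count matrix with its sample
#' metadata (cell type, age in months, replicate, number of cells). Library
#' sizes are derived from column sums of the raw counts.
#'
#' @param counts Numeric matrix, features x samples, non-negative.
#' @param samples data.frame with columns `cell_type`, `age_months`,
#'   `replicate`, `n_cells` (one row per column of `counts`).
#' @param normalization `"raw"` or `"CPM"`.
#' @param library_size Optional explicit library sizes; defaults to column
#'   sums (mandatory to supply for CPM matrices).
#' @return A `count_matrix` object.
#' @export
count_matrix <- function(counts, samples, normalization = "raw",
                         library_size = NULL) {
  counts <- as.matrix(counts)
  stopifnot(is.data.frame(samples), nrow(samples) == ncol(counts))
  req <- c("cell_type", "age_months", "replicate", "n_cells")
  miss <- setdiff(req, names(samples))
  if (length(miss)) stop("sample metadata missing columns: ", paste(miss, collapse = ", "))
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(samples$n_cells <= 0)) stop("n_cells must be positive")
  normalization <- match.arg(normalization, c("raw", "CPM"))
  if (is.null(library_size)) {
    if (normalization == "CPM") stop("CPM matrices need explicit library sizes")
    library_size <- colSums(counts)
  }
  samples$library_size <- as.numeric(library_size)
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("feature_%05d", seq_len(nrow(counts)))
  }
  if (anyDuplicated(rownames(counts))) stop("feature ids must be unique")
  colnames(counts) <- sample_id(samples)
  structure(list(counts = counts, samples = samples,
                 normalization = normalization),
            class = "count_matrix")
}

#' Canonical sample identifiers ("celltype.age.rep")
#' @param samples Sample metadata data.frame.
#' @return Character vector of ids.
#' @export
sample_id <- function(samples) {
  paste(samples$cell_type, samples$age_months, samples$replicate, sep = ".")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d features x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts), x$normalization))
  cat("cell types:", paste(unique(x$samples$cell_type), collapse = ", "), "\n")
  cat("ages (months):", paste(sort(unique(x$samples$age_months)), collapse = ", "), "\n")
  invisible(x)
}

#' Count fragments overlapping intervals, per pseudo-bulk sample
#'
#' Whole-fragment overlap semantics: a fragment overlapping an interval by at
#' least 1 bp increments that interval's count for the fragment's sample; a
#' fragment spanning k intervals increments all k. Barcodes absent from the
#' mapping are skipped (tallied in attribute `n_unmapped`), since fragment
#' files retain filtered nuclei.
#'
#' @param fragments data.frame (chrom, start, end, barcode).
#' @param intervals Disjoint `genomic_intervals` (pre-merged).
#' @param barcode_to_sample Named character vector: barcode -> sample id.
#' @param samples Sample metadata (one row per distinct sample id, with
#'   `cell_type`, `age_months`, `replicate`, `n_cells`).
#' @return A raw `count_matrix`; attribute `n_unmapped` counts skipped
#'   fragments.
#' @export
count_fragments_in_intervals <- function(fragments, intervals,
                                         barcode_to_sample, samples) {
  validate_intervals(intervals)
  sid <- sample_id(samples)
  smp <- barcode_to_sample[fragments$barcode]
  unmapped <- is.na(smp)
  frg <- fragments[!unmapped, , drop = FALSE]
  smp <- smp[!unmapped]
  fr_gr <- GenomicRanges::GRanges(frg$chrom,
                                  IRanges::IRanges(frg$start + 1, frg$end))
  hits <- GenomicRanges::findOverlaps(fr_gr, gi_to_gr(intervals),
                                      ignore.strand = TRUE)
  si <- match(smp[S4Vectors::queryHits(hits)], sid)
  if (anyNA(si)) stop("barcode mapping points to a sample id absent from metadata")
  counts <- matrix(0, nrow = nrow(intervals), ncol = length(sid),
                   dimnames = list(intervals$id, sid))
  tab <- table(factor(S4Vectors::subjectHits(hits), levels = seq_len(nrow(intervals))),
               factor(si, levels = seq_along(sid)))
  counts[] <- as.numeric(tab)
  out <- count_matrix(counts, samples)
  attr(out, "n_unmapped") <- sum(unmapped)
  if (sum(unmapped) > 0) {
    warning(sprintf("%d fragments with unmapped barcodes were skipped", sum(unmapped)))
  }
  out
}

#' Write / read a count matrix as TSV
#'
#' Feature ids in the first column; sample-key column headers
#' "celltype.age.rep". Metadata travels in a sidecar TSV with suffix
#' ".samples.tsv".
#'
#' @param x A `count_matrix`.
#' @param path Output TSV path.
#' @export
write_count_matrix <- function(x, path) {
  df <- data.frame(feature_id = rownames(x$counts), x$counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- x$samples
  meta$sample <- sample_id(meta)
  utils::write.table(meta, paste0(path, ".samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_matrix
#' @param normalization Passed through to [count_matrix()].
#' @export
read_count_matrix <- function(path, normalization = "raw") {
  df <- data.table::fread(path, sep = "\t", data.table = FALSE)
  meta <- data.table::fread(paste0(path, ".samples.tsv"), sep = "\t",
                            data.table = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  ls <- if ("library_size" %in% names(meta)) meta$library_size else NULL
  count_matrix(m, meta[, c("cell_type", "age_months", "replicate", "n_cells")],
               normalization = normalization, library_size = ls)
}
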