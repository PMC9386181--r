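#' Counts-per-million normalization
#'
#' Plain per-million scaling of raw counts (no library-size re-weighting):
#' `cpm = count / sample_total * 1e6`, via [edgeR::cpm()].
#'
#' @param counts genes x samples non-negative count matrix.
#' @return CPM matrix of the same shape; every column sums to 1e6.
#' @export
cpm_normalize <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  tot <- colSums(counts)
  if (any(tot == 0)) {
    bad <- colnames(counts)[tot == 0] %||% which(tot == 0)
    stop("zero-total sample: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  edgeR::cpm(counts, normalized.lib.sizes = FALSE, log = FALSE)
}

#' Log2 transform of CPM values
#'
#' `log2(cpm + prior)` with a pseudo-count in CPM units; the default prior of
#' 1 maps zero counts to exactly 0 on the log2-CPM scale.
#'
#' @param cpm CPM matrix from [cpm_normalize()].
#' @param prior pseudo-CPM added before the log (non-negative).
#' @return log2-CPM matrix, finite everywhere.
#' @export
log2_transform <- function(cpm, prior = 1) {
  if (prior < 0) stop("prior must be non-negative", call. = FALSE)
  log2(as.matrix(cpm) + prior)
}

#' Filter low-expressed genes
#'
#' A gene is kept iff it is expressed (log2-CPM at or above `min_log2cpm`) in
#' at least `min_frac` of the samples; genes expressed in under half the
#' samples, or only at low level, are dropped.
#'
#' @param x log2-CPM matrix (genes x samples).
#' @param min_log2cpm expression floor on the log2-CPM scale.
#' @param min_frac minimum fraction of samples at or above the floor.
#' @return list with `matrix` (kept rows), `kept` (gene ids) and `report`
#'   (tibble: n_input, n_kept, n_removed).
#' @export
filter_genes <- function(x, min_log2cpm = 0, min_frac = 0.5) {
  if (min_frac < 0 || min_frac > 1)
    stop("min_frac must lie in [0, 1]", call. = FALSE)
  x <- as.matrix(x)
  frac <- rowMeans(x >= min_log2cpm)
  keep <- frac >= min_frac
  list(matrix = x[keep, , drop = FALSE],
       kept = rownames(x)[keep] %||% which(keep),
       report = tibble::tibble(n_input = nrow(x), n_kept = sum(keep),
                               n_removed = sum(!keep)))
}

#' Remove batch structure by per-batch mean centering
#'
#' For each gene, subtracts the batch mean and restores the overall gene
#' mean, so per-batch gene means are equalized while each gene's grand mean
#' is preserved. A deliberately simple location-only batch adjustment;
#' singleton batches collapse to the gene mean (warned, not an error).
#'
#' @param x log2-CPM matrix (genes x samples).
#' @param batches either a tibble with columns sample_id and batch, or a
#'   vector of batch labels aligned with `colnames(x)`.
#' @return adjusted matrix of the same shape.
#' @export
center_batches <- function(x, batches) {
  x <- as.matrix(x)
  if (is.data.frame(batches)) {
    b <- batches$batch[match(colnames(x), batches$sample_id)]
  } else b <- as.vector(batches)
  if (length(b) != ncol(x) || anyNA(b))
    stop("every sample must carry a batch label", call. = FALSE)
  sizes <- table(b)
  if (any(sizes == 1)) warning("singleton batch(es): ",
                               paste(names(sizes)[sizes == 1], collapse = ", "))
  gene_mean <- rowMeans(x)
  out <- x
  for (lvl in unique(b)) {
    cols <- b == lvl
    bm <- rowMeans(x[, cols, drop = FALSE])
    out[, cols] <- x[, cols, drop = FALSE] - bm + gene_mean
  }
  out
}
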