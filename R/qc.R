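#' Transcript-count QC filter with a lenient surface threshold
#'
#' Cells with fewer than `min_transcripts` detected transcripts are
#' excluded, except cells at the keratinized skin surface
#' (`surface_flag`), where transcriptional activity drops during
#' keratinocyte differentiation and a more lenient minimum applies.
#' Both thresholds are inclusive minima: a non-surface cell with
#' exactly `min_transcripts` is retained.
#'
#' @param dataset A `spatial_dataset` with `total_transcripts` populated.
#' @param min_transcripts Strict minimum (default 50).
#' @param surface_min Lenient minimum for surface cells (default 10);
#'   must not exceed `min_transcripts`.
#' @return The filtered `spatial_dataset`, with a `qc_report` attribute:
#'   list(n_in, n_kept, n_removed_standard, n_removed_surface,
#'   min_transcripts, surface_min).
#' @export
qc_filter <- function(dataset, min_transcripts = 50L, surface_min = 10L) {
  stopifnot(inherits(dataset, "spatial_dataset"))
  if (surface_min > min_transcripts)
    stop("surface_min (", surface_min, ") must not exceed min_transcripts (",
         min_transcripts, ")")
  tot <- dataset$cells$total_transcripts
  if (anyNA(tot)) stop("total_transcripts must be populated before QC")
  surf <- dataset$cells$surface_flag %in% TRUE
  keep <- ifelse(surf, tot >= surface_min, tot >= min_transcripts)
  out <- subset_cells(dataset, keep)
  attr(out, "qc_report") <- list(
    n_in = length(keep), n_kept = sum(keep),
    n_removed_standard = sum(!keep & !surf),
    n_removed_surface = sum(!keep & surf),
    min_transcripts = min_transcripts, surface_min = surface_min
  )
  out
}

#' Log-normalize a count matrix
#'
#' The standard library-size normalization: each cell's counts are
#' rescaled to a fixed total (`scale_total`, default 1e4) and
#' log1p-transformed, `log1p(count * scale_total / cell_total)`. Zero
#' counts map to zero and the per-cell transform is strictly monotone,
#' so values are nonnegative and invariant to per-cell rescaling of
#' the raw counts.
#'
#' @param counts Cells x genes count matrix (or a `spatial_dataset`).
#' @param scale_total Per-cell target total (default 1e4).
#' @return A cells x genes matrix of log-normalized values (dgCMatrix).
#' @export
log_normalize <- function(counts, scale_total = 1e4) {
  if (inherits(counts, "spatial_dataset")) counts <- counts$counts
  stopifnot(scale_total > 0)
  tot <- Matrix::rowSums(counts)
  zero <- which(tot == 0)
  if (length(zero))
    stop("cell(s) with zero total counts: ",
         paste(utils::head(rownames(counts)[zero] %||% zero, 5), collapse = ", "))
  m <- as_dgc(counts)
  fac <- scale_total / tot
  # operate on nonzero entries only: log1p(0) = 0 preserves sparsity
  rows <- m@i + 1L
  m@x <- log1p(m@x * fac[rows])
  m
}

#' Rank genes by excess variance and pick the top set
#'
#' A mean-variance-trend method in the vst spirit, operating on raw
#' counts (where overdispersion is visible at fixed mean): per-gene
#' mean and variance of the counts are computed, a loess of
#' log10(variance) on log10(mean) is fitted across expressed genes,
#' and genes are ranked by their residual from the trend (excess
#' variance over the expectation at that mean). Ties are broken
#' lexicographically by gene name, so the ranking is deterministic;
#' constant genes rank last.
#'
#' @param counts Cells x genes count matrix (a `spatial_dataset` is
#'   also accepted).
#' @param n_top How many genes to return (between 1 and the gene
#'   count).
#' @param span Loess span for the trend fit (default 1: with at most a
#'   few hundred panel genes, a wide window keeps boundary genes from
#'   dominating their own local fit).
#' @return Character vector of `n_top` gene names, ranked.
#' @export
select_variable_genes <- function(counts, n_top, span = 1) {
  if (inherits(counts, "spatial_dataset")) counts <- counts$counts
  if (n_top <= 0) stop("n_top must be positive")
  if (n_top > ncol(counts)) stop("n_top exceeds gene count")
  n <- nrow(counts)
  mu <- Matrix::colMeans(counts)
  v <- (Matrix::colMeans(counts^2) - mu^2) * n / max(1, n - 1)
  resid <- rep(-Inf, length(v))          # constant genes rank last
  ok <- v > 0 & mu > 0
  if (sum(ok) >= 4) {
    # robust degree-1 fit so a minority of genuinely overdispersed genes
    # (which also have the noisiest means, hence extreme x with high
    # local leverage) cannot pull the trend toward themselves
    fit <- stats::loess(log10(v[ok]) ~ log10(mu[ok]), span = span,
                        degree = 1, family = "symmetric",
                        control = stats::loess.control(surface = "direct"))
    resid[ok] <- log10(v[ok]) - fit$fitted
  } else {
    resid[ok] <- v[ok]
  }
  g <- colnames(counts)
  ord <- order(-resid, g)
  g[ord][seq_len(n_top)]
}

#' Jointly row-scale binned expression blocks
#'
#' For heatmaps that juxtapose several binned-mean matrices sharing
#' gene rows (e.g. spatial bins next to dissociated cell types), each
#' gene row is z-scored across the concatenation of all blocks'
#' columns, then split back, so colors are comparable across blocks.
#' The population standard deviation (divide by n) is used.
#' Zero-variance rows map to all zeros.
#'
#' @param blocks A list of gene x bin matrices with identical rownames,
#'   or a single matrix.
#' @return A list of z-scored blocks of the same shapes (or a single
#'   matrix if a single matrix was given).
#' @export
row_scale_joint <- function(blocks) {
  single <- is.matrix(blocks)
  if (single) blocks <- list(blocks)
  gene_sets <- lapply(blocks, rownames)
  if (any(vapply(gene_sets, is.null, logical(1))))
    stop("all blocks must have rownames (genes)")
  if (length(blocks) > 1 &&
      !all(vapply(gene_sets[-1], identical, logical(1), gene_sets[[1]])))
    stop("blocks must share an identical gene row set")
  cat_m <- do.call(cbind, blocks)
  mu <- rowMeans(cat_m)
  sd_pop <- sqrt(rowMeans((cat_m - mu)^2))
  z <- (cat_m - mu) / ifelse(sd_pop > 0, sd_pop, 1)
  z[sd_pop == 0, ] <- 0
  splits <- rep(seq_along(blocks), vapply(blocks, ncol, integer(1)))
  out <- lapply(seq_along(blocks), function(i) {
    b <- z[, splits == i, drop = FALSE]
    colnames(b) <- colnames(blocks[[i]])
    b
  })
  if (single) out[[1]] else out
}
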