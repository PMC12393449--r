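#' Spatial dataset: cell table plus aligned gene count matrix
#'
#' The universal currency of the pipeline: one or more seqFISH-style
#' sections represented as a validated cell table (centroids in pixels,
#' y increasing with depth from the outer surface) and a cells x genes
#' nonnegative integer count matrix aligned row-for-row by `cell_id`.
#'
#' @param cells A data.frame with at least `cell_id`, `x_px`, `y_px`.
#'   Optional columns `sample_id`, `section_id`, `cell_type`,
#'   `surface_flag`, `total_transcripts` are filled with defaults when
#'   absent; unknown columns are preserved.
#' @param counts A cells x genes matrix (base or `Matrix` sparse) of
#'   nonnegative integers, or `NULL`. Row order must match `cells`.
#' @param um_per_px Microns per pixel for this dataset (default 0.1).
#' @return An object of class `spatial_dataset`: a list with elements
#'   `cells`, `counts` (dgCMatrix or NULL) and `um_per_px`.
#'   `total_transcripts` is recomputed from the count matrix whenever
#'   counts are present, so the two can never disagree.
#' @export
spatial_dataset <- function(cells, counts = NULL, um_per_px = 0.1) {
  cells <- validate_cell_table(cells)
  if (!is.null(counts)) {
    counts <- validate_count_matrix(counts, cells$cell_id)
    cells$total_transcripts <- as.integer(round(Matrix::rowSums(counts)))
  }
  structure(
    list(cells = cells, counts = counts, um_per_px = um_per_px),
    class = "spatial_dataset"
  )
}

#' @export
print.spatial_dataset <- function(x, ...) {
  cat(sprintf(
    "<spatial_dataset> %d cells, %s genes, %d section(s), %.3g um/px\n",
    nrow(x$cells),
    if (is.null(x$counts)) "no" else as.character(ncol(x$counts)),
    length(unique(x$cells$section_id)), x$um_per_px
  ))
  if (!is.null(x$cells$cell_type)) {
    tt <- sort(table(x$cells$cell_type), decreasing = TRUE)
    cat("  cell types:", paste(sprintf("%s(%d)", names(tt), tt), collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
dim.spatial_dataset <- function(x) {
  c(nrow(x$cells), if (is.null(x$counts)) 0L else ncol(x$counts))
}

validate_cell_table <- function(cells) {
  if (!is.data.frame(cells)) stop("cells must be a data.frame")
  need <- c("cell_id", "x_px", "y_px")
  miss <- setdiff(need, names(cells))
  if (length(miss)) stop("cell table missing required column(s): ",
                         paste(miss, collapse = ", "))
  cells$cell_id <- as.character(cells$cell_id)
  dup <- unique(cells$cell_id[duplicated(cells$cell_id)])
  if (length(dup)) stop("duplicate cell_id(s): ",
                        paste(utils::head(dup, 5), collapse = ", "))
  for (cc in c("x_px", "y_px")) {
    v <- cells[[cc]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))))
      stop("non-numeric ", cc, " at row(s): ",
           paste(utils::head(if (length(bad)) bad else seq_len(nrow(cells)), 5),
                 collapse = ", "))
    }
    if (nrow(cells) && any(!is.finite(v))) {
      stop("non-finite ", cc, " at row(s): ",
           paste(utils::head(which(!is.finite(v)), 5), collapse = ", "))
    }
  }
  n <- nrow(cells)
  if (is.null(cells$sample_id))  cells$sample_id  <- rep("sample1", n)
  if (is.null(cells$section_id)) cells$section_id <- rep("section1", n)
  if (is.null(cells$cell_type))  cells$cell_type  <- rep("unlabeled", n)
  if (is.null(cells$surface_flag)) cells$surface_flag <- rep(FALSE, n)
  cells$surface_flag <- as.logical(cells$surface_flag)
  if (is.null(cells$total_transcripts))
    cells$total_transcripts <- rep(NA_integer_, n)
  rownames(cells) <- NULL
  cells
}

validate_count_matrix <- function(counts, cell_ids) {
  counts <- as_dgc(counts)
  if (any(counts@x < 0)) stop("count matrix has negative entries")
  if (any(counts@x != round(counts@x))) stop("count matrix has non-integer entries")
  if (is.null(colnames(counts))) stop("count matrix must carry gene names")
  if (anyDuplicated(colnames(counts))) stop("duplicated gene names in count matrix")
  if (nrow(counts) != length(cell_ids))
    stop("count matrix has ", nrow(counts), " rows but cell table has ",
         length(cell_ids), " cells")
  if (!is.null(rownames(counts)) && nrow(counts) > 0 &&
      !identical(rownames(counts), as.character(cell_ids))) {
    off <- which(rownames(counts) != cell_ids)
    stop("cell_id mismatch between counts and cell table; first offenders: ",
         paste(utils::head(rownames(counts)[off], 5), collapse = ", "))
  }
  rownames(counts) <- as.character(cell_ids)
  counts
}

#' Subset a spatial dataset by cell
#'
#' @param dataset A `spatial_dataset`.
#' @param keep Logical or integer index over cells, or character cell ids.
#' @return The subset `spatial_dataset` (count rows follow the cells).
#' @export
subset_cells <- function(dataset, keep) {
  stopifnot(inherits(dataset, "spatial_dataset"))
  if (is.character(keep)) keep <- match(keep, dataset$cells$cell_id)
  cells <- dataset$cells[keep, , drop = FALSE]
  counts <- if (is.null(dataset$counts)) NULL else
    dataset$counts[keep, , drop = FALSE]
  spatial_dataset(cells, counts, dataset$um_per_px)
}
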