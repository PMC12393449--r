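#' Convert a pixel distance to microns
#'
#' All geometry in the package is done in pixel units; conversion to
#' physical units happens only at reporting time, using a per-section
#' pixel scale.
#'
#' @param d_px Nonnegative pixel distance(s).
#' @param um_per_px Microns per pixel (positive scalar). The default,
#'   0.1 um/px, corresponds to a 15 px segmentation expansion spanning
#'   ~1.5 um on a GenePS-style instrument.
#' @return Distance(s) in microns.
#' @examples
#' px_to_um(15)            # 1.5
#' px_to_um(400, 0.103)    # 41.2
#' @export
px_to_um <- function(d_px, um_per_px = 0.1) {
  stopifnot(is.numeric(d_px), is.numeric(um_per_px), length(um_per_px) == 1L)
  if (um_per_px <= 0) stop("um_per_px must be > 0")
  if (any(d_px < 0, na.rm = TRUE)) stop("pixel distances must be nonnegative")
  d_px * um_per_px
}

# Chunked exact k-nearest-neighbour search in Euclidean space.
# Returns list(index, dist): n x k matrices, self excluded.
# Exact by construction; chunking only bounds memory.
knn_brute <- function(x, k, chunk = 512L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k >= n) stop("k must be < number of points")
  sq <- rowSums(x^2)
  idx <- matrix(NA_integer_, n, k)
  dst <- matrix(NA_real_, n, k)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    rows <- s:e
    # squared distances of chunk rows vs all points
    d2 <- outer(sq[rows], sq, `+`) - 2 * tcrossprod(x[rows, , drop = FALSE], x)
    d2[d2 < 0] <- 0
    for (j in seq_along(rows)) {
      i <- rows[j]
      di <- d2[j, ]
      di[i] <- Inf  # exclude self
      ord <- order(di)[seq_len(k)]
      idx[i, ] <- ord
      dst[i, ] <- sqrt(di[ord])
    }
  }
  list(index = idx, dist = dst)
}

# Pairwise squared distances between two point sets, chunked over rows of a.
# f(rows, d2) is called per chunk with the row indices and the chunk x nrow(b)
# squared-distance matrix; used so callers never materialise n x m.
pairwise_apply <- function(a, b, f, chunk = 1024L) {
  a <- as.matrix(a); b <- as.matrix(b)
  sqb <- rowSums(b^2)
  for (s in seq(1L, nrow(a), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(a))
    rows <- s:e
    d2 <- outer(rowSums(a[rows, , drop = FALSE]^2), sqb, `+`) -
      2 * tcrossprod(a[rows, , drop = FALSE], b)
    d2[d2 < 0] <- 0
    f(rows, d2)
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Coerce any matrix to dgCMatrix, preserving dimnames. Matrix() detects
# numerically symmetric inputs and returns symmetric storage carrying a
# single dimname set, which would corrupt cell ids on square matrices.
as_dgc <- function(x) {
  dn <- dimnames(x)
  x <- methods::as(methods::as(methods::as(
    Matrix::Matrix(x, sparse = TRUE), "dMatrix"), "generalMatrix"),
    "CsparseMatrix")
  dimnames(x) <- dn
  x
}
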