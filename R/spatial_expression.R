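#' Local (neighborhood) expression around focal cells
#'
#' For each focal cell, the mean normalized expression of a gene over
#' neighboring cells within a radius (default 400 px, ~41 um),
#' excluding the focal cell itself, optionally restricted to a set of
#' neighbor cell types. Cells with no eligible neighbor get NA and a
#' neighbor count of 0.
#'
#' @param dataset A `spatial_dataset`.
#' @param expr Cells x genes normalized expression matrix aligned to
#'   the dataset.
#' @param gene Gene symbol.
#' @param focal_cells Character cell ids, or a logical/integer index
#'   over cells; defaults to all cells.
#' @param radius Neighborhood radius in px (default 400).
#' @param neighbor_types Optional character vector restricting which
#'   cell types count as neighbors.
#' @param include_focal Include the focal cell itself (default FALSE).
#' @return data.frame(cell_id, value, n_neighbors).
#' @export
local_expression <- function(dataset, expr, gene, focal_cells = NULL,
                             radius = 400, neighbor_types = NULL,
                             include_focal = FALSE) {
  stopifnot(inherits(dataset, "spatial_dataset"), radius > 0)
  if (!gene %in% colnames(expr)) stop("unknown gene: ", gene)
  cells <- dataset$cells
  focal <- if (is.null(focal_cells)) seq_len(nrow(cells))
  else if (is.character(focal_cells)) match(focal_cells, cells$cell_id)
  else if (is.logical(focal_cells)) which(focal_cells)
  else as.integer(focal_cells)
  if (anyNA(focal)) stop("focal_cells contains unknown cell ids")
  if (!length(focal))
    return(data.frame(cell_id = character(0), value = numeric(0),
                      n_neighbors = integer(0)))
  nb_ok <- if (is.null(neighbor_types)) rep(TRUE, nrow(cells)) else
    cells$cell_type %in% neighbor_types
  nb_idx <- which(nb_ok)
  e <- as.numeric(expr[, gene])
  fp <- cbind(cells$x_px[focal], cells$y_px[focal])
  np <- cbind(cells$x_px[nb_idx], cells$y_px[nb_idx])
  val <- rep(NA_real_, length(focal)); cnt <- integer(length(focal))
  r2 <- radius^2
  pairwise_apply(fp, np, function(rows, d2) {
    for (j in seq_along(rows)) {
      within <- nb_idx[d2[j, ] <= r2]
      if (!include_focal) within <- setdiff(within, focal[rows[j]])
      cnt[rows[j]] <<- length(within)
      if (length(within)) val[rows[j]] <<- mean(e[within])
    }
  })
  data.frame(cell_id = cells$cell_id[focal], value = val,
             n_neighbors = cnt, stringsAsFactors = FALSE)
}

#' Kernel-smoothed expression surface
#'
#' Nadaraya-Watson smoothing of per-cell expression over space: at
#' each grid node, the Gaussian-weighted mean of all cells' values
#' (weights exp(-d^2 / (2 sigma^2)), truncated at 3 sigma). Nodes with
#' zero total weight are masked (NA). Being a weighted mean, the
#' surface is bounded by the range of the input values.
#'
#' @param dataset A `spatial_dataset`.
#' @param expr Cells x genes normalized expression matrix.
#' @param gene Gene symbol.
#' @param sigma Kernel sd in px (default 400).
#' @param grid_spacing Grid step in px (default sigma/4).
#' @return A `smoothed_map`: list(x, y, values, gene, sigma).
#' @export
smooth_expression_map <- function(dataset, expr, gene, sigma = 400,
                                  grid_spacing = sigma / 4) {
  stopifnot(inherits(dataset, "spatial_dataset"), sigma > 0)
  if (!gene %in% colnames(expr)) stop("unknown gene: ", gene)
  cells <- dataset$cells
  if (!nrow(cells)) stop("no cells to smooth")
  e <- as.numeric(expr[, gene])
  gx <- seq(min(cells$x_px), max(cells$x_px) + grid_spacing, by = grid_spacing)
  gy <- seq(min(cells$y_px), max(cells$y_px) + grid_spacing, by = grid_spacing)
  pts <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
  cp <- cbind(cells$x_px, cells$y_px)
  s2 <- 2 * sigma^2; r2 <- (3 * sigma)^2
  num <- numeric(nrow(pts)); den <- numeric(nrow(pts))
  pairwise_apply(pts, cp, function(rows, d2) {
    w <- exp(-d2 / s2)
    w[d2 > r2] <- 0
    num[rows] <<- as.numeric(w %*% e)
    den[rows] <<- rowSums(w)
  })
  vals <- ifelse(den > 0, num / den, NA_real_)
  structure(list(x = gx, y = gy,
                 values = matrix(vals, length(gx), length(gy)),
                 gene = gene, sigma = sigma),
            class = "smoothed_map")
}

#' Quantile-anchored contour levels for a smoothed map
#'
#' `n_levels` values evenly spaced between the empirical `threshold`
#' quantile (type-7) of the unmasked surface values and the surface
#' maximum; the defaults (threshold 0.9, 6 levels) outline the top
#' decile of a smoothed expression surface.
#'
#' @param map A `smoothed_map`.
#' @param threshold Lower-anchor quantile in (0, 1) (default 0.9).
#' @param n_levels Number of levels (default 6).
#' @return Numeric vector of `n_levels` level values.
#' @export
contour_levels <- function(map, threshold = 0.9, n_levels = 6L) {
  stopifnot(threshold > 0, threshold < 1, n_levels >= 1)
  v <- map$values[!is.na(map$values)]
  if (!length(v)) stop("surface is fully masked; no contour levels")
  q <- stats::quantile(v, threshold, type = 7, names = FALSE)
  if (n_levels == 1L) return(q)
  seq(q, max(v), length.out = n_levels)
}

#' Rolling mean of values along a continuous ordering
#'
#' Cells are sorted by `order_score`; a centered moving average with a
#' window of `max(1, round(window_prop * n))` cells is computed, with
#' windows clipped (shrunk) at the edges. With `window_prop = 1` the
#' central values approach the global mean and the curve is near-flat.
#'
#' @param values Per-cell values.
#' @param order_score Per-cell ordering score (same length).
#' @param window_prop Window size as a fraction of n, in (0, 1]
#'   (default 0.1).
#' @return data.frame(order_score, value, smoothed), sorted by score.
#' @export
rolling_mean_by_score <- function(values, order_score, window_prop = 0.1) {
  stopifnot(length(values) == length(order_score),
            window_prop > 0, window_prop <= 1)
  n <- length(values)
  if (n == 0)
    return(data.frame(order_score = numeric(0), value = numeric(0),
                      smoothed = numeric(0)))
  ord <- order(order_score)
  v <- values[ord]
  w <- max(1L, as.integer(round(window_prop * n)))
  h_left <- (w - 1L) %/% 2L
  h_right <- w - 1L - h_left
  cs <- cumsum(c(0, v))
  lo <- pmax(1L, seq_len(n) - h_left)
  hi <- pmin(n, seq_len(n) + h_right)
  sm <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  data.frame(order_score = order_score[ord], value = v, smoothed = sm)
}
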