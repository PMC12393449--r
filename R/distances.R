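#' Minimum distance from focal cells to the nearest cell of target types
#'
#' The spatial-context statistic used to place cells relative to
#' tissue structures: e.g. distance of each CD14+ myeloid cell to the
#' closest basal keratinocyte (a proxy for distance to the epidermis)
#' or to the closest CD4/CD8 T cell (distance to lymphocyte
#' aggregates). Unlike the colocalization score, the density of the
#' target type does not matter, only the nearest centroid. Distances
#' are Euclidean on centroids; the minimum is taken over the union of
#' the target types.
#'
#' @param dataset A `spatial_dataset` with cell types.
#' @param focal_type Cell type whose cells are measured.
#' @param target_types Character vector of target cell types.
#' @param name Column name for the distance (default built from the
#'   targets).
#' @return data.frame(cell_id, <name>_px, <name>_um, depth_px).
#' @export
min_distance_to_type <- function(dataset, focal_type, target_types,
                                 name = paste(target_types, collapse = "_")) {
  stopifnot(inherits(dataset, "spatial_dataset"))
  cells <- dataset$cells
  focal <- which(cells$cell_type == focal_type)
  if (!length(focal)) stop("no cells of focal type ", focal_type)
  targ <- which(cells$cell_type %in% target_types)
  if (!length(targ))
    stop("no cells of target type(s): ", paste(target_types, collapse = ", "))
  fp <- cbind(cells$x_px[focal], cells$y_px[focal])
  tp <- cbind(cells$x_px[targ], cells$y_px[targ])
  dmin <- rep(Inf, length(focal))
  pairwise_apply(fp, tp, function(rows, d2) {
    dmin[rows] <<- sqrt(apply(d2, 1, min))
  })
  out <- data.frame(cell_id = cells$cell_id[focal],
                    dist_px = dmin,
                    dist_um = px_to_um(dmin, dataset$um_per_px),
                    depth_px = cells$y_px[focal],
                    stringsAsFactors = FALSE)
  names(out)[2:3] <- paste0("dist_", name, c("_px", "_um"))
  out
}

#' Depth distributions of cell types
#'
#' Gaussian kernel density of y (depth) per requested type, evaluated
#' on a grid shared across types so ridgeline-style comparisons line
#' up, plus quartile summaries. Types with fewer than 2 cells get
#' quartiles only.
#'
#' @param dataset A `spatial_dataset`.
#' @param types Cell types to profile (default: all present).
#' @param bandwidth KDE bandwidth in px (default: Silverman's rule per
#'   type via [stats::density()] when NULL).
#' @param n_grid Grid resolution (default 512).
#' @return list(grid, density: type x grid matrix (rows NA when
#'   undefined), quartiles: type x 3 matrix).
#' @export
depth_profile <- function(dataset, types = NULL, bandwidth = NULL,
                          n_grid = 512L) {
  stopifnot(inherits(dataset, "spatial_dataset"))
  cells <- dataset$cells
  if (is.null(types)) types <- sort(unique(cells$cell_type))
  ys <- cells$y_px[cells$cell_type %in% types]
  if (!length(ys)) stop("no cells of the requested types")
  pad <- if (is.null(bandwidth)) diff(range(ys)) * 0.2 + 1 else 4 * bandwidth
  grid <- seq(min(ys) - pad, max(ys) + pad, length.out = n_grid)
  dens <- matrix(NA_real_, length(types), n_grid,
                 dimnames = list(types, NULL))
  quarts <- matrix(NA_real_, length(types), 3,
                   dimnames = list(types, c("q25", "q50", "q75")))
  for (ty in types) {
    y <- cells$y_px[cells$cell_type == ty]
    if (!length(y)) next
    quarts[ty, ] <- stats::quantile(y, c(0.25, 0.5, 0.75), type = 7,
                                    names = FALSE)
    if (length(y) >= 2 && stats::sd(y) > 0) {
      d <- stats::density(y, bw = if (is.null(bandwidth)) "nrd0" else bandwidth,
                          from = grid[1], to = grid[n_grid], n = n_grid)
      dens[ty, ] <- d$y
    }
  }
  list(grid = grid, density = dens, quartiles = quarts)
}

#' Join a transition ordering with distance metrics
#'
#' Inner join on cell id of a `transition_ordering` and a distance
#' table for the same focal cells, plus marginal rolling means of the
#' transition score ordered along each distance axis (the marginal
#' curves of a distance-vs-distance scatter colored by DC1).
#'
#' @param ordering A `transition_ordering`.
#' @param distances A data.frame from [min_distance_to_type()] (or
#'   several merged); all `dist_*_px` columns get a marginal curve.
#' @param window_prop Rolling-window fraction (default 0.1).
#' @return list(table: joined data.frame, marginals: named list of
#'   rolling-mean data.frames keyed by distance column).
#' @export
transition_distance_table <- function(ordering, distances,
                                      window_prop = 0.1) {
  tab <- merge(as.data.frame(ordering), distances, by = "cell_id")
  lost <- nrow(ordering) - nrow(tab)
  if (lost > 0)
    warning(lost, " cell(s) of the ordering missing from the distance table")
  dist_cols <- grep("^dist_.*_px$", names(tab), value = TRUE)
  marginals <- lapply(dist_cols, function(dc)
    rolling_mean_by_score(tab$rank01, tab[[dc]], window_prop))
  names(marginals) <- dist_cols
  list(table = tab, marginals = marginals)
}
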