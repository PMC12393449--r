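# Diffusion-map ordering of a continuous cell-state transition.
#
# The CD14+ myeloid LYVE1 -> MMP9 continuum is recovered by embedding
# the subset with PCA, building a symmetrized kNN graph with adaptive
# Gaussian kernels, density-normalizing (alpha = 1) and taking the
# leading nontrivial eigenvector of the Markov operator (DC1). The
# orientation is anchored on marker genes and the per-cell rank along
# oriented DC1 is the transition score.

#' Centered PCA via singular value decomposition
#'
#' Deterministic sign convention: within each component the loading of
#' largest magnitude is made positive (earliest gene wins magnitude
#' ties), so repeated runs agree exactly.
#'
#' @param expr Cells x genes numeric matrix (typically log-normalized,
#'   restricted to selected genes).
#' @param n_components Number of components (<= min(n_cells - 1,
#'   n_genes)).
#' @return list(scores cells x k, loadings genes x k, sdev,
#'   var_explained).
#' @export
pca_embed <- function(expr, n_components = 5L) {
  x <- as.matrix(expr)
  n <- nrow(x); p <- ncol(x)
  if (n_components > min(n - 1L, p))
    stop("n_components exceeds min(n_cells - 1, n_genes)")
  xc <- sweep(x, 2, colMeans(x))
  sv <- svd(xc, nu = n_components, nv = n_components)
  if (n_components > sum(sv$d > sv$d[1] * 1e-12))
    stop("n_components exceeds the numerical rank of the centered matrix")
  for (j in seq_len(n_components)) {
    i <- which.max(abs(sv$v[, j]))
    if (sv$v[i, j] < 0) {
      sv$v[, j] <- -sv$v[, j]
      sv$u[, j] <- -sv$u[, j]
    }
  }
  d <- sv$d[seq_len(n_components)]
  scores <- sweep(sv$u, 2, d, `*`)
  rownames(scores) <- rownames(x)
  rownames(sv$v) <- colnames(x)
  sdev <- sv$d / sqrt(max(1, n - 1))
  list(scores = scores, loadings = sv$v[, seq_len(n_components), drop = FALSE],
       sdev = sdev[seq_len(n_components)],
       var_explained = sv$d^2 / sum(svd(xc, nu = 0, nv = 0)$d^2))
}

#' Diffusion map of an embedded cell subset
#'
#' Builds a symmetric (union) kNN graph on the embedding, weights
#' edges with adaptive Gaussian kernels
#' `w_ij = exp(-d_ij^2 / (sig_i^2 + sig_j^2))` where `sig_i` is the
#' distance from i to its ceiling(k/3)-th neighbor, applies the
#' density normalization (alpha = 1, dividing by the degree at both
#' endpoints) and decomposes the resulting Markov operator. The
#' trivial constant eigenvector (eigenvalue 1) is discarded; diffusion
#' component i is the (i+1)-th right eigenvector scaled by its
#' eigenvalue, with a deterministic sign (largest-magnitude entry
#' positive).
#'
#' @param embedding Cells x d numeric matrix (e.g. PCA scores).
#' @param k Neighbors per cell (default 200; capped at n - 1 with a
#'   warning).
#' @param n_components Number of diffusion components (default 2).
#' @return list(eigenvalues, components cells x m, k).
#' @export
diffusion_map <- function(embedding, k = 200L, n_components = 2L) {
  x <- as.matrix(embedding)
  n <- nrow(x)
  if (n < 3) stop("need at least 3 cells")
  if (k < 2) stop("k must be >= 2")
  if (k > n - 1L) {
    warning("k capped at n - 1 = ", n - 1L)
    k <- n - 1L
  }
  nn <- knn_brute(x, k)
  sig <- nn$dist[, ceiling(k / 3)]
  sig[sig <= 0] <- min(sig[sig > 0], 1e-12)

  ii <- rep(seq_len(n), each = k)
  jj <- as.vector(t(nn$index))
  dd <- as.vector(t(nn$dist))
  w <- exp(-dd^2 / (sig[ii]^2 + sig[jj]^2))
  W <- Matrix::sparseMatrix(i = ii, j = jj, x = w, dims = c(n, n))
  W <- pmax2_sym(W)                      # union of neighborhoods, symmetric
  q <- Matrix::rowSums(W)
  if (any(q == 0)) stop("disconnected cell(s) in the kNN graph; increase k")
  if (!graph_connected(W)) stop("kNN graph is disconnected; increase k")
  Dq <- Matrix::Diagonal(x = 1 / q)
  W1 <- Dq %*% W %*% Dq                  # alpha = 1 density normalization
  d1 <- Matrix::rowSums(W1)
  inv_sqrt <- 1 / sqrt(d1)
  Ds <- Matrix::Diagonal(x = inv_sqrt)
  S <- Ds %*% W1 %*% Ds                  # symmetric conjugate of the Markov op

  m <- n_components + 1L
  if (n <= 2000) {
    es <- eigen(as.matrix(S), symmetric = TRUE)
    evals <- es$values[seq_len(m)]
    evecs <- es$vectors[, seq_len(m), drop = FALSE]
  } else {
    ar <- igraph::arpack(
      function(v, extra = NULL) as.numeric(S %*% v),
      options = list(n = n, nev = m, ncv = max(2 * m + 10L, 20L),
                     which = "LA", maxiter = 5000),
      sym = TRUE)
    ord <- order(ar$values, decreasing = TRUE)
    evals <- ar$values[ord][seq_len(m)]
    evecs <- ar$vectors[, ord, drop = FALSE][, seq_len(m), drop = FALSE]
  }
  # right eigenvectors of the Markov operator
  phi <- evecs * inv_sqrt
  phi <- sweep(phi, 2, sqrt(colSums(phi^2)), `/`)
  comp <- phi[, -1, drop = FALSE]
  lam <- evals[-1]
  for (j in seq_len(ncol(comp))) {
    i <- which.max(abs(comp[, j]))
    if (comp[i, j] < 0) comp[, j] <- -comp[, j]
  }
  comp <- sweep(comp, 2, lam, `*`)
  rownames(comp) <- rownames(x)
  colnames(comp) <- paste0("DC", seq_len(ncol(comp)))
  list(eigenvalues = lam, components = comp, k = k)
}

# elementwise max(W, t(W)) for a sparse matrix
pmax2_sym <- function(W) {
  Wt <- Matrix::t(W)
  A <- (W + Wt) / 2
  B <- abs(W - Wt) / 2
  A + B
}

graph_connected <- function(W) {
  g <- igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected")
  igraph::count_components(g) == 1L
}

#' Orient DC1 on anchor genes and rank the cells
#'
#' The diffusion component's sign is arbitrary; it is fixed so that
#' the `anchor_up` gene (default MMP9) has higher mean expression in
#' the top DC1 quartile than in the bottom quartile (falling back to
#' the reverse on `anchor_down`, default LYVE1, when the up anchor is
#' uninformative). Ranks 1..n are assigned along the oriented DC1,
#' ties broken by cell id.
#'
#' @param dc1 Named per-cell DC1 values (names = cell ids) or an
#'   unnamed vector aligned to `expr` rows.
#' @param expr Cells x genes normalized expression for the same cells.
#' @param anchor_up Gene expected to increase along the transition.
#' @param anchor_down Gene expected to decrease.
#' @param n_bins Optional bin count; if given, equal-size bin
#'   assignments are attached (see [bin_aggregate()] for the rule).
#' @return A `transition_ordering`: data.frame(cell_id, dc1, rank,
#'   rank01[, bin]) with attributes `sign` and `anchors`.
#' @export
orient_and_rank <- function(dc1, expr, anchor_up = "MMP9",
                            anchor_down = "LYVE1", n_bins = NULL) {
  ids <- names(dc1) %||% rownames(expr) %||% as.character(seq_along(dc1))
  stopifnot(length(dc1) == nrow(expr))
  for (g in c(anchor_up, anchor_down))
    if (!g %in% colnames(expr)) stop("anchor gene not in expression: ", g)
  qs <- stats::quantile(dc1, c(0.25, 0.75), type = 7)
  top <- dc1 >= qs[2]; bot <- dc1 <= qs[1]
  up_diff <- mean(expr[top, anchor_up]) - mean(expr[bot, anchor_up])
  down_diff <- mean(expr[top, anchor_down]) - mean(expr[bot, anchor_down])
  sgn <- if (up_diff > 0) 1 else if (up_diff < 0) -1
  else if (down_diff < 0) 1 else if (down_diff > 0) -1
  else stop("orientation undecidable: anchors flat across DC1 quartiles; ",
            "supply an explicit sign by negating dc1")
  oriented <- sgn * dc1
  rk <- order(order(oriented, ids))
  out <- data.frame(cell_id = ids, dc1 = oriented, rank = rk,
                    rank01 = if (length(rk) > 1) (rk - 1) / (length(rk) - 1) else 0,
                    stringsAsFactors = FALSE)
  if (!is.null(n_bins)) out$bin <- bin_assign(rk, n_bins)
  attr(out, "sign") <- sgn
  attr(out, "anchors") <- c(up = anchor_up, down = anchor_down)
  class(out) <- c("transition_ordering", "data.frame")
  out
}

# equal-size contiguous rank blocks; larger bins first when n %% n_bins != 0
bin_assign <- function(ranks, n_bins) {
  n <- length(ranks)
  if (n_bins < 1 || n_bins > n) stop("n_bins must be in [1, n]")
  base <- n %/% n_bins; extra <- n %% n_bins
  sizes <- c(rep(base + 1L, extra), rep(base, n_bins - extra))
  bin_of_pos <- rep(seq_len(n_bins), sizes)
  bin_of_pos[ranks]
}

#' Aggregate expression into equal-size bins along the ordering
#'
#' Rank-ordered cells are split into `n_bins` contiguous blocks whose
#' sizes differ by at most one (the larger blocks come first); each
#' gene's normalized expression is averaged within each bin. 7,200
#' cells into 50 bins gives exactly 144 cells per bin.
#'
#' @param ordering A `transition_ordering` (or any data.frame with
#'   `cell_id` and `rank`).
#' @param expr Cells x genes normalized expression with rownames
#'   matching `cell_id`.
#' @param n_bins Number of bins (1..n).
#' @param genes Genes to aggregate (default: all columns of `expr`).
#' @return list(means: gene x bin matrix, sizes: per-bin cell counts,
#'   bins: per-cell bin assignment aligned to `ordering`).
#' @export
bin_aggregate <- function(ordering, expr, n_bins, genes = colnames(expr)) {
  stopifnot(all(c("cell_id", "rank") %in% names(ordering)))
  n <- nrow(ordering)
  if (n_bins > n) stop("n_bins exceeds the number of cells")
  miss <- setdiff(genes, colnames(expr))
  if (length(miss)) stop("gene(s) absent from expression: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  bins <- bin_assign(ordering$rank, n_bins)
  e <- as.matrix(expr[ordering$cell_id, genes, drop = FALSE])
  means <- matrix(NA_real_, length(genes), n_bins,
                  dimnames = list(genes, paste0("bin", seq_len(n_bins))))
  for (b in seq_len(n_bins))
    means[, b] <- colMeans(e[bins == b, , drop = FALSE])
  list(means = means, sizes = as.integer(table(factor(bins, seq_len(n_bins)))),
       bins = bins)
}

#' Full transition-ordering chain on a labeled dataset
#'
#' Convenience wrapper: subset to a cell type, log-normalize, select
#' the top variable genes, embed with PCA, run the diffusion map and
#' orient/rank on the anchor genes.
#'
#' @param dataset A QC-filtered `spatial_dataset`.
#' @param cell_type Subset label (default "Myeloid_CD14").
#' @param n_var_genes Variable genes for the embedding (default 100).
#' @param n_pcs Principal components (default 5).
#' @param k Diffusion-map neighbors (default 200, capped at n - 1).
#' @param anchor_up,anchor_down Orientation anchors (MMP9 / LYVE1).
#' @param n_bins Optional equal-size bin count to attach.
#' @return A `transition_ordering` (see [orient_and_rank()]), with the
#'   subset expression matrix as attribute `"expr"`.
#' @export
transition_ordering <- function(dataset, cell_type = "Myeloid_CD14",
                                n_var_genes = 100L, n_pcs = 5L, k = 200L,
                                anchor_up = "MMP9", anchor_down = "LYVE1",
                                n_bins = NULL) {
  sub <- subset_cells(dataset, dataset$cells$cell_type == cell_type)
  if (nrow(sub$cells) < 3) stop("fewer than 3 cells of type ", cell_type)
  expr <- log_normalize(sub$counts)
  genes <- select_variable_genes(sub$counts, min(n_var_genes, ncol(expr)))
  emb <- pca_embed(as.matrix(expr[, genes, drop = FALSE]),
                   min(n_pcs, length(genes), nrow(expr) - 1L))
  dm <- diffusion_map(emb$scores, k = min(k, nrow(expr) - 1L))
  dc1 <- stats::setNames(dm$components[, 1], sub$cells$cell_id)
  out <- orient_and_rank(dc1, expr, anchor_up, anchor_down, n_bins = n_bins)
  attr(out, "expr") <- expr
  out
}
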