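test_that("PCA matches the covariance eigen-decomposition oracle", {
  set.seed(17)
  x <- matrix(rnorm(500), 50, 10)
  p <- pca_embed(x, 5)
  ev <- eigen(cov(x), symmetric = TRUE)$values
  expect_equal(p$sdev[1:5]^2, ev[1:5], tolerance = 1e-8)
  expect_equal(p$var_explained[1:5], (ev / sum(ev))[1:5], tolerance = 1e-8)
  # scores are orthogonal
  g <- crossprod(p$scores)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
  # rank-1 data: PC1 explains essentially everything
  line <- outer(seq(-1, 1, length.out = 30), c(1, 2, -1))
  p1 <- pca_embed(line, 1)
  expect_gt(p1$var_explained[1], 0.999)
  expect_error(pca_embed(line, 3), "rank")
  expect_error(pca_embed(x, 11), "exceeds")
})

test_that("PCA signs are deterministic", {
  set.seed(18)
  x <- matrix(rnorm(200), 20, 10)
  p1 <- pca_embed(x, 3); p2 <- pca_embed(x, 3)
  expect_identical(p1$scores, p2$scores)
  for (j in 1:3) expect_gt(p1$loadings[which.max(abs(p1$loadings[, j])), j], 0)
})

test_that("diffusion map orders points along a 1D manifold", {
  # equally spaced line: DC1 tracks position (tiny boundary-bandwidth
  # wobble aside) and is strictly monotone in the interior
  xs <- seq(0, 1000, length.out = 50)
  dm <- diffusion_map(cbind(xs, 0 * xs), k = 10)
  rho <- cor(dm$components[, 1], xs, method = "spearman")
  expect_gte(abs(rho), 0.999)
  inner <- order(xs)[4:47]
  expect_true(all(diff(dm$components[inner, 1]) > 0) ||
              all(diff(dm$components[inner, 1]) < 0))
  # DC1 is never the trivial constant eigenvector
  expect_gt(sd(dm$components[, 1]), 0)
  expect_true(all(dm$eigenvalues < 1))
})

test_that("diffusion map tolerates noise on the manifold", {
  set.seed(23)
  for (s in 1:5) {
    n <- 1000
    x <- runif(n, 0, 1000)
    pts <- cbind(x, rnorm(n, 0, 50))   # noise sd = 5% of length
    dm <- diffusion_map(pts, k = 200)
    expect_gte(abs(cor(dm$components[, 1], x, method = "spearman")), 0.9)
  }
})

test_that("diffusion map guards its inputs", {
  set.seed(1)
  pts <- matrix(rnorm(20), 10, 2)
  expect_warning(diffusion_map(pts, k = 50), "capped")
  expect_error(diffusion_map(pts[1:2, ], k = 2), "at least 3")
  # two far-apart clusters with tiny k: disconnected
  far <- rbind(matrix(rnorm(20), 10, 2),
               matrix(rnorm(20, mean = 1e6), 10, 2))
  expect_error(diffusion_map(far, k = 3), "disconnected|increase k")
})

test_that("orientation anchors the transition and ranks deterministically", {
  set.seed(29)
  n <- 100
  t_true <- runif(n)
  expr <- cbind(MMP9 = 3 * t_true + rnorm(n, 0, 0.1),
                LYVE1 = 3 * (1 - t_true) + rnorm(n, 0, 0.1))
  rownames(expr) <- sprintf("c%03d", 1:n)
  dc1 <- -(t_true - 0.5)   # anti-aligned on purpose
  names(dc1) <- rownames(expr)
  ord <- orient_and_rank(dc1, expr)
  expect_equal(sort(ord$rank), 1:n)
  expect_gt(cor(ord$rank, t_true, method = "spearman"), 0.99)
  # negating dc1 flips the sign attribute but not the ranks
  ord2 <- orient_and_rank(-dc1, expr)
  expect_equal(ord2$rank, ord$rank)
  expect_equal(attr(ord2, "sign"), -attr(ord, "sign"))
  # undecidable orientation is an error
  flat <- expr; flat[] <- 1
  expect_error(orient_and_rank(dc1, flat), "undecidable")
  expect_error(orient_and_rank(dc1, expr[, 1, drop = FALSE]), "anchor")
})

test_that("equal-size binning follows the division algorithm", {
  ranks <- sample(100)
  b <- skinspatial:::bin_assign(ranks, 30)
  sizes <- as.integer(table(b))
  expect_equal(sizes, c(rep(4, 10), rep(3, 20)))     # 100 = 30*3 + 10
  expect_equal(max(sizes) - min(sizes), 1)
  # concatenated bins reproduce rank order
  expect_true(all(diff(b[order(ranks)]) >= 0))
  # 7200 cells into 50 bins -> 144 each
  expect_equal(unique(table(skinspatial:::bin_assign(sample(7200), 50))[1]),
               144)
})

test_that("bin aggregation averages expression within rank blocks", {
  n <- 10
  ord <- data.frame(cell_id = paste0("c", 1:n), rank = n:1)
  expr <- matrix(as.numeric(1:n), n, 1, dimnames = list(ord$cell_id, "G"))
  # bins of size 1: means equal per-cell values along the rank order
  ba <- bin_aggregate(ord, expr, n_bins = 10)
  expect_equal(as.numeric(ba$means), n:1)
  expect_equal(ba$sizes, rep(1L, 10))
  ba2 <- bin_aggregate(ord, expr, n_bins = 2)
  expect_equal(as.numeric(ba2$means), c(mean(10:6), mean(5:1)))
  expect_error(bin_aggregate(ord, expr, n_bins = 11), "exceeds")
  expect_error(bin_aggregate(ord, expr, n_bins = 2, genes = "missing"),
               "absent")
})

test_that("the full chain recovers the latent transition from tissue", {
  ok <- 0
  for (s in 1:3) {
    g <- generate_tissue(small_skin_config(), seed = s + 100)
    ds <- qc_filter(g$dataset)
    ord <- transition_ordering(ds)
    m <- merge(as.data.frame(ord), g$ground_truth[, c("cell_id", "t")],
               by = "cell_id")
    if (cor(m$rank, m$t, method = "spearman") >= 0.8) ok <- ok + 1
  }
  expect_gte(ok, 2)
})

test_that("negating anchor expression reverses the recovered orientation", {
  set.seed(31)
  n <- 60
  t_true <- runif(n)
  expr <- cbind(MMP9 = 2 * t_true, LYVE1 = 2 * (1 - t_true))
  rownames(expr) <- sprintf("c%03d", 1:n)
  dc1 <- stats::setNames(t_true - 0.5, rownames(expr))
  a <- orient_and_rank(dc1, expr)
  swapped <- expr[, c("LYVE1", "MMP9")]
  colnames(swapped) <- c("MMP9", "LYVE1")
  b <- orient_and_rank(dc1, swapped)
  expect_equal(attr(b, "sign"), -attr(a, "sign"))
  expect_equal(b$rank, n + 1L - a$rank)   # distinct dc1: exact reversal
})
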