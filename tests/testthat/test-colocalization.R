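test_that("the exact kernel score matches closed forms", {
  kp <- kernel_params(sd = 100)
  # kernel max at d = 0, value at d = sigma, truncation, additivity
  expect_equal(coloc_score_exact(c(0, 0), rbind(c(0, 0)), kp), 1)
  expect_equal(coloc_score_exact(c(100, 0), rbind(c(0, 0)), kp),
               exp(-0.5), tolerance = 1e-12)
  expect_equal(coloc_score_exact(c(350, 0), rbind(c(0, 0)), kp), 0)
  expect_equal(coloc_score_exact(c(0, 0), rbind(c(0, 0), c(0, 0)), kp), 2)
  # empty reference set scores 0, not an error
  expect_equal(coloc_score_exact(c(0, 0), NULL, kp), 0)
  # pdf-normalized mode scales by 1/(2 pi sigma^2)
  kpn <- kernel_params(sd = 100, normalized_pdf = TRUE)
  expect_equal(coloc_score_exact(c(0, 0), rbind(c(0, 0)), kpn),
               1 / (2 * pi * 100^2))
  expect_error(kernel_params(sd = 0), "sd")
  expect_error(kernel_params(sd = 10, truncation_radius = 5), "truncation")
})

test_that("with one reference the score decreases in distance then truncates", {
  kp <- kernel_params(sd = 50)
  d <- seq(0, 149, by = 1)
  s <- coloc_score_exact(cbind(d, 0), rbind(c(0, 0)), kp)
  expect_true(all(diff(s) < 0))
  expect_equal(coloc_score_exact(cbind(151, 0), rbind(c(0, 0)), kp), 0)
})

test_that("scores are additive over reference subsets", {
  set.seed(21)
  kp <- kernel_params(sd = 120)
  refA <- cbind(runif(30, 0, 800), runif(30, 0, 800))
  refB <- cbind(runif(20, 0, 800), runif(20, 0, 800))
  q <- cbind(runif(50, 0, 800), runif(50, 0, 800))
  expect_equal(coloc_score_exact(q, rbind(refA, refB), kp),
               coloc_score_exact(q, refA, kp) + coloc_score_exact(q, refB, kp),
               tolerance = 1e-12)
})

test_that("gridded fields reproduce the exact oracle within 1% of the max", {
  set.seed(11)
  for (i in 1:100) {
    sd <- runif(1, 100, 400)
    kp <- kernel_params(sd = sd)
    ref <- cbind(runif(100, 0, 2000), runif(100, 0, 2000))
    fld <- create_field(ref, kp, grid_spacing = sd / 4)
    q <- cbind(runif(1000, -200, 2200), runif(1000, -200, 2200))
    err <- max(abs(evaluate_field(fld, q) - coloc_score_exact(q, ref, kp)))
    expect_lt(err, 0.01 * max(fld$values))
  }
})

test_that("field construction honors its contracts", {
  kp <- kernel_params(sd = 100)
  expect_error(create_field(rbind(c(0, 0)), kp, grid_spacing = 30),
               "sd/4")
  # empty reference -> all-zero field
  f0 <- create_field(matrix(numeric(0), 0, 2), kp)
  expect_true(all(f0$values == 0))
  # single reference: the node nearest the centroid dominates (the
  # grid is anchored on the reference bbox, so a node lands on it)
  f1 <- create_field(rbind(c(57, 43)), kp)
  peak <- which(f1$values == max(f1$values), arr.ind = TRUE)
  expect_equal(f1$x[peak[1]], 57)
  expect_equal(f1$y[peak[2]], 43)
  expect_equal(max(f1$values), 1)
  # grid nodes evaluate to their stored values; outside the box -> 0
  expect_equal(evaluate_field(f1, cbind(f1$x[3], f1$y[4])),
               f1$values[3, 4])
  expect_equal(evaluate_field(f1, cbind(1e6, 1e6)), 0)
})

test_that("the colocalization matrix is directional and order invariant", {
  kp <- kernel_params(sd = 100)
  cells <- data.frame(
    cell_id = paste0("c", 1:4),
    x_px = c(100, -100, 0, 0), y_px = c(0, 0, 100, 0),
    cell_type = c("A", "A", "A", "B"))
  ds <- spatial_dataset(cells)
  cm <- colocalization_matrix(ds, kp)
  # three A cells each at distance sigma from the single B cell
  expect_equal(cm$raw["A", "B"], exp(-0.5), tolerance = 1e-12)
  expect_equal(cm$raw["B", "A"], 3 * exp(-0.5), tolerance = 1e-12)
  expect_equal(cm$raw["B", "A"] / cm$raw["A", "B"], 3, tolerance = 1e-12)
  # permuting cell order leaves the matrix unchanged
  perm <- c(3, 1, 4, 2)
  ds_p <- spatial_dataset(cells[perm, ], NULL)
  expect_equal(colocalization_matrix(ds_p, kp)$raw, cm$raw, tolerance = 1e-12)
  # coincident A and B cells all score 1.0 everywhere
  co <- spatial_dataset(data.frame(cell_id = c("x", "y"), x_px = 0, y_px = 0,
                                   cell_type = c("A", "B")))
  expect_true(all(colocalization_matrix(co, kp)$raw == 1))
})

test_that("grid mode agrees with exact mode on a labeled section", {
  set.seed(31)
  n <- 120
  cells <- data.frame(cell_id = paste0("c", 1:n),
                      x_px = runif(n, 0, 1500), y_px = runif(n, 0, 1500),
                      cell_type = sample(c("A", "B", "C"), n, replace = TRUE))
  ds <- spatial_dataset(cells)
  kp <- kernel_params(sd = 200)
  exact <- colocalization_matrix(ds, kp, mode = "exact")
  grid <- colocalization_matrix(ds, kp, mode = "grid")
  expect_equal(grid$raw, exact$raw, tolerance = 0.01)
})

test_that("normalization fixes self = 100 and all-cell mean = 0", {
  set.seed(41)
  n <- 200
  cells <- data.frame(cell_id = paste0("c", 1:n),
                      x_px = runif(n, 0, 2000), y_px = runif(n, 0, 2000),
                      cell_type = sample(c("A", "B", "C"), n, replace = TRUE))
  ds <- spatial_dataset(cells)
  cm <- normalize_coloc_matrix(colocalization_matrix(ds, kernel_params(sd = 300)))
  s <- cm$samples[[1]]
  for (R in colnames(s$norm_cell_scores)) {
    expect_lt(abs(mean(s$norm_cell_scores[, R])), 1e-9)
    expect_equal(cm$normalized[R, R], 100, tolerance = 1e-9)
  }
  # the affine formula itself: mean_all 2, mean_self 4, raw 3 -> 50
  expect_equal(100 * (3 - 2) / (4 - 2), 50)
  cnst <- s$norm_constants
  got <- 100 * (3 - cnst$mean_all[1]) / (cnst$mean_self[1] - cnst$mean_all[1])
  expect_true(is.finite(got))
})

test_that("degenerate columns are flagged, not normalized", {
  # one cell of each type at the same spot: mean_self == mean_all everywhere
  ds <- spatial_dataset(data.frame(cell_id = c("a", "b"), x_px = 0, y_px = 0,
                                   cell_type = c("A", "B")))
  expect_warning(cm <- normalize_coloc_matrix(
    colocalization_matrix(ds, kernel_params(sd = 100))), "degenerate")
  expect_setequal(cm$degenerate, c("A", "B"))
})

test_that("hierarchical ordering recovers block structure", {
  m <- rbind(c(10, 10, 0, 0), c(10, 10, 0, 0),
             c(0, 0, 10, 10), c(0, 0, 10, 10)) +
    matrix(c(0.1, 0.2, 0.3, 0.4), 4, 4)
  dimnames(m) <- list(paste0("r", 1:4), paste0("k", 1:4))
  ord <- order_matrix_hclust(m)
  pos <- match(paste0("r", 1:4), ord$row_order)
  expect_true(abs(pos[1] - pos[2]) == 1 && abs(pos[3] - pos[4]) == 1)
  # identical rows merge first at height 0
  m2 <- rbind(a = c(1, 2), b = c(1, 2), c = c(9, 9))
  hc <- order_matrix_hclust(m2)$row_hclust
  expect_equal(hc$height[1], 0)
  # permuting rows yields the same partition
  ord_p <- order_matrix_hclust(m[c(3, 1, 4, 2), ])
  grp <- function(o) paste(sort(o[1:2]), collapse = "") # leading pair
  expect_true(grp(ord_p$row_order) %in% c("r1r2", "r3r4"))
  # single row: trivial ordering
  expect_equal(order_matrix_hclust(m[1, , drop = FALSE])$row_order, "r1")
})
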