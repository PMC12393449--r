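le_fixture <- function() {
  cells <- data.frame(
    cell_id = paste0("c", 1:5),
    x_px = c(0, 100, -100, 0, 2000),
    y_px = c(0, 0, 0, 300, 0),
    cell_type = c("F", "N", "N", "N", "N"))
  counts <- matrix(1L, 5, 1, dimnames = list(cells$cell_id, "G"))
  ds <- spatial_dataset(cells, counts)
  expr <- matrix(c(9, 2, 6, 4, 8), 5, 1,
                 dimnames = list(cells$cell_id, "G"))
  list(ds = ds, expr = expr)
}

test_that("local expression averages neighbors and excludes the focal cell", {
  f <- le_fixture()
  r <- local_expression(f$ds, f$expr, "G", focal_cells = "c1", radius = 400)
  # neighbors of c1 within 400 px: c2 (2), c3 (6), c4 (4); focal c1 excluded
  expect_equal(r$value, mean(c(2, 6, 4)))
  expect_equal(r$n_neighbors, 3)
  # neighbors 2.0 and 6.0 -> 4.0
  r2 <- local_expression(f$ds, f$expr, "G", focal_cells = "c1", radius = 150)
  expect_equal(r2$value, 4)
  # a single neighbor's value passes through
  r1 <- local_expression(f$ds, f$expr, "G", focal_cells = "c4", radius = 310)
  expect_equal(r1$value, 9)
  expect_equal(r1$n_neighbors, 1)
  # no neighbors in radius: NA with count 0
  r3 <- local_expression(f$ds, f$expr, "G", focal_cells = "c5", radius = 100)
  expect_true(is.na(r3$value) && r3$n_neighbors == 0)
  # neighbor-type filter and focal inclusion switch
  r4 <- local_expression(f$ds, f$expr, "G", focal_cells = "c1",
                         radius = 400, include_focal = TRUE)
  expect_equal(r4$value, mean(c(9, 2, 6, 4)))
  expect_error(local_expression(f$ds, f$expr, "NOPE"), "unknown gene")
  r0 <- local_expression(f$ds, f$expr, "G", focal_cells = character(0))
  expect_equal(nrow(r0), 0)
})

test_that("local expression is invariant to cell order and translation", {
  set.seed(8)
  n <- 80
  cells <- data.frame(cell_id = paste0("c", 1:n),
                      x_px = runif(n, 0, 1000), y_px = runif(n, 0, 1000))
  counts <- matrix(rpois(n, 5), n, 1, dimnames = list(cells$cell_id, "G"))
  ds <- spatial_dataset(cells, counts)
  expr <- log_normalize(ds$counts + 1L)
  base <- local_expression(ds, expr, "G", radius = 300)
  perm <- sample(n)
  ds_p <- spatial_dataset(cells[perm, ], counts[perm, , drop = FALSE])
  shuf <- local_expression(ds_p, expr[perm, , drop = FALSE], "G", radius = 300)
  expect_equal(shuf[match(base$cell_id, shuf$cell_id), "value"], base$value)
  cells_t <- cells; cells_t$x_px <- cells_t$x_px + 5000
  ds_t <- spatial_dataset(cells_t, counts)
  expect_equal(local_expression(ds_t, expr, "G", radius = 300)$value,
               base$value)
})

test_that("the smoothed surface is a bounded weighted mean", {
  f <- le_fixture()
  sm <- smooth_expression_map(f$ds, f$expr, "G", sigma = 200)
  v <- sm$values[!is.na(sm$values)]
  expect_true(all(v >= min(f$expr) - 1e-12 & v <= max(f$expr) + 1e-12))
  # constant input -> constant surface on unmasked nodes
  cexpr <- f$expr; cexpr[] <- 3.5
  smc <- smooth_expression_map(f$ds, cexpr, "G", sigma = 200)
  expect_equal(unique(round(smc$values[!is.na(smc$values)], 12)), 3.5)
  # two equidistant cells: midpoint is the simple average
  cells <- data.frame(cell_id = c("a", "b"), x_px = c(-100, 100), y_px = 0)
  ds2 <- spatial_dataset(cells, matrix(1L, 2, 1, dimnames = list(cells$cell_id, "G")))
  e2 <- matrix(c(2, 8), 2, 1, dimnames = list(cells$cell_id, "G"))
  sm2 <- smooth_expression_map(ds2, e2, "G", sigma = 150, grid_spacing = 25)
  mid <- sm2$values[which(sm2$x == 0), which(sm2$y == 0)]
  expect_equal(mid, 5)
  # single cell: surface at its location equals its value
  ds1 <- spatial_dataset(data.frame(cell_id = "a", x_px = 0, y_px = 0),
                         matrix(1L, 1, 1, dimnames = list("a", "G")))
  e1 <- matrix(7, 1, 1, dimnames = list("a", "G"))
  sm1 <- smooth_expression_map(ds1, e1, "G", sigma = 100, grid_spacing = 25)
  expect_equal(sm1$values[1, 1], 7)
})

test_that("contour levels match the quantile/linspace oracle", {
  sm <- structure(list(values = matrix(0:99, 10, 10)), class = "smoothed_map")
  lv <- contour_levels(sm, threshold = 0.9, n_levels = 6)
  expect_length(lv, 6)
  q <- quantile(0:99, 0.9, type = 7, names = FALSE)
  expect_equal(lv, seq(q, 99, length.out = 6))
  # constant surface: all levels equal that constant
  smc <- structure(list(values = matrix(4, 3, 3)), class = "smoothed_map")
  expect_equal(contour_levels(smc), rep(4, 6))
  smna <- structure(list(values = matrix(NA_real_, 2, 2)),
                    class = "smoothed_map")
  expect_error(contour_levels(smna), "masked")
  expect_error(contour_levels(sm, threshold = 1), "threshold")
})

test_that("rolling means shrink their windows at the edges", {
  r <- rolling_mean_by_score(c(1, 2, 3, 4, 5), c(10, 20, 30, 40, 50),
                             window_prop = 3 / 5)
  expect_equal(r$smoothed, c(1.5, 2, 3, 4, 4.5))
  # constant values -> constant curve
  rc <- rolling_mean_by_score(rep(2, 9), 9:1, window_prop = 0.3)
  expect_true(all(rc$smoothed == 2))
  # full window: central value is the global mean, curve near-flat
  v <- c(5, 1, 4, 2, 3)
  rf <- rolling_mean_by_score(v, seq_along(v), window_prop = 1)
  expect_equal(rf$smoothed[3], mean(v))
  expect_equal(nrow(rf), length(v))
  # monotone input gives monotone output
  rm <- rolling_mean_by_score(1:50, 50:1, window_prop = 0.2)
  expect_true(all(diff(rm$smoothed) <= 0 + 1e-12) ||
              all(diff(rm$smoothed) >= 0 - 1e-12))
  expect_equal(nrow(rolling_mean_by_score(numeric(0), numeric(0))), 0)
})
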