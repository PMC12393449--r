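# Fixtures are built in code; nothing is read from disk.

# tiny labeled dataset with hand-placed coordinates
toy_dataset <- function() {
  cells <- data.frame(
    cell_id = paste0("c", 1:6),
    x_px = c(0, 100, 0, 300, 400, 0),
    y_px = c(0, 0, 100, 0, 0, 400),
    cell_type = c("A", "A", "A", "B", "B", "C"),
    stringsAsFactors = FALSE
  )
  counts <- matrix(c(5L, 0L, 2L, 9L, 1L, 4L,
                     0L, 3L, 7L, 1L, 6L, 2L,
                     8L, 2L, 0L, 0L, 3L, 5L),
                   nrow = 6,
                   dimnames = list(cells$cell_id, c("g1", "g2", "g3")))
  spatial_dataset(cells, counts)
}

# random small dataset for round-trip property tests
random_dataset <- function(n = 10, g = 5) {
  cells <- data.frame(
    cell_id = paste0("r", sample.int(1e6, n)),
    x_px = runif(n, 0, 1000),
    y_px = runif(n, 0, 1000),
    sample_id = sample(c("s1", "s2"), n, replace = TRUE),
    cell_type = sample(c("A", "B"), n, replace = TRUE),
    surface_flag = sample(c(TRUE, FALSE), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  counts <- matrix(rpois(n * g, 3), n,
                   dimnames = list(cells$cell_id, paste0("g", seq_len(g))))
  spatial_dataset(cells, counts)
}

# scaled-down skin config (~700 cells) for fast module tests
small_skin_config <- function() {
  cfg <- default_skin_config()
  cfg$width_px <- 3000
  cfg$intensity <- lapply(cfg$intensity, function(v) v * 0.4)
  cfg$aggregates <- lapply(cfg$aggregates[1:2], function(a) {
    a$counts <- ceiling(a$counts * 0.5); a
  })
  cfg$aggregates[[2]]$center <- c(2200, 1400)
  validate_tissue_config(cfg)
  cfg
}
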