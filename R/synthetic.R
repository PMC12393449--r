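# Seeded generator of skin-like seqFISH sections with known ground truth.
#
# The geometry is a vertical section: y = 0 at the keratinized outer
# surface, increasing with depth. Layers (cornified/suprabasal band,
# basal band at the dermal-epidermal junction, papillary dermis,
# reticular dermis) partition [0, height]. Cells are placed by
# homogeneous Poisson processes per layer plus isotropic Gaussian
# immune aggregates; counts follow a negative-binomial model whose
# CD14-myeloid means ride a latent depth-coupled transition t in [0,1]
# (t high = superficial, MMP9-skewed; t low = deep, LYVE1-skewed).

#' Default skin tissue configuration
#'
#' Produces roughly 4,000-5,500 cells in a 6,000 x 9,000 px section
#' (0.1 um/px): a stratified epidermis with a basal band, papillary and
#' reticular dermis, three lymphocyte-rich aggregates beneath the
#' dermal-epidermal junction, a CD14+ myeloid population whose M1/M2
#' marker program follows a latent depth-coupled transition, and
#' fibroblast CCL2/CCL8 expression decaying with distance from the
#' nearest aggregate. Keratinocytes in the outermost band are flagged
#' as surface cells and given a reduced expected library size, so the
#' lenient QC path is exercised.
#'
#' @return A validated `tissue_config` (a list; see
#'   [validate_tissue_config()] for the invariants).
#' @export
default_skin_config <- function() {
  width <- 6000; height <- 9000
  layers <- list(
    epidermis_upper = c(0, 550),
    epidermis_basal = c(550, 700),
    papillary       = c(700, 2700),
    reticular       = c(2700, 9000)
  )
  # expected cell counts per (layer, type); converted to intensities below
  expected <- list(
    epidermis_upper = c(KC_suprabasal = 800),
    epidermis_basal = c(KC_basal = 350),
    papillary = c(FB_proinf = 350, Myeloid_CD14 = 250, T_CD4 = 120,
                  T_CD8 = 80, Endothelial = 150),
    reticular = c(FB_mesenchymal = 1200, Myeloid_CD14 = 350,
                  Endothelial = 350, T_CD4 = 80, T_CD8 = 50)
  )
  intensity <- lapply(names(layers), function(ln) {
    b <- layers[[ln]]
    expected[[ln]] / (width * (b[2] - b[1]))
  })
  names(intensity) <- names(layers)

  aggregates <- list(
    list(center = c(1200, 1500), sd = 300,
         counts = c(T_CD4 = 80, T_CD8 = 40, Myeloid_CD14 = 50, FB_proinf = 30)),
    list(center = c(3200, 1300), sd = 300,
         counts = c(T_CD4 = 80, T_CD8 = 40, Myeloid_CD14 = 50, FB_proinf = 30)),
    list(center = c(5000, 1800), sd = 300,
         counts = c(T_CD4 = 80, T_CD8 = 40, Myeloid_CD14 = 50, FB_proinf = 30))
  )

  housekeeping <- c("ACTB", "GAPDH", "B2M", "RPL13A", "RPS18", "EEF1A1",
                    "TUBB", "HSP90AB1", "PPIA", "YWHAZ", "UBC", "TPT1",
                    "FTL", "FTH1", "RPL10")
  m1 <- c("IL1B", "CXCL9", "CD86", "TNFAIP6")
  m2 <- c("MRC1", "CD163", "F13A1", "STAB1", "FOLR2")
  markers <- list(
    KC_basal       = c(KRT14 = 30, KRT5 = 25, COL17A1 = 10),
    KC_suprabasal  = c(KRT10 = 30, KRT1 = 25, IVL = 10),
    FB_proinf      = c(COL1A1 = 20, PDGFRA = 12, CCL19 = 15, CXCL12 = 10),
    FB_mesenchymal = c(COL1A1 = 25, COL3A1 = 20, PDGFRA = 12, CXCL12 = 6),
    T_CD4          = c(CD3D = 18, CD4 = 12, IL7R = 10, TNF = 6, IFNG = 3),
    T_CD8          = c(CD3D = 18, CD8A = 14, GZMB = 10, TNF = 4, IFNG = 8),
    Myeloid_CD14   = c(CD14 = 18, LYZ = 20, AIF1 = 12),
    Endothelial    = c(PECAM1 = 20, VWF = 16)
  )
  types <- names(markers)
  genes <- unique(c(housekeeping, unlist(lapply(markers, names)),
                    "LYVE1", "MMP9", m1, m2, "CCL2", "CCL8"))
  type_means <- matrix(0, length(types), length(genes),
                       dimnames = list(types, genes))
  type_means[, housekeeping] <- 6
  for (ty in types) type_means[ty, names(markers[[ty]])] <- markers[[ty]]

  list(
    width_px = width, height_px = height,
    um_per_px = 0.1,
    layers = layers,
    intensity = intensity,
    aggregates = aggregates,
    surface_band_px = 250,
    surface_types = c("KC_suprabasal", "KC_basal"),
    surface_lib_factor = 0.35,
    expression = list(
      genes = genes,
      type_means = type_means,
      dispersion = stats::setNames(rep(2, length(types)), types)
    ),
    transition = list(
      type = "Myeloid_CD14", a = 1.1, b = 1.15, sigma_t = 0.07,
      floor = 0.3,
      up = c(stats::setNames(25, "MMP9"), stats::setNames(rep(8, 4), m1)),
      down = c(stats::setNames(25, "LYVE1"), stats::setNames(rep(8, 5), m2))
    ),
    chemokine = list(
      genes = c("CCL2", "CCL8"),
      types = c("FB_proinf", "FB_mesenchymal"),
      floor = 0.3, amplitude = 18, lambda = 600
    )
  )
}

#' Validate a tissue configuration
#'
#' Invariants: positive section dimensions; layer y-intervals partition
#' `[0, height]` contiguously; all intensities, expression means and
#' dispersions nonnegative; aggregate sds positive.
#'
#' @param config A tissue configuration list.
#' @return The config, invisibly, or an error.
#' @export
validate_tissue_config <- function(config) {
  stopifnot(config$width_px > 0, config$height_px > 0)
  b <- do.call(rbind, config$layers)
  b <- b[order(b[, 1]), , drop = FALSE]
  if (b[1, 1] != 0 || b[nrow(b), 2] != config$height_px ||
      (nrow(b) > 1 && any(b[-1, 1] != b[-nrow(b), 2])))
    stop("layers must partition [0, height_px]")
  for (ln in names(config$intensity)) {
    if (!ln %in% names(config$layers)) stop("intensity for unknown layer: ", ln)
    if (any(config$intensity[[ln]] < 0)) stop("negative intensity in layer ", ln)
  }
  if (any(config$expression$type_means < 0)) stop("negative expression mean")
  if (any(config$expression$dispersion < 0)) stop("negative dispersion")
  for (ag in config$aggregates) {
    if (ag$sd <= 0) stop("aggregate sd must be > 0")
    if (any(ag$counts < 0)) stop("negative aggregate count")
  }
  invisible(config)
}

#' Expected number of cells under a configuration
#' @param config A tissue configuration.
#' @return Expected total cell count (Poisson mean).
#' @export
expected_cell_count <- function(config) {
  n <- 0
  for (ln in names(config$intensity)) {
    b <- config$layers[[ln]]
    n <- n + sum(config$intensity[[ln]]) * config$width_px * (b[2] - b[1])
  }
  n + sum(vapply(config$aggregates, function(a) sum(a$counts), numeric(1)))
}

#' Serialize / restore a tissue configuration as JSON
#'
#' @param config A tissue configuration.
#' @param path Output (or input) JSON path.
#' @return `write_tissue_config` returns `path` invisibly;
#'   `read_tissue_config` returns the validated config.
#' @export
write_tissue_config <- function(config, path) {
  cfg <- config
  # named numeric vectors become JSON objects (as.list keeps names)
  cfg$intensity <- lapply(cfg$intensity, as.list)
  cfg$aggregates <- lapply(cfg$aggregates, function(a) {
    a$counts <- as.list(a$counts); a
  })
  tm <- cfg$expression$type_means
  cfg$expression$type_means <- stats::setNames(
    lapply(rownames(tm), function(ty) as.list(tm[ty, ])), rownames(tm))
  cfg$expression$dispersion <- as.list(cfg$expression$dispersion)
  cfg$transition$up <- as.list(cfg$transition$up)
  cfg$transition$down <- as.list(cfg$transition$down)
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_tissue_config
#' @export
read_tissue_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  num <- function(x) as.numeric(unlist(x))
  nvec <- function(x) unlist(lapply(x, as.numeric))  # keeps names
  cfg$width_px <- num(cfg$width_px); cfg$height_px <- num(cfg$height_px)
  cfg$um_per_px <- num(cfg$um_per_px)
  cfg$layers <- lapply(cfg$layers, num)
  cfg$intensity <- lapply(cfg$intensity, nvec)
  cfg$aggregates <- lapply(cfg$aggregates, function(a)
    list(center = num(a$center), sd = num(a$sd), counts = nvec(a$counts)))
  cfg$surface_band_px <- num(cfg$surface_band_px)
  cfg$surface_types <- as.character(unlist(cfg$surface_types))
  cfg$surface_lib_factor <- num(cfg$surface_lib_factor)
  genes <- as.character(unlist(cfg$expression$genes))
  tm <- cfg$expression$type_means
  mat <- do.call(rbind, lapply(tm, function(r) nvec(r)[genes]))
  dimnames(mat) <- list(names(tm), genes)
  cfg$expression <- list(genes = genes, type_means = mat,
                         dispersion = nvec(cfg$expression$dispersion))
  tr <- cfg$transition
  cfg$transition <- list(type = as.character(tr$type), a = num(tr$a),
                         b = num(tr$b), sigma_t = num(tr$sigma_t),
                         floor = num(tr$floor),
                         up = nvec(tr$up), down = nvec(tr$down))
  ck <- cfg$chemokine
  cfg$chemokine <- list(genes = as.character(unlist(ck$genes)),
                        types = as.character(unlist(ck$types)),
                        floor = num(ck$floor), amplitude = num(ck$amplitude),
                        lambda = num(ck$lambda))
  validate_tissue_config(cfg)
  cfg
}

#' Generate a synthetic skin section
#'
#' Draws cell positions from per-layer homogeneous Poisson processes
#' plus Gaussian immune aggregates, assigns the latent CD14 transition
#' parameter t = clamp(a - b * depth + eps) with depth = y/height and
#' eps ~ N(0, sigma_t^2), and samples counts from the negative-binomial
#' expression model. Identical (config, seed) pairs give identical
#' output.
#'
#' @param config A tissue configuration (see [default_skin_config()]).
#' @param seed Integer seed.
#' @return A list with `dataset` (a [spatial_dataset()]) and
#'   `ground_truth`: a data.frame (cell_id, cell_type, t, depth_px,
#'   aggregate_id, d_agg_px; t and aggregate_id are NA outside the
#'   transition type) plus the generating mean matrix as attribute
#'   `"type_means"`.
#' @export
generate_tissue <- function(config, seed = 1L) {
  validate_tissue_config(config)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")

  xs <- ys <- numeric(0); types <- character(0); agg_id <- integer(0)
  for (ln in names(config$intensity)) {
    b <- config$layers[[ln]]
    h <- b[2] - b[1]
    for (ty in names(config$intensity[[ln]])) {
      if (config$intensity[[ln]][[ty]] > 0 && h <= 0)
        stop("degenerate layer ", ln, " has positive intensity for ", ty)
      lam <- config$intensity[[ln]][[ty]] * config$width_px * h
      n <- stats::rpois(1, lam)
      if (n > 0) {
        xs <- c(xs, stats::runif(n, 0, config$width_px))
        ys <- c(ys, stats::runif(n, b[1], b[2]))
        types <- c(types, rep(ty, n))
        agg_id <- c(agg_id, rep(NA_integer_, n))
      }
    }
  }
  for (ai in seq_along(config$aggregates)) {
    ag <- config$aggregates[[ai]]
    for (ty in names(ag$counts)) {
      n <- stats::rpois(1, ag$counts[[ty]])
      if (n > 0) {
        xs <- c(xs, pmin(pmax(stats::rnorm(n, ag$center[1], ag$sd), 0),
                         config$width_px))
        ys <- c(ys, pmin(pmax(stats::rnorm(n, ag$center[2], ag$sd), 0),
                         config$height_px))
        types <- c(types, rep(ty, n))
        agg_id <- c(agg_id, rep(ai, n))
      }
    }
  }
  n <- length(xs)
  cells <- data.frame(
    cell_id = sprintf("c%06d", seq_len(n)),
    x_px = xs, y_px = ys,
    sample_id = rep("synthetic", n), section_id = rep("s1", n),
    cell_type = types,
    surface_flag = types %in% config$surface_types & ys < config$surface_band_px,
    total_transcripts = rep(NA_integer_, n),
    stringsAsFactors = FALSE
  )

  # latent transition for the designated type
  tr <- config$transition
  tt <- rep(NA_real_, n)
  is_tr <- types == tr$type
  if (any(is_tr)) {
    depth <- ys[is_tr] / config$height_px
    tt[is_tr] <- pmin(pmax(tr$a - tr$b * depth +
                             stats::rnorm(sum(is_tr), 0, tr$sigma_t), 0), 1)
  }

  # distance to nearest aggregate center (for the chemokine gradient)
  d_agg <- rep(Inf, n); near_agg <- rep(NA_integer_, n)
  if (length(config$aggregates)) {
    ctr <- do.call(rbind, lapply(config$aggregates, `[[`, "center"))
    d2 <- outer(xs^2 + ys^2, rowSums(ctr^2), `+`) -
      2 * cbind(xs, ys) %*% t(ctr)
    d2[d2 < 0] <- 0
    near_agg <- max.col(-d2)
    d_agg <- sqrt(d2[cbind(seq_len(n), near_agg)])
  }

  counts <- generate_counts(
    data.frame(cell_type = types, t = tt, d_agg_px = d_agg,
               surface_flag = cells$surface_flag, stringsAsFactors = FALSE),
    config, seed = NULL)
  rownames(counts) <- cells$cell_id

  dataset <- spatial_dataset(cells, counts, um_per_px = config$um_per_px)
  gt <- data.frame(
    cell_id = cells$cell_id, cell_type = types,
    t = tt, depth_px = ys,
    aggregate_id = if (n) ifelse(is_tr, near_agg, NA_integer_) else integer(0),
    d_agg_px = if (n) d_agg else numeric(0), stringsAsFactors = FALSE
  )
  attr(gt, "type_means") <- config$expression$type_means
  list(dataset = dataset, ground_truth = gt)
}

#' Sample counts from the negative-binomial expression model
#'
#' Per-cell per-gene means start from the configured type baseline and
#' are modified by (i) the transition response, linear in t for the
#' `up` genes and in (1 - t) for the `down` genes of the transition
#' type, (ii) the fibroblast chemokine gradient
#' `floor + amplitude * exp(-d_agg^2 / (2 lambda^2))`, and (iii) the
#' surface library-size factor. Counts are NB(mu, size = dispersion);
#' infinite dispersion degenerates to Poisson.
#'
#' @param cells data.frame with `cell_type` and optional `t`,
#'   `d_agg_px`, `surface_flag`.
#' @param config A tissue configuration (its `expression`, `transition`,
#'   `chemokine`, surface fields are used).
#' @param seed Integer seed, or NULL to use the current RNG state.
#' @return A cells x genes sparse integer matrix.
#' @export
generate_counts <- function(cells, config, seed = 1L) {
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
             sample.kind = "Rejection")
  }
  ex <- config$expression
  unknown <- setdiff(unique(cells$cell_type), rownames(ex$type_means))
  if (length(unknown)) stop("unknown cell type(s): ",
                            paste(unknown, collapse = ", "))
  n <- nrow(cells); genes <- ex$genes
  mu <- ex$type_means[cells$cell_type, , drop = FALSE]
  rownames(mu) <- NULL

  tr <- config$transition
  if (!is.null(tr) && !is.null(cells$t)) {
    i <- which(cells$cell_type == tr$type & !is.na(cells$t))
    if (length(i)) {
      for (g in names(tr$up))
        mu[i, g] <- tr$up[[g]] * cells$t[i] + tr$floor
      for (g in names(tr$down))
        mu[i, g] <- tr$down[[g]] * (1 - cells$t[i]) + tr$floor
    }
  }
  ck <- config$chemokine
  if (!is.null(ck) && !is.null(cells$d_agg_px)) {
    i <- which(cells$cell_type %in% ck$types & is.finite(cells$d_agg_px))
    if (length(i)) {
      w <- exp(-cells$d_agg_px[i]^2 / (2 * ck$lambda^2))
      for (g in ck$genes) mu[i, g] <- ck$floor + ck$amplitude * w
    }
  }
  if (!is.null(cells$surface_flag) && !is.null(config$surface_lib_factor)) {
    i <- which(cells$surface_flag %in% TRUE)
    if (length(i)) mu[i, ] <- mu[i, ] * config$surface_lib_factor
  }

  size <- ex$dispersion[cells$cell_type]
  counts <- matrix(0L, n, length(genes), dimnames = list(NULL, genes))
  for (j in seq_along(genes)) {
    m <- mu[, j]
    pois <- !is.finite(size)
    v <- integer(n)
    if (any(pois)) v[pois] <- stats::rpois(sum(pois), m[pois])
    if (any(!pois)) v[!pois] <- stats::rnbinom(sum(!pois), mu = m[!pois],
                                               size = size[!pois])
    counts[, j] <- v
  }
  as_dgc(counts)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
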