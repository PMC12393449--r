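#' Run the full spatial analysis pipeline
#'
#' Config-driven orchestration of all stages: obtain data (generate a
#' synthetic section or read a written dataset), QC-filter,
#' log-normalize, compute and normalize the directional colocalization
#' matrix with hierarchical ordering, order the myeloid transition and
#' bin expression along it, compute local expression and a smoothed
#' expression map, and distance-to-structure tables. Every stage logs
#' its parameters and row counts; identical (config, seed) pairs give
#' identical outputs. The transition stage is skipped with a logged
#' reason when the transition cell type is absent.
#'
#' @param config A run configuration list (see [default_run_config()]),
#'   or a path to a YAML/JSON file of one.
#' @param out_dir Output directory; created if needed. When NULL,
#'   nothing is written and the results are only returned.
#' @return Invisibly, list(report, results); `report` is also written
#'   as `report.json` when `out_dir` is given.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  seed <- config$seed %||% 1L
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
    message(msg)
    log_lines <<- c(log_lines, msg)
  }
  stages <- list()
  results <- list()
  run_stage <- function(name, f) {
    t0 <- proc.time()[["elapsed"]]
    r <- tryCatch(f(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    # wall time goes to the log only, so report.json is seed-deterministic
    say("stage %s: %.3f s", name, proc.time()[["elapsed"]] - t0)
    stages[[name]] <<- list(completed = TRUE)
    r
  }

  # --- data ---------------------------------------------------------
  if (!is.null(config$input_dir) && !is.null(config$tissue))
    stop("config must set exactly one of input_dir / tissue")
  gt <- NULL
  ds <- run_stage("data", function() {
    if (!is.null(config$input_dir)) {
      say("reading dataset from %s", config$input_dir)
      read_dataset(config$input_dir)
    } else {
      tc <- config$tissue %||% default_skin_config()
      say("generating synthetic tissue (seed %d)", seed)
      g <- generate_tissue(tc, seed = seed)
      gt <<- g$ground_truth
      g$dataset
    }
  })
  say("data: %d cells, %d genes", nrow(ds$cells), ncol(ds$counts))

  # --- qc + normalization ------------------------------------------
  qc_cfg <- config$qc %||% list()
  ds_qc <- run_stage("qc", function()
    qc_filter(ds, qc_cfg$min_transcripts %||% 50L,
              qc_cfg$surface_min %||% 10L))
  qcr <- attr(ds_qc, "qc_report")
  say("qc: kept %d / %d cells (removed %d standard, %d surface)",
      qcr$n_kept, qcr$n_in, qcr$n_removed_standard, qcr$n_removed_surface)
  expr <- run_stage("normalize", function()
    log_normalize(ds_qc, config$scale_total %||% 1e4))

  # --- colocalization ----------------------------------------------
  kp <- do.call(kernel_params, config$kernel %||% list())
  cm <- run_stage("colocalization", function() {
    m <- colocalization_matrix(ds_qc, kp,
                               mode = config$coloc_mode %||% "exact")
    normalize_coloc_matrix(m)
  })
  ord <- order_matrix_hclust(cm$normalized)
  say("colocalization: %d x %d normalized matrix", nrow(cm$normalized),
      ncol(cm$normalized))
  results$coloc <- cm
  results$coloc_order <- ord

  # --- transition ---------------------------------------------------
  tr_cfg <- config$transition %||% list()
  tr_type <- tr_cfg$cell_type %||% "Myeloid_CD14"
  n_tr <- sum(ds_qc$cells$cell_type == tr_type)
  if (n_tr >= max(10L, (tr_cfg$n_pcs %||% 5L) + 1L)) {
    ordering <- run_stage("transition", function()
      transition_ordering(ds_qc, tr_type,
                          n_var_genes = tr_cfg$n_var_genes %||% 100L,
                          n_pcs = tr_cfg$n_pcs %||% 5L,
                          k = tr_cfg$k %||% 200L,
                          anchor_up = tr_cfg$anchor_up %||% "MMP9",
                          anchor_down = tr_cfg$anchor_down %||% "LYVE1",
                          n_bins = tr_cfg$n_bins %||% 30L))
    say("transition: ordered %d %s cells", nrow(ordering), tr_type)
    results$transition <- ordering
    results$transition_bins <- bin_aggregate(
      ordering, attr(ordering, "expr"),
      n_bins = min(tr_cfg$n_bins %||% 30L, nrow(ordering)))
  } else {
    say("transition: skipped (%d cells of type %s; need >= %d)",
        n_tr, tr_type, max(10L, (tr_cfg$n_pcs %||% 5L) + 1L))
    stages$transition <- list(skipped = TRUE,
                              reason = sprintf("only %d cells of type %s",
                                               n_tr, tr_type))
  }

  # --- spatial expression ------------------------------------------
  le_cfg <- config$local_expression %||% list()
  le_gene <- le_cfg$gene %||% "TNF"
  if (le_gene %in% colnames(expr)) {
    focal <- if (is.null(le_cfg$focal_type)) NULL else
      ds_qc$cells$cell_id[ds_qc$cells$cell_type == le_cfg$focal_type]
    results$local_expression <- run_stage("local_expression", function()
      local_expression(ds_qc, expr, le_gene, focal_cells = focal,
                       radius = le_cfg$radius %||% 400))
    say("local expression of %s around %d focal cells", le_gene,
        nrow(results$local_expression))
    results$smoothed_map <- run_stage("smooth_map", function()
      smooth_expression_map(ds_qc, expr, le_gene,
                            sigma = le_cfg$sigma %||% 400))
    results$contours <- contour_levels(results$smoothed_map,
                                       le_cfg$threshold %||% 0.9,
                                       le_cfg$n_levels %||% 6L)
  }

  # --- distances ----------------------------------------------------
  di_cfg <- config$distances %||% list()
  focal_type <- di_cfg$focal_type %||% tr_type
  tgts <- di_cfg$targets %||%
    list(epidermis = "KC_basal", lymphocytes = c("T_CD4", "T_CD8"))
  have <- unique(ds_qc$cells$cell_type)
  if (focal_type %in% have) {
    dtabs <- list()
    for (nm in names(tgts)) {
      if (!any(tgts[[nm]] %in% have)) next
      dtabs[[nm]] <- run_stage(paste0("distance_", nm), function()
        min_distance_to_type(ds_qc, focal_type, intersect(tgts[[nm]], have),
                             name = nm))
    }
    if (length(dtabs)) {
      dt <- Reduce(function(a, b) merge(a, b, by = c("cell_id", "depth_px")),
                   dtabs)
      results$distances <- dt
      if (!is.null(results$transition))
        results$transition_distance <- transition_distance_table(
          results$transition, dt, di_cfg$window_prop %||% 0.1)
    }
  }
  results$depth_profile <- run_stage("depth_profile", function()
    depth_profile(ds_qc))

  # --- report -------------------------------------------------------
  report <- list(
    schema_version = "1.0",
    seed = seed,
    n_cells_in = nrow(ds$cells),
    qc = qcr,
    n_genes = ncol(ds$counts),
    coloc = list(sd = kp$sd, truncation_radius = kp$truncation_radius,
                 types = rownames(cm$normalized),
                 degenerate_columns = cm$degenerate),
    transition = if (!is.null(results$transition)) list(
      n_cells = nrow(results$transition),
      sign = attr(results$transition, "sign"),
      bin_sizes = results$transition_bins$sizes
    ) else stages$transition,
    stages = stages
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_dataset(ds_qc, file.path(out_dir, "dataset"))
    utils::write.table(
      data.frame(round(cm$normalized, 10)) , file.path(out_dir, "coloc_normalized.tsv"),
      sep = "\t", quote = FALSE, col.names = NA)
    if (!is.null(results$transition))
      utils::write.table(as.data.frame(results$transition),
                         file.path(out_dir, "transition.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(results$distances))
      utils::write.table(results$distances,
                         file.path(out_dir, "distances.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(gt)) {
      utils::write.table(gt, file.path(out_dir, "ground_truth.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  if (!is.null(gt)) results$ground_truth <- gt
  invisible(list(report = report, results = results))
}

#' Default run configuration
#'
#' Synthetic-data demo configuration: the default skin tissue, the
#' standard QC thresholds (50 / 10), sd = 400 px kernels, the 100
#' variable-gene / 5 PC / k = 200 transition chain with 30 bins, and
#' distance targets for the epidermis (basal keratinocytes) and
#' lymphocyte aggregates (CD4/CD8 T cells).
#'
#' @param seed Integer seed (default 1).
#' @return A run-config list accepted by [run_pipeline()].
#' @export
default_run_config <- function(seed = 1L) {
  list(seed = as.integer(seed), tissue = NULL, input_dir = NULL,
       qc = list(min_transcripts = 50L, surface_min = 10L),
       scale_total = 1e4,
       kernel = list(sd = 400),
       transition = list(cell_type = "Myeloid_CD14", n_var_genes = 100L,
                         n_pcs = 5L, k = 200L, n_bins = 30L,
                         anchor_up = "MMP9", anchor_down = "LYVE1"),
       local_expression = list(gene = "TNF", focal_type = "Myeloid_CD14",
                               radius = 400, sigma = 400,
                               threshold = 0.9, n_levels = 6L),
       distances = list(focal_type = "Myeloid_CD14",
                        targets = list(epidermis = "KC_basal",
                                       lymphocytes = c("T_CD4", "T_CD8")),
                        window_prop = 0.1))
}

#' Read a run configuration from YAML or JSON
#' @param path Path to a `.yaml`/`.yml` or `.json` run config.
#' @return The configuration list, merged over the defaults.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  base <- default_run_config()
  utils::modifyList(base, cfg)
}
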