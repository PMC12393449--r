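#' Read a cell table from a delimited text file
#'
#' Expects a header naming at least `cell_id`, `x_px`, `y_px`; optional
#' columns (`sample_id`, `section_id`, `cell_type`, `surface_flag`,
#' `total_transcripts`) are validated when present and defaulted when
#' absent. Unknown columns are preserved.
#'
#' @param path Path to the file.
#' @param sep Field delimiter (default tab).
#' @return A validated cell table (data.frame).
#' @export
read_cell_table <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = c(cell_id = "character"),
                          quote = "", comment.char = "")
  validate_cell_table(df)
}

#' Read a gene count matrix
#'
#' Two on-disk layouts are supported: Matrix Market coordinate format
#' (`format = "mtx"`, cells x genes) with a companion plain-text gene
#' name file, and a dense delimited table (`format = "dense"`) whose
#' first column holds cell ids and whose header holds gene symbols.
#'
#' @param path Path to the `.mtx` or dense table.
#' @param format `"mtx"` or `"dense"`.
#' @param genes_path For `"mtx"`: path to the one-gene-per-line file
#'   (default `<path minus .mtx>_genes.txt`).
#' @param cell_ids For `"mtx"`: character vector of cell ids aligned to
#'   matrix rows (usually from the cell table of the same directory).
#' @return A cells x genes sparse integer matrix (`dgCMatrix`).
#' @export
read_count_matrix <- function(path, format = c("mtx", "dense"),
                              genes_path = NULL, cell_ids = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "mtx") {
    m <- as_dgc(Matrix::readMM(path))  # symmetric MTX files expand here
    if (length(m@x) && any(m@x < 0)) stop("negative entry in count matrix")
    if (is.null(genes_path)) genes_path <- sub("\\.mtx$", "_genes.txt", path)
    if (!file.exists(genes_path)) stop("gene name file not found: ", genes_path)
    genes <- readLines(genes_path)
    if (length(genes) != ncol(m))
      stop("gene file has ", length(genes), " names for ", ncol(m), " columns")
    colnames(m) <- genes
    if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(nrow(m)))
    if (length(cell_ids) != nrow(m))
      stop("cell_id mismatch: ", nrow(m), " matrix rows vs ",
           length(cell_ids), " ids; first offenders: ",
           paste(utils::head(cell_ids, 5), collapse = ", "))
    rownames(m) <- cell_ids
    validate_count_matrix(m, cell_ids)
  } else {
    df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                            stringsAsFactors = FALSE, check.names = FALSE)
    m <- as.matrix(df)
    if (length(m) && any(m < 0)) stop("negative entry in count matrix")
    validate_count_matrix(m, rownames(df))
  }
}

#' Write a spatial dataset to a directory
#'
#' Emits four files: `cells.tsv` (cell table; its row order defines the
#' count-matrix row order), `counts.mtx` (Matrix Market), `genes.txt`
#' (one symbol per line) and `params.json` (pixel scale and shape).
#' Returns a manifest data.frame listing every file with an MD5
#' checksum; writing the same dataset twice yields identical checksums.
#'
#' @param dataset A `spatial_dataset`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest (also written as `manifest.json`).
#' @export
write_dataset <- function(dataset, out_dir) {
  stopifnot(inherits(dataset, "spatial_dataset"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)

  cells_path <- file.path(out_dir, "cells.tsv")
  cells_out <- dataset$cells
  for (cc in names(cells_out)) {           # %.17g round-trips doubles exactly
    if (is.double(cells_out[[cc]]))
      cells_out[[cc]] <- ifelse(is.na(cells_out[[cc]]), NA,
                                sprintf("%.17g", cells_out[[cc]]))
  }
  utils::write.table(cells_out, cells_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  counts <- dataset$counts
  if (is.null(counts)) {
    counts <- Matrix::Matrix(0, nrow(dataset$cells), 0, sparse = TRUE)
    colnames(counts) <- character(0)
  }
  mtx_path <- file.path(out_dir, "counts.mtx")
  # triplet form writes a "general" header even for symmetric values
  Matrix::writeMM(methods::as(counts, "TsparseMatrix"), mtx_path)
  genes_path <- file.path(out_dir, "genes.txt")
  writeLines(as.character(colnames(counts) %||% character(0)), genes_path)
  params_path <- file.path(out_dir, "params.json")
  jsonlite::write_json(
    list(um_per_px = dataset$um_per_px,
         n_cells = nrow(dataset$cells), n_genes = ncol(counts)),
    params_path, auto_unbox = TRUE, digits = NA)

  files <- c(cells_path, mtx_path, genes_path, params_path)
  manifest <- data.frame(
    file = basename(files),
    md5 = unname(tools::md5sum(files)),
    stringsAsFactors = FALSE
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  invisible(manifest)
}

#' Read a spatial dataset written by [write_dataset()]
#'
#' @param dir Directory containing `cells.tsv`, `counts.mtx`,
#'   `genes.txt`, `params.json`.
#' @return A `spatial_dataset`.
#' @export
read_dataset <- function(dir) {
  cells <- read_cell_table(file.path(dir, "cells.tsv"))
  params <- jsonlite::read_json(file.path(dir, "params.json"))
  counts <- read_count_matrix(file.path(dir, "counts.mtx"), "mtx",
                              genes_path = file.path(dir, "genes.txt"),
                              cell_ids = cells$cell_id)
  if (ncol(counts) == 0) counts <- NULL
  spatial_dataset(cells, counts, um_per_px = params$um_per_px)
}
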