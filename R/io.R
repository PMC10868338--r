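#' Read a single-cell dataset from disk
#'
#' Unified reader over the common interchange formats. Whatever the on-disk
#' orientation, the returned matrix has cells as rows: Matrix Market triplet
#' directories and 10x-style HDF5, which store features x cells, are
#' transposed on read.
#'
#' Formats:
#' \describe{
#'   \item{`mtx_dir`}{a directory holding `matrix.mtx` (features x cells),
#'     `features.tsv` (or `genes.tsv`) and `barcodes.tsv`.}
#'   \item{`csv`}{dense comma-separated table, first row feature names, first
#'     column cell names.}
#'   \item{`tenx_h5`}{HDF5 with one group containing `data`/`indices`/
#'     `indptr`/`shape` (CSC, cells in columns) plus feature and barcode name
#'     arrays.}
#'   \item{`h5ad`}{the annotated-matrix HDF5 dialect written by
#'     [write_dataset()]: `/X` dense cells x features plus `obs`, `var`,
#'     `obsm/spatial` and `uns` groups.}
#' }
#'
#' @param path file or directory path.
#' @param format one of `"mtx_dir"`, `"csv"`, `"tenx_h5"`, `"h5ad"`.
#' @return an `omics_dataset` (layer_state `counts` unless the h5ad file
#'   records otherwise).
#' @export
read_dataset <- function(path, format = c("mtx_dir", "csv", "tenx_h5", "h5ad")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop(sprintf("path does not exist: %s", path), call. = FALSE)
  }
  switch(format,
    mtx_dir = read_mtx_dir(path),
    csv = read_csv_dataset(path),
    tenx_h5 = read_tenx_h5(path),
    h5ad = read_h5ad_dialect(path)
  )
}

read_mtx_dir <- function(path) {
  mtx <- file.path(path, "matrix.mtx")
  if (!file.exists(mtx)) stop("matrix.mtx not found in ", path, call. = FALSE)
  feat_file <- file.path(path, "features.tsv")
  if (!file.exists(feat_file)) feat_file <- file.path(path, "genes.tsv")
  bc_file <- file.path(path, "barcodes.tsv")
  m <- Matrix::readMM(mtx) # features x cells on disk
  features <- utils::read.delim(feat_file, header = FALSE,
                                stringsAsFactors = FALSE)[[1]]
  barcodes <- utils::read.delim(bc_file, header = FALSE,
                                stringsAsFactors = FALSE)[[1]]
  if (nrow(m) != length(features) || ncol(m) != length(barcodes)) {
    stop(sprintf(
      "format error: matrix is %d features x %d cells but name files have %d features and %d barcodes",
      nrow(m), ncol(m), length(features), length(barcodes)
    ), call. = FALSE)
  }
  counts <- t(as.matrix(m)) # -> cells x features
  if (min(counts) < 0) {
    stop("validation error: negative entries in matrix", call. = FALSE)
  }
  omics_dataset(counts, obs_names = barcodes, var_names = features)
}

read_csv_dataset <- function(path) {
  df <- utils::read.csv(path, header = TRUE, row.names = 1,
                        check.names = FALSE)
  counts <- as.matrix(df)
  if (!is.numeric(counts)) {
    stop("format error: non-numeric values in CSV matrix", call. = FALSE)
  }
  if (nrow(counts) > 0 && min(counts) < 0) {
    stop("validation error: negative entries in matrix", call. = FALSE)
  }
  omics_dataset(counts, obs_names = rownames(df), var_names = colnames(df))
}

read_tenx_h5 <- function(path) {
  top <- rhdf5::h5ls(path, recursive = FALSE)
  group <- top$name[top$otype == "H5I_GROUP"][1]
  if (is.na(group)) stop("format error: no group in HDF5 file", call. = FALSE)
  g <- function(x) paste0("/", group, "/", x)
  shape <- as.integer(rhdf5::h5read(path, g("shape")))
  data <- as.numeric(rhdf5::h5read(path, g("data")))
  indices <- as.integer(rhdf5::h5read(path, g("indices")))
  indptr <- as.integer(rhdf5::h5read(path, g("indptr")))
  contents <- rhdf5::h5ls(path)$name
  feat_path <- if ("features" %in% contents) g("features/name") else g("genes")
  features <- as.character(rhdf5::h5read(path, feat_path))
  barcodes <- as.character(rhdf5::h5read(path, g("barcodes")))
  m <- Matrix::sparseMatrix(
    i = indices + 1L, p = indptr, x = data,
    dims = shape, repr = "C"
  ) # features x cells (CSC, cells in columns)
  if (shape[1] != length(features) || shape[2] != length(barcodes)) {
    stop(sprintf(
      "format error: shape %d x %d does not match %d feature and %d barcode names",
      shape[1], shape[2], length(features), length(barcodes)
    ), call. = FALSE)
  }
  counts <- t(as.matrix(m))
  if (length(counts) && min(counts) < 0) {
    stop("validation error: negative entries in matrix", call. = FALSE)
  }
  omics_dataset(counts, obs_names = barcodes, var_names = features)
}

read_h5ad_dialect <- function(path) {
  # /X stored features x cells so that h5 column-major layout round-trips
  # the R cells x features matrix bit-exactly
  X <- rhdf5::h5read(path, "/X")
  obs_names <- as.character(rhdf5::h5read(path, "/obs/_index"))
  var_names <- as.character(rhdf5::h5read(path, "/var/_index"))
  batch <- as.character(rhdf5::h5read(path, "/obs/batch"))
  batch_levels <- as.character(rhdf5::h5read(path, "/uns/batch_levels"))
  layer_state <- as.character(rhdf5::h5read(path, "/uns/layer_state"))
  modality <- as.character(rhdf5::h5read(path, "/uns/modality"))
  contents <- rhdf5::h5ls(path)
  full <- paste0(ifelse(contents$group == "/", "", contents$group),
                 "/", contents$name)
  coords <- NULL
  if ("/obsm/spatial" %in% full) {
    coords <- t(rhdf5::h5read(path, "/obsm/spatial"))
  }
  counts <- t(X)
  omics_dataset(
    counts,
    obs_names = obs_names, var_names = var_names,
    batch = factor(batch, levels = batch_levels),
    modality = modality, coords = coords, layer_state = layer_state
  )
}

#' Write a dataset to disk
#'
#' Writers for the two interchange formats this package emits: the
#' annotated-matrix HDF5 dialect (`h5ad`, lossless: doubles round-trip
#' bit-exactly) and dense CSV (matrix only; names in header/rownames).
#'
#' @param ds an `omics_dataset`.
#' @param path output file path (overwritten if present).
#' @param format `"h5ad"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path, format = c("h5ad", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(ds, "omics_dataset"))
  if (format == "csv") {
    df <- as.data.frame(ds$counts)
    rownames(df) <- ds$obs_names
    colnames(df) <- ds$var_names
    utils::write.csv(df, path, quote = FALSE)
    return(invisible(path))
  }
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(t(ds$counts), path, "/X")
  rhdf5::h5createGroup(path, "obs")
  rhdf5::h5createGroup(path, "var")
  rhdf5::h5createGroup(path, "uns")
  rhdf5::h5write(ds$obs_names, path, "/obs/_index")
  rhdf5::h5write(as.character(ds$batch), path, "/obs/batch")
  rhdf5::h5write(ds$var_names, path, "/var/_index")
  rhdf5::h5write(levels(ds$batch), path, "/uns/batch_levels")
  rhdf5::h5write(ds$layer_state, path, "/uns/layer_state")
  rhdf5::h5write(ds$modality, path, "/uns/modality")
  if (!is.null(ds$coords)) {
    rhdf5::h5createGroup(path, "obsm")
    rhdf5::h5write(t(ds$coords), path, "/obsm/spatial")
  }
  rhdf5::h5closeAll()
  invisible(path)
}
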