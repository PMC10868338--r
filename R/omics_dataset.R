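#' Annotated cell-by-feature matrix
#'
#' `omics_dataset()` constructs the container shared by every model in the
#' package: a cells x features matrix with per-cell batch labels, a modality
#' tag, optional 2-D spatial coordinates and open metadata tables. Cells are
#' always rows, whatever the on-disk orientation of the source file.
#'
#' @param counts numeric matrix, cells x features. Non-negative when
#'   `layer_state == "counts"`.
#' @param obs_names character vector of unique cell/spot identifiers. Defaults
#'   to rownames of `counts` or `cell_1..n`.
#' @param var_names character vector of unique feature identifiers. Defaults
#'   to colnames of `counts` or `gene_1..p`.
#' @param batch per-cell batch annotation (coerced to factor with at least one
#'   level). Defaults to a single batch `"0"`.
#' @param modality one of `"rna"`, `"atac"`, `"protein"`, `"spatial"`.
#' @param coords optional cells x 2 numeric matrix of spatial coordinates.
#' @param layer_state `"counts"` (raw) or `"lognorm"` (normalized + log1p).
#' @param obs_meta,var_meta optional data.frames of per-cell / per-feature
#'   annotations.
#' @return An object of class `omics_dataset`.
#' @export
omics_dataset <- function(counts,
                          obs_names = NULL,
                          var_names = NULL,
                          batch = NULL,
                          modality = c("rna", "atac", "protein", "spatial"),
                          coords = NULL,
                          layer_state = c("counts", "lognorm"),
                          obs_meta = NULL,
                          var_meta = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  modality <- match.arg(modality)
  layer_state <- match.arg(layer_state)

  if (is.null(obs_names)) {
    obs_names <- rownames(counts)
    if (is.null(obs_names)) obs_names <- paste0("cell_", seq_len(nrow(counts)))
  }
  if (is.null(var_names)) {
    var_names <- colnames(counts)
    if (is.null(var_names)) var_names <- paste0("gene_", seq_len(ncol(counts)))
  }
  obs_names <- as.character(obs_names)
  var_names <- as.character(var_names)

  if (is.null(batch)) batch <- rep("0", nrow(counts))
  batch <- as.factor(batch)

  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    storage.mode(coords) <- "double"
  }

  ds <- structure(
    list(
      counts = counts,
      obs_names = obs_names,
      var_names = var_names,
      batch = batch,
      modality = modality,
      coords = coords,
      layer_state = layer_state,
      obs_meta = obs_meta,
      var_meta = var_meta
    ),
    class = "omics_dataset"
  )
  validate_omics_dataset(ds)
  ds
}

#' Validate an omics_dataset
#'
#' Checks the container invariants: name lengths match matrix dimensions,
#' names are unique, counts are non-negative in the `counts` layer, every cell
#' carries a batch label, and coordinates (if present) are a complete cells x 2
#' matrix.
#'
#' @param ds an `omics_dataset`.
#' @return `ds`, invisibly; errors describe the violated invariant.
#' @export
validate_omics_dataset <- function(ds) {
  if (nrow(ds$counts) != length(ds$obs_names)) {
    stop(sprintf(
      "dimension mismatch: matrix has %d rows but %d observation names",
      nrow(ds$counts), length(ds$obs_names)
    ), call. = FALSE)
  }
  if (ncol(ds$counts) != length(ds$var_names)) {
    stop(sprintf(
      "dimension mismatch: matrix has %d columns but %d feature names",
      ncol(ds$counts), length(ds$var_names)
    ), call. = FALSE)
  }
  if (anyDuplicated(ds$obs_names)) {
    stop("validation error: duplicate observation names", call. = FALSE)
  }
  if (anyDuplicated(ds$var_names)) {
    stop("validation error: duplicate feature names", call. = FALSE)
  }
  if (ds$layer_state == "counts" && nrow(ds$counts) > 0 &&
      min(ds$counts) < 0) {
    stop("validation error: negative entries in counts layer", call. = FALSE)
  }
  if (length(ds$batch) != nrow(ds$counts)) {
    stop("validation error: batch label length differs from cell count",
         call. = FALSE)
  }
  if (anyNA(ds$batch)) {
    stop("validation error: missing batch labels", call. = FALSE)
  }
  if (nlevels(ds$batch) < 1) {
    stop("validation error: batch must have at least one level", call. = FALSE)
  }
  if (!is.null(ds$coords)) {
    if (ncol(ds$coords) != 2) {
      stop("validation error: coords must have exactly 2 columns",
           call. = FALSE)
    }
    if (nrow(ds$coords) != nrow(ds$counts)) {
      stop("validation error: coords row count differs from cell count",
           call. = FALSE)
    }
    if (anyNA(ds$coords) || any(!is.finite(ds$coords))) {
      stop("validation error: coords contain missing or non-finite values",
           call. = FALSE)
    }
  }
  invisible(ds)
}

#' @export
print.omics_dataset <- function(x, ...) {
  cat(sprintf(
    "omics_dataset: %d cells x %d features [%s, %s]\n",
    nrow(x$counts), ncol(x$counts), x$modality, x$layer_state
  ))
  cat(sprintf("  batch levels: %s\n",
              paste(levels(x$batch), collapse = ", ")))
  if (!is.null(x$coords)) cat("  spatial coords: yes\n")
  invisible(x)
}

#' @export
dim.omics_dataset <- function(x) dim(x$counts)

# Row/column subset preserving all aligned annotations.
subset_dataset <- function(ds, obs_idx = NULL, var_idx = NULL) {
  if (is.null(obs_idx)) obs_idx <- seq_len(nrow(ds$counts))
  if (is.null(var_idx)) var_idx <- seq_len(ncol(ds$counts))
  omics_dataset(
    counts = ds$counts[obs_idx, var_idx, drop = FALSE],
    obs_names = ds$obs_names[obs_idx],
    var_names = ds$var_names[var_idx],
    batch = droplevels(ds$batch[obs_idx]),
    modality = ds$modality,
    coords = if (!is.null(ds$coords)) ds$coords[obs_idx, , drop = FALSE],
    layer_state = ds$layer_state,
    obs_meta = if (!is.null(ds$obs_meta)) ds$obs_meta[obs_idx, , drop = FALSE],
    var_meta = if (!is.null(ds$var_meta)) ds$var_meta[var_idx, , drop = FALSE]
  )
}
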