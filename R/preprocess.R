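#' Filter features by total count
#'
#' Keeps features whose column total is at least `min_total_counts`; the
#' surviving features keep their original order and observations are untouched.
#' This is the gene filter applied before model fitting (e.g. dropping genes
#' with fewer than 10 reads across all cells).
#'
#' @param ds an `omics_dataset` in the `counts` layer.
#' @param min_total_counts non-negative threshold on per-feature total counts.
#' @return the filtered `omics_dataset`.
#' @export
filter_features <- function(ds, min_total_counts) {
  stopifnot(inherits(ds, "omics_dataset"))
  if (ds$layer_state != "counts") {
    stop("filter_features requires the counts layer", call. = FALSE)
  }
  if (!is.numeric(min_total_counts) || length(min_total_counts) != 1 ||
      min_total_counts < 0) {
    stop("min_total_counts must be a single non-negative number",
         call. = FALSE)
  }
  keep <- which(colSums(ds$counts) >= min_total_counts)
  if (length(keep) == 0) {
    stop(sprintf(
      "empty result: no feature has total counts >= %g", min_total_counts
    ), call. = FALSE)
  }
  subset_dataset(ds, var_idx = keep)
}

#' Filter observations (cells/spots) by total count
#'
#' Row-wise mirror of [filter_features()]: keeps cells whose total count is at
#' least `min_total_counts`. Spatial coordinates and metadata are filtered in
#' lockstep.
#'
#' @inheritParams filter_features
#' @return the filtered `omics_dataset`.
#' @export
filter_observations <- function(ds, min_total_counts) {
  stopifnot(inherits(ds, "omics_dataset"))
  if (ds$layer_state != "counts") {
    stop("filter_observations requires the counts layer", call. = FALSE)
  }
  if (!is.numeric(min_total_counts) || length(min_total_counts) != 1 ||
      min_total_counts < 0) {
    stop("min_total_counts must be a single non-negative number",
         call. = FALSE)
  }
  keep <- which(rowSums(ds$counts) >= min_total_counts)
  if (length(keep) == 0) {
    stop(sprintf(
      "empty result: no observation has total counts >= %g", min_total_counts
    ), call. = FALSE)
  }
  subset_dataset(ds, obs_idx = keep)
}

#' Library-size normalization and log1p transform
#'
#' Rescales each cell's counts to sum to `target_sum`, then applies
#' `log(1 + x)`. All-zero cells pass through unchanged (no division by zero).
#' The result is flagged `layer_state = "lognorm"`, the layer every
#' integration model and the spatial test consume.
#'
#' @param ds an `omics_dataset` in the `counts` layer.
#' @param target_sum positive per-cell total to scale to (default `1e4`).
#' @return the transformed `omics_dataset`.
#' @export
normalize_log <- function(ds, target_sum = 1e4) {
  stopifnot(inherits(ds, "omics_dataset"))
  if (ds$layer_state != "counts") {
    stop("normalize_log requires the counts layer", call. = FALSE)
  }
  if (!is.numeric(target_sum) || length(target_sum) != 1 || target_sum <= 0) {
    stop("parameter error: target_sum must be positive", call. = FALSE)
  }
  totals <- rowSums(ds$counts)
  scale <- ifelse(totals > 0, target_sum / totals, 0)
  out <- ds
  out$counts <- log1p(ds$counts * scale)
  out$layer_state <- "lognorm"
  out
}

#' Select highly variable genes by dispersion
#'
#' Ranks features by variance-to-mean dispersion computed on the lognorm
#' values and keeps the top `n_top`, preserving their original column order.
#' Ties are broken in favour of earlier columns.
#'
#' @param ds an `omics_dataset` (lognorm layer expected).
#' @param n_top number of features to keep (positive, at most the feature
#'   count).
#' @return the reduced `omics_dataset`.
#' @export
select_hvg <- function(ds, n_top) {
  stopifnot(inherits(ds, "omics_dataset"))
  p <- ncol(ds$counts)
  if (!is.numeric(n_top) || length(n_top) != 1 || n_top < 1 || n_top != round(n_top)) {
    stop("parameter error: n_top must be a positive integer", call. = FALSE)
  }
  if (n_top > p) {
    stop(sprintf(
      "parameter error: n_top (%d) exceeds feature count (%d)", n_top, p
    ), call. = FALSE)
  }
  mu <- colMeans(ds$counts)
  v <- apply(ds$counts, 2, stats::var)
  dispersion <- ifelse(mu > 0, v / mu, 0)
  # stable sort: ties keep original column order
  ord <- order(-dispersion, seq_len(p))
  keep <- sort(ord[seq_len(n_top)])
  subset_dataset(ds, var_idx = keep)
}

#' Concatenate datasets over shared features
#'
#' Row-stacks two or more datasets over the intersection of their feature
#' names (in the first dataset's order) and records the dataset of origin in
#' the `batch` column — the per-cell batch annotation that conditions the
#' integration models.
#'
#' @param ds_list list of at least two `omics_dataset`s sharing a
#'   `layer_state`.
#' @param batch_names optional character vector of batch labels, one per
#'   dataset (default `"0", "1", ...`).
#' @return a single `omics_dataset` whose `batch` has one level per input.
#' @export
concatenate <- function(ds_list, batch_names = NULL) {
  if (!is.list(ds_list) || length(ds_list) < 2) {
    stop("parameter error: concatenate needs at least 2 datasets",
         call. = FALSE)
  }
  states <- vapply(ds_list, function(d) d$layer_state, character(1))
  if (length(unique(states)) != 1) {
    stop("validation error: datasets differ in layer_state", call. = FALSE)
  }
  if (is.null(batch_names)) {
    batch_names <- as.character(seq_along(ds_list) - 1L)
  }
  shared <- ds_list[[1]]$var_names
  for (d in ds_list[-1]) shared <- shared[shared %in% d$var_names]
  if (length(shared) == 0) {
    stop("integration impossible: the datasets share no feature names",
         call. = FALSE)
  }
  mats <- lapply(ds_list, function(d) {
    d$counts[, match(shared, d$var_names), drop = FALSE]
  })
  obs <- unlist(lapply(ds_list, function(d) d$obs_names))
  if (anyDuplicated(obs)) {
    # disambiguate barcodes repeated across datasets
    obs <- unlist(lapply(seq_along(ds_list), function(i) {
      paste0(batch_names[i], ":", ds_list[[i]]$obs_names)
    }))
  }
  batch <- factor(
    rep(batch_names, vapply(ds_list, function(d) nrow(d$counts), integer(1))),
    levels = batch_names
  )
  omics_dataset(
    counts = do.call(rbind, mats),
    obs_names = obs,
    var_names = shared,
    batch = batch,
    modality = ds_list[[1]]$modality,
    layer_state = states[1]
  )
}
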