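#' Integration result container
#'
#' Every `fit_*` integration function returns this structure: the latent
#' embedding (posterior means of z), the batch-corrected expression matrix,
#' the fitted model handle with its loss trace, and the per-cell batch labels
#' carried through.
#'
#' @name integration_result
#' @keywords internal
NULL

new_integration_result <- function(latent, corrected, model, batch,
                                   obs_names, var_names) {
  rownames(latent) <- obs_names
  rownames(corrected) <- obs_names
  colnames(corrected) <- var_names
  structure(
    list(latent = latent, corrected = corrected, model = model,
         batch = batch, obs_names = obs_names, var_names = var_names),
    class = "integration_result"
  )
}

#' @export
print.integration_result <- function(x, ...) {
  cat(sprintf(
    "integration_result (%s): %d cells, latent dim %d, %d corrected features\n",
    x$model$kind, nrow(x$latent), ncol(x$latent), ncol(x$corrected)
  ))
  invisible(x)
}

check_unpaired_inputs <- function(ds_list) {
  if (!is.list(ds_list) || length(ds_list) < 2) {
    stop("parameter error: integration needs at least 2 datasets",
         call. = FALSE)
  }
  for (d in ds_list) {
    if (d$layer_state != "lognorm") {
      stop("integration expects lognorm input; run normalize_log first",
           call. = FALSE)
    }
  }
}

#' Conditional variational integration of unpaired datasets
#'
#' Non-linear CCA-style integration: a shared encoder maps each cell's
#' expression to a variational posterior over a common latent space z, and the
#' decoder receives z concatenated with a one-hot encoding of the cell's batch
#' b, so reconstruction is batch-conditioned and z is free to encode shared
#' biology. Loss = reconstruction + beta * KL. The `corrected` matrix decodes
#' every cell's posterior mean under the reference batch code (the first
#' dataset), putting all cells on one expression scale.
#'
#' @param ds_list list of >= 2 `omics_dataset`s in the lognorm layer with a
#'   non-empty feature-name intersection.
#' @param config a [training_config()].
#' @return an `integration_result`.
#' @export
fit_vipcca <- function(ds_list, config = training_config()) {
  check_unpaired_inputs(ds_list)
  ds <- concatenate(ds_list)
  X <- ds$counts
  model <- withr::with_seed(
    config$seed,
    build_vae_model("cvae", ncol(X), config, n_batches = nlevels(ds$batch))
  )
  fit <- vae_train(model, X, ds$batch, config, obs_names = ds$obs_names)
  post <- posterior_of(fit, X)
  corrected <- decode_latent(fit, post$mean, batch_code = 1L)
  new_integration_result(post$mean, corrected, fit, ds$batch,
                         ds$obs_names, ds$var_names)
}

#' Domain-adversarial variational integration of unpaired datasets
#'
#' As [fit_vipcca()] but batch invariance of the latent space is enforced
#' adversarially instead of by conditioning: a domain-classifier head on z is
#' trained to predict the batch while the encoder receives the reversed
#' gradient of the domain cross-entropy scaled by `adversarial_weight`,
#' driving z toward batch invariance. The decoder takes z alone, so
#' `corrected` is decoded directly from the latent means.
#'
#' @inheritParams fit_vipcca
#' @return an `integration_result`.
#' @export
fit_davae <- function(ds_list, config = training_config()) {
  check_unpaired_inputs(ds_list)
  ds <- concatenate(ds_list)
  X <- ds$counts
  model <- withr::with_seed(
    config$seed,
    build_vae_model("davae", ncol(X), config, n_batches = nlevels(ds$batch))
  )
  fit <- vae_train(model, X, ds$batch, config, obs_names = ds$obs_names)
  post <- posterior_of(fit, X)
  corrected <- decode_latent(fit, post$mean)
  new_integration_result(post$mean, corrected, fit, ds$batch,
                         ds$obs_names, ds$var_names)
}

#' Multi-view shared-latent integration of paired modalities
#'
#' For paired measurements (the same cells observed in two modalities, e.g.
#' RNA + protein or RNA + ATAC): a single encoder consumes the concatenation
#' of both views and yields one posterior z per cell; two view-specific
#' decoders reconstruct each modality. Loss = recon_x + recon_y + beta * KL.
#' The returned latent is the joint embedding; `corrected` is the decoded
#' view-x matrix.
#'
#' @param ds_x,ds_y `omics_dataset`s with identical `obs_names` in identical
#'   order (the pairing); feature sets may differ arbitrarily.
#' @param config a [training_config()].
#' @return an `integration_result`.
#' @export
fit_vimcca <- function(ds_x, ds_y, config = training_config()) {
  stopifnot(inherits(ds_x, "omics_dataset"), inherits(ds_y, "omics_dataset"))
  if (nrow(ds_x$counts) != nrow(ds_y$counts) ||
      any(ds_x$obs_names != ds_y$obs_names)) {
    bad <- if (nrow(ds_x$counts) != nrow(ds_y$counts)) 1L else
      which(ds_x$obs_names != ds_y$obs_names)[1]
    stop(sprintf(
      "pairing error: obs_names disagree starting at index %d", bad
    ), call. = FALSE)
  }
  X <- ds_x$counts
  Y <- ds_y$counts
  model <- withr::with_seed(
    config$seed,
    build_vae_model("vimcca", ncol(X) + ncol(Y), config, n_batches = 1L,
                    d_out_x = ncol(X), d_out_y = ncol(Y))
  )
  fit <- vae_train(model, X, ds_x$batch, config,
                   obs_names = ds_x$obs_names, Xy = Y)
  post <- posterior_of(fit, X, Xy = Y)
  corrected <- decode_latent(fit, post$mean, view = "dec_x")
  new_integration_result(post$mean, corrected, fit, ds_x$batch,
                         ds_x$obs_names, ds_x$var_names)
}

#' k-nearest-neighbour label transfer in a shared latent space
#'
#' Transfers annotations from a reference embedding (e.g. well-annotated
#' scRNA-seq cells) to query cells co-embedded in the same latent space (e.g.
#' scATAC-seq): each query cell takes the majority label among its
#' `k_neighbors` Euclidean-nearest reference cells. Ties are broken by the
#' smaller mean neighbour distance, then lexicographically by label.
#'
#' @param ref_latent reference cells x k matrix.
#' @param ref_labels per-reference-cell labels.
#' @param query_latent query cells x k matrix (same latent dimension).
#' @param k_neighbors number of neighbours to vote (at most the reference
#'   size).
#' @return a list with `predicted` (character vector) and `confidence`
#'   (winning vote fraction in `[0, 1]`), class `label_transfer_result`.
#' @export
transfer_labels <- function(ref_latent, ref_labels, query_latent,
                            k_neighbors = 15) {
  ref_latent <- as.matrix(ref_latent)
  query_latent <- as.matrix(query_latent)
  ref_labels <- as.character(ref_labels)
  if (ncol(ref_latent) != ncol(query_latent)) {
    stop("reference and query latent dimensions differ", call. = FALSE)
  }
  if (length(ref_labels) != nrow(ref_latent)) {
    stop("ref_labels length must match reference rows", call. = FALSE)
  }
  if (k_neighbors > nrow(ref_latent)) {
    stop(sprintf(
      "parameter error: k_neighbors (%d) exceeds reference size (%d)",
      k_neighbors, nrow(ref_latent)
    ), call. = FALSE)
  }
  D <- euclidean_cross_dist(query_latent, ref_latent)
  nq <- nrow(query_latent)
  predicted <- character(nq)
  confidence <- numeric(nq)
  for (i in seq_len(nq)) {
    ord <- order(D[i, ])[seq_len(k_neighbors)]
    labs <- ref_labels[ord]
    tab <- table(labs)
    top <- max(tab)
    winners <- names(tab)[tab == top]
    if (length(winners) > 1) {
      meand <- vapply(winners, function(w) mean(D[i, ord[labs == w]]),
                      numeric(1))
      winners <- winners[meand == min(meand)]
      winners <- sort(winners)
    }
    predicted[i] <- winners[1]
    confidence[i] <- top / k_neighbors
  }
  structure(list(predicted = predicted, confidence = confidence),
            class = "label_transfer_result")
}

# squared-expansion trick; clamps tiny negatives from cancellation
euclidean_cross_dist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  sqrt(pmax(d2, 0))
}
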