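#' Simulate unpaired multi-batch single-cell data
#'
#' Generative model with planted structure: per-gene base log-means are
#' N(0, 1); each cell type perturbs a random 20% of genes with effects
#' N(0, type_effect_sd^2); each batch adds per-gene offsets
#' N(0, batch_effect_sd^2); per-cell library-size factors are log-normal
#' (sdlog 0.3); counts are negative binomial with dispersion 2. Cell types are
#' shared across batches with identical proportions, so the planted biology is
#' the signal an integration method should recover and the batch offsets are
#' the nuisance it should remove.
#'
#' @param n_cells_per_batch integer vector of per-batch cell counts
#'   (default `c(500, 500)`).
#' @param n_genes number of genes (default 200).
#' @param n_types number of cell types (>= 2; default 3).
#' @param batch_effect_sd SD of per-gene batch offsets on the log scale
#'   (default 0.8, a moderate batch effect).
#' @param type_effect_sd SD of type effects on the log scale (default 1.2, a
#'   strong type signal; must be > 0).
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @return a list with `datasets` (list of `omics_dataset`s, one per batch)
#'   and `truth` (a `sim_truth`: per-cell `cell_types`, the
#'   `batch_offsets` matrix, and the seed).
#' @export
simulate_batches <- function(n_cells_per_batch = c(500, 500),
                             n_genes = 200,
                             n_types = 3,
                             batch_effect_sd = 0.8,
                             type_effect_sd = 1.2,
                             seed = 0) {
  if (n_types < 2) {
    stop("parameter error: n_types must be >= 2", call. = FALSE)
  }
  if (type_effect_sd <= 0) {
    stop("parameter error: type_effect_sd must be > 0", call. = FALSE)
  }
  n_batches <- length(n_cells_per_batch)
  withr::local_seed(seed)

  base <- stats::rnorm(n_genes)
  type_eff <- matrix(0, n_types, n_genes)
  for (t in seq_len(n_types)) {
    hit <- sample.int(n_genes, max(1, round(0.2 * n_genes)))
    type_eff[t, hit] <- stats::rnorm(length(hit), sd = type_effect_sd)
  }
  batch_off <- matrix(stats::rnorm(n_batches * n_genes, sd = batch_effect_sd),
                      n_batches, n_genes)

  datasets <- vector("list", n_batches)
  types_all <- list()
  for (b in seq_len(n_batches)) {
    nc <- n_cells_per_batch[b]
    types <- rep_len(seq_len(n_types), nc) # identical proportions per batch
    lib <- exp(stats::rnorm(nc, sd = 0.3))
    logmu <- matrix(base, nc, n_genes, byrow = TRUE) +
      type_eff[types, , drop = FALSE] +
      matrix(batch_off[b, ], nc, n_genes, byrow = TRUE)
    mu <- exp(logmu) * lib
    counts <- matrix(
      stats::rnbinom(nc * n_genes, size = 2, mu = as.vector(mu)),
      nc, n_genes
    )
    datasets[[b]] <- omics_dataset(
      counts,
      obs_names = sprintf("b%d_cell_%04d", b - 1, seq_len(nc)),
      var_names = sprintf("gene_%04d", seq_len(n_genes)),
      batch = rep(as.character(b - 1), nc),
      modality = if (b == 1) "rna" else "atac"
    )
    types_all[[b]] <- types
  }
  truth <- structure(
    list(cell_types = unlist(types_all), batch_offsets = batch_off,
         type_effects = type_eff, sv_mask = NULL, seed = seed),
    class = "sim_truth"
  )
  list(datasets = datasets, truth = truth)
}

#' Simulate paired two-view single-cell data
#'
#' One latent cell type per cell drives both views through independent
#' loading matrices (type effects drawn separately per view), emulating paired
#' assays such as CITE-seq or 10x Multiome. Observation names are identical
#' and aligned across the views.
#'
#' @param n_cells number of paired cells (default 400).
#' @param n_genes_x,n_genes_y feature counts of the two views (defaults 150
#'   and 60).
#' @param n_types number of cell types (>= 2; default 3).
#' @param type_effect_sd SD of per-view type effects (default 1.2).
#' @param seed integer seed.
#' @return list with `ds_x`, `ds_y` (paired `omics_dataset`s) and `truth`.
#' @export
simulate_paired <- function(n_cells = 400,
                            n_genes_x = 150,
                            n_genes_y = 60,
                            n_types = 3,
                            type_effect_sd = 1.2,
                            seed = 0) {
  if (n_types < 2) {
    stop("parameter error: n_types must be >= 2", call. = FALSE)
  }
  withr::local_seed(seed)
  types <- rep_len(seq_len(n_types), n_cells)
  obs <- sprintf("cell_%05d", seq_len(n_cells))

  one_view <- function(n_genes, modality) {
    base <- stats::rnorm(n_genes)
    type_eff <- matrix(0, n_types, n_genes)
    for (t in seq_len(n_types)) {
      hit <- sample.int(n_genes, max(1, round(0.2 * n_genes)))
      type_eff[t, hit] <- stats::rnorm(length(hit), sd = type_effect_sd)
    }
    lib <- exp(stats::rnorm(n_cells, sd = 0.3))
    mu <- exp(matrix(base, n_cells, n_genes, byrow = TRUE) +
                type_eff[types, , drop = FALSE]) * lib
    counts <- matrix(
      stats::rnbinom(n_cells * n_genes, size = 2, mu = as.vector(mu)),
      n_cells, n_genes
    )
    omics_dataset(
      counts, obs_names = obs,
      var_names = sprintf("%s_feat_%04d", modality, seq_len(n_genes)),
      modality = modality
    )
  }
  ds_x <- one_view(n_genes_x, "rna")
  ds_y <- one_view(n_genes_y, "protein")
  truth <- structure(
    list(cell_types = types, batch_offsets = NULL, sv_mask = NULL,
         seed = seed),
    class = "sim_truth"
  )
  list(ds_x = ds_x, ds_y = ds_y, truth = truth)
}

#' Simulate spatial transcriptomics with planted spatially variable genes
#'
#' Spots lie on a `grid_side` x `grid_side` integer lattice. Every gene has an
#' iid N(baseline, noise_sd^2) log-expression baseline; the first `n_sv` genes
#' additionally receive a spatial pattern on the log scale, cycling through
#' three kinds (coordinates normalized to `[0, 1]`): gradient
#' `a * (x - 0.5)`, hotspot `a * exp(-||s - c||^2 / (2 r^2))` centred at c
#' with radius `r = 0.2`, periodic `a * sin(2 pi x / 0.5)`. Log values are
#' exponentiated and Poisson-sampled.
#'
#' @param grid_side lattice side length (default 10, i.e. 100 spots).
#' @param n_genes total genes (default 200).
#' @param n_sv number of spatially variable genes (default 20).
#' @param amplitude pattern amplitude `a` on the log scale (default 2).
#' @param noise_sd SD of the iid log-scale noise (> 0; default 0.5).
#' @param baseline baseline log-mean expression (default 1).
#' @param seed integer seed.
#' @return list with `sds` (a spatial `omics_dataset`) and `truth`
#'   (including the per-gene `sv_mask` and `pattern_kind`).
#' @export
simulate_spatial <- function(grid_side = 10,
                             n_genes = 200,
                             n_sv = 20,
                             amplitude = 2,
                             noise_sd = 0.5,
                             baseline = 1,
                             seed = 0) {
  if (noise_sd <= 0) {
    stop("parameter error: noise_sd must be > 0", call. = FALSE)
  }
  if (n_sv > n_genes) {
    stop("parameter error: n_sv exceeds n_genes", call. = FALSE)
  }
  withr::local_seed(seed)
  coords <- as.matrix(expand.grid(x = seq_len(grid_side),
                                  y = seq_len(grid_side)))
  n_spots <- nrow(coords)
  xn <- (coords[, 1] - 1) / max(grid_side - 1, 1)
  yn <- (coords[, 2] - 1) / max(grid_side - 1, 1)

  kinds <- c("gradient", "hotspot", "periodic")
  pattern_kind <- if (n_sv > 0) kinds[(seq_len(n_sv) - 1) %% 3 + 1] else
    character(0)
  pattern_value <- function(kind) {
    switch(kind,
      gradient = amplitude * (xn - 0.5),
      hotspot = amplitude * exp(-((xn - 0.5)^2 + (yn - 0.5)^2) / (2 * 0.2^2)),
      periodic = amplitude * sin(2 * pi * xn / 0.5)
    )
  }

  logmu <- matrix(stats::rnorm(n_spots * n_genes, mean = baseline,
                               sd = noise_sd), n_spots, n_genes)
  for (g in seq_len(n_sv)) {
    logmu[, g] <- logmu[, g] + pattern_value(pattern_kind[g])
  }
  counts <- matrix(stats::rpois(n_spots * n_genes, exp(as.vector(logmu))),
                   n_spots, n_genes)
  sds <- omics_dataset(
    counts,
    obs_names = sprintf("spot_%04d", seq_len(n_spots)),
    var_names = sprintf("gene_%04d", seq_len(n_genes)),
    modality = "spatial",
    coords = coords
  )
  truth <- structure(
    list(cell_types = NULL, batch_offsets = NULL,
         sv_mask = seq_len(n_genes) <= n_sv,
         pattern_kind = pattern_kind, seed = seed),
    class = "sim_truth"
  )
  list(sds = sds, truth = truth)
}
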