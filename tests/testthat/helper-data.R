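# Small in-code fixtures shared across test files.

tiny_dataset <- function(counts = matrix(c(5, 3, 0, 0, 12, 4), 2, 3),
                         ...) {
  omics_dataset(counts,
                obs_names = paste0("c", seq_len(nrow(counts))),
                var_names = paste0("g", seq_len(ncol(counts))),
                ...)
}

random_counts_dataset <- function(n_cells, n_genes, seed = 1,
                                  lambda = 2, ...) {
  counts <- withr::with_seed(
    seed, matrix(stats::rpois(n_cells * n_genes, lambda), n_cells, n_genes)
  )
  omics_dataset(counts,
                obs_names = sprintf("c%03d", seq_len(n_cells)),
                var_names = sprintf("g%03d", seq_len(n_genes)),
                ...)
}

# two small lognorm datasets with shared features, for integration tests
small_integration_pair <- function(seed = 0, n_cells = 60, n_genes = 40) {
  sim <- simulate_batches(n_cells_per_batch = c(n_cells, n_cells),
                          n_genes = n_genes, seed = seed)
  list(datasets = lapply(sim$datasets, normalize_log), truth = sim$truth)
}

fast_config <- function(...) {
  args <- list(latent_dim = 4, hidden_sizes = c(16, 8), epochs = 3,
               batch_size = 32)
  over <- list(...)
  args[names(over)] <- over
  do.call(training_config, args)
}
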