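#' Training configuration for the variational models
#'
#' Collects every tunable of the shared training loop. All randomness in a fit
#' (weight initialization, minibatch shuffling, reparameterization noise)
#' derives from `seed`, so a fit is reproducible given (data, config).
#'
#' @param latent_dim dimension k of the latent space (default 16).
#' @param hidden_sizes integer vector of encoder hidden-layer widths; the
#'   decoder mirrors them in reverse (default `c(128, 64)`).
#' @param epochs number of passes over the data (default 50).
#' @param batch_size minibatch size (default 128).
#' @param learning_rate Adam step size (default 1e-3).
#' @param seed integer seed for all training randomness.
#' @param likelihood observation model: `"gaussian"` (lognorm input, learned
#'   global per-feature variance) or `"negative_binomial"` (raw counts,
#'   learned per-feature dispersion).
#' @param kl_weight beta weight on the KL term of the ELBO (default 1).
#' @param adversarial_weight lambda weight on the domain-adversarial term
#'   (domain-adversarial model only; default 0.3). The reversed gradient is
#'   scaled internally by `lambda * n_features` so that the O(1) per-cell
#'   domain cross-entropy competes with the O(n_features) reconstruction term
#'   regardless of data width.
#' @param adv_steps inner classifier updates per minibatch (domain-adversarial
#'   model only; default 5). 0 falls back to a single simultaneous
#'   gradient-reversal step.
#' @return an object of class `training_config`.
#' @export
training_config <- function(latent_dim = 16,
                            hidden_sizes = c(128, 64),
                            epochs = 50,
                            batch_size = 128,
                            learning_rate = 1e-3,
                            seed = 0,
                            likelihood = c("gaussian", "negative_binomial"),
                            kl_weight = 1,
                            adversarial_weight = 0.3,
                            adv_steps = 5) {
  likelihood <- match.arg(likelihood)
  cfg <- list(
    latent_dim = as.integer(latent_dim),
    hidden_sizes = as.integer(hidden_sizes),
    epochs = as.integer(epochs),
    batch_size = as.integer(batch_size),
    learning_rate = learning_rate,
    seed = as.integer(seed),
    likelihood = likelihood,
    kl_weight = kl_weight,
    adversarial_weight = adversarial_weight,
    adv_steps = as.integer(adv_steps)
  )
  if (length(cfg$hidden_sizes) < 1) {
    stop("parameter error: at least one hidden layer is required",
         call. = FALSE)
  }
  if (any(c(cfg$latent_dim, cfg$hidden_sizes, cfg$epochs, cfg$batch_size) < 1)) {
    stop("parameter error: sizes, epochs and batch_size must be positive",
         call. = FALSE)
  }
  if (cfg$learning_rate <= 0) {
    stop("parameter error: learning_rate must be positive", call. = FALSE)
  }
  if (cfg$kl_weight < 0 || cfg$adversarial_weight < 0) {
    stop("parameter error: kl_weight and adversarial_weight must be >= 0",
         call. = FALSE)
  }
  structure(cfg, class = "training_config")
}

#' Read / write a training configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_training_config` returns a `training_config`;
#'   `write_training_config` returns `path` invisibly.
#' @export
read_training_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(training_config, raw)
}

#' @rdname read_training_config
#' @param cfg a `training_config`.
#' @export
write_training_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Write a loss trace as CSV
#'
#' One row per epoch with columns `epoch,total,recon,kl,adv`.
#'
#' @param trace the `loss_trace` data.frame of a fitted model.
#' @param path output CSV path.
#' @export
write_loss_trace <- function(trace, path) {
  utils::write.csv(trace, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
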