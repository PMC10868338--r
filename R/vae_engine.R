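#' Variational posterior over the latent space
#'
#' Per-cell Gaussian posterior q(z|x) = N(mean, diag(exp(logvar))): the
#' low-dimensional embedding every integration model estimates.
#'
#' @param mean cells x k matrix of posterior means.
#' @param logvar cells x k matrix of natural-log variances.
#' @return an object of class `variational_posterior`.
#' @export
variational_posterior <- function(mean, logvar) {
  mean <- as.matrix(mean)
  logvar <- as.matrix(logvar)
  if (!identical(dim(mean), dim(logvar))) {
    stop("mean and logvar must have identical shape", call. = FALSE)
  }
  if (any(!is.finite(logvar)) || any(!is.finite(mean))) {
    stop("numeric error: non-finite posterior parameters", call. = FALSE)
  }
  structure(list(mean = mean, logvar = logvar),
            class = "variational_posterior")
}

#' KL divergence from the posterior to the standard-normal prior
#'
#' Closed form per cell: `0.5 * sum_j (mu^2 + exp(logvar) - logvar - 1)`,
#' the regularizer of the ELBO.
#'
#' @param post a `variational_posterior`.
#' @return non-negative numeric vector, one entry per cell.
#' @export
kl_standard_normal <- function(post) {
  stopifnot(inherits(post, "variational_posterior"))
  0.5 * rowSums(post$mean^2 + exp(post$logvar) - post$logvar - 1)
}

#' Reconstruction log-likelihood of one observation
#'
#' Evaluates the decoder's observation model at `x`. Gaussian:
#' `sum_j -0.5 * ((x_j - mu_j)^2 / var_j + log(2 pi var_j))`. Negative
#' binomial (mean/dispersion parameterization, for raw counts):
#' `sum_j log NB(x_j; mean_j, dispersion_j)`.
#'
#' @param x numeric observation vector.
#' @param decoded list of distribution parameters: `list(mean, var)` for
#'   gaussian, `list(mean, dispersion)` for negative_binomial (each a vector
#'   of length `length(x)` or a scalar).
#' @param likelihood `"gaussian"` or `"negative_binomial"`.
#' @return scalar log-likelihood.
#' @export
reconstruction_loglik <- function(x, decoded,
                                  likelihood = c("gaussian", "negative_binomial")) {
  likelihood <- match.arg(likelihood)
  if (likelihood == "gaussian") {
    mu <- rep_len(decoded$mean, length(x))
    v <- rep_len(decoded$var, length(x))
    if (any(v <= 0)) stop("variance must be positive", call. = FALSE)
    return(sum(-0.5 * ((x - mu)^2 / v + log(2 * pi * v))))
  }
  if (any(x < 0) || any(x != round(x))) {
    stop("validation error: negative_binomial requires non-negative integer x",
         call. = FALSE)
  }
  m <- rep_len(decoded$mean, length(x))
  theta <- rep_len(decoded$dispersion, length(x))
  sum(stats::dnbinom(x, size = theta, mu = m, log = TRUE))
}

#' Reparameterized sample from a variational posterior
#'
#' Draws `z = mean + exp(logvar/2) * eps` with standard-normal `eps`,
#' deterministic given `seed`.
#'
#' @param post a `variational_posterior`.
#' @param seed integer seed.
#' @return cells x k numeric matrix.
#' @export
reparameterized_sample <- function(post, seed) {
  stopifnot(inherits(post, "variational_posterior"))
  n <- nrow(post$mean)
  k <- ncol(post$mean)
  eps <- withr::with_seed(seed, matrix(stats::rnorm(n * k), n, k))
  post$mean + exp(post$logvar / 2) * eps
}

## ------------------------------------------------------------------
## Dense MLP primitives (manual forward/backward, ReLU hidden layers)
## ------------------------------------------------------------------

# Seeded uniform fan-in initialization: W ~ U(-s, s), s = sqrt(6/(fi+fo)).
init_dense <- function(fan_in, fan_out) {
  s <- sqrt(6 / (fan_in + fan_out))
  list(
    W = matrix(stats::runif(fan_in * fan_out, -s, s), fan_in, fan_out),
    b = rep(0, fan_out)
  )
}

init_stack <- function(sizes) {
  lapply(seq_len(length(sizes) - 1), function(l) {
    init_dense(sizes[l], sizes[l + 1])
  })
}

# Forward through ReLU hidden stack. Returns post-activations H (H[[1]] = X)
# and pre-activations Z for the backward pass.
stack_forward <- function(X, layers) {
  H <- vector("list", length(layers) + 1)
  Z <- vector("list", length(layers))
  H[[1]] <- X
  for (l in seq_along(layers)) {
    Z[[l]] <- sweep(H[[l]] %*% layers[[l]]$W, 2, layers[[l]]$b, "+")
    H[[l + 1]] <- pmax(Z[[l]], 0)
  }
  list(H = H, Z = Z)
}

# Backward: dOut is gradient w.r.t. the stack's post-activation output.
stack_backward <- function(cache, layers, dOut) {
  grads <- vector("list", length(layers))
  dH <- dOut
  for (l in rev(seq_along(layers))) {
    dZ <- dH * (cache$Z[[l]] > 0)
    grads[[l]] <- list(
      W = crossprod(cache$H[[l]], dZ),
      b = colSums(dZ)
    )
    dH <- tcrossprod(dZ, layers[[l]]$W)
  }
  list(dIn = dH, grads = grads)
}

linear_forward <- function(H, head) {
  sweep(H %*% head$W, 2, head$b, "+")
}

# returns grads for the head and gradient w.r.t. its input
linear_backward <- function(H, head, dOut) {
  list(
    grads = list(W = crossprod(H, dOut), b = colSums(dOut)),
    dIn = tcrossprod(dOut, head$W)
  )
}

## ------------------------------------------------------------------
## Adam over an arbitrary nested parameter list
## ------------------------------------------------------------------

zeros_like <- function(p) {
  if (is.list(p)) lapply(p, zeros_like) else p * 0
}

adam_init <- function(params) {
  list(m = zeros_like(params), v = zeros_like(params), t = 0)
}

adam_update_rec <- function(p, g, m, v, lr_t, beta1, beta2, eps) {
  if (is.list(p)) {
    out_p <- p; out_m <- m; out_v <- v
    for (i in seq_along(p)) {
      r <- adam_update_rec(p[[i]], g[[i]], m[[i]], v[[i]],
                           lr_t, beta1, beta2, eps)
      out_p[[i]] <- r$p; out_m[[i]] <- r$m; out_v[[i]] <- r$v
    }
    return(list(p = out_p, m = out_m, v = out_v))
  }
  m2 <- beta1 * m + (1 - beta1) * g
  v2 <- beta2 * v + (1 - beta2) * g^2
  list(p = p - lr_t * m2 / (sqrt(v2) + eps), m = m2, v = v2)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  lr_t <- lr * sqrt(1 - beta2^state$t) / (1 - beta1^state$t)
  r <- adam_update_rec(params, grads, state$m, state$v,
                       lr_t, beta1, beta2, eps)
  list(params = r$p, state = list(m = r$m, v = r$v, t = state$t))
}

# elementwise sum of two nested grad lists
grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.list(a)) return(mapply(grads_add, a, b, SIMPLIFY = FALSE))
  a + b
}

## ------------------------------------------------------------------
## Model construction
## ------------------------------------------------------------------

# kind: "cvae" (batch-conditioned decoder), "davae" (plain decoder +
# adversary), "vimcca" (shared encoder over two concatenated views, two
# decoders). d_in = encoder input width; d_out_* = decoder output widths.
build_vae_model <- function(kind, d_in, config, n_batches = 1,
                            d_out_x = d_in, d_out_y = NULL) {
  k <- config$latent_dim
  hs <- config$hidden_sizes
  enc_sizes <- c(d_in, hs)
  dec_cond <- kind == "cvae"
  dec_in <- if (dec_cond) k + n_batches else k
  dec_sizes <- c(dec_in, rev(hs))
  params <- list(
    enc = list(
      stack = init_stack(enc_sizes),
      mu = init_dense(hs[length(hs)], k),
      lv = init_dense(hs[length(hs)], k)
    ),
    dec_x = list(
      stack = init_stack(dec_sizes),
      out = init_dense(hs[1], d_out_x),
      lik = rep(0, d_out_x) # per-feature log-variance / log-dispersion
    )
  )
  if (kind == "vimcca") {
    params$dec_y <- list(
      stack = init_stack(dec_sizes),
      out = init_dense(hs[1], d_out_y),
      lik = rep(0, d_out_y)
    )
  }
  if (kind == "davae") {
    params$adv <- list(
      stack = init_stack(c(k, 64L, 64L)),
      out = init_dense(64L, n_batches)
    )
  }
  structure(
    list(kind = kind, params = params, d_in = d_in, dec_cond = dec_cond,
         n_batches = n_batches, d_out_x = d_out_x, d_out_y = d_out_y,
         config = config),
    class = "vae_model"
  )
}

encode_cells <- function(model, X) {
  cache <- stack_forward(X, model$params$enc$stack)
  top <- cache$H[[length(cache$H)]]
  list(
    mu = linear_forward(top, model$params$enc$mu),
    lv = linear_forward(top, model$params$enc$lv),
    cache = cache, top = top
  )
}

decode_cells <- function(model, Dinput, view = "dec_x") {
  dec <- model$params[[view]]
  cache <- stack_forward(Dinput, dec$stack)
  top <- cache$H[[length(cache$H)]]
  list(out = linear_forward(top, dec$out), cache = cache, top = top)
}

## ------------------------------------------------------------------
## Loss + gradients for one minibatch
## ------------------------------------------------------------------

# Gaussian negative log-likelihood pieces; lik = per-feature log-variance.
gauss_recon <- function(X, Xhat, loglik_par) {
  v <- exp(loglik_par)
  R <- X - Xhat
  B <- nrow(X)
  loss <- sum(sweep(R^2, 2, 2 * v, "/")) / B +
    0.5 * nrow(X) * sum(log(2 * pi * v)) / B
  dXhat <- sweep(-R, 2, v, "/") / B
  dlik <- (0.5 * colSums(1 - sweep(R^2, 2, v, "/"))) / B
  list(loss = loss, dXhat = dXhat, dlik = dlik)
}

# NB negative log-likelihood; decoder output o is the log-mean, lik is the
# per-feature log-dispersion.
nb_recon <- function(X, O, loglik_par) {
  B <- nrow(X)
  M <- exp(pmin(O, 30)) # guard against overflow early in training
  theta <- exp(loglik_par)
  Th <- matrix(theta, B, length(theta), byrow = TRUE)
  ll <- lgamma(X + Th) - lgamma(Th) - lgamma(X + 1) +
    Th * log(Th / (Th + M)) + X * log(M / (Th + M) + (X == 0))
  loss <- -sum(ll) / B
  dO <- -(X - M * (X + Th) / (Th + M)) / B
  dtheta_mat <- digamma(X + Th) - digamma(Th) + log(Th / (Th + M)) +
    1 - (X + Th) / (Th + M)
  dlik <- -colSums(dtheta_mat * Th) / B
  list(loss = loss, dXhat = dO, dlik = dlik)
}

# Domain-classifier cross-entropy with gradients for the classifier
# parameters and for its input z.
adversary_grad <- function(adv, z, Bq) {
  B <- nrow(z)
  ac <- stack_forward(z, adv$stack)
  atop <- ac$H[[length(ac$H)]]
  logits <- linear_forward(atop, adv$out)
  P <- softmax_rows(logits)
  loss <- -sum(log(pmax(rowSums(P * Bq), 1e-12))) / B
  dlogits <- (P - Bq) / B
  ha <- linear_backward(atop, adv$out, dlogits)
  sa <- stack_backward(ac, adv$stack, ha$dIn)
  list(loss = loss, grads = list(stack = sa$grads, out = ha$grads),
       dz = sa$dIn)
}

softmax_rows <- function(L) {
  L <- L - apply(L, 1, max)
  E <- exp(L)
  E / rowSums(E)
}

# One minibatch of the joint objective. Returns loss components and the
# gradient list mirroring model$params. Xy is the second view (vimcca only);
# Bq is the one-hot batch matrix.
vae_loss_grad <- function(model, X, Bq, eps, Xy = NULL) {
  cfg <- model$config
  B <- nrow(X)
  kind <- model$kind
  enc_in <- if (kind == "vimcca") cbind(X, Xy) else X
  enc <- encode_cells(model, enc_in)
  z <- enc$mu + exp(enc$lv / 2) * eps

  dec_cond <- isTRUE(model$dec_cond)
  dec_in <- if (dec_cond) cbind(z, Bq) else z
  dx <- decode_cells(model, dec_in, "dec_x")
  rec <- if (cfg$likelihood == "gaussian") {
    gauss_recon(X, dx$out, model$params$dec_x$lik)
  } else {
    nb_recon(X, dx$out, model$params$dec_x$lik)
  }
  recon_loss <- rec$loss

  grads <- list(enc = NULL, dec_x = NULL)

  # backprop decoder x
  hx <- linear_backward(dx$top, model$params$dec_x$out, rec$dXhat)
  sx <- stack_backward(dx$cache, model$params$dec_x$stack, hx$dIn)
  grads$dec_x <- list(stack = sx$grads, out = hx$grads, lik = rec$dlik)
  dz <- if (dec_cond) {
    sx$dIn[, seq_len(ncol(z)), drop = FALSE]
  } else {
    sx$dIn
  }

  # second view (vimcca)
  if (kind == "vimcca") {
    dy <- decode_cells(model, z, "dec_y")
    recy <- if (cfg$likelihood == "gaussian") {
      gauss_recon(Xy, dy$out, model$params$dec_y$lik)
    } else {
      nb_recon(Xy, dy$out, model$params$dec_y$lik)
    }
    recon_loss <- recon_loss + recy$loss
    hy <- linear_backward(dy$top, model$params$dec_y$out, recy$dXhat)
    sy <- stack_backward(dy$cache, model$params$dec_y$stack, hy$dIn)
    grads$dec_y <- list(stack = sy$grads, out = hy$grads, lik = recy$dlik)
    dz <- dz + sy$dIn
  }

  # adversary (davae): classifier descends the domain cross-entropy, the
  # encoder ascends it (gradient reversal at z). The per-cell cross-entropy
  # is O(1) while the reconstruction term is O(#features), so the reversal is
  # scaled by lambda * #features to keep the two forces comparable across
  # data widths.
  adv_loss <- 0
  adv_scale <- cfg$adversarial_weight * ncol(X)
  if (kind == "davae") {
    af <- adversary_grad(model$params$adv, z, Bq)
    adv_loss <- af$loss
    grads$adv <- af$grads
    dz <- dz - adv_scale * af$dz
  }

  # KL(q || N(0, I)) term
  kl_loss <- sum(0.5 * (enc$mu^2 + exp(enc$lv) - enc$lv - 1)) / B
  beta <- cfg$kl_weight

  # gradients into the posterior heads
  dmu <- dz + beta * enc$mu / B
  dlv <- dz * eps * 0.5 * exp(enc$lv / 2) +
    beta * 0.5 * (exp(enc$lv) - 1) / B

  hm <- linear_backward(enc$top, model$params$enc$mu, dmu)
  hv <- linear_backward(enc$top, model$params$enc$lv, dlv)
  se <- stack_backward(enc$cache, model$params$enc$stack, hm$dIn + hv$dIn)
  grads$enc <- list(stack = se$grads, mu = hm$grads, lv = hv$grads)

  total <- recon_loss + beta * kl_loss + adv_scale * adv_loss
  list(
    components = c(total = total, recon = recon_loss, kl = kl_loss,
                   adv = adv_loss),
    grads = grads
  )
}

## ------------------------------------------------------------------
## Training loop
## ------------------------------------------------------------------

#' Train a variational model
#'
#' Seeded minibatch Adam optimization of a model built by the integration
#' fitters. Cells are processed in an order derived from the lexicographic
#' order of their names, so a fit is equivariant under permutation of the
#' input cells: permuting the rows of the data permutes the fitted latent
#' rows identically (up to floating-point summation noise).
#'
#' @param model a `vae_model` (built internally by the `fit_*` functions).
#' @param X cells x features numeric matrix (encoder input / view x).
#' @param batch factor of per-cell batch labels.
#' @param config a `training_config`.
#' @param obs_names per-cell identifiers (define the canonical RNG order).
#' @param Xy optional second view (multi-view model only).
#' @return an object of class `fitted_model`: the trained parameter store,
#'   the config echo, and `loss_trace`, a data.frame with one row per epoch
#'   and columns `epoch,total,recon,kl,adv`.
#' @export
vae_train <- function(model, X, batch, config, obs_names = NULL, Xy = NULL) {
  n <- nrow(X)
  if (n == 0) stop("parameter error: no cells to train on", call. = FALSE)
  if (ncol(X) != model$d_in && model$kind != "vimcca") {
    stop(sprintf(
      "feature dimension %d does not match model input %d",
      ncol(X), model$d_in
    ), call. = FALSE)
  }
  if (is.null(obs_names)) obs_names <- as.character(seq_len(n))
  Bq <- matrix(0, n, nlevels(batch))
  Bq[cbind(seq_len(n), as.integer(batch))] <- 1
  k <- config$latent_dim

  # canonical cell order: independent of the input row order
  canon <- order(obs_names)

  withr::local_seed(config$seed)
  # (re)initialize parameters inside the seeded scope for reproducibility
  model$params <- build_vae_model(
    model$kind, model$d_in, config, model$n_batches,
    model$d_out_x, if (!is.null(model$d_out_y)) model$d_out_y else model$d_in
  )$params
  if (model$kind != "vimcca") model$params$dec_y <- NULL

  # the adversary trains in its own inner loop (alternating updates), so it
  # keeps a separate optimizer state from the encoder/decoder parameters
  has_adv <- model$kind == "davae"
  main_names <- setdiff(names(model$params), "adv")
  opt <- adam_init(model$params[main_names])
  if (has_adv) adv_opt <- adam_init(model$params$adv)
  trace <- matrix(0, config$epochs, 4,
                  dimnames = list(NULL, c("total", "recon", "kl", "adv")))

  for (epoch in seq_len(config$epochs)) {
    perm <- canon[sample.int(n)]
    starts <- seq(1, n, by = config$batch_size)
    acc <- c(total = 0, recon = 0, kl = 0, adv = 0)
    for (s in starts) {
      idx <- perm[s:min(s + config$batch_size - 1, n)]
      nb <- length(idx)
      Xb <- X[idx, , drop = FALSE]
      Bb <- Bq[idx, , drop = FALSE]
      eps <- matrix(stats::rnorm(nb * k), nb, k)
      if (has_adv && config$adv_steps > 0) {
        # classifier catches up on the current (frozen) latent sample
        encb <- encode_cells(model, Xb)
        zfix <- encb$mu + exp(encb$lv / 2) * eps
        for (it in seq_len(config$adv_steps)) {
          ag <- adversary_grad(model$params$adv, zfix, Bb)
          st2 <- adam_step(model$params$adv, ag$grads, adv_opt,
                           config$learning_rate)
          model$params$adv <- st2$params
          adv_opt <- st2$state
        }
      }
      lg <- vae_loss_grad(
        model, Xb, Bb, eps,
        if (!is.null(Xy)) Xy[idx, , drop = FALSE]
      )
      if (any(!is.finite(lg$components))) {
        stop(sprintf(
          "divergence error: non-finite loss at epoch %d (learning_rate %g)",
          epoch, config$learning_rate
        ), call. = FALSE)
      }
      acc <- acc + lg$components * nb
      st <- adam_step(model$params[main_names], lg$grads[main_names], opt,
                      config$learning_rate)
      model$params[main_names] <- st$params
      opt <- st$state
      if (has_adv && config$adv_steps == 0) {
        # pure gradient-reversal variant: one simultaneous step
        st3 <- adam_step(model$params$adv, lg$grads$adv, adv_opt,
                         config$learning_rate)
        model$params$adv <- st3$params
        adv_opt <- st3$state
      }
    }
    trace[epoch, ] <- acc / n
  }

  structure(
    list(
      kind = model$kind,
      params = model$params,
      config = config,
      dec_cond = model$dec_cond,
      d_in = model$d_in,
      n_batches = model$n_batches,
      d_out_x = model$d_out_x,
      d_out_y = model$d_out_y,
      batch_levels = levels(batch),
      loss_trace = data.frame(epoch = seq_len(config$epochs), trace)
    ),
    class = "fitted_model"
  )
}

#' @export
print.fitted_model <- function(x, ...) {
  last <- x$loss_trace[nrow(x$loss_trace), ]
  cat(sprintf(
    "fitted %s model: %d epochs, final loss %.4f (recon %.4f, kl %.4f)\n",
    x$kind, nrow(x$loss_trace), last$total, last$recon, last$kl
  ))
  invisible(x)
}

# Posterior for all cells under a fitted model (deterministic forward pass).
posterior_of <- function(fit, X, Xy = NULL) {
  m <- list(kind = fit$kind, params = fit$params)
  enc_in <- if (fit$kind == "vimcca") cbind(X, Xy) else X
  enc <- encode_cells(m, enc_in)
  variational_posterior(enc$mu, enc$lv)
}

# Decode latent points; batch_code (factor level index, 1-based) selects the
# one-hot condition for the batch-conditioned decoder.
decode_latent <- function(fit, Z, batch_code = 1L, view = "dec_x") {
  m <- list(kind = fit$kind, params = fit$params)
  dec_in <- if (isTRUE(fit$dec_cond)) {
    oh <- matrix(0, nrow(Z), fit$n_batches)
    oh[, batch_code] <- 1
    cbind(Z, oh)
  } else {
    Z
  }
  out <- decode_cells(m, dec_in, view)$out
  if (fit$config$likelihood == "negative_binomial") out <- exp(pmin(out, 30))
  out
}
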