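ns <- asNamespace("scunify")

test_that("KL to the standard normal matches closed form and a Monte-Carlo oracle", {
  k <- 4
  zero <- variational_posterior(matrix(0, 3, k), matrix(0, 3, k))
  expect_equal(kl_standard_normal(zero), rep(0, 3))

  one <- variational_posterior(matrix(1, 1, 1), matrix(0, 1, 1))
  expect_equal(kl_standard_normal(one), 0.5)

  # Monte-Carlo oracle: E_q[log q(z) - log p(z)] with 1e5 draws
  set.seed(42)
  mu <- rnorm(k)
  lv <- rnorm(k, sd = 0.5)
  post <- variational_posterior(matrix(mu, 1), matrix(lv, 1))
  z <- matrix(rnorm(1e5 * k, mean = rep(mu, each = 1e5),
                    sd = rep(exp(lv / 2), each = 1e5)), ncol = k)
  logq <- rowSums(dnorm(z, rep(mu, each = 1e5), rep(exp(lv / 2), each = 1e5),
                        log = TRUE))
  logp <- rowSums(dnorm(z, log = TRUE))
  mc <- mean(logq - logp)
  expect_lt(abs(kl_standard_normal(post) - mc) / mc, 0.01)
})

test_that("reconstruction log-likelihoods match closed forms and the Poisson limit", {
  k <- 6
  x <- rnorm(k)
  expect_equal(
    reconstruction_loglik(x, list(mean = x, var = 1), "gaussian"),
    -(k / 2) * log(2 * pi)
  )

  # NB at zero: theta * log(theta / (theta + m))
  m <- 3.7; theta <- 1.4
  expect_equal(
    reconstruction_loglik(0, list(mean = m, dispersion = theta),
                          "negative_binomial"),
    theta * log(theta / (theta + m))
  )
  expect_error(
    reconstruction_loglik(1.5, list(mean = 1, dispersion = 1),
                          "negative_binomial"),
    "integer"
  )

  # Poisson limit: theta = 1e6 matches Poisson log-pmf within 1e-3
  for (xx in c(0, 3, 20)) for (mm in c(0.5, 10)) {
    expect_lt(
      abs(reconstruction_loglik(xx, list(mean = mm, dispersion = 1e6),
                                "negative_binomial") -
            dpois(xx, mm, log = TRUE)),
      1e-3
    )
  }
})

test_that("reparameterized sampling is seeded and converges to the posterior", {
  post <- variational_posterior(matrix(1:6 / 2, 2, 3),
                                matrix(-60, 2, 3))
  z <- reparameterized_sample(post, seed = 1)
  expect_lt(max(abs(z - post$mean)), 1e-10) # near-zero variance

  post2 <- variational_posterior(matrix(0.3, 2, 3), matrix(log(0.8), 2, 3))
  expect_identical(reparameterized_sample(post2, 7),
                   reparameterized_sample(post2, 7))

  # sample variance over 1e4 draws within 5% of exp(logvar)
  post3 <- variational_posterior(matrix(0, 1, 2),
                                 matrix(c(log(0.5), log(2)), 1, 2))
  draws <- vapply(seq_len(1e4),
                  function(s) reparameterized_sample(post3, s)[1, ],
                  numeric(2))
  expect_lt(max(abs(apply(draws, 1, var) / c(0.5, 2) - 1)), 0.05)
})

test_that("backprop gradients match central finite differences", {
  # the independent oracle for the entire training machinery
  set.seed(5)
  cfg <- training_config(latent_dim = 3, hidden_sizes = c(5, 4),
                         kl_weight = 0.7, adversarial_weight = 0.9, seed = 5)
  n <- 6; d <- 7; dy <- 4
  X <- matrix(rnorm(n * d), n, d)
  Y <- matrix(rnorm(n * dy), n, dy)
  Bq <- diag(2)[rep(1:2, length.out = n), ]
  h <- 1e-5

  num_grad <- function(model, get, set, f) {
    p0 <- get(model$params)
    g <- p0 * 0
    for (i in seq_along(p0)) {
      pa <- set(model$params, i, p0[i] + h)
      pb <- set(model$params, i, p0[i] - h)
      g[i] <- (f(pa) - f(pb)) / (2 * h)
    }
    g
  }

  for (kind in c("cvae", "davae", "vimcca")) {
    d_in <- if (kind == "vimcca") d + dy else d
    model <- ns$build_vae_model(kind, d_in, cfg, n_batches = 2,
                                d_out_x = d, d_out_y = dy)
    eps <- matrix(rnorm(n * 3), n, 3)
    Xy <- if (kind == "vimcca") Y
    lg <- ns$vae_loss_grad(model, X, Bq, eps, Xy)
    comp <- function(p, what) {
      m <- model; m$params <- p
      ns$vae_loss_grad(m, X, Bq, eps, Xy)$components[[what]]
    }
    # decoder weights against the total loss
    gd <- num_grad(model,
                   function(p) p$dec_x$out$W,
                   function(p, i, v) { p$dec_x$out$W[i] <- v; p },
                   function(p) comp(p, "total"))
    expect_lt(max(abs(gd - lg$grads$dec_x$out$W)), 1e-6)
    # per-feature likelihood parameter
    gl <- num_grad(model,
                   function(p) p$dec_x$lik,
                   function(p, i, v) { p$dec_x$lik[i] <- v; p },
                   function(p) comp(p, "total"))
    expect_lt(max(abs(gl - lg$grads$dec_x$lik)), 1e-6)
    # encoder: for davae the objective is recon + beta*KL - lambda*d*adv
    # (gradient reversal); otherwise the total
    enc_obj <- if (kind == "davae") {
      function(p) comp(p, "recon") + cfg$kl_weight * comp(p, "kl") -
        cfg$adversarial_weight * d * comp(p, "adv")
    } else {
      function(p) comp(p, "total")
    }
    ge <- num_grad(model,
                   function(p) p$enc$stack[[1]]$W,
                   function(p, i, v) { p$enc$stack[[1]]$W[i] <- v; p },
                   enc_obj)
    expect_lt(max(abs(ge - lg$grads$enc$stack[[1]]$W)), 1e-5)
    if (kind == "davae") {
      ga <- num_grad(model,
                     function(p) p$adv$out$W,
                     function(p, i, v) { p$adv$out$W[i] <- v; p },
                     function(p) comp(p, "adv"))
      expect_lt(max(abs(ga - lg$grads$adv$out$W)), 1e-6)
    }
    if (kind == "vimcca") {
      gy <- num_grad(model,
                     function(p) p$dec_y$out$W,
                     function(p, i, v) { p$dec_y$out$W[i] <- v; p },
                     function(p) comp(p, "total"))
      expect_lt(max(abs(gy - lg$grads$dec_y$out$W)), 1e-6)
    }
  }
})

test_that("NB training gradient matches finite differences", {
  set.seed(9)
  cfg <- training_config(latent_dim = 2, hidden_sizes = 4,
                         likelihood = "negative_binomial", seed = 9)
  n <- 5; d <- 6
  X <- matrix(rpois(n * d, 3), n, d)
  Bq <- diag(2)[rep(1:2, length.out = n), ]
  model <- ns$build_vae_model("cvae", d, cfg, n_batches = 2)
  eps <- matrix(rnorm(n * 2), n, 2)
  lg <- ns$vae_loss_grad(model, X, Bq, eps)
  h <- 1e-5
  f <- function(p) {
    m <- model; m$params <- p
    ns$vae_loss_grad(m, X, Bq, eps)$components[["recon"]]
  }
  p0 <- model$params$dec_x$lik
  g <- p0 * 0
  for (i in seq_along(p0)) {
    pa <- model$params; pa$dec_x$lik[i] <- p0[i] + h
    pb <- model$params; pb$dec_x$lik[i] <- p0[i] - h
    g[i] <- (f(pa) - f(pb)) / (2 * h)
  }
  expect_lt(max(abs(g - lg$grads$dec_x$lik)), 1e-6)
})

test_that("training is seeded, records a full trace, and reduces the loss", {
  pair <- small_integration_pair(seed = 4, n_cells = 20, n_genes = 15)
  cfg <- fast_config(epochs = 1, seed = 2)
  r1 <- fit_vipcca(pair$datasets, cfg)
  expect_equal(nrow(r1$model$loss_trace), 1)

  cfg <- fast_config(epochs = 4, seed = 2)
  r2 <- fit_vipcca(pair$datasets, cfg)
  r3 <- fit_vipcca(pair$datasets, cfg)
  expect_equal(r2$model$loss_trace, r3$model$loss_trace, tolerance = 1e-6)

  # 300-cell autoencodable data, 30 epochs: loss decreases end to end
  pair <- small_integration_pair(seed = 8, n_cells = 150, n_genes = 30)
  cfg <- training_config(latent_dim = 8, hidden_sizes = c(32, 16),
                         epochs = 30, seed = 1)
  fit <- fit_vipcca(pair$datasets, cfg)
  tr <- fit$model$loss_trace
  expect_lt(tr$total[nrow(tr)], tr$total[1])
})

test_that("reported epoch loss decomposes into its weighted terms", {
  pair <- small_integration_pair(seed = 6, n_cells = 25, n_genes = 20)
  cfg <- fast_config(seed = 3, kl_weight = 0.6, adversarial_weight = 0.2)
  for (fitfun in list(fit_vipcca, fit_davae)) {
    tr <- fitfun(pair$datasets, cfg)$model$loss_trace
    n_feat <- 20
    recombined <- tr$recon + cfg$kl_weight * tr$kl +
      cfg$adversarial_weight * n_feat * tr$adv
    expect_equal(tr$total, recombined, tolerance = 1e-6)
  }
})

test_that("zero-weight terms reduce the model to a plain autoencoder", {
  pair <- small_integration_pair(seed = 10, n_cells = 20, n_genes = 15)
  cfg0 <- fast_config(seed = 5, kl_weight = 0, adversarial_weight = 0)
  tr <- fit_davae(pair$datasets, cfg0)$model$loss_trace
  # KL and adversarial columns are recorded but unweighted
  expect_equal(tr$total, tr$recon, tolerance = 1e-8)
  expect_true(all(tr$kl >= 0))

  # with lambda = 0 the encoder/decoder path is identical whether the
  # adversary trains in its inner loop or in a simultaneous step
  cfg1 <- fast_config(seed = 5, kl_weight = 1, adversarial_weight = 0,
                      adv_steps = 5)
  cfg2 <- fast_config(seed = 5, kl_weight = 1, adversarial_weight = 0,
                      adv_steps = 0)
  t1 <- fit_davae(pair$datasets, cfg1)$model$loss_trace
  t2 <- fit_davae(pair$datasets, cfg2)$model$loss_trace
  expect_equal(t1$recon, t2$recon, tolerance = 1e-6)
  expect_equal(t1$kl, t2$kl, tolerance = 1e-6)
})

test_that("KL term is invariant to permuting cells", {
  set.seed(3)
  post <- variational_posterior(matrix(rnorm(40), 10, 4),
                                matrix(rnorm(40, sd = 0.3), 10, 4))
  kl <- kl_standard_normal(post)
  perm <- sample(10)
  post_p <- variational_posterior(post$mean[perm, ], post$logvar[perm, ])
  expect_equal(kl_standard_normal(post_p), kl[perm])
})

test_that("training diverges loudly rather than silently", {
  pair <- small_integration_pair(seed = 12, n_cells = 15, n_genes = 10)
  cfg <- fast_config(seed = 1, learning_rate = 1e6, epochs = 10)
  expect_error(fit_vipcca(pair$datasets, cfg), "divergence error.*epoch")
})

test_that("training config round-trips through YAML; trace writes as CSV", {
  cfg <- training_config(latent_dim = 9, epochs = 7, seed = 123,
                         likelihood = "negative_binomial")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_training_config(cfg, path)
  back <- read_training_config(path)
  expect_equal(unclass(back), unclass(cfg))

  trace <- data.frame(epoch = 1:2, total = c(2, 1), recon = c(1.5, 0.7),
                      kl = c(0.5, 0.3), adv = c(0, 0))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_loss_trace(trace, csv)
  expect_equal(utils::read.csv(csv), trace)
})
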