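#' Configuration of the spatially-variable-gene test
#'
#' @param lengthscale_grid positive numeric vector of kernel lengthscales to
#'   profile over. `NULL` (default) means 10 log-spaced values spanning the
#'   range from the smallest non-zero pairwise spot distance to the largest,
#'   computed from the data at run time.
#' @param p_mode `"mixture_chi2"` (default; boundary-corrected 50:50 mixture
#'   of a point mass at 0 and chi-squared with 1 df) or `"permutation"`
#'   (assumption-free fallback permuting spot coordinates).
#' @param n_permutations permutation count (>= 20; default 200).
#' @param jitter diagonal jitter added for numerical stability (default 1e-6).
#' @param fdr_alpha significance level on BH-adjusted q-values (default 0.05).
#' @return an object of class `visgp_config`.
#' @export
visgp_config <- function(lengthscale_grid = NULL,
                         p_mode = c("mixture_chi2", "permutation"),
                         n_permutations = 200,
                         jitter = 1e-6,
                         fdr_alpha = 0.05) {
  p_mode <- match.arg(p_mode)
  if (!is.null(lengthscale_grid)) {
    if (length(lengthscale_grid) == 0 || any(lengthscale_grid <= 0)) {
      stop("parameter error: lengthscale_grid must be non-empty and positive",
           call. = FALSE)
    }
  }
  if (n_permutations < 20) {
    stop("parameter error: n_permutations must be >= 20", call. = FALSE)
  }
  structure(
    list(lengthscale_grid = lengthscale_grid, p_mode = p_mode,
         n_permutations = as.integer(n_permutations), jitter = jitter,
         fdr_alpha = fdr_alpha),
    class = "visgp_config"
  )
}

#' Squared-exponential kernel over spot coordinates
#'
#' `K_ij = exp(-||s_i - s_j||^2 / (2 * lengthscale^2))`: symmetric with unit
#' diagonal; covariance decays with squared distance.
#'
#' @param coords spots x 2 numeric matrix.
#' @param lengthscale positive kernel lengthscale (coordinate units).
#' @return spots x spots covariance matrix.
#' @export
se_kernel <- function(coords, lengthscale) {
  if (!is.numeric(lengthscale) || length(lengthscale) != 1 ||
      lengthscale <= 0) {
    stop("parameter error: lengthscale must be positive", call. = FALSE)
  }
  coords <- as.matrix(coords)
  d2 <- unname(as.matrix(stats::dist(coords)))^2
  exp(-d2 / (2 * lengthscale^2))
}

#' Gaussian-process log marginal likelihood
#'
#' Log density of `y ~ N(mu * 1, sigma2_s * K + sigma2_n * I)`, evaluated
#' exactly via Cholesky factorization with jitter escalation (up to 1e-3) on
#' failure.
#'
#' @param y numeric spot vector.
#' @param K spots x spots kernel matrix.
#' @param sigma2_s spatial variance component (>= 0).
#' @param sigma2_n noise variance component (> 0).
#' @param mu scalar mean.
#' @param jitter initial diagonal jitter (default 0).
#' @return scalar log marginal likelihood.
#' @export
gp_log_marginal <- function(y, K, sigma2_s, sigma2_n, mu, jitter = 0) {
  n <- length(y)
  stopifnot(nrow(K) == n, ncol(K) == n, sigma2_s >= 0, sigma2_n > 0)
  Sigma <- sigma2_s * K + diag(sigma2_n, n)
  j <- jitter
  repeat {
    L <- tryCatch(chol(Sigma + diag(j, n)), error = function(e) NULL)
    if (!is.null(L)) break
    j <- if (j == 0) 1e-8 else j * 10
    if (j > 1e-3) {
      stop("conditioning error: Cholesky failed after jitter escalation",
           call. = FALSE)
    }
  }
  r <- y - mu
  alpha <- backsolve(L, forwardsolve(t(L), r))
  -0.5 * (sum(r * alpha) + 2 * sum(log(diag(L))) + n * log(2 * pi))
}

## ------------------------------------------------------------------
## Profiled likelihood-ratio machinery
## ------------------------------------------------------------------

default_lengthscale_grid <- function(coords, n_grid = 10) {
  d <- stats::dist(as.matrix(coords))
  d <- d[d > 0]
  if (length(d) == 0) stop("all spots coincide", call. = FALSE)
  exp(seq(log(min(d)), log(max(d)), length.out = n_grid))
}

# Eigendecompositions of the kernel at each grid lengthscale, shared across
# genes for a fixed set of coordinates.
spatial_basis <- function(coords, cfg) {
  grid <- cfg$lengthscale_grid
  if (is.null(grid)) grid <- default_lengthscale_grid(coords)
  basis <- lapply(grid, function(ell) {
    K <- se_kernel(coords, ell)
    e <- eigen(K + diag(cfg$jitter, nrow(K)), symmetric = TRUE)
    yproj <- NULL
    list(lengthscale = ell, values = pmax(e$values, 0),
         U = e$vectors, ones = crossprod(e$vectors, rep(1, nrow(K)))[, 1])
  })
  list(grid = grid, basis = basis, n = nrow(as.matrix(coords)))
}

# Profile log-likelihood at one lengthscale: with delta = sigma2_n/sigma2_s,
# mu and sigma2_s have closed-form MLEs in the eigenbasis; delta is optimized
# numerically on a bounded log grid. Returns the maximized log-lik and the
# implied variance components.
profile_loglik_at <- function(yproj, ones, lambda, n) {
  obj <- function(logdelta) {
    delta <- exp(logdelta)
    w <- 1 / (lambda + delta)
    denom <- sum(w * ones^2)
    mu <- if (denom > 0) sum(w * ones * yproj) / denom else 0
    r <- yproj - mu * ones
    s2 <- sum(w * r^2) / n
    if (s2 <= 0) s2 <- .Machine$double.eps
    -0.5 * (n * log(s2) + sum(log(lambda + delta)) + n + n * log(2 * pi))
  }
  opt <- stats::optimize(function(ld) -obj(ld), interval = c(-10, 10))
  logdelta <- opt$minimum
  # recover components at the optimum
  delta <- exp(logdelta)
  w <- 1 / (lambda + delta)
  denom <- sum(w * ones^2)
  mu <- if (denom > 0) sum(w * ones * yproj) / denom else 0
  r <- yproj - mu * ones
  s2s <- sum(w * r^2) / n
  list(loglik = -opt$objective, sigma2_s = s2s, sigma2_n = delta * s2s,
       mu = mu, delta = delta)
}

null_loglik <- function(y) {
  n <- length(y)
  mu <- mean(y)
  s2 <- mean((y - mu)^2)
  if (s2 <= 0) return(NA_real_)
  -0.5 * (n * log(2 * pi * s2) + n)
}

fit_gene_core <- function(y, sb) {
  n <- sb$n
  sdy <- stats::sd(y)
  degenerate_result <- function() {
    list(llr = 0, p = 1, lengthscale = NA_real_, fsv = 0, degenerate = TRUE)
  }
  if (!is.finite(sdy) || sdy == 0) return(degenerate_result())
  ys <- (y - mean(y)) / sdy
  L0 <- null_loglik(ys)
  best <- list(loglik = -Inf)
  best_ell <- NA_real_
  for (b in sb$basis) {
    yproj <- crossprod(b$U, ys)[, 1]
    pr <- profile_loglik_at(yproj, b$ones, b$values, n)
    if (pr$loglik > best$loglik) {
      best <- pr
      best_ell <- b$lengthscale
    }
  }
  llr <- max(best$loglik - L0, 0)
  list(llr = llr, p = NA_real_, lengthscale = best_ell,
       fsv = 1 / (1 + best$delta), degenerate = FALSE)
}

mixture_chi2_p <- function(llr) {
  if (llr <= 0) return(1)
  0.5 * stats::pchisq(2 * llr, df = 1, lower.tail = FALSE)
}

#' Test one gene for spatial variability
#'
#' Gaussian-process likelihood-ratio test. The gene's (lognorm) expression is
#' standardized, then the null model (iid noise: `sigma2_s = 0`, closed-form
#' MLE) is compared against the spatial alternative
#' `y ~ N(mu, sigma2_s K(ell) + sigma2_n I)` maximized over the lengthscale
#' grid with variance components profiled at each grid point. The statistic is
#' `llr = max_ell L1 - L0`, clipped at 0. P-values use the boundary-corrected
#' 50:50 mixture of a point mass at 0 and chi-squared(1), or a coordinate
#' permutation null.
#'
#' @param y numeric expression vector over spots (lognorm scale).
#' @param coords spots x 2 coordinate matrix.
#' @param cfg a [visgp_config()].
#' @param seed seed for the permutation null (permutation mode only).
#' @return a one-row data.frame with `llr`, `p`, `lengthscale`, `fsv`
#'   (spatial fraction of variance) and `degenerate`.
#' @export
fit_gene <- function(y, coords, cfg = visgp_config(), seed = 0) {
  sb <- spatial_basis(coords, cfg)
  res <- fit_gene_core(y, sb)
  res$p <- gene_pvalue(y, res, sb, cfg, seed)
  as.data.frame(res)
}

gene_pvalue <- function(y, res, sb, cfg, seed) {
  if (res$degenerate) return(1)
  if (cfg$p_mode == "mixture_chi2") return(mixture_chi2_p(res$llr))
  perm_stats <- withr::with_seed(seed, {
    vapply(seq_len(cfg$n_permutations), function(i) {
      fit_gene_core(y[sample.int(length(y))], sb)$llr
    }, numeric(1))
  })
  (1 + sum(perm_stats >= res$llr)) / (1 + cfg$n_permutations)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a p-value vector, mapped back to
#' input order and capped at 1.
#'
#' @param pvals numeric p-values in (0, 1].
#' @return adjusted q-values in input order.
#' @export
bh_adjust <- function(pvals) {
  stats::p.adjust(pvals, method = "BH")
}

#' Scan a spatial dataset for spatially variable genes
#'
#' The full pipeline: drop features and spots with total counts below 10,
#' library-normalize and log-transform, test every gene with [fit_gene()]
#' (sharing the kernel eigendecompositions across genes), BH-adjust, and rank
#' by ascending p (ties by descending llr).
#'
#' @param sds an `omics_dataset` with spatial coordinates, counts layer.
#' @param cfg a [visgp_config()].
#' @param seed permutation seed (permutation mode).
#' @param min_counts filter threshold on feature and spot totals (default 10).
#' @return a data.frame with one row per tested gene: `gene`, `llr`,
#'   `lengthscale`, `fsv`, `p`, `q`, `significant` (q below `fdr_alpha`),
#'   `degenerate`.
#' @export
run_visgp <- function(sds, cfg = visgp_config(), seed = 0, min_counts = 10) {
  stopifnot(inherits(sds, "omics_dataset"))
  if (is.null(sds$coords)) {
    stop("validation error: spatial coordinates required", call. = FALSE)
  }
  if (sds$layer_state != "counts") {
    stop("run_visgp expects the counts layer", call. = FALSE)
  }
  ds <- filter_features(sds, min_counts)
  ds <- filter_observations(ds, min_counts)
  if (nrow(ds$counts) < 3) {
    stop("empty result: fewer than 3 spots after filtering", call. = FALSE)
  }
  ds <- normalize_log(ds)
  sb <- spatial_basis(ds$coords, cfg)
  rows <- lapply(seq_len(ncol(ds$counts)), function(j) {
    res <- fit_gene_core(ds$counts[, j], sb)
    res$p <- gene_pvalue(ds$counts[, j], res, sb, cfg, seed + j)
    res
  })
  out <- data.frame(
    gene = ds$var_names,
    llr = vapply(rows, `[[`, numeric(1), "llr"),
    lengthscale = vapply(rows, `[[`, numeric(1), "lengthscale"),
    fsv = vapply(rows, `[[`, numeric(1), "fsv"),
    p = vapply(rows, `[[`, numeric(1), "p"),
    degenerate = vapply(rows, `[[`, logical(1), "degenerate"),
    stringsAsFactors = FALSE
  )
  out$q <- bh_adjust(out$p)
  out$significant <- out$q < cfg$fdr_alpha
  out[order(out$p, -out$llr), c("gene", "llr", "lengthscale", "fsv",
                                "p", "q", "significant", "degenerate")]
}
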