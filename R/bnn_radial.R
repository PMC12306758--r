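# Variational Bayesian neural network with radial weight posteriors.
#
# Each parameter tensor carries a location mu and a positive scale sigma
# (softplus of an unconstrained parameter). A posterior draw is
#   w = mu + sigma * (eps / ||eps||) * r,
# with eps standard normal of the tensor's dimension and r a scalar
# standard normal: the noise direction is uniform on the sphere and the
# radius |r| is that of a 1-D Gaussian, which avoids the "soap-bubble"
# concentration of high-dimensional mean-field Gaussians. Training
# maximizes the ELBO: Monte-Carlo expected Bernoulli log-likelihood minus
# a weighted KL divergence to a factorized Gaussian weight prior, the KL
# estimated as the (analytic) negative entropy of the radial posterior
# plus a Monte-Carlo cross-entropy against the prior.

# Differential entropy of the unit radial distribution in d dimensions
# (sigma = 1): direction uniform on the sphere, radius |r|, r ~ N(0,1).
radial_entropy_const <- function(d) {
  if (d == 1L) return(0.5 * log(2 * pi) + 0.5)
  elog_abs_r <- -(0.57721566490153286 + log(2)) / 2 # E[log |r|], r ~ N(0,1)
  log_sphere <- log(2) + (d / 2) * log(pi) - lgamma(d / 2)
  -log(2) + 0.5 * log(2 * pi) + 0.5 + log_sphere + (d - 1) * elog_abs_r
}

bnn_param_template <- function(d_in, config) {
  # mirror the linear-head network parameter structure
  net <- net_init(d_in, config)
  net_get_params(net)
}

#' Initialize a radial variational state
#'
#' @param d_in Input dimensionality.
#' @param config A [train_config()] with `head = "linear"`.
#' @param prior_scale Standard deviation of the factorized Gaussian weight
#'   prior.
#' @param sigma0 Initial posterior scale (small, so training starts near a
#'   deterministic Kaiming-initialized network).
#' @return A `radial_state` with `mu`, `rho` (unconstrained scales),
#'   prior scale and the template network used for forward passes.
#' @export
radial_init <- function(d_in, config, prior_scale = 1, sigma0 = 0.05) {
  stopifnot(config$head == "linear", prior_scale > 0, sigma0 > 0)
  mu <- bnn_param_template(d_in, config)
  rho <- rapply(mu, function(x) x * 0 + inv_softplus(sigma0),
                how = "replace")
  structure(list(mu = mu, rho = rho, prior_scale = prior_scale,
                 d_in = d_in, config = config,
                 template = net_init(d_in, config)),
            class = "radial_state")
}

# Draw direction tensors (eps_hat * r) for every parameter array.
radial_directions <- function(mu) {
  rapply(mu, function(x) {
    eps <- stats::rnorm(length(x))
    if (!is.null(dim(x))) dim(eps) <- dim(x)
    nrm <- sqrt(sum(eps^2))
    if (nrm == 0) eps else eps / nrm * stats::rnorm(1L)
  }, how = "replace")
}

#' Sample one weight realization from a radial state
#'
#' @param state A `radial_state`.
#' @param seed Integer seed for the draw.
#' @return List with the sampled parameter set `w` and the noise
#'   directions `dir` (`w = mu + softplus(rho) * dir`).
#' @export
sample_weights <- function(state, seed) {
  dir <- with_seed(seed, radial_directions(state$mu))
  sigma <- rapply(state$rho, softplus, how = "replace")
  w <- map2_params(state$mu, map2_params(sigma, dir, `*`), `+`)
  list(w = w, dir = dir, sigma = sigma)
}

# elementwise binary op over two identically shaped nested param lists
map2_params <- function(a, b, f) {
  if (is.list(a)) {
    out <- Map(function(x, y) map2_params(x, y, f), a, b)
    out
  } else {
    f(a, b)
  }
}

sum_params <- function(p, f = identity) {
  if (is.list(p)) sum(vapply(p, sum_params, numeric(1), f = f)) else sum(f(p))
}

param_leaves <- function(p) {
  if (is.list(p)) unlist(lapply(p, param_leaves), recursive = FALSE)
  else list(p)
}

#' Negative ELBO objective and its gradients
#'
#' `loss = -(MC expected log-likelihood - kl_weight * KL(q || p))`, with
#' the likelihood term the mean Bernoulli log-likelihood over the batch
#' averaged over `n_draws` weight draws, and the KL term the analytic
#' negative entropy of the radial posterior plus a Monte-Carlo
#' cross-entropy against the Gaussian prior (an unbiased KL estimate,
#' non-negative in expectation).
#'
#' @param state A `radial_state`.
#' @param X,y Batch design matrix and labels.
#' @param seed Seed controlling the weight draw(s).
#' @param n_draws Monte-Carlo draws per evaluation (default 1).
#' @param kl_weight Non-negative KL weight (default `1 / nrow(X)`; for
#'   minibatch training pass `1 / n_train`).
#' @return List with `loss`, `kl` (the MC KL estimate), `lik` (mean
#'   cross-entropy part) and gradients `grad$mu`, `grad$rho`.
#' @export
elbo_objective <- function(state, X, y, seed, n_draws = 1L,
                           kl_weight = NULL) {
  if (nrow(X) == 0L) stop("empty batch")
  if (is.null(kl_weight)) kl_weight <- 1 / nrow(X)
  stopifnot(kl_weight >= 0, n_draws >= 1L)
  sigma <- rapply(state$rho, softplus, how = "replace")
  dsig <- rapply(state$rho, stats::plogis, how = "replace") # d sigma / d rho
  s2 <- state$prior_scale^2
  # analytic entropy H(q) = sum log sigma + sum_d H_unit(d); its gradient
  # lives purely on rho
  ent_const <- sum(vapply(param_leaves(state$mu), function(x) {
    radial_entropy_const(length(x))
  }, numeric(1)))
  entropy <- sum_params(sigma, log) + ent_const
  g_mu <- rapply(state$mu, function(x) x * 0, how = "replace")
  g_rho <- g_mu
  lik <- 0
  cross_ent <- 0
  for (dr in seq_len(n_draws)) {
    sw <- sample_weights(state, derive_seed(seed, dr))
    net <- net_set_params(state$template, sw$w)
    net$config$ridge <- 0
    lg <- net_loss_grad(net, X, y)
    if (!is.finite(lg$loss)) stop("non-finite likelihood term")
    lik <- lik + lg$loss / n_draws
    # -log p(w) = sum 0.5 log(2 pi s2) + w^2 / (2 s2)
    ce_draw <- sum_params(sw$w, function(w) {
      0.5 * log(2 * pi * s2) + w^2 / (2 * s2)
    })
    cross_ent <- cross_ent + ce_draw / n_draws
    # likelihood grads chain to mu directly and to rho via dir * dsigma
    g_mu <- map2_params(g_mu, lg$grad, function(a, b) a + b / n_draws)
    g_rho <- map2_params(
      g_rho,
      map2_params(map2_params(lg$grad, sw$dir, `*`), dsig, `*`),
      function(a, b) a + b / n_draws)
    # prior cross-entropy grads: d(-log p)/dw = w / s2
    gw <- rapply(sw$w, function(w) w / s2 * kl_weight / n_draws,
                 how = "replace")
    g_mu <- map2_params(g_mu, gw, `+`)
    g_rho <- map2_params(g_rho, map2_params(map2_params(gw, sw$dir, `*`),
                                            dsig, `*`), `+`)
  }
  kl <- -entropy + cross_ent
  if (!is.finite(kl)) stop("non-finite KL term")
  # entropy gradient: d(-H)/drho = -(1/sigma) * dsigma/drho
  g_rho <- map2_params(
    g_rho,
    map2_params(sigma, dsig, function(s, d) -kl_weight * d / s),
    `+`)
  list(loss = lik + kl_weight * kl, lik = lik, kl = kl,
       grad = list(mu = g_mu, rho = g_rho))
}

#' Train a radial Bayesian neural network by maximizing the ELBO
#'
#' Adam on the variational parameters with one weight draw per step;
#' early stopping monitors the validation cross-entropy of the posterior
#' location network (`w = mu`).
#'
#' @param X,y Training design matrix and labels.
#' @param Xval,yval Validation data.
#' @param config A [train_config()] (`head = "linear"`).
#' @param prior_scale Gaussian prior standard deviation (default 1).
#' @param sigma0 Initial posterior scale.
#' @param n_draws Monte-Carlo draws per objective evaluation.
#' @param kl_weight KL weight; default `1 / nrow(X)` (per-record scaling).
#' @return A `bnn_model` with the fitted state and training trace.
#' @export
train_bnn <- function(X, y, Xval, yval, config, prior_scale = 1,
                      sigma0 = 0.05, n_draws = 1L, kl_weight = NULL) {
  state <- radial_init(ncol(X), config, prior_scale, sigma0)
  if (is.null(kl_weight)) kl_weight <- 1 / nrow(X)
  n <- nrow(X)
  bs <- min(config$batch_size, n)
  params <- list(mu = state$mu, rho = state$rho)
  m <- adam_state_like(params)
  v <- adam_state_like(params)
  t <- 0L
  best_val <- Inf
  best_params <- params
  best_epoch <- 0L
  since_best <- 0L
  trace <- data.frame(epoch = integer(), train_loss = numeric(),
                      val_loss = numeric())
  for (epoch in seq_len(config$max_epochs)) {
    idx_order <- if (bs < n) {
      with_seed(derive_seed(config$seed, 2000L + epoch), sample.int(n))
    } else {
      seq_len(n)
    }
    starts <- seq(1L, n, by = bs)
    epoch_loss <- 0
    for (s in starts) {
      take <- idx_order[s:min(s + bs - 1L, n)]
      t <- t + 1L
      ob <- elbo_objective(state, X[take, , drop = FALSE], y[take],
                           seed = derive_seed(config$seed, 30000L + t),
                           n_draws = n_draws, kl_weight = kl_weight)
      epoch_loss <- epoch_loss + ob$loss * length(take)
      upd <- adam_update(params, list(mu = ob$grad$mu, rho = ob$grad$rho),
                         m, v, t, config)
      m <- upd$m
      v <- upd$v
      params <- upd$p
      state$mu <- params$mu
      state$rho <- params$rho
    }
    mu_net <- net_set_params(state$template, state$mu)
    val_loss <- net_ce(mu_net, Xval, yval)
    if (!is.finite(val_loss)) stop("non-finite validation loss")
    trace <- rbind(trace, data.frame(epoch = epoch,
                                     train_loss = epoch_loss / n,
                                     val_loss = val_loss))
    if (val_loss < best_val) {
      best_val <- val_loss
      best_params <- params
      best_epoch <- epoch
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best >= config$patience) break
    }
  }
  state$mu <- best_params$mu
  state$rho <- best_params$rho
  structure(list(state = state, trace = trace, best_epoch = best_epoch,
                 d_in = ncol(X), config = config),
            class = "bnn_model")
}

#' @export
print.bnn_model <- function(x, ...) {
  cat(sprintf("<bnn_model: radial variational network, d_in = %d>\n",
              x$d_in))
  invisible(x)
}

#' @rdname predict_logit_samples
#' @param M Number of posterior weight draws (BNN method; default 200).
#' @param seed Seed for the prediction draws (BNN method).
#' @export
predict_logit_samples.bnn_model <- function(model, X, M = 200L,
                                            seed = 1L, ...) {
  X <- as.matrix(X)
  if (ncol(X) != model$d_in) stop("input dimensionality mismatch")
  if (M < 1L) stop("M must be >= 1")
  draws <- matrix(0, nrow(X), M)
  for (i in seq_len(M)) {
    sw <- sample_weights(model$state, derive_seed(seed, 40000L + i))
    net <- net_set_params(model$state$template, sw$w)
    draws[, i] <- net_logits(net, X)
  }
  logit_posterior(draws = draws)
}

#' @rdname predict_prob
#' @export
predict_prob.bnn_model <- function(model, X, ...) {
  post <- predict_logit_samples(model, X, ...)
  rowMeans(stats::plogis(post$draws))
}
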