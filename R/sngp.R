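# Spectral-normalized neural Gaussian process.
#
# A distance-preserving feature extractor (residual blocks, every hidden
# weight matrix spectrally normalized below 1) feeds a Gaussian-process
# output head approximated with D random Fourier features. The GP mean is
# trained discriminatively with ridge-penalized cross-entropy; the latent
# covariance is set post hoc by the Laplace form
#   P = lambda I + sum_i p_i (1 - p_i) phi_i phi_i^T,
# giving a closed-form Gaussian posterior over the latent log-odds whose
# variance depends on the inputs only through the features phi — never on
# the realized labels except via the fitted-probability weights.

#' Train an SNGP model
#'
#' Trains backbone and RFF head weights jointly by cross-entropy with the
#' configured ridge on the head (the MAP of a GP classifier with prior
#' precision `lambda = config$ridge`), then accumulates the Laplace
#' precision over the training set and caches its Cholesky factor for
#' variance queries (query cost independent of training size).
#'
#' @param X,y Training design matrix and labels.
#' @param Xval,yval Validation data for early stopping.
#' @param config A [train_config()] with `head = "rff"`; `sn_bound` and
#'   `residual` default on for this family (set explicitly to override).
#' @param cov_likelihood Covariance-update likelihood: `"gaussian"`
#'   (default) accumulates unit-weight feature outer products, so the
#'   latent variance is a pure function of feature-space geometry;
#'   `"binomial"` uses the Fisher weights `p (1 - p)` of the Laplace
#'   approximation, which imports the cross-entropy loss curvature into
#'   the variance (inflated at probability extremes).
#' @return An `sngp_model`.
#' @export
train_sngp <- function(X, y, Xval, yval, config,
                       cov_likelihood = c("gaussian", "binomial")) {
  cov_likelihood <- match.arg(cov_likelihood)
  stopifnot(config$head == "rff")
  if (config$ridge <= 0) stop("SNGP requires a positive ridge (prior precision)")
  fit <- train_supervised(NULL, X, y, Xval, yval, config)
  net <- refine_head(fit$net, X, y)
  net <- laplace_precision(net, X,
                           weights = if (cov_likelihood == "gaussian") {
                             rep(1, nrow(X))
                           })
  structure(list(net = net, trace = fit$trace, best_epoch = fit$best_epoch,
                 d_in = ncol(X), config = config,
                 cov_likelihood = cov_likelihood),
            class = "sngp_model")
}

#' Solve the RFF-head weight subproblem exactly
#'
#' With the backbone frozen, the head weights minimize a convex
#' ridge-penalized cross-entropy: `sum_i ce(phi_i^T beta, y_i) +
#' lambda/2 ||beta||^2`, the MAP of the GP classifier the head
#' approximates. Newton iteration solves it to numerical tolerance,
#' removing stochastic-optimizer error from the GP mean so it is exactly
#' consistent with the closed-form Laplace covariance. Uses the
#' representer form (an `n x n` solve, with `beta = Phi^T (y - p) /
#' lambda` at the optimum) when `n <= D`, otherwise a `D x D` Newton
#' step.
#'
#' @param net A trained `"rff"`-head network.
#' @param X,y Training design matrix and labels.
#' @param max_iter,tol Newton controls.
#' @return The network with refined `head$beta`.
#' @export
refine_head <- function(net, X, y, max_iter = 50L, tol = 1e-10) {
  stopifnot(net$head$type == "rff")
  H <- backbone_forward(net, X)$H
  phi <- rff_map(net$head, H)
  n <- nrow(phi)
  D <- ncol(phi)
  lambda <- net$head$lambda
  if (n <= D) {
    G <- tcrossprod(phi) / lambda
    diag(G) <- diag(G) + 1e-10
    f <- drop(phi %*% net$head$beta)
    for (it in seq_len(max_iter)) {
      p <- stats::plogis(f)
      W <- pmax(p * (1 - p), 1e-12)
      sW <- sqrt(W)
      B <- sW * t(sW * G)
      diag(B) <- diag(B) + 1
      R <- chol(B)
      b <- W * f + (y - p)
      a <- b - sW * backsolve(R, backsolve(R, sW * (G %*% b),
                                           transpose = TRUE))
      f_new <- drop(G %*% a)
      delta <- max(abs(f_new - f))
      f <- f_new
      if (delta < tol) break
    }
    net$head$beta <- drop(crossprod(phi, y - stats::plogis(f))) / lambda
  } else {
    beta <- net$head$beta
    for (it in seq_len(max_iter)) {
      f <- drop(phi %*% beta)
      p <- stats::plogis(f)
      g <- drop(crossprod(phi, p - y)) + lambda * beta
      W <- pmax(p * (1 - p), 1e-12)
      Hm <- crossprod(phi * sqrt(W))
      diag(Hm) <- diag(Hm) + lambda
      step <- drop(solve(Hm, g))
      beta <- beta - step
      if (max(abs(step)) < tol) break
    }
    net$head$beta <- beta
  }
  net
}

#' Accumulate the Laplace precision of the RFF head
#'
#' `P = lambda I + sum_i w_i phi_i phi_i^T` with `w_i = p_i (1 - p_i)` the
#' Bernoulli Fisher weights at the fitted probabilities. `P` is symmetric
#' with eigenvalues bounded below by `lambda`; its upper-triangular
#' Cholesky factor is cached for variance queries.
#'
#' @param net A trained `"rff"`-head network.
#' @param X Training design matrix.
#' @param weights Optional explicit per-instance weights (defaults to the
#'   fitted `p (1 - p)`).
#' @return The network with `head$precision` and `head$chol` set.
#' @export
laplace_precision <- function(net, X, weights = NULL) {
  stopifnot(net$head$type == "rff")
  H <- backbone_forward(net, X)$H
  phi <- rff_map(net$head, H)
  if (is.null(weights)) {
    p <- stats::plogis(drop(phi %*% net$head$beta))
    if (!all(is.finite(p))) stop("non-finite fitted probabilities")
    weights <- p * (1 - p)
  }
  stopifnot(length(weights) == nrow(X), all(is.finite(weights)))
  P <- crossprod(phi * sqrt(weights))
  diag(P) <- diag(P) + net$head$lambda
  net$head$precision <- P
  net$head$chol <- chol(P)
  net
}

#' Closed-form Gaussian latent posterior of an SNGP
#'
#' Latent mean `m(x) = phi(x)^T beta` from the trained output weights and
#' latent variance `k(x, x) = phi(x)^T P^{-1} phi(x)` from the cached
#' Laplace precision; no sampling is performed.
#'
#' @param model An `sngp_model` (or a raw `"rff"`-head network with its
#'   precision finalized).
#' @param X Query design matrix.
#' @return A Gaussian-form [logit_posterior()].
#' @export
predict_latent <- function(model, X) {
  net <- if (inherits(model, "sngp_model")) model$net else model
  stopifnot(net$head$type == "rff")
  if (is.null(net$head$chol)) {
    stop("precision not finalized; run laplace_precision() first")
  }
  X <- as.matrix(X)
  H <- backbone_forward(net, X)$H
  phi <- rff_map(net$head, H)
  mn <- drop(phi %*% net$head$beta)
  # var = || R^-T phi ||^2 rowwise, P = R^T R
  u <- backsolve(net$head$chol, t(phi), transpose = TRUE)
  vr <- colSums(u^2)
  logit_posterior(mean = mn, variance = vr)
}

#' Predictive probability from a Gaussian latent posterior
#'
#' Default is the variance-adjusted (mean-field probit-style) sigmoid,
#' `sigmoid(mean / sqrt(1 + (pi / 8) * variance))`, which integrates the
#' sigmoid over the latent Gaussian approximately; `adjust = FALSE` gives
#' the plain sigmoid of the mean. The adjusted probability always lies
#' between `sigmoid(mean)` and 1/2.
#'
#' @param mean,variance Latent Gaussian parameters (`variance >= 0`).
#' @param adjust Apply the variance adjustment (default `TRUE`).
#' @return Class-1 probability vector.
#' @export
latent_to_probability <- function(mean, variance, adjust = TRUE) {
  stopifnot(all(variance >= 0))
  if (adjust) {
    stats::plogis(mean / sqrt(1 + (pi / 8) * variance))
  } else {
    stats::plogis(mean)
  }
}

#' @rdname predict_prob
#' @param adjust Variance-adjust the sigmoid link (SNGP method).
#' @export
predict_prob.sngp_model <- function(model, X, adjust = TRUE, ...) {
  post <- predict_latent(model, X)
  latent_to_probability(post$mean, post$variance, adjust)
}

#' Default SNGP training configuration
#'
#' Residual backbone with spectral bound just below 1 (so every hidden
#' layer is a contraction and the stack preserves distances up to that
#' bound), RFF head with ridge prior precision 1.
#'
#' @param widths Hidden widths (equal, for the residual blocks).
#' @param rff_features Number of random Fourier features.
#' @param seed Integer seed.
#' @param ... Overrides passed to [train_config()].
#' @return A [train_config()].
#' @export
sngp_config <- function(widths = c(32L, 32L, 32L), rff_features = 1024L,
                        seed = 1L, ...) {
  args <- list(widths = widths, residual = TRUE, sn_bound = 0.95,
               ridge = 1, rff_features = rff_features,
               rff_lengthscale = 2, head = "rff", seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(train_config, args)
}
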