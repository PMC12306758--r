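# Exact Gaussian-process reference.
#
# Implements the mean-reversion argument directly: a GP prior with a
# distance-decaying (Gaussian/RBF) kernel conditioned on data through a
# Gaussian pseudo-likelihood. Where observations carry no information
# about the query — no local data, or local labels fully noisy — the
# posterior predictive reverts to the prior predictive. The same module
# provides the Laplace-mode GP binary classifier that serves as the exact
# reference for the SNGP random-Fourier-feature head.

rbf_kernel <- function(X1, X2, variance, lengthscale) {
  X1 <- as.matrix(X1)
  X2 <- as.matrix(X2)
  d2 <- outer(rowSums(X1^2), rowSums(X2^2), "+") - 2 * tcrossprod(X1, X2)
  d2[d2 < 0] <- 0
  variance * exp(-d2 / (2 * lengthscale^2))
}

#' Gaussian-process prior specification
#'
#' @param mean Constant prior mean function value.
#' @param variance Kernel (prior) variance.
#' @param lengthscale Kernel length-scale of the Gaussian/RBF kernel
#'   `k(x, x') = variance * exp(-||x - x'||^2 / (2 lengthscale^2))`.
#' @param jitter Diagonal jitter added to training kernel matrices for
#'   Cholesky stability.
#' @return A `gp_prior` object.
#' @export
gp_prior <- function(mean = 0, variance = 1, lengthscale = 1,
                     jitter = 1e-8) {
  stopifnot(variance > 0, lengthscale > 0, jitter >= 0)
  structure(list(mean = mean, variance = variance,
                 lengthscale = lengthscale, jitter = jitter),
            class = "gp_prior")
}

#' Condition a GP on observations with a Gaussian pseudo-likelihood
#'
#' Per-point noise variances allow the Laplace-weighted form used to
#' validate the SNGP head (`noise_var = 1 / (p (1 - p))`) as well as plain
#' regression; `Inf` noise makes an observation carry no information.
#'
#' @param gp A [gp_prior()].
#' @param X Training inputs (matrix or vector), possibly 0 rows.
#' @param y Training targets.
#' @param noise_var Scalar or per-point observation-noise variances.
#' @return A `gp_fit` for [gp_posterior()].
#' @export
gp_fit <- function(gp, X, y, noise_var = 1e-6) {
  stopifnot(inherits(gp, "gp_prior"))
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(length(y) == n)
  noise_var <- rep_len(noise_var, n)
  keep <- is.finite(noise_var) # infinite noise = no information: drop
  X <- X[keep, , drop = FALSE]
  y <- y[keep]
  noise_var <- noise_var[keep]
  n <- nrow(X)
  fit <- list(gp = gp, X = X, y = y, noise_var = noise_var, n = n)
  if (n > 0L) {
    K <- rbf_kernel(X, X, gp$variance, gp$lengthscale)
    diag(K) <- diag(K) + noise_var + gp$jitter
    fit$chol <- tryCatch(chol(K), error = function(e) {
      stop("singular kernel matrix; increase jitter")
    })
    fit$alpha <- backsolve(fit$chol,
                           backsolve(fit$chol, y - gp$mean,
                                     transpose = TRUE))
  }
  structure(fit, class = "gp_fit")
}

#' Posterior mean and variance of a fitted GP
#'
#' Standard conditional-Gaussian formulas. With no (informative) training
#' data the posterior equals the prior exactly: mean `m(x)` and variance
#' `k(x, x)`.
#'
#' @param fit A [gp_fit()] (or a bare [gp_prior()], treated as empty fit).
#' @param Xstar Query inputs.
#' @return List with `mean` and `variance` vectors.
#' @export
gp_posterior <- function(fit, Xstar) {
  if (inherits(fit, "gp_prior")) {
    fit <- gp_fit(fit, matrix(numeric(0), 0, ncol(as.matrix(Xstar))),
                  numeric(0))
  }
  stopifnot(inherits(fit, "gp_fit"))
  Xstar <- as.matrix(Xstar)
  gp <- fit$gp
  if (fit$n == 0L) {
    return(list(mean = rep(gp$mean, nrow(Xstar)),
                variance = rep(gp$variance, nrow(Xstar))))
  }
  Ks <- rbf_kernel(Xstar, fit$X, gp$variance, gp$lengthscale)
  mn <- gp$mean + drop(Ks %*% fit$alpha)
  V <- backsolve(fit$chol, t(Ks), transpose = TRUE)
  vr <- pmax(gp$variance - colSums(V^2), 0)
  list(mean = mn, variance = vr)
}

#' Partition training data into local and outer subsets around a query
#'
#' `D_loc = {i : ||x_star - x_i|| <= r}`, the rest `D_out`. Also reports
#' the largest kernel value between the query and any outer point, to
#' verify that `r` was chosen from the kernel's effective support.
#'
#' @param gp A [gp_prior()] (for the kernel).
#' @param xstar Query point.
#' @param X Training inputs.
#' @param r Positive radius.
#' @return List with index vectors `loc`, `out` and `max_out_kernel`.
#' @export
locality_partition <- function(gp, xstar, X, r) {
  stopifnot(r > 0)
  X <- as.matrix(X)
  d <- sqrt(rowSums(sweep(X, 2L, as.numeric(xstar))^2))
  loc <- which(d <= r)
  out <- which(d > r)
  kmax <- if (length(out) > 0L) {
    max(rbf_kernel(matrix(as.numeric(xstar), 1L), X[out, , drop = FALSE],
                   gp$variance, gp$lengthscale))
  } else {
    0
  }
  list(loc = loc, out = out, max_out_kernel = kmax)
}

#' Laplace-mode exact GP binary classifier
#'
#' Finds the posterior mode of the latent function under a Bernoulli
#' likelihood and GP prior with kernel `k_RBF / lambda` (zero mean) by
#' Newton iteration, and returns the Laplace-approximate latent posterior
#' at queries: the exact counterpart of a ridge-penalized cross-entropy
#' fit on random Fourier features with prior precision `lambda`.
#'
#' @param X,y Training inputs and 0/1 labels.
#' @param lengthscale Kernel length-scale.
#' @param lambda Prior precision (kernel variance `1 / lambda`).
#' @param jitter Diagonal jitter.
#' @param max_iter,tol Newton iteration controls.
#' @return A `gp_laplace` object; query with [predict_latent_gp()].
#' @export
gp_classify_laplace <- function(X, y, lengthscale, lambda = 1,
                                jitter = 1e-8, max_iter = 100L,
                                tol = 1e-10) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(length(y) == n, all(y %in% 0:1), lambda > 0)
  K <- rbf_kernel(X, X, 1 / lambda, lengthscale)
  diag(K) <- diag(K) + jitter
  f <- rep(0, n)
  for (it in seq_len(max_iter)) {
    p <- stats::plogis(f)
    W <- p * (1 - p)
    sW <- sqrt(W)
    B <- sW * t(sW * K) # sqrt(W) K sqrt(W)
    diag(B) <- diag(B) + 1
    R <- chol(B)
    b <- W * f + (y - p)
    a <- b - sW * backsolve(R, backsolve(R, sW * (K %*% b),
                                         transpose = TRUE))
    f_new <- drop(K %*% a)
    if (max(abs(f_new - f)) < tol) {
      f <- f_new
      break
    }
    f <- f_new
  }
  p <- stats::plogis(f)
  structure(list(X = X, y = y, f_hat = f, p_hat = p,
                 grad = y - p, W = p * (1 - p),
                 lengthscale = lengthscale, lambda = lambda,
                 jitter = jitter), class = "gp_laplace")
}

#' Latent posterior of the Laplace-mode GP classifier at query points
#'
#' @param model A `gp_laplace` fit.
#' @param Xstar Query inputs.
#' @return A Gaussian-form [logit_posterior()].
#' @export
predict_latent_gp <- function(model, Xstar) {
  stopifnot(inherits(model, "gp_laplace"))
  Xstar <- as.matrix(Xstar)
  Ks <- rbf_kernel(Xstar, model$X, 1 / model$lambda, model$lengthscale)
  mn <- drop(Ks %*% model$grad)
  sW <- sqrt(model$W)
  K <- rbf_kernel(model$X, model$X, 1 / model$lambda, model$lengthscale)
  B <- sW * t(sW * K)
  diag(B) <- diag(B) + 1
  R <- chol(B)
  V <- backsolve(R, sW * t(Ks), transpose = TRUE)
  vr <- pmax(1 / model$lambda - colSums(V^2), 0)
  logit_posterior(mean = mn, variance = vr)
}

#' Mean-reversion check along a ray leaving the data support
#'
#' Evaluates a predictor's latent mean and variance along an ordered ray
#' of query points moving away from all training data and checks that the
#' mean reverts to the prior reference value and the variance grows
#' toward the prior variance. In strict mode (exact GP) the far end must
#' match the prior within `tol`; in trend mode (approximate models such
#' as SNGP) only the monotone trend beyond `noise_tol` is asserted.
#'
#' @param object An `sngp_model`, `gp_fit`, `gp_laplace`, or a function
#'   `X -> list(mean, variance)`.
#' @param prior_mean,prior_variance Prior reference values.
#' @param ray Matrix of query points ordered by increasing distance from
#'   the data.
#' @param tol Far-end tolerance for strict mode.
#' @param noise_tol Absolute tolerance for the trend comparisons (the
#'   posterior mean may oscillate around the prior near the data edge, so
#'   the decay is asserted on the near-vs-far envelope, not pointwise).
#' @param strict Require far-end agreement with the prior within `tol`.
#' @return List with `pass`, the failure `reasons`, and the `profile`
#'   data.frame (per-point mean deviation and variance).
#' @export
mean_reversion_check <- function(object, prior_mean, prior_variance, ray,
                                 tol = 1e-6, noise_tol = 0.05,
                                 strict = TRUE) {
  latent <- latent_moments(object, ray)
  dev <- abs(latent$mean - prior_mean)
  vr <- latent$variance
  m <- length(dev)
  stopifnot(m >= 3L)
  third <- ceiling(m / 3)
  near <- seq_len(third)
  far <- (m - third + 1L):m
  reasons <- character(0)
  if (max(dev[far]) > max(noise_tol, 0.2 * max(dev[near]))) {
    reasons <- c(reasons, "mean deviation does not decay along the ray")
  }
  if (mean(vr[far]) < mean(vr[near]) - noise_tol) {
    reasons <- c(reasons, "variance does not increase along the ray")
  }
  if (strict) {
    if (dev[m] >= tol) {
      reasons <- c(reasons, sprintf("far-end mean deviation %.3g >= %.3g",
                                    dev[m], tol))
    }
    if (abs(vr[m] - prior_variance) >= tol) {
      reasons <- c(reasons, sprintf("far-end variance gap %.3g >= %.3g",
                                    abs(vr[m] - prior_variance), tol))
    }
  }
  list(pass = length(reasons) == 0L, reasons = reasons,
       profile = data.frame(index = seq_len(m), mean_deviation = dev,
                            variance = vr))
}

# latent mean/variance interface shared by the predictors
latent_moments <- function(object, X) {
  if (is.function(object)) {
    object(X)
  } else if (inherits(object, "sngp_model")) {
    post <- predict_latent(object, X)
    list(mean = post$mean, variance = post$variance)
  } else if (inherits(object, "gp_laplace")) {
    post <- predict_latent_gp(object, X)
    list(mean = post$mean, variance = post$variance)
  } else if (inherits(object, c("gp_fit", "gp_prior"))) {
    gp_posterior(object, X)
  } else {
    stop("predictor without a latent-mean interface")
  }
}
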