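# Fully-connected backbone shared by all model families.
#
# Implemented directly on matrix operations: forward pass, reverse-mode
# gradients, Adam updates, Kaiming-uniform initialization, optional
# residual connections and spectral normalization of hidden layers. The
# networks here are small (tabular inputs, a few hidden layers), so dense
# BLAS calls dominate and no compiled code is needed.

#' Kaiming-uniform weight initialization
#'
#' Entries drawn uniformly on `[-bound, bound]` with
#' `bound = gain * sqrt(6 / fan_in)`; `fan_in` is the first element of
#' `shape`. With the default `gain = 1` this is the standard
#' ReLU-networks bound.
#'
#' @param shape `c(fan_in, fan_out)` of the weight matrix.
#' @param seed Integer seed.
#' @param gain Multiplicative gain for the activation in use.
#' @return A `fan_in x fan_out` matrix.
#' @export
init_kaiming_uniform <- function(shape, seed, gain = 1) {
  stopifnot(length(shape) == 2L, all(shape >= 1L))
  if (shape[1] < 1L) stop("zero fan-in")
  bound <- gain * sqrt(6 / shape[1])
  with_seed(seed, {
    matrix(stats::runif(prod(shape), -bound, bound), shape[1], shape[2])
  })
}

#' Spectral normalization of a weight matrix
#'
#' Rescales `W` so its largest singular value does not exceed `c`:
#' `W' = W * min(1, c / sigma_max(W))`. Direction (and all singular
#' vectors) are preserved; a zero matrix is returned unchanged. Uses exact
#' SVD — the per-step estimate used during training is the power
#' iteration in `power_iteration_sigma()`.
#'
#' @param W Weight matrix.
#' @param c Positive spectral bound.
#' @return The rescaled matrix.
#' @export
spectral_normalize <- function(W, c) {
  stopifnot(c > 0)
  s <- svd(W, nu = 0, nv = 0)$d[1]
  if (s <= c || s == 0) W else W * (c / s)
}

#' One-vector power iteration estimate of the top singular value
#'
#' @param W Weight matrix.
#' @param u Current left singular vector estimate (length `nrow(W)`), or
#'   `NULL` to start from a deterministic vector.
#' @param iters Number of iterations (default 1; called once per training
#'   step the estimate tracks the slowly-moving weights).
#' @return List with `sigma` and the updated `u`.
#' @export
power_iteration_sigma <- function(W, u = NULL, iters = 1L) {
  if (is.null(u)) u <- rep(1 / sqrt(nrow(W)), nrow(W))
  for (i in seq_len(iters)) {
    v <- drop(crossprod(W, u))
    nv <- sqrt(sum(v^2))
    if (nv == 0) return(list(sigma = 0, u = u))
    v <- v / nv
    u <- drop(W %*% v)
    nu <- sqrt(sum(u^2))
    if (nu == 0) return(list(sigma = 0, u = u))
    u <- u / nu
  }
  list(sigma = drop(u %*% W %*% v), u = u)
}

#' Training configuration for the supervised backbone loop
#'
#' @param widths Hidden layer widths (equal widths required when
#'   `residual = TRUE`).
#' @param residual Use residual (identity skip) hidden blocks beyond the
#'   first hidden layer.
#' @param lr,beta1,beta2,eps Adam hyperparameters.
#' @param batch_size Minibatch size; `Inf` (default) trains full-batch.
#' @param max_epochs Maximum epochs.
#' @param patience Early-stopping patience in epochs (>= 1), on validation
#'   cross-entropy.
#' @param sn_bound Spectral-norm bound applied to every backbone weight
#'   matrix after each update, or `NULL` for no normalization.
#' @param weight_decay L2 penalty coefficient on all weight matrices
#'   (biases excluded), added to the mean-loss objective as
#'   `weight_decay / 2 * sum(W^2)`; tempers overconfident logit tails.
#' @param ridge Ridge penalty on head output weights, as the coefficient
#'   `lambda` of `lambda/2 * ||beta||^2` added to the *summed*
#'   cross-entropy (so the per-mean loss carries `lambda / (2 n)`); also
#'   the prior precision of the RFF head's Laplace covariance.
#' @param rff_features,rff_lengthscale Size and kernel length-scale of the
#'   random-Fourier-feature head (`head = "rff"`).
#' @param head `"linear"` (single logit) or `"rff"` (GP head).
#' @param seed Integer seed controlling initialization and shuffling.
#' @return A `train_config` list.
#' @export
train_config <- function(widths = c(32L, 32L, 32L), residual = FALSE,
                         lr = 0.01, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                         batch_size = Inf, max_epochs = 200L, patience = 20L,
                         sn_bound = NULL, ridge = 0, weight_decay = 0,
                         rff_features = 1024L, rff_lengthscale = 2,
                         head = c("linear", "rff"), seed = 1L) {
  head <- match.arg(head)
  stopifnot(patience >= 1L, all(widths >= 1L), lr > 0)
  if (residual && length(unique(widths)) != 1L) {
    stop("residual blocks require equal hidden widths")
  }
  structure(list(widths = as.integer(widths), residual = residual, lr = lr,
                 beta1 = beta1, beta2 = beta2, eps = eps,
                 batch_size = batch_size, max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), sn_bound = sn_bound,
                 ridge = ridge, weight_decay = weight_decay,
                 rff_features = as.integer(rff_features),
                 rff_lengthscale = rff_lengthscale, head = head,
                 seed = as.integer(seed)),
            class = "train_config")
}

# Build a network: backbone hidden layers + head.
net_init <- function(d_in, config) {
  widths <- config$widths
  dims <- c(d_in, widths)
  layers <- vector("list", length(widths))
  for (k in seq_along(widths)) {
    layers[[k]] <- list(
      W = init_kaiming_uniform(c(dims[k], dims[k + 1L]),
                               derive_seed(config$seed, 100L + k)),
      b = rep(0, dims[k + 1L]))
  }
  h_out <- dims[length(dims)]
  head <- if (config$head == "linear") {
    list(type = "linear",
         W = init_kaiming_uniform(c(h_out, 1L),
                                  derive_seed(config$seed, 200L)),
         b = 0)
  } else {
    D <- config$rff_features
    Omega <- with_seed(derive_seed(config$seed, 300L), {
      matrix(stats::rnorm(D * h_out), D, h_out) / config$rff_lengthscale
    })
    boff <- with_seed(derive_seed(config$seed, 301L), {
      stats::runif(D, 0, 2 * pi)
    })
    list(type = "rff", Omega = Omega, boff = boff, D = D,
         lengthscale = config$rff_lengthscale,
         beta = rep(0, D), lambda = config$ridge,
         precision = NULL, chol = NULL)
  }
  structure(list(layers = layers, head = head, residual = config$residual,
                 d_in = d_in, config = config,
                 sn_u = vector("list", length(widths))),
            class = "uq_net")
}

# Forward through the backbone; optionally keep caches for backprop.
backbone_forward <- function(net, X, cache = FALSE) {
  H <- X
  Zs <- if (cache) vector("list", length(net$layers)) else NULL
  Hs <- if (cache) vector("list", length(net$layers) + 1L) else NULL
  if (cache) Hs[[1L]] <- H
  for (k in seq_along(net$layers)) {
    ly <- net$layers[[k]]
    Z <- sweep(H %*% ly$W, 2L, ly$b, "+")
    A <- relu(Z)
    H <- if (net$residual && k > 1L) H + A else A
    if (cache) {
      Zs[[k]] <- Z
      Hs[[k + 1L]] <- H
    }
  }
  if (cache) list(H = H, Zs = Zs, Hs = Hs) else list(H = H)
}

#' Random-Fourier-feature map
#'
#' `phi(h) = sqrt(2 / D) * cos(Omega h + b)` with `Omega` rows drawn from
#' `N(0, 1/lengthscale^2)` and offsets uniform on `[0, 2 pi)`; inner
#' products of the features approximate the Gaussian kernel
#' `exp(-||h - h'||^2 / (2 lengthscale^2))`.
#'
#' @param head An RFF head (from a `"rff"`-head network).
#' @param H Matrix of backbone outputs, one row per instance.
#' @return `n x D` feature matrix with row norms bounded by `sqrt(2)`.
#' @export
rff_map <- function(head, H) {
  stopifnot(identical(head$type, "rff"))
  H <- as.matrix(H)
  if (ncol(H) != ncol(head$Omega)) stop("feature dimension mismatch")
  A <- sweep(H %*% t(head$Omega), 2L, head$boff, "+")
  sqrt(2 / head$D) * cos(A)
}

head_logits <- function(net, H, cache = FALSE) {
  if (net$head$type == "linear") {
    z <- drop(H %*% net$head$W) + net$head$b
    if (cache) list(z = z) else list(z = z)
  } else {
    phi <- rff_map(net$head, H)
    list(z = drop(phi %*% net$head$beta), phi = phi)
  }
}

# Full forward: latent logits.
net_logits <- function(net, X) {
  H <- backbone_forward(net, X)$H
  head_logits(net, H)$z
}

# Loss (mean cross-entropy + head ridge) and gradients w.r.t. all
# parameters, via reverse mode.
net_loss_grad <- function(net, X, y) {
  n <- nrow(X)
  fb <- backbone_forward(net, X, cache = TRUE)
  hd <- head_logits(net, fb$H, cache = TRUE)
  z <- hd$z
  loss <- mean(softplus(z) - y * z)
  ridge <- net$config$ridge
  dz <- matrix((stats::plogis(z) - y) / n, ncol = 1L)
  g <- list(layers = vector("list", length(net$layers)), head = NULL)
  if (net$head$type == "linear") {
    g$head <- list(W = crossprod(fb$H, dz), b = sum(dz))
    dH <- dz %*% t(net$head$W)
    if (ridge > 0) {
      loss <- loss + ridge / (2 * n) * (sum(net$head$W^2) + net$head$b^2)
      g$head$W <- g$head$W + ridge / n * net$head$W
      g$head$b <- g$head$b + ridge / n * net$head$b
    }
  } else {
    phi <- hd$phi
    g$head <- list(beta = drop(crossprod(phi, dz)))
    if (ridge > 0) {
      loss <- loss + ridge / (2 * n) * sum(net$head$beta^2)
      g$head$beta <- g$head$beta + ridge / n * net$head$beta
    }
    # d phi = dz beta^T ; phi = sqrt(2/D) cos(A), dA = -sqrt(2/D) sin(A) dphi
    A <- sweep(fb$H %*% t(net$head$Omega), 2L, net$head$boff, "+")
    dA <- -(dz %*% t(net$head$beta)) * sqrt(2 / net$head$D) * sin(A)
    dH <- dA %*% net$head$Omega
  }
  for (k in rev(seq_along(net$layers))) {
    dZ <- dH * (fb$Zs[[k]] > 0)
    g$layers[[k]] <- list(W = crossprod(fb$Hs[[k]], dZ), b = colSums(dZ))
    dH_prev <- dZ %*% t(net$layers[[k]]$W)
    if (net$residual && k > 1L) dH_prev <- dH_prev + dH
    dH <- dH_prev
  }
  wd <- net$config$weight_decay %||% 0
  if (wd > 0) {
    for (k in seq_along(net$layers)) {
      loss <- loss + wd / 2 * sum(net$layers[[k]]$W^2)
      g$layers[[k]]$W <- g$layers[[k]]$W + wd * net$layers[[k]]$W
    }
    if (net$head$type == "linear") {
      loss <- loss + wd / 2 * sum(net$head$W^2)
      g$head$W <- g$head$W + wd * net$head$W
    }
  }
  list(loss = loss, grad = g)
}

# Mean cross-entropy (no ridge), used for validation monitoring.
net_ce <- function(net, X, y) {
  z <- net_logits(net, X)
  mean(softplus(z) - y * z)
}

adam_state_like <- function(params) {
  rapply(params, function(x) x * 0, how = "replace")
}

adam_update <- function(params, grads, m, v, t, config) {
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(walk, p, g, m, v)
      list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else {
      m2 <- config$beta1 * m + (1 - config$beta1) * g
      v2 <- config$beta2 * v + (1 - config$beta2) * g^2
      mh <- m2 / (1 - config$beta1^t)
      vh <- v2 / (1 - config$beta2^t)
      list(p = p - config$lr * mh / (sqrt(vh) + config$eps), m = m2, v = v2)
    }
  }
  walk(params, grads, m, v)
}

net_get_params <- function(net) {
  list(layers = lapply(net$layers, function(l) list(W = l$W, b = l$b)),
       head = if (net$head$type == "linear") {
         list(W = net$head$W, b = net$head$b)
       } else {
         list(beta = net$head$beta)
       })
}

net_set_params <- function(net, params) {
  for (k in seq_along(net$layers)) {
    net$layers[[k]]$W <- params$layers[[k]]$W
    net$layers[[k]]$b <- params$layers[[k]]$b
  }
  if (net$head$type == "linear") {
    net$head$W <- params$head$W
    net$head$b <- params$head$b
  } else {
    net$head$beta <- params$head$beta
  }
  net
}

apply_spectral_norm <- function(net) {
  c <- net$config$sn_bound
  if (is.null(c)) return(net)
  for (k in seq_along(net$layers)) {
    pi_ <- power_iteration_sigma(net$layers[[k]]$W, net$sn_u[[k]])
    net$sn_u[[k]] <- pi_$u
    if (pi_$sigma > c && pi_$sigma > 0) {
      net$layers[[k]]$W <- net$layers[[k]]$W * (c / pi_$sigma)
    }
  }
  net
}

#' Train a network with Adam and early stopping
#'
#' Minimizes mean cross-entropy (plus any configured head ridge) on the
#' training set, evaluating validation cross-entropy each epoch; training
#' stops once the validation loss has failed to improve for
#' `config$patience` consecutive epochs, and the parameter state with the
#' best validation loss seen is returned. With a finite
#' `config$batch_size` the minibatch order is reshuffled each epoch from
#' the config seed, so fixed seed and config give identical traces.
#'
#' @param net A network from the internal constructor (or `NULL` to build
#'   one from `config` and `ncol(X)`).
#' @param X,y Training design matrix and 0/1 labels.
#' @param Xval,yval Validation data (disjoint from training).
#' @param config A [train_config()].
#' @return List with the fitted `net`, the per-epoch `trace`
#'   (train/validation loss) and `best_epoch`.
#' @export
train_supervised <- function(net, X, y, Xval, yval, config = NULL) {
  if (is.null(net)) net <- net_init(ncol(X), config)
  config <- net$config
  n <- nrow(X)
  bs <- min(config$batch_size, n)
  m <- v <- NULL
  t <- 0L
  best_val <- Inf
  best_params <- net_get_params(net)
  best_epoch <- 0L
  since_best <- 0L
  trace <- data.frame(epoch = integer(), train_loss = numeric(),
                      val_loss = numeric())
  net <- apply_spectral_norm(net)
  for (epoch in seq_len(config$max_epochs)) {
    idx_order <- if (bs < n) {
      with_seed(derive_seed(config$seed, 1000L + epoch), sample.int(n))
    } else {
      seq_len(n)
    }
    starts <- seq(1L, n, by = bs)
    epoch_loss <- 0
    for (s in starts) {
      take <- idx_order[s:min(s + bs - 1L, n)]
      lg <- net_loss_grad(net, X[take, , drop = FALSE], y[take])
      if (!is.finite(lg$loss)) {
        stop(sprintf("non-finite training loss at epoch %d", epoch))
      }
      epoch_loss <- epoch_loss + lg$loss * length(take)
      t <- t + 1L
      params <- net_get_params(net)
      if (is.null(m)) {
        m <- adam_state_like(params)
        v <- adam_state_like(params)
      }
      upd <- adam_update(params, lg$grad, m, v, t, config)
      m <- upd$m
      v <- upd$v
      net <- net_set_params(net, upd$p)
      net <- apply_spectral_norm(net)
    }
    val_loss <- net_ce(net, Xval, yval)
    if (!is.finite(val_loss)) {
      stop(sprintf("non-finite validation loss at epoch %d", epoch))
    }
    trace <- rbind(trace, data.frame(epoch = epoch,
                                     train_loss = epoch_loss / n,
                                     val_loss = val_loss))
    if (val_loss < best_val) {
      best_val <- val_loss
      best_params <- net_get_params(net)
      best_epoch <- epoch
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best >= config$patience) break
    }
  }
  net <- net_set_params(net, best_params)
  if (!is.null(config$sn_bound)) {
    # exact projection: the per-step power iteration tracks sigma_max only
    # approximately, so enforce the bound exactly on the returned state
    for (k in seq_along(net$layers)) {
      net$layers[[k]]$W <- spectral_normalize(net$layers[[k]]$W,
                                              config$sn_bound)
    }
  }
  list(net = net, trace = trace, best_epoch = best_epoch,
       best_val_loss = best_val)
}
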