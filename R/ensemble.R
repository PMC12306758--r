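# Deep ensemble: particle-based approximate posterior.
#
# M networks share one architecture and training recipe but differ in
# their Kaiming-uniform initializations (and, with minibatching, in
# shuffling order); their latent outputs at a query point form M draws
# from the implicit functional posterior.

#' Train an ensemble of independently initialized networks
#'
#' Each member is trained by [train_supervised()] with cross-entropy loss
#' on identical data; member seeds are distinct streams derived from
#' `config$seed`, so diversity comes from initialization (and shuffling
#' when minibatching), not from data subsampling.
#'
#' @param X,y Training design matrix and labels.
#' @param Xval,yval Validation data for early stopping.
#' @param config A [train_config()] shared by all members.
#' @param M Number of members (>= 1).
#' @return An `ensemble_model`.
#' @export
train_ensemble <- function(X, y, Xval, yval, config, M) {
  M <- as.integer(M)
  if (M < 1L) stop("M must be >= 1")
  members <- vector("list", M)
  for (i in seq_len(M)) {
    cfg_i <- config
    cfg_i$seed <- derive_seed(config$seed, 5000L + i)
    fit <- tryCatch(
      train_supervised(NULL, X, y, Xval, yval, cfg_i),
      error = function(e) {
        stop(sprintf("ensemble member %d failed: %s", i, conditionMessage(e)))
      })
    members[[i]] <- fit$net
  }
  structure(list(members = members, M = M, d_in = ncol(X),
                 config = config), class = "ensemble_model")
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat(sprintf("<ensemble_model: M = %d members, d_in = %d>\n", x$M, x$d_in))
  invisible(x)
}

#' Posterior log-odds draws from a fitted model
#'
#' Generic: returns a sample-form [logit_posterior()] whose column `i` is
#' the latent log-odds of posterior draw `i` at each input row.
#'
#' @param model A fitted model (`ensemble_model` or `bnn_model`).
#' @param X Design matrix of query instances.
#' @param ... Method-specific arguments (`M`, `seed` for the BNN).
#' @return A `logit_posterior` in sample form.
#' @export
predict_logit_samples <- function(model, X, ...) {
  UseMethod("predict_logit_samples")
}

#' @rdname predict_logit_samples
#' @export
predict_logit_samples.ensemble_model <- function(model, X, ...) {
  X <- as.matrix(X)
  if (ncol(X) != model$d_in) stop("input dimensionality mismatch")
  draws <- vapply(model$members, function(net) net_logits(net, X),
                  numeric(nrow(X)))
  logit_posterior(draws = matrix(draws, nrow = nrow(X)))
}

#' Predictive class-1 probability of an ensemble
#'
#' Bayesian model average: the mean over members of the sigmoid of each
#' member's latent output.
#'
#' @param model An `ensemble_model` (or `bnn_model`).
#' @param X Query design matrix.
#' @param ... Passed to [predict_logit_samples()].
#' @return Probability vector.
#' @export
predict_prob <- function(model, X, ...) {
  UseMethod("predict_prob")
}

#' @rdname predict_prob
#' @export
predict_prob.ensemble_model <- function(model, X, ...) {
  post <- predict_logit_samples(model, X, ...)
  rowMeans(stats::plogis(post$draws))
}
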