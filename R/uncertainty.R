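# Logit-space uncertainty measures for binary classifiers.
#
# All measures operate on the latent log-odds (pre-sigmoid model output),
# not on probabilities: working in logit space decouples the uncertainty in
# a prediction from the prior class frequency and from the aleatoric
# entropy of the outcome itself.

#' Construct a per-instance posterior over the latent log-odds
#'
#' A `logit_posterior` carries, for each instance, either `M` Monte-Carlo
#' draws of the posterior log-odds (sample form; e.g. ensemble member
#' outputs or Bayesian-neural-network weight samples) or the mean and
#' variance of a closed-form Gaussian latent posterior (Gaussian form; e.g.
#' the random-Fourier-feature GP head of an SNGP).
#'
#' @param draws Numeric matrix, `n` instances by `M` draws (sample form).
#' @param mean,variance Numeric vectors of length `n` (Gaussian form).
#' @return An object of class `logit_posterior`.
#' @export
logit_posterior <- function(draws = NULL, mean = NULL, variance = NULL) {
  if (!is.null(draws)) {
    if (!is.null(mean) || !is.null(variance)) {
      stop("supply either `draws` or (`mean`, `variance`), not both")
    }
    draws <- as.matrix(draws)
    if (ncol(draws) < 1L) stop("sample form requires at least one draw")
    if (!all(is.finite(draws))) stop("non-finite log-odds draws")
    out <- list(form = "sample", draws = draws, n = nrow(draws),
                M = ncol(draws))
  } else {
    if (is.null(mean) || is.null(variance)) {
      stop("Gaussian form requires both `mean` and `variance`")
    }
    if (length(mean) != length(variance)) {
      stop("`mean` and `variance` lengths differ")
    }
    if (!all(is.finite(mean)) || !all(is.finite(variance))) {
      stop("non-finite Gaussian parameters")
    }
    if (any(variance < 0)) stop("negative latent variance")
    out <- list(form = "gaussian", mean = as.numeric(mean),
                variance = as.numeric(variance), n = length(mean))
  }
  class(out) <- "logit_posterior"
  out
}

#' @export
print.logit_posterior <- function(x, ...) {
  if (x$form == "sample") {
    cat(sprintf("<logit_posterior: sample form, n = %d, M = %d draws>\n",
                x$n, x$M))
  } else {
    cat(sprintf("<logit_posterior: Gaussian form, n = %d>\n", x$n))
  }
  invisible(x)
}

posterior_mean <- function(post) {
  if (post$form == "sample") rowMeans(post$draws) else post$mean
}

posterior_variance <- function(post) {
  if (post$form == "sample") {
    if (post$M == 1L) {
      warning("sample variance undefined for a single draw; returning 0")
      rep(0, post$n)
    } else {
      apply(post$draws, 1L, stats::var)
    }
  } else {
    post$variance
  }
}

#' Prior log-odds from training labels
#'
#' The neutral reference point of all logit-space measures:
#' `log(count(y = 1) / count(y = 0))`. Estimated from training-set class
#' frequencies, which for `n >> 1` carries negligible sampling uncertainty
#' relative to the per-instance posterior spread.
#'
#' @param labels Binary (0/1) label vector.
#' @return Scalar prior log-odds.
#' @export
prior_log_odds <- function(labels) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("both classes must be present to estimate prior log-odds")
  }
  log(n1 / n0)
}

#' Bayes factor from posterior log-odds
#'
#' `K = exp(l1x - l1)`: the ratio of the likelihoods of the two outcomes,
#' equal to the posterior odds divided by the prior odds. `K = 1` means
#' the instance carries no evidence beyond the prior.
#'
#' @param l1x Posterior log-odds value(s).
#' @param l1 Prior log-odds.
#' @return Bayes factor(s), positive.
#' @export
bayes_factor <- function(l1x, l1) {
  stopifnot(all(is.finite(l1x)), is.finite(l1))
  exp(l1x - l1)
}

#' Evidential strength
#'
#' `ES = |E[l1x] - l1|`: the absolute deviation of the posterior-mean
#' log-odds from the prior log-odds, i.e. `|E[log K]|`. Symmetric in which
#' hypothesis the evidence favors; zero at neutral evidence. Under Bayesian
#' mean reversion ES acts as an (inverse) measure of total uncertainty.
#'
#' @param post A `logit_posterior`.
#' @param l1 Prior log-odds.
#' @return Numeric vector of per-instance ES values (non-negative).
#' @export
evidential_strength <- function(post, l1) {
  stopifnot(inherits(post, "logit_posterior"), is.finite(l1))
  abs(posterior_mean(post) - l1)
}

#' Total uncertainty
#'
#' Strictly monotone transform of evidential strength into `(0, 1]`:
#' `u_tot = exp(-k * ES)`. Equals 1 when the evidence equally supports both
#' hypotheses (`K = 1`) and tends to 0 under overwhelming evidence for
#' either hypothesis.
#'
#' @param es Evidential strength value(s).
#' @param k Positive decay rate. Only affects the scale of the measure,
#'   never the instance ranking.
#' @return `u_tot` in `(0, 1]`.
#' @export
total_uncertainty <- function(es, k = 1) {
  if (!is.numeric(k) || length(k) != 1L || k <= 0) stop("k must be > 0")
  stopifnot(all(es >= 0))
  exp(-k * es)
}

#' Epistemic uncertainty
#'
#' `u_epi = 1 - exp(-k * Var[l1x])`: a monotone transform of the variance
#' of the posterior log-odds into `[0, 1)`. Zero for a delta-distributed
#' functional posterior, approaching 1 as the posterior widens without
#' bound. Sample form uses the unbiased (n-1) sample variance across draws;
#' Gaussian form uses the stored latent variance with no sampling.
#'
#' @param post A `logit_posterior`.
#' @param k Positive decay rate.
#' @return Numeric vector of per-instance `u_epi` values in `[0, 1)`.
#' @export
epistemic_uncertainty <- function(post, k = 1) {
  if (!is.numeric(k) || length(k) != 1L || k <= 0) stop("k must be > 0")
  stopifnot(inherits(post, "logit_posterior"))
  v <- posterior_variance(post)
  # 1 - exp(-kv) via expm1 for accuracy at small variances
  -expm1(-k * v)
}

#' Score a cohort's posterior with all logit-space measures
#'
#' Vectorizes evidential strength, total and epistemic uncertainty over the
#' instances of a `logit_posterior`. The Gaussian-form path is fully
#' closed-form and never samples.
#'
#' @param post A `logit_posterior` over the cohort.
#' @param l1 Prior log-odds from the training labels.
#' @param k Positive decay rate.
#' @return A data.frame with columns `es`, `u_tot`, `u_epi` and attributes
#'   `l1`, `k`.
#' @export
score_instances <- function(post, l1, k = 1) {
  es <- evidential_strength(post, l1)
  out <- data.frame(
    es = es,
    u_tot = total_uncertainty(es, k),
    u_epi = epistemic_uncertainty(post, k)
  )
  attr(out, "l1") <- l1
  attr(out, "k") <- k
  out
}
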