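# Population-level metrics and uncertainty-ranked stratification.

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney concordance probability via mid-ranks, so
#' tied scores contribute 1/2. Invariant under strictly monotone transforms
#' of the scores.
#'
#' @param scores Numeric prediction scores (higher = more class-1).
#' @param labels Binary 0/1 labels.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes required for AUROC")
  r <- rank(scores) # average ranks for ties
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Average precision: the mean, over positive instances taken in
#' decreasing-score order, of the precision at that instance's threshold.
#' Tied scores are processed as a block so the result does not depend on
#' their internal order.
#'
#' @inheritParams auroc
#' @return AUPRC in `(0, 1]`.
#' @export
auprc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  n1 <- sum(labels == 1L)
  if (n1 == 0L) stop("no positive instances")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- labels[o]
  # block-wise cumulative counts over distinct thresholds
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  last <- !duplicated(grp, fromLast = TRUE) # last index of each block
  tp_b <- tp[last]
  fp_b <- fp[last]
  prec <- tp_b / (tp_b + fp_b)
  dtp <- diff(c(0, tp_b))
  sum(prec * dtp) / n1
}

#' Expected calibration error and calibration curve
#'
#' Bins predictions into `bins` equal-width probability bins; ECE is the
#' bin-count-weighted mean absolute gap between the mean predicted
#' probability (confidence) and the empirical class-1 frequency. Empty bins
#' are excluded.
#'
#' @param probs Predicted class-1 probabilities in `[0, 1]`.
#' @param labels Binary 0/1 labels.
#' @param bins Number of equal-width bins (default 10).
#' @return For `ece()`, the scalar expected calibration error. For
#'   `calibration_curve()`, a data.frame with per-bin mean probability,
#'   empirical frequency and count.
#' @export
ece <- function(probs, labels, bins = 10L) {
  cc <- calibration_curve(probs, labels, bins)
  sum(cc$count / sum(cc$count) * abs(cc$mean_prob - cc$frequency))
}

#' @rdname ece
#' @export
calibration_curve <- function(probs, labels, bins = 10L) {
  labels <- as.integer(labels)
  stopifnot(length(probs) == length(labels), all(labels %in% 0:1))
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (bins < 1L) stop("bins must be >= 1")
  edges <- seq(0, 1, length.out = bins + 1L)
  idx <- findInterval(probs, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  keep <- sort(unique(idx))
  data.frame(
    bin = keep,
    mean_prob = vapply(keep, function(b) mean(probs[idx == b]), numeric(1)),
    frequency = vapply(keep, function(b) mean(labels[idx == b]), numeric(1)),
    count = vapply(keep, function(b) sum(idx == b), numeric(1))
  )
}

#' Mean negative Bernoulli log-likelihood
#'
#' Probabilities are clipped away from 0 and 1 by `floor` before taking
#' logs, so deterministic predictions yield a large finite penalty instead
#' of an infinity.
#'
#' @inheritParams ece
#' @param floor Clipping floor (default `1e-12`).
#' @param reduce If `FALSE`, return the per-instance NLL vector.
#' @return Mean (or per-instance) negative log-likelihood.
#' @export
nll <- function(probs, labels, floor = 1e-12, reduce = TRUE) {
  labels <- as.integer(labels)
  stopifnot(length(probs) == length(labels), all(labels %in% 0:1))
  p <- pmin(pmax(probs, floor), 1 - floor)
  ll <- -(labels * log(p) + (1 - labels) * log(1 - p))
  if (reduce) mean(ll) else ll
}

#' Spearman rank correlation with average-rank tie handling
#'
#' Pearson correlation of mid-ranks. Constant inputs have no defined rank
#' correlation and raise an error (callers that can encounter them should
#' test with `is_constant()` semantics first).
#'
#' @param x,y Equal-length numeric vectors.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
spearman <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("Spearman correlation undefined for constant input")
  }
  stats::cor(rank(x), rank(y))
}

#' Sliding-window stratification of predictive performance by uncertainty
#'
#' Sorts instances in ascending uncertainty (ties broken by stable original
#' order), slides a window of `floor(n / window_frac_inv)` instances with
#' stride 1, and records each window's mean and summed per-instance NLL.
#' The Spearman coefficient between window rank and window mean NLL
#' summarizes whether higher uncertainty identifies worse-predicted
#' subsets; it is invariant to the decay rate `k` used to form the
#' uncertainty measure because `k` never changes the instance ranking.
#'
#' @param nll_instance Per-instance negative log-likelihood values.
#' @param uncertainty Per-instance uncertainty scores (same length).
#' @param window_frac_inv Window size denominator: window = `floor(n / 3)`
#'   for the default 3.
#' @return A list of class `stratification_result`: per-window table,
#'   window size, Spearman coefficient (`NA` with `degenerate = TRUE` when
#'   the uncertainty vector is constant), and the difference in summed NLL
#'   between the highest- and lowest-uncertainty windows.
#' @export
sliding_window_stratification <- function(nll_instance, uncertainty,
                                          window_frac_inv = 3L) {
  n <- length(nll_instance)
  stopifnot(length(uncertainty) == n, n >= 3L)
  w <- max(1L, n %/% window_frac_inv)
  ord <- order(uncertainty, seq_len(n)) # stable in original order on ties
  x <- nll_instance[ord]
  cs <- c(0, cumsum(x))
  n_win <- n - w + 1L
  win_sum <- cs[(w + 1L):(n + 1L)] - cs[1L:n_win]
  win_mean <- win_sum / w
  degenerate <- (max(uncertainty) == min(uncertainty))
  rho <- if (degenerate || stats::sd(win_mean) == 0) {
    NA_real_
  } else {
    spearman(seq_len(n_win), win_mean)
  }
  out <- list(
    windows = data.frame(rank = seq_len(n_win), mean_nll = win_mean,
                         sum_nll = win_sum),
    window_size = w,
    spearman = rho,
    degenerate = degenerate,
    nll_diff = win_sum[n_win] - win_sum[1L]
  )
  class(out) <- "stratification_result"
  out
}

#' @export
print.stratification_result <- function(x, ...) {
  cat(sprintf(
    "<stratification: %d windows of %d, Spearman = %s, NLL diff = %.4g>\n",
    nrow(x$windows), x$window_size,
    if (x$degenerate) "undefined (constant uncertainty)"
    else sprintf("%.3f", x$spearman),
    x$nll_diff))
  invisible(x)
}

#' Correlate epistemic uncertainty with a toy-law ground-truth quantity
#'
#' Pairs each test instance's `u_epi` with the generative law's true local
#' data density or true label noise at that instance, and reports the
#' Spearman coefficient together with the paired values.
#'
#' @param law A `toy_law`.
#' @param points Matrix of test-instance coordinates (n x 2).
#' @param u_epi Per-instance epistemic uncertainty.
#' @param target `"density"` for `p(x0, x1)` or `"noise"` for
#'   `p1 * (1 - p1)`.
#' @return List with `spearman` and the paired data.frame `pairs`.
#' @export
correlate_uncertainty_with <- function(law, points, u_epi,
                                       target = c("density", "noise")) {
  target <- match.arg(target)
  val <- if (target == "density") {
    true_density(law, points)
  } else {
    true_label_noise(law, points)
  }
  stopifnot(length(u_epi) == length(val))
  list(
    spearman = spearman(u_epi, val),
    target = target,
    pairs = data.frame(u_epi = u_epi, value = val)
  )
}

#' Loss-curvature profile of the logistic link
#'
#' The inverse Bernoulli Fisher information `1 / (p (1 - p))`: under a
#' second-order (Laplace-style) view of the cross-entropy loss, the latent
#' logit variance of implicit-prior models scales with this profile, which
#' is minimal (4) at `p = 0.5` and blows up at the probability extremes.
#' This is the mechanism by which logit-space dispersion of ensembles and
#' weight-space variational networks mirrors the *inverse* of the
#' aleatoric noise `p (1 - p)`.
#'
#' @param p Probabilities strictly inside `(0, 1)`.
#' @return `1 / (p (1 - p))`.
#' @export
curvature_profile <- function(p) {
  if (any(p <= 0 | p >= 1)) stop("curvature defined only on (0, 1)")
  1 / (p * (1 - p))
}
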