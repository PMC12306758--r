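# Two-dimensional toy data with disentangled uncertainty sources.
#
# The generative law makes the class probability a linear ramp along x0
# while the training-point density is a linear ramp along x1, so label
# noise (aleatoric) and data sparsity (epistemic) are statistically
# independent by construction. Test data use the same label law but
# uniform density, exposing the regions the training density undersampled.

#' Generative law of the 2D toy distribution
#'
#' @param alpha,beta Intercept and slope of the class-probability ramp
#'   `p1(x0) = clip(alpha + beta * x0, 0, 1)`.
#' @param dens_a,dens_b Intercept and slope of the (unnormalized) training
#'   density weight `w(x1) = dens_a + dens_b * x1`; it must be positive on
#'   the domain and is normalized internally to integrate to 1.
#' @param n_train,n_test Sample sizes.
#' @param seed Integer seed owned by the law; sampling is a pure function
#'   of the law.
#' @return An object of class `toy_law`.
#' @details Defaults place the problem on the unit square with
#'   `p1(x0) = x0` and `w(x1) = 0.25 + 1.5 * x1` (after normalization the
#'   dense edge has 7x the density of the sparse edge), `n_train = n_test
#'   = 4000`.
#' @export
toy_law <- function(alpha = 0, beta = 1, dens_a = 0.25, dens_b = 1.5,
                    n_train = 4000L, n_test = 4000L, seed = 1L) {
  # normalize w over [0,1]: integral = dens_a + dens_b / 2
  Z <- dens_a + dens_b / 2
  if (Z <= 0) stop("density weight must have positive mass")
  a <- dens_a / Z
  b <- dens_b / Z
  if (a <= 0 || a + b <= 0) {
    stop("density weight w(x1) must be strictly positive on [0, 1]")
  }
  if (n_train < 0 || n_test < 0) stop("negative sample size")
  law <- list(alpha = alpha, beta = beta, dens_a = a, dens_b = b,
              n_train = as.integer(n_train), n_test = as.integer(n_test),
              seed = as.integer(seed))
  class(law) <- "toy_law"
  law
}

#' Class-probability ramp of a toy law
#'
#' @param law A `toy_law`.
#' @param x0 Coordinates along the label axis.
#' @return `clip(alpha + beta * x0, 0, 1)`.
#' @export
toy_p1 <- function(law, x0) {
  pmin(pmax(law$alpha + law$beta * x0, 0), 1)
}

# inverse-CDF sampler for the linear density a + b*x on [0,1]
sample_linear_density <- function(n, a, b) {
  u <- stats::runif(n)
  if (abs(b) < 1e-12) {
    u
  } else {
    # solve a*x + b*x^2/2 = u
    (-a + sqrt(a^2 + 2 * b * u)) / b
  }
}

toy_cohort <- function(x0, x1, law) {
  p1 <- toy_p1(law, x0)
  y <- stats::rbinom(length(x0), 1L, p1)
  structure(list(
    features = data.frame(x0 = x0, x1 = x1),
    labels = y,
    true_p = p1,
    true_logit = stats::qlogis(pmin(pmax(p1, 1e-12), 1 - 1e-12)),
    schema = data.frame(column = c("x0", "x1"),
                        kind = c("continuous", "continuous"),
                        stringsAsFactors = FALSE),
    law = law
  ), class = "cohort")
}

#' Sample the toy training set
#'
#' `x0` uniform, `x1` from the linear density ramp `w`, labels independent
#' Bernoulli draws from `p1(x0)`.
#'
#' @param law A `toy_law`.
#' @return A `cohort` of `law$n_train` points with stored ground truth.
#' @export
sample_toy_train <- function(law) {
  stopifnot(inherits(law, "toy_law"))
  with_seed(law$seed, {
    x0 <- stats::runif(law$n_train)
    x1 <- sample_linear_density(law$n_train, law$dens_a, law$dens_b)
    toy_cohort(x0, x1, law)
  })
}

#' Sample the toy test set
#'
#' Same label law as training but uniform density on both axes, so the
#' test set covers regions the training density undersampled.
#'
#' @param law A `toy_law`.
#' @return A `cohort` of `law$n_test` points.
#' @export
sample_toy_test <- function(law) {
  stopifnot(inherits(law, "toy_law"))
  with_seed(derive_seed(law$seed, 1L), {
    x0 <- stats::runif(law$n_test)
    x1 <- stats::runif(law$n_test)
    toy_cohort(x0, x1, law)
  })
}

check_in_domain <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("toy points must be 2-column")
  if (any(points < -1e-9 | points > 1 + 1e-9)) {
    stop("points outside the unit-square domain")
  }
  points
}

#' True training-data density of a toy law
#'
#' `p(x0, x1) = 1 * w(x1)`: the x0 factor is uniform, so the joint density
#' is the normalized linear ramp in x1 alone.
#'
#' @param law A `toy_law`.
#' @param points n x 2 matrix of in-domain points.
#' @return Per-point density values.
#' @export
true_density <- function(law, points) {
  points <- check_in_domain(points)
  law$dens_a + law$dens_b * points[, 2L]
}

#' True label noise of a toy law
#'
#' The Bernoulli variance `p1(x0) * (1 - p1(x0))`: the aleatoric
#' uncertainty at each point, a pure function of x0.
#'
#' @inheritParams true_density
#' @return Per-point `p1 (1 - p1)` values.
#' @export
true_label_noise <- function(law, points) {
  points <- check_in_domain(points)
  p1 <- toy_p1(law, points[, 1L])
  p1 * (1 - p1)
}
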