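# Random-Fourier-feature GP head and the SNGP model.

make_rff_head <- function(h_dim = 3L, D = 4096L, ell = 2, lambda = 1,
                          seed = 40L) {
  cfg <- train_config(widths = integer(0), head = "rff",
                      rff_features = D, rff_lengthscale = ell,
                      ridge = lambda, seed = seed)
  logituq:::net_init(h_dim, cfg)$head
}

test_that("RFF inner products approximate the Gaussian kernel", {
  D <- 4096L
  head <- make_rff_head(D = D, ell = 2)
  set.seed(41)
  H <- matrix(stats::rnorm(20 * 3), 20, 3)
  phi <- rff_map(head, H)
  # squared norms concentrate at 1
  expect_true(all(abs(rowSums(phi^2) - 1) < 3 / sqrt(D)))
  expect_true(all(sqrt(rowSums(phi^2)) <= sqrt(2)))
  # cross products match the exact RBF kernel
  K_hat <- tcrossprod(phi)
  d2 <- as.matrix(stats::dist(H))^2
  K <- exp(-d2 / (2 * 2^2))
  expect_lt(max(abs(K_hat - K)), 3 / sqrt(D))
  # frozen projection: same seed, same features
  head2 <- make_rff_head(D = D, ell = 2)
  expect_identical(head$Omega, head2$Omega)
  expect_identical(head$boff, head2$boff)
  expect_error(rff_map(head, matrix(0, 2, 5)), "mismatch")
})

test_that("prior-only precision gives variance phi' phi / lambda", {
  lambda <- 2.5
  head <- make_rff_head(D = 512L, lambda = lambda)
  cfg <- train_config(widths = integer(0), head = "rff",
                      rff_features = 512L, rff_lengthscale = 2,
                      ridge = lambda, seed = 40L)
  net <- logituq:::net_init(3L, cfg)
  # no training data: P = lambda I
  net <- laplace_precision(net, matrix(numeric(0), 0, 3),
                           weights = numeric(0))
  expect_equal(net$head$precision, diag(lambda, 512L), tolerance = 1e-12)
  X <- matrix(stats::rnorm(15), 5, 3)
  post <- predict_latent(net, X)
  phi <- rff_map(net$head, X)
  expect_equal(post$variance, rowSums(phi^2) / lambda, tolerance = 1e-10)
})

test_that("conditioning on more data never inflates predictive variance", {
  cfg <- train_config(widths = integer(0), head = "rff",
                      rff_features = 256L, rff_lengthscale = 1,
                      ridge = 1, seed = 42L)
  net <- logituq:::net_init(1L, cfg)
  set.seed(43)
  X <- matrix(stats::rnorm(30), ncol = 1)
  w <- stats::runif(30, 0.05, 0.25)
  Xq <- matrix(seq(-3, 3, length.out = 11), ncol = 1)
  prev_var <- rep(Inf, 11)
  for (n in c(0L, 5L, 15L, 30L)) {
    net_n <- laplace_precision(net, X[seq_len(n), , drop = FALSE],
                               weights = w[seq_len(n)])
    v <- predict_latent(net_n, Xq)$variance
    expect_true(all(v <= prev_var + 1e-10))
    prev_var <- v
  }
})

test_that("sequential rank-one accumulation equals batch construction", {
  cfg <- train_config(widths = integer(0), head = "rff",
                      rff_features = 128L, rff_lengthscale = 1,
                      ridge = 0.5, seed = 44L)
  net <- logituq:::net_init(2L, cfg)
  set.seed(45)
  X <- matrix(stats::rnorm(24), 12, 2)
  w <- stats::runif(12, 0.01, 0.25)
  phi <- rff_map(net$head, X)
  P_seq <- diag(0.5, 128L)
  for (i in 1:12) P_seq <- P_seq + w[i] * tcrossprod(phi[i, ])
  net_b <- laplace_precision(net, X, weights = w)
  expect_lt(max(abs(P_seq - net_b$head$precision)), 1e-8)
  # eigenvalues bounded below by lambda
  expect_gte(min(eigen(net_b$head$precision, symmetric = TRUE,
                       only.values = TRUE)$values), 0.5 - 1e-8)
})

test_that("variance ignores labels except through the fitted weights", {
  fx <- fixture_sngp_1d()
  net <- fx$model$net
  # rebuild the precision with the labels permuted but the fitted
  # probabilities (hence weights) frozen: variance must not move
  p <- stats::plogis(drop(rff_map(net$head,
                                  logituq:::backbone_forward(net, fx$X)$H) %*%
                            net$head$beta))
  net_perm <- laplace_precision(net, fx$X, weights = p * (1 - p))
  Xq <- matrix(seq(-2.5, 2.5, length.out = 9), ncol = 1)
  expect_equal(predict_latent(net_perm, Xq)$variance,
               predict_latent(fx$model, Xq)$variance, tolerance = 1e-12)
})

test_that("strong prior precision shrinks variance to zero", {
  cfg <- train_config(widths = integer(0), head = "rff",
                      rff_features = 256L, rff_lengthscale = 1,
                      ridge = 1e12, seed = 46L)
  net <- logituq:::net_init(1L, cfg)
  net <- laplace_precision(net, matrix(stats::rnorm(10), ncol = 1),
                           weights = rep(0.25, 10))
  v <- predict_latent(net, matrix(c(-1, 0, 2), ncol = 1))$variance
  expect_lt(max(v), 1e-11)
})

test_that("latent mean and variance match the exact Laplace-weighted GP", {
  fx <- fixture_sngp_1d()
  for (Xq in list(fx$X, matrix(seq(-3, 3, length.out = 21), ncol = 1))) {
    ps <- predict_latent(fx$model, Xq)
    pg <- predict_latent_gp(fx$oracle, Xq)
    expect_lt(sqrt(sum((ps$mean - pg$mean)^2) / sum(pg$mean^2)), 0.05)
    expect_lt(sqrt(sum((ps$variance - pg$variance)^2) /
                     sum(pg$variance^2)), 0.05)
  }
})

test_that("variance is distance-aware on clustered data", {
  cfg <- train_config(widths = integer(0), head = "rff",
                      rff_features = 1024L, rff_lengthscale = 0.5,
                      ridge = 1, seed = 47L)
  net <- logituq:::net_init(1L, cfg)
  set.seed(48)
  X <- matrix(stats::rnorm(60, 0, 0.3), ncol = 1) # dense near 0
  net <- laplace_precision(net, X, weights = rep(0.25, 60))
  v <- predict_latent(net, matrix(c(0, 4), ncol = 1))$variance
  expect_gt(v[2] / v[1], 2)
})

test_that("probability link handles the variance adjustment limits", {
  expect_equal(latent_to_probability(1.2, 0), stats::plogis(1.2))
  expect_equal(latent_to_probability(5, 1e12), 0.5, tolerance = 1e-4)
  # adjusted probability always lies between sigmoid(mean) and 1/2
  grid <- expand.grid(m = seq(-4, 4, by = 0.5), v = c(0.1, 1, 10, 100))
  p_adj <- latent_to_probability(grid$m, grid$v)
  p_raw <- stats::plogis(grid$m)
  expect_true(all(p_adj >= pmin(p_raw, 0.5) - 1e-12 &
                    p_adj <= pmax(p_raw, 0.5) + 1e-12))
  expect_error(latent_to_probability(0, -1))
})

test_that("querying before finalizing the precision errors", {
  cfg <- train_config(widths = integer(0), head = "rff",
                      rff_features = 64L, ridge = 1, seed = 49L)
  net <- logituq:::net_init(2L, cfg)
  expect_error(predict_latent(net, matrix(0, 1, 2)), "not finalized")
})
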