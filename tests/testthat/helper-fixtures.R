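# Shared fixtures, built lazily and cached so expensive fits happen at
# most once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# small linearly separable 2-D problem
separable_data <- function(n = 20L, seed = 42L) {
  set.seed(seed)
  X <- matrix(stats::runif(n * 2, -1, 1), n, 2)
  y <- as.integer(X[, 1] + X[, 2] > 0)
  # keep a margin so the classes are cleanly separable
  keep <- abs(X[, 1] + X[, 2]) > 0.2
  list(X = X[keep, , drop = FALSE], y = y[keep])
}

# noisy logistic 2-D problem with train/validation split
logistic_data <- function(n = 300L, seed = 7L) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n * 2), n, 2)
  y <- stats::rbinom(n, 1L, stats::plogis(1.5 * X[, 1] - X[, 2]))
  tr <- seq_len(floor(0.8 * n))
  va <- setdiff(seq_len(n), tr)
  list(Xtr = X[tr, ], ytr = y[tr], Xval = X[va, ], yval = y[va])
}

tiny_config <- function(...) {
  train_config(widths = c(8L, 8L), lr = 0.05, max_epochs = 40L,
               patience = 8L, seed = 11L, ...)
}

fixture_ensemble <- function() {
  fixture("ensemble", function() {
    d <- logistic_data()
    train_ensemble(d$Xtr, d$ytr, d$Xval, d$yval, tiny_config(), M = 5L)
  })
}

fixture_bnn <- function() {
  fixture("bnn", function() {
    d <- logistic_data()
    train_bnn(d$Xtr, d$ytr, d$Xval, d$yval,
              train_config(widths = c(8L), lr = 0.05, max_epochs = 60L,
                           patience = 60L, seed = 13L))
  })
}

fixture_sngp_1d <- function() {
  # head-only SNGP on a 1-D logistic problem, plus its exact GP oracle
  fixture("sngp_1d", function() {
    set.seed(4)
    n <- 40L
    X <- matrix(sort(stats::runif(n, -2, 2)), ncol = 1)
    y <- stats::rbinom(n, 1L, stats::plogis(1.5 * X[, 1]))
    cfg <- train_config(widths = integer(0), head = "rff",
                        rff_features = 4096L, rff_lengthscale = 2,
                        ridge = 1, lr = 0.05, max_epochs = 30L,
                        patience = 30L, seed = 9L)
    model <- train_sngp(X, y, X, y, cfg, cov_likelihood = "binomial")
    oracle <- gp_classify_laplace(X, y, lengthscale = 2, lambda = 1)
    list(X = X, y = y, model = model, oracle = oracle)
  })
}
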