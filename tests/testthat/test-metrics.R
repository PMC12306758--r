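# Discrimination, calibration, NLL, rank correlation, stratification.

test_that("AUROC equals the pairwise concordance probability", {
  expect_equal(auroc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  set.seed(70)
  n <- 5000L
  y <- stats::rbinom(n, 1L, 0.5)
  s <- stats::runif(n)
  expect_equal(auroc(s, y), 0.5, tolerance = 0.03)
  # brute-force pairwise count at n = 30, with ties
  set.seed(71)
  y30 <- stats::rbinom(30, 1L, 0.4)
  s30 <- round(stats::runif(30), 1)
  pos <- which(y30 == 1L)
  neg <- which(y30 == 0L)
  conc <- 0
  for (i in pos) {
    for (j in neg) {
      conc <- conc + (s30[i] > s30[j]) + 0.5 * (s30[i] == s30[j])
    }
  }
  expect_equal(auroc(s30, y30), conc / (length(pos) * length(neg)),
               tolerance = 1e-12)
  # invariance under strictly monotone transforms
  expect_equal(auroc(exp(3 * s30), y30), auroc(s30, y30))
  expect_error(auroc(s30, rep(1L, 30)), "both classes")
})

test_that("AUPRC is the average precision over positives", {
  expect_equal(auprc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  # hand case: scores descending 0.9(+), 0.8(-), 0.7(+)
  # precision at the two positives: 1/1 and 2/3
  expect_equal(auprc(c(0.7, 0.8, 0.9), c(1, 0, 1)), (1 + 2 / 3) / 2)
  # chance level ~ prevalence
  set.seed(72)
  y <- stats::rbinom(4000L, 1L, 0.25)
  expect_equal(auprc(stats::runif(4000L), y), 0.25, tolerance = 0.05)
})

test_that("ECE matches hand binning and calibrated predictions score 0", {
  # predictions equal to empirical bin frequencies
  p <- c(0.25, 0.25, 0.25, 0.25, 0.75, 0.75, 0.75, 0.75)
  y <- c(1, 0, 0, 0, 1, 1, 1, 0)
  expect_equal(ece(p, y, bins = 2L), 0)
  # two-bin hand case: |0.2 - 0.5| * 1/2 + |0.8 - 1| * 1/2 = 0.25
  expect_equal(ece(c(0.2, 0.2, 0.8, 0.8), c(0, 1, 1, 1), bins = 2L), 0.25)
  # permutation invariance
  set.seed(73)
  p2 <- stats::runif(200)
  y2 <- stats::rbinom(200, 1L, p2)
  perm <- sample(200)
  expect_equal(ece(p2, y2), ece(p2[perm], y2[perm]))
  cc <- calibration_curve(p2, y2, bins = 10L)
  expect_equal(sum(cc$count), 200)
  expect_true(all(cc$mean_prob >= 0 & cc$mean_prob <= 1))
  expect_error(ece(c(0.5, 1.2), c(0, 1)), "0, 1")
})

test_that("NLL is the clipped mean Bernoulli deviance", {
  expect_equal(nll(rep(0.5, 10), stats::rbinom(10, 1, 0.5)), log(2))
  # perfect confident predictions: floor-controlled, -> 0 as floor -> 0
  expect_equal(nll(c(1, 0), c(1, 0), floor = 1e-12), -log(1 - 1e-12))
  expect_lt(nll(c(1, 0), c(1, 0), floor = 1e-15),
            nll(c(1, 0), c(1, 0), floor = 1e-12) + 1e-20)
  # elementwise hand computation on 5 instances
  p <- c(0.2, 0.9, 0.5, 0.7, 0.1)
  y <- c(0, 1, 1, 0, 0)
  hand <- -c(log(0.8), log(0.9), log(0.5), log(0.3), log(0.9))
  expect_equal(nll(p, y, reduce = FALSE), hand)
  expect_equal(nll(p, y), mean(hand))
})

test_that("Spearman matches the closed form on tie-free permutations", {
  set.seed(74)
  for (i in 1:10) {
    x <- sample(10)
    y <- sample(10)
    d2 <- sum((rank(x) - rank(y))^2)
    expect_equal(spearman(x, y), 1 - 6 * d2 / (10 * 99), tolerance = 1e-12)
  }
  x <- stats::rnorm(30)
  expect_equal(spearman(x, exp(2 * x)), 1)
  expect_equal(spearman(x, rev(sort(x))[rank(x)]), -1)
  expect_error(spearman(rep(1, 5), 1:5), "constant")
})

test_that("sliding-window stratification counts and orders windows", {
  # n = 9 -> window 3, 7 windows
  res <- sliding_window_stratification(stats::runif(9), stats::runif(9))
  expect_equal(res$window_size, 3L)
  expect_equal(nrow(res$windows), 7L)
  # NLL strictly increasing with uncertainty -> Spearman 1
  u <- 1:30 / 30
  res2 <- sliding_window_stratification(u * 2, u)
  expect_equal(res2$spearman, 1)
  expect_gt(res2$nll_diff, 0)
  # constant uncertainty is flagged, not silently numeric
  res3 <- sliding_window_stratification(stats::runif(12), rep(0.3, 12))
  expect_true(res3$degenerate)
  expect_true(is.na(res3$spearman))
})

test_that("stratification matches a naive implementation", {
  set.seed(75)
  nll_i <- stats::rexp(30)
  u <- round(stats::runif(30), 1) # ties on purpose
  res <- sliding_window_stratification(nll_i, u)
  # naive: explicit stable sort, explicit windows, cor on ranks
  ord <- order(u, seq_along(u))
  x <- nll_i[ord]
  w <- 10L
  means <- vapply(1:21, function(s) mean(x[s:(s + w - 1L)]), numeric(1))
  expect_equal(res$windows$mean_nll, means, tolerance = 1e-12)
  expect_equal(res$spearman, stats::cor(rank(1:21), rank(means)),
               tolerance = 1e-12)
  expect_equal(res$nll_diff, sum(x[21:30]) - sum(x[1:10]),
               tolerance = 1e-12)
})

test_that("stratification ranking is invariant to the decay rate k", {
  set.seed(76)
  draws <- matrix(stats::rnorm(40 * 8, sd = 1.5), 40, 8)
  post <- logit_posterior(draws = draws)
  nll_i <- stats::rexp(40)
  rhos <- vapply(c(0.2, 1, 5), function(k) {
    sc <- score_instances(post, l1 = -1, k = k)
    sliding_window_stratification(nll_i, sc$u_tot)$spearman
  }, numeric(1))
  expect_equal(rhos[1], rhos[2])
  expect_equal(rhos[2], rhos[3])
})

test_that("uncertainty-vs-truth correlations behave at the extremes", {
  law <- toy_law(seed = 77L)
  set.seed(78)
  pts <- cbind(stats::runif(500), stats::runif(500))
  dens <- true_density(law, pts)
  # u_epi identical to the truth: perfect rank correlation
  r1 <- correlate_uncertainty_with(law, pts, dens, "density")
  expect_equal(r1$spearman, 1)
  # independent u_epi: near-zero correlation
  r0 <- correlate_uncertainty_with(law, pts, stats::runif(500), "density")
  expect_lt(abs(r0$spearman), 0.1)
  # agrees with computing spearman on the exported pairs
  u <- stats::runif(500)
  r2 <- correlate_uncertainty_with(law, pts, u, "noise")
  expect_equal(r2$spearman, spearman(r2$pairs$u_epi, r2$pairs$value))
})

test_that("curvature profile is the inverse Bernoulli information", {
  expect_equal(curvature_profile(0.5), 4)
  p <- c(0.01, 0.2, 0.35)
  expect_equal(curvature_profile(p), curvature_profile(1 - p))
  expect_equal(curvature_profile(0.01) / curvature_profile(0.5),
               (1 / 0.0099) / 4)
  expect_error(curvature_profile(c(0.5, 1)), "0, 1")
})
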