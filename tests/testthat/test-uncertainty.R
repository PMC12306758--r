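# Logit-space uncertainty measures.

test_that("prior log-odds reflects class frequencies", {
  expect_equal(prior_log_odds(c(0, 1, 0, 1)), 0)
  # screening-cohort counts: 536 positive vs 2474 + 4654 negative
  expect_equal(prior_log_odds(rep(c(1L, 0L), c(536L, 7128L))),
               log(536 / 7128))
  expect_equal(round(log(536 / 7128), 3), -2.588)
  expect_error(prior_log_odds(rep(1L, 10)), "both classes")
  # adding equal counts to both classes pulls the prior toward neutrality
  for (n1 in c(2L, 5L)) {
    for (n0 in c(7L, 20L)) {
      for (add in c(3L, 10L)) {
        l_before <- prior_log_odds(rep(c(1L, 0L), c(n1, n0)))
        l_after <- prior_log_odds(rep(c(1L, 0L), c(n1 + add, n0 + add)))
        expect_lt(abs(l_after), abs(l_before) + 1e-12)
      }
    }
  }
})

test_that("Bayes factor is the exponentiated log-odds shift", {
  expect_equal(bayes_factor(-1.3, -1.3), 1)
  expect_equal(bayes_factor(log(2), 0), 2)
  set.seed(1)
  l1x <- stats::rnorm(50)
  l1 <- -2.1
  expect_equal(log(bayes_factor(l1x, l1)), l1x - l1, tolerance = 1e-12)
  expect_true(all(bayes_factor(l1x, l1) > 0))
})

test_that("evidential strength is the absolute posterior-prior mean gap", {
  l1 <- -2.5
  post_neutral <- logit_posterior(draws = matrix(l1, 3, 10))
  expect_equal(evidential_strength(post_neutral, l1), rep(0, 3))
  # symmetric draws around the prior are neutral in the mean
  post_sym <- logit_posterior(draws = cbind(l1 + 0.7, l1 - 0.7))
  expect_equal(evidential_strength(post_sym, l1), 0)
  # matches a naive loop
  set.seed(2)
  draws <- matrix(stats::rnorm(6 * 9), 6, 9)
  post <- logit_posterior(draws = draws)
  naive <- vapply(seq_len(6), function(i) abs(mean(draws[i, ]) - l1),
                  numeric(1))
  expect_equal(evidential_strength(post, l1), naive)
})

test_that("total uncertainty transforms ES into (0, 1]", {
  expect_equal(total_uncertainty(0, k = 1), 1)
  expect_lt(total_uncertainty(1e6, k = 1), 1e-12)
  expect_equal(total_uncertainty(log(2), k = 1), 0.5)
  expect_error(total_uncertainty(1, k = 0), "k must be")
  es <- seq(0, 10, by = 0.5)
  u <- total_uncertainty(es, k = 0.7)
  expect_true(all(diff(u) < 0))
  expect_true(all(u > 0 & u <= 1))
})

test_that("epistemic uncertainty transforms the log-odds variance", {
  delta <- logit_posterior(draws = matrix(1.4, 5, 20))
  expect_equal(epistemic_uncertainty(delta, k = 1), rep(0, 5))
  g0 <- logit_posterior(mean = c(0, 2), variance = c(0, 0))
  expect_equal(epistemic_uncertainty(g0, k = 1), c(0, 0))
  ginf <- logit_posterior(mean = 0, variance = 1e6)
  expect_gt(epistemic_uncertainty(ginf, k = 1), 1 - 1e-12)
  # two-point sample {0, 2}: unbiased variance 2
  two <- logit_posterior(draws = matrix(c(0, 2), 1, 2))
  expect_equal(epistemic_uncertainty(two, k = 1), 1 - exp(-2))
  # single draw: variance undefined, returns 0 with a warning
  expect_warning(
    u1 <- epistemic_uncertainty(logit_posterior(draws = matrix(1, 2, 1))),
    "single draw")
  expect_equal(u1, c(0, 0))
})

test_that("sample-form and Gaussian-form scoring agree for a Gaussian", {
  set.seed(3)
  mu <- c(-3, -1, 0.5)
  sg2 <- c(0.2, 1, 2.3)
  M <- 1e5
  draws <- t(vapply(seq_along(mu), function(i) {
    stats::rnorm(M, mu[i], sqrt(sg2[i]))
  }, numeric(M)))
  l1 <- -2
  s_samp <- score_instances(logit_posterior(draws = draws), l1, k = 1)
  s_gaus <- score_instances(logit_posterior(mean = mu, variance = sg2),
                            l1, k = 1)
  expect_equal(s_samp$es, s_gaus$es, tolerance = 0.02)
  expect_equal(s_samp$u_epi, s_gaus$u_epi, tolerance = 0.02)
})

test_that("scores respect permutation, decay-rate and symmetry contracts", {
  set.seed(4)
  draws <- matrix(stats::rnorm(8 * 30, sd = 2), 8, 30)
  l1 <- -1.2
  post <- logit_posterior(draws = draws)
  sc1 <- score_instances(post, l1, k = 1)
  # permutation of instances permutes scores identically
  perm <- sample(8)
  sc_p <- score_instances(logit_posterior(draws = draws[perm, ]), l1, k = 1)
  expect_equal(sc_p$u_tot, sc1$u_tot[perm])
  expect_equal(sc_p$u_epi, sc1$u_epi[perm])
  # doubling k squares u_tot
  sc2 <- score_instances(post, l1, k = 2)
  expect_equal(sc2$u_tot, sc1$u_tot^2)
  # class relabeling (negate all log-odds) leaves all measures unchanged
  sc_n <- score_instances(logit_posterior(draws = -draws), -l1, k = 1)
  expect_equal(sc_n$es, sc1$es)
  expect_equal(sc_n$u_tot, sc1$u_tot)
  expect_equal(sc_n$u_epi, sc1$u_epi)
  # rank equivalence: u_tot reverses the ES ranking for any k
  for (k in c(0.3, 1, 4)) {
    sck <- score_instances(post, l1, k = k)
    expect_equal(order(sck$u_tot), order(sck$es, decreasing = TRUE))
    expect_equal(rank(sck$u_epi), rank(apply(draws, 1, stats::var)))
  }
  # bounds
  expect_true(all(sc1$u_tot > 0 & sc1$u_tot <= 1))
  expect_true(all(sc1$u_epi >= 0 & sc1$u_epi < 1))
  expect_true(all(sc1$es >= 0))
})

test_that("mixed posterior construction is rejected", {
  expect_error(logit_posterior(draws = matrix(1, 2, 2), mean = 1,
                               variance = 1), "not both")
  expect_error(logit_posterior(mean = 1), "both")
  expect_error(logit_posterior(mean = c(1, 2), variance = c(1, -1)),
               "negative")
})
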