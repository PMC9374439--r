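test_that("C2ST sits at chance for identical distributions and at one for disjoint ones", {
  set.seed(90)
  x <- matrix(rnorm(4000 * 2), 4000, 2)
  sc <- c2st(x[1:2000, ], x[2001:4000, ], seed = 91)
  expect_lt(abs(as.numeric(sc) - 0.5), 0.03)
  a <- matrix(runif(600, 0, 1), 300, 2)
  b <- matrix(runif(600, 10, 11), 300, 2)
  expect_gte(as.numeric(c2st(a, b, seed = 92)), 0.99)
  expect_error(c2st(a, b[, 1, drop = FALSE]), "dimensionality")
  expect_error(c2st(a[1:50, ], b), "at least 100")
})

test_that("C2ST approaches the Bayes accuracy of two unit-variance Gaussians", {
  set.seed(93)
  a <- matrix(rnorm(10000), ncol = 1)
  b <- matrix(rnorm(10000, mean = 1), ncol = 1)
  sc <- as.numeric(c2st(a, b, seed = 94))
  expect_lt(abs(sc - stats::pnorm(0.5)), 0.02)
})

test_that("posterior metrics are exact on constructed cases", {
  set.seed(95)
  ref <- matrix(rnorm(3000 * 3), 3000, 3)
  m_id <- posterior_metrics(ref, ref, true_params = c(0, 0, 0))
  expect_equal(m_id$mean_diff, 0)
  expect_equal(m_id$var_diff, 0)
  expect_lt(abs(m_id$c2st - 0.5), 0.04)
  # shift one dimension by exactly one reference standard deviation
  shifted <- ref
  shifted[, 2] <- shifted[, 2] + stats::sd(ref[, 2])
  m_sh <- posterior_metrics(shifted, ref)
  expect_equal(m_sh$per_dim$mean_diff[2], 1, tolerance = 1e-12)
  expect_equal(m_sh$per_dim$mean_diff[1], 0, tolerance = 1e-12)
  # brute-force recomputation from raw draws
  samples <- matrix(rnorm(2000 * 2, sd = 2), 2000, 2)
  truth <- c(0.3, -0.2)
  m <- posterior_metrics(samples, ref[, 1:2], true_params = truth)
  expect_equal(m$per_dim$mean_diff,
               abs(colMeans(samples) - colMeans(ref[, 1:2])) /
                 apply(ref[, 1:2], 2, stats::sd), tolerance = 1e-12)
  expect_equal(m$per_dim$var_diff,
               abs(apply(samples, 2, stats::var) - apply(ref[, 1:2], 2, stats::var)) /
                 apply(ref[, 1:2], 2, stats::var), tolerance = 1e-12)
  expect_equal(m$mse_mean, mean((colMeans(samples) - truth)^2),
               tolerance = 1e-12)
  expect_error(posterior_metrics(samples, cbind(ref[, 1], 1)), "zero variance")
})

test_that("SBC is uniform when the posterior equals the prior", {
  prior <- ddm_prior()
  res <- sbc(prior,
             simulate_fn = function(theta, seed) NULL,
             posterior_fn = function(obs, seed) sample_prior(prior, 300,
                                                             seed = seed),
             n_runs = 100, L = 300, seed = 96)
  expect_equal(dim(res$ranks), c(100, 4))
  expect_true(all(res$ks_pvalues > 0.01))
})

test_that("SBC flags a degenerate point-mass posterior", {
  prior <- ddm_prior()
  res <- sbc(prior,
             simulate_fn = function(theta, seed) NULL,
             posterior_fn = function(obs, seed)
               matrix(rep(prior$lower, each = 100), 100), # always below truth
             n_runs = 20, L = 100, seed = 97)
  expect_true(all(res$ranks == 100))
  expect_true(all(res$ks_pvalues < 0.01))
})

test_that("SBC passes for an exactly computed truncated-normal posterior", {
  # 1-d toy: theta ~ U(box), y ~ N(theta, 1); the exact posterior is a
  # truncated normal, sampled by inverse-CDF
  prior <- ddm_prior(lower = c(mu = -3), upper = c(mu = 3))
  res <- sbc(prior,
             simulate_fn = function(theta, seed) {
               set.seed(seed); rnorm(1, theta[1], 1)
             },
             posterior_fn = function(y, seed) {
               set.seed(seed)
               plo <- pnorm(-3, y, 1); phi <- pnorm(3, y, 1)
               matrix(qnorm(runif(400, plo, phi), y, 1), ncol = 1)
             },
             n_runs = 100, L = 400, seed = 98)
  expect_true(all(res$ks_pvalues > 0.01))
  # failed runs are skipped and counted
  res2 <- sbc(prior,
              simulate_fn = function(theta, seed) NULL,
              posterior_fn = local({
                k <- 0
                function(obs, seed) {
                  k <<- k + 1
                  if (k == 3) stop("boom")
                  matrix(runif(100, -3, 3), ncol = 1)
                }
              }),
              n_runs = 20, L = 100, seed = 99)
  expect_equal(res2$n_failed, 1)
  expect_equal(nrow(res2$ranks), 19)
})

test_that("likelihood accuracy metrics are zero on self-comparison and finite otherwise", {
  prior <- ddm_prior()
  self <- likelihood_accuracy("analytic", prior, n_obs = 5,
                              n_params_per_obs = 50, seed = 100)
  expect_true(all(as.matrix(self) == 0))
  est <- small_mnle()
  metrics <- likelihood_accuracy(est, prior, n_obs = 5,
                                 n_params_per_obs = 100, seed = 101)
  expect_true(all(as.matrix(metrics) >= 0))
  expect_true(all(is.finite(as.matrix(metrics))))
  expect_length(attr(metrics, "means"), 4)
})

test_that("predictive checks compare observed, prior and posterior simulations", {
  prior <- ddm_prior()
  p0 <- c(v = 0.8, a = 1.2, w = 0.5, tau = 0.4)
  observed <- simulate_ddm(p0, 500, seed = 102)
  sim_fn <- function(theta, seed) {
    mnler::simulate_ddm(theta, nrow(theta), seed = seed)
  }
  # point-mass "posterior" at the truth
  point <- matrix(rep(p0, each = 300), 300, dimnames = list(NULL, names(p0)))
  pc <- predictive_check(point, sim_fn, observed, n_sims = 1000, seed = 103,
                         prior = prior)
  s <- pc$summary
  expect_identical(sort(s$source),
                   sort(c("observed", "posterior_predictive",
                          "prior_predictive")))
  expect_equal(s$n[s$source == "posterior_predictive"], 1000)
  expect_equal(s$n[s$source == "prior_predictive"], 1000)
  f_obs <- s$choice_fraction[s$source == "observed"]
  f_pp <- s$choice_fraction[s$source == "posterior_predictive"]
  se <- sqrt(f_obs * (1 - f_obs)) * sqrt(1 / 1000 + 1 / 500)
  expect_lt(abs(f_pp - f_obs), 3 * se)
  # a concentrated posterior predicts tighter reaction times than the prior
  expect_gte(s$rt_iqr[s$source == "prior_predictive"],
             s$rt_iqr[s$source == "posterior_predictive"])
})
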