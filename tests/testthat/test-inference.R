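test_that("the joint potential matches a naive per-trial loop and respects support", {
  prior <- ddm_prior()
  tr <- param_transform(prior)
  p0 <- c(v = 0.5, a = 1.2, w = 0.5, tau = 0.4)
  tt <- simulate_ddm(p0, 100, seed = 71)
  pot <- joint_potential("analytic", prior, tt)
  u0 <- tr$to_unconstrained(matrix(p0, 1, dimnames = list(NULL, names(p0))))[1, ]
  manual <- sum(wfpt_log_density(tt$choice, tt$rt, p0)) +
    sum(-log(prior$upper - prior$lower)) +
    tr$log_abs_det_jacobian(matrix(u0, 1))
  expect_equal(pot(u0), manual, tolerance = 1e-10)
  # single trial: potential is that trial's contribution alone
  pot1 <- joint_potential("analytic", prior, tt[1, , drop = FALSE])
  manual1 <- wfpt_log_density(tt$choice[1], tt$rt[1], p0) +
    sum(-log(prior$upper - prior$lower)) +
    tr$log_abs_det_jacobian(matrix(u0, 1))
  expect_equal(pot1(u0), manual1, tolerance = 1e-10)
  # non-finite unconstrained states are rejected
  expect_identical(pot(c(Inf, 0, 0, 0)), -Inf)
  # mnle backend agrees with its own batched evaluator
  est <- small_mnle()
  potm <- joint_potential("mnle", prior, tt, est = est)
  manual_m <- sum(mnle_log_prob(est, tt, p0)) +
    sum(-log(prior$upper - prior$lower)) +
    tr$log_abs_det_jacobian(matrix(u0, 1))
  expect_equal(potm(u0), manual_m, tolerance = 1e-8)
  expect_error(joint_potential("mnle", prior, tt), "requires a trained")
})

test_that("SIS initialization reproduces the prior under a flat potential", {
  prior <- ddm_prior()
  tr <- param_transform(prior)
  flat <- function(u) 0
  attr(flat, "transform") <- tr
  starts <- init_chains_sis(flat, prior, n_chains = 400, n_proposals = 5000,
                            seed = 72)
  th <- tr$to_constrained(starts)
  set.seed(1)
  for (j in seq_len(4)) {
    p <- suppressWarnings(stats::ks.test(
      ks_jitter(th[, j], dt = 1e-9),
      function(q) stats::punif(q, prior$lower[j], prior$upper[j]))$p.value)
    expect_gt(p, 0.01)
  }
})

test_that("SIS initialization concentrates on a sharply peaked potential", {
  prior <- ddm_prior()
  tr <- param_transform(prior)
  u_star <- tr$to_unconstrained(
    matrix(c(0.3, 1.2, 0.5, 0.8), 1,
           dimnames = list(NULL, c("v", "a", "w", "tau"))))[1, ]
  peak <- function(u) -sum((u - u_star)^2) / (2 * 0.3^2)
  attr(peak, "transform") <- tr
  starts <- init_chains_sis(peak, prior, n_chains = 50, n_proposals = 8000,
                            seed = 73)
  d <- sqrt(rowSums(sweep(starts, 2, u_star)^2))
  # all starts inside the 99.9% ball of the Gaussian peak
  expect_true(all(d < 0.3 * sqrt(stats::qchisq(0.999, 4))))
  imp <- function(u) -Inf
  attr(imp, "transform") <- tr
  expect_error(init_chains_sis(imp, prior, n_chains = 2, n_proposals = 50),
               "zero or non-finite")
})

test_that("slice sampling recovers a standard normal target", {
  pot <- function(u) -0.5 * sum(u^2)
  set.seed(74)
  starts <- matrix(rnorm(8, sd = 0.5), 4, 2)
  s <- slice_sample(pot, starts, n_samples = 10000, burn_in = 100, thin = 1,
                    seed = 75)
  expect_equal(nrow(s$draws), 10000)
  expect_true(all(abs(colMeans(s$draws)) < 0.05))
  expect_true(all(abs(apply(s$draws, 2, var) - 1) < 0.1))
  expect_identical(sort(unique(s$chain)), 1:4)
})

test_that("slice sampling matches a conjugate Gaussian posterior", {
  # prior mu ~ N(0, 1), data y_i ~ N(mu, sigma^2): posterior in closed form
  set.seed(76)
  sigma <- 1.5
  y <- rnorm(25, 0.7, sigma)
  post_var <- 1 / (1 + length(y) / sigma^2)
  post_mean <- post_var * sum(y) / sigma^2
  pot <- function(u) -0.5 * u^2 - sum((y - u)^2) / (2 * sigma^2)
  s <- slice_sample(pot, matrix(c(0, 1), 2, 1), n_samples = 6000,
                    burn_in = 200, thin = 1, seed = 77)
  x <- s$draws[, 1]
  expect_lt(abs(mean(x) - post_mean), 3 * mcmc_se(x))
  expect_lt(abs(var(x) - post_var), 3 * mcmc_se((x - mean(x))^2))
})

test_that("posterior draws always stay inside the prior box", {
  prior <- ddm_prior()
  p0 <- c(v = 1, a = 1, w = 0.5, tau = 0.5)
  tt <- simulate_ddm(p0, 30, seed = 78)
  cfg <- mcmc_config(n_chains = 2, n_samples = 200, burn_in = 50, thin = 1,
                     n_proposals = 500)
  s <- ddm_posterior(tt, prior, backend = "analytic", config = cfg, seed = 79)
  expect_equal(nrow(s$draws), 200)
  expect_true(all(sweep(s$draws, 2, prior$lower, ">=") &
                    sweep(s$draws, 2, prior$upper, "<=")))
  # determinism of the full pipeline
  s2 <- ddm_posterior(tt, prior, backend = "analytic", config = cfg, seed = 79)
  expect_identical(s$draws, s2$draws)
})

test_that("posterior samples round-trip through CSV", {
  prior <- ddm_prior()
  set.seed(80)
  draws <- sample_prior(prior, 120, seed = 81)
  s <- structure(list(draws = draws, draws_u = NULL,
                      chain = rep(1:2, each = 60), backend = "analytic",
                      n_chains = 2, burn_in = 10, thin = 1),
                 class = "posterior_samples")
  path <- withr::local_tempfile(fileext = ".csv")
  write_posterior(s, path)
  s2 <- read_posterior(path)
  expect_equal(unname(s2$draws), unname(draws))
  expect_identical(s2$chain, rep(1:2, each = 60))
  expect_identical(s2$backend, "analytic")
})

test_that("an ensemble of identical members reproduces the single posterior", {
  est <- small_mnle()
  p0 <- c(v = 0.6, a = 1.1, w = 0.5, tau = 0.6)
  tt <- simulate_ddm(p0, 20, seed = 82)
  cfg <- mcmc_config(n_chains = 2, n_samples = 150, burn_in = 50, thin = 1,
                     n_proposals = 500)
  ens <- ensemble_posterior(list(est, est), ddm_prior(), tt, config = cfg,
                            seed = 83)
  expect_equal(as.integer(table(ens$member)), c(150L, 150L))
  single <- ddm_posterior(tt, ddm_prior(), backend = "mnle", est = est,
                          config = mcmc_config(n_chains = 2, n_samples = 300,
                                               burn_in = 50, thin = 1,
                                               n_proposals = 500),
                          seed = 84)
  # chance level up to small-sample classifier noise (n = 300 per set)
  sc <- c2st(ens$draws, single$draws, seed = 85)
  expect_lt(as.numeric(sc), 0.6)
})
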