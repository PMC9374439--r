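test_that("prior sampling respects bounds, moments and determinism", {
  prior <- ddm_prior()
  th <- sample_prior(prior, 1000, seed = 1)
  expect_equal(dim(th), c(1000, 4))
  expect_true(all(th[, "v"] > -2 & th[, "v"] < 2))
  expect_true(all(th[, "a"] > 0.5 & th[, "a"] < 2))
  expect_true(all(th[, "w"] > 0.3 & th[, "w"] < 0.7))
  expect_true(all(th[, "tau"] > 0.2 & th[, "tau"] < 1.8))
  # per-dimension means within 3 standard errors of the interval midpoint
  th_big <- sample_prior(prior, 1e5, seed = 2)
  mid <- (prior$lower + prior$upper) / 2
  se <- (prior$upper - prior$lower) / sqrt(12) / sqrt(1e5)
  expect_true(all(abs(colMeans(th_big) - mid) < 3 * se))
  # determinism and near-degenerate intervals
  expect_identical(sample_prior(prior, 50, seed = 7),
                   sample_prior(prior, 50, seed = 7))
  eps <- 1e-9
  tiny <- ddm_prior(lower = c(v = 1, a = 1), upper = c(v = 1 + eps, a = 1 + eps))
  expect_true(all(abs(sample_prior(tiny, 5, seed = 1) - 1) <= eps))
})

test_that("invalid prior bounds are rejected", {
  expect_error(ddm_prior(lower = c(v = 1), upper = c(v = 0)), "strictly below")
  expect_error(ddm_prior(lower = c(v = 1), upper = c(a = 2)), "identical names")
})

test_that("prior JSON round-trips", {
  prior <- ddm_prior(collapsing = TRUE)
  path <- withr::local_tempfile(fileext = ".json")
  write_prior_json(prior, path)
  p2 <- read_prior_json(path)
  expect_equal(p2$lower, prior$lower)
  expect_equal(p2$upper, prior$upper)
})

test_that("constant-bound simulator obeys the non-decision offset and symmetry", {
  p <- c(v = 0, a = 1.2, w = 0.5, tau = 0.35)
  tt <- simulate_ddm(p, 20000, seed = 3)
  expect_true(all(tt$rt > 0.35))
  # symmetric setup: choice fraction within 3 SE of one half
  expect_lt(abs(mean(tt$choice) - 0.5), 3 * sqrt(0.25 / 20000))
})

test_that("simulated choice fractions match the analytic absorption probability", {
  for (p in list(c(v = 1, a = 1.5, w = 0.5, tau = 0.3),
                 c(v = -0.8, a = 1.0, w = 0.6, tau = 0.5))) {
    n <- 30000
    tt <- simulate_ddm(p, n, seed = 11)
    p_true <- upper_choice_prob(p["v"], p["a"], p["w"])
    expect_lt(abs(mean(tt$choice) - p_true),
              3 * sqrt(p_true * (1 - p_true) / n))
  }
})

test_that("simulation is deterministic and independent of batching", {
  p <- c(v = 0.5, a = 1, w = 0.5, tau = 0.3)
  a1 <- simulate_ddm(p, 200, seed = 9)
  a2 <- simulate_ddm(p, 200, seed = 9)
  expect_identical(a1$rt, a2$rt)
  expect_identical(a1$choice, a2$choice)
  # per-trial counter-based streams: a shorter run is a prefix of a longer one
  b <- simulate_ddm(p, 50, seed = 9)
  expect_identical(b$rt, a1$rt[1:50])
})

test_that("halving dt changes the choice probability by less than Monte-Carlo error", {
  p <- c(v = 0.6, a = 1.2, w = 0.45, tau = 0.3)
  n <- 30000
  f1 <- mean(simulate_ddm(p, n, dt = 2e-4, seed = 5)$choice)
  f2 <- mean(simulate_ddm(p, n, dt = 1e-4, seed = 6)$choice)
  expect_lt(abs(f1 - f2), 3 * sqrt(0.25 / n) * sqrt(2))
})

test_that("collapsing bounds with zero slope reduce to the constant-bound model", {
  p4 <- c(v = 0.4, a = 1.3, w = 0.55, tau = 0.4)
  p5 <- c(p4, gamma = 0)
  n <- 20000
  const <- simulate_ddm(p4, n, seed = 21)
  coll <- simulate_collapsing_ddm(p5, n, seed = 22)
  expect_true(all(coll$rt > 0.4))
  expect_gt(prop.test(c(sum(const$choice), sum(coll$choice)),
                      c(n, n))$p.value, 0.01)
  set.seed(1)
  expect_gt(suppressWarnings(
    ks.test(ks_jitter(const$rt), ks_jitter(coll$rt))$p.value), 0.01)
})

test_that("collapsing bounds shorten decision times", {
  p <- c(v = 0.3, a = 1.5, w = 0.5, tau = 0.4)
  n <- 20000
  t_const <- mean(simulate_collapsing_ddm(c(p, gamma = 0), n, seed = 31)$rt)
  t_coll <- mean(simulate_collapsing_ddm(c(p, gamma = -0.5), n, seed = 31)$rt)
  expect_lt(t_coll, t_const)
})

test_that("parameter validation rejects out-of-domain values", {
  expect_error(simulate_ddm(c(v = 0, a = -1, w = 0.5, tau = 0.3), 5), "a must")
  expect_error(simulate_ddm(c(v = 0, a = 1, w = 1.2, tau = 0.3), 5), "w must")
  expect_error(simulate_ddm(c(v = 0, a = 1, w = 0.5, tau = -0.1), 5), "tau")
  expect_error(simulate_collapsing_ddm(c(v = 0, a = 1, w = 0.5, tau = 0.3),
                                       5), "gamma")
  expect_error(simulate_ddm(c(v = 0, a = 1, w = 0.5, tau = 0.3, gamma = -1),
                            5), "constant-bound")
})

test_that("training-set generation aligns parameters and trials reproducibly", {
  prior <- ddm_prior()
  ts <- generate_training_set(prior, 100, seed = 8)
  expect_equal(nrow(ts$theta), 100)
  expect_equal(nrow(ts$trials), 100)
  expect_identical(ts$trials$trial, 1:100)
  expect_true(all(ts$trials$rt > ts$theta[, "tau"]))
  ts2 <- generate_training_set(prior, 100, seed = 8)
  expect_identical(ts$theta, ts2$theta)
  expect_identical(ts$trials$rt, ts2$trials$rt)
  expect_error(generate_training_set(prior, 10, model = "ddm_collapse"),
               "gamma")
})

test_that("trial tables round-trip through CSV at full precision", {
  tt <- simulate_ddm(c(v = 1, a = 1, w = 0.5, tau = 0.3), 50, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials(tt, path)
  header <- readLines(path, n = 1)
  expect_identical(header, "trial,choice,rt")
  tt2 <- read_trials(path)
  expect_equal(tt2$rt, tt$rt)
  expect_identical(tt2$choice, tt$choice)
})
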