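# Conditional spline-flow tests: exact invertibility, correct log-Jacobian,
# analytic gradients, normalization, and density recovery on a known target.

make_perturbed_flow <- function(n_transforms = 2, n_bins = 8, seed = 3) {
  set.seed(seed)
  n <- 30
  theta <- cbind(v = runif(n, -2, 2), a = runif(n, 0.5, 2))
  trials <- trial_table(choice = rbinom(n, 1, 0.5), rt = rexp(n) + 0.2)
  hy <- nn_hyper(max_epochs = 0, hidden = c(8, 8),
                 n_transforms = n_transforms, n_bins = n_bins)
  flow <- train_rt_flow(theta, trials, hy, seed = seed)
  for (t in seq_along(flow$nets)) for (l in seq_along(flow$nets[[t]]$W)) {
    W <- flow$nets[[t]]$W[[l]]
    flow$nets[[t]]$W[[l]] <- W + matrix(rnorm(length(W), sd = 0.3), nrow(W))
    flow$nets[[t]]$b[[l]] <- flow$nets[[t]]$b[[l]] +
      rnorm(length(flow$nets[[t]]$b[[l]]), sd = 0.3)
  }
  list(flow = flow, theta = theta, trials = trials)
}

test_that("the spline transform is exactly invertible", {
  ns <- asNamespace("mnler")
  set.seed(5)
  raw <- matrix(rnorm(50 * 29, sd = 0.8), 50, 29)
  sp <- ns$.spline_params(raw, 10L, 10)
  x <- c(runif(46, -9.9, 9.9), -11, 11, -10, 10) # interior + tails + edges
  sp2 <- ns$.spline_params(raw[rep(1, 50), ], 10L, 10)
  fw <- ns$.spline_forward(x, sp)
  back <- ns$.spline_inverse(fw$z, sp)
  expect_lt(max(abs(back - x)), 1e-8)
})

test_that("the log-Jacobian matches a numerical derivative of the map", {
  ns <- asNamespace("mnler")
  set.seed(6)
  raw <- matrix(rnorm(20 * 29, sd = 0.8), 20, 29)
  sp <- ns$.spline_params(raw, 10L, 10)
  x <- runif(20, -9, 9)
  fw <- ns$.spline_forward(x, sp)
  h <- 1e-6
  num <- (ns$.spline_forward(x + h, sp)$z - ns$.spline_forward(x - h, sp)$z) /
    (2 * h)
  expect_equal(fw$logdet, log(num), tolerance = 1e-5)
})

test_that("analytic training gradients match finite differences", {
  ns <- asNamespace("mnler")
  mk <- make_perturbed_flow()
  flow <- mk$flow
  ctx <- ns$.flow_context(flow, mk$theta, mk$trials$choice)
  y_std <- (log(mk$trials$rt) - flow$y_mean) / flow$y_sd
  loss_fn <- function(fl) {
    fw <- ns$.flow_forward_std(fl, ctx, y_std)
    mean(0.5 * fw$z^2 + 0.5 * log(2 * pi) - fw$logdet)
  }
  lg <- ns$.flow_loss_grad(flow, ctx, y_std)
  eps <- 1e-6
  set.seed(8)
  for (t in seq_along(flow$nets)) for (l in seq_along(flow$nets[[t]]$W)) {
    for (k in 1:4) {
      i <- sample(nrow(flow$nets[[t]]$W[[l]]), 1)
      j <- sample(ncol(flow$nets[[t]]$W[[l]]), 1)
      f2 <- flow; f2$nets[[t]]$W[[l]][i, j] <- f2$nets[[t]]$W[[l]][i, j] + eps
      f3 <- flow; f3$nets[[t]]$W[[l]][i, j] <- f3$nets[[t]]$W[[l]][i, j] - eps
      fd <- (loss_fn(f2) - loss_fn(f3)) / (2 * eps)
      an <- unname(lg$grads[[t]]$gW[[l]][i, j])
      expect_equal(an, unname(fd), tolerance = 1e-4)
    }
  }
})

test_that("an arbitrary conditional flow density integrates to one", {
  mk <- make_perturbed_flow(seed = 11)
  flow <- mk$flow
  for (i in 1:3) {
    th <- mk$theta[i, , drop = FALSE]
    cc <- mk$trials$choice[i]
    mass <- stats::integrate(function(r)
      exp(flow_log_density(flow, th, rep(cc, length(r)), r)),
      0, Inf, rel.tol = 1e-6, subdivisions = 2000L)$value
    expect_equal(mass, 1, tolerance = 1e-2)
  }
})

test_that("the flow recovers a known shifted-exponential density", {
  flow <- cached("exp_flow", {
    set.seed(1)
    n <- 5000
    theta <- cbind(v = runif(n, -2, 2), a = runif(n, 0.5, 2))
    trials <- trial_table(choice = rbinom(n, 1, 0.5), rt = 0.5 + rexp(n))
    train_rt_flow(theta, trials, quick_hyper(), seed = 2)
  })
  grid <- seq(0.55, 4, by = 0.05)
  th0 <- cbind(v = 0.3, a = 1.2)
  dens <- exp(flow_log_density(flow, th0, rep(1, length(grid)), grid))
  expect_lt(mean(abs(dens - stats::dexp(grid - 0.5))), 0.05)
})

test_that("flow training is deterministic given the seed", {
  set.seed(10)
  n <- 600
  theta <- cbind(v = runif(n, -2, 2), a = runif(n, 0.5, 2))
  trials <- trial_table(choice = rbinom(n, 1, 0.5), rt = 0.3 + rexp(n))
  hy <- nn_hyper(max_epochs = 5, hidden = c(16, 16))
  f1 <- train_rt_flow(theta, trials, hy, seed = 5)
  f2 <- train_rt_flow(theta, trials, hy, seed = 5)
  expect_identical(f1$best_val, f2$best_val)
  expect_identical(f1$nets[[1]]$W[[1]], f2$nets[[1]]$W[[1]])
})

test_that("emulator samples follow the flow's own density", {
  ns <- asNamespace("mnler")
  flow <- cached("exp_flow", {
    set.seed(1)
    n <- 5000
    theta <- cbind(v = runif(n, -2, 2), a = runif(n, 0.5, 2))
    trials <- trial_table(choice = rbinom(n, 1, 0.5), rt = 0.5 + rexp(n))
    train_rt_flow(theta, trials, quick_hyper(), seed = 2)
  })
  th0 <- cbind(v = 0.3, a = 1.2)
  grid <- seq(1e-4, 15, length.out = 3000)
  d <- exp(flow_log_density(flow, th0, rep(1, length(grid)), grid))
  cdf <- c(0, cumsum((d[-1] + d[-length(d)]) / 2 * diff(grid)))
  Ffun <- stats::approxfun(grid, cdf / max(cdf), yleft = 0, yright = 1)
  set.seed(9)
  s <- ns$.flow_sample(flow, th0, rep(1, 4000))
  expect_gt(suppressWarnings(ks.test(s, Ffun)$p.value), 0.01)
})
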