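# Shared fixtures. Heavy objects (trained estimators) are built once per
# session and cached in the global environment so that several test files
# can reuse them.

if (!exists(".mnler_test_cache", envir = globalenv())) {
  assign(".mnler_test_cache", new.env(parent = emptyenv()),
         envir = globalenv())
}

cached <- function(name, expr) {
  cache <- get(".mnler_test_cache", envir = globalenv())
  if (!exists(name, envir = cache)) assign(name, expr, envir = cache)
  get(name, envir = cache)
}

# closed-form probability that a unit-noise diffusion with drift v started
# at w*a hits the upper bound a before 0 (independent oracle for the
# quadrature-based choice_probability and for simulated choice fractions)
upper_choice_prob <- function(v, a, w) {
  ifelse(abs(v) < 1e-12, w, (1 - exp(-2 * v * w * a)) / (1 - exp(-2 * v * a)))
}

# break the dt-grid ties of simulated reaction times before a KS test
ks_jitter <- function(x, dt = 1e-4) x + stats::runif(length(x), -dt / 2, dt / 2)

quick_hyper <- function(...) nn_hyper(max_epochs = 60, patience = 10, ...)

# small but usable estimator for structural and sampling tests
small_mnle <- function() cached("small_mnle", {
  prior <- ddm_prior()
  ts <- generate_training_set(prior, 8000, seed = 4242)
  train_mnle(ts$theta, ts$trials, prior = prior,
             choice_hyper = quick_hyper(), flow_hyper = quick_hyper(),
             seed = 4242)
})

# batch-means standard error for autocorrelated MCMC draws
mcmc_se <- function(x, n_batches = 20) {
  n <- length(x)
  bs <- floor(n / n_batches)
  bm <- vapply(seq_len(n_batches),
               function(b) mean(x[((b - 1) * bs + 1):(b * bs)]), numeric(1))
  stats::sd(bm) / sqrt(n_batches)
}
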