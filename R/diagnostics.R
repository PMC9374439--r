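# Evaluation machinery: likelihood-accuracy metrics against the analytic
# density, classifier two-sample tests, simulation-based calibration, and
# posterior-predictive checks.

.huber <- function(r, delta = 1) {
  a <- abs(r)
  mean(ifelse(a <= delta, 0.5 * r^2, delta * (a - 0.5 * delta)))
}

#' Likelihood-accuracy metrics against the analytic density
#'
#' For each of `n_obs` single-trial observations simulated from
#' prior-sampled parameters, evaluates the estimated and the analytic
#' likelihood of that observation under `n_params_per_obs` fresh prior
#' draws, and records Huber loss and mean squared error on both the
#' likelihood and the log-likelihood scale. For the log-scale metrics both
#' likelihoods are floored at `lik_floor` (default `1e-7`, the conventional
#' kernel-density floor of likelihood-approximation methods): without a
#' floor, parameter draws just outside the analytic support (`rt` near
#' `tau`) contribute arbitrarily large squared errors and the metric
#' degenerates.
#'
#' @param est a trained [train_mnle()] estimator, or the string
#'   `"analytic"` for a self-comparison (all metrics are then exactly 0)
#' @param prior a [ddm_prior()] without `gamma`
#' @param n_obs number of observations (default 100)
#' @param n_params_per_obs prior draws per observation (default 1000)
#' @param huber_delta Huber threshold (default 1)
#' @param lik_floor floor applied to likelihoods on the log scale
#' @param seed integer seed
#' @return data frame with one row per observation and columns
#'   `huber_lik`, `mse_lik`, `huber_loglik`, `mse_loglik`; column means in
#'   the `"means"` attribute
#' @export
likelihood_accuracy <- function(est, prior, n_obs = 100,
                                n_params_per_obs = 1000, huber_delta = 1,
                                lik_floor = 1e-7, seed = 1) {
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old))
  set.seed(seed)
  theta_obs <- sample_prior(prior, n_obs)
  out <- data.frame(huber_lik = numeric(n_obs), mse_lik = numeric(n_obs),
                    huber_loglik = numeric(n_obs),
                    mse_loglik = numeric(n_obs))
  for (i in seq_len(n_obs)) {
    obs <- simulate_ddm(theta_obs[i, ], 1, seed = seed * 1000 + i)
    theta_test <- sample_prior(prior, n_params_per_obs)
    ll_ref <- vapply(seq_len(n_params_per_obs), function(p)
      wfpt_log_density(obs$choice, obs$rt, theta_test[p, ]), numeric(1))
    ll_est <- if (identical(est, "analytic")) ll_ref
    else mnle_log_prob(est, obs, theta_test)[1, ]
    l_ref <- exp(ll_ref)
    l_est <- exp(ll_est)
    out$huber_lik[i] <- .huber(l_est - l_ref, huber_delta)
    out$mse_lik[i] <- mean((l_est - l_ref)^2)
    lf <- log(lik_floor)
    d_log <- pmax(ll_est, lf) - pmax(ll_ref, lf)
    out$huber_loglik[i] <- .huber(d_log, huber_delta)
    out$mse_loglik[i] <- mean(d_log^2)
  }
  attr(out, "means") <- colMeans(out)
  out
}

#' Classifier two-sample test (C2ST)
#'
#' Cross-validated held-out accuracy of a classifier trained to distinguish
#' two sample sets. Samples are z-scored jointly and the classes balanced by
#' subsampling the larger set. An accuracy of 0.5 means the distributions
#' are indistinguishable to the classifier; 1.0 means perfectly separable.
#'
#' @param samples_a,samples_b matrices with equal numbers of columns (or
#'   `posterior_samples` objects), at least 100 rows each
#' @param folds number of cross-validation folds (default 5)
#' @param seed integer seed
#' @param classifier `"mlp"` (small feed-forward network, default) or
#'   `"logistic"`
#' @return mean held-out accuracy, with per-fold accuracies in the
#'   `"folds"` attribute
#' @export
c2st <- function(samples_a, samples_b, folds = 5, seed = 1,
                 classifier = c("mlp", "logistic")) {
  classifier <- match.arg(classifier)
  if (inherits(samples_a, "posterior_samples")) samples_a <- samples_a$draws
  if (inherits(samples_b, "posterior_samples")) samples_b <- samples_b$draws
  samples_a <- as.matrix(samples_a)
  samples_b <- as.matrix(samples_b)
  if (ncol(samples_a) != ncol(samples_b))
    stop("sample sets have different dimensionality", call. = FALSE)
  if (nrow(samples_a) < 100 || nrow(samples_b) < 100)
    stop("need at least 100 draws per sample set", call. = FALSE)
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old))
  set.seed(seed)
  n <- min(nrow(samples_a), nrow(samples_b))
  X <- rbind(samples_a[sample(nrow(samples_a), n), , drop = FALSE],
             samples_b[sample(nrow(samples_b), n), , drop = FALSE])
  y <- rep(c(0, 1), each = n)
  X <- scale(X)
  X[!is.finite(X)] <- 0  # constant dimensions carry no signal
  perm <- sample(2 * n)
  X <- X[perm, , drop = FALSE]
  y <- y[perm]
  fold_id <- rep_len(seq_len(folds), 2 * n)
  acc <- numeric(folds)
  for (f in seq_len(folds)) {
    tr_i <- which(fold_id != f)
    te_i <- which(fold_id == f)
    if (classifier == "logistic") {
      df <- data.frame(y = y[tr_i], X[tr_i, , drop = FALSE])
      fit <- suppressWarnings(stats::glm(y ~ ., data = df,
                                         family = stats::binomial()))
      pr <- stats::predict(fit, newdata = data.frame(X[te_i, , drop = FALSE]),
                           type = "response")
      acc[f] <- mean((pr > 0.5) == y[te_i])
    } else {
      acc[f] <- .c2st_mlp_fold(X[tr_i, , drop = FALSE], y[tr_i],
                               X[te_i, , drop = FALSE], y[te_i])
    }
  }
  structure(mean(acc), folds = acc)
}

# small fixed-budget MLP classifier for one CV fold; L2 weight decay keeps
# the classifier from memorizing individual draws, which would bias the
# held-out accuracy on strongly overlapping sample sets
.c2st_mlp_fold <- function(Xtr, ytr, Xte, yte, hidden = c(16, 16),
                           epochs = 40, batch = 200, lr = 2e-3,
                           weight_decay = 2e-2) {
  net <- .mlp_init(ncol(Xtr), hidden, 1)
  state <- .adam_init(net)
  n <- nrow(Xtr)
  for (ep in seq_len(epochs)) {
    idx_all <- sample(n)
    nb <- ceiling(n / batch)
    for (bi in seq_len(nb)) {
      idx <- idx_all[((bi - 1) * batch + 1):min(bi * batch, n)]
      fw <- .mlp_forward(net, Xtr[idx, , drop = FALSE], cache = TRUE)
      logit <- fw$out[, 1]
      dlogit <- (stats::plogis(logit) - ytr[idx]) / length(idx)
      g <- .mlp_backward(net, fw, cbind(dlogit))
      for (l in seq_along(g$gW))
        g$gW[[l]] <- g$gW[[l]] + weight_decay * net$W[[l]]
      st <- .adam_step(net, g, state, lr)
      net <- st$net
      state <- st$state
    }
  }
  pr <- stats::plogis(.mlp_forward(net, Xte)[, 1])
  mean((pr > 0.5) == yte)
}

#' Simulation-based calibration (SBC)
#'
#' Repeatedly draws a ground-truth parameter from the prior, simulates an
#' observation, infers a posterior, and ranks the ground truth among `L`
#' posterior draws per dimension. For a calibrated inference procedure the
#' ranks are uniform on `{0, ..., L}`; per-dimension uniformity is tested
#' with a Kolmogorov-Smirnov test on the randomized probability integral
#' transform of the ranks.
#'
#' @param prior a [ddm_prior()]
#' @param simulate_fn function `(theta, seed) -> observation` (any object
#'   the posterior function accepts)
#' @param posterior_fn function `(observation, seed) -> draw matrix` with at
#'   least `L` rows (columns in prior order)
#' @param n_runs number of SBC runs (>= 20)
#' @param L posterior draws per run used for ranking (default 1000)
#' @param seed integer seed
#' @return list with `ranks` (completed-runs x d matrix), `L`,
#'   `n_failed`, `ks_pvalues` (per dimension), and `ecdf` (plot data:
#'   normalized rank grid and empirical CDF per dimension)
#' @export
sbc <- function(prior, simulate_fn, posterior_fn, n_runs, L = 1000,
                seed = 1) {
  stopifnot(n_runs >= 20)
  d <- prior_dim(prior)
  ranks <- matrix(NA_integer_, n_runs, d,
                  dimnames = list(NULL, prior$names))
  n_failed <- 0
  for (r in seq_len(n_runs)) {
    run_seed <- seed * 10000 + r
    theta_star <- sample_prior(prior, 1, seed = run_seed)[1, ]
    obs <- simulate_fn(theta_star, run_seed + 1)
    draws <- tryCatch(posterior_fn(obs, run_seed + 2), error = function(e) {
      message("sbc: run ", r, " failed (", conditionMessage(e), "); skipped")
      NULL
    })
    if (is.null(draws)) { n_failed <- n_failed + 1; next }
    draws <- as.matrix(draws)
    if (nrow(draws) < L)
      stop("posterior_fn returned fewer than L = ", L, " draws",
           call. = FALSE)
    draws <- draws[seq_len(L), , drop = FALSE]
    ranks[r, ] <- colSums(sweep(draws, 2, theta_star, "<"))
  }
  ranks <- ranks[stats::complete.cases(ranks), , drop = FALSE]
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old))
  set.seed(seed)
  u <- (ranks + matrix(stats::runif(length(ranks)), nrow(ranks))) / (L + 1)
  ks_p <- apply(u, 2, function(x)
    suppressWarnings(stats::ks.test(x, "punif"))$p.value)
  grid <- seq(0, 1, length.out = 101)
  ecdf_mat <- apply(ranks / L, 2, function(x) stats::ecdf(x)(grid))
  list(ranks = ranks, L = L, n_failed = n_failed, ks_pvalues = ks_p,
       ecdf = list(grid = grid, cdf = ecdf_mat))
}

#' Write SBC rank arrays as CSV
#'
#' Long format with header `run,param,rank`, one row per completed run and
#' parameter dimension.
#' @param res result of [sbc()]
#' @param path output CSV path
#' @export
write_sbc_ranks <- function(res, path) {
  df <- data.frame(
    run = rep(seq_len(nrow(res$ranks)), times = ncol(res$ranks)),
    param = rep(colnames(res$ranks), each = nrow(res$ranks)),
    rank = as.vector(res$ranks))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Posterior accuracy metrics against a reference posterior
#'
#' Per-dimension and dimension-averaged discrepancies between an
#' approximate posterior sample and a reference sample: absolute difference
#' in posterior means normalized by the reference standard deviation,
#' absolute difference in posterior variances normalized by the reference
#' variance, mean squared error of the posterior mean against the
#' ground-truth parameters, and the C2ST score between the two samples.
#'
#' @param samples,reference_samples draw matrices (or `posterior_samples`)
#' @param true_params optional ground-truth parameter vector
#' @param c2st_seed seed for the C2ST classifier
#' @return list with `per_dim` data frame and scalar summaries
#'   `mean_diff`, `var_diff`, `mse_mean` (averaged over dimensions) and
#'   `c2st`
#' @export
posterior_metrics <- function(samples, reference_samples, true_params = NULL,
                              c2st_seed = 1) {
  if (inherits(samples, "posterior_samples")) samples <- samples$draws
  if (inherits(reference_samples, "posterior_samples"))
    reference_samples <- reference_samples$draws
  samples <- as.matrix(samples)
  reference_samples <- as.matrix(reference_samples)
  if (ncol(samples) != ncol(reference_samples))
    stop("sample sets have different dimensionality", call. = FALSE)
  m_s <- colMeans(samples)
  m_r <- colMeans(reference_samples)
  v_s <- apply(samples, 2, stats::var)
  v_r <- apply(reference_samples, 2, stats::var)
  if (any(v_r <= 0))
    stop("reference posterior has zero variance in some dimension",
         call. = FALSE)
  per_dim <- data.frame(
    mean_diff = abs(m_s - m_r) / sqrt(v_r),
    var_diff = abs(v_s - v_r) / v_r)
  if (!is.null(true_params))
    per_dim$se_mean <- (m_s - true_params)^2
  score <- c2st(samples, reference_samples, seed = c2st_seed)
  list(per_dim = per_dim,
       mean_diff = mean(per_dim$mean_diff),
       var_diff = mean(per_dim$var_diff),
       mse_mean = if (!is.null(true_params)) mean(per_dim$se_mean),
       c2st = as.numeric(score))
}

#' Posterior-predictive check
#'
#' Simulates trials from parameters resampled from the posterior (and, if a
#' prior is given, from the prior) and compares choice fractions and
#' reaction-time quantiles with the observed data.
#'
#' @param posterior_samples a `posterior_samples` object or draw matrix
#' @param simulator function `(theta_matrix, seed) -> trial_table`
#'   simulating one trial per row of `theta_matrix`
#' @param observed the observed [trial_table()]
#' @param n_sims number of predictive trials per source
#' @param seed integer seed
#' @param prior optional [ddm_prior()] for a prior-predictive reference
#' @return list with `summary` (one row per source: choice fraction and rt
#'   quantiles) and `samples` (the predictive trial tables)
#' @export
predictive_check <- function(posterior_samples, simulator, observed,
                             n_sims = 1000, seed = 1, prior = NULL) {
  draws <- if (inherits(posterior_samples, "posterior_samples"))
    posterior_samples$draws else as.matrix(posterior_samples)
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old))
  set.seed(seed)
  idx <- sample(nrow(draws), n_sims, replace = TRUE)
  post_pred <- simulator(draws[idx, , drop = FALSE], seed + 1)
  sources <- list(observed = observed, posterior_predictive = post_pred)
  if (!is.null(prior)) {
    theta_prior <- sample_prior(prior, n_sims, seed = seed + 2)
    sources$prior_predictive <- simulator(theta_prior, seed + 3)
  }
  qs <- c(0.05, 0.25, 0.5, 0.75, 0.95)
  summ <- do.call(rbind, lapply(names(sources), function(nm) {
    tt <- sources[[nm]]
    data.frame(source = nm, n = nrow(tt),
               choice_fraction = mean(tt$choice),
               rt_iqr = stats::IQR(tt$rt),
               t(stats::setNames(stats::quantile(tt$rt, qs),
                                 paste0("rt_q", qs * 100))))
  }))
  list(summary = summ, samples = sources)
}
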