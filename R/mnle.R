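#' Train a mixed neural likelihood estimator
#'
#' The mixed likelihood estimator factorizes the joint likelihood of a trial
#' `(c, rt)` into a discrete and a continuous part,
#' `q(c, rt | theta) = q(c | theta) * q(rt | c, theta)`,
#' and trains the two components separately on the same simulated data: a
#' Bernoulli choice network ([train_choice_model()]) and a conditional
#' spline flow over log reaction times ([train_rt_flow()]).
#'
#' @param theta parameter matrix (one row per simulated trial)
#' @param trials a [trial_table()] aligned with `theta`
#' @param prior optional [ddm_prior()] recorded as the training proposal
#' @param choice_hyper,flow_hyper [nn_hyper()] configs for the two
#'   components
#' @param seed integer seed; component seeds are derived from it
#' @return an object of class `mnle_estimator`
#' @examples
#' \donttest{
#' prior <- ddm_prior()
#' ts <- generate_training_set(prior, 2000, seed = 1)
#' est <- train_mnle(ts$theta, ts$trials, prior = prior, seed = 1)
#' }
#' @export
train_mnle <- function(theta, trials, prior = NULL,
                       choice_hyper = nn_hyper(), flow_hyper = nn_hyper(),
                       seed = 1) {
  theta <- .as_param_matrix(theta)
  stopifnot(nrow(theta) == nrow(trials))
  choice_model <- train_choice_model(theta, trials$choice, choice_hyper,
                                     seed = seed * 2 + 1)
  rt_flow <- train_rt_flow(theta, trials, flow_hyper, seed = seed * 2 + 2)
  structure(list(choice_model = choice_model, rt_flow = rt_flow,
                 prior = prior, n_train = nrow(theta), seed = seed,
                 param_names = colnames(theta)),
            class = "mnle_estimator")
}

#' @export
print.mnle_estimator <- function(x, ...) {
  cat("Mixed neural likelihood estimator\n")
  cat("  training budget:", x$n_train, "simulations | trained:",
      x$choice_model$trained && x$rt_flow$trained, "\n")
  cat("  choice net hidden:", paste(x$choice_model$hidden, collapse = "x"),
      "| flow:", x$rt_flow$n_transforms, "transforms,",
      x$rt_flow$K, "bins, tail bound", x$rt_flow$B, "\n")
  if (!is.null(x$rt_flow$best_val))
    cat("  validation NLL (flow):", signif(x$rt_flow$best_val, 5), "\n")
  invisible(x)
}

#' Evaluate the learned joint log-likelihood
#'
#' Computes `log q(c | theta) + log q(rt | c, theta)` for every combination
#' of trial and parameter vector, the access pattern used during MCMC
#' (many trials evaluated under a batch of parameters at once).
#'
#' @param est a trained [train_mnle()] estimator
#' @param trials a [trial_table()] (or data frame with `choice`, `rt`)
#' @param theta parameter matrix, one row per parameter vector
#' @param use_cpp evaluate with the compiled forward pass (default); the
#'   reference R path is retained for verification
#' @return an `n_trials` x `n_params` matrix of log-densities; entries are
#'   `-Inf` where `rt <= 0`
#' @export
mnle_log_prob <- function(est, trials, theta, use_cpp = TRUE) {
  stopifnot(inherits(est, "mnle_estimator"))
  if (!(est$choice_model$trained || est$rt_flow$trained) &&
      is.null(est$choice_model$net))
    stop("estimator has no fitted components", call. = FALSE)
  theta <- .as_param_matrix(theta)
  if (use_cpp) return(.mnle_log_prob_cpp_path(est, trials, theta))
  n_t <- nrow(trials)
  n_p <- nrow(theta)
  out <- matrix(NA_real_, n_t, n_p)
  rho_logit <- stats::qlogis(predict_choice_prob(est$choice_model, theta))
  for (p in seq_len(n_p)) {
    ll_c <- ifelse(trials$choice == 1,
                   -.softplus(-rho_logit[p]), -.softplus(rho_logit[p]))
    ll_rt <- flow_log_density(est$rt_flow, theta[p, , drop = FALSE],
                              trials$choice, trials$rt)
    out[, p] <- ll_c + ll_rt
  }
  out
}

# prebuilt fast closure for MCMC: theta vector -> summed log-likelihood of
# the trial table; avoids per-call marshalling of the network weights
.mnle_loglik_closure <- function(est, trials, param_order = NULL) {
  cm <- est$choice_model
  fl <- est$rt_flow
  cmW <- cm$net$W; cmb <- cm$net$b
  flW <- lapply(fl$nets, `[[`, "W")
  flb <- lapply(fl$nets, `[[`, "b")
  ch <- as.integer(trials$choice)
  rt <- trials$rt
  if (!is.null(param_order) && !is.null(est$param_names) &&
      !identical(param_order, est$param_names)) {
    ip <- match(est$param_names, param_order)
    if (any(is.na(ip)))
      stop("estimator parameters (", paste(est$param_names, collapse = ", "),
           ") do not match the prior (", paste(param_order, collapse = ", "),
           ")", call. = FALSE)
    return(local({
      inner <- .mnle_loglik_closure(est, trials)
      function(theta) inner(theta[ip])
    }))
  }
  function(theta) {
    tcm <- matrix((theta - cm$ctx_mean) / cm$ctx_sd, nrow = 1)
    tfl <- matrix((theta - fl$ctx_mean) / fl$ctx_sd, nrow = 1)
    sum(.mnle_logprob_cpp(ch, rt, tcm, tfl, cmW, cmb, flW, flb,
                          fl$K, fl$B, fl$y_mean, fl$y_sd,
                          .SPLINE_MIN_BIN, .SPLINE_MIN_DERIV,
                          .SPLINE_DERIV_OFFSET))
  }
}

# compiled forward pass shared by MCMC; mirrors the R reference path exactly
.mnle_log_prob_cpp_path <- function(est, trials, theta) {
  cm <- est$choice_model
  fl <- est$rt_flow
  theta_cm <- sweep(sweep(theta, 2, cm$ctx_mean, "-"), 2, cm$ctx_sd, "/")
  theta_fl <- sweep(sweep(theta, 2, fl$ctx_mean, "-"), 2, fl$ctx_sd, "/")
  .mnle_logprob_cpp(as.integer(trials$choice), trials$rt,
                    theta_cm, theta_fl,
                    cm$net$W, cm$net$b,
                    lapply(fl$nets, `[[`, "W"), lapply(fl$nets, `[[`, "b"),
                    fl$K, fl$B, fl$y_mean, fl$y_sd,
                    .SPLINE_MIN_BIN, .SPLINE_MIN_DERIV,
                    .SPLINE_DERIV_OFFSET)
}

#' Sample synthetic trials from the estimator (emulator property)
#'
#' Draws `c ~ Bernoulli(rho(theta))` from the choice network and then
#' `rt` from the flow conditioned on `(theta, c)` -- synthetic data without
#' running the simulator.
#'
#' @param est a trained [train_mnle()] estimator
#' @param params a single parameter vector (named or in training order)
#' @param n number of trials
#' @param seed integer seed
#' @return a [trial_table()] with `n` rows
#' @export
mnle_sample <- function(est, params, n, seed = NULL) {
  stopifnot(inherits(est, "mnle_estimator"), n >= 1)
  theta <- .as_param_matrix(params)
  if (!is.null(seed)) {
    old <- .save_rng_state()
    on.exit(.restore_rng_state(old))
    set.seed(seed)
  }
  rho <- predict_choice_prob(est$choice_model, theta)
  choice <- stats::rbinom(n, 1, rho)
  rt <- .flow_sample(est$rt_flow, theta, choice)
  trial_table(choice = choice, rt = rt)
}

#' Save / load an estimator checkpoint
#'
#' The checkpoint is a single JSON archive holding both components' weights,
#' architecture descriptors, standardization statistics and (if present) the
#' training proposal prior. Loading validates the weight shapes against the
#' declared architecture and fails loudly on any mismatch.
#'
#' @param est an `mnle_estimator`
#' @param path file path for the JSON checkpoint
#' @export
save_mnle <- function(est, path) {
  ser_net <- function(net) list(
    dims = net$dims,
    W = lapply(net$W, function(m) list(dim = dim(m), data = as.numeric(m))),
    b = net$b)
  obj <- list(
    format = "mnler-checkpoint-1",
    n_train = est$n_train, seed = est$seed,
    param_names = est$param_names,
    prior = if (!is.null(est$prior))
      list(lower = as.list(est$prior$lower),
           upper = as.list(est$prior$upper)),
    choice_model = list(
      ctx_mean = est$choice_model$ctx_mean, ctx_sd = est$choice_model$ctx_sd,
      hidden = est$choice_model$hidden, trained = est$choice_model$trained,
      net = ser_net(est$choice_model$net)),
    rt_flow = list(
      K = est$rt_flow$K, B = est$rt_flow$B,
      n_transforms = est$rt_flow$n_transforms,
      ctx_mean = est$rt_flow$ctx_mean, ctx_sd = est$rt_flow$ctx_sd,
      y_mean = est$rt_flow$y_mean, y_sd = est$rt_flow$y_sd,
      hidden = est$rt_flow$hidden, trained = est$rt_flow$trained,
      nets = lapply(est$rt_flow$nets, ser_net)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_mnle
#' @return `load_mnle` returns the restored `mnle_estimator`
#' @export
load_mnle <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$format) || obj$format != "mnler-checkpoint-1")
    stop("not an mnler checkpoint: ", path, call. = FALSE)
  obj$param_names <- unlist(obj$param_names)
  de_net <- function(sn, d_in, hidden, d_out, what) {
    dims <- as.numeric(unlist(sn$dims))
    if (!identical(dims, as.numeric(c(d_in, hidden, d_out))))
      stop("checkpoint descriptor mismatch in ", what,
           ": stored dims (", paste(dims, collapse = ", "),
           ") do not match declared architecture (",
           paste(c(d_in, hidden, d_out), collapse = ", "), ")",
           call. = FALSE)
    L <- length(dims) - 1
    W <- vector("list", L)
    for (l in seq_len(L)) {
      wl <- sn$W[[l]]
      wd <- as.integer(unlist(wl$dim))
      m <- matrix(as.numeric(unlist(wl$data)), wd[1], wd[2])
      if (!identical(dim(m), as.integer(dims[l:(l + 1)])))
        stop("checkpoint weight shape mismatch in ", what, " layer ", l,
             call. = FALSE)
      W[[l]] <- m
    }
    b <- lapply(sn$b, function(x) as.numeric(unlist(x)))
    list(W = W, b = b, dims = dims, L = L)
  }
  d <- length(obj$param_names)
  cm <- obj$choice_model
  choice_model <- structure(list(
    ctx_mean = unlist(cm$ctx_mean), ctx_sd = unlist(cm$ctx_sd),
    d_theta = d, param_names = obj$param_names, hidden = unlist(cm$hidden),
    trained = isTRUE(cm$trained),
    net = de_net(cm$net, d, unlist(cm$hidden), 1, "choice model")),
    class = "choice_model")
  flj <- obj$rt_flow
  nets <- lapply(seq_len(flj$n_transforms), function(t)
    de_net(flj$nets[[t]], d + 1, unlist(flj$hidden), 3 * flj$K - 1,
           paste("flow transform", t)))
  rt_flow <- structure(list(
    K = flj$K, B = flj$B, n_transforms = flj$n_transforms,
    ctx_mean = unlist(flj$ctx_mean), ctx_sd = unlist(flj$ctx_sd),
    y_mean = flj$y_mean, y_sd = flj$y_sd, d_theta = d,
    param_names = obj$param_names, hidden = unlist(flj$hidden),
    trained = isTRUE(flj$trained), nets = nets), class = "rt_flow")
  prior <- if (!is.null(obj$prior))
    ddm_prior(lower = unlist(obj$prior$lower), upper = unlist(obj$prior$upper))
  structure(list(choice_model = choice_model, rt_flow = rt_flow,
                 prior = prior, n_train = obj$n_train, seed = obj$seed,
                 param_names = obj$param_names),
            class = "mnle_estimator")
}
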