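#' Simulate the simple drift-diffusion model
#'
#' Euler-Maruyama simulation of a decision variable `X` with drift `v` and
#' unit noise between an absorbing lower bound at 0 and upper bound at `a`,
#' starting at `w * a`. A trial ends when `X` crosses a bound: choice `c = 1`
#' on the upper bound, `c = 0` on the lower bound, and the reaction time is
#' the non-decision time `tau` plus the first-passage time. A within-step
#' Brownian-bridge crossing test removes the boundary discretization bias of
#' the Euler scheme.
#'
#' Trajectories not absorbed within `max_t` seconds of decision time are
#' resimulated with a fresh stream up to 3 times, after which an error is
#' raised (silent censoring would bias the output).
#'
#' @param params named numeric vector (or single-row matrix) with `v`, `a`,
#'   `w`, `tau` (and optionally `gamma` for [simulate_collapsing_ddm()]).
#'   Alternatively a matrix with `n_trials` rows for per-trial parameters.
#' @param n_trials number of trials to simulate
#' @param dt Euler step in seconds (default 1e-4)
#' @param max_t decision-time cap in seconds beyond `tau` (default 10)
#' @param seed integer seed; per-trial streams are derived from it with a
#'   counter-based scheme, so the output is independent of batching
#' @return a `trial_table` data frame with columns `trial`, `choice`, `rt`.
#'   For the collapsing-bound model, the attribute `"forced"` marks trials
#'   decided at the bound-pinch time.
#' @examples
#' x <- simulate_ddm(c(v = 1, a = 1.5, w = 0.5, tau = 0.3), 10, seed = 1)
#' @export
simulate_ddm <- function(params, n_trials, dt = 1e-4, max_t = 10, seed = 1) {
  p <- .check_ddm_params(params, need_gamma = FALSE)
  if (any(p$gamma != 0))
    stop("simulate_ddm() is the constant-bound model; use ",
         "simulate_collapsing_ddm() for gamma < 0", call. = FALSE)
  .simulate_impl(p, n_trials, dt, max_t, seed)
}

#' Simulate the DDM with linearly collapsing bounds
#'
#' As [simulate_ddm()], but with symmetric linearly collapsing bounds:
#' `b_up(t) = a + gamma * t` and `b_lo(t) = -gamma * t` with slope
#' `gamma <= 0`, so both bounds approach `a / 2`. If the bounds meet before
#' absorption, a decision is forced at the pinch time (the choice given by
#' the side of `a / 2` the decision variable is on) and the trial is flagged
#' in the `"forced"` attribute.
#'
#' @inheritParams simulate_ddm
#' @export
simulate_collapsing_ddm <- function(params, n_trials, dt = 1e-4, max_t = 10,
                                    seed = 1) {
  p <- .check_ddm_params(params, need_gamma = TRUE)
  .simulate_impl(p, n_trials, dt, max_t, seed)
}

.simulate_impl <- function(p, n_trials, dt, max_t, seed) {
  stopifnot(n_trials >= 1, dt > 0, max_t > 0)
  res <- .ddm_sim_cpp(as.integer(n_trials), p$v, p$a, p$w, p$tau, p$gamma,
                      dt, max_t, as.numeric(seed), 3L)
  out <- trial_table(choice = res$choice, rt = res$rt)
  attr(out, "forced") <- which(res$forced)
  out
}

.check_ddm_params <- function(params, need_gamma = FALSE) {
  params <- .as_param_matrix(params)
  nm <- colnames(params)
  if (is.null(nm)) {
    nm <- if (ncol(params) >= 5) c("v", "a", "w", "tau", "gamma")[seq_len(ncol(params))]
          else c("v", "a", "w", "tau")[seq_len(ncol(params))]
    colnames(params) <- nm
  }
  need <- c("v", "a", "w", "tau")
  if (!all(need %in% nm))
    stop("params must contain v, a, w, tau", call. = FALSE)
  v <- params[, "v"]; a <- params[, "a"]; w <- params[, "w"]
  tau <- params[, "tau"]
  gamma <- if ("gamma" %in% nm) params[, "gamma"] else rep(0, nrow(params))
  if (need_gamma && !"gamma" %in% nm)
    stop("collapsing-bound model requires a gamma parameter", call. = FALSE)
  if (any(a <= 0)) stop("boundary separation a must be > 0", call. = FALSE)
  if (any(w <= 0 | w >= 1)) stop("starting point w must be in (0, 1)",
                                 call. = FALSE)
  if (any(tau <= 0)) stop("non-decision time tau must be > 0", call. = FALSE)
  if (any(gamma > 0)) stop("collapse slope gamma must be <= 0", call. = FALSE)
  list(v = v, a = a, w = w, tau = tau, gamma = gamma)
}

#' Construct / validate a trial table
#'
#' A trial table is the package's observation container: one row per trial
#' with a binary choice (0 = lower bound, 1 = upper bound) and a reaction
#' time in seconds.
#'
#' @param choice integer vector of 0/1 choices
#' @param rt numeric vector of reaction times (> 0), same length
#' @return a data frame of class `trial_table` with columns `trial`,
#'   `choice`, `rt`
#' @export
trial_table <- function(choice, rt) {
  if (length(choice) != length(rt))
    stop("choice and rt must have the same length", call. = FALSE)
  if (length(choice) == 0) stop("trial table must be nonempty", call. = FALSE)
  choice <- as.integer(choice)
  if (any(!choice %in% c(0L, 1L))) stop("choices must be 0 or 1", call. = FALSE)
  if (any(!is.finite(rt)) || any(rt <= 0))
    stop("reaction times must be finite and > 0", call. = FALSE)
  structure(data.frame(trial = seq_along(choice), choice = choice, rt = rt),
            class = c("trial_table", "data.frame"))
}

#' Generate a training set of (parameters, simulation) pairs
#'
#' Draws `N` parameter vectors from the prior and runs exactly one simulation
#' per vector, the training-data layout used to fit the mixed likelihood
#' estimator.
#'
#' @param prior a [ddm_prior()]; must include `gamma` when
#'   `model = "ddm_collapse"`
#' @param N simulation budget (one trial per parameter vector)
#' @param model `"ddm"` (constant bounds) or `"ddm_collapse"`
#' @param seed integer seed (drives both the prior draws and the simulator)
#' @param dt,max_t passed to the simulator
#' @return list with `theta` (`N` x d matrix) and `trials` (`trial_table`
#'   with `N` rows, row `i` simulated from `theta[i, ]`)
#' @export
generate_training_set <- function(prior, N, model = c("ddm", "ddm_collapse"),
                                  seed = 1, dt = 1e-4, max_t = 10) {
  model <- match.arg(model)
  stopifnot(N >= 1)
  if (model == "ddm_collapse" && !"gamma" %in% prior$names)
    stop("model 'ddm_collapse' requires a prior with a gamma dimension",
         call. = FALSE)
  theta <- sample_prior(prior, N, seed = seed)
  p <- .check_ddm_params(theta, need_gamma = (model == "ddm_collapse"))
  trials <- .simulate_impl(p, N, dt, max_t, seed + 1)
  list(theta = theta, trials = trials)
}

#' Read / write trial tables as CSV
#'
#' CSV format: header `trial,choice,rt`, choices coded 0/1, reaction times in
#' seconds at full float precision.
#' @param path file path
#' @return `read_trials` returns a `trial_table`
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("trial", "choice", "rt") %in% names(df)))
    stop("trial CSV must have columns trial, choice, rt", call. = FALSE)
  trial_table(choice = df$choice, rt = df$rt)
}

#' @rdname read_trials
#' @param trials a `trial_table` to serialize
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(as.data.frame(trials)[, c("trial", "choice", "rt")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
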