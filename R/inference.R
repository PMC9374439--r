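#' Joint potential over i.i.d. trials in unconstrained space
#'
#' Builds the unnormalized log posterior density evaluated through the
#' box-to-real transform: the sum of per-trial log-likelihoods (analytic
#' Wiener density or learned mixed likelihood), the log prior, and the
#' log-absolute-Jacobian of the transform. States mapping outside the prior
#' box get `-Inf`.
#'
#' @param backend `"analytic"` (simple DDM only) or `"mnle"`
#' @param prior a [ddm_prior()]
#' @param trials a nonempty [trial_table()]
#' @param est a trained [train_mnle()] estimator (required for
#'   `backend = "mnle"`)
#' @return a function `u -> log density` (scalar in, scalar out; `u` is a
#'   vector in unconstrained space), with the transform attached as the
#'   `"transform"` attribute
#' @export
joint_potential <- function(backend = c("analytic", "mnle"), prior, trials,
                            est = NULL) {
  backend <- match.arg(backend)
  stopifnot(inherits(prior, "ddm_prior"), nrow(trials) >= 1)
  if (backend == "analytic" && "gamma" %in% prior$names)
    stop("the analytic likelihood requires constant bounds (no gamma)",
         call. = FALSE)
  if (backend == "mnle") {
    if (is.null(est) || !inherits(est, "mnle_estimator"))
      stop("backend 'mnle' requires a trained mnle_estimator", call. = FALSE)
    if (!(est$choice_model$trained && est$rt_flow$trained))
      stop("the supplied estimator is untrained", call. = FALSE)
  }
  tr <- param_transform(prior)
  lp_const <- -sum(log(prior$upper - prior$lower))
  loglik <- if (backend == "analytic") {
    iv <- match(c("v", "a", "w", "tau"), prior$names)
    ch <- as.integer(trials$choice)
    rt <- trials$rt
    function(theta) sum(.wfpt_logd_cpp(ch, rt, theta[iv[1]], theta[iv[2]],
                                       theta[iv[3]], theta[iv[4]], 1e-7))
  } else {
    .mnle_loglik_closure(est, trials, param_order = prior$names)
  }
  lo <- unname(prior$lower)
  rng <- unname(prior$upper - prior$lower)
  log_rng <- log(rng)
  pot <- function(u) {
    if (any(!is.finite(u))) return(-Inf)
    s <- stats::plogis(u)
    ll <- loglik(lo + rng * s)
    if (!is.finite(ll)) return(-Inf)
    ll + lp_const + sum(log_rng + log(s) + log1p(-s))
  }
  attr(pot, "transform") <- tr
  attr(pot, "backend") <- backend
  pot
}

#' Initialize MCMC chains by sequential importance sampling
#'
#' Draws `n_proposals` parameter vectors from the prior, weights them by the
#' exponentiated potential, and resamples `n_chains` starting points
#' proportionally to the weights. All returned points have finite potential.
#'
#' @param potential a [joint_potential()] (or any function of an
#'   unconstrained-space vector)
#' @param prior a [ddm_prior()]
#' @param n_chains number of chains to initialize (default 10)
#' @param n_proposals number of prior draws (default 10000)
#' @param seed integer seed
#' @return `n_chains` x d matrix of unconstrained-space starting points
#' @export
init_chains_sis <- function(potential, prior, n_chains = 10,
                            n_proposals = 10000, seed = NULL) {
  stopifnot(n_proposals >= n_chains)
  if (!is.null(seed)) {
    old <- .save_rng_state()
    on.exit(.restore_rng_state(old))
    set.seed(seed)
  }
  tr <- attr(potential, "transform")
  if (is.null(tr)) tr <- param_transform(prior)
  theta <- sample_prior(prior, n_proposals)
  u <- tr$to_unconstrained(theta)
  lp <- apply(u, 1, potential)
  ok <- is.finite(lp)
  if (!any(ok))
    stop("all SIS proposal weights are zero or non-finite; ",
         "increase n_proposals", call. = FALSE)
  w <- exp(lp[ok] - max(lp[ok]))
  pick <- sample(which(ok), n_chains, replace = TRUE, prob = w)
  u[pick, , drop = FALSE]
}

#' MCMC configuration
#'
#' Defaults: 10 parallel chains, 500 burn-in sweeps per chain, thinning 10,
#' 1000 pooled retained draws; initial slice width 1 in unconstrained space
#' with a cap of 20 step-out expansions per side.
#'
#' @param n_chains number of chains
#' @param n_samples total pooled draws retained (split across chains)
#' @param burn_in discarded sweeps per chain
#' @param thin keep every `thin`-th sweep
#' @param n_proposals SIS proposals for initialization
#' @param slice_width initial slice bracket width
#' @param max_expansions cap on bracket expansions per side
#' @return a list of class `mcmc_config`
#' @export
mcmc_config <- function(n_chains = 10, n_samples = 1000, burn_in = 500,
                        thin = 10, n_proposals = 10000, slice_width = 1,
                        max_expansions = 20) {
  structure(list(n_chains = n_chains, n_samples = n_samples,
                 burn_in = burn_in, thin = thin, n_proposals = n_proposals,
                 slice_width = slice_width, max_expansions = max_expansions),
            class = "mcmc_config")
}

# one univariate slice-sampling update (stepping out + shrinkage, Neal 2003)
.slice_update_dim <- function(u, j, lp0, potential, width, max_expansions) {
  logy <- lp0 - stats::rexp(1)
  lower <- u[j] - stats::runif(1) * width
  upper <- lower + width
  f <- function(x) { uu <- u; uu[j] <- x; potential(uu) }
  k <- 0
  while (f(lower) > logy && k < max_expansions) { lower <- lower - width; k <- k + 1 }
  k <- 0
  while (f(upper) > logy && k < max_expansions) { upper <- upper + width; k <- k + 1 }
  repeat {
    if (upper - lower < 1e-12)
      stop("slice bracket collapsed at state (",
           paste(signif(u, 4), collapse = ", "), "), dim ", j, call. = FALSE)
    x1 <- stats::runif(1, lower, upper)
    lp1 <- f(x1)
    if (lp1 > logy) {
      u[j] <- x1
      return(list(u = u, lp = lp1))
    }
    if (x1 < u[j]) lower <- x1 else upper <- x1
  }
}

#' Axis-wise slice sampling
#'
#' Runs coordinate-wise slice sampling (stepping-out and shrinkage) from a
#' set of starting points, one chain per start. Burn-in sweeps are
#' discarded, the remainder thinned, and draws pooled across chains.
#'
#' @param potential function: unconstrained vector -> log density; must be
#'   finite at every start
#' @param starts matrix of starting points (rows = chains)
#' @param n_samples total pooled draws to retain
#' @param burn_in burn-in sweeps per chain
#' @param thin thinning interval
#' @param seed integer seed
#' @param slice_width,max_expansions see [mcmc_config()]
#' @return a `posterior_samples` object: list with `draws`
#'   (constrained-space matrix if the potential carries a transform,
#'   otherwise raw), `draws_u`, `chain` id per draw, and metadata
#' @export
slice_sample <- function(potential, starts, n_samples = 1000, burn_in = 500,
                         thin = 10, seed = NULL, slice_width = 1,
                         max_expansions = 20) {
  if (is.null(dim(starts))) starts <- matrix(starts, nrow = 1)
  n_chains <- nrow(starts)
  d <- ncol(starts)
  if (!is.null(seed)) {
    old <- .save_rng_state()
    on.exit(.restore_rng_state(old))
    set.seed(seed)
  }
  per_chain <- ceiling(n_samples / n_chains)
  draws <- matrix(NA_real_, n_chains * per_chain, d)
  row <- 0
  chain_id <- integer(0)
  for (ch in seq_len(n_chains)) {
    u <- starts[ch, ]
    lp <- potential(u)
    if (!is.finite(lp))
      stop("starting point of chain ", ch, " has non-finite potential",
           call. = FALSE)
    n_sweeps <- burn_in + per_chain * thin
    kept <- 0
    for (sw in seq_len(n_sweeps)) {
      for (j in seq_len(d)) {
        upd <- .slice_update_dim(u, j, lp, potential, slice_width,
                                 max_expansions)
        u <- upd$u
        lp <- upd$lp
      }
      if (sw > burn_in && (sw - burn_in) %% thin == 0) {
        row <- row + 1
        kept <- kept + 1
        draws[row, ] <- u
        chain_id <- c(chain_id, ch)
        if (kept >= per_chain) break
      }
    }
  }
  draws <- draws[seq_len(row), , drop = FALSE]
  keep <- seq_len(min(n_samples, nrow(draws)))
  # trim evenly across chains when per_chain * n_chains > n_samples
  ord <- order(rep(seq_len(per_chain), n_chains)[seq_len(row)])
  draws <- draws[ord, , drop = FALSE][keep, , drop = FALSE]
  chain_id <- chain_id[ord][keep]
  tr <- attr(potential, "transform")
  theta <- if (!is.null(tr)) tr$to_constrained(draws) else draws
  structure(list(draws = theta, draws_u = draws, chain = chain_id,
                 backend = attr(potential, "backend"),
                 n_chains = n_chains, burn_in = burn_in, thin = thin),
            class = "posterior_samples")
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat("Posterior samples:", nrow(x$draws), "draws,", x$n_chains,
      "chains", if (!is.null(x$backend)) paste0("(", x$backend, " backend)"),
      "\n")
  print(round(rbind(mean = colMeans(x$draws),
                    sd = apply(x$draws, 2, stats::sd)), 4))
  invisible(x)
}

#' Posterior sampling for DDM observations
#'
#' Convenience wrapper tying together [joint_potential()],
#' [init_chains_sis()] and [slice_sample()].
#'
#' @inheritParams joint_potential
#' @param config an [mcmc_config()]
#' @param seed integer seed (drives initialization and sampling)
#' @return a `posterior_samples` object
#' @export
ddm_posterior <- function(trials, prior, backend = c("analytic", "mnle"),
                          est = NULL, config = mcmc_config(), seed = 1) {
  backend <- match.arg(backend)
  pot <- joint_potential(backend, prior, trials, est = est)
  starts <- init_chains_sis(pot, prior, n_chains = config$n_chains,
                            n_proposals = config$n_proposals, seed = seed)
  slice_sample(pot, starts, n_samples = config$n_samples,
               burn_in = config$burn_in, thin = config$thin,
               seed = seed + 1, slice_width = config$slice_width,
               max_expansions = config$max_expansions)
}

#' Ensemble posterior from several estimators
#'
#' Runs the same MCMC once per ensemble member (estimators trained with
#' identical settings but different random initialization) and pools the
#' draws with equal weight, tagging each draw with its member index.
#'
#' @param estimators list of at least two trained [train_mnle()] estimators
#' @param prior a [ddm_prior()]
#' @param trials observed [trial_table()]
#' @param config an [mcmc_config()]; each member contributes
#'   `n_samples` draws
#' @param seed integer seed
#' @return a `posterior_samples` object with a `member` field
#' @export
ensemble_posterior <- function(estimators, prior, trials,
                               config = mcmc_config(), seed = 1) {
  stopifnot(length(estimators) >= 2)
  res <- vector("list", length(estimators))
  for (m in seq_along(estimators)) {
    res[[m]] <- tryCatch(
      ddm_posterior(trials, prior, backend = "mnle", est = estimators[[m]],
                    config = config, seed = seed + 97 * m),
      error = function(e)
        stop("ensemble member ", m, " failed: ", conditionMessage(e),
             call. = FALSE))
  }
  draws <- do.call(rbind, lapply(res, `[[`, "draws"))
  draws_u <- do.call(rbind, lapply(res, `[[`, "draws_u"))
  member <- rep(seq_along(res), vapply(res, function(r) nrow(r$draws),
                                       integer(1)))
  chain <- unlist(lapply(res, `[[`, "chain"))
  structure(list(draws = draws, draws_u = draws_u, chain = chain,
                 member = member, backend = "mnle-ensemble",
                 n_chains = res[[1]]$n_chains, burn_in = res[[1]]$burn_in,
                 thin = res[[1]]$thin),
            class = "posterior_samples")
}

#' Read / write posterior samples as CSV
#'
#' CSV header `chain,draw,<param names...>`; a JSON sidecar (same path with
#' extension `.meta.json`) records backend and MCMC settings.
#' @param path CSV file path
#' @return `read_posterior` returns a `posterior_samples`
#' @export
read_posterior <- function(path) {
  df <- utils::read.csv(path)
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else list()
  draws <- as.matrix(df[, setdiff(names(df), c("chain", "draw")),
                        drop = FALSE])
  structure(list(draws = draws, draws_u = NULL, chain = df$chain,
                 backend = meta$backend, n_chains = meta$n_chains,
                 burn_in = meta$burn_in, thin = meta$thin),
            class = "posterior_samples")
}

#' @rdname read_posterior
#' @param samples a `posterior_samples` object
#' @export
write_posterior <- function(samples, path) {
  df <- data.frame(chain = samples$chain,
                   draw = seq_len(nrow(samples$draws)))
  df <- cbind(df, as.data.frame(samples$draws))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(backend = samples$backend, n_chains = samples$n_chains,
               burn_in = samples$burn_in, thin = samples$thin)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
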