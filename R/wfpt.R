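#' Analytic Wiener first-passage-time log-density
#'
#' Exact likelihood of an observation `(choice, rt)` under the simple
#' (constant-bound) drift-diffusion model, computed with the classical
#' series expansion of the first-passage density of a Wiener process between
#' two absorbing bounds. Both the small-time and the large-time series are
#' implemented and the one needing fewer terms at the requested truncation
#' tolerance is selected per observation; the number of terms is chosen
#' adaptively so the truncation error of the (time-normalized) density is
#' below `err_tol`.
#'
#' @param choice 0/1 vector: 1 = upper-bound crossing, 0 = lower-bound
#' @param rt reaction times in seconds (vector, same length as `choice`)
#' @param params named vector with `v`, `a`, `w`, `tau` (no `gamma`)
#' @param err_tol truncation tolerance on the density (default 1e-7)
#' @return vector of log joint densities (1/s scale); `-Inf` where
#'   `rt <= tau` (outside the support, zero likelihood)
#' @examples
#' wfpt_log_density(1, 0.8, c(v = 1, a = 1.5, w = 0.5, tau = 0.3))
#' @export
wfpt_log_density <- function(choice, rt, params, err_tol = 1e-7) {
  stopifnot(err_tol > 0)
  p <- .check_ddm_params(params, need_gamma = FALSE)
  if (length(p$v) != 1)
    stop("wfpt_log_density() takes a single parameter vector", call. = FALSE)
  if (any(p$gamma != 0))
    stop("analytic likelihood is only available for constant bounds",
         call. = FALSE)
  n <- max(length(choice), length(rt))
  choice <- rep_len(as.integer(choice), n)
  rt <- rep_len(rt, n)
  .wfpt_logd_core(choice, rt, p$v, p$a, p$w, p$tau, err_tol)
}

# unchecked vectorized core (scalar parameters, vector observations)
.wfpt_logd_core <- function(choice, rt, v, a, w, tau, err_tol = 1e-7) {
  n <- length(rt)
  out <- rep(-Inf, n)
  t <- rt - tau
  ok <- is.finite(t) & t > 0
  if (!any(ok)) return(out)
  # map both choices onto the lower-bound density via (v, w) -> (-v, 1 - w)
  up <- choice == 1
  v_eff <- ifelse(up, -v, v)
  w_eff <- ifelse(up, 1 - w, w)
  u <- t / a^2                       # normalized decision time
  logf1 <- rep(-Inf, n)
  iok <- which(ok)
  ks <- .wfpt_k_small(u[iok], err_tol)
  kl <- .wfpt_k_large(u[iok], err_tol)
  use_small <- ks < kl
  is <- iok[use_small]
  il <- iok[!use_small]
  if (length(is))
    logf1[is] <- .wfpt_f1_small(u[is], w_eff[is], max(ks[use_small]))
  if (length(il))
    logf1[il] <- .wfpt_f1_large(u[il], w_eff[il], max(kl[!use_small]))
  out[iok] <- (-2 * log(a) - v_eff[iok] * a * w_eff[iok] -
                 v_eff[iok]^2 * t[iok] / 2 + logf1[iok])
  out
}

# terms required by the small-time expansion (Navarro & Fuss 2009)
.wfpt_k_small <- function(u, eps) {
  ks <- rep(2, length(u))
  cond <- 2 * sqrt(2 * pi * u) * eps < 1
  ks[cond] <- 2 + sqrt(-2 * u[cond] * log(2 * eps * sqrt(2 * pi * u[cond])))
  pmax(ks, sqrt(u) + 1)
}

# terms required by the large-time expansion
.wfpt_k_large <- function(u, eps) {
  kl <- 1 / (pi * sqrt(u))
  cond <- pi * u * eps < 1
  kl[cond] <- pmax(sqrt(-2 * log(pi * u[cond] * eps) / (pi^2 * u[cond])),
                   kl[cond])
  kl
}

# signed log-sum-exp over the columns of a term matrix given log-magnitudes
# and signs; returns log of the (positive) sum, -Inf on total underflow
.signed_lse <- function(logmag, sign) {
  m <- apply(logmag, 1, max)
  s <- rowSums(sign * exp(logmag - m))
  res <- rep(-Inf, nrow(logmag))
  pos <- is.finite(m) & s > 0
  res[pos] <- m[pos] + log(s[pos])
  res
}

# log f1 in normalized time, small-time form: sum over image charges
.wfpt_f1_small <- function(u, w, K) {
  kk <- seq(-ceiling(K), ceiling(K))
  sk <- outer(w, 2 * kk, "+")                       # n x terms
  logmag <- log(abs(sk)) - sk^2 / (2 * u)
  logmag[sk == 0] <- -Inf
  .signed_lse(logmag, sign(sk)) - 0.5 * log(2 * pi) - 1.5 * log(u)
}

# log f1 in normalized time, large-time (eigenfunction) form
.wfpt_f1_large <- function(u, w, K) {
  kk <- seq_len(max(1, ceiling(K)))
  n <- length(u)
  sinterm <- sin(outer(pi * w, kk, "*"))
  logmag <- matrix(log(kk), n, length(kk), byrow = TRUE) -
    outer(u, kk^2 * pi^2 / 2, "*") + log(abs(sinterm))
  .signed_lse(logmag, sign(sinterm)) + log(pi)
}

#' Probability of an upper-bound choice under the simple DDM
#'
#' Integrates the analytic first-passage density of the upper bound over all
#' reaction times by adaptive quadrature.
#'
#' @inheritParams wfpt_log_density
#' @param rel_tol relative tolerance passed to the quadrature
#' @return `P(c = 1)` in `[0, 1]`
#' @export
choice_probability <- function(params, err_tol = 1e-7, rel_tol = 1e-8) {
  p <- .check_ddm_params(params, need_gamma = FALSE)
  f <- function(rt) exp(wfpt_log_density(1L, rt, params, err_tol))
  res <- tryCatch(
    stats::integrate(f, lower = p$tau, upper = Inf, rel.tol = rel_tol,
                     subdivisions = 500L),
    error = function(e)
      stop("quadrature for choice probability failed: ", conditionMessage(e),
           " (params: ", paste(signif(unlist(p), 4), collapse = ", "), ")",
           call. = FALSE))
  min(max(res$value, 0), 1)
}

#' Total analytic log-likelihood of a trial table
#'
#' Sum of [wfpt_log_density()] over the rows of a trial table, i.e. the
#' joint log-likelihood of i.i.d. trials.
#'
#' @param trials a [trial_table()]
#' @inheritParams wfpt_log_density
#' @return scalar total log-likelihood; `-Inf` if any trial has
#'   `rt <= tau`
#' @export
analytic_loglik <- function(trials, params, err_tol = 1e-7) {
  stopifnot(nrow(trials) >= 1)
  sum(wfpt_log_density(trials$choice, trials$rt, params, err_tol))
}

# conditional reaction-time CDF given the choice, as an interpolating
# function on a dense grid (used for KS tests against simulated data)
.wfpt_cdf_fun <- function(params, choice, t_max = 20, n_grid = 4000) {
  p <- .check_ddm_params(params, need_gamma = FALSE)
  grid <- seq(p$tau + 1e-9, p$tau + t_max, length.out = n_grid)
  dens <- exp(wfpt_log_density(choice, grid, params))
  cdf <- c(0, cumsum((dens[-1] + dens[-n_grid]) / 2 * diff(grid)))
  total <- cdf[n_grid]
  if (total <= 0) stop("degenerate conditional density", call. = FALSE)
  f <- stats::approxfun(grid, cdf / total, yleft = 0, yright = 1, rule = 2)
  function(q) pmin(pmax(f(q), 0), 1)
}
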