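#' Bijection between a box prior's support and unconstrained space
#'
#' Per-dimension affine-then-logit map: the prior box is first rescaled to
#' `(0, 1)` and then mapped through the logit to the real line. The
#' log-absolute-Jacobian of the inverse map (unconstrained to constrained)
#' is available in closed form, which is what MCMC in unconstrained space
#' needs.
#'
#' @param prior a [ddm_prior()]
#' @return a list of class `param_transform` with functions
#'   `to_unconstrained(theta)`, `to_constrained(u)` (both matrix-in,
#'   matrix-out) and `log_abs_det_jacobian(u)` (per-row log |d theta / d u|)
#' @export
param_transform <- function(prior) {
  lo <- prior$lower
  hi <- prior$upper
  rng <- hi - lo
  to_u <- function(theta) {
    theta <- .as_param_matrix(theta, prior)
    p <- sweep(sweep(theta, 2, lo, "-"), 2, rng, "/")
    stats::qlogis(p)
  }
  to_theta <- function(u) {
    if (is.null(dim(u))) u <- matrix(u, nrow = 1)
    p <- stats::plogis(u)
    th <- sweep(sweep(p, 2, rng, "*"), 2, lo, "+")
    colnames(th) <- prior$names
    th
  }
  ladj <- function(u) {
    if (is.null(dim(u))) u <- matrix(u, nrow = 1)
    # d theta_j / d u_j = range_j * sigma(u_j) (1 - sigma(u_j))
    rowSums(sweep(stats::plogis(u, log.p = TRUE) +
                    stats::plogis(-u, log.p = TRUE), 2, log(rng), "+"))
  }
  structure(list(to_unconstrained = to_u, to_constrained = to_theta,
                 log_abs_det_jacobian = ladj, prior = prior),
            class = "param_transform")
}
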