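#' Uniform prior specification for DDM parameters
#'
#' Constructs a box (independent-uniform) prior over the parameters of the
#' drift-diffusion model. The defaults are the standard ranges used for the
#' simple DDM: drift rate `v` in (-2, 2), boundary separation `a` in
#' (0.5, 2), relative starting point `w` in (0.3, 0.7) and non-decision time
#' `tau` in (0.2, 1.8) seconds. With `collapsing = TRUE` a fifth parameter is
#' added, the boundary-collapse slope `gamma` in (-1, 0) (evidence units per
#' second, non-positive: bounds collapse linearly toward each other).
#'
#' @param lower,upper named numeric vectors of bounds; names define the
#'   parameter order. Defaults to the DDM box above.
#' @param collapsing if `TRUE` (and `lower`/`upper` are left at their
#'   defaults), append the `gamma` dimension for the collapsing-bound DDM.
#' @return an object of class `ddm_prior` with elements `lower`, `upper`,
#'   `names`.
#' @examples
#' p <- ddm_prior()
#' theta <- sample_prior(p, 10, seed = 1)
#' @export
ddm_prior <- function(lower = NULL, upper = NULL, collapsing = FALSE) {
  if (is.null(lower) && is.null(upper)) {
    lower <- c(v = -2, a = 0.5, w = 0.3, tau = 0.2)
    upper <- c(v = 2, a = 2, w = 0.7, tau = 1.8)
    if (collapsing) {
      lower <- c(lower, gamma = -1)
      upper <- c(upper, gamma = 0)
    }
  }
  if (is.null(names(lower)) || is.null(names(upper)))
    stop("prior bounds must be named numeric vectors", call. = FALSE)
  if (!identical(names(lower), names(upper)))
    stop("lower and upper bounds must have identical names", call. = FALSE)
  if (any(!is.finite(lower)) || any(!is.finite(upper)))
    stop("prior bounds must be finite", call. = FALSE)
  if (any(lower >= upper))
    stop("every lower bound must be strictly below its upper bound",
         call. = FALSE)
  structure(list(lower = lower, upper = upper, names = names(lower)),
            class = "ddm_prior")
}

#' @export
print.ddm_prior <- function(x, ...) {
  cat("Independent uniform prior over", length(x$names), "parameters:\n")
  for (nm in x$names)
    cat(sprintf("  %-6s ~ U(%g, %g)\n", nm, x$lower[[nm]], x$upper[[nm]]))
  invisible(x)
}

#' Number of parameter dimensions of a prior
#' @param prior a `ddm_prior`
#' @return integer dimension
#' @export
prior_dim <- function(prior) length(prior$names)

#' Sample parameter vectors from a box prior
#'
#' @param prior a [ddm_prior()]
#' @param n number of draws (>= 1)
#' @param seed integer seed; draws are reproducible given the seed
#' @return an `n` x `d` matrix with one parameter vector per row, columns
#'   named after the parameters
#' @export
sample_prior <- function(prior, n, seed = NULL) {
  stopifnot(inherits(prior, "ddm_prior"), n >= 1)
  if (!is.null(seed)) {
    old <- .save_rng_state()
    on.exit(.restore_rng_state(old))
    set.seed(seed)
  }
  d <- prior_dim(prior)
  u <- matrix(stats::runif(n * d), nrow = n, ncol = d)
  theta <- sweep(sweep(u, 2, prior$upper - prior$lower, "*"), 2,
                 prior$lower, "+")
  colnames(theta) <- prior$names
  theta
}

#' Log-density of a box prior
#' @param prior a [ddm_prior()]
#' @param theta parameter matrix (rows = vectors) or a single vector
#' @return vector of log-densities; `-Inf` outside the box
#' @export
log_prior_density <- function(prior, theta) {
  theta <- .as_param_matrix(theta, prior)
  inside <- apply(sweep(theta, 2, prior$lower, ">=") &
                    sweep(theta, 2, prior$upper, "<="), 1, all)
  lp <- rep(-Inf, nrow(theta))
  lp[inside] <- -sum(log(prior$upper - prior$lower))
  lp
}

#' Read / write a prior as JSON
#'
#' The JSON format maps each parameter name to a two-element `[low, high]`
#' array.
#' @param path file path
#' @return `read_prior_json` returns a `ddm_prior`
#' @export
read_prior_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lo <- vapply(obj, function(b) b[[1]], numeric(1))
  hi <- vapply(obj, function(b) b[[2]], numeric(1))
  ddm_prior(lower = lo, upper = hi)
}

#' @rdname read_prior_json
#' @param prior a `ddm_prior` to serialize
#' @export
write_prior_json <- function(prior, path) {
  obj <- lapply(prior$names, function(nm)
    c(prior$lower[[nm]], prior$upper[[nm]]))
  names(obj) <- prior$names
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

# coerce vector/matrix/data.frame input to a parameter matrix in prior order
.as_param_matrix <- function(theta, prior = NULL) {
  if (is.data.frame(theta)) theta <- as.matrix(theta)
  if (is.null(dim(theta))) theta <- matrix(theta, nrow = 1)
  if (!is.null(prior)) {
    if (ncol(theta) != prior_dim(prior))
      stop("parameter matrix has ", ncol(theta), " columns but the prior has ",
           prior_dim(prior), " dimensions", call. = FALSE)
    if (!is.null(colnames(theta)) && all(prior$names %in% colnames(theta)))
      theta <- theta[, prior$names, drop = FALSE]
  }
  theta
}

.save_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
  invisible(NULL)
}
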