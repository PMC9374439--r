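# Bernoulli choice network: a small feed-forward net mapping (standardized)
# model parameters to the logit of the probability of an upper-bound choice.

#' Train the Bernoulli choice model
#'
#' Fits a feed-forward network predicting the Bernoulli probability
#' `rho(theta) = P(c = 1 | theta)` by minimizing the mean negative Bernoulli
#' log-likelihood (logistic loss) with Adam, early-stopped on a validation
#' split. Conditioning parameters are z-scored with training-set statistics.
#'
#' @param theta parameter matrix, one row per trial
#' @param choices 0/1 vector aligned with `theta`
#' @param hyper a [nn_hyper()]; `hidden` defaults to `c(32, 32)`
#' @param seed integer seed controlling initialization and batching
#' @return an object of class `choice_model`
#' @export
train_choice_model <- function(theta, choices, hyper = nn_hyper(), seed = 1) {
  theta <- .as_param_matrix(theta)
  choices <- as.numeric(choices)
  stopifnot(nrow(theta) == length(choices), all(choices %in% c(0, 1)))
  if (is.null(hyper$hidden)) hyper$hidden <- c(32, 32)
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old))
  set.seed(seed)
  model <- list(ctx_mean = colMeans(theta),
                ctx_sd = pmax(apply(theta, 2, stats::sd), 1e-12),
                d_theta = ncol(theta), param_names = colnames(theta),
                hidden = hyper$hidden, trained = FALSE, seed = seed)
  model$net <- .mlp_init(ncol(theta), hyper$hidden, 1)
  X <- sweep(sweep(theta, 2, model$ctx_mean, "-"), 2, model$ctx_sd, "/")
  loss_grad <- function(nets, idx) {
    fw <- .mlp_forward(nets[[1]], X[idx, , drop = FALSE], cache = TRUE)
    logit <- fw$out[, 1]
    y <- choices[idx]
    # stable logistic loss: log(1 + e^z) - y z
    loss <- mean(.softplus(logit) - y * logit)
    dlogit <- (stats::plogis(logit) - y) / length(idx)
    list(loss = loss,
         grads = list(.mlp_backward(nets[[1]], fw, cbind(dlogit))))
  }
  val_loss <- function(nets, idx) {
    logit <- .mlp_forward(nets[[1]], X[idx, , drop = FALSE])[, 1]
    mean(.softplus(logit) - choices[idx] * logit)
  }
  fit <- .train_loop(list(model$net), nrow(theta), loss_grad, val_loss, hyper)
  model$net <- fit$nets[[1]]
  model$history <- fit$history
  model$best_val <- fit$best_val
  model$trained <- hyper$max_epochs >= 1
  class(model) <- "choice_model"
  model
}

#' Predicted probability of an upper-bound choice
#'
#' @param model a `choice_model` from [train_choice_model()]
#' @param theta parameter matrix (rows = parameter vectors)
#' @return vector of probabilities in (0, 1)
#' @export
predict_choice_prob <- function(model, theta) {
  theta <- .as_param_matrix(theta)
  X <- sweep(sweep(theta, 2, model$ctx_mean, "-"), 2, model$ctx_sd, "/")
  stats::plogis(.mlp_forward(model$net, X)[, 1])
}
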