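# Minimal feed-forward network machinery: vectorized forward/backward passes
# with ReLU hidden layers and an Adam optimizer. This is deliberately small:
# all networks in the package condition on 4-6 inputs and use 2 hidden
# layers, so plain BLAS-backed matrix products are fast enough.

.mlp_init <- function(d_in, hidden, d_out, final_scale = 1) {
  dims <- c(d_in, hidden, d_out)
  L <- length(dims) - 1
  W <- vector("list", L)
  b <- vector("list", L)
  for (l in seq_len(L)) {
    sd <- sqrt(2 / dims[l])                 # He initialization
    if (l == L) sd <- sd * final_scale
    W[[l]] <- matrix(stats::rnorm(dims[l] * dims[l + 1], sd = sd),
                     dims[l], dims[l + 1])
    b[[l]] <- rep(0, dims[l + 1])
  }
  list(W = W, b = b, dims = dims, L = L)
}

# forward pass; returns output and the activations needed for backprop
.mlp_forward <- function(net, X, cache = FALSE) {
  A <- X
  As <- if (cache) vector("list", net$L) else NULL
  for (l in seq_len(net$L)) {
    if (cache) As[[l]] <- A
    Z <- A %*% net$W[[l]]
    Z <- sweep(Z, 2, net$b[[l]], "+")
    A <- if (l < net$L) pmax(Z, 0) else Z
  }
  if (cache) list(out = A, As = As) else A
}

# backprop given dL/d(output); returns weight gradients and dL/d(input)
.mlp_backward <- function(net, fw, dOut) {
  gW <- vector("list", net$L)
  gb <- vector("list", net$L)
  delta <- dOut
  for (l in rev(seq_len(net$L))) {
    A <- fw$As[[l]]
    gW[[l]] <- crossprod(A, delta)
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      delta <- tcrossprod(delta, net$W[[l]])
      # ReLU mask: the input to layer l was the ReLU output of layer l-1
      delta <- delta * (A > 0)
    }
  }
  list(gW = gW, gb = gb)
}

.adam_init <- function(net) {
  zero_like <- function(x) lapply(x, function(m) m * 0)
  list(mW = zero_like(net$W), vW = zero_like(net$W),
       mb = zero_like(net$b), vb = zero_like(net$b), t = 0)
}

.adam_step <- function(net, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (l in seq_len(net$L)) {
    state$mW[[l]] <- beta1 * state$mW[[l]] + (1 - beta1) * grads$gW[[l]]
    state$vW[[l]] <- beta2 * state$vW[[l]] + (1 - beta2) * grads$gW[[l]]^2
    net$W[[l]] <- net$W[[l]] - lr * (state$mW[[l]] / bc1) /
      (sqrt(state$vW[[l]] / bc2) + eps)
    state$mb[[l]] <- beta1 * state$mb[[l]] + (1 - beta1) * grads$gb[[l]]
    state$vb[[l]] <- beta2 * state$vb[[l]] + (1 - beta2) * grads$gb[[l]]^2
    net$b[[l]] <- net$b[[l]] - lr * (state$mb[[l]] / bc1) /
      (sqrt(state$vb[[l]] / bc2) + eps)
  }
  list(net = net, state = state)
}

#' Training hyperparameters for the neural estimators
#'
#' Defaults follow standard neural simulation-based-inference practice:
#' Adam with learning rate 5e-4, minibatches of 256, a 90/10
#' train/validation split, and early stopping after 20 epochs without
#' validation improvement.
#'
#' @param batch_size minibatch size
#' @param lr Adam learning rate
#' @param max_epochs hard cap on training epochs; `0` returns the estimator
#'   at initialization (an untrained baseline)
#' @param patience early-stopping patience in epochs
#' @param val_frac fraction of the data held out for validation
#' @param hidden integer vector of hidden-layer widths (model-specific
#'   defaults are applied by the training functions when `NULL`)
#' @param lr_decay multiplicative learning-rate decay applied after
#'   `lr_patience` epochs without validation improvement (plateau schedule);
#'   set to 1 to disable
#' @param lr_patience epochs without improvement before the rate is decayed
#' @param n_transforms number of stacked spline transforms (flow only)
#' @param n_bins number of rational-quadratic spline bins (flow only)
#' @param tail_bound spline tail bound B in standardized log-rt space
#' @return a list of class `nn_hyper`
#' @export
nn_hyper <- function(batch_size = 256, lr = 5e-4, max_epochs = 300,
                     patience = 20, val_frac = 0.1, hidden = NULL,
                     lr_decay = 0.5, lr_patience = 5,
                     n_transforms = 2, n_bins = 16, tail_bound = 5) {
  structure(list(batch_size = batch_size, lr = lr, max_epochs = max_epochs,
                 patience = patience, val_frac = val_frac, hidden = hidden,
                 lr_decay = lr_decay, lr_patience = lr_patience,
                 n_transforms = n_transforms, n_bins = n_bins,
                 tail_bound = tail_bound),
            class = "nn_hyper")
}

# Generic minibatch training loop with early stopping on a validation split.
#   nets       : list of networks updated jointly
#   loss_grad  : function(nets, idx) -> list(loss, grads = list per net)
#   val_loss   : function(nets, idx) -> scalar
# Assumes the caller has seeded the RNG. Returns best nets + history.
.train_loop <- function(nets, n, loss_grad, val_loss, hyper) {
  perm <- sample.int(n)
  n_val <- max(1, round(hyper$val_frac * n))
  if (n < 10) n_val <- 0
  val_idx <- if (n_val > 0) perm[seq_len(n_val)] else integer(0)
  train_idx <- if (n_val > 0) perm[-seq_len(n_val)] else perm
  states <- lapply(nets, .adam_init)
  best <- nets
  best_val <- Inf
  wait <- 0
  lr <- hyper$lr
  lr_wait <- 0
  if (is.null(hyper$lr_decay)) hyper$lr_decay <- 1
  if (is.null(hyper$lr_patience)) hyper$lr_patience <- Inf
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  if (hyper$max_epochs < 1)
    return(list(nets = nets, history = history, best_val = NA_real_))
  for (epoch in seq_len(hyper$max_epochs)) {
    idx_all <- sample(train_idx)
    nb <- ceiling(length(idx_all) / hyper$batch_size)
    tl <- 0
    for (bi in seq_len(nb)) {
      idx <- idx_all[((bi - 1) * hyper$batch_size + 1):
                       min(bi * hyper$batch_size, length(idx_all))]
      lg <- loss_grad(nets, idx)
      if (!is.finite(lg$loss))
        stop("non-finite training loss at epoch ", epoch,
             " (loss = ", lg$loss, ")", call. = FALSE)
      tl <- tl + lg$loss * length(idx)
      for (j in seq_along(nets)) {
        st <- .adam_step(nets[[j]], lg$grads[[j]], states[[j]], lr)
        nets[[j]] <- st$net
        states[[j]] <- st$state
      }
    }
    vl <- if (n_val > 0) val_loss(nets, val_idx) else tl / length(idx_all)
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = tl / length(idx_all), val_loss = vl))
    if (vl < best_val - 1e-9) {
      best_val <- vl
      best <- nets
      wait <- 0
      lr_wait <- 0
    } else {
      wait <- wait + 1
      lr_wait <- lr_wait + 1
      if (wait >= hyper$patience) break
      if (lr_wait >= hyper$lr_patience && hyper$lr_decay < 1 &&
          lr > 1e-5) {
        lr <- lr * hyper$lr_decay
        lr_wait <- 0
        # resume finer optimization from the best weights seen so far
        nets <- best
      }
    }
  }
  list(nets = best, history = history, best_val = best_val)
}
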