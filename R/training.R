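#' Training configuration
#'
#' Mini-batch backpropagation settings.  The TAG model trains with RMSprop
#' for 50 epochs from its deterministic initialization; the dense
#' comparators train with Adam for 1,000 epochs on the same mini-batches.
#'
#' @param optimizer `"rmsprop"` or `"adam"`.
#' @param lr learning rate; the default 1e-2 lets the TAG model converge
#'   within its 50-epoch budget (comparators use 1e-3 with Adam, see
#'   [run_mlp_sweep()]).
#' @param batch_size mini-batch size (default 8).
#' @param epochs training epochs.
#' @param lambda L2 weight-decay coefficient (applies to weights, not
#'   biases).
#' @param l1 L1 (lasso) coefficient used to sparsify comparator networks; 0
#'   for the TAG model.
#' @param seed seed controlling the mini-batch shuffling.
#' @param rho RMSprop squared-gradient decay.
#' @param beta1,beta2 Adam moment decays.
#' @param eps numerical stabilizer in both optimizers.
#' @return list of class `train_config`.
#' @export
train_config <- function(optimizer = c("rmsprop", "adam"), lr = 1e-2,
                         batch_size = 8L, epochs = 50L, lambda = 1e-4,
                         l1 = 0, seed = 1L, rho = 0.99, beta1 = 0.9,
                         beta2 = 0.999, eps = 1e-8) {
  optimizer <- match.arg(optimizer)
  stopifnot(batch_size >= 1, epochs >= 1, lambda >= 0, l1 >= 0, lr >= 0)
  structure(list(optimizer = optimizer, lr = lr,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lambda = lambda, l1 = l1,
                 seed = as.integer(seed), rho = rho, beta1 = beta1,
                 beta2 = beta2, eps = eps),
            class = "train_config")
}

direction_onehot <- function(direction) {
  lev <- c(45, 135, 225, 315)
  idx <- match(direction, lev)
  if (anyNA(idx)) stopf("direction labels must be one of 45/135/225/315")
  out <- matrix(0, length(direction), 4L)
  out[cbind(seq_along(idx), idx)] <- 1
  out
}

binary_cross_entropy <- function(p, y, eps = 1e-7) {
  p <- clip_prob(p, eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# categorical cross-entropy of the four directional activations after a
# normalized-exponential (softmax); activations are tanh outputs, not
# probabilities, hence the explicit normalization
categorical_cross_entropy <- function(A_dir, direction, eps = 1e-7) {
  probs <- clip_prob(softmax_rows(A_dir), eps)
  onehot <- direction_onehot(direction)
  -mean(rowSums(onehot * log(probs)) )
}

sum_sq_weights <- function(params) {
  if (inherits(params, "tag_params"))
    sum(params$W_ff^2) + sum(params$W_lat^2) + sum(params$glob_out^2) +
      sum(params$w_jump^2)
  else sum(vapply(params$W, function(w) sum(w^2), numeric(1)))
}

sum_abs_weights <- function(params) {
  if (inherits(params, "tag_params"))
    sum(abs(params$W_ff)) + sum(abs(params$W_lat)) +
      sum(abs(params$glob_out)) + sum(abs(params$w_jump))
  else sum(vapply(params$W, function(w) sum(abs(w)), numeric(1)))
}

#' Multi-objective loss of the TAG model
#'
#' Equal-weight sum of the binary cross-entropy of the jump output against
#' the attack label and the categorical cross-entropy of the four
#' directional interneuron activations (through a normalized exponential)
#' against the background-direction label, plus an L2 weight-decay term
#' `(lambda/2) * sum(w^2)` over the weights.
#'
#' @param out a [tag_forward()] result for the batch.
#' @param y attack labels (0/1).
#' @param direction background-direction labels in degrees.
#' @param params current parameters (for the regularization terms).
#' @param cfg a [train_config()].
#' @return list of class `loss_breakdown` with `bce_jump`, `cce_direction`,
#'   `l2_term`, `l1_term` and `total`.
#' @export
tag_loss <- function(out, y, direction, params, cfg = train_config()) {
  bce <- binary_cross_entropy(out$jump, y)
  cce <- categorical_cross_entropy(out$A2[, 1:4, drop = FALSE], direction)
  l2 <- cfg$lambda / 2 * sum_sq_weights(params)
  l1 <- cfg$l1 * sum_abs_weights(params)
  structure(list(bce_jump = bce, cce_direction = cce, l2_term = l2,
                 l1_term = l1, total = bce + cce + l2 + l1),
            class = "loss_breakdown")
}

#' Binary cross-entropy loss of a dense comparator
#'
#' @param out an [mlp_forward()] result.
#' @param y attack labels.
#' @param params current parameters.
#' @param cfg a [train_config()]; `l1 > 0` adds the lasso term, `lambda > 0`
#'   an optional weight decay (off by default for comparators).
#' @return a `loss_breakdown` list (with `cce_direction = 0`).
#' @export
mlp_loss <- function(out, y, params, cfg = train_config()) {
  bce <- binary_cross_entropy(out$jump, y)
  l2 <- cfg$lambda / 2 * sum_sq_weights(params)
  l1 <- cfg$l1 * sum_abs_weights(params)
  structure(list(bce_jump = bce, cce_direction = 0, l2_term = l2,
                 l1_term = l1, total = bce + l2 + l1),
            class = "loss_breakdown")
}

# analytic gradient of tag_loss w.r.t. every parameter, masked.
tag_gradient <- function(params, X, y, direction, cfg,
                         mask = attr(params, "mask")) {
  n <- nrow(X)
  out <- tag_forward(params, X, mask)
  delta_s <- (out$jump - y) / n
  dA2 <- outer(delta_s, params$w_jump[1:6])
  probs <- softmax_rows(out$A2[, 1:4, drop = FALSE])
  dA2[, 1:4] <- dA2[, 1:4] + (probs - direction_onehot(direction)) / n
  dZ2 <- dA2 * (1 - out$A2^2)
  g_b <- stats::setNames(numeric(7), interneuron_names())
  g_b[1:6] <- colSums(dZ2)
  g_Wlat <- matrix(0, 7, 7, dimnames = dimnames(params$W_lat))
  dA1 <- dZ2
  if (mask$has_lateral) {
    g_Wlat[1:6, 1:6] <- crossprod(dZ2, out$A1)
    dA1 <- dA1 + dZ2 %*% params$W_lat[1:6, 1:6, drop = FALSE]
  }
  dZ1 <- dA1 * (1 - out$A1^2)
  g_Wff <- matrix(0, 7, 16, dimnames = dimnames(params$W_ff))
  g_Wff[1:6, ] <- crossprod(dZ1, X)
  g_glob_out <- stats::setNames(numeric(6), names(params$glob_out))
  g_wjump <- stats::setNames(numeric(7), interneuron_names())
  g_wjump[1:6] <- colSums(out$A2 * delta_s)
  if (mask$has_glob) {
    g_glob_out[] <- colSums(dZ1 * out$g)
    dg <- drop(dZ1 %*% params$glob_out) + delta_s * params$w_jump[[7L]]
    dpre <- dg * (1 - out$g^2)
    g_b["glob"] <- sum(dpre)
    dzg <- dpre * (1 - out$hg^2)
    g_Wff["glob", ] <- colSums(dzg * X)
    g_wjump["glob"] <- sum(delta_s * out$g)
  }
  g <- list(W_ff = g_Wff + cfg$lambda * params$W_ff,
            W_lat = g_Wlat + cfg$lambda * params$W_lat,
            glob_out = g_glob_out + cfg$lambda * params$glob_out,
            w_jump = g_wjump + cfg$lambda * params$w_jump,
            b = g_b, b_jump = sum(delta_s))
  if (cfg$l1 > 0)
    for (nm in c("W_ff", "W_lat", "glob_out", "w_jump"))
      g[[nm]] <- g[[nm]] + cfg$l1 * sign(params[[nm]])
  msk <- tag_mask_numeric(mask)
  for (nm in names(g)) g[[nm]] <- g[[nm]] * msk[[nm]]
  g
}

# analytic gradient of mlp_loss
mlp_gradient <- function(params, X, y, cfg) {
  n <- nrow(X)
  out <- mlp_forward(params, X)
  L <- length(params$W)
  gW <- vector("list", L)
  gb <- vector("list", L)
  delta <- matrix((out$jump - y) / n, ncol = 1L)   # d loss / d s
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(out$H[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      # H[[l]] is the post-tanh activation feeding layer l
      dA <- delta %*% t(params$W[[l]])
      delta <- dA * (1 - out$H[[l]]^2)
    }
  }
  for (l in seq_len(L)) {
    gW[[l]] <- gW[[l]] + cfg$lambda * params$W[[l]]
    if (cfg$l1 > 0) gW[[l]] <- gW[[l]] + cfg$l1 * sign(params$W[[l]])
  }
  list(W = gW, b = gb)
}

# one optimizer step on a flat numeric vector; returns list(theta, state)
optimizer_step <- function(theta, grad, state, cfg) {
  if (cfg$optimizer == "rmsprop") {
    state$v <- cfg$rho * state$v + (1 - cfg$rho) * grad^2
    theta <- theta - cfg$lr * grad / (sqrt(state$v) + cfg$eps)
  } else {
    state$t <- state$t + 1L
    state$m <- cfg$beta1 * state$m + (1 - cfg$beta1) * grad
    state$v <- cfg$beta2 * state$v + (1 - cfg$beta2) * grad^2
    mhat <- state$m / (1 - cfg$beta1^state$t)
    vhat <- state$v / (1 - cfg$beta2^state$t)
    theta <- theta - cfg$lr * mhat / (sqrt(vhat) + cfg$eps)
  }
  list(theta = theta, state = state)
}

new_opt_state <- function(n, cfg) {
  if (cfg$optimizer == "rmsprop") list(v = numeric(n))
  else list(m = numeric(n), v = numeric(n), t = 0L)
}

# epoch-wise reshuffled mini-batches; a pure function of (n, cfg) so that
# two models trained under the same config see the same batches
epoch_batches <- function(n, batch_size, epoch_seed) {
  set.seed(epoch_seed)
  idx <- sample.int(n)
  split(idx, ceiling(seq_along(idx) / batch_size))
}

#' Train a model by mini-batch backpropagation
#'
#' Generic over the two model families.  TAG parameters always start from
#' the deterministic initialization and gradients flow only through masked
#' weights; comparators start from their seeded random initialization.
#' Mini-batches are reshuffled every epoch from the run seed, so two models
#' trained with the same config and dataset see identical batches.
#'
#' @param params a `tag_params` or `mlp_params` object.
#' @param dataset a `tag_dataset`; the train split is used.
#' @param cfg a [train_config()].
#' @return the trained parameter object, with the per-epoch mean training
#'   loss attached as attribute `loss_trace` and `cfg` as attribute
#'   `train_config`.
#' @export
train_model <- function(params, dataset, cfg = train_config()) {
  UseMethod("train_model")
}

#' @export
train_model.tag_params <- function(params, dataset, cfg = train_config()) {
  mask <- attr(params, "mask")
  d <- dataset_matrices(dataset, "train")
  run_training(params, cfg, n_rows = nrow(d$X),
    grad_fn = function(p, idx)
      tag_gradient(p, d$X[idx, , drop = FALSE], d$y[idx], d$direction[idx],
                   cfg, mask),
    loss_fn = function(p, idx) {
      out <- tag_forward(p, d$X[idx, , drop = FALSE], mask)
      tag_loss(out, d$y[idx], d$direction[idx], p, cfg)$total
    })
}

#' @export
train_model.mlp_params <- function(params, dataset, cfg = train_config()) {
  d <- dataset_matrices(dataset, "train")
  run_training(params, cfg, n_rows = nrow(d$X),
    grad_fn = function(p, idx)
      mlp_gradient(p, d$X[idx, , drop = FALSE], d$y[idx], cfg),
    loss_fn = function(p, idx) {
      out <- mlp_forward(p, d$X[idx, , drop = FALSE])
      mlp_loss(out, d$y[idx], p, cfg)$total
    })
}

run_training <- function(params, cfg, n_rows, grad_fn, loss_fn) {
  skeleton <- unclass(params)
  extra_attrs <- attributes(params)
  extra_attrs <- extra_attrs[setdiff(names(extra_attrs), "names")]
  rebuild <- function(theta) {
    p <- unflatten_params(theta, skeleton)
    for (a in names(extra_attrs)) attr(p, a) <- extra_attrs[[a]]
    p
  }
  theta <- flatten_params(skeleton)
  state <- new_opt_state(length(theta), cfg)
  trace <- numeric(cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    batches <- epoch_batches(n_rows, cfg$batch_size,
                             cfg$seed * 10000L + epoch)
    epoch_loss <- 0
    for (idx in batches) {
      p <- rebuild(theta)
      g <- grad_fn(p, idx)
      l <- loss_fn(p, idx)
      if (!is.finite(l))
        stopf("training diverged (non-finite loss) at epoch %d", epoch)
      step <- optimizer_step(theta, flatten_params(g), state, cfg)
      theta <- step$theta
      state <- step$state
      epoch_loss <- epoch_loss + l * length(idx)
    }
    trace[epoch] <- epoch_loss / n_rows
  }
  out <- rebuild(theta)
  attr(out, "loss_trace") <- trace
  attr(out, "train_config") <- cfg
  out
}
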