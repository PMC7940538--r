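#' Specify a fully connected comparator network
#'
#' Universal-approximation baselines: `n_hidden_layers` tanh hidden layers of
#' equal `width` on the 16 features, and a single sigmoid output.  Zero
#' hidden layers gives the logistic-regression comparator.
#'
#' @param n_hidden_layers 0, 1 or 3.
#' @param width neurons per hidden layer (ignored when 0 layers).
#' @return list of class `mlp_spec`.
#' @export
mlp_spec <- function(n_hidden_layers, width = NULL) {
  if (!n_hidden_layers %in% c(0, 1, 3))
    stopf("n_hidden_layers must be 0, 1 or 3")
  if (n_hidden_layers > 0 && (is.null(width) || width < 1))
    stopf("width must be >= 1 for a hidden-layer model")
  structure(list(n_hidden_layers = as.integer(n_hidden_layers),
                 width = if (n_hidden_layers > 0) as.integer(width) else 0L,
                 n_inputs = 16L),
            class = "mlp_spec")
}

#' The logistic-regression comparator
#'
#' A single sigmoid neuron on all 16 feature-map activations: 16 weights and
#' one bias, a linear decision boundary in feature space.
#'
#' @param seed seed for the (fan-in scaled) random initialization.
#' @return an `mlp_params` object.
#' @export
logistic_model <- function(seed = 1L) build_mlp(mlp_spec(0), seed = seed)

# layer sizes including input and output
mlp_layer_sizes <- function(spec) {
  c(spec$n_inputs, rep(spec$width, spec$n_hidden_layers), 1L)
}

#' Number of parameters of a dense comparator
#'
#' @param spec an [mlp_spec()].
#' @return integer count of weights plus biases.
#' @export
mlp_count_parameters <- function(spec) {
  sz <- mlp_layer_sizes(spec)
  sum(sz[-length(sz)] * sz[-1]) + sum(sz[-1])
}

#' Build (initialize) a dense comparator network
#'
#' Weights are drawn from a centred uniform distribution scaled by the
#' inverse square root of the fan-in; biases start at zero.
#'
#' @param spec an [mlp_spec()].
#' @param seed integer seed.
#' @return list of class `mlp_params` with elements `W` (list of
#'   `in x out` matrices) and `b` (list of vectors); `spec` attached as an
#'   attribute.
#' @export
build_mlp <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "mlp_spec"))
  set.seed(seed)
  sz <- mlp_layer_sizes(spec)
  W <- vector("list", length(sz) - 1L)
  b <- vector("list", length(sz) - 1L)
  for (l in seq_along(W)) {
    lim <- 1 / sqrt(sz[l])
    W[[l]] <- matrix(runif(sz[l] * sz[l + 1], -lim, lim), sz[l], sz[l + 1])
    b[[l]] <- numeric(sz[l + 1])
  }
  p <- structure(list(W = W, b = b), class = "mlp_params")
  attr(p, "spec") <- spec
  p
}

#' Forward pass of a dense comparator
#'
#' @param params an `mlp_params` object.
#' @param X n x 16 input matrix.
#' @return list with `jump` (n output probabilities), `H` (list of hidden
#'   activations per layer, inputs first) and `s` (output pre-activation).
#' @export
mlp_forward <- function(params, X) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
  L <- length(params$W)
  H <- vector("list", L)   # H[[l]] = input to layer l
  A <- X
  for (l in seq_len(L)) {
    H[[l]] <- A
    Z <- A %*% params$W[[l]] + rep(params$b[[l]], each = nrow(A))
    A <- if (l < L) tanh(Z) else Z
  }
  s <- drop(A)
  list(jump = sigmoid(s), H = H, s = s)
}

#' Magnitude pruning by percentile
#'
#' Pools the absolute values of all weight-matrix entries (biases are never
#' pruned) into a single ascending ranking and sets the lowest `percentile`
#' percent to exactly zero; surviving count is
#' `ceiling((1 - percentile/100) * W)`.
#'
#' @param params an `mlp_params` object (typically trained).
#' @param percentile in `[0, 100]`.
#' @return list with `params` (pruned copy, plus a `prune_mask` attribute),
#'   `n_surviving` and `n_total` weight counts.
#' @export
prune_by_percentile <- function(params, percentile) {
  if (percentile < 0 || percentile > 100)
    stopf("percentile must lie in [0, 100]")
  w <- unlist(lapply(params$W, as.numeric))
  n_total <- length(w)
  n_zero <- n_total - as.integer(ceiling((1 - percentile / 100) * n_total))
  keep <- rep(TRUE, n_total)
  if (n_zero > 0) keep[order(abs(w))[seq_len(n_zero)]] <- FALSE
  w[!keep] <- 0
  pos <- 0L
  mask <- vector("list", length(params$W))
  for (l in seq_along(params$W)) {
    n <- length(params$W[[l]])
    params$W[[l]][] <- w[pos + seq_len(n)]
    mask[[l]] <- matrix(keep[pos + seq_len(n)], nrow(params$W[[l]]))
    pos <- pos + n
  }
  attr(params, "prune_mask") <- mask
  list(params = params, n_surviving = sum(keep), n_total = n_total)
}
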