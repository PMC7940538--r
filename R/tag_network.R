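#' @title Sparse TAG network: masks, deterministic init, forward pass
#'
#' @description The terminal-abdominal-ganglion (TAG) model is a small
#' network with a fixed, biologically motivated connectivity: 16 input
#' (feature-map) neurons, seven hidden interneurons -- four
#' direction-selective cells (`d45`, `d135`, `d225`, `d315`), two air-speed
#' cells (`slow`, `fast`) and a global background-regulation cell (`glob`)
#' -- and one sigmoidal `jump` output.  Every weight lives inside an
#' explicit connectivity mask; entries outside the mask are identically
#' zero and are never updated.
#'
#' @name tag_network
NULL

tag_variants <- function() c("I", "I+L", "I+G", "I+L+G")

interneuron_names <- function() c("d45", "d135", "d225", "d315",
                                  "slow", "fast", "glob")

# input indices (1-based) in the fixed (side, length, orientation) order
input_index <- function(side, length, orientation_deg) {
  pops <- subpopulations()
  which(pops$side == side & pops$length == length &
          pops$orientation_deg == orientation_deg)
}

#' Build the connectivity masks of an ablation variant
#'
#' Feed-forward: each directional interneuron receives the two same-angle
#' slow (long-hair) inputs; `slow` receives the four rear (135/225) slow
#' inputs; `fast` the four rear fast inputs; `glob` all eight slow inputs.
#' Lateral: all-to-all (including self) among the four directional cells,
#' mutual `slow`/`fast` coupling, and uni-directional synapses from the two
#' speed cells onto each directional cell.  `glob` sends one regulatory
#' synapse to each of the six other interneurons.  All seven interneurons
#' (six without the global-regulation component) project to `jump`.
#'
#' @param variant one of `"I"`, `"I+L"`, `"I+G"`, `"I+L+G"`: interneurons
#'   only, plus lateral connections, plus global regulation, or both.
#' @return list of class `tag_mask` with logical elements `ff` (7 x 16),
#'   `lat` (7 x 7, `[post, pre]`), `glob_out` (6), `jump` (7), `b` (7),
#'   `b_jump` (1) and fields `variant`, `has_glob`, `has_lateral`.
#' @export
tag_masks <- function(variant = "I+L+G") {
  if (!variant %in% tag_variants())
    stopf("unknown variant '%s' (expected one of %s)", variant,
          paste(tag_variants(), collapse = ", "))
  has_glob <- grepl("G", variant, fixed = TRUE)
  has_lateral <- grepl("L", variant, fixed = TRUE)
  inter <- interneuron_names()
  ff <- matrix(FALSE, 7, 16, dimnames = list(inter, feature_names()))
  for (ang in c(45, 135, 225, 315)) {
    d <- paste0("d", ang)
    ff[d, input_index("left", "long", ang)] <- TRUE
    ff[d, input_index("right", "long", ang)] <- TRUE
  }
  for (s in c("left", "right")) for (ang in c(135, 225)) {
    ff["slow", input_index(s, "long", ang)] <- TRUE
    ff["fast", input_index(s, "short", ang)] <- TRUE
  }
  if (has_glob)
    for (s in c("left", "right")) for (ang in c(45, 135, 225, 315))
      ff["glob", input_index(s, "long", ang)] <- TRUE
  lat <- matrix(FALSE, 7, 7, dimnames = list(inter, inter))
  if (has_lateral) {
    dd <- paste0("d", c(45, 135, 225, 315))
    lat[dd, dd] <- TRUE                 # all-to-all incl. self
    lat["slow", "fast"] <- TRUE
    lat["fast", "slow"] <- TRUE
    lat[dd, c("slow", "fast")] <- TRUE  # speed -> direction, uni-directional
  }
  glob_out <- rep(has_glob, 6)
  names(glob_out) <- inter[1:6]
  jump <- c(rep(TRUE, 6), has_glob)
  names(jump) <- inter
  b <- c(rep(TRUE, 6), has_glob)
  names(b) <- inter
  structure(list(variant = variant, has_glob = has_glob,
                 has_lateral = has_lateral, ff = ff, lat = lat,
                 glob_out = glob_out, jump = jump, b = b, b_jump = TRUE),
            class = "tag_mask")
}

#' Deterministic parameter initialization
#'
#' No random draws: every trainable parameter starts at +1, 0 or -1
#' according to the logical role of its connection.  Masked feed-forward
#' weights (including the inputs to `glob`) start at +1; the regulatory
#' synapses from `glob` to the other interneurons start at -1; lateral
#' weights between opposite directional pairs (45/225 and 135/315) start at
#' -1 and all other lateral weights at 0; the jump weights start at +1 from
#' `fast`, -1 from `slow` and 0 elsewhere; all biases start at 0.
#'
#' @param mask a [tag_masks()] object.
#' @return list of class `tag_params` with numeric elements `W_ff` (7 x 16),
#'   `W_lat` (7 x 7), `glob_out` (6), `w_jump` (7), `b` (7), `b_jump` (1)
#'   and the mask attached as attribute `mask`.
#' @export
tag_init <- function(mask = tag_masks()) {
  stopifnot(inherits(mask, "tag_mask"))
  W_ff <- ifelse(mask$ff, 1, 0)
  W_lat <- matrix(0, 7, 7, dimnames = dimnames(mask$lat))
  if (mask$has_lateral) {
    W_lat["d45", "d225"] <- W_lat["d225", "d45"] <- -1
    W_lat["d135", "d315"] <- W_lat["d315", "d135"] <- -1
  }
  glob_out <- ifelse(mask$glob_out, -1, 0)
  w_jump <- stats::setNames(numeric(7), interneuron_names())
  w_jump["fast"] <- 1
  w_jump["slow"] <- -1
  b <- stats::setNames(numeric(7), interneuron_names())
  p <- structure(list(W_ff = W_ff, W_lat = W_lat, glob_out = glob_out,
                      w_jump = w_jump, b = b, b_jump = 0),
                 class = "tag_params")
  attr(p, "mask") <- mask
  p
}

# numeric 0/1 masks in the same shape as the parameter list
tag_mask_numeric <- function(mask) {
  list(W_ff = mask$ff * 1,
       W_lat = mask$lat * 1,
       glob_out = as.numeric(mask$glob_out),
       w_jump = as.numeric(mask$jump),
       b = as.numeric(mask$b),
       b_jump = 1)
}

#' Forward pass of the TAG model
#'
#' One-step-unrolled evaluation: `glob` is computed first as
#' `g = tanh(tanh(W_glob x) + b_glob)`; each of the six other interneurons
#' applies tanh to its feed-forward drive plus the glob input (step 1), and
#' then tanh to the sum of that first activation, the lateral drive computed
#' from the *step-1* activations, and its bias (step 2).  The jump output is
#' a sigmoid over the seven (or six, without global regulation) interneuron
#' activations.  Variants without lateral connections skip the lateral sum;
#' variants without global regulation carry no `glob` terms.
#'
#' @param params a [tag_init()]-shaped `tag_params` list.
#' @param X n x 16 input matrix (rows are feature vectors).
#' @param mask the `tag_mask`; defaults to the one attached to `params`.
#' @return list with `jump` (n probabilities in (0,1)), `A2` (n x 6 final
#'   interneuron activations), `g` (n glob activations, 0 when absent) and
#'   the intermediates `A1`, `hg` needed for backpropagation.
#' @export
tag_forward <- function(params, X, mask = attr(params, "mask")) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
  if (ncol(X) != 16L) stopf("X must have 16 columns, got %d", ncol(X))
  n <- nrow(X)
  if (mask$has_glob) {
    zg <- drop(X %*% params$W_ff[7L, ])
    hg <- tanh(zg)
    g <- tanh(hg + params$b[[7L]])
  } else {
    hg <- g <- numeric(n)
  }
  Z1 <- X %*% t(params$W_ff[1:6, , drop = FALSE])
  if (mask$has_glob) Z1 <- Z1 + outer(g, params$glob_out)
  A1 <- tanh(Z1)
  Z2 <- A1 + rep(params$b[1:6], each = n)
  if (mask$has_lateral)
    Z2 <- Z2 + A1 %*% t(params$W_lat[1:6, 1:6, drop = FALSE])
  A2 <- tanh(Z2)
  s <- drop(A2 %*% params$w_jump[1:6]) + params$b_jump
  if (mask$has_glob) s <- s + g * params$w_jump[[7L]]
  list(jump = sigmoid(s), A2 = A2, A1 = A1, g = g, hg = hg, s = s)
}

#' Count trainable parameters of a variant
#'
#' @param variant an ablation variant name, or `"logistic"` for the
#'   single-neuron comparator (16 weights + 1 bias).
#' @param include_biases count bias terms as parameters?
#' @return integer count.
#' @export
count_parameters <- function(variant = "I+L+G", include_biases = FALSE) {
  if (identical(variant, "logistic")) return(if (include_biases) 17L else 16L)
  m <- tag_masks(variant)
  w <- sum(m$ff) + sum(m$lat) + sum(m$glob_out) + sum(m$jump)
  if (include_biases) w <- w + sum(m$b) + 1L
  as.integer(w)
}

#' Serialize TAG parameters (with their mask) to JSON
#'
#' @param params a `tag_params` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tag_params <- function(params, path) {
  mask <- attr(params, "mask")
  obj <- list(variant = mask$variant,
              W_ff = params$W_ff, W_lat = params$W_lat,
              glob_out = params$glob_out, w_jump = params$w_jump,
              b = params$b, b_jump = params$b_jump,
              mask = list(ff = mask$ff * 1, lat = mask$lat * 1,
                          glob_out = mask$glob_out * 1, jump = mask$jump * 1,
                          b = mask$b * 1))
  jsonlite::write_json(obj, path, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' Read TAG parameters back from JSON
#'
#' Validates the stored values against the stored mask: any nonzero entry
#' outside the mask is an error.
#'
#' @param path file written by [write_tag_params()].
#' @return a `tag_params` object.
#' @export
read_tag_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  mask <- tag_masks(obj$variant)
  p <- tag_init(mask)
  dn_ff <- dimnames(p$W_ff); dn_lat <- dimnames(p$W_lat)
  p$W_ff <- matrix(as.numeric(obj$W_ff), 7, 16, dimnames = dn_ff)
  p$W_lat <- matrix(as.numeric(obj$W_lat), 7, 7, dimnames = dn_lat)
  p$glob_out <- stats::setNames(as.numeric(obj$glob_out), names(p$glob_out))
  p$w_jump <- stats::setNames(as.numeric(obj$w_jump), names(p$w_jump))
  p$b <- stats::setNames(as.numeric(obj$b), names(p$b))
  p$b_jump <- as.numeric(obj$b_jump)
  if (any(p$W_ff[!mask$ff] != 0) || any(p$W_lat[!mask$lat] != 0))
    stopf("stored weights violate the connectivity mask of variant %s",
          obj$variant)
  p
}
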