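# shared numeric helpers

sigmoid <- function(x) 1 / (1 + exp(-x))

#' @noRd
clip_prob <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

deg2rad <- function(deg) deg * pi / 180

# flatten a list of numeric arrays to one vector and back; used so the
# optimizers can treat every model as a flat parameter vector
flatten_params <- function(p) unlist(p, use.names = FALSE)

unflatten_params <- function(v, skeleton) {
  pos <- 0L
  fill <- function(skel) {
    if (is.list(skel)) return(lapply(skel, fill))
    n <- length(skel)
    x <- v[pos + seq_len(n)]
    pos <<- pos + n
    dim(x) <- dim(skel)
    dimnames(x) <- dimnames(skel)
    names(x) <- names(skel)
    x
  }
  fill(skeleton)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
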