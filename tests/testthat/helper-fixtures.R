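# small shared fixtures, built once per test run

tiny_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_dataset(30, seed = 42L)
    cache
  }
})

# a deterministic non-symmetric parameter point for gradient checks: the
# masked init shifted by small seeded perturbations
perturbed_tag_params <- function(variant = "I+L+G", sd = 0.3, seed = 7L) {
  mask <- tag_masks(variant)
  p <- tag_init(mask)
  msk <- cercatag:::tag_mask_numeric(mask)
  set.seed(seed)
  for (nm in c("W_ff", "W_lat", "glob_out", "w_jump", "b"))
    p[[nm]][] <- p[[nm]] + rnorm(length(p[[nm]]), 0, sd) * as.numeric(msk[[nm]])
  p$b_jump <- 0.1
  p
}

flatten_tag <- function(p) unlist(unclass(p))

rebuild_tag <- function(theta, skeleton, mask) {
  p <- cercatag:::unflatten_params(theta, skeleton)
  attr(p, "mask") <- mask
  class(p) <- "tag_params"
  p
}
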