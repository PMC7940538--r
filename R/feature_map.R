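#' Leaky resistor-capacitor input-neuron configuration
#'
#' Each of the 16 input-layer neurons integrates the spikes of one hair
#' sub-population as a parallel RC circuit fed by a current source:
#' `C dV/dt = i(t) - V/R`, with a pulse of `i_in` lasting one integration
#' step per spike.  Default values give a membrane time constant
#' `R * C = 20` ms and a per-spike voltage increment `i_in * dt / C = 10` mV.
#'
#' @param C capacitance in farads (default 0.1 pF).
#' @param R resistance in ohms (default 200 G-ohm).
#' @param i_in pulse current in amperes (default 1 pA).
#' @param dt forward-Euler step in seconds (default 1 ms).
#' @param duration simulated interval in seconds.
#' @param voltage_scale dimensionless factor applied to `Vc` before the
#'   baseline subtraction and tanh, so that activations live in the
#'   informative range of tanh (default 10: one spike contributes +0.1).
#' @param snapshot_lag seconds after each candidate attack-peak time at
#'   which the feature snapshot is read out (default 10 ms, half an RC time
#'   constant, so the attack transient is still prominent in the trace).
#' @return A list of class `rc_config`.
#' @export
rc_config <- function(C = 0.1e-12, R = 200e9, i_in = 1e-12, dt = 1e-3,
                      duration = 1, voltage_scale = 10, snapshot_lag = 0.010) {
  if (dt <= 0) stopf("dt must be positive")
  stopifnot(C > 0, R > 0, i_in > 0, duration > 0, voltage_scale > 0,
            snapshot_lag >= 0)
  structure(list(C = C, R = R, i_in = i_in, dt = dt, duration = duration,
                 voltage_scale = voltage_scale, snapshot_lag = snapshot_lag),
            class = "rc_config")
}

#' Integrate a spike train through the leaky RC circuit
#'
#' Forward-Euler solution of `dV/dt = i(t)/C - V/(R C)` with `V(0) = 0`;
#' the input current is `i_in` (summed over coincident spikes) during the
#' step containing each spike.  Implemented as a first-order recursive
#' filter, which is algebraically identical to the Euler recursion
#' `V[t+1] = V[t] (1 - dt/RC) + i[t] dt / C`.
#'
#' @param spike_times numeric vector of spike times in `[0, duration]`.
#' @param rc an [rc_config()].
#' @param duration override of `rc$duration`.
#' @return numeric vector of `Vc` (volts), one entry per Euler step (the
#'   value at the *end* of each step).
#' @export
integrate_spikes <- function(spike_times, rc = rc_config(),
                             duration = rc$duration) {
  n_steps <- as.integer(round(duration / rc$dt))
  if (n_steps < 1L) stopf("duration shorter than one integration step")
  if (length(spike_times) &&
      (min(spike_times) < 0 || max(spike_times) > duration))
    stopf("spike times outside [0, duration]")
  counts <- spike_counts_per_step(spike_times, rc$dt, n_steps)
  rc_filter(counts, rc)
}

# bin spike times into Euler steps (step k covers ((k-1) dt, k dt])
spike_counts_per_step <- function(spike_times, dt, n_steps) {
  if (!length(spike_times)) return(numeric(n_steps))
  bins <- pmin(pmax(ceiling(spike_times / dt), 1L), n_steps)
  tabulate(bins, nbins = n_steps)
}

# recursive-filter core shared by integrate_spikes and build_dataset;
# accepts a vector or a (steps x neurons) matrix of per-step spike counts
rc_filter <- function(counts, rc) {
  decay <- 1 - rc$dt / (rc$R * rc$C)
  if (decay <= 0)
    stopf("dt >= RC: the forward-Euler integrator is unstable at this step")
  gain <- rc$i_in * rc$dt / rc$C
  if (is.matrix(counts)) {
    out <- counts
    for (j in seq_len(ncol(counts)))
      out[, j] <- stats::filter(gain * counts[, j], decay, method = "recursive")
    out
  } else {
    as.numeric(stats::filter(gain * counts, decay, method = "recursive"))
  }
}

#' Input-neuron activation
#'
#' The feature-map output: hyperbolic tangent of the difference between the
#' (scaled) instantaneous capacitor voltage and its per-neuron mean over the
#' training split, so that average ambient drive maps to an activation near
#' zero.
#'
#' @param Vc_sample scaled capacitor voltage(s).
#' @param baseline_mean per-neuron training-split mean on the same scale.
#' @return activation(s) in `(-1, 1)`.
#' @export
activation <- function(Vc_sample, baseline_mean) tanh(Vc_sample - baseline_mean)

feature_names <- function() sprintf("f%02d", 0:15)

# raw (scaled) snapshot voltages for one simulation: 2 x 16 matrix, one row
# per candidate attack slot
simulation_snapshots <- function(raster, rc) {
  n_steps <- as.integer(round(rc$duration / rc$dt))
  pops <- subpopulations()
  idx <- raster$events$.pop
  counts <- matrix(0, n_steps, nrow(pops))
  bins <- pmin(pmax(ceiling(raster$events$spike_time_s / rc$dt), 1L), n_steps)
  for (k in seq_len(nrow(pops))) {
    sel <- idx == k
    if (any(sel)) counts[, k] <- tabulate(bins[sel], nbins = n_steps)
  }
  V <- rc_filter(counts, rc)
  slots <- sort(c(0.350, 0.700))
  take <- pmin(pmax(as.integer(round((slots + rc$snapshot_lag) / rc$dt)), 1L),
               n_steps)
  V[take, , drop = FALSE] * rc$voltage_scale
}

#' Build the labeled snapshot dataset
#'
#' Runs `n_sims` seeded one-second hair simulations; each contributes two
#' 16-feature snapshots of the input-neuron voltages, read out
#' `snapshot_lag` seconds after the two candidate attack-peak times (350 and
#' 700 ms).  The snapshot at the slot where the attack actually occurred is
#' labeled 1 (attack), the other 0 (ambient), so classes are balanced by
#' construction; both rows carry the trial's background direction.  Rows are
#' shuffled and split into equal train/test halves; the per-neuron baseline
#' means of Eq.-style background subtraction are computed on the training
#' half only and stored with the dataset.
#'
#' @param n_sims number of simulations (>= 1).
#' @param bounds,cfg,rc configuration objects.
#' @param seed integer seed controlling every random draw.
#' @return data.frame of class `tag_dataset` with columns `f00..f15`,
#'   `attack` (0/1), `direction` (degrees), `split` (`"train"`/`"test"`),
#'   `sim_id`, `snapshot_s`; attributes `baseline_means` (named numeric,
#'   scaled volts) and `n_sims`.
#' @export
build_dataset <- function(n_sims, bounds = stimulus_bounds(),
                          cfg = hair_config(), rc = rc_config(), seed = 1L) {
  if (n_sims < 1) stopf("n_sims must be >= 1: cannot build an empty dataset")
  set.seed(seed)
  feats <- matrix(NA_real_, 2L * n_sims, 16L,
                  dimnames = list(NULL, feature_names()))
  attack <- integer(2L * n_sims)
  direction <- numeric(2L * n_sims)
  sim_id <- integer(2L * n_sims)
  snapshot_s <- numeric(2L * n_sims)
  slots <- sort(c(0.350, 0.700))
  for (i in seq_len(n_sims)) {
    stim <- sample_stimulus(bounds)
    raster <- simulate_hairs(stim, cfg)
    snaps <- simulation_snapshots(raster, rc)
    rows <- 2L * i - c(1L, 0L)
    feats[rows, ] <- snaps
    attack[rows] <- as.integer(abs(slots - stim$attack_time) < 1e-9)
    direction[rows] <- stim$background_direction
    sim_id[rows] <- i
    snapshot_s[rows] <- slots + rc$snapshot_lag
  }
  n <- 2L * n_sims
  perm <- sample.int(n)   # first half of the shuffled order becomes train
  split <- character(n)
  split[perm[seq_len(n %/% 2)]] <- "train"
  split[perm[(n %/% 2 + 1L):n]] <- "test"
  train <- split == "train"
  baseline <- colMeans(feats[train, , drop = FALSE])
  out <- data.frame(activation(feats, rep(baseline, each = n)),
                    attack = attack, direction = direction, split = split,
                    sim_id = sim_id, snapshot_s = snapshot_s,
                    stringsAsFactors = FALSE)
  names(out)[1:16] <- feature_names()
  attr(out, "baseline_means") <- baseline
  attr(out, "n_sims") <- n_sims
  class(out) <- c("tag_dataset", "data.frame")
  out
}

#' Extract model inputs/labels from a dataset
#'
#' @param dataset a `tag_dataset`.
#' @param split `"train"`, `"test"` or `"all"`.
#' @return list with `X` (n x 16 matrix), `y` (attack labels) and
#'   `direction` (degrees).
#' @export
dataset_matrices <- function(dataset, split = c("train", "test", "all")) {
  split <- match.arg(split)
  d <- if (split == "all") dataset else dataset[dataset$split == split, ]
  list(X = as.matrix(d[, feature_names()]), y = d$attack,
       direction = d$direction)
}

#' Write a dataset (and its baseline means) to disk
#'
#' @param dataset a `tag_dataset`.
#' @param path CSV output path; the baseline means go to a JSON sidecar
#'   `<path>.baseline.json`.
#' @return `path`, invisibly.
#' @export
write_dataset_csv <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE,
                   quote = FALSE)
  jsonlite::write_json(as.list(attr(dataset, "baseline_means")),
                       paste0(path, ".baseline.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
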