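#' Stimulus sampling ranges
#'
#' Bounds for the five per-simulation random variables that define one
#' 1-second trial: ambient (background) air-current intensity and direction,
#' and the attack angle, speed and attacker size.  The attack peaks at one of
#' two fixed times (350 or 700 ms), chosen equiprobably.
#'
#' @param intensity numeric length-2, background drive bounds (dimensionless;
#'   sets per-hair baseline spike counts).
#' @param attack_angle numeric length-2, degrees; attacks come from behind
#'   the animal (0 degrees points at the head).
#' @param attack_speed numeric length-2, 1/seconds; the attack-locked spike
#'   jitter has standard deviation `1/attack_speed`.
#' @param attacker_size numeric length-2, dimensionless amplitude factor.
#' @param attack_times the two candidate attack-peak times in seconds.
#' @param directions admissible background directions in degrees.
#' @return A list of class `stimulus_bounds`.
#' @export
stimulus_bounds <- function(intensity = c(15, 30),
                            attack_angle = c(120, 240),
                            attack_speed = c(100, 500),
                            attacker_size = c(0.75, 1),
                            attack_times = c(0.350, 0.700),
                            directions = c(45, 135, 225, 315)) {
  b <- list(intensity = as.numeric(intensity),
            attack_angle = as.numeric(attack_angle),
            attack_speed = as.numeric(attack_speed),
            attacker_size = as.numeric(attacker_size),
            attack_times = as.numeric(attack_times),
            directions = as.numeric(directions))
  for (nm in c("intensity", "attack_angle", "attack_speed", "attacker_size")) {
    r <- b[[nm]]
    if (length(r) != 2L || any(!is.finite(r)) || r[1] > r[2])
      stopf("invalid bounds for '%s': need finite lo <= hi", nm)
  }
  class(b) <- "stimulus_bounds"
  b
}

#' Hair sub-population configuration
#'
#' Parameters of the statistical filiform-hair model: 16 sub-populations
#' (left/right cercus x long/short hair x four socket orientations), each of
#' `n_hairs` hairs.  Long hairs are tuned to slow air currents, short hairs
#' to fast ones; short-hair baseline rates are `short_baseline_factor` of the
#' long-hair rate, and their attack-locked spikes lead the long hairs by
#' `short_latency_shift` seconds.
#'
#' @param n_hairs hairs per sub-population.
#' @param orientations the four preferred socket angles, degrees.
#' @param beta1 floor of the directional response probability.
#' @param beta2 floor of the contralateral (cercus side) response probability.
#' @param alpha decay rate (per radian) of the contralateral response as the
#'   attack angle departs from straight behind (180 degrees).
#' @param short_latency_shift seconds by which short-hair attack spikes lead.
#' @param short_baseline_factor baseline-rate ratio of short to long hairs.
#' @param direction_gain modulation of baseline counts for hairs aligned
#'   with (`1 + gain`) or opposite to (`1 - gain`) the background direction.
#' @param poisson_baseline if `TRUE`, baseline spike counts are Poisson draws
#'   around the deterministic product instead of the rounded product.
#' @return A list of class `hair_config`.
#' @export
hair_config <- function(n_hairs = 60,
                        orientations = c(45, 135, 225, 315),
                        beta1 = 0.1, beta2 = 0.1, alpha = 2.0,
                        short_latency_shift = 0.010,
                        short_baseline_factor = 0.5,
                        direction_gain = 0.5,
                        poisson_baseline = FALSE) {
  stopifnot(n_hairs >= 1, beta1 >= 0, beta1 <= 1, beta2 >= 0, beta2 <= 1,
            alpha > 0, short_baseline_factor > 0, short_baseline_factor <= 1,
            direction_gain >= 0, direction_gain < 1)
  cfg <- list(n_hairs = as.integer(n_hairs), orientations = orientations,
              beta1 = beta1, beta2 = beta2, alpha = alpha,
              short_latency_shift = short_latency_shift,
              short_baseline_factor = short_baseline_factor,
              direction_gain = direction_gain,
              poisson_baseline = isTRUE(poisson_baseline))
  class(cfg) <- "hair_config"
  cfg
}

#' The 16 hair sub-populations
#'
#' Fixed ordering convention used everywhere in the package: side (left then
#' right), length (long then short), orientation (45, 135, 225, 315).  This
#' is also the ordering of the 16 feature-map input neurons.
#'
#' @return data.frame with columns `side`, `length`, `orientation_deg`.
#' @export
subpopulations <- function() {
  g <- expand.grid(orientation_deg = c(45, 135, 225, 315),
                   length = c("long", "short"),
                   side = c("left", "right"),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g[, c("side", "length", "orientation_deg")]
}

#' Draw the parameters of one simulated trial
#'
#' All five stimulus variables are sampled uniformly within their bounds;
#' the background direction and the attack time are drawn equiprobably from
#' their discrete sets.
#'
#' @param bounds a [stimulus_bounds()] object.
#' @return A list of class `stimulus_params`.
#' @export
sample_stimulus <- function(bounds = stimulus_bounds()) {
  stopifnot(inherits(bounds, "stimulus_bounds"))
  u <- function(r) runif(1L, r[1], r[2])
  s <- list(background_intensity = u(bounds$intensity),
            background_direction = sample(bounds$directions, 1L),
            attack_angle = u(bounds$attack_angle),
            attack_speed = u(bounds$attack_speed),
            attacker_size = u(bounds$attacker_size),
            attack_time = sample(bounds$attack_times, 1L))
  class(s) <- "stimulus_params"
  s
}

#' Baseline spike count for one hair
#'
#' Deterministic integer count of background-driven spikes for a hair of the
#' given sub-population: `round(intensity * length_factor * direction_factor)`
#' where the length factor is 1 for long hairs and
#' `short_baseline_factor` for short hairs, and the direction factor is
#' `1 + direction_gain` for hairs whose socket orientation matches the
#' background direction, `1 - direction_gain` for the opposite orientation
#' and 1 otherwise.
#'
#' @param side `"left"` or `"right"` (does not affect the baseline).
#' @param length `"long"` or `"short"`.
#' @param orientation_deg the hair's preferred angle.
#' @param stim a `stimulus_params` object.
#' @param cfg a [hair_config()] object.
#' @return non-negative integer count.
#' @export
baseline_spike_count <- function(side, length, orientation_deg, stim,
                                 cfg = hair_config()) {
  length_factor <- if (identical(length, "short")) cfg$short_baseline_factor else 1
  opposite <- (stim$background_direction + 180) %% 360
  direction_factor <-
    if (orientation_deg == stim$background_direction) 1 + cfg$direction_gain
    else if (orientation_deg == opposite) 1 - cfg$direction_gain
    else 1
  as.integer(round(stim$background_intensity * length_factor * direction_factor))
}

#' Probability that a hair fires an attack-locked spike
#'
#' The Bernoulli success probability `p = p_theta * p_side * s`.  The
#' directional term is a raised cosine with floor `beta1`,
#' `p_theta = (1 - beta1) * max(cos|theta_p - theta|, 0) + beta1`; the side
#' term is 1 on the cercus ipsilateral to the attack and decays
#' exponentially with the angular departure from straight behind on the
#' contralateral cercus, `p_side = (1 - beta2) * exp(-alpha |pi - theta|) +
#' beta2` (theta in radians).  An attack from exactly behind (180 degrees)
#' gives `p_side = 1` on both cerci.
#'
#' @param orientation_deg the hair's preferred angle theta_p.
#' @param side `"left"` or `"right"`.
#' @param stim a `stimulus_params` object.
#' @param cfg a [hair_config()] object.
#' @return probability in `[0, 1]`.
#' @export
attack_response_probability <- function(orientation_deg, side, stim,
                                        cfg = hair_config()) {
  theta <- stim$attack_angle
  ct <- cos(deg2rad(abs(orientation_deg - theta)))
  p_theta <- (1 - cfg$beta1) * max(ct, 0) + cfg$beta1
  attack_side <- if (theta < 180) "left" else if (theta > 180) "right" else side
  p_side <- if (identical(side, attack_side)) 1
  else (1 - cfg$beta2) * exp(-cfg$alpha * abs(pi - deg2rad(theta))) + cfg$beta2
  p_theta * p_side * stim$attacker_size
}

#' Add attack-locked spikes to a baseline raster
#'
#' Per hair, one Bernoulli trial with the probability from
#' [attack_response_probability()]; on success one extra spike time is drawn
#' from a normal distribution centred on the attack-peak time (short hairs
#' lead by `short_latency_shift`) with standard deviation `1/attack_speed`,
#' clipped to `[0, 1]`.
#'
#' @param raster a `spike_raster` holding baseline spikes only.
#' @param stim,cfg as elsewhere.
#' @return The raster with attack spikes merged in (still sorted per hair).
#' @export
inject_attack <- function(raster, stim, cfg = hair_config()) {
  stopifnot(inherits(raster, "spike_raster"))
  att <- draw_attack_spikes(stim, cfg)
  raster$events <- assemble_events(
    c(raster$events$.pop, att$pop),
    c(raster$events$hair_index, att$hair),
    c(raster$events$spike_time_s, att$time))
  raster
}

# attack-locked spikes for all sub-populations as parallel vectors
draw_attack_spikes <- function(stim, cfg) {
  pops <- subpopulations()
  sd_att <- 1 / stim$attack_speed
  pop <- hair <- integer(0)
  time <- numeric(0)
  for (k in seq_len(nrow(pops))) {
    p <- attack_response_probability(pops$orientation_deg[k], pops$side[k],
                                     stim, cfg)
    fires <- which(rbinom(cfg$n_hairs, 1L, p) == 1L)
    if (!length(fires)) next
    mu <- stim$attack_time -
      if (pops$length[k] == "short") cfg$short_latency_shift else 0
    t_att <- pmin(pmax(rnorm(length(fires), mu, sd_att), 0), 1)
    pop <- c(pop, rep.int(k, length(fires)))
    hair <- c(hair, fires - 1L)
    time <- c(time, t_att)
  }
  list(pop = pop, hair = hair, time = time)
}

# canonical sorted events data.frame from (sub-population, hair, time)
# vectors; the integer sub-population index is kept in hidden column .pop
assemble_events <- function(pop, hair, time) {
  o <- order(pop, hair, time)
  pops <- subpopulations()
  data.frame(side = pops$side[pop[o]], length = pops$length[pop[o]],
             orientation_deg = pops$orientation_deg[pop[o]],
             hair_index = hair[o], spike_time_s = time[o],
             .pop = pop[o], stringsAsFactors = FALSE)
}

#' Simulate one second of ensemble hair spiking
#'
#' Generates the baseline raster (uniform spike times on `[0, 1]`, counts per
#' [baseline_spike_count()]) for all 16 sub-populations x `n_hairs` hairs,
#' then injects one attack per [inject_attack()].  A pure function of
#' `(stim, cfg)` and the RNG state: seed the session RNG for reproducibility.
#'
#' @param stim a `stimulus_params` object.
#' @param cfg a [hair_config()] object.
#' @param attack if `FALSE`, return the baseline-only raster.
#' @return A list of class `spike_raster` with element `events`, a
#'   data.frame (`side`, `length`, `orientation_deg`, `hair_index`,
#'   `spike_time_s`) sorted by sub-population, hair and time, plus the
#'   generating `stim` and `n_hairs` as attributes.
#' @export
simulate_hairs <- function(stim, cfg = hair_config(), attack = TRUE) {
  pops <- subpopulations()
  pop <- hair <- integer(0)
  time <- numeric(0)
  for (k in seq_len(nrow(pops))) {
    cnt <- baseline_spike_count(pops$side[k], pops$length[k],
                                pops$orientation_deg[k], stim, cfg)
    counts <- if (cfg$poisson_baseline) rpois(cfg$n_hairs, cnt)
              else rep.int(cnt, cfg$n_hairs)
    total <- sum(counts)
    if (total == 0L) next
    pop <- c(pop, rep.int(k, total))
    hair <- c(hair, rep.int(seq_len(cfg$n_hairs) - 1L, counts))
    time <- c(time, runif(total))
  }
  if (attack) {
    att <- draw_attack_spikes(stim, cfg)
    pop <- c(pop, att$pop)
    hair <- c(hair, att$hair)
    time <- c(time, att$time)
  }
  structure(list(events = assemble_events(pop, hair, time), stim = stim,
                 n_hairs = cfg$n_hairs),
            class = "spike_raster")
}

#' Write spike events to CSV
#'
#' @param raster a `spike_raster`.
#' @param path output file.
#' @param sim_id identifier recorded in the first column.
#' @return `path`, invisibly.
#' @export
write_raster_csv <- function(raster, path, sim_id = 1L) {
  cols <- c("side", "length", "orientation_deg", "hair_index", "spike_time_s")
  ev <- cbind(sim_id = sim_id, raster$events[, cols])
  utils::write.csv(ev, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Flatten stimulus draws into a data.frame
#'
#' One row per simulation; useful for logging the draws of a whole study as
#' CSV.
#'
#' @param x a `stimulus_params` object (or a list of them via
#'   [stimulus_log()]).
#' @param ... unused.
#' @return one-row data.frame.
#' @export
as.data.frame.stimulus_params <- function(x, ...) {
  data.frame(background_intensity = x$background_intensity,
             background_direction = x$background_direction,
             attack_angle = x$attack_angle, attack_speed = x$attack_speed,
             attacker_size = x$attacker_size, attack_time = x$attack_time)
}

#' @rdname as.data.frame.stimulus_params
#' @param stims list of `stimulus_params`.
#' @param path optional CSV path; when given the log is also written there.
#' @export
stimulus_log <- function(stims, path = NULL) {
  log <- do.call(rbind, lapply(stims, as.data.frame))
  log <- cbind(sim_id = seq_len(nrow(log)), log)
  if (!is.null(path))
    utils::write.csv(log, path, row.names = FALSE, quote = FALSE)
  log
}

#' Write spike events in a compact JSON form
#'
#' Events grouped per sub-population: spike times and hair indices as
#' parallel arrays.
#'
#' @param raster a `spike_raster`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_raster_json <- function(raster, path) {
  pops <- subpopulations()
  out <- lapply(seq_len(nrow(pops)), function(k) {
    sel <- raster$events$.pop == k
    list(side = pops$side[k], length = pops$length[k],
         orientation_deg = pops$orientation_deg[k],
         hair_index = raster$events$hair_index[sel],
         spike_time_s = raster$events$spike_time_s[sel])
  })
  jsonlite::write_json(list(n_hairs = raster$n_hairs, subpopulations = out),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("<spike_raster> 16 sub-populations x %d hairs, %d spikes\n",
              x$n_hairs, nrow(x$events)))
  invisible(x)
}
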