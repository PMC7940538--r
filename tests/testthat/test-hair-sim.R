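test_that("stimulus draws respect their bounds", {
  set.seed(1)
  b <- stimulus_bounds()
  for (i in 1:200) {
    s <- sample_stimulus(b)
    expect_gte(s$attack_angle, 120); expect_lte(s$attack_angle, 240)
    expect_gte(s$attacker_size, 0.75); expect_lte(s$attacker_size, 1)
    expect_gte(s$background_intensity, b$intensity[1])
    expect_lte(s$background_intensity, b$intensity[2])
    expect_true(s$attack_time %in% c(0.350, 0.700))
    expect_true(s$background_direction %in% c(45, 135, 225, 315))
  }
})

test_that("degenerate bounds give constant fields and bad bounds error", {
  set.seed(2)
  b <- stimulus_bounds(attacker_size = c(0.9, 0.9))
  sizes <- replicate(20, sample_stimulus(b)$attacker_size)
  expect_true(all(sizes == 0.9))
  expect_error(stimulus_bounds(intensity = c(10, 5)), "lo <= hi")
})

test_that("baseline spike counts follow the intensity x length x direction product", {
  cfg <- hair_config()  # gain 0.5, short factor 0.5
  stim <- list(background_intensity = 20, background_direction = 45)
  # aligned long hair: round(20 * 1 * 1.5) = 30
  expect_identical(baseline_spike_count("left", "long", 45, stim, cfg), 30L)
  # opposite orientation: round(20 * 1 * 0.5) = 10
  expect_identical(baseline_spike_count("left", "long", 225, stim, cfg), 10L)
  # short hairs at half the long rate at neutral orientation
  expect_identical(baseline_spike_count("left", "short", 135, stim, cfg) * 2L,
                   baseline_spike_count("left", "long", 135, stim, cfg))
  # zero drive, zero spikes
  stim0 <- list(background_intensity = 0, background_direction = 45)
  expect_identical(baseline_spike_count("right", "long", 45, stim0, cfg), 0L)
})

test_that("attack response probability follows the cosine/side/size product", {
  cfg <- hair_config(beta1 = 0.1, beta2 = 0.1)
  stim <- function(angle, size = 1) list(attack_angle = angle,
                                         attacker_size = size)
  # perfectly aligned, ipsilateral, full size
  expect_equal(attack_response_probability(225, "right", stim(225), cfg), 1)
  # scaling by attacker size alone
  expect_equal(attack_response_probability(225, "right", stim(225, 0.75), cfg),
               0.75)
  # 90 degrees off, ipsilateral: cosine term vanishes, floor beta1 remains
  expect_equal(attack_response_probability(225, "left", stim(135), cfg), 0.1)
  # attack from exactly behind excites both cerci fully (p_side = 1)
  p_l <- attack_response_probability(135, "left", stim(180), cfg)
  p_r <- attack_response_probability(135, "right", stim(180), cfg)
  expect_equal(p_l, p_r)
})

test_that("probability bounds and contralateral monotonicity hold", {
  cfg <- hair_config(beta1 = 0.1, beta2 = 0.1, alpha = 2)
  lo <- cfg$beta1 * cfg$beta2 * 0.75
  for (theta in seq(120, 240, by = 7.5))
    for (orient in c(45, 135, 225, 315))
      for (side in c("left", "right"))
        for (s in c(0.75, 0.9, 1)) {
          p <- attack_response_probability(orient, side,
                 list(attack_angle = theta, attacker_size = s), cfg)
          expect_gte(p, lo - 1e-12); expect_lte(p, 1)
        }
  # contralateral response decays as the attack angle departs from 180
  angles <- c(180, 170, 150, 130, 121)   # left-side attacks, right cercus
  ps <- vapply(angles, function(a)
    attack_response_probability(135, "right",
                                list(attack_angle = a, attacker_size = 1),
                                cfg) /
      attack_response_probability(135, "left",
                                  list(attack_angle = a, attacker_size = 1),
                                  cfg),
    numeric(1))
  expect_true(all(diff(ps) < 1e-12))
})

test_that("attack injection adds one spike per successful Bernoulli trial", {
  cfg <- hair_config()
  # aligned rear attack at full size: p = 1 for the right long 225 hairs
  stim <- structure(list(background_intensity = 10,
                         background_direction = 45, attack_angle = 225,
                         attack_speed = 1e6, attacker_size = 1,
                         attack_time = 0.350), class = "stimulus_params")
  set.seed(3)
  base <- simulate_hairs(stim, cfg, attack = FALSE)
  set.seed(4)
  full <- inject_attack(base, stim, cfg)
  sub <- function(r) sum(r$events$side == "right" & r$events$length == "long" &
                           r$events$orientation_deg == 225)
  expect_identical(sub(full) - sub(base), as.integer(cfg$n_hairs))
  # near-infinite attack speed: injected spikes sit at the attack time
  att <- full$events[full$events$side == "right" & full$events$length == "long" &
                       full$events$orientation_deg == 225, ]
  expect_true(any(abs(att$spike_time_s - 0.350) < 1e-4))
})

test_that("short-hair attack spikes lead long-hair spikes by the latency shift", {
  cfg <- hair_config(n_hairs = 200)
  stim <- structure(list(background_intensity = 0, background_direction = 45,
                         attack_angle = 180, attack_speed = 1000,
                         attacker_size = 1, attack_time = 0.700),
                    class = "stimulus_params")
  set.seed(5)
  r <- simulate_hairs(stim, cfg)   # no baseline spikes: intensity 0
  mu_long <- mean(r$events$spike_time_s[r$events$length == "long"])
  mu_short <- mean(r$events$spike_time_s[r$events$length == "short"])
  # 10 ms lead, Monte-Carlo tolerance 3 sigma / sqrt(n)
  expect_equal(mu_long - mu_short, cfg$short_latency_shift,
               tolerance = 0.05)
  expect_equal(mu_long, 0.700, tolerance = 1e-3)
})

test_that("simulate is deterministic and covers 16 sub-populations", {
  set.seed(11)
  stim <- sample_stimulus()
  set.seed(12); r1 <- simulate_hairs(stim)
  set.seed(12); r2 <- simulate_hairs(stim)
  expect_identical(r1$events, r2$events)
  key <- unique(r1$events[, c("side", "length", "orientation_deg")])
  expect_identical(nrow(key), 16L)
  expect_true(all(r1$events$hair_index %in% 0:59))
  expect_true(all(r1$events$spike_time_s >= 0 & r1$events$spike_time_s <= 1))
  # sorted ascending within each hair
  o <- order(r1$events$.pop, r1$events$hair_index, r1$events$spike_time_s)
  expect_identical(o, seq_len(nrow(r1$events)))
})

test_that("spike events round-trip through CSV", {
  set.seed(13)
  r <- simulate_hairs(sample_stimulus(), hair_config(n_hairs = 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_raster_csv(r, path, sim_id = 9L)
  back <- read.csv(path)
  expect_identical(nrow(back), nrow(r$events))
  expect_identical(names(back), c("sim_id", "side", "length",
                                  "orientation_deg", "hair_index",
                                  "spike_time_s"))
  expect_true(all(back$sim_id == 9L))
  expect_equal(back$spike_time_s, r$events$spike_time_s, tolerance = 1e-12)
})

test_that("stimulus logs and JSON rasters serialize faithfully", {
  set.seed(17)
  stims <- replicate(3, sample_stimulus(), simplify = FALSE)
  path <- withr::local_tempfile(fileext = ".csv")
  log <- stimulus_log(stims, path)
  expect_identical(nrow(log), 3L)
  back <- read.csv(path)
  expect_equal(back$attack_angle, vapply(stims, `[[`, numeric(1),
                                         "attack_angle"), tolerance = 1e-9)
  r <- simulate_hairs(stims[[1]], hair_config(n_hairs = 4))
  jpath <- withr::local_tempfile(fileext = ".json")
  write_raster_json(r, jpath)
  j <- jsonlite::read_json(jpath, simplifyVector = TRUE)
  expect_identical(length(j$subpopulations$side), 16L)
  expect_identical(sum(lengths(j$subpopulations$spike_time_s)),
                   nrow(r$events))
})
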