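test_that("condition presets carry the published calibration values", {
  liq <- make_preset("LIQUID")
  expect_equal(liq$tumble_bias_true, 0.12)
  expect_equal(liq$run_speed, 21)
  sw <- make_preset("SWARM")
  expect_equal(sw$tumble_bias_true, 0.04)
  expect_equal(sw$run_speed, 25)
  # hard agar abolishes the swarm response: liquid-like behavior
  hard <- make_preset("HARD")
  expect_equal(hard$tumble_bias_true, liq$tumble_bias_true)
  expect_equal(hard$run_speed, liq$run_speed)
  # overrides replace fields individually
  z <- make_preset("LIQUID", tumble_bias_true = 0)
  expect_equal(z$tumble_bias_true, 0)
  expect_equal(z$run_speed, liq$run_speed)
  expect_equal(mean_run_duration(z), Inf)
  expect_error(make_preset("BROTH"), "valid labels")
  expect_error(make_preset("LIQUID", swim_fast = 1), "unknown preset field")
})

test_that("implied mean run duration follows the bias identity", {
  p <- make_preset("LIQUID")
  expect_equal(mean_run_duration(p), 0.2 * (1 - 0.12) / 0.12)
})

test_that("a zero-bias noise-free cell swims in a straight line at run speed", {
  p <- make_preset("LIQUID", tumble_bias_true = 0, rotational_diffusion = 0,
                   localization_sigma = 0)
  tr <- simulate_trajectory(p, duration = 10, dt = 0.1, seed = 1)
  sp <- sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2) / 0.1
  expect_equal(sp, rep(21, length(sp)), tolerance = 1e-12)
  # collinear: cross products of consecutive displacements vanish
  dx <- diff(tr$x_um); dy <- diff(tr$y_um)
  expect_lt(max(abs(dx[-1] * dy[-length(dy)] - dy[-1] * dx[-length(dx)])), 1e-9)
  expect_true(all(tr$true_state == "RUN"))
})

test_that("state-label tumbling fraction converges to the preset bias", {
  p <- make_preset("LIQUID", nonmotile_fraction = 0)
  tb <- vapply(1:150, function(s)
    mean(simulate_trajectory(p, 100, 0.1, seed = s)$true_state == "TUMBLE"),
    numeric(1))
  # law of large numbers: SE of the mean over 150 x 100 s is ~0.0025
  expect_equal(mean(tb), 0.12, tolerance = 0.008 / 0.12)
})

test_that("non-motile cells diffuse with the preset Brownian coefficient", {
  p <- make_preset("LIQUID", brownian_D = 0.4)
  D <- vapply(1:40, function(s) {
    tr <- simulate_trajectory(p, 100, 0.1, seed = s, brownian = TRUE)
    diffusion_coefficient(tr)
  }, numeric(1))
  expect_equal(mean(D), 0.4, tolerance = 0.15 / 0.4)
})

test_that("population generator mixes motile and non-motile cells reproducibly", {
  p <- make_preset("LIQUID", nonmotile_fraction = 1)
  popA <- simulate_population(p, 10, 10, 0.1, seed = 3)
  expect_true(all(popA$samples$true_state == "BROWNIAN"))
  expect_true(all(!popA$cells$motile_true))
  popB <- simulate_population(p, 10, 10, 0.1, seed = 3)
  expect_identical(popA$samples, popB$samples)   # bit-reproducible
  p2 <- make_preset("LIQUID", nonmotile_fraction = 0.3)
  pop2 <- simulate_population(p2, 600, 6, 0.1, seed = 5)
  expect_equal(mean(!pop2$cells$motile_true), 0.3, tolerance = 0.06 / 0.3)
  # ground-truth labels stored alongside positions
  expect_true(all(c("cell_id", "frame", "t_s", "x_um", "y_um", "true_state")
                  %in% names(pop2$samples)))
})

test_that("simulator rejects invalid sampling arguments", {
  p <- make_preset("LIQUID")
  expect_error(simulate_trajectory(p, 10, dt = 0), "duration >= dt > 0")
  expect_error(simulate_trajectory(p, 0.05, dt = 0.1), "duration >= dt > 0")
})

test_that("motor telegraph reversal counts have the preset mean", {
  p <- make_motor_preset("LIQUID")
  revs <- vapply(1:60, function(s)
    attr(simulate_motor_trace(p, 60, seed = s), "true_reversals"), numeric(1))
  se <- stats::sd(revs) / sqrt(length(revs))
  expect_lt(abs(mean(revs) - 38), 3 * se + 1e-9)
})

test_that("motor trace edge cases behave per contract", {
  # no switching: constant CCW orbit at the CCW frequency
  p0 <- make_motor_preset("LIQUID", reversal_rate = 0, cw_bias = 0,
                          center_jitter_sigma = 0)
  tr <- simulate_motor_trace(p0, 1, seed = 1)
  expect_true(all(!tr$true_cw))
  r <- sqrt(tr$x_um^2 + tr$y_um^2)
  expect_equal(max(abs(r - 0.2)), 0, tolerance = 1e-9)  # jitter-free orbit radius
  sp <- rotation_speed(tr)
  expect_equal(mean(sp$freq_hz), -68, tolerance = 0.01 / 68)
  expect_error(make_motor_preset("LIQUID", cw_bias = 0),
               "inconsistent")
  expect_error(simulate_motor_trace(p0, 0), "duration")
})

test_that("decay generator is exact without noise and constant at rate zero", {
  pr <- make_decay_preset("LIQUID", lognormal_sigma = 0, decay_rate = 2.7e-3,
                          sample_times = seq(0, 120, 30))
  d <- simulate_decay(pr, 1, seed = 1)
  expect_equal(d$intensity, 1000 * exp(-2.7e-3 * d$t_min), tolerance = 1e-12)
  pr0 <- make_decay_preset("LIQUID", lognormal_sigma = 0, decay_rate = 0)
  d0 <- simulate_decay(pr0, 1, seed = 1)
  expect_true(all(d0$intensity == d0$intensity[1]))
  expect_error(make_decay_preset("LIQUID", sample_times = c(-5, 0, 10)),
               ">= 0")
})

test_that("fitted decay rates recover the generator rate within 10%", {
  pr <- make_decay_preset("LIQUID", lognormal_sigma = 0.1)
  rates <- vapply(1:20, function(s) {
    unname(decay_rate_set(simulate_decay(pr, 6, seed = s))$mean_rate)
  }, numeric(1))
  expect_equal(mean(rates), 2.7e-3, tolerance = 0.1)
})

test_that("fluorescence scenes honor their trivial contracts", {
  p0 <- make_fluor_preset("LIQUID", n_cells = 0, frame_size = 64L)
  sc0 <- render_fluor_scene(p0, seed = 1)
  expect_equal(nrow(sc0$truth), 0)
  expect_true(all(sc0$mask == 0))
  # noise-free, background-free scene: per-cell sums equal drawn expression
  p1 <- make_fluor_preset("LIQUID", n_cells = 5, frame_size = 128L,
                          background_level = 0, autofluorescence = 0,
                          shot_noise = FALSE)
  sc1 <- render_fluor_scene(p1, seed = 2)
  sums <- vapply(seq_len(5), function(i) sum(sc1$yfp[sc1$mask == i]), numeric(1))
  expect_equal(sums, sc1$truth$yfp_true, tolerance = 1e-9)
  # masks are non-overlapping by construction (labels partition pixels)
  expect_true(all(sc1$mask %in% 0:5))
})

test_that("rendered ground truth survives trajectory file round-trips", {
  p <- make_preset("LIQUID")
  pop <- simulate_population(p, 5, 6, 0.1, seed = 9)
  path <- tempfile(fileext = ".csv")
  write_trajectories(pop$samples, path)
  back <- read_trajectories(path)
  expect_equal(back$x_um, pop$samples$x_um, tolerance = 1e-12)
  expect_identical(back$true_state, pop$samples$true_state)
})
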