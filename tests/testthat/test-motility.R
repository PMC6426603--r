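test_that("diffusion coefficient is zero for a stationary cell", {
  tr <- data.frame(t_s = seq(0, 20, 0.1), x_um = 0, y_um = 0)
  expect_equal(diffusion_coefficient(tr), 0)
  expect_error(diffusion_coefficient(tr[1:20, ]), "5 s")
})

test_that("motile classification separates swimmers from Brownian cells", {
  expect_false(classify_motile(0.4))
  expect_true(classify_motile(10))    # boundary inclusive
  p <- make_preset("LIQUID", nonmotile_fraction = 0)
  tr <- simulate_trajectory(p, 100, 0.1, seed = 6)
  expect_gt(diffusion_coefficient(tr), 10)
})

test_that("a straight constant-speed track has zero tumble bias", {
  p <- make_preset("LIQUID", tumble_bias_true = 0, rotational_diffusion = 0,
                   localization_sigma = 0)
  tr <- simulate_trajectory(p, 20, 0.1, seed = 1)
  seg <- segment_tumbles(tr)
  expect_equal(tumble_bias(seg), 0)
  expect_equal(swim_speed(tr, seg), 21, tolerance = 1e-9)
})

test_that("tumble bias is the fraction of tumble-labeled frames", {
  seg <- structure(list(state = rep(c("TUMBLE", "RUN"), c(12, 88)),
                        run_durations = 8.8, tumble_count = 1, dt = 0.1),
                   class = "run_tumble_segmentation")
  expect_equal(tumble_bias(seg), 0.12)
  expect_error(tumble_bias(structure(list(state = character(0)),
                                     class = "run_tumble_segmentation")),
               "empty")
})

test_that("segmentation agrees with simulator ground truth on >90% of frames", {
  for (cond in c("LIQUID", "SWARM")) {
    p <- make_preset(cond, nonmotile_fraction = 0)
    agree <- vapply(1:10, function(s) {
      tr <- simulate_trajectory(p, 60, 0.1, seed = 100 + s)
      seg <- segment_tumbles(tr)
      mean((seg$state == "TUMBLE") == (tr$true_state == "TUMBLE"))
    }, numeric(1))
    expect_gt(min(agree), 0.9)
  }
})

test_that("tumble-bias estimator is calibrated across the preset sweep", {
  # scaled-down sweep: 80 cells x 60 s per bias level
  for (tb in c(0.02, 0.08, 0.2)) {
    p <- make_preset("LIQUID", tumble_bias_true = tb, nonmotile_fraction = 0)
    est <- vapply(1:80, function(s)
      tumble_bias(segment_tumbles(simulate_trajectory(p, 60, 0.1,
                                                      seed = s * 13))),
      numeric(1))
    expect_equal(stats::median(est), tb, tolerance = 0.012 / tb)
  }
})

test_that("raising the true bias never lowers the estimated median bias", {
  meds <- vapply(c(0.02, 0.08, 0.2), function(tb) {
    p <- make_preset("LIQUID", tumble_bias_true = tb, nonmotile_fraction = 0)
    stats::median(vapply(1:40, function(s)
      tumble_bias(segment_tumbles(simulate_trajectory(p, 60, 0.1,
                                                      seed = s * 17))),
      numeric(1)))
  }, numeric(1))
  expect_true(all(diff(meds) > 0))
})

test_that("speed and bias are negatively correlated across single cells", {
  p <- make_preset("LIQUID", nonmotile_fraction = 0)
  res <- t(vapply(1:60, function(s) {
    tr <- simulate_trajectory(p, 100, 0.1, seed = 300 + s)
    seg <- segment_tumbles(tr)
    # mean speed over all frames vs tumble bias: more tumbling, slower cell
    dt <- 0.1
    allsp <- mean(sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2) / dt)
    c(sp = allsp, tb = tumble_bias(seg))
  }, numeric(2)))
  expect_gt(stats::cor(res[, "sp"], 1 - res[, "tb"]), 0)
})

test_that("localization noise sets the speed floor of a stationary track", {
  sigma <- 0.05; dt <- 0.1; n <- 20000
  set.seed(8)
  x <- stats::rnorm(n, 0, sigma); y <- stats::rnorm(n, 0, sigma)
  sp <- mean(sqrt(diff(x)^2 + diff(y)^2)) / dt
  # |d| is Rayleigh with scale sigma*sqrt(2): mean = sigma*sqrt(pi)
  expect_equal(sp, sigma * sqrt(pi) / dt, tolerance = 0.02)
})

test_that("weighted mean and median follow their definitions", {
  expect_equal(weighted_median(c(0.1, 0.3), c(3, 1)) <
               weighted_median(c(0.1, 0.3), c(1, 3)), TRUE)
  # two cells, weights 3:1 -> weighted mean 0.15
  s <- data.frame(cell_id = 1:2, duration_s = c(3, 1),
                  diffusion_coefficient = 100, is_motile = TRUE,
                  tumble_bias = c(0.1, 0.3), mean_speed = c(20, 22),
                  weight = c(3, 1))
  ps <- population_summary(s)
  expect_equal(ps$tb_mean, 0.15)
  # single cell: the summary is that cell
  ps1 <- population_summary(s[1, ])
  expect_equal(ps1$tb_median, 0.1)
  expect_equal(ps1$speed_mean, 20)
})

test_that("weighted median matches frame-expanded brute force on integer weights", {
  set.seed(21)
  for (r in 1:20) {
    x <- stats::runif(7)
    w <- sample(1:5, 7, replace = TRUE)
    expanded <- rep(x, w)
    expect_equal(weighted_median(x, w), stats::median(expanded),
                 tolerance = 1e-12)
  }
  # unit weights reduce exactly to the plain median of an odd sample
  x <- c(3, 1, 4, 1, 5)
  expect_equal(weighted_median(x), stats::median(x))
})

test_that("weighted histograms conserve total weight and integrate to one", {
  p <- make_preset("LIQUID", nonmotile_fraction = 0)
  pop <- simulate_population(p, 25, 30, 0.1, seed = 41)
  sm <- summarize_motility(pop)
  h <- motility_histogram(sm, "tumble_bias")
  expect_equal(sum(h$weight), sum(sm$weight))
  expect_equal(sum(h$density * (h$bin_high - h$bin_low)), 1, tolerance = 1e-9)
})

test_that("population pipeline excludes non-motile cells from statistics", {
  p <- make_preset("LIQUID", nonmotile_fraction = 0.4)
  pop <- simulate_population(p, 40, 30, 0.1, seed = 31)
  sm <- summarize_motility(pop)
  expect_true(all(is.na(sm$tumble_bias[!sm$is_motile])))
  truth <- pop$cells$motile_true
  expect_equal(sm$is_motile, truth)   # perfect separation at D = 10
})
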