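test_that("background is the pixelwise mean and subtraction clips at zero", {
  f1 <- matrix(0, 8, 8); f2 <- matrix(2, 8, 8)
  st <- structure(list(frames = list(f1, f2), fps = 10, pixel_size = 0.65),
                  class = "frame_stack")
  bg <- compute_background(st)
  expect_true(all(bg == 1))
  sub <- subtract_background(st, bg)
  expect_true(all(sub$frames[[1]] == 0))   # clipped, not -1
  expect_true(all(sub$frames[[2]] == 1))
  # constant stack: background equals the constant, residual all zero
  stc <- structure(list(frames = list(f2, f2), fps = 10, pixel_size = 0.65),
                   class = "frame_stack")
  subc <- subtract_background(stc)
  expect_true(all(subc$frames[[1]] == 0))
  expect_error(compute_background(list(f1)), "at least 2")
})

test_that("a moving cell survives background subtraction intact", {
  p <- make_preset("LIQUID", nonmotile_fraction = 0)
  pop <- simulate_population(p, 3, 4, 0.1, seed = 2, field_size_um = 60)
  st <- render_frames(pop, frame_size = 256, snr = Inf, seed = 1,
                      background = 100)
  sub <- subtract_background(st)
  # background estimate close to the flat baseline away from trajectories
  bg <- compute_background(st)
  expect_equal(stats::median(bg), 100, tolerance = 0.02 / 100)
  # the cell peak remains high in the residual
  expect_gt(max(sub$frames[[1]]), 500)
})

test_that("radial-symmetry refinement recovers subpixel centers", {
  truth <- c(30.25, 41.75)
  img <- outer(0:63, 0:63, function(y, x)
    exp(-((x - truth[1])^2 + (y - truth[2])^2) / (2 * 1.2^2)))
  pk <- which(img == max(img), arr.ind = TRUE)
  h <- 3L
  ctr <- radial_symmetry_center(img[(pk[1] - h):(pk[1] + h),
                                    (pk[2] - h):(pk[2] + h)])
  est <- c(pk[2] - h - 1 + ctr[1], pk[1] - h - 1 + ctr[2])
  # brute-force centroid of the noiseless spot agrees with the truth
  w <- img / sum(img)
  centroid <- c(sum(outer(rep(1, 64), 0:63) * w), sum(outer(0:63, rep(1, 64)) * w))
  expect_equal(centroid, truth, tolerance = 1e-6)
  expect_lt(sqrt(sum((est - truth)^2)), 0.1)
})

test_that("flat frames yield no detections without error", {
  st <- structure(list(frames = list(matrix(5, 32, 32), matrix(5, 32, 32)),
                       fps = 10, pixel_size = 0.65), class = "frame_stack")
  det <- detect_cells(subtract_background(st))
  expect_equal(nrow(det), 0)
  expect_error(detect_cells(st, fdr = 1.2), "fdr")
})

test_that("detection recall and precision exceed 95% on a dense SNR-5 scene", {
  p <- make_preset("LIQUID", nonmotile_fraction = 0)
  pop <- simulate_population(p, 200, 0.2, dt = 0.1, seed = 7,
                             field_size_um = 900)
  st <- render_frames(pop, frame_size = 1536, snr = 5, seed = 7)
  # subtract the known flat baseline (the long-stack background estimate is
  # exercised separately)
  st$frames <- lapply(st$frames, function(f) pmax(f - 100, 0))
  det <- detect_cells(st, fdr = 0.05)
  sc <- detection_scores(det, st$truth)
  expect_gt(sc$recall, 0.95)
  expect_gt(sc$precision, 0.95)
})

test_that("empirical FDR on pure-noise stacks stays within 1.5x nominal", {
  fdp <- c()
  for (s in 1:25) {
    d <- detect_cells(subtract_background(noise_stack(6000 + s)), fdr = 0.05)
    fdp <- c(fdp, vapply(0:2, function(fr) as.numeric(sum(d$frame == fr) > 0),
                         numeric(1)))
  }
  expect_lte(mean(fdp), 1.5 * 0.05 + 1e-9)
})

test_that("bipartite matcher equals brute-force enumeration", {
  set.seed(11)
  for (r in 1:10) {
    n <- sample(2:5, 1)
    a <- matrix(stats::runif(n * n), n, n)
    p <- swarmotility:::hungarian_solve(a)
    expect_equal(sum(a[cbind(p, seq_len(n))]), brute_force_assignment_cost(a),
                 tolerance = 1e-12)
  }
  # rectangular with gating: the far detection stays unmatched
  cost <- matrix(c(0.1, Inf), 1, 2)
  m <- match_bipartite(cost, nomatch_cost = 5)
  expect_equal(m, 1L)
})

test_that("linking follows parallel tracks, closes gaps, ignores input order", {
  # two parallel non-crossing straight tracks
  det <- do.call(rbind, lapply(0:9, function(fr)
    data.frame(frame = fr, x_px = c(10 + 3 * fr, 10 + 3 * fr),
               y_px = c(10, 40), score = 1)))
  trk <- link_trajectories(det, fps = 10, pixel_size = 0.65)
  expect_equal(length(unique(trk$cell_id)), 2)
  ok <- vapply(split(trk, trk$cell_id),
               function(tt) stats::sd(tt$y_um) < 1e-9, logical(1))
  expect_true(all(ok))
  # permutation invariance to detection order within frames
  set.seed(4)
  det2 <- det[sample.int(nrow(det)), ]
  det2 <- det2[order(det2$frame), ]
  trk2 <- link_trajectories(det2, fps = 10, pixel_size = 0.65)
  expect_equal(length(unique(trk2$cell_id)), 2)
  for (tt in split(trk2, trk2$cell_id)) expect_lt(stats::sd(tt$y_um), 1e-9)
  # one-frame gap closing: a single missing frame leaves one track
  det3 <- data.frame(frame = c(0, 1, 3, 4), x_px = c(0, 3, 9, 12),
                     y_px = 5, score = 1)
  trk3 <- link_trajectories(det3, fps = 10, pixel_size = 0.65)
  expect_equal(length(unique(trk3$cell_id)), 1)
  expect_equal(sort(unique(trk3$frame)), 0:4)  # gap interpolated
})

test_that("detect+link on noiseless frames returns exactly k accurate tracks", {
  p <- make_preset("LIQUID", nonmotile_fraction = 0)
  pop <- simulate_population(p, 6, 3, 0.1, seed = 21, field_size_um = 100)
  st <- render_frames(pop, frame_size = 320, snr = Inf, seed = 3)
  det <- detect_cells(subtract_background(st), fdr = 0.05)
  trk <- link_trajectories(det, fps = st$fps, pixel_size = st$pixel_size)
  expect_equal(length(unique(trk$cell_id)), 6)
  errs <- unlist(lapply(split(trk, trk$cell_id), function(tt)
    vapply(seq_len(nrow(tt)), function(i) {
      g <- st$truth[st$truth$frame == tt$frame[i], ]
      min(sqrt((g$x_px * st$pixel_size - tt$x_um[i])^2 +
               (g$y_px * st$pixel_size - tt$y_um[i])^2)) / st$pixel_size
    }, numeric(1))))
  expect_lt(sqrt(mean(errs^2)), 0.2)   # px RMS
})

test_that("short trajectories are discarded at the duration threshold", {
  tr <- data.frame(
    cell_id = rep(1:3, times = c(31, 51, 801)),
    t_s = c(seq(0, 3, 0.1), seq(0, 5, 0.1), seq(0, 80, 0.1)))
  tr$frame <- ave(seq_len(nrow(tr)), tr$cell_id, FUN = seq_along)
  tr$x_um <- 0; tr$y_um <- 0
  out <- filter_short(tr, 5)
  expect_setequal(unique(out$cell_id), c(2, 3))   # 5 s boundary inclusive
  expect_equal(attr(out, "n_before"), 3)
  expect_equal(attr(out, "n_after"), 2)
  expect_identical(nrow(filter_short(tr, 0)), nrow(tr))
})
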