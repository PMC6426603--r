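#' Simulate one run-and-tumble trajectory
#'
#' Generates the planar path of a single motile cell in a pseudo-2D chamber.
#' The cell alternates runs and tumbles following a two-state Markov chain at
#' the frame resolution `dt` (geometric dwell times with the preset means, so
#' the stationary tumbling fraction equals `tumble_bias_true` exactly).
#' During runs the heading undergoes rotational diffusion and the speed
#' relaxes exponentially toward `run_speed` with time constant
#' `speed_recovery_tau` after each tumble; displacement over each frame
#' interval is the exact integral of the recovery curve. Tumbles are
#' stationary and the heading is redrawn uniformly on exit. Observed
#' positions carry isotropic Gaussian localization noise.
#'
#' @param preset a [make_preset()] object.
#' @param duration total duration, s.
#' @param dt frame interval, s (default 0.1, i.e. 10 fps). Must satisfy
#'   `dt <= mean_tumble_duration`.
#' @param seed integer seed; the trajectory is bit-reproducible for a fixed
#'   seed.
#' @param cell_id identifier stored in the output.
#' @param brownian if `TRUE`, simulate a non-motile cell instead: pure
#'   Brownian motion with diffusion coefficient `preset$brownian_D`.
#' @param origin length-2 numeric, starting position in um.
#' @return a data.frame with columns `cell_id`, `frame` (0-based), `t_s`,
#'   `x_um`, `y_um`, `true_state` (`"RUN"`, `"TUMBLE"` or `"BROWNIAN"`).
#'   Column `true_state` labels the state of the interval starting at each
#'   frame.
#' @examples
#' traj <- simulate_trajectory(make_preset("LIQUID"), duration = 20, seed = 1)
#' mean(traj$true_state == "TUMBLE")
#' @export
simulate_trajectory <- function(preset, duration, dt = 0.1, seed = 1L,
                                cell_id = 1L, brownian = FALSE,
                                origin = c(0, 0)) {
  if (dt <= 0 || duration < dt) stop("need duration >= dt > 0")
  n <- as.integer(floor(duration / dt))
  tt <- (0:(n - 1)) * dt
  set.seed(as.integer(seed))
  sig <- preset$localization_sigma

  if (brownian) {
    step_sd <- sqrt(2 * preset$brownian_D * dt)
    x <- cumsum(c(0, stats::rnorm(n - 1, 0, step_sd)))
    y <- cumsum(c(0, stats::rnorm(n - 1, 0, step_sd)))
    return(data.frame(
      cell_id = cell_id, frame = 0:(n - 1), t_s = tt,
      x_um = origin[1] + x + stats::rnorm(n, 0, sig),
      y_um = origin[2] + y + stats::rnorm(n, 0, sig),
      true_state = "BROWNIAN", stringsAsFactors = FALSE))
  }

  tb <- preset$tumble_bias_true
  mean_tum <- preset$mean_tumble_duration
  if (tb > 0 && dt > mean_tum + 1e-12)
    stop("dt must not exceed mean_tumble_duration")
  # geometric dwell lengths in frames; stationary tumble fraction == tb
  p_rt <- if (tb == 0) 0 else dt / mean_run_duration(preset)  # run -> tumble
  p_tr <- dt / mean_tum                                       # tumble -> run

  # build the state sequence segment by segment
  state <- integer(0)                     # 1 = RUN, 2 = TUMBLE
  cur <- if (stats::runif(1) < tb && tb > 0) 2L else 1L
  while (length(state) < n) {
    p_exit <- if (cur == 1L) p_rt else p_tr
    len <- if (p_exit <= 0) n else stats::rgeom(1, p_exit) + 1L
    state <- c(state, rep(cur, min(len, n - length(state))))
    cur <- 3L - cur
  }

  # headings: diffuse during runs, redraw uniformly on tumble exit
  v0 <- preset$run_speed
  tau <- preset$speed_recovery_tau
  dth <- stats::rnorm(n, 0, sqrt(2 * preset$rotational_diffusion * dt))
  new_heading <- stats::runif(n, 0, 2 * pi)

  run <- state == 1L
  # time since last tumble exit, in frames (cells start fully recovered)
  since <- integer(n)
  s <- 1000L                              # large: steady state at t = 0
  exit_prev <- c(FALSE, state[-n] == 2L & state[-1] == 1L)
  for (i in seq_len(n)) {
    if (exit_prev[i]) s <- 0L
    since[i] <- s
    if (run[i]) s <- s + 1L
  }

  theta <- numeric(n)
  th <- stats::runif(1, 0, 2 * pi)
  for (i in seq_len(n)) {
    if (exit_prev[i]) th <- new_heading[i]
    else if (i > 1L && run[i]) th <- th + dth[i]
    theta[i] <- th
  }

  # exact displacement magnitude over each run interval
  s1 <- since * dt
  s2 <- s1 + dt
  disp <- ifelse(run, v0 * ((s2 - s1) - tau * (exp(-s1 / tau) - exp(-s2 / tau))), 0)
  x <- cumsum(c(0, (disp * cos(theta))[-n]))
  y <- cumsum(c(0, (disp * sin(theta))[-n]))

  data.frame(
    cell_id = cell_id, frame = 0:(n - 1), t_s = tt,
    x_um = origin[1] + x + stats::rnorm(n, 0, sig),
    y_um = origin[2] + y + stats::rnorm(n, 0, sig),
    true_state = c("RUN", "TUMBLE")[state], stringsAsFactors = FALSE)
}

#' Simulate a mixed population of motile and non-motile cells
#'
#' Draws `n_cells` trajectories from a condition preset; a fraction
#' `preset$nonmotile_fraction` of cells is non-motile (Brownian). Per-cell
#' seeds are derived deterministically from the master seed, so the output is
#' reproducible and individual cells can be regenerated in isolation.
#'
#' @inheritParams simulate_trajectory
#' @param n_cells number of cells (>= 1).
#' @param field_size_um side of the square field over which starting
#'   positions are scattered uniformly (default 100; 0 starts every cell at
#'   the origin). Starting positions do not affect per-cell motility
#'   statistics but control cell density in rendered movies.
#' @return an object of class `trajectory_set`: a list with elements
#'   `samples` (row-bound per-frame data.frame as in [simulate_trajectory()]),
#'   `cells` (data.frame `cell_id`, `motile_true`, `seed`), `dt`, and
#'   `preset`.
#' @export
simulate_population <- function(preset, n_cells, duration, dt = 0.1, seed = 1L,
                                field_size_um = 100) {
  if (n_cells < 1) stop("n_cells must be >= 1")
  set.seed(as.integer(seed))
  cell_seeds <- sample.int(.Machine$integer.max - 1L, n_cells)
  motile <- stats::runif(n_cells) >= preset$nonmotile_fraction
  origins <- matrix(stats::runif(2 * n_cells, 0, field_size_um), ncol = 2)
  trajs <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    trajs[[i]] <- simulate_trajectory(preset, duration, dt,
                                      seed = cell_seeds[i], cell_id = i,
                                      brownian = !motile[i],
                                      origin = origins[i, ])
  }
  structure(list(
    samples = do.call(rbind, trajs),
    cells   = data.frame(cell_id = seq_len(n_cells), motile_true = motile,
                         seed = cell_seeds),
    dt      = dt,
    preset  = preset
  ), class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat("<trajectory_set>", nrow(x$cells), "cells,",
      nrow(x$samples), "samples, dt =", x$dt, "s\n")
  invisible(x)
}

#' Simulate a tethered-bead motor trace
#'
#' The motor state follows a continuous-time two-state telegraph process
#' whose switching rates are set by [motor_switching_rates()], so the
#' expected number of sign changes per minute equals `reversal_rate` and the
#' stationary CW time-fraction equals `cw_bias`. The bead center orbits the
#' rotation axis at `orbit_radius`, advancing at `+2*pi*cw_frequency` (CW,
#' decreasing image angle) or `-2*pi*ccw_frequency` per second, with Gaussian
#' center jitter on each coordinate.
#'
#' @param preset a [make_motor_preset()] object.
#' @param duration s.
#' @param seed integer seed.
#' @return an object of class `bead_trace`: data.frame `t_s`, `x_um`, `y_um`,
#'   `true_cw` (logical), with attributes `fps` and `true_reversals` (number
#'   of state switches in the sampled span).
#' @export
simulate_motor_trace <- function(preset, duration, seed = 1L) {
  if (duration <= 0) stop("duration must be > 0")
  fps <- preset$fps
  n <- as.integer(floor(duration * fps))
  set.seed(as.integer(seed))
  rates <- motor_switching_rates(preset)

  # continuous-time state path sampled at the frame times
  cw <- logical(n)
  if (preset$reversal_rate == 0) {
    state_cw <- preset$cw_bias >= 0.5
    cw[] <- state_cw
    n_switch <- 0L
  } else {
    t_cur <- 0
    state_cw <- stats::runif(1) < preset$cw_bias
    i <- 1L
    n_switch <- 0L
    t_end <- n / fps
    while (t_cur < t_end) {
      rate <- if (state_cw) rates[["cw_to_ccw"]] else rates[["ccw_to_cw"]]
      dwell <- stats::rexp(1, rate)
      j <- min(n, as.integer(ceiling((t_cur + dwell) * fps)))
      if (j >= i) cw[i:j] <- state_cw
      i <- j + 1L
      t_cur <- t_cur + dwell
      if (t_cur < t_end) n_switch <- n_switch + 1L
      state_cw <- !state_cw
    }
  }

  # math angle: CCW rotation increases it, CW decreases it
  omega <- ifelse(cw, -2 * pi * preset$cw_frequency, 2 * pi * preset$ccw_frequency)
  theta <- cumsum(omega / fps) - omega[1] / fps
  r <- preset$orbit_radius
  jit <- preset$center_jitter_sigma
  out <- data.frame(
    t_s  = (0:(n - 1)) / fps,
    x_um = r * cos(theta) + stats::rnorm(n, 0, jit),
    y_um = r * sin(theta) + stats::rnorm(n, 0, jit),
    true_cw = cw)
  structure(out, fps = fps, true_reversals = n_switch, class = c("bead_trace", "data.frame"))
}

#' Simulate chloramphenicol-chase decay courses
#'
#' Band intensity I(t) = I0 * exp(-k t) * eps, with eps lognormal(0, sigma^2)
#' independent across time points and replicates.
#'
#' @param preset a [make_decay_preset()] object.
#' @param n_replicates number of chase replicates.
#' @param seed integer seed.
#' @return data.frame `replicate`, `t_min`, `intensity`.
#' @export
simulate_decay <- function(preset, n_replicates = 6L, seed = 1L) {
  set.seed(as.integer(seed))
  tt <- preset$sample_times
  k <- preset$decay_rate
  out <- do.call(rbind, lapply(seq_len(n_replicates), function(r) {
    eps <- stats::rlnorm(length(tt), 0, preset$lognormal_sigma)
    data.frame(replicate = r, t_min = tt,
               intensity = preset$initial_intensity * exp(-k * tt) * eps)
  }))
  stopifnot(all(out$intensity > 0))
  out
}

#' Simulate paired Western-blot band intensities for two conditions
#'
#' Each replicate lane carries a target band and a loading-control band, both
#' with independent multiplicative lognormal noise. The swarm-condition
#' target is scaled by `ratio` relative to liquid; loading is condition
#' independent (equal loading by construction).
#'
#' @param ratio true swarm/liquid level ratio (default 1.5, the published
#'   CheZ elevation in swarmers).
#' @param n_replicates replicates per condition.
#' @param sigma lognormal noise SD per band.
#' @param target_base,loading_base noise-free band intensities, a.u.
#' @param seed integer seed.
#' @return data.frame `condition`, `replicate`, `target`, `loading`.
#' @export
simulate_blot <- function(ratio = 1.5, n_replicates = 6L, sigma = 0.1,
                          target_base = 500, loading_base = 800, seed = 1L) {
  set.seed(as.integer(seed))
  conds <- c("LIQUID", "SWARM")
  out <- do.call(rbind, lapply(conds, function(cc) {
    mult <- if (cc == "SWARM") ratio else 1
    data.frame(
      condition = cc, replicate = seq_len(n_replicates),
      target  = target_base * mult * stats::rlnorm(n_replicates, 0, sigma),
      loading = loading_base * stats::rlnorm(n_replicates, 0, sigma))
  }))
  out
}
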