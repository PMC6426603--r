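#' Signed rotation frequency of a tethered bead
#'
#' Recovers the motor rotation frequency from the bead-center coordinate
#' series: the orbit center is the coordinate-wise mean of the positions,
#' the bead angle is unwrapped atan2 about that center, and the frequency is
#' a Savitzky-Golay local-polynomial derivative of the angle. Sign
#' convention: CW rotation positive, CCW negative (so a wild-type motor
#' spends most of its time at negative frequency).
#'
#' @param trace a [simulate_motor_trace()] result, or any data.frame with
#'   `t_s`, `x_um`, `y_um` uniformly sampled (attribute `fps` or inferred).
#' @param smooth_window s; width of the local polynomial window (default
#'   0.008).
#' @return an object of class `speed_trace`: data.frame `t_s`, `freq_hz`
#'   with attribute `fps`.
#' @export
rotation_speed <- function(trace, smooth_window = 0.008) {
  fps <- attr(trace, "fps")
  if (is.null(fps)) fps <- 1 / stats::median(diff(trace$t_s))
  n <- nrow(trace)
  if (n / fps < 0.1) stop("need at least 0.1 s of samples")
  # mean, not median: over whole revolutions the mean is exactly the orbit
  # center, while a median is biased when the sampling strobes the phase
  cx <- mean(trace$x_um)
  cy <- mean(trace$y_um)
  rx <- trace$x_um - cx; ry <- trace$y_um - cy
  r <- sqrt(rx^2 + ry^2)
  if (stats::median(r) < 1e-6) stop("degenerate orbit: zero radius")
  theta <- atan2(ry, rx)
  theta <- cumsum(c(theta[1], wrap_pi(diff(theta))))  # unwrap
  k <- round(smooth_window * fps)
  if (k %% 2 == 0) k <- k + 1L
  k <- max(5L, min(k, n - (1 - n %% 2)))
  dtheta <- signal::sgolayfilt(theta, p = 2, n = k, m = 1)  # rad/sample
  freq <- -dtheta * fps / (2 * pi)   # CW positive
  structure(data.frame(t_s = trace$t_s, freq_hz = freq),
            fps = fps, class = c("speed_trace", "data.frame"))
}

#' Count motor reversals and the CW fraction
#'
#' A reversal is a zero crossing of the signed frequency whose new sign
#' persists for at least `debounce` seconds; shorter excursions are treated
#' as noise. The rate is normalized per minute.
#'
#' @param speed a [rotation_speed()] result.
#' @param debounce s (default 0.01).
#' @return list `reversals_per_min`, `n_reversals`, `cw_fraction`,
#'   `mean_abs_freq_hz`, `duration_s`.
#' @export
count_reversals <- function(speed, debounce = 0.01) {
  fps <- attr(speed, "fps")
  f <- speed$freq_hz
  s <- sign(f)
  # carry forward through exact zeros
  if (any(s == 0)) {
    nz <- s != 0
    if (!any(nz)) s[] <- 1 else {
      idx <- cummax(ifelse(nz, seq_along(s), 0L))
      s <- ifelse(idx > 0, s[pmax(idx, 1L)], s[which(nz)[1]])
    }
  }
  r <- rle(s)
  min_len <- max(1L, as.integer(round(debounce * fps)))
  keep <- r$lengths >= min_len
  vals <- r$values[keep]
  n_rev <- if (length(vals) > 1) sum(diff(vals) != 0) else 0L
  dur <- length(f) / fps
  list(reversals_per_min = n_rev / (dur / 60),
       n_reversals = n_rev,
       cw_fraction = mean(s > 0),
       mean_abs_freq_hz = mean(abs(f)),
       duration_s = dur)
}

#' Bead drag model for torque estimation
#'
#' Rotational drag of a sphere of radius `a` spinning about an axis offset by
#' the eccentricity `r_e`: xi = 8 pi eta a^3 + 6 pi eta a r_e^2 (spin drag
#' plus the translational drag of the eccentric orbit).
#'
#' @param viscosity Pa.s (default 9.6e-4, aqueous buffer at ~22 C).
#' @param bead_radius um (default 0.375, a 0.75-um-diameter polystyrene
#'   bead).
#' @param eccentricity um; offset of the bead center from the rotation axis
#'   (default 0.2). Not printed by torque-calibration protocols in general;
#'   treat as a configuration knob and report it with any torque value.
#' @return object of class `drag_model` with the drag coefficient `xi_si`
#'   in N.m.s.
#' @export
drag_model <- function(viscosity = 9.6e-4, bead_radius = 0.375,
                       eccentricity = 0.2) {
  if (viscosity <= 0 || bead_radius <= 0 || eccentricity < 0)
    stop("non-physical drag parameters")
  a <- bead_radius * 1e-6
  re <- eccentricity * 1e-6
  xi <- 8 * pi * viscosity * a^3 + 6 * pi * viscosity * a * re^2
  structure(list(viscosity = viscosity, bead_radius = bead_radius,
                 eccentricity = eccentricity, xi_si = xi),
            class = "drag_model")
}

#' Motor torque from the CCW rotation frequency
#'
#' At steady rotation the motor torque balances viscous drag:
#' tau = 2 pi f xi, reported in pN.nm. Linear in frequency, so condition
#' ratios depend only on the frequency ratio for a fixed drag model.
#'
#' @param ccw_frequency Hz (> 0; use the unsigned CCW speed).
#' @param drag a [drag_model()].
#' @return torque in pN.nm.
#' @examples
#' motor_torque(68, drag_model())
#' @export
motor_torque <- function(ccw_frequency, drag = drag_model()) {
  if (any(ccw_frequency < 0)) stop("frequency must be >= 0")
  2 * pi * ccw_frequency * drag$xi_si * 1e21   # N.m -> pN.nm
}

#' Ensemble motor statistics over simulated bead traces
#'
#' Convenience wrapper: simulates `n_traces` telegraph bead traces from a
#' motor preset, runs [rotation_speed()] and [count_reversals()] on each,
#' and returns per-trace and ensemble summaries.
#'
#' @param preset a [make_motor_preset()].
#' @param n_traces number of traces.
#' @param duration s per trace.
#' @param seed master seed; per-trace seeds are derived deterministically.
#' @return list with `per_trace` (data.frame) and ensemble means
#'   `mean_reversals_per_min`, `mean_abs_freq_hz`, `mean_cw_fraction`.
#' @export
motor_ensemble <- function(preset, n_traces = 200L, duration = 60, seed = 1L) {
  set.seed(as.integer(seed))
  seeds <- sample.int(.Machine$integer.max - 1L, n_traces)
  rows <- vector("list", n_traces)
  for (i in seq_len(n_traces)) {
    tr <- simulate_motor_trace(preset, duration, seed = seeds[i])
    cr <- count_reversals(rotation_speed(tr))
    rows[[i]] <- data.frame(trace = i,
                            reversals_per_min = cr$reversals_per_min,
                            mean_abs_freq_hz = cr$mean_abs_freq_hz,
                            cw_fraction = cr$cw_fraction,
                            true_reversals = attr(tr, "true_reversals"))
  }
  per <- do.call(rbind, rows)
  list(per_trace = per,
       mean_reversals_per_min = mean(per$reversals_per_min),
       mean_abs_freq_hz = mean(per$mean_abs_freq_hz),
       mean_cw_fraction = mean(per$cw_fraction))
}
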