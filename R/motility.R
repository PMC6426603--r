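#' Diffusion coefficient from the mean squared displacement
#'
#' Fits MSD(tau) = 4 D tau by ordinary least squares through the origin over
#' a fixed lag window (2D relation). Used to separate swimming cells from
#' cells driven only by Brownian motion.
#'
#' @param traj single-cell data.frame with columns `t_s`, `x_um`, `y_um`,
#'   uniformly sampled.
#' @param lag_window numeric length-2, lag range in seconds (default
#'   `c(2, 10)`).
#' @param n_lags number of lag values evaluated across the window.
#' @return diffusion coefficient, um^2/s.
#' @export
diffusion_coefficient <- function(traj, lag_window = c(2, 10), n_lags = 9L) {
  n <- nrow(traj)
  if (n < 2) stop("too few samples")
  dt <- stats::median(diff(traj$t_s))
  if ((n - 1) * dt < 5) stop("trajectory shorter than 5 s")
  lag_frames <- unique(pmax(1L, round(seq(lag_window[1], lag_window[2],
                                          length.out = n_lags) / dt)))
  lag_frames <- lag_frames[lag_frames < n]
  if (!length(lag_frames)) stop("too few samples for the requested lag window")
  msd <- vapply(lag_frames, function(L) {
    dx <- traj$x_um[(1 + L):n] - traj$x_um[1:(n - L)]
    dy <- traj$y_um[(1 + L):n] - traj$y_um[1:(n - L)]
    mean(dx^2 + dy^2)
  }, numeric(1))
  tau <- lag_frames * dt
  sum(msd * tau) / sum(tau^2) / 4
}

#' Classify a cell as motile from its diffusion coefficient
#'
#' Cells with D below the threshold are driven only by Brownian motion and
#' are excluded from swimming-speed and tumble-bias population statistics.
#' The boundary is inclusive: D equal to the threshold counts as motile.
#'
#' @param D diffusion coefficient(s), um^2/s.
#' @param threshold um^2/s, default 10.
#' @return logical, `TRUE` for motile.
#' @export
classify_motile <- function(D, threshold = 10) {
  D >= threshold
}

#' Run/tumble segmentation of a trajectory
#'
#' Labels each frame interval RUN or TUMBLE. A frame is a tumble candidate
#' when its instantaneous speed falls below `alpha` times the rolling median
#' speed (window `speed_window` seconds); optionally a turn-rate channel
#' flags frames whose heading change exceeds `omega_min` rad/s while the
#' speed is below the rolling median. Tumble segments separated by runs
#' shorter than `merge_gap` seconds can be merged (hysteresis). The defaults
#' (`alpha = 0.15`, turn channel and merging off) are calibrated against the
#' generator's ground-truth state labels; see the methods vignette for the
#' calibration argument.
#'
#' @param traj single-cell data.frame with `t_s`, `x_um`, `y_um`.
#' @param alpha speed threshold relative to the rolling median run speed.
#' @param omega_min rad/s; turn-rate threshold (default `Inf` disables the
#'   channel).
#' @param merge_gap s; run gaps shorter than this between tumbles are
#'   relabeled TUMBLE (default 0 disables merging).
#' @param speed_window s; rolling-median window.
#' @return an object of class `run_tumble_segmentation`: list with `state`
#'   (character per frame), `run_durations` (s), `tumble_count`, `dt`.
#' @export
segment_tumbles <- function(traj, alpha = 0.15, omega_min = Inf,
                            merge_gap = 0, speed_window = 2) {
  n <- nrow(traj)
  dt <- stats::median(diff(traj$t_s))
  if ((n - 1) * dt < 1) stop("need at least 1 s of samples")
  dx <- diff(traj$x_um); dy <- diff(traj$y_um)
  speed <- sqrt(dx^2 + dy^2) / dt            # speed of interval i -> i+1
  k <- max(3L, round(speed_window / dt))
  k <- min(k, length(speed))
  if (k %% 2 == 0) k <- k - 1L
  rollmed <- stats::runmed(speed, k, endrule = "median")
  # clustered tumbles depress the local median; floor the reference at a
  # global upper quantile so the threshold tracks the run speed
  rollmed <- pmax(rollmed, stats::quantile(speed, 0.7, names = FALSE))
  tumble <- speed < alpha * rollmed
  if (is.finite(omega_min)) {
    ang <- atan2(dy, dx)
    turn <- abs(wrap_pi(diff(ang))) / dt     # rad/s, at interior intervals
    turn <- c(turn[1], turn)
    tumble <- tumble | (turn > omega_min & speed < rollmed)
  }
  state <- c(ifelse(tumble, "TUMBLE", "RUN"))
  state <- c(state, state[n - 1])            # last frame inherits
  if (merge_gap > 0) {
    r <- rle(state)
    idx <- which(r$values == "RUN" & r$lengths * dt < merge_gap)
    idx <- idx[idx > 1 & idx < length(r$values)]
    if (length(idx)) {
      r$values[idx] <- "TUMBLE"
      state <- inverse.rle(r)
    }
  }
  r <- rle(state)
  structure(list(
    state = state,
    run_durations = r$lengths[r$values == "RUN"] * dt,
    tumble_count = sum(r$values == "TUMBLE"),
    dt = dt
  ), class = "run_tumble_segmentation")
}

wrap_pi <- function(a) ((a + pi) %% (2 * pi)) - pi

#' Tumble bias of a segmented trajectory
#'
#' Fraction of frames labeled TUMBLE.
#' @param seg a [segment_tumbles()] result.
#' @return fraction in \[0, 1\].
#' @export
tumble_bias <- function(seg) {
  if (!length(seg$state)) stop("empty segmentation")
  mean(seg$state == "TUMBLE")
}

#' Tumble-excluded swimming speed
#'
#' Mean frame-to-frame displacement per unit time over run frames, excluding
#' tumble frames and, by default, a post-tumble recovery window: cells need
#' about 0.5 s to regain full swimming speed after a tumble, so frames inside
#' that window under-report the run speed.
#'
#' @param traj single-cell data.frame with `t_s`, `x_um`, `y_um`.
#' @param seg matching [segment_tumbles()] result.
#' @param recovery_window s of run frames excluded after each tumble
#'   (default 0.5; set 0 for the plain run-frame mean).
#' @return um/s.
#' @export
swim_speed <- function(traj, seg, recovery_window = 0.5) {
  n <- nrow(traj)
  dt <- seg$dt
  dx <- diff(traj$x_um); dy <- diff(traj$y_um)
  speed <- sqrt(dx^2 + dy^2) / dt
  st <- seg$state[1:(n - 1)]
  keep <- st == "RUN"
  if (recovery_window > 0) {
    w <- as.integer(ceiling(recovery_window / dt))
    tum <- st == "TUMBLE"
    # frames within w frames after a tumble frame are excluded
    recent <- rep(FALSE, n - 1)
    last_tum <- -Inf
    for (i in seq_len(n - 1)) {
      if (tum[i]) last_tum <- i
      else if (i - last_tum <= w) recent[i] <- TRUE
    }
    keep <- keep & !recent
  }
  if (!any(keep)) stop("no run frames outside the recovery window")
  mean(speed[keep])
}

#' Per-cell motility summaries for a trajectory set
#'
#' Runs the single-cell estimators over every trajectory: diffusion
#' coefficient, motile classification, run/tumble segmentation, tumble bias
#' and tumble-excluded speed. Non-motile cells get `NA` tumble bias and
#' speed (their segmentation is not interpreted).
#'
#' @param samples per-frame data.frame (`cell_id`, `t_s`, `x_um`, `y_um`) or
#'   a `trajectory_set`.
#' @param threshold motile-classification threshold, um^2/s.
#' @param ... passed to [segment_tumbles()].
#' @return data.frame `cell_id`, `duration_s`, `diffusion_coefficient`,
#'   `is_motile`, `tumble_bias`, `mean_speed`, `weight` (trajectory duration,
#'   s).
#' @export
summarize_motility <- function(samples, threshold = 10, ...) {
  if (inherits(samples, "trajectory_set")) samples <- samples$samples
  out <- lapply(split(samples, samples$cell_id), function(tr) {
    tr <- tr[order(tr$t_s), ]
    dur <- tr$t_s[nrow(tr)] - tr$t_s[1]
    D <- diffusion_coefficient(tr)
    mot <- classify_motile(D, threshold)
    tb <- sp <- NA_real_
    if (mot) {
      seg <- segment_tumbles(tr, ...)
      tb <- tumble_bias(seg)
      sp <- tryCatch(swim_speed(tr, seg), error = function(e) NA_real_)
    }
    data.frame(cell_id = tr$cell_id[1], duration_s = dur,
               diffusion_coefficient = D, is_motile = mot,
               tumble_bias = tb, mean_speed = sp, weight = dur)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Weighted median
#'
#' The 50% point of the cumulative weight distribution: the smallest value
#' whose cumulative weight reaches half the total, averaging the two
#' bracketing values when the boundary falls exactly between them. With
#' integer weights this equals the plain median of the weight-expanded
#' sample, so duration weighting is exactly frame-level pooling.
#'
#' @param x values. @param w positive weights.
#' @return numeric scalar.
#' @export
weighted_median <- function(x, w = rep(1, length(x))) {
  ok <- !is.na(x) & !is.na(w)
  x <- x[ok]; w <- w[ok]
  if (!length(x)) stop("no non-missing values")
  if (any(w <= 0)) stop("weights must be > 0")
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w)
  half <- cw[length(cw)] / 2
  k <- which(cw >= half - 1e-12)[1]
  if (abs(cw[k] - half) < 1e-9 * cw[length(cw)] && k < length(x))
    (x[k] + x[k + 1]) / 2
  else x[k]
}

#' Duration-weighted histogram of a per-cell motility statistic
#'
#' Bin counts weighted by trajectory duration, for plotting population
#' distributions of tumble bias or speed; rows sum to the total weight.
#'
#' @param summaries output of [summarize_motility()].
#' @param variable `"tumble_bias"` or `"mean_speed"`.
#' @param breaks bin boundaries (default: 30 equal bins over the range).
#' @return data.frame `bin_low`, `bin_high`, `weight`, `density`.
#' @export
motility_histogram <- function(summaries, variable = c("tumble_bias",
                                                       "mean_speed"),
                               breaks = NULL) {
  variable <- match.arg(variable)
  mot <- summaries[summaries$is_motile & !is.na(summaries[[variable]]), ]
  if (!nrow(mot)) stop("no motile cells")
  x <- mot[[variable]]; w <- mot$weight
  if (is.null(breaks)) breaks <- seq(min(x), max(x), length.out = 31)
  idx <- cut(x, breaks, include.lowest = TRUE, labels = FALSE)
  wt <- vapply(seq_len(length(breaks) - 1),
               function(b) sum(w[idx == b]), numeric(1))
  widths <- diff(breaks)
  data.frame(bin_low = breaks[-length(breaks)], bin_high = breaks[-1],
             weight = wt, density = wt / (sum(wt) * widths))
}

#' Population summary of per-cell motility statistics
#'
#' Duration-weighted mean and median of tumble bias and speed over motile
#' cells, matching the convention that each trajectory is weighted by its
#' length so longer (better estimated) trajectories count more.
#'
#' @param summaries output of [summarize_motility()].
#' @return list with `n_cells`, `n_motile`, and weighted `tb_mean`,
#'   `tb_median`, `speed_mean`, `speed_median`.
#' @export
population_summary <- function(summaries) {
  mot <- summaries[summaries$is_motile & !is.na(summaries$tumble_bias), ]
  if (!nrow(mot)) stop("no motile cells")
  w <- mot$weight
  wm <- function(x) sum(w * x, na.rm = TRUE) / sum(w[!is.na(x)])
  list(
    n_cells = nrow(summaries), n_motile = nrow(mot),
    tb_mean = wm(mot$tumble_bias),
    tb_median = weighted_median(mot$tumble_bias, w),
    speed_mean = wm(mot$mean_speed),
    speed_median = weighted_median(mot$mean_speed, w)
  )
}
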