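#' Background image of a frame stack
#'
#' Pixelwise mean over all frames. Because swimming cells visit each pixel
#' only transiently, the temporal mean converges to the static background.
#'
#' @param stack a `frame_stack` (or plain list of matrices).
#' @return matrix, same shape as one frame.
#' @export
compute_background <- function(stack) {
  frames <- if (inherits(stack, "frame_stack")) stack$frames else stack
  if (length(frames) < 2) stop("need at least 2 frames")
  Reduce(`+`, frames) / length(frames)
}

#' Subtract the background, clipping at zero
#'
#' @param stack a `frame_stack`.
#' @param background matrix from [compute_background()] (computed if
#'   missing).
#' @return the stack with background-subtracted frames.
#' @export
subtract_background <- function(stack, background = NULL) {
  if (is.null(background)) background <- compute_background(stack)
  stack$frames <- lapply(stack$frames, function(f) pmax(f - background, 0))
  stack$background_subtracted <- TRUE
  stack
}

#' Subpixel center by radial symmetry
#'
#' Least-squares intersection of the gradient lines of an intensity patch:
#' for a radially symmetric spot every intensity gradient points through the
#' center, so the point minimizing the summed squared distance to the
#' gradient lines is the spot center. Gradients are taken on the 45-degree
#' midpoint lattice; each line is weighted by gradient magnitude squared
#' over distance to the patch centroid.
#'
#' @param patch intensity matrix (row = y).
#' @return c(x, y), 0-based pixel coordinates within the patch.
#' @export
radial_symmetry_center <- function(patch) {
  ny <- nrow(patch); nx <- ncol(patch)
  # midpoint-lattice derivatives along the two diagonals
  du <- patch[2:ny, 2:nx] - patch[1:(ny - 1), 1:(nx - 1)]
  dv <- patch[1:(ny - 1), 2:nx] - patch[2:ny, 1:(nx - 1)]
  # gradient in (x, y): u along (+x, +y)/sqrt2, v along (+x, -y)/sqrt2
  gx <- (du + dv) / sqrt(2)
  gy <- (du - dv) / sqrt(2)
  mg2 <- gx^2 + gy^2
  if (sum(mg2) <= 0) return(c((nx - 1) / 2, (ny - 1) / 2))
  xm <- outer(rep(1, ny - 1), 0:(nx - 2)) + 0.5
  ym <- outer(0:(ny - 2), rep(1, nx - 1)) + 0.5
  # weights: |grad|^2 / distance to magnitude-weighted centroid
  xc <- sum(xm * mg2) / sum(mg2); yc <- sum(ym * mg2) / sum(mg2)
  dc <- sqrt((xm - xc)^2 + (ym - yc)^2) + 0.5
  w <- mg2 / dc
  # line through (xm, ym) with direction (gx, gy): minimize sum w * d_perp^2
  m2 <- gy^2; mxy <- gx * gy; m1 <- gx^2
  A11 <- sum(w * m2);  A12 <- -sum(w * mxy)
  A22 <- sum(w * m1)
  b1 <- sum(w * (m2 * xm - mxy * ym))
  b2 <- sum(w * (m1 * ym - mxy * xm))
  det <- A11 * A22 - A12^2
  if (abs(det) < 1e-12) return(c(xc, yc))
  x <- (A22 * b1 - A12 * b2) / det
  y <- (A11 * b2 - A12 * b1) / det
  c(x, y)
}

#' Detect cell centers with FDR-controlled thresholding
#'
#' Frames are first matched-filtered with a Gaussian kernel of the spot
#' width, which maximizes peak signal-to-noise and removes the dependence of
#' the peak height on the subpixel spot position. Candidate spots are local
#' maxima (within a `2*halfwin+1` neighborhood) of the filtered frame that
#' rise at least 2 robust SDs above the frame median. The null distribution
#' of such maxima is calibrated per stack by Monte Carlo: synthetic noise
#' fields matching the robust background statistics of the residual frames
#' are pushed through the identical clip/filter/maxima pipeline and a Gumbel
#' law is fitted to the resulting maxima; each candidate's p-value is the
#' fitted upper tail at its peak value, and candidates are kept by
#' Benjamini-Hochberg per frame at the requested false-discovery rate. Kept
#' peaks are refined to subpixel precision by [radial_symmetry_center()].
#'
#' @param stack background-subtracted `frame_stack`.
#' @param fdr false-discovery rate in (0, 1), default 0.05.
#' @param halfwin neighborhood half-width for maxima and refinement, px.
#' @param smooth_sigma matched-filter width, px (default 1.2; 0 disables).
#' @param n_calibration noise fields simulated for the null fit.
#' @return data.frame `frame` (0-based), `x_px`, `y_px` (0-based subpixel),
#'   `score` (filtered peak intensity above the frame median).
#' @export
detect_cells <- function(stack, fdr = 0.05, halfwin = 3L, smooth_sigma = 1.2,
                         n_calibration = 3L) {
  if (fdr <= 0 || fdr >= 1) stop("fdr must be in (0, 1)")
  frames <- stack$frames
  if (!length(frames)) stop("empty stack")
  w <- 2L * halfwin + 1L
  # pre-filter noise scale of the residual frames (upper-quantile based:
  # immune to the zero-clipping of background subtraction)
  raw <- frames[[1]]
  med0 <- stats::median(raw)
  rsd0 <- (stats::quantile(raw, 0.975, names = FALSE) - med0) /
    stats::qnorm(0.975)
  gum <- NULL
  if (is.finite(rsd0) && rsd0 > 1e-9) {
    # Monte-Carlo null: same clipping, same filter, same maxima definition
    maxima <- unlist(lapply(seq_len(n_calibration), function(i) {
      sim <- matrix(stats::rnorm(length(raw), med0, rsd0),
                    nrow(raw), ncol(raw))
      sim <- pmax(sim, 0)
      if (smooth_sigma > 0) sim <- gauss_smooth(sim, smooth_sigma)
      dil <- row_running_max(col_running_max(sim, w), w)
      sim[sim == dil]
    }))
    beta <- stats::sd(maxima) * sqrt(6) / pi
    mu_g <- mean(maxima) - 0.5772156649 * beta
    gum <- list(mu = mu_g, beta = beta)
  }
  out <- vector("list", length(frames))
  for (fi in seq_along(frames)) {
    img <- frames[[fi]]
    if (smooth_sigma > 0) img <- gauss_smooth(img, smooth_sigma)
    det <- detect_frame(img, fdr, halfwin, gum)
    if (nrow(det)) det$frame <- fi - 1L
    out[[fi]] <- det
  }
  out <- do.call(rbind, out)
  if (is.null(out) || !nrow(out))
    return(data.frame(frame = integer(0), x_px = numeric(0),
                      y_px = numeric(0), score = numeric(0)))
  out[, c("frame", "x_px", "y_px", "score")]
}

detect_frame <- function(img, fdr, halfwin, gum = NULL) {
  empty <- data.frame(x_px = numeric(0), y_px = numeric(0),
                      score = numeric(0), frame = integer(0))
  med <- stats::median(img)
  rsd <- (stats::quantile(img, 0.975, names = FALSE) - med) /
    stats::qnorm(0.975)
  w <- 2L * halfwin + 1L
  dil <- row_running_max(col_running_max(img, w), w)
  cand <- which(img == dil & img > med + 2 * max(rsd, 1e-12), arr.ind = TRUE)
  if (!nrow(cand)) return(empty)
  v <- img[cand]
  o <- order(v, decreasing = TRUE)
  cand <- cand[o, , drop = FALSE]; v <- v[o]
  if (is.null(gum)) {
    # noise-free residual: every candidate is real structure
    sel <- seq_along(v)
  } else {
    p_cand <- 1 - exp(-exp(-(v - gum$mu) / gum$beta))
    sel <- bh_select(p_cand, fdr)
  }
  if (!length(sel)) return(empty)
  ny <- nrow(img); nx <- ncol(img)
  res <- lapply(sel, function(i) {
    r <- cand[i, 1]; cc <- cand[i, 2]
    y0 <- max(1L, r - halfwin); y1 <- min(ny, r + halfwin)
    x0 <- max(1L, cc - halfwin); x1 <- min(nx, cc + halfwin)
    ctr <- radial_symmetry_center(img[y0:y1, x0:x1])
    data.frame(x_px = x0 - 1 + ctr[1], y_px = y0 - 1 + ctr[2],
               score = v[i] - med, frame = NA_integer_)
  })
  do.call(rbind, res)
}

# Benjamini-Hochberg selection: indices of hypotheses rejected at level q
bh_select <- function(p, q) {
  m <- length(p)
  o <- order(p)
  th <- q * seq_len(m) / m
  k <- max(c(0L, which(p[o] <= th)))
  if (k == 0L) integer(0) else o[seq_len(k)]
}

col_running_max <- function(m, w) {
  h <- (w - 1L) %/% 2L
  n <- nrow(m)
  out <- m
  for (d in seq_len(h)) {
    up <- m[c((1 + d):n, rep(n, d)), , drop = FALSE]
    dn <- m[c(rep(1, d), 1:(n - d)), , drop = FALSE]
    out <- pmax(out, up, dn)
  }
  out
}

row_running_max <- function(m, w) t(col_running_max(t(m), w))

# separable Gaussian smoothing with reflected edges
gauss_smooth <- function(img, sigma) {
  h <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-h:h, 0, sigma)
  k <- k / sum(k)
  smooth_cols <- function(m) {
    n <- nrow(m)
    pad <- rbind(m[h:1, , drop = FALSE], m, m[n:(n - h + 1), , drop = FALSE])
    out <- stats::filter(pad, k, sides = 2)
    out[(h + 1):(h + n), , drop = FALSE]
  }
  t(smooth_cols(t(smooth_cols(img))))
}

#' Link detections into trajectories
#'
#' Frame-to-frame bipartite minimum-cost matching. The cost of pairing a
#' track with a detection blends the two motion hypotheses the linker
#' supports: distance to the constant-velocity prediction and distance to
#' the current position (random reorientation); the cheaper hypothesis is
#' used. Pairings beyond the gating radius (maximum expected displacement
#' plus localization slack) are infeasible; tracks missing one frame remain
#' eligible with a widened gate (one-frame gap closing, the gap position
#' interpolated), and unmatched detections start new tracks. The assignment
#' is solved exactly (Jonker-Volgenant), so linking is invariant to the
#' order of detections within a frame.
#'
#' @param detections data.frame from [detect_cells()].
#' @param fps frames/s.
#' @param pixel_size um/px.
#' @param expected_speed_range um/s, default `c(20, 30)`; the upper end sets
#'   the gate.
#' @param max_gap frames a track may coast unmatched (default 1).
#' @param gate_slack_px additive slack on the gate, px.
#' @return data.frame `cell_id`, `frame`, `t_s`, `x_um`, `y_um`.
#' @export
link_trajectories <- function(detections, fps, pixel_size,
                              expected_speed_range = c(20, 30),
                              max_gap = 1L, gate_slack_px = 3) {
  if (!nrow(detections))
    return(data.frame(cell_id = integer(0), frame = integer(0),
                      t_s = numeric(0), x_um = numeric(0), y_um = numeric(0)))
  detections <- detections[order(detections$frame), ]
  gate1 <- max(expected_speed_range) / fps / pixel_size + gate_slack_px
  frames <- min(detections$frame):max(detections$frame)
  # active track state
  tracks <- list()   # each: id, x, y, vx, vy, age (frames since last seen)
  next_id <- 1L
  rows <- list()
  add_row <- function(id, fr, x, y)
    rows[[length(rows) + 1L]] <<- data.frame(cell_id = id, frame = fr,
                                             x_px = x, y_px = y)
  for (fr in frames) {
    d <- detections[detections$frame == fr, , drop = FALSE]
    nd <- nrow(d)
    nt <- length(tracks)
    assigned_d <- rep(FALSE, nd)
    if (nt && nd) {
      cost <- matrix(Inf, nt, nd)
      for (i in seq_len(nt)) {
        tr <- tracks[[i]]
        steps <- tr$age + 1L
        gate <- gate1 * steps
        px <- tr$x + tr$vx * steps; py <- tr$y + tr$vy * steps
        d_pred <- sqrt((d$x_px - px)^2 + (d$y_px - py)^2)
        d_cur <- sqrt((d$x_px - tr$x)^2 + (d$y_px - tr$y)^2)
        cc <- pmin(d_pred, d_cur)
        cc[d_cur > gate] <- Inf
        cost[i, ] <- cc
      }
      m <- match_bipartite(cost, nomatch_cost = gate1)
      for (i in seq_len(nt)) {
        j <- m[i]
        if (is.na(j)) next
        tr <- tracks[[i]]
        steps <- tr$age + 1L
        if (tr$age > 0) {   # interpolate the gap frames
          for (g in seq_len(tr$age)) {
            add_row(tr$id, tr$frame + g,
                    tr$x + (d$x_px[j] - tr$x) * g / steps,
                    tr$y + (d$y_px[j] - tr$y) * g / steps)
          }
        }
        tracks[[i]] <- list(id = tr$id, x = d$x_px[j], y = d$y_px[j],
                            vx = (d$x_px[j] - tr$x) / steps,
                            vy = (d$y_px[j] - tr$y) / steps,
                            age = 0L, frame = fr)
        add_row(tr$id, fr, d$x_px[j], d$y_px[j])
        assigned_d[j] <- TRUE
      }
      matched_t <- !is.na(m)
    } else matched_t <- rep(FALSE, nt)
    # age or retire unmatched tracks
    if (nt) {
      keep <- rep(TRUE, nt)
      for (i in seq_len(nt)) {
        if (matched_t[i]) next
        tracks[[i]]$age <- tracks[[i]]$age + 1L
        if (tracks[[i]]$age > max_gap) keep[i] <- FALSE
      }
      tracks <- tracks[keep]
    }
    # births
    for (j in which(!assigned_d)) {
      tracks[[length(tracks) + 1L]] <- list(id = next_id, x = d$x_px[j],
                                            y = d$y_px[j], vx = 0, vy = 0,
                                            age = 0L, frame = fr)
      add_row(next_id, fr, d$x_px[j], d$y_px[j])
      next_id <- next_id + 1L
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$cell_id, out$frame), ]
  data.frame(cell_id = out$cell_id, frame = out$frame,
             t_s = out$frame / fps,
             x_um = out$x_px * pixel_size, y_um = out$y_px * pixel_size)
}

#' Exact bipartite minimum-cost matching with unmatched option
#'
#' Solves the rectangular assignment problem by the Jonker-Volgenant
#' shortest-augmenting-path algorithm on a square matrix padded with
#' per-item no-match costs, so any row or column may remain unmatched at
#' cost `nomatch_cost`. Infeasible pairings are `Inf`.
#'
#' @param cost numeric matrix (rows = tracks, cols = detections).
#' @param nomatch_cost cost of leaving an item unmatched.
#' @return integer vector over rows: matched column index or `NA`.
#' @export
match_bipartite <- function(cost, nomatch_cost) {
  nr <- nrow(cost); nc <- ncol(cost)
  n <- nr + nc
  BIG <- nomatch_cost * (n + 2) + sum(cost[is.finite(cost)]) + 1
  a <- matrix(BIG, n, n)
  a[seq_len(nr), seq_len(nc)] <- pmin(cost, BIG)
  # no-match blocks on the diagonals
  a[cbind(seq_len(nr), nc + seq_len(nr))] <- nomatch_cost
  a[cbind(nr + seq_len(nc), seq_len(nc))] <- nomatch_cost
  a[nr + seq_len(nc), nc + seq_len(nr)] <- 0
  p <- hungarian_solve(a)   # p[j] = row assigned to column j
  res <- rep(NA_integer_, nr)
  for (j in seq_len(nc)) {
    i <- p[j]
    if (!is.na(i) && i <= nr && is.finite(cost[i, j])) res[i] <- j
  }
  res
}

# Jonker-Volgenant / Hungarian, square matrix, O(n^3). Returns p with
# p[j] = row matched to column j.
hungarian_solve <- function(a) {
  n <- nrow(a)
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1)   # p[j+1] = row matched to column j (1-based shift)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(INF, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- INF
      j1 <- 0L
      for (j in seq_len(n)) {
        if (used[j + 1]) next
        cur <- a[i0, j] - u[i0 + 1] - v[j + 1]
        if (cur < minv[j + 1]) { minv[j + 1] <- cur; way[j + 1] <- j0 }
        if (minv[j + 1] < delta) { delta <- minv[j + 1]; j1 <- j }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else minv[j + 1] <- minv[j + 1] - delta
      }
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  out <- rep(NA_integer_, n)
  for (j in seq_len(n)) if (p[j + 1] > 0) out[j] <- p[j + 1]
  out
}

#' Drop trajectories shorter than a minimum duration
#'
#' @param trajectories data.frame with `cell_id` and `t_s`.
#' @param min_duration s (default 5).
#' @return the filtered data.frame, with attributes `n_before`/`n_after`.
#' @export
filter_short <- function(trajectories, min_duration = 5) {
  if (min_duration < 0) stop("min_duration must be >= 0")
  dur <- tapply(trajectories$t_s, trajectories$cell_id,
                function(t) max(t) - min(t))
  keep_ids <- names(dur)[dur >= min_duration]
  out <- trajectories[as.character(trajectories$cell_id) %in% keep_ids, ]
  attr(out, "n_before") <- length(dur)
  attr(out, "n_after") <- length(keep_ids)
  out
}
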