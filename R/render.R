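#' Render a trajectory set as a phase-contrast-like frame stack
#'
#' Draws each cell as a Gaussian intensity spot over a uniform background
#' with additive Gaussian pixel noise, emulating low-magnification
#' phase-contrast movies. Ground-truth subpixel centers are retained as
#' metadata for detector/linker validation.
#'
#' @param set a [simulate_population()] result (positions in um).
#' @param pixel_size um/px (default 0.65, 10x-equivalent sampling).
#' @param psf_sigma spot width, px (default 1.2).
#' @param snr peak spot amplitude over the pixel-noise SD; `Inf` renders
#'   noise-free frames.
#' @param frame_size px (square frames); positions are shifted so the
#'   bounding box is centered, and an error lists offending cells if the
#'   field cannot contain them.
#' @param background mean background level, a.u.
#' @param noise_sd pixel noise SD, a.u.
#' @param seed integer seed for the pixel noise.
#' @return object of class `frame_stack`: list with `frames` (list of
#'   matrices, row = y), `fps`, `pixel_size`, and `truth` (data.frame
#'   `cell_id`, `frame`, `x_px`, `y_px`, 0-based pixel coordinates).
#' @export
render_frames <- function(set, pixel_size = 0.65, psf_sigma = 1.2, snr = 10,
                          frame_size = 256L, background = 100, noise_sd = 10,
                          seed = 1L) {
  stopifnot(inherits(set, "trajectory_set"))
  s <- set$samples
  margin <- 4 * psf_sigma + 1
  xpx <- s$x_um / pixel_size
  ypx <- s$y_um / pixel_size
  xpx <- xpx - min(xpx) + margin + (frame_size - diff(range(xpx)) - 2 * margin) / 2
  ypx <- ypx - min(ypx) + margin + (frame_size - diff(range(ypx)) - 2 * margin) / 2
  out_of <- xpx < margin | xpx > frame_size - 1 - margin |
            ypx < margin | ypx > frame_size - 1 - margin
  if (any(out_of))
    stop("cells out of frame: ",
         paste(sort(unique(s$cell_id[out_of])), collapse = ", "),
         " (increase frame_size)")
  amp <- if (is.finite(snr)) snr * noise_sd else 1000
  frames_idx <- sort(unique(s$frame))
  set.seed(as.integer(seed))
  frames <- lapply(frames_idx, function(fr) {
    img <- matrix(background, frame_size, frame_size)
    if (is.finite(snr)) img <- img + matrix(stats::rnorm(frame_size^2, 0, noise_sd),
                                            frame_size, frame_size)
    sel <- which(s$frame == fr)
    for (j in sel) {
      cx <- xpx[j]; cy <- ypx[j]
      x0 <- max(0L, floor(cx - 4 * psf_sigma)); x1 <- min(frame_size - 1L, ceiling(cx + 4 * psf_sigma))
      y0 <- max(0L, floor(cy - 4 * psf_sigma)); y1 <- min(frame_size - 1L, ceiling(cy + 4 * psf_sigma))
      gx <- exp(-((x0:x1) - cx)^2 / (2 * psf_sigma^2))
      gy <- exp(-((y0:y1) - cy)^2 / (2 * psf_sigma^2))
      img[(y0:y1) + 1L, (x0:x1) + 1L] <-
        img[(y0:y1) + 1L, (x0:x1) + 1L] + amp * outer(gy, gx)
    }
    img
  })
  truth <- data.frame(cell_id = s$cell_id, frame = s$frame,
                      x_px = xpx, y_px = ypx)
  structure(list(frames = frames, fps = 1 / set$dt, pixel_size = pixel_size,
                 truth = truth),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  cat("<frame_stack>", length(x$frames), "frames of",
      paste(dim(x$frames[[1]]), collapse = "x"), "px, fps", x$fps, "\n")
  invisible(x)
}

#' Render a two-channel fluorescence scene
#'
#' Places non-overlapping elliptical cells at random positions and
#' orientations; each cell's total fluorescence per channel is drawn
#' lognormal around the channel mean with coefficient of variation
#' `expression_cv`, spread uniformly over the cell pixels; cellular
#' autofluorescence is added inside cells, a uniform background everywhere,
#' and optional Poisson shot noise on each pixel.
#'
#' @param preset a [make_fluor_preset()].
#' @param seed integer seed.
#' @return list with `yfp`, `cherry` (matrices), `mask` (integer label
#'   matrix, 0 = background), and `truth` (data.frame `cell_id`, `area_px`,
#'   `yfp_true`, `cherry_true`).
#' @export
render_fluor_scene <- function(preset, seed = 1L) {
  set.seed(as.integer(seed))
  n <- preset$n_cells
  sz <- preset$frame_size
  mask <- matrix(0L, sz, sz)
  truth <- data.frame(cell_id = integer(0), area_px = numeric(0),
                      yfp_true = numeric(0), cherry_true = numeric(0))
  if (n > 0) {
    cv <- preset$expression_cv
    sdlog <- sqrt(log(1 + cv^2))
    placed <- 0L
    attempts <- 0L
    max_attempts <- 200L * n
    xs <- ys <- ar <- numeric(n)
    while (placed < n) {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        stop("could not place ", n, " non-overlapping cells after ",
             max_attempts, " attempts; reduce n_cells or mean_area")
      area <- max(20, stats::rnorm(1, preset$mean_area, preset$area_sd))
      # 1:3 aspect rod-like ellipse
      b <- sqrt(area / (3 * pi)); a <- 3 * b
      cx <- stats::runif(1, a + 2, sz - a - 2)
      cy <- stats::runif(1, a + 2, sz - a - 2)
      phi <- stats::runif(1, 0, pi)
      xr <- max(1L, floor(cx - a - 1)):min(sz, ceiling(cx + a + 1))
      yr <- max(1L, floor(cy - a - 1)):min(sz, ceiling(cy + a + 1))
      gx <- outer(rep(1, length(yr)), xr - cx)
      gy <- outer(yr - cy, rep(1, length(xr)))
      u <- gx * cos(phi) + gy * sin(phi)
      v <- -gx * sin(phi) + gy * cos(phi)
      inside <- (u / a)^2 + (v / b)^2 <= 1
      if (any(mask[yr, xr][inside] != 0)) next
      placed <- placed + 1L
      sub <- mask[yr, xr]; sub[inside] <- placed; mask[yr, xr] <- sub
      xs[placed] <- cx; ys[placed] <- cy; ar[placed] <- sum(inside)
    }
    truth <- data.frame(
      cell_id = seq_len(n), area_px = ar,
      yfp_true = preset$yfp_mean * stats::rlnorm(n, -sdlog^2 / 2, sdlog),
      cherry_true = preset$cherry_mean * stats::rlnorm(n, -sdlog^2 / 2, sdlog))
  }
  draw <- function(totals) {
    img <- matrix(preset$background_level, sz, sz)
    for (i in seq_len(nrow(truth))) {
      px <- mask == i
      img[px] <- img[px] + (totals[i] + preset$autofluorescence) / truth$area_px[i]
    }
    if (isTRUE(preset$shot_noise)) {
      img <- matrix(stats::rpois(sz * sz, pmax(img, 0)), sz, sz)
    }
    img
  }
  list(yfp = draw(truth$yfp_true), cherry = draw(truth$cherry_true),
       mask = mask, truth = truth)
}
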