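# shared fixture builders (all generated in code; nothing on disk)

noise_stack <- function(seed, n_frames = 3, size = 96, mean = 100, sd = 10) {
  set.seed(seed)
  structure(list(
    frames = lapply(seq_len(n_frames),
                    function(i) matrix(stats::rnorm(size^2, mean, sd), size, size)),
    fps = 10, pixel_size = 0.65),
    class = "frame_stack")
}

# recall/precision of detections against rendered ground truth
detection_scores <- function(det, truth, tol_px = 2) {
  hits <- 0; fp <- 0
  for (fr in unique(truth$frame)) {
    d <- det[det$frame == fr, , drop = FALSE]
    g <- truth[truth$frame == fr, , drop = FALSE]
    if (!nrow(d)) next
    dd <- sqrt(outer(d$x_px, g$x_px, "-")^2 + outer(d$y_px, g$y_px, "-")^2)
    hits <- hits + sum(apply(dd, 2, min) < tol_px)
    fp <- fp + sum(apply(dd, 1, min) >= tol_px)
  }
  list(recall = hits / nrow(truth), precision = 1 - fp / max(nrow(det), 1))
}

# fraction of consecutive linked pairs that join the same ground-truth cell
linking_identity <- function(tracks, truth, pixel_size, tol_um = 1) {
  correct <- 0; total <- 0
  for (id in unique(tracks$cell_id)) {
    tt <- tracks[tracks$cell_id == id, ]
    tid <- vapply(seq_len(nrow(tt)), function(i) {
      g <- truth[truth$frame == tt$frame[i], ]
      dd <- sqrt((g$x_px * pixel_size - tt$x_um[i])^2 +
                 (g$y_px * pixel_size - tt$y_um[i])^2)
      if (min(dd) < tol_um) g$cell_id[which.min(dd)] else NA_integer_
    }, integer(1))
    ok <- !is.na(tid)
    if (nrow(tt) < 2) next
    pair_ok <- ok[-1] & ok[-length(ok)]
    total <- total + sum(pair_ok)
    correct <- correct + sum(tid[-1] == tid[-length(tid)] & pair_ok, na.rm = TRUE)
  }
  correct / total
}

# brute-force minimal assignment cost by permutation enumeration
brute_force_assignment_cost <- function(a) {
  n <- nrow(a)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(r) c(v[i], r))))
  }
  min(vapply(perms(seq_len(n)),
             function(p) sum(a[cbind(seq_len(n), p)]), numeric(1)))
}
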