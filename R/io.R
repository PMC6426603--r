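#' Write and read trajectory tables
#'
#' CSV interchange with the schema `cell_id, frame, t_s, x_um, y_um`
#' (optional `true_state` and any extra columns, which round-trip
#' unchanged).
#'
#' @param trajectories per-frame data.frame (a `trajectory_set$samples` or
#'   linker output).
#' @param path file path.
#' @return `write_trajectories` returns the path invisibly;
#'   `read_trajectories` returns the data.frame.
#' @export
write_trajectories <- function(trajectories, path) {
  check_traj_schema(trajectories)
  utils::write.csv(trajectories, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_traj_schema(out)
  bad <- vapply(split(out$t_s, out$cell_id),
                function(t) is.unsorted(t, strictly = TRUE), logical(1))
  if (any(bad))
    stop("times not strictly increasing for cell(s): ",
         paste(names(bad)[bad], collapse = ", "))
  out
}

check_traj_schema <- function(df) {
  req <- c("cell_id", "frame", "t_s", "x_um", "y_um")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("trajectory table missing column(s): ", paste(miss, collapse = ", "))
  invisible(df)
}

#' Write and read a frame stack as a multi-page 16-bit TIFF
#'
#' Intensities are scaled by `scale` into the 16-bit range on write and
#' unscaled on read, so round-trips preserve values to 1/`scale`.
#'
#' @param stack a `frame_stack`.
#' @param path file path.
#' @param scale a.u. per 16-bit unit step.
#' @return `write_frame_stack` returns the path invisibly;
#'   `read_frame_stack` a `frame_stack` (without ground-truth metadata).
#' @export
write_frame_stack <- function(stack, path, scale = 1) {
  imgs <- lapply(stack$frames, function(f) {
    m <- pmin(pmax(f / scale, 0), 65535) / 65535
    m
  })
  tiff::writeTIFF(imgs, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_frame_stack
#' @param fps,pixel_size metadata to attach on read.
#' @export
read_frame_stack <- function(path, fps = 10, pixel_size = 0.65, scale = 1) {
  imgs <- tiff::readTIFF(path, all = TRUE)
  structure(list(frames = lapply(imgs, function(m) m * 65535 * scale),
                 fps = fps, pixel_size = pixel_size),
            class = "frame_stack")
}

#' Write and read preset objects as JSON
#'
#' Any of the package's preset objects (motility, motor, decay, fluorescence
#' scene) round-trips through JSON with its class recorded, so a run can be
#' reproduced from its serialized configuration.
#'
#' @param preset a preset object.
#' @param path file path.
#' @return `write_preset` the path, invisibly; `read_preset` the restored
#'   preset.
#' @export
write_preset <- function(preset, path) {
  payload <- c(list(.class = class(preset)[1]), unclass(preset))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_preset
#' @export
read_preset <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- payload$.class
  payload$.class <- NULL
  structure(payload, class = cls)
}

#' Run the full two-condition motility pipeline
#'
#' Simulates liquid- and swarm-preset populations, runs motile
#' classification, run/tumble segmentation and the population summaries,
#' and compares conditions with the trajectory-weighted permutation ANOVA.
#' Optional branches exercise the motor, blot and signaling analyses.
#' The report echoes every parameter, the seed, and counts at each stage;
#' the same config and seed reproduce it exactly.
#'
#' @param config list (or path to a JSON file) with optional elements
#'   `seed`, `n_cells`, `duration_s`, `dt_s`, `min_duration_s`,
#'   `conditions` (character), `n_perm`, `with_motor`, `motor_traces`,
#'   `motor_duration_s`, `with_blot`, `with_signaling`.
#' @param out_json optional path; the report is written there as JSON.
#' @return the report, a nested list.
#' @export
run_pipeline <- function(config = list(), out_json = NULL) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  cfg <- utils::modifyList(list(
    seed = 1L, n_cells = 100L, duration_s = 50, dt_s = 0.1,
    min_duration_s = 5, conditions = c("LIQUID", "SWARM"), n_perm = 1000L,
    with_motor = FALSE, motor_traces = 20L, motor_duration_s = 60,
    with_blot = FALSE, with_signaling = FALSE), config)
  conds <- cfg$conditions
  summaries <- list()
  cond_reports <- list()
  for (i in seq_along(conds)) {
    cc <- conds[i]
    pop <- simulate_population(make_preset(cc), cfg$n_cells, cfg$duration_s,
                               cfg$dt_s, seed = cfg$seed + i)
    samp <- filter_short(pop$samples, cfg$min_duration_s)
    sm <- summarize_motility(samp)
    sm$condition <- cc
    summaries[[cc]] <- sm
    ps <- population_summary(sm)
    cond_reports[[cc]] <- c(list(condition = cc,
                                 n_simulated = cfg$n_cells,
                                 n_after_duration_filter = attr(samp, "n_after")),
                            ps)
  }
  all_sm <- do.call(rbind, summaries)
  mot <- all_sm[all_sm$is_motile & !is.na(all_sm$tumble_bias), ]
  stats_rep <- NULL
  if (length(conds) >= 2 && nrow(mot) > length(conds)) {
    pr <- permutation_pvalue(mot$tumble_bias, mot$condition, mot$weight,
                             n_perm = cfg$n_perm, seed = cfg$seed)
    stats_rep <- list(F_observed = pr$F_observed, p_value = pr$p_value,
                      df1 = pr$df1, df2 = pr$df2, n = pr$n, K = pr$K,
                      n_perm = pr$n_perm)
  }
  report <- list(
    schema_version = "1.0",
    config = cfg,
    conditions = cond_reports,
    tumble_bias_anova = stats_rep)
  if (isTRUE(cfg$with_motor)) {
    report$motor <- lapply(intersect(conds, c("LIQUID", "SWARM")), function(cc) {
      e <- motor_ensemble(make_motor_preset(cc), cfg$motor_traces,
                          cfg$motor_duration_s, seed = cfg$seed)
      list(condition = cc,
           mean_reversals_per_min = e$mean_reversals_per_min,
           mean_abs_freq_hz = e$mean_abs_freq_hz,
           mean_cw_fraction = e$mean_cw_fraction)
    })
  }
  if (isTRUE(cfg$with_blot)) {
    blot <- normalize_bands(simulate_blot(seed = cfg$seed), reference = "LIQUID")
    fc <- fold_change(blot)
    rates <- lapply(c("LIQUID", "SWARM"), function(cc) {
      d <- simulate_decay(make_decay_preset(cc), 6L, seed = cfg$seed)
      unname(decay_rate_set(d)$mean_rate)
    })
    report$blot <- list(chez_fold = fc$fold, fold_p_value = fc$p_value,
                        decay_rate_liquid = rates[[1]],
                        decay_rate_swarm = rates[[2]])
  }
  if (isTRUE(cfg$with_signaling)) {
    sw <- chez_fold_sweep(c(1, 1.3, 1.5))
    report$signaling <- list(fold = sw$fold, tumble_bias = sw$tumble_bias)
  }
  if (!is.null(out_json))
    jsonlite::write_json(report, out_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  report
}
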