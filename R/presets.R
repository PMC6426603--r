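#' Condition presets for the run-and-tumble trajectory generator
#'
#' Returns the generative parameters of one growth condition. The calibration
#' values are the published condition medians for *E. coli* MG1655: cells
#' grown in liquid run at ~21 um/s with a tumble bias of ~0.12, cells lifted
#' from the edge of a swarm run at ~25 um/s with a tumble bias of ~0.04, and
#' cells grown on hard (non-swarmable) agar behave like liquid-grown cells.
#'
#' @param condition one of `"LIQUID"`, `"SWARM"`, `"HARD"`.
#' @param ... named overrides for individual preset fields (see Details).
#'
#' @details Fields and units:
#' \describe{
#'   \item{run_speed}{asymptotic run speed, um/s}
#'   \item{tumble_bias_true}{fraction of time spent tumbling, in \[0,1\]}
#'   \item{mean_tumble_duration}{s; mean run duration is derived as
#'     `mean_tumble_duration * (1 - TB) / TB`}
#'   \item{rotational_diffusion}{heading diffusion during runs, rad^2/s}
#'   \item{speed_recovery_tau}{s; speed relaxes toward `run_speed` after each
#'     tumble with this time constant (~95% recovery by 0.5 s)}
#'   \item{nonmotile_fraction}{fraction of cells that are non-motile}
#'   \item{brownian_D}{diffusion coefficient of non-motile cells, um^2/s}
#'   \item{localization_sigma}{isotropic localization noise on observed
#'     positions, um}
#' }
#'
#' @return an object of class `motility_preset` (a named list).
#' @examples
#' make_preset("LIQUID")
#' make_preset("SWARM", nonmotile_fraction = 0)
#' @export
make_preset <- function(condition = c("LIQUID", "SWARM", "HARD"), ...) {
  if (length(condition) != 1L || !condition %in% c("LIQUID", "SWARM", "HARD"))
    stop("unknown condition '", paste(condition, collapse = ","),
         "'; valid labels are LIQUID, SWARM, HARD", call. = FALSE)
  base <- list(
    condition            = condition,
    run_speed            = 21,
    tumble_bias_true     = 0.12,
    mean_tumble_duration = 0.2,
    rotational_diffusion = 0.06,
    speed_recovery_tau   = 0.17,
    nonmotile_fraction   = 0.1,
    brownian_D           = 0.4,
    localization_sigma   = 0.05
  )
  if (condition == "SWARM") {
    base$run_speed        <- 25
    base$tumble_bias_true <- 0.04
  }
  # HARD agar abolishes the swarm response: liquid-like behavior.
  ov <- list(...)
  bad <- setdiff(names(ov), names(base))
  if (length(bad)) stop("unknown preset field(s): ", paste(bad, collapse = ", "))
  base[names(ov)] <- ov
  validate_motility_preset(structure(base, class = "motility_preset"))
}

validate_motility_preset <- function(p) {
  stopifnot(is.list(p))
  if (p$tumble_bias_true < 0 || p$tumble_bias_true > 1)
    stop("tumble_bias_true must be in [0, 1]")
  if (p$run_speed < 0) stop("run_speed must be >= 0")
  if (p$mean_tumble_duration <= 0) stop("mean_tumble_duration must be > 0")
  if (p$nonmotile_fraction < 0 || p$nonmotile_fraction > 1)
    stop("nonmotile_fraction must be in [0, 1]")
  if (p$brownian_D < 0 || p$localization_sigma < 0)
    stop("brownian_D and localization_sigma must be >= 0")
  if (p$tumble_bias_true > 0 && !is.finite(mean_run_duration(p)))
    stop("implied mean run duration is not finite")
  p
}

#' Mean run duration implied by a motility preset
#'
#' `mean_tumble_duration * (1 - TB) / TB`; infinite when the tumble bias is 0.
#' @param preset a [make_preset()] object.
#' @return seconds.
#' @export
mean_run_duration <- function(preset) {
  tb <- preset$tumble_bias_true
  if (tb == 0) return(Inf)
  preset$mean_tumble_duration * (1 - tb) / tb
}

#' @export
print.motility_preset <- function(x, ...) {
  cat("<motility_preset:", x$condition, "> run_speed", x$run_speed,
      "um/s, TB", x$tumble_bias_true, "\n")
  invisible(x)
}

#' Condition presets for the tethered-bead motor generator
#'
#' Parameters of the two-state CW/CCW motor telegraph process and the orbit
#' of the attached bead. Calibrated to the published single-motor statistics:
#' liquid-grown motors rotate at ~68 Hz with ~38 reversals/min, swarmer
#' motors at ~78 Hz with ~9 reversals/min and a strong CCW bias.
#'
#' @param condition `"LIQUID"` or `"SWARM"`.
#' @param ... named overrides (fields: `ccw_frequency`, `cw_frequency` Hz;
#'   `reversal_rate` reversals/min; `cw_bias` time-fraction CW;
#'   `orbit_radius`, `center_jitter_sigma` um; `fps` frames/s).
#' @return an object of class `motor_preset`.
#' @export
make_motor_preset <- function(condition = c("LIQUID", "SWARM"), ...) {
  condition <- match.arg(condition)
  base <- list(
    condition           = condition,
    ccw_frequency       = 68,
    cw_frequency        = 68,
    reversal_rate       = 38,
    cw_bias             = 0.12,
    orbit_radius        = 0.2,
    center_jitter_sigma = 0.01,
    fps                 = 1250
  )
  if (condition == "SWARM") {
    base$ccw_frequency <- 78
    base$cw_frequency  <- 78
    base$reversal_rate <- 9
    base$cw_bias       <- 0.03
  }
  ov <- list(...)
  bad <- setdiff(names(ov), names(base))
  if (length(bad)) stop("unknown preset field(s): ", paste(bad, collapse = ", "))
  base[names(ov)] <- ov
  p <- structure(base, class = "motor_preset")
  if (p$ccw_frequency <= 0 || p$cw_frequency <= 0) stop("frequencies must be > 0")
  if (p$reversal_rate < 0) stop("reversal_rate must be >= 0")
  if (p$cw_bias < 0 || p$cw_bias > 1) stop("cw_bias must be in [0, 1]")
  if (p$reversal_rate > 0 && (p$cw_bias <= 0 || p$cw_bias >= 1))
    stop("inconsistent preset: reversal_rate > 0 requires cw_bias in (0, 1)")
  p
}

#' Telegraph switching rates implied by a motor preset
#'
#' For reversal rate R (sign changes per minute) and CW time-fraction b, the
#' exit rates are k(CCW->CW) = R/(2(1-b)) and k(CW->CCW) = R/(2b), so that the
#' stationary CW fraction is b and the expected sign changes per minute is R.
#'
#' @param preset a [make_motor_preset()] object.
#' @return named numeric, rates in s^-1: `ccw_to_cw`, `cw_to_ccw`.
#' @export
motor_switching_rates <- function(preset) {
  R <- preset$reversal_rate / 60
  b <- preset$cw_bias
  if (preset$reversal_rate == 0) return(c(ccw_to_cw = 0, cw_to_ccw = 0))
  c(ccw_to_cw = R / (2 * (1 - b)), cw_to_ccw = R / (2 * b))
}

#' Condition presets for the protein-decay generator
#'
#' Chloramphenicol-chase decay of CheZ: first-order loss at 2.7e-3 min^-1 in
#' liquid-grown cells and 1.5e-4 min^-1 in swarmers (the protein is nearly
#' stable over 6 h in the swarm condition). Band intensities carry
#' multiplicative lognormal measurement noise.
#'
#' @param condition `"LIQUID"` or `"SWARM"`.
#' @param ... named overrides (fields: `initial_intensity` a.u.; `decay_rate`
#'   min^-1; `lognormal_sigma`; `sample_times` min).
#' @return an object of class `decay_preset`.
#' @export
make_decay_preset <- function(condition = c("LIQUID", "SWARM"), ...) {
  condition <- match.arg(condition)
  base <- list(
    condition         = condition,
    initial_intensity = 1000,
    decay_rate        = if (condition == "LIQUID") 2.7e-3 else 1.5e-4,
    lognormal_sigma   = 0.1,
    sample_times      = seq(0, 360, by = 15)
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(base))
  if (length(bad)) stop("unknown preset field(s): ", paste(bad, collapse = ", "))
  base[names(ov)] <- ov
  p <- structure(base, class = "decay_preset")
  if (p$decay_rate < 0) stop("decay_rate must be >= 0")
  if (p$initial_intensity <= 0) stop("initial_intensity must be > 0")
  if (!length(p$sample_times)) stop("sample_times must be nonempty")
  if (any(p$sample_times < 0)) stop("sample_times must be >= 0")
  if (is.unsorted(p$sample_times, strictly = TRUE)) stop("sample_times must be increasing")
  p
}

#' Presets for the two-channel fluorescence scene generator
#'
#' Emulates epifluorescence snapshots of cells carrying CheY-mYFP and
#' CheZ-mCherry fusions. In the swarm condition both channels are brighter
#' and the mCherry/mYFP ratio is raised by 1.25 relative to liquid.
#'
#' @param condition `"LIQUID"` or `"SWARM"`.
#' @param ... named overrides (fields: `n_cells`; `mean_area`, `area_sd` px;
#'   `yfp_mean`, `cherry_mean` a.u./cell; `expression_cv`;
#'   `background_level` a.u./px; `autofluorescence` a.u./cell;
#'   `frame_size` px; `shot_noise` logical).
#' @return an object of class `fluor_scene_preset`.
#' @export
make_fluor_preset <- function(condition = c("LIQUID", "SWARM"), ...) {
  condition <- match.arg(condition)
  base <- list(
    condition        = condition,
    n_cells          = 60,
    mean_area        = 120,
    area_sd          = 18,
    yfp_mean         = 4000,
    cherry_mean      = 4000,
    expression_cv    = 0.3,
    background_level = 20,
    autofluorescence = 300,
    frame_size       = 512L,
    shot_noise       = TRUE
  )
  if (condition == "SWARM") {
    # both channels up; cherry/yfp ratio shifted by 1.25
    base$yfp_mean    <- 6000
    base$cherry_mean <- 6000 * 1.25
  }
  ov <- list(...)
  bad <- setdiff(names(ov), names(base))
  if (length(bad)) stop("unknown preset field(s): ", paste(bad, collapse = ", "))
  base[names(ov)] <- ov
  p <- structure(base, class = "fluor_scene_preset")
  if (p$n_cells < 0) stop("n_cells must be >= 0")
  if (p$yfp_mean < 0 || p$cherry_mean < 0 || p$background_level < 0 ||
      p$autofluorescence < 0)
    stop("means, background and autofluorescence must be >= 0")
  if (p$expression_cv < 0) stop("expression_cv must be >= 0")
  p
}
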