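#' Futile-cycle parameters for the CheA/CheZ control of CheY~P
#'
#' A kinase (CheA) phosphorylates CheY at maximal rate `V_A` and a
#' phosphatase (CheZ) dephosphorylates CheY~P at maximal rate `V_Z`, with
#' Michaelis constants `K_A`, `K_Z` expressed as fractions of total CheY.
#' When both enzymes are near saturation (K << 1, the zero-order regime,
#' which holds in E. coli because CheY far outnumbers CheA and CheZ), the
#' steady-state phosphorylated fraction is ultrasensitive to the ratio
#' V_A/V_Z.
#'
#' @param V_A,V_Z maximal kinase and phosphatase rates (same arbitrary
#'   concentration/time unit; only the ratio matters for the steady state).
#' @param K_A,K_Z Michaelis constants as fractions of total CheY.
#' @param Y_T total CheY concentration, uM (default 9.7, a standard
#'   literature value for E. coli).
#' @return object of class `futile_cycle_params`.
#' @export
futile_cycle_params <- function(V_A = 1, V_Z = 1, K_A = 0.01, K_Z = 0.01,
                                Y_T = 9.7) {
  if (any(c(V_A, V_Z, K_A, K_Z, Y_T) <= 0)) stop("all parameters must be > 0")
  structure(list(V_A = V_A, V_Z = V_Z, K_A = K_A, K_Z = K_Z, Y_T = Y_T),
            class = "futile_cycle_params")
}

#' Steady-state phosphorylated fraction of the futile cycle
#'
#' Closed-form root in \[0, 1\] of the balance
#' `V_A (1 - Yp) / (K_A + 1 - Yp) = V_Z Yp / (K_Z + Yp)`
#' (the Goldbeter-Koshland function). Solved from the quadratic
#' `(V_Z - V_A) Yp^2 + (V_A (1 - K_Z) - V_Z (1 + K_A)) Yp + V_A K_Z = 0`
#' with the numerically stable quadratic formula; the linear case
#' V_A == V_Z is handled exactly.
#'
#' @param params a [futile_cycle_params()].
#' @return phosphorylated fraction Yp in \[0, 1\].
#' @examples
#' gk_steady_state(futile_cycle_params(V_A = 1, V_Z = 1))  # 0.5 by symmetry
#' @export
gk_steady_state <- function(params) {
  a <- params$V_A; z <- params$V_Z
  KA <- params$K_A; KZ <- params$K_Z
  if (a == 0) return(0)
  A <- z - a
  B <- a * (1 - KZ) - z * (1 + KA)
  C <- a * KZ
  if (abs(A) < 1e-14 * max(a, z)) return(-C / B)
  q <- -(B + sign(B) * sqrt(B^2 - 4 * A * C)) / 2
  roots <- c(q / A, C / q)
  roots <- roots[roots >= -1e-12 & roots <= 1 + 1e-12]
  if (!length(roots)) stop("no root in [0, 1]; invalid parameters")
  min(max(roots[1], 0), 1)
}

#' Motor response linking CheY~P to tumble bias
#'
#' A Hill function: the CW (tumble) bias is
#' `(Yp * Y_T)^n / (K_half^n + (Yp * Y_T)^n)`. The steep cooperativity of
#' the flagellar switch (Hill coefficient ~10, half-point ~3.1 uM CheY~P)
#' is what converts a modest change in CheY~P into a large change in
#' tumble bias.
#'
#' @param K_half uM CheY~P at half-maximal CW bias (default 3.1).
#' @param hill_n Hill coefficient (default 10; must be >= 1).
#' @return object of class `motor_response`.
#' @export
motor_response <- function(K_half = 3.1, hill_n = 10) {
  if (K_half <= 0) stop("K_half must be > 0")
  if (hill_n < 1) stop("hill_n must be >= 1")
  structure(list(K_half = K_half, hill_n = hill_n), class = "motor_response")
}

#' Predicted tumble bias from the futile-cycle steady state
#'
#' @param params a [futile_cycle_params()].
#' @param motor a [motor_response()].
#' @return tumble bias in \[0, 1\].
#' @export
tumble_bias_prediction <- function(params, motor = motor_response()) {
  yp_um <- gk_steady_state(params) * params$Y_T
  x <- (yp_um / motor$K_half)^motor$hill_n
  x / (1 + x)
}

#' Tumble-bias response to CheZ fold changes
#'
#' Calibrates the kinase/phosphatase ratio so the baseline tumble bias
#' equals `tb_baseline` (the liquid-grown median), then scales the
#' phosphatase rate `V_Z` by each fold and recomputes the predicted tumble
#' bias. In the zero-order regime a 1.3-1.5x CheZ elevation collapses the
#' tumble bias several-fold, which is the quantitative rationale for how a
#' ~30-50% CheZ increase can shift the tumble bias from ~0.12 to ~0.04;
#' in the first-order regime (K >> 1) the same fold barely moves it.
#'
#' @param folds numeric vector of CheZ fold changes (1 = baseline).
#' @param tb_baseline tumble bias at fold 1 (default 0.12).
#' @param params a [futile_cycle_params()]; `V_A` is recalibrated, `V_Z`
#'   kept as the fold-1 phosphatase rate.
#' @param motor a [motor_response()].
#' @return data.frame `fold`, `Yp`, `tumble_bias`.
#' @export
chez_fold_sweep <- function(folds = seq(0.5, 2, by = 0.05),
                            tb_baseline = 0.12,
                            params = futile_cycle_params(),
                            motor = motor_response()) {
  # target phosphorylated fraction at baseline from the inverse Hill
  x <- tb_baseline / (1 - tb_baseline)
  yp_target <- motor$K_half * x^(1 / motor$hill_n) / params$Y_T
  if (yp_target >= 1)
    stop("calibration failure: target CheY~P exceeds total CheY ",
         "(tb_baseline too high for this motor response)")
  f <- function(log_ratio) {
    p <- params; p$V_A <- p$V_Z * exp(log_ratio)
    gk_steady_state(p) - yp_target
  }
  sol <- tryCatch(stats::uniroot(f, c(-30, 30), tol = 1e-12),
                  error = function(e)
                    stop("calibration failure: ", conditionMessage(e)))
  params$V_A <- params$V_Z * exp(sol$root)
  out <- do.call(rbind, lapply(folds, function(fd) {
    p <- params; p$V_Z <- p$V_Z * fd
    yp <- gk_steady_state(p)
    data.frame(fold = fd, Yp = yp,
               tumble_bias = tumble_bias_prediction(p, motor))
  }))
  out
}
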