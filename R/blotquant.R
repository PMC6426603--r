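#' Loading-normalized band levels
#'
#' Divides each target band by the same-lane loading-control band and
#' optionally rescales so the mean level of a reference condition is 1.
#'
#' @param measurements data.frame with columns `condition`, `target`,
#'   `loading` (e.g. from [simulate_blot()]).
#' @param reference condition label scaled to 1, or `NULL` for raw ratios.
#' @return the input with a `level` column appended.
#' @export
normalize_bands <- function(measurements, reference = NULL) {
  req <- c("condition", "target", "loading")
  miss <- setdiff(req, names(measurements))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (any(measurements$loading <= 0)) stop("loading intensities must be > 0")
  measurements$level <- measurements$target / measurements$loading
  if (!is.null(reference)) {
    ref <- measurements$level[measurements$condition == reference]
    if (!length(ref)) stop("no rows for reference condition '", reference, "'")
    measurements$level <- measurements$level / mean(ref)
  }
  measurements
}

#' Condition fold change of normalized band levels
#'
#' Ratio of mean normalized levels between two conditions, with a two-sided
#' two-sample t-test on the per-replicate values.
#'
#' @param normalized output of [normalize_bands()].
#' @param numerator,denominator condition labels (default `"SWARM"` over
#'   `"LIQUID"`).
#' @return list `fold`, `p_value`, `n` (replicates per condition).
#' @export
fold_change <- function(normalized, numerator = "SWARM",
                        denominator = "LIQUID") {
  a <- normalized$level[normalized$condition == numerator]
  b <- normalized$level[normalized$condition == denominator]
  if (length(a) < 2 || length(b) < 2)
    stop("need at least 2 replicates per condition")
  if (length(a) < 3 || length(b) < 3)
    warning("fewer than 3 replicates per condition; p-value unreliable")
  tt <- stats::t.test(a, b)
  list(fold = mean(a) / mean(b), p_value = tt$p.value,
       n = c(length(a), length(b)))
}

#' First-order degradation rate from a chase time course
#'
#' Ordinary least squares of log intensity on time; the rate is the negated
#' slope. With multiplicative lognormal noise this is the maximum-likelihood
#' estimator, and it is invariant to intensity rescaling.
#'
#' @param course data.frame with `t_min` and `intensity` for one replicate
#'   (intensities already loading-normalized if a control is available).
#' @param window optional numeric length-2; restrict the fit to this time
#'   range (default all points).
#' @return list `rate` (min^-1), `se`, `r_squared`, `n_points`.
#' @export
decay_rate <- function(course, window = NULL) {
  if (!is.null(window))
    course <- course[course$t_min >= window[1] & course$t_min <= window[2], ]
  if (nrow(course) < 3) stop("need at least 3 time points")
  if (any(course$intensity <= 0)) stop("intensities must be > 0")
  fit <- stats::lm(log(intensity) ~ t_min, data = course)
  sm <- suppressWarnings(summary(fit))   # exact fits trip a summary warning
  list(rate = -unname(stats::coef(fit)[2]),
       se = sm$coefficients[2, 2],
       r_squared = sm$r.squared,
       n_points = nrow(course))
}

#' Per-replicate degradation rates and condition comparison
#'
#' Fits [decay_rate()] per replicate, aggregates as mean +/- SD, and, when
#' two conditions are supplied, compares the per-replicate rates with a
#' two-sample t-test.
#'
#' @param courses data.frame `replicate`, `t_min`, `intensity`, optionally
#'   `condition`.
#' @param window passed to [decay_rate()].
#' @return list with `per_replicate` (data.frame `condition`, `replicate`,
#'   `rate`), `mean_rate` (named by condition), `sd_rate`, and `p_value`
#'   (NA unless exactly two conditions).
#' @export
decay_rate_set <- function(courses, window = NULL) {
  if (is.null(courses$condition)) courses$condition <- "ALL"
  per <- do.call(rbind, lapply(
    split(courses, list(courses$condition, courses$replicate), drop = TRUE),
    function(d) data.frame(condition = d$condition[1],
                           replicate = d$replicate[1],
                           rate = decay_rate(d, window)$rate)))
  rownames(per) <- NULL
  mu <- vapply(split(per$rate, per$condition), mean, numeric(1))
  sdv <- vapply(split(per$rate, per$condition), stats::sd, numeric(1))
  pv <- NA_real_
  if (length(unique(per$condition)) == 2) {
    sp <- split(per$rate, per$condition)
    pv <- stats::t.test(sp[[1]], sp[[2]])$p.value
  }
  list(per_replicate = per, mean_rate = mu, sd_rate = sdv, p_value = pv)
}
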