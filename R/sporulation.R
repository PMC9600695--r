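# Sporulation quantification: CFU estimates from serial-dilution spot counts,
# post/pre heat-kill efficiency, the lag <-> log10(spores) calibration, and the
# assay's detection limit.

#' Serial-dilution spot counts
#'
#' Colony counts from 10 uL spots of a serial dilution series (the screen
#' diluted 10 uL into 90 uL, i.e. 10-fold steps, and spotted 10 uL of each).
#'
#' @param dilution_factors strictly decreasing dilution factors
#'   (e.g. `c(1, 1e-1, 1e-2, ...)`)
#' @param counts colonies counted per spot (non-negative integers)
#' @param spot_volume_uL volume plated per spot in uL (default 10)
#' @param countable_range counts accepted as reliable, default `c(3, 30)`
#'   per 10 uL spot (below: too few for a stable estimate; above: colonies
#'   merge)
#' @return an object of class `spot_count_series`
#' @export
spot_count_series <- function(dilution_factors, counts, spot_volume_uL = 10,
                              countable_range = c(3, 30)) {
  stopifnot(is.numeric(dilution_factors), is.numeric(counts),
            length(dilution_factors) == length(counts),
            length(dilution_factors) >= 1L)
  if (any(dilution_factors <= 0) || any(diff(dilution_factors) >= 0))
    stop("dilution_factors must be positive and strictly decreasing")
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  stopifnot(spot_volume_uL > 0, length(countable_range) == 2L,
            countable_range[1L] <= countable_range[2L])
  structure(
    list(dilution_factors = dilution_factors, counts = as.integer(counts),
         spot_volume_uL = spot_volume_uL, countable_range = countable_range),
    class = "spot_count_series"
  )
}

#' Estimate CFU/mL from a dilution series
#'
#' Uses the most-concentrated dilution whose count falls in the countable
#' range (the largest reliable count has the smallest relative Poisson
#' error): `cfu_per_ml = count / spot_volume_mL / dilution_factor`. If every
#' spot is empty the sample is below the detection limit (`cfu_per_ml = 0`,
#' `below_lod = TRUE`). If no count is countable but some are non-zero, the
#' most-concentrated non-zero count is used and the estimate is flagged
#' `outside_countable = TRUE`. If every count exceeds the countable range the
#' series is too numerous to count and an error is raised.
#'
#' @param series a [spot_count_series()]
#' @return an object of class `cfu_estimate`: `cfu_per_ml`, `dilution_used`,
#'   `count_used`, `below_lod`, `outside_countable`
#' @export
cfu_from_spot_counts <- function(series) {
  stopifnot(inherits(series, "spot_count_series"))
  cnt <- series$counts
  rng <- series$countable_range
  vol_ml <- series$spot_volume_uL * 1e-3
  mk <- function(cfu, dil, count, lod = FALSE, outside = FALSE) {
    structure(list(cfu_per_ml = cfu, dilution_used = dil, count_used = count,
                   below_lod = lod, outside_countable = outside),
              class = "cfu_estimate")
  }
  if (all(cnt == 0L))
    return(mk(0, NA_real_, 0L, lod = TRUE))
  if (all(cnt > rng[2L]))
    stop("all spot counts exceed the countable range (too numerous to count)")
  in_range <- which(cnt >= rng[1L] & cnt <= rng[2L])
  if (length(in_range)) {
    i <- in_range[1L]  # dilution factors are decreasing: first = most concentrated
    return(mk(cnt[i] / vol_ml / series$dilution_factors[i],
              series$dilution_factors[i], cnt[i]))
  }
  i <- which(cnt > 0L)[1L]
  mk(cnt[i] / vol_ml / series$dilution_factors[i],
     series$dilution_factors[i], cnt[i], outside = TRUE)
}

#' @export
print.cfu_estimate <- function(x, ...) {
  cat(sprintf("<cfu_estimate> %.4g CFU/mL%s%s\n", x$cfu_per_ml,
              if (x$below_lod) " (below detection limit)" else
                sprintf(" (count %d at dilution %.3g)", x$count_used, x$dilution_used),
              if (isTRUE(x$outside_countable)) " [outside countable range]" else ""))
  invisible(x)
}

#' Sporulation efficiency
#'
#' Ratio of CFU after heat killing (only spores survive 80 degC for 30 min)
#' to CFU before heat killing (spores plus vegetative cells). Values above 1
#' can occur through counting noise and are flagged, not clipped.
#'
#' @param pre [cfu_from_spot_counts()] estimate before heat kill
#' @param post estimate after heat kill
#' @return an object of class `efficiency_result`: `pre_cfu_per_ml`,
#'   `post_cfu_per_ml`, `efficiency`, `below_lod`, `exceeds_one`
#' @export
sporulation_efficiency <- function(pre, post) {
  stopifnot(inherits(pre, "cfu_estimate"), inherits(post, "cfu_estimate"))
  if (!is.finite(pre$cfu_per_ml) || pre$cfu_per_ml <= 0)
    stop("undefined efficiency: pre-heat-kill CFU estimate is not positive")
  eff <- post$cfu_per_ml / pre$cfu_per_ml
  structure(
    list(pre_cfu_per_ml = pre$cfu_per_ml, post_cfu_per_ml = post$cfu_per_ml,
         efficiency = eff, below_lod = isTRUE(post$below_lod),
         exceeds_one = eff > 1),
    class = "efficiency_result"
  )
}

#' @export
print.efficiency_result <- function(x, ...) {
  cat(sprintf("<efficiency_result> %.3g (post %.4g / pre %.4g CFU/mL)%s%s\n",
              x$efficiency, x$post_cfu_per_ml, x$pre_cfu_per_ml,
              if (x$below_lod) " [post below LOD]" else "",
              if (x$exceeds_one) " [>1: counting noise]" else ""))
  invisible(x)
}

#' Outgrowth assay constants
#'
#' Fixed parameters of the optical-density sporulation assay: the volume
#' transferred into the outgrowth well, the outgrowth dilution, and the
#' effective doubling time during exponential outgrowth (~20 min).
#'
#' @param inoculum_volume_uL inoculum volume in uL (default 1)
#' @param outgrowth_dilution fold dilution into fresh medium (default 200,
#'   i.e. 1:200)
#' @param doubling_time_min doubling time in minutes (default 20)
#' @return an object of class `assay_constants`
#' @export
assay_constants <- function(inoculum_volume_uL = 1, outgrowth_dilution = 200,
                            doubling_time_min = 20) {
  stopifnot(inoculum_volume_uL > 0, outgrowth_dilution >= 1,
            doubling_time_min > 0)
  structure(list(inoculum_volume_uL = inoculum_volume_uL,
                 outgrowth_dilution = outgrowth_dilution,
                 doubling_time_min = doubling_time_min),
            class = "assay_constants")
}

#' Detection limit of the outgrowth assay
#'
#' One spore in the transfer volume is the smallest detectable inoculum, so
#' the limit of detection in the original culture is
#' `1 / (inoculum_volume_uL * 1e-3 mL)` CFU/mL — 10^3 CFU/mL for the 1 uL
#' inoculum used in the screen.
#'
#' @param constants an [assay_constants()]
#' @return detection limit in CFU/mL
#' @export
detection_limit <- function(constants = assay_constants()) {
  stopifnot(inherits(constants, "assay_constants"))
  1 / (constants$inoculum_volume_uL * 1e-3)
}

#' Expected lag shift from a dilution
#'
#' Under exponential outgrowth, diluting the inoculum `d`-fold delays the
#' time to any fixed OD by `log2(d)` doublings:
#' `shift = log2(d) * doubling_time_min / 60` hours. With a 20-min doubling
#' time a 10-fold dilution adds ~1.107 h, the assay's "~1 h per decade".
#'
#' @param dilution_factor fold dilution (>= 1)
#' @param doubling_time_min doubling time in minutes (default 20)
#' @return expected additional lag in hours
#' @export
expected_lag_shift <- function(dilution_factor, doubling_time_min = 20) {
  stopifnot(is.numeric(dilution_factor), all(dilution_factor >= 1),
            doubling_time_min > 0)
  log2(dilution_factor) * doubling_time_min / 60
}

#' Fit the lag vs log10(spore count) calibration
#'
#' Lag to OD 0.2 is negatively and linearly related to the log10 of the spore
#' inoculum (each missing decade costs ~`log2(10)` doublings). Ordinary least
#' squares of lag on log10(count); censored lags (NA) are excluded.
#'
#' @param lags_h lag times in hours (NA = censored, dropped with a warning)
#' @param spore_counts positive spore counts, same length
#' @return an object of class `spore_calibration`: `intercept_h`,
#'   `coef_h_per_log10` (expected negative), `r_squared`, `n`
#' @export
fit_lag_calibration <- function(lags_h, spore_counts) {
  stopifnot(is.numeric(lags_h), is.numeric(spore_counts),
            length(lags_h) == length(spore_counts))
  keep <- is.finite(lags_h) & is.finite(spore_counts)
  if (any(!keep)) warning(sum(!keep), " censored or non-finite point(s) dropped")
  lags_h <- lags_h[keep]
  spore_counts <- spore_counts[keep]
  if (length(lags_h) < 2L)
    stop("calibration needs at least 2 uncensored points")
  if (any(spore_counts <= 0))
    stop("spore counts must be positive")
  x <- log10(spore_counts)
  if (stats::sd(x) == 0)
    stop("degenerate fit: spore counts have no spread on the log10 scale")
  fit <- stats::lm(lags_h ~ x)
  tss <- sum((lags_h - mean(lags_h))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else NA_real_
  structure(
    list(intercept_h = unname(stats::coef(fit)[1L]),
         coef_h_per_log10 = unname(stats::coef(fit)[2L]),
         r_squared = r2,
         n = length(lags_h)),
    class = "spore_calibration"
  )
}

#' @export
print.spore_calibration <- function(x, ...) {
  cat(sprintf("<spore_calibration> lag = %.3f %+.3f * log10(spores) h (r^2 = %.3f, n = %d)\n",
              x$intercept_h, x$coef_h_per_log10, x$r_squared, x$n))
  invisible(x)
}

#' Predict spore counts from lag times
#'
#' Inverts the calibration: `log10(N) = (lag - intercept) / coefficient`.
#' Predictions below one spore are flagged below the detection limit. The
#' equivalent concentration in the original culture follows from the
#' inoculum volume.
#'
#' @param cal a [fit_lag_calibration()] result (coefficient must be negative)
#' @param lag_h lag time(s) in hours
#' @param inoculum_volume_uL inoculum volume for the CFU/mL conversion
#'   (default 1)
#' @return a data.frame with `lag_h`, `spores`, `cfu_per_ml`, `below_lod`
#' @export
predict_spore_count <- function(cal, lag_h, inoculum_volume_uL = 1) {
  stopifnot(inherits(cal, "spore_calibration"), is.numeric(lag_h),
            inoculum_volume_uL > 0)
  if (!is.finite(cal$coef_h_per_log10) || cal$coef_h_per_log10 >= 0)
    stop("calibration error: coefficient must be negative (lag decreases with spores)")
  n <- 10^((lag_h - cal$intercept_h) / cal$coef_h_per_log10)
  data.frame(lag_h = lag_h, spores = n,
             cfu_per_ml = n / (inoculum_volume_uL * 1e-3),
             below_lod = n < 1)
}
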