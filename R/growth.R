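# Plate-reader OD600 time series: parsing, blank correction, growth calls and
# lag-time extraction.

#' Growth curve container
#'
#' A time-ordered OD600 series for one well. Times are in hours and must be
#' strictly increasing; OD values must be finite, and non-negative once the
#' curve is blank-corrected.
#'
#' @param t times in hours, strictly increasing, length >= 2
#' @param od OD600 readings
#' @param well well label
#' @param blanked has a blank already been subtracted?
#' @return an object of class `growth_curve`
#' @export
growth_curve <- function(t, od, well = "", blanked = FALSE) {
  stopifnot(is.numeric(t), is.numeric(od))
  if (length(t) != length(od) || length(t) < 2L)
    stop("t and od must have equal length >= 2")
  if (!all(is.finite(t)) || !all(is.finite(od)))
    stop("times and OD values must be finite")
  if (any(diff(t) <= 0))
    stop("times must be strictly increasing")
  if (blanked && any(od < -1e-9))
    stop("blank-corrected OD must be non-negative")
  structure(list(t = t, od = od, well = as.character(well),
                 blanked = isTRUE(blanked)),
            class = "growth_curve")
}

#' @export
print.growth_curve <- function(x, ...) {
  cat(sprintf("<growth_curve> well=%s, %d points over %.2g-%.2g h, OD %.3g-%.3g%s\n",
              x$well, length(x$t), min(x$t), max(x$t), min(x$od), max(x$od),
              if (x$blanked) " (blanked)" else ""))
  invisible(x)
}

#' Read a plate-reader export
#'
#' Wide CSV: one `time` column plus one column per well. Times are converted
#' to hours.
#'
#' @param path CSV path
#' @param time_unit unit of the time column: "h", "min" or "s"
#' @return named list of [growth_curve()] objects, one per well column
#' @export
read_plate_reader <- function(path, time_unit = c("h", "min", "s")) {
  time_unit <- match.arg(time_unit)
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  tcol <- which(tolower(names(d)) == "time")
  if (length(tcol) != 1L)
    stop("expected exactly one 'time' column in ", path)
  t <- as.numeric(d[[tcol]]) / switch(time_unit, h = 1, min = 60, s = 3600)
  if (any(!is.finite(t)))
    stop("non-numeric or missing values in the time column")
  if (any(diff(t) <= 0))
    stop("time column must be strictly increasing (duplicated or reordered rows?)")
  wells <- names(d)[-tcol]
  bad <- wells[vapply(wells, function(w) any(!is.finite(as.numeric(d[[w]]))),
                      logical(1))]
  if (length(bad))
    stop("missing or non-numeric OD values in wells: ", paste(bad, collapse = ", "))
  stats::setNames(
    lapply(wells, function(w) growth_curve(t, as.numeric(d[[w]]), well = w)),
    wells
  )
}

#' Blank-correct a growth curve
#'
#' `min_blank_well` subtracts the minimum reading of the blank well from every
#' sample (the screen's blank rule) and clips at zero; `preblanked` marks the
#' curve as already corrected (plates blanked before inoculation) and returns
#' it unchanged.
#'
#' @param curve a [growth_curve()]
#' @param mode "min_blank_well" or "preblanked"
#' @param blank_curve a [growth_curve()] from a medium-only well
#'   (required for `min_blank_well`)
#' @return a blank-corrected [growth_curve()]
#' @export
blank_correct <- function(curve, mode = c("min_blank_well", "preblanked"),
                          blank_curve = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(curve, "growth_curve"))
  if (mode == "preblanked") {
    curve$blanked <- TRUE
    return(curve)
  }
  if (is.null(blank_curve) || !inherits(blank_curve, "growth_curve"))
    stop("min_blank_well mode requires a blank_curve")
  growth_curve(curve$t, pmax(curve$od - min(blank_curve$od), 0),
               well = curve$well, blanked = TRUE)
}

#' Growth/no-growth call at a fixed time
#'
#' The screen scored a full knockdown as "did not grow" when OD600 stayed
#' strictly below 0.075 at the call time (5 h in LB, 8 h in MSgg). The OD at
#' the call time is linearly interpolated between the flanking samples, and
#' `grew` is `od_at_call >= threshold_od` — a reading exactly at the
#' threshold counts as growth, matching the strict "<" of the no-growth
#' criterion.
#'
#' @param curve a [growth_curve()]
#' @param threshold_od no-growth threshold (default 0.075)
#' @param call_time_h time of the call in hours, within the observed range
#' @return an object of class `growth_call`: `well`, `grew`, `threshold_od`,
#'   `call_time_h`, `od_at_call`
#' @export
call_growth <- function(curve, threshold_od = 0.075, call_time_h) {
  stopifnot(inherits(curve, "growth_curve"), threshold_od > 0)
  if (call_time_h < curve$t[1L] || call_time_h > curve$t[length(curve$t)])
    stop("call time ", call_time_h, " h outside the observed range [",
         curve$t[1L], ", ", curve$t[length(curve$t)], "] h")
  od_at <- stats::approx(curve$t, curve$od, xout = call_time_h)$y
  structure(list(well = curve$well, grew = od_at >= threshold_od,
                 threshold_od = threshold_od, call_time_h = call_time_h,
                 od_at_call = od_at),
            class = "growth_call")
}

#' @export
print.growth_call <- function(x, ...) {
  cat(sprintf("<growth_call> well=%s: %s (OD %.4g %s %.4g at %g h)\n",
              x$well, if (x$grew) "grew" else "no growth", x$od_at_call,
              if (x$grew) ">=" else "<", x$threshold_od, x$call_time_h))
  invisible(x)
}

#' Lag time to an OD threshold
#'
#' Lag is the time for the culture to first reach the threshold OD (0.2 in
#' the sporulation outgrowth assay), linearly interpolated between the last
#' sample below and the first sample at or above the threshold. A curve
#' already at or above the threshold has lag 0; a curve that never reaches it
#' is censored (`lag_h = NA`).
#'
#' @param curve a blank-corrected [growth_curve()]
#' @param threshold_od lag threshold (default 0.2)
#' @return an object of class `lag_result`: `well`, `lag_h` (NA if censored),
#'   `censored`, `threshold_od`
#' @export
lag_time <- function(curve, threshold_od = 0.2) {
  stopifnot(inherits(curve, "growth_curve"), threshold_od > 0)
  if (!curve$blanked)
    stop("lag_time expects a blank-corrected curve (run blank_correct first)")
  res <- list(well = curve$well, lag_h = NA_real_, censored = TRUE,
              threshold_od = threshold_od)
  hit <- which(curve$od >= threshold_od)
  if (length(hit)) {
    i <- hit[1L]
    res$censored <- FALSE
    res$lag_h <- if (i == 1L) 0 else
      curve$t[i - 1L] + (threshold_od - curve$od[i - 1L]) *
        (curve$t[i] - curve$t[i - 1L]) / (curve$od[i] - curve$od[i - 1L])
  }
  structure(res, class = "lag_result")
}

#' @export
print.lag_result <- function(x, ...) {
  cat(sprintf("<lag_result> well=%s: %s (threshold OD %.3g)\n", x$well,
              if (x$censored) "censored (threshold never reached)"
              else sprintf("lag %.3f h", x$lag_h), x$threshold_od))
  invisible(x)
}
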