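#' Infer the colony grid from one corner colony
#'
#' Colonies are spotted on a regular lattice (centre-to-centre spacing 9 mm in
#' the screen's plates). Given the manually recorded centre of one corner
#' colony, all other centres follow from the known spacing: centres form a
#' rectangular lattice with pitch `spacing_mm / mm_per_px` pixels, ordered
#' row-major from the corner. The corner is taken as the top-left colony
#' (rows and columns extend toward increasing pixel indices).
#'
#' @param img a [plate_image()] (used for bounds checking)
#' @param corner_center_px `(row, col)` pixel centre of the corner colony,
#'   1-based
#' @param n_rows,n_cols grid shape
#' @param spacing_mm centre-to-centre colony spacing in mm (default 9)
#' @param well_labels optional character vector of strain labels, row-major,
#'   length `n_rows * n_cols`
#' @return an object of class `colony_grid` with fields `centers_px`
#'   (n x 2 matrix, row-major order), `n_rows`, `n_cols`, `spacing_mm`,
#'   `pitch_px`, `corner_center_px`, `well_labels`
#' @export
infer_grid <- function(img, corner_center_px, n_rows, n_cols, spacing_mm = 9,
                       well_labels = NULL) {
  stopifnot(inherits(img, "plate_image"),
            is.numeric(corner_center_px), length(corner_center_px) == 2L,
            n_rows >= 1, n_cols >= 1, spacing_mm > 0)
  pitch <- spacing_mm / img$mm_per_px
  ij <- expand.grid(j = seq_len(n_cols), i = seq_len(n_rows))  # row-major order
  centers <- cbind(row = corner_center_px[1L] + (ij$i - 1L) * pitch,
                   col = corner_center_px[2L] + (ij$j - 1L) * pitch)
  bad <- which(centers[, 1L] < 1 | centers[, 1L] > nrow(img$pixels) |
               centers[, 2L] < 1 | centers[, 2L] > ncol(img$pixels))
  if (length(bad)) {
    stop("inferred colony centre outside image bounds at grid position (",
         ij$i[bad[1L]], ", ", ij$j[bad[1L]], "): pixel (",
         round(centers[bad[1L], 1L], 1), ", ", round(centers[bad[1L], 2L], 1), ")")
  }
  if (!is.null(well_labels) && length(well_labels) != nrow(centers))
    stop("well_labels must have length n_rows * n_cols")
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         corner_center_px = as.numeric(corner_center_px),
         spacing_mm = spacing_mm, pitch_px = pitch, centers_px = centers,
         well_labels = well_labels),
    class = "colony_grid"
  )
}

#' @export
print.colony_grid <- function(x, ...) {
  cat(sprintf("<colony_grid> %dx%d, spacing %.3g mm (%.3g px), corner (%.1f, %.1f)\n",
              x$n_rows, x$n_cols, x$spacing_mm, x$pitch_px,
              x$corner_center_px[1L], x$corner_center_px[2L]))
  invisible(x)
}

#' Read a plate map
#'
#' CSV with columns `position,row,col,strain,is_control` describing which
#' strain sits at each grid position and which positions are internal
#' (parent-strain) controls.
#'
#' @param path path to the CSV file
#' @return a data.frame ordered row-major (by `row` then `col`)
#' @export
read_plate_map <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("position", "row", "col", "strain", "is_control")
  miss <- setdiff(need, names(m))
  if (length(miss)) stop("plate map is missing columns: ", paste(miss, collapse = ", "))
  m$is_control <- as.logical(m$is_control)
  m[order(m$row, m$col), , drop = FALSE]
}

#' Measure colony diameter along the diagonal
#'
#' Mirrors the screen's manual FIJI measurement: the intensity profile is
#' sampled (bilinearly, at 1-px steps) along the 45-degree diagonal through
#' the colony centre, and the diameter is the distance between the two
#' outermost crossings of the colony/background threshold. The threshold is
#' the midpoint between the 5th percentile (background) and 95th percentile
#' (colony interior) of the profile, so the measurement is invariant to a
#' constant intensity offset. Colonies are assumed brighter than background.
#'
#' @param img a [plate_image()]
#' @param center_px `(row, col)` colony centre, 1-based, strictly inside the
#'   image
#' @param max_radius_px how far along the diagonal to sample, in pixels
#'   (default: to the image edge). On gridded plates, set this below the
#'   distance to the diagonal neighbour so its colony cannot contribute a
#'   crossing; [measure_plate()] does this from the grid pitch.
#' @return diameter in mm; 0 if the profile never crosses the threshold
#' @export
measure_colony_diameter <- function(img, center_px, max_radius_px = Inf) {
  stopifnot(inherits(img, "plate_image"),
            is.numeric(center_px), length(center_px) == 2L, max_radius_px > 0)
  nr <- nrow(img$pixels); nc <- ncol(img$pixels)
  if (center_px[1L] <= 1 || center_px[1L] >= nr ||
      center_px[2L] <= 1 || center_px[2L] >= nc)
    stop("colony centre must lie strictly inside the image")
  step <- 1 / sqrt(2)  # unit pixel distance per diagonal step
  t_max <- floor(min(center_px[1L] - 1, nr - center_px[1L],
                     center_px[2L] - 1, nc - center_px[2L],
                     max_radius_px * step) / step)
  if (t_max < 1) stop("max_radius_px leaves no profile to sample")
  tt <- seq.int(-t_max, t_max)
  rr <- center_px[1L] + tt * step
  cc <- center_px[2L] + tt * step
  prof <- bilinear_sample(img$pixels, rr, cc)
  thr <- mean(stats::quantile(prof, c(0.05, 0.95), names = FALSE))
  above <- prof >= thr
  if (all(above) || !any(above)) return(0)
  first <- which(above)[1L]
  last <- which(above)[length(which(above))]
  # sub-sample crossing positions by linear interpolation on the profile
  t1 <- if (first == 1L) tt[1L] else
    tt[first - 1L] + (thr - prof[first - 1L]) / (prof[first] - prof[first - 1L])
  t2 <- if (last == length(tt)) tt[length(tt)] else
    tt[last] + (prof[last] - thr) / (prof[last] - prof[last + 1L])
  (t2 - t1) * img$mm_per_px
}

# Bilinear sampling of matrix x at fractional (row, col) coordinates.
bilinear_sample <- function(x, r, c) {
  nr <- nrow(x); nc <- ncol(x)
  r <- pmin(pmax(r, 1), nr)
  c <- pmin(pmax(c, 1), nc)
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0; fc <- c - c0
  (1 - fr) * (1 - fc) * x[cbind(r0, c0)] +
    (1 - fr) * fc * x[cbind(r0, c0 + 1)] +
    fr * (1 - fc) * x[cbind(r0 + 1, c0)] +
    fr * fc * x[cbind(r0 + 1, c0 + 1)]
}

# Indices of pixels whose centre lies within radius_px of center_px.
circle_pixels <- function(dim_img, center_px, radius_px) {
  r_lo <- max(1L, floor(center_px[1L] - radius_px))
  r_hi <- min(dim_img[1L], ceiling(center_px[1L] + radius_px))
  c_lo <- max(1L, floor(center_px[2L] - radius_px))
  c_hi <- min(dim_img[2L], ceiling(center_px[2L] + radius_px))
  if (r_lo > r_hi || c_lo > c_hi) return(integer(0))
  g <- expand.grid(r = r_lo:r_hi, c = c_lo:c_hi)
  d2 <- (g$r - center_px[1L])^2 + (g$c - center_px[2L])^2
  keep <- d2 <= radius_px^2
  (g$c[keep] - 1L) * dim_img[1L] + g$r[keep]
}

#' Colony fluorescence, blank-corrected and normalized
#'
#' Quantifies reporter fluorescence within a fixed circle around the colony
#' centre, the way the screen measured RFP knockdown and matrix-reporter
#' expression. Two modes:
#' \describe{
#'   \item{`normalized`}{`(raw - blank) / (reference - blank)` where `raw` is
#'     the mean intensity inside the circle, `blank_value` the measurement of
#'     an unlabelled (wild-type) control and `reference_value` that of the
#'     fully expressing control; 0 means blank level, 1 means full expression.}
#'   \item{`per_area`}{`(total intensity - blank_value * n_pixels)` divided by
#'     the circle area in mm^2 (pixel count times `mm_per_px^2`), the
#'     intensity-per-unit-area readout of the mNeongreen assay.}
#' }
#'
#' @param img a [plate_image()]
#' @param center_px `(row, col)` colony centre
#' @param radius_px measurement circle radius in pixels (> 0); the screen used
#'   a circle the size of the largest colony on the plate
#' @param blank_value scalar blank intensity (same units as pixels)
#' @param reference_value scalar reference intensity (normalized mode only)
#' @param mode "normalized" or "per_area"
#' @return a single numeric value
#' @export
colony_fluorescence <- function(img, center_px, radius_px, blank_value,
                                reference_value = NULL,
                                mode = c("normalized", "per_area")) {
  mode <- match.arg(mode)
  stopifnot(inherits(img, "plate_image"), radius_px > 0,
            is.numeric(blank_value), length(blank_value) == 1L)
  idx <- circle_pixels(dim(img$pixels), center_px, radius_px)
  if (length(idx) == 0L) stop("measurement circle contains no pixels")
  vals <- img$pixels[idx]
  if (mode == "normalized") {
    if (is.null(reference_value))
      stop("normalized mode requires a reference_value")
    if (reference_value == blank_value)
      stop("invalid calibration: reference_value equals blank_value")
    (mean(vals) - blank_value) / (reference_value - blank_value)
  } else {
    area_mm2 <- length(vals) * img$mm_per_px^2
    (sum(vals) - blank_value * length(vals)) / area_mm2
  }
}

#' Measure all colonies on a plate
#'
#' Convenience wrapper running [measure_colony_diameter()] (and optionally
#' [colony_fluorescence()]) over every grid position.
#'
#' @param img a [plate_image()]
#' @param grid a [infer_grid()] result
#' @param radius_px fluorescence circle radius; `NULL` skips fluorescence
#' @param blank_value,reference_value,mode passed to [colony_fluorescence()]
#' @return a data.frame with one row per grid position: `position`, `row`,
#'   `col`, `center_row`, `center_col`, `strain`, `diameter_mm` and, when
#'   requested, `fluorescence`
#' @export
measure_plate <- function(img, grid, radius_px = NULL, blank_value = 0,
                          reference_value = NULL, mode = "normalized") {
  stopifnot(inherits(grid, "colony_grid"))
  n <- nrow(grid$centers_px)
  ij <- expand.grid(j = seq_len(grid$n_cols), i = seq_len(grid$n_rows))
  out <- data.frame(
    position = seq_len(n), row = ij$i, col = ij$j,
    center_row = grid$centers_px[, 1L], center_col = grid$centers_px[, 2L],
    strain = if (is.null(grid$well_labels)) NA_character_ else grid$well_labels,
    diameter_mm = vapply(seq_len(n), function(k)
      measure_colony_diameter(img, grid$centers_px[k, ],
                              max_radius_px = 0.7 * grid$pitch_px), numeric(1))
  )
  if (!is.null(radius_px)) {
    out$fluorescence <- vapply(seq_len(n), function(k)
      colony_fluorescence(img, grid$centers_px[k, ], radius_px, blank_value,
                          reference_value, mode), numeric(1))
  }
  out
}
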