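# Wrinkling quantification: morphological background removal, binarization,
# small-component filtering, radial wrinkling intensity W(r), area-normalized
# density, and control-normalized classification.

#' Wrinkle pipeline parameters
#'
#' @param disk_radius_px radius of the disc structuring element used for the
#'   morphological background estimate (default 15 px, read as a radius; the
#'   structuring-element "size" convention is ambiguous, so it is exposed)
#' @param min_component_px minimum surviving connected-component size after
#'   binarization (default 50 px)
#' @param binarize_level threshold applied to the contrast-adjusted image
#'   (default 0.5, the common binarization default); ignored when
#'   `method = "otsu"`
#' @param stretch_percentiles low/high percentiles mapped to \[0, 1\] in the
#'   contrast stretch (default 1 and 99, mimicking the usual saturation
#'   defaults)
#' @param connectivity pixel connectivity for component removal (8 or 4)
#' @param method "fixed" threshold at `binarize_level` (default) or "otsu"
#' @return an object of class `wrinkle_params`
#' @export
wrinkle_params <- function(disk_radius_px = 15, min_component_px = 50,
                           binarize_level = 0.5, stretch_percentiles = c(1, 99),
                           connectivity = 8, method = c("fixed", "otsu")) {
  method <- match.arg(method)
  stopifnot(disk_radius_px >= 1, min_component_px >= 0,
            binarize_level > 0, binarize_level < 1,
            length(stretch_percentiles) == 2L,
            stretch_percentiles[1L] < stretch_percentiles[2L],
            connectivity %in% c(4, 8))
  structure(
    list(disk_radius_px = disk_radius_px, min_component_px = min_component_px,
         binarize_level = binarize_level,
         stretch_percentiles = stretch_percentiles,
         connectivity = connectivity, method = method),
    class = "wrinkle_params"
  )
}

#' Binarized wrinkle mask
#'
#' The wrinkle-quantification front end. Wrinkle ridges are narrow relative
#' to the disc structuring element, so a morphological opening estimates the
#' smooth background (colony body plus uneven illumination) underneath them:
#' \enumerate{
#'   \item background = grayscale opening with a disc of radius
#'     `disk_radius_px`;
#'   \item residual = image - background, clipped at 0 (the top-hat);
#'   \item contrast stretch mapping the residual's low/high percentiles to
#'     \[0, 1\] with clipping;
#'   \item binarize: stretched value strictly greater than `binarize_level`
#'     (or the Otsu level);
#'   \item remove connected components smaller than `min_component_px`.
#' }
#' Because opening and subtraction commute with intensity scaling and the
#' percentile stretch removes the scale, the mask is invariant to multiplying
#' all intensities by a positive constant.
#'
#' @param img a [plate_image()] (grayscale, \[0, 1\])
#' @param params a [wrinkle_params()]
#' @return an object of class `wrinkle_mask`: fields `pixels` (logical
#'   matrix) and `params`
#' @export
preprocess_to_mask <- function(img, params = wrinkle_params()) {
  stopifnot(inherits(img, "plate_image"), inherits(params, "wrinkle_params"))
  x <- img$pixels
  kern <- disc_kernel(params$disk_radius_px)
  bg <- gray_opening(x, kern)
  resid <- pmax(x - bg, 0)
  q <- stats::quantile(resid, params$stretch_percentiles / 100, names = FALSE)
  if (q[2L] > q[1L]) {
    stretched <- clip01((resid - q[1L]) / (q[2L] - q[1L]))
  } else {
    stretched <- matrix(0, nrow(x), ncol(x))  # featureless residual
  }
  level <- if (params$method == "otsu") otsu_level(stretched) else params$binarize_level
  bw <- stretched > level
  bw <- remove_small_components(bw, params$min_component_px, params$connectivity)
  structure(list(pixels = bw, params = params), class = "wrinkle_mask")
}

# Drop foreground components with fewer than min_px pixels.
remove_small_components <- function(bw, min_px, connectivity = 8) {
  if (min_px <= 1 || !any(bw)) return(bw)
  lab <- label_components(bw, connectivity)
  sizes <- tabulate(lab[lab > 0L])
  small <- which(sizes < min_px)
  if (length(small)) bw[lab %in% small] <- FALSE
  bw
}

#' @export
print.wrinkle_mask <- function(x, ...) {
  cat(sprintf("<wrinkle_mask> %dx%d px, %d foreground px (%.2f%%)\n",
              nrow(x$pixels), ncol(x$pixels), sum(x$pixels),
              100 * mean(x$pixels)))
  invisible(x)
}

#' Radial wrinkling intensity W(r)
#'
#' Cumulative count of wrinkle (foreground) pixels whose centre lies within
#' distance `r` of the colony centre, for integer radii `r = 1..r_max`.
#' Distances are compared on squared integers, so the counts are exact.
#' The in-circle pixel totals `A(r)` (the discrete circle areas, clipped to
#' the image) are carried alongside for area normalization.
#'
#' @param mask a [preprocess_to_mask()] result
#' @param center_px `(row, col)` colony centre, 1-based, inside the mask
#' @param r_max largest radius in pixels (>= 1)
#' @return an object of class `radial_profile`: `radii_px` (1..r_max), `W`
#'   (non-decreasing counts), `area_px`, `center_px`
#' @export
radial_profile <- function(mask, center_px, r_max) {
  stopifnot(inherits(mask, "wrinkle_mask"), r_max >= 1)
  bw <- mask$pixels
  nr <- nrow(bw); nc <- ncol(bw)
  if (center_px[1L] < 1 || center_px[1L] > nr ||
      center_px[2L] < 1 || center_px[2L] > nc)
    stop("colony centre outside the mask")
  r_max <- as.integer(r_max)
  r_lo <- max(1L, floor(center_px[1L] - r_max))
  r_hi <- min(nr, ceiling(center_px[1L] + r_max))
  c_lo <- max(1L, floor(center_px[2L] - r_max))
  c_hi <- min(nc, ceiling(center_px[2L] + r_max))
  g <- expand.grid(r = r_lo:r_hi, c = c_lo:c_hi)
  d2 <- (g$r - center_px[1L])^2 + (g$c - center_px[2L])^2
  fg <- bw[cbind(g$r, g$c)]
  radii <- seq_len(r_max)
  d2_fg_sorted <- sort(d2[fg])
  d2_all_sorted <- sort(d2)
  W <- findInterval(radii^2, d2_fg_sorted)
  A <- findInterval(radii^2, d2_all_sorted)
  structure(
    list(radii_px = radii, W = W, area_px = A,
         center_px = as.numeric(center_px)),
    class = "radial_profile"
  )
}

#' Wrinkling density
#'
#' Total wrinkling intensity within the measured colony radius, normalized to
#' colony area: `W(R) / A(R)`, a dimensionless fraction in \[0, 1\].
#'
#' @param profile a [radial_profile()]
#' @param colony_radius_px measured colony radius in pixels (integer within
#'   `1..r_max`; non-integer radii are floored with a warning)
#' @return wrinkling density in \[0, 1\]
#' @export
wrinkling_density <- function(profile, colony_radius_px) {
  stopifnot(inherits(profile, "radial_profile"))
  if (colony_radius_px != floor(colony_radius_px)) {
    warning("colony radius floored to ", floor(colony_radius_px), " px")
    colony_radius_px <- floor(colony_radius_px)
  }
  r_max <- profile$radii_px[length(profile$radii_px)]
  if (colony_radius_px < 1 || colony_radius_px > r_max)
    stop("colony radius ", colony_radius_px, " outside profile range 1..", r_max)
  profile$W[colony_radius_px] / profile$area_px[colony_radius_px]
}

#' Normalize densities to internal controls
#'
#' Every plate carries parent-strain control colonies; densities are divided
#' by the arithmetic mean of the control densities on the same plate, so that
#' a control-like colony scores ~1.
#'
#' @param densities numeric vector of wrinkling densities
#' @param control_positions indices into `densities` marking control colonies
#' @return normalized densities (same length as `densities`)
#' @export
normalize_to_controls <- function(densities, control_positions) {
  stopifnot(is.numeric(densities))
  if (length(control_positions) < 1L)
    stop("at least one control position is required")
  if (any(control_positions < 1 | control_positions > length(densities)))
    stop("control position outside the density vector")
  ctrl <- mean(densities[control_positions])
  if (!is.finite(ctrl) || ctrl <= 0)
    stop("calibration error: mean control density is ", ctrl,
         " (must be positive)")
  densities / ctrl
}

#' Classify colonies by control-normalized density
#'
#' Low wrinklers fall strictly below `low_cutoff` (0.2 relative to internal
#' controls, the screen's published cutoff); colonies strictly above
#' `high_cutoff` are flagged high. The screen curated its high wrinklers
#' manually, so `high_cutoff` has no published default and is `Inf` unless
#' set.
#'
#' @param normalized control-normalized densities
#' @param low_cutoff strict lower cutoff (default 0.2)
#' @param high_cutoff strict upper cutoff (default `Inf`, i.e. disabled)
#' @return factor with levels `low`, `normal`, `high`
#' @export
classify_colonies <- function(normalized, low_cutoff = 0.2, high_cutoff = Inf) {
  stopifnot(is.numeric(normalized), low_cutoff < high_cutoff)
  lab <- ifelse(normalized < low_cutoff, "low",
                ifelse(normalized > high_cutoff, "high", "normal"))
  factor(lab, levels = c("low", "normal", "high"))
}

#' Score wrinkling for every colony on a plate
#'
#' End-to-end wrapper: mask, per-colony radial profiles, densities, control
#' normalization and classification.
#'
#' @param img a [plate_image()]
#' @param grid a [infer_grid()] result
#' @param colony_radius_px measured colony radius in pixels: a single value
#'   or one per colony
#' @param control_positions indices of control colonies (row-major grid
#'   order)
#' @param params a [wrinkle_params()]
#' @param low_cutoff,high_cutoff passed to [classify_colonies()]
#' @return a data.frame with `position`, `row`, `col`, `strain`, `density`,
#'   `normalized_density`, `label`
#' @export
score_wrinkling <- function(img, grid, colony_radius_px, control_positions,
                            params = wrinkle_params(), low_cutoff = 0.2,
                            high_cutoff = Inf) {
  stopifnot(inherits(grid, "colony_grid"))
  n <- nrow(grid$centers_px)
  radii <- rep_len(colony_radius_px, n)
  mask <- preprocess_to_mask(img, params)
  dens <- vapply(seq_len(n), function(k) {
    prof <- radial_profile(mask, grid$centers_px[k, ], ceiling(radii[k]))
    wrinkling_density(prof, floor(radii[k]))
  }, numeric(1))
  norm <- normalize_to_controls(dens, control_positions)
  ij <- expand.grid(j = seq_len(grid$n_cols), i = seq_len(grid$n_rows))
  data.frame(
    position = seq_len(n), row = ij$i, col = ij$j,
    strain = if (is.null(grid$well_labels)) NA_character_ else grid$well_labels,
    density = dens, normalized_density = norm,
    label = classify_colonies(norm, low_cutoff, high_cutoff)
  )
}
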