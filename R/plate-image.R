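#' Plate image container
#'
#' A calibrated grayscale photograph (or fluorescence scan) of a colony array.
#' Pixels are stored as a base-R matrix indexed `[row, col]` with intensities
#' in \[0, 1\]; `mm_per_px` carries the physical scale. All pixel coordinates
#' in this package are 1-based `(row, col)` pairs, and circle membership is
#' Euclidean distance from the pixel centre `<= r`.
#'
#' @param pixels numeric matrix of intensities in \[0, 1\]
#' @param mm_per_px physical scale, millimetres per pixel (> 0)
#' @param plate_id optional plate label
#' @param channel acquisition channel: "visible", "rfp" or "mneongreen"
#' @return an object of class `plate_image`
#' @export
plate_image <- function(pixels, mm_per_px, plate_id = "",
                        channel = c("visible", "rfp", "mneongreen")) {
  channel <- match.arg(channel)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("pixels must be a numeric matrix")
  if (nrow(pixels) == 0L || ncol(pixels) == 0L)
    stop("zero-size image")
  if (!all(is.finite(pixels)))
    stop("pixel values must be finite")
  if (min(pixels) < 0 || max(pixels) > 1)
    stop("pixel values must lie in [0, 1]; rescale before construction")
  if (!is.numeric(mm_per_px) || length(mm_per_px) != 1L || !is.finite(mm_per_px) ||
      mm_per_px <= 0)
    stop("mm_per_px must be a single positive number")
  structure(
    list(pixels = pixels, mm_per_px = mm_per_px,
         plate_id = as.character(plate_id), channel = channel),
    class = "plate_image"
  )
}

#' @export
print.plate_image <- function(x, ...) {
  cat(sprintf("<plate_image> %dx%d px, %.4g mm/px, channel=%s%s\n",
              nrow(x$pixels), ncol(x$pixels), x$mm_per_px, x$channel,
              if (nzchar(x$plate_id)) paste0(", id=", x$plate_id) else ""))
  invisible(x)
}

# ITU-R BT.709 luminance weights for RGB -> grayscale.
.lum_weights <- c(0.2126, 0.7152, 0.0722)

#' Load a plate photograph
#'
#' Reads a TIFF or PNG image, converts multichannel data to grayscale with
#' fixed luminance weights (0.2126, 0.7152, 0.0722; an alpha channel, if
#' present, is dropped), and rescales intensities to \[0, 1\] if the file's
#' native range falls outside it.
#'
#' @param path path to a TIFF or PNG file
#' @param mm_per_px physical scale in mm/pixel (the camera setup is not
#'   self-describing, so the scale is a required input)
#' @param channel acquisition channel label, see [plate_image()]
#' @return a [plate_image()]
#' @export
load_plate_image <- function(path, mm_per_px,
                             channel = c("visible", "rfp", "mneongreen")) {
  channel <- match.arg(channel)
  if (!file.exists(path)) stop("cannot read image file: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '", ext, "' (expected TIFF or PNG): ", path)
  )
  if (length(dim(arr)) == 3L) {
    nch <- dim(arr)[3L]
    if (nch >= 3L) {
      arr <- arr[, , 1L] * .lum_weights[1L] + arr[, , 2L] * .lum_weights[2L] +
        arr[, , 3L] * .lum_weights[3L]
    } else {
      arr <- arr[, , 1L]
    }
  }
  if (!is.matrix(arr)) arr <- as.matrix(arr)
  if (length(arr) == 0L) stop("zero-size image: ", path)
  rng <- range(arr)
  if (rng[1L] < 0 || rng[2L] > 1) {
    arr <- if (rng[2L] > rng[1L]) (arr - rng[1L]) / (rng[2L] - rng[1L])
           else matrix(0, nrow(arr), ncol(arr))
  }
  plate_image(clip01(arr), mm_per_px, plate_id = basename(path), channel = channel)
}

#' Rotate a plate image so the plate edges align with the axes
#'
#' The screen's plate photographs are taken with the dish slightly skewed;
#' downstream grid inference assumes axis-aligned rows and columns. Rotation
#' uses bilinear interpolation about the image centre; samples falling outside
#' the source image take the median border intensity. `angle_deg = 0` returns
#' the input pixels untouched.
#'
#' With `angle_deg = "auto"` the skew is estimated from the plate outline:
#' the image is thresholded at the Otsu level, the largest connected
#' component (the plate) is taken, and the orientation of its minimum-area
#' bounding rectangle (folded into (-45, 45]) gives the correction angle. If
#' no foreground is found the image is returned unrotated with a warning.
#'
#' @param img a [plate_image()]
#' @param angle_deg rotation in degrees, counter-clockwise, in (-45, 45\];
#'   or "auto"
#' @return a rotated [plate_image()] with attribute `angle_deg` recording the
#'   rotation applied
#' @export
rotate_to_axes <- function(img, angle_deg = "auto") {
  stopifnot(inherits(img, "plate_image"))
  if (identical(angle_deg, "auto")) {
    angle_deg <- tryCatch(-estimate_plate_angle(img$pixels), error = function(e) {
      warning("auto-rotation: ", conditionMessage(e), "; falling back to 0")
      0
    })
  }
  stopifnot(is.numeric(angle_deg), length(angle_deg) == 1L)
  if (angle_deg <= -45 || angle_deg > 45)
    stop("rotation angle must lie in (-45, 45] degrees")
  out <- img
  if (angle_deg != 0)
    out$pixels <- clip01(rotate_bilinear(img$pixels, angle_deg))
  attr(out, "angle_deg") <- angle_deg
  out
}

# Bilinear rotation of a matrix by `angle` degrees counter-clockwise about its
# centre (rows increase downward, so the (row, col) frame is left-handed and a
# counter-clockwise image rotation maps output -> source with the plain
# rotation matrix). Out-of-image samples take the median border value.
rotate_bilinear <- function(x, angle) {
  nr <- nrow(x)
  nc <- ncol(x)
  th <- angle * pi / 180
  cr <- (nr + 1) / 2
  cc <- (nc + 1) / 2
  g <- expand.grid(r = seq_len(nr), c = seq_len(nc))
  dr <- g$r - cr
  dc <- g$c - cc
  # inverse mapping: source coordinates for each output pixel
  sr <- cr + cos(th) * dr - sin(th) * dc
  sc <- cc + sin(th) * dr + cos(th) * dc
  pad <- stats::median(c(x[1, ], x[nr, ], x[, 1], x[, nc]))
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  px <- function(ri, ci) {
    ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
    v <- rep(pad, length(ri))
    v[ok] <- x[cbind(ri[ok], ci[ok])]
    v
  }
  v <- (1 - fr) * (1 - fc) * px(r0, c0) + (1 - fr) * fc * px(r0, c0 + 1) +
    fr * (1 - fc) * px(r0 + 1, c0) + fr * fc * px(r0 + 1, c0 + 1)
  matrix(v, nr, nc)
}

# Estimate the skew angle of the dominant rectangular object (the plate):
# Otsu threshold -> largest 8-connected component -> minimum-area bounding
# rectangle over the convex hull -> orientation folded into (-45, 45].
estimate_plate_angle <- function(x) {
  bw <- x > otsu_level(x)
  if (!any(bw)) stop("no detectable plate edge (empty threshold)")
  lab <- label_components(bw, connectivity = 8)
  tab <- tabulate(lab[lab > 0L])
  keep <- which.max(tab)
  idx <- which(lab == keep)
  rr <- ((idx - 1L) %% nrow(x)) + 1L
  cc <- ((idx - 1L) %/% nrow(x)) + 1L
  pts <- cbind(rr, cc)
  hull <- pts[grDevices::chull(pts), , drop = FALSE]
  if (nrow(hull) < 3L) stop("no detectable plate edge (degenerate component)")
  # the minimum-area rectangle shares an orientation with a hull edge
  n <- nrow(hull)
  e <- hull[c(2:n, 1L), ] - hull
  ang <- atan2(e[, 1L], e[, 2L])  # edge angle in the (row, col) frame
  best_area <- Inf
  best_ang <- 0
  for (a in unique(round(ang, 12))) {
    u <- c(cos(a), sin(a))
    v <- c(-sin(a), cos(a))
    pu <- hull[, 2L] * u[1L] + hull[, 1L] * u[2L]
    pv <- hull[, 2L] * v[1L] + hull[, 1L] * v[2L]
    area <- diff(range(pu)) * diff(range(pv))
    if (area < best_area) {
      best_area <- area
      best_ang <- a
    }
  }
  deg <- best_ang * 180 / pi
  # fold into (-45, 45]: the rectangle is the same every 90 degrees
  deg <- ((deg + 45) %% 90) - 45
  if (deg == -45) deg <- 45
  deg
}
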