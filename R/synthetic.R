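# Synthetic fixtures with known ground truth: gridded plate images with
# wrinkle ridges, exponential outgrowth curves, and Poisson dilution spot
# counts. Every generator is a pure function of its spec and seed.

#' Synthetic plate specification
#'
#' Describes a gridded colony plate image. Defaults emulate the screen's
#' setup: a 96-position (8 x 12) array at 9 mm spacing, imaged at 10 px/mm,
#' with ~2.5 mm-radius colonies. Each colony is a flat-topped dome with a
#' smooth cosine shoulder; wrinkle ridges are random curvilinear arcs of
#' width `ridge_width_px` (narrow relative to the opening disc, so they
#' survive background subtraction) drawn until the target fraction of colony
#' pixels carries ridge. A thin bright frame marks the plate wall, a smooth
#' planar gradient emulates uneven illumination, and additive Gaussian noise
#' (clipped to \[0, 1\]) emulates sensor noise.
#'
#' @param n_rows,n_cols grid shape (default 8 x 12)
#' @param spacing_mm colony spacing (default 9 mm)
#' @param mm_per_px pixel scale (default 0.1 mm/px)
#' @param margin_mm margin between the outer colony centres and the image
#'   edge (default 6 mm)
#' @param colony_radius_mm colony radius (default 2.5 mm; must satisfy
#'   `2 * radius < spacing`)
#' @param base_intensity colony plateau intensity (default 0.55)
#' @param background agar background intensity (default 0.25)
#' @param wrinkle_fraction target fraction of colony pixels carrying ridges,
#'   scalar or one value per colony in row-major order (default 0)
#' @param ridge_width_px ridge width (default 3 px)
#' @param ridge_contrast added intensity of a ridge (default 0.25)
#' @param gradient_amplitude peak-to-peak planar illumination gradient
#'   (default 0.05)
#' @param noise_sd additive Gaussian noise SD (default 0.005)
#' @param frame_contrast added intensity of the plate-wall frame
#'   (default 0.3)
#' @param frame_width_px frame thickness (default 4 px)
#' @param seed RNG seed (mandatory)
#' @return an object of class `synth_plate_spec`
#' @export
synth_plate_spec <- function(n_rows = 8, n_cols = 12, spacing_mm = 9,
                             mm_per_px = 0.1, margin_mm = 6,
                             colony_radius_mm = 2.5, base_intensity = 0.55,
                             background = 0.25, wrinkle_fraction = 0,
                             ridge_width_px = 3, ridge_contrast = 0.25,
                             gradient_amplitude = 0.05, noise_sd = 0.005,
                             frame_contrast = 0.3, frame_width_px = 4,
                             seed) {
  if (missing(seed)) stop("seed is mandatory")
  n <- n_rows * n_cols
  wf <- rep_len(wrinkle_fraction, n)
  stopifnot(all(wf >= 0), all(wf <= 1), 2 * colony_radius_mm < spacing_mm,
            margin_mm > colony_radius_mm, mm_per_px > 0,
            base_intensity > background, ridge_width_px >= 1, noise_sd >= 0)
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         spacing_mm = spacing_mm, mm_per_px = mm_per_px, margin_mm = margin_mm,
         colony_radius_mm = colony_radius_mm, base_intensity = base_intensity,
         background = background, wrinkle_fraction = wf,
         ridge_width_px = ridge_width_px, ridge_contrast = ridge_contrast,
         gradient_amplitude = gradient_amplitude, noise_sd = noise_sd,
         frame_contrast = frame_contrast, frame_width_px = frame_width_px,
         seed = as.integer(seed)),
    class = "synth_plate_spec"
  )
}

#' Generate a synthetic plate image with wrinkle ground truth
#'
#' @param spec a [synth_plate_spec()]
#' @return a list:
#'   \describe{
#'     \item{image}{a [plate_image()]}
#'     \item{grid}{the matching [infer_grid()] result}
#'     \item{truth}{list with `ridge_mask` (logical matrix of true ridge
#'       pixels), `wrinkle_fraction` (achieved fraction per colony),
#'       `colony_radius_px`}
#'   }
#' @export
synth_plate_image <- function(spec) {
  stopifnot(inherits(spec, "synth_plate_spec"))
  with_seed(spec$seed, {
    pitch <- spec$spacing_mm / spec$mm_per_px
    margin <- spec$margin_mm / spec$mm_per_px
    R <- spec$colony_radius_mm / spec$mm_per_px
    nr <- as.integer(round((spec$n_rows - 1) * pitch + 2 * margin))
    nc <- as.integer(round((spec$n_cols - 1) * pitch + 2 * margin))
    ij <- expand.grid(j = seq_len(spec$n_cols), i = seq_len(spec$n_rows))
    centers <- cbind(row = margin + (ij$i - 1) * pitch,
                     col = margin + (ij$j - 1) * pitch)
    if (any(centers[, 1L] - R < 1 | centers[, 1L] + R > nr |
            centers[, 2L] - R < 1 | centers[, 2L] + R > nc))
      stop("colonies do not fit inside the image")

    img <- matrix(spec$background, nr, nc)
    # uneven illumination: planar gradient, peak-to-peak = gradient_amplitude
    gr <- matrix(rep((seq_len(nr) - 1) / max(1, nr - 1), nc), nr, nc)
    gc <- matrix(rep((seq_len(nc) - 1) / max(1, nc - 1), each = nr), nr, nc)
    img <- img + spec$gradient_amplitude * ((gr + gc) / 2 - 0.5)
    # plate wall: thin bright rectangular frame inset half a margin
    inset <- max(2L, as.integer(round(margin / 3)))
    w <- as.integer(spec$frame_width_px)
    frame <- matrix(FALSE, nr, nc)
    frame[inset:(inset + w - 1L), inset:(nc - inset + 1L)] <- TRUE
    frame[(nr - inset - w + 2L):(nr - inset + 1L), inset:(nc - inset + 1L)] <- TRUE
    frame[inset:(nr - inset + 1L), inset:(inset + w - 1L)] <- TRUE
    frame[inset:(nr - inset + 1L), (nc - inset - w + 2L):(nc - inset + 1L)] <- TRUE
    img[frame] <- img[frame] + spec$frame_contrast

    ridge_mask <- matrix(FALSE, nr, nc)
    achieved <- numeric(nrow(centers))
    for (k in seq_len(nrow(centers))) {
      ctr <- centers[k, ]
      r_lo <- floor(ctr[1L] - R); r_hi <- ceiling(ctr[1L] + R)
      c_lo <- floor(ctr[2L] - R); c_hi <- ceiling(ctr[2L] + R)
      rows <- r_lo:r_hi; cols <- c_lo:c_hi
      d <- sqrt(outer((rows - ctr[1L])^2, (cols - ctr[2L])^2, `+`))
      # flat-topped dome: plateau to 0.7 R, cosine shoulder to the rim
      s <- matrix(0, length(rows), length(cols))
      s[d <= 0.7 * R] <- 1
      sh <- d > 0.7 * R & d <= R
      s[sh] <- 0.5 * (1 + cos(pi * (d[sh] - 0.7 * R) / (0.3 * R)))
      img[rows, cols] <- img[rows, cols] + (spec$base_intensity - spec$background) * s
      # ridges: random quadratic Bezier arcs until the target pixel fraction
      n_col_px <- sum(d <= R)
      target <- spec$wrinkle_fraction[k] * n_col_px
      local <- matrix(FALSE, length(rows), length(cols))
      iter <- 0L
      while (sum(local) < target && iter < 400L) {
        iter <- iter + 1L
        local <- local | ridge_arc(length(rows), length(cols),
                                   c(ctr[1L] - r_lo + 1, ctr[2L] - c_lo + 1),
                                   0.85 * R, spec$ridge_width_px)
      }
      local <- local & d <= 0.95 * R  # keep ridges inside the colony body
      img[rows, cols][local] <- img[rows, cols][local] + spec$ridge_contrast
      ridge_mask[rows, cols] <- ridge_mask[rows, cols] | local
      achieved[k] <- sum(local) / n_col_px
    }
    if (spec$noise_sd > 0)
      img <- img + matrix(stats::rnorm(nr * nc, 0, spec$noise_sd), nr, nc)
    pimg <- plate_image(clip01(img), spec$mm_per_px, plate_id = "synthetic")
    grid <- infer_grid(pimg, centers[1L, ], spec$n_rows, spec$n_cols,
                       spacing_mm = spec$spacing_mm)
    list(image = pimg,
         grid = grid,
         truth = list(ridge_mask = ridge_mask, wrinkle_fraction = achieved,
                      colony_radius_px = R))
  })
}

# One random curvilinear ridge: a quadratic Bezier through three random
# points inside the colony, rasterized by stamping width/2-radius discs along
# a dense sampling of the curve.
ridge_arc <- function(nr, nc, center, r_spread, width_px) {
  p <- replicate(3, {
    a <- stats::runif(1, 0, 2 * pi)
    rr <- r_spread * sqrt(stats::runif(1))
    center + rr * c(cos(a), sin(a))
  })
  tt <- seq(0, 1, length.out = 120L)
  b1 <- (1 - tt)^2; b2 <- 2 * tt * (1 - tt); b3 <- tt^2
  cr <- b1 * p[1L, 1L] + b2 * p[1L, 2L] + b3 * p[1L, 3L]
  cc <- b1 * p[2L, 1L] + b2 * p[2L, 2L] + b3 * p[2L, 3L]
  m <- matrix(FALSE, nr, nc)
  half <- width_px / 2
  hw <- ceiling(half)
  off <- expand.grid(dr = -hw:hw, dc = -hw:hw)
  off <- off[off$dr^2 + off$dc^2 <= half^2, , drop = FALSE]
  rr <- rep(round(cr), each = nrow(off)) + off$dr
  cc2 <- rep(round(cc), each = nrow(off)) + off$dc
  ok <- rr >= 1 & rr <= nr & cc2 >= 1 & cc2 <= nc
  m[cbind(rr[ok], cc2[ok])] <- TRUE
  m
}

#' Synthetic growth-curve specification
#'
#' An exponential outgrowth curve from `N0` initial cells (or germinating
#' spores): flat at the pre-germination level until `lag_offset_h`, then
#' doubling every `doubling_time_min` minutes, saturating at
#' `carrying_capacity_od`, with additive Gaussian noise. `od_per_cell`
#' converts cells in the well to OD600 (default 6.25e-9: OD 1 at ~1.6e8
#' cells in a 200 uL well, i.e. ~8e8 cells/mL).
#'
#' @param N0 initial cell/spore count in the well
#' @param doubling_time_min doubling time (default 20 min)
#' @param lag_offset_h germination/adaptation delay before exponential growth
#'   (default 1 h)
#' @param carrying_capacity_od OD plateau (default 1.4)
#' @param od_per_cell OD per cell in the well (default 6.25e-9)
#' @param sampling_interval_h reader sampling interval (default 0.25 h)
#' @param duration_h total observation time (default 24 h)
#' @param noise_sd additive OD noise SD (default 0.003)
#' @param seed RNG seed (mandatory)
#' @return an object of class `synth_curve_spec`
#' @export
synth_curve_spec <- function(N0 = 1e4, doubling_time_min = 20,
                             lag_offset_h = 1, carrying_capacity_od = 1.4,
                             od_per_cell = 6.25e-9,
                             sampling_interval_h = 0.25, duration_h = 24,
                             noise_sd = 0.003, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(N0 >= 0, doubling_time_min > 0, lag_offset_h >= 0,
            carrying_capacity_od > 0, od_per_cell > 0,
            sampling_interval_h > 0, duration_h > sampling_interval_h,
            noise_sd >= 0)
  structure(
    list(N0 = N0, doubling_time_min = doubling_time_min,
         lag_offset_h = lag_offset_h,
         carrying_capacity_od = carrying_capacity_od,
         od_per_cell = od_per_cell,
         sampling_interval_h = sampling_interval_h, duration_h = duration_h,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "synth_curve_spec"
  )
}

# Deterministic curve + closed-form truth (no RNG).
synth_growth_curve_impl <- function(spec, N0 = spec$N0, well = "synthetic") {
  t <- seq(0, spec$duration_h, by = spec$sampling_interval_h)
  td_h <- spec$doubling_time_min / 60
  od0 <- spec$od_per_cell * N0
  od <- if (N0 <= 0) rep(0, length(t)) else
    pmin(spec$carrying_capacity_od,
         od0 * 2^(pmax(0, t - spec$lag_offset_h) / td_h))
  if (spec$noise_sd > 0)
    od <- pmax(od + stats::rnorm(length(t), 0, spec$noise_sd), 0)
  thr <- 0.2
  true_lag <- if (N0 <= 0 || spec$carrying_capacity_od < thr) NA_real_
    else if (od0 >= thr) 0
    else spec$lag_offset_h + td_h * log2(thr / od0)
  list(curve = growth_curve(t, od, well = well, blanked = TRUE),
       truth = list(N0 = N0, true_lag_h = true_lag,
                    doubling_time_min = spec$doubling_time_min,
                    lag_offset_h = spec$lag_offset_h))
}

#' Generate a synthetic outgrowth curve
#'
#' @param spec a [synth_curve_spec()]
#' @return a list with `curve` (a [growth_curve()], blanked) and `truth`
#'   (`N0`, `true_lag_h` — the closed-form time to OD 0.2, NA if never
#'   reached — and the generating parameters)
#' @export
synth_growth_curve <- function(spec) {
  stopifnot(inherits(spec, "synth_curve_spec"))
  with_seed(spec$seed, synth_growth_curve_impl(spec))
}

#' Generate a 10-fold dilution series of outgrowth curves
#'
#' Emulates the spore-dilution experiment: a post-heat-kill culture is
#' serially diluted 10-fold and each dilution is grown out. The expected
#' spore count in dilution `k` is `base_spore_count * 10^-(k-1)`; with
#' `sample_poisson = TRUE` the realized inoculum is a Poisson draw (so
#' sub-single-spore dilutions yield flat curves with probability
#' `exp(-lambda)`), with `FALSE` the expected count is used exactly
#' (noise-free closed-form checks).
#'
#' @param base_spore_count expected spores in the undiluted inoculum
#' @param n_dilutions number of 10-fold dilutions (including the undiluted
#'   inoculum)
#' @param spec a [synth_curve_spec()] (its `N0` is ignored; its seed governs
#'   the whole series)
#' @param sample_poisson draw inocula from Poisson(lambda)? (default TRUE)
#' @return a list with `curves` (list of [growth_curve()]) and `truth`
#'   (data.frame: `dilution`, `expected_spores`, `spores`, `true_lag_h`)
#' @export
synth_outgrowth_series <- function(base_spore_count, n_dilutions, spec,
                                   sample_poisson = TRUE) {
  stopifnot(inherits(spec, "synth_curve_spec"), base_spore_count >= 0,
            n_dilutions >= 1)
  with_seed(spec$seed, {
    lam <- base_spore_count * 10^(-(seq_len(n_dilutions) - 1))
    n0 <- if (sample_poisson) stats::rpois(n_dilutions, lam) else lam
    sims <- lapply(seq_len(n_dilutions), function(k)
      synth_growth_curve_impl(spec, N0 = n0[k],
                              well = sprintf("dilution_%d", k)))
    list(curves = lapply(sims, `[[`, "curve"),
         truth = data.frame(
           dilution = 10^(-(seq_len(n_dilutions) - 1)),
           expected_spores = lam, spores = n0,
           true_lag_h = vapply(sims, function(s) s$truth$true_lag_h,
                               numeric(1))))
  })
}

#' Generate Poisson spot counts for a dilution series
#'
#' Counts are drawn as `Poisson(true_cfu_per_ml * spot_volume_mL *
#' dilution_factor)`, the sampling model of colony counting.
#'
#' @param true_cfu_per_ml true concentration of the undiluted sample
#' @param dilution_factors strictly decreasing dilution factors
#'   (default `10^(0:-5)`)
#' @param spot_volume_uL spotted volume (default 10 uL)
#' @param seed RNG seed
#' @param countable_range passed to [spot_count_series()]
#' @return a list with `series` (a [spot_count_series()]) and `truth`
#'   (`true_cfu_per_ml`, `expected_counts`)
#' @export
synth_spot_counts <- function(true_cfu_per_ml, dilution_factors = 10^(0:-5),
                              spot_volume_uL = 10, seed,
                              countable_range = c(3, 30)) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(true_cfu_per_ml >= 0)
  lam <- true_cfu_per_ml * spot_volume_uL * 1e-3 * dilution_factors
  counts <- with_seed(seed, stats::rpois(length(lam), lam))
  list(series = spot_count_series(dilution_factors, counts, spot_volume_uL,
                                  countable_range),
       truth = list(true_cfu_per_ml = true_cfu_per_ml,
                    expected_counts = lam))
}
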