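# Wrinkle mask pipeline, radial profiles, density, normalization and
# classification, checked against brute-force oracles and on synthetic plates.

test_that("mask pipeline: flat fields, planted ridges, small components", {
  p <- wrinkle_params(disk_radius_px = 5, min_component_px = 50)
  # constant image: opening equals the image, residual 0, empty mask
  expect_false(any(preprocess_to_mask(pim(matrix(0.37, 40, 40)), p)$pixels))
  # narrow bright ridge (width 3 < disc diameter) survives opening exactly
  m <- matrix(0.2, 60, 80)
  ridge <- cbind(rep(20:22, each = 67), rep(7:73, 3))  # 3 x 67 = 201 px
  m[ridge] <- 0.7
  mask <- preprocess_to_mask(pim(m), p)
  planted <- matrix(FALSE, 60, 80); planted[ridge] <- TRUE
  expect_identical(unname(mask$pixels), planted)
  expect_identical(unname(mask$pixels), unname(oracle_mask(m, p)))
  # a supra-threshold component of 49 px is removed
  m2 <- matrix(0.2, 60, 80)
  m2[30, 11:59] <- 0.7  # 49-px line
  expect_false(any(preprocess_to_mask(pim(m2), p)$pixels))
  # image smaller than the structuring element is rejected
  expect_error(preprocess_to_mask(pim(matrix(0.5, 8, 8)), p), "structuring")
})

test_that("mask equals the brute-force oracle on random images", {
  set.seed(101)
  p_small <- wrinkle_params(disk_radius_px = 4, min_component_px = 20)
  for (i in 1:25) {
    nr <- sample(20:48, 1); nc <- sample(20:48, 1)
    x <- matrix(runif(nr * nc), nr, nc)
    # add a few bright narrow bars so the mask is non-trivial
    for (b in 1:3) {
      r0 <- sample(nr - 2, 1); c0 <- sample(nc - 8, 1)
      x[r0:(r0 + 1), c0:(c0 + 7)] <- x[r0:(r0 + 1), c0:(c0 + 7)] + 1
    }
    x <- x / max(x)
    got <- preprocess_to_mask(pim(x), p_small)$pixels
    expect_identical(unname(got), unname(oracle_mask(x, p_small)))
  }
})

test_that("8-connected labeling matches flood fill and differs from 4-connectivity", {
  set.seed(7)
  for (i in 1:10) {
    bw <- matrix(runif(30 * 30) < 0.35, 30, 30)
    for (conn in c(8, 4)) {
      got <- label_components(bw, conn)
      want <- oracle_label(bw, conn)
      # same partition: label images agree up to renaming
      expect_equal(max(got), max(want))
      expect_true(all(tapply(want[bw], got[bw], function(v) length(unique(v))) == 1))
    }
  }
  # two diagonal pixels: one component at 8-connectivity, two at 4
  bw <- matrix(FALSE, 3, 3); bw[1, 1] <- bw[2, 2] <- TRUE
  expect_equal(max(label_components(bw, 8)), 1L)
  expect_equal(max(label_components(bw, 4)), 2L)
})

test_that("radial profile counts foreground pixels exactly", {
  p <- wrinkle_params(disk_radius_px = 3, min_component_px = 0)
  empty <- structure(list(pixels = matrix(FALSE, 21, 21), params = p),
                     class = "wrinkle_mask")
  prof0 <- radial_profile(empty, c(11, 11), 8)
  expect_true(all(prof0$W == 0))
  full <- structure(list(pixels = matrix(TRUE, 21, 21), params = p),
                    class = "wrinkle_mask")
  prof1 <- radial_profile(full, c(11, 11), 8)
  expect_equal(prof1$W[5], 81L)  # lattice pixels with distance <= 5
  for (r in c(1, 3, 5, 8))
    expect_equal(prof1$W[r], oracle_circle_count(full$pixels, c(11, 11), r))
  # monotone in r, bounded by the discrete circle area
  set.seed(3)
  rnd <- structure(list(pixels = matrix(runif(441) < 0.4, 21, 21), params = p),
                   class = "wrinkle_mask")
  prof <- radial_profile(rnd, c(11, 11), 10)
  expect_true(all(diff(prof$W) >= 0))
  expect_true(all(prof$W <= prof$area_px))
  for (r in c(2, 6, 10))
    expect_equal(prof$W[r], oracle_circle_count(rnd$pixels, c(11, 11), r))
  expect_error(radial_profile(rnd, c(40, 11), 5), "outside")
})

test_that("wrinkling density is W(R)/A(R) in [0,1]", {
  p <- wrinkle_params()
  full <- structure(list(pixels = matrix(TRUE, 41, 41), params = p),
                    class = "wrinkle_mask")
  expect_equal(wrinkling_density(radial_profile(full, c(21, 21), 15), 15), 1.0)
  none <- structure(list(pixels = matrix(FALSE, 41, 41), params = p),
                    class = "wrinkle_mask")
  expect_equal(wrinkling_density(radial_profile(none, c(21, 21), 15), 15), 0.0)
  # half-plane through the centre: density 1/2 up to the centre row
  half <- matrix(FALSE, 41, 41); half[1:20, ] <- TRUE
  hm <- structure(list(pixels = half, params = p), class = "wrinkle_mask")
  R <- 15
  d <- wrinkling_density(radial_profile(hm, c(21, 21), R), R)
  expect_lt(abs(d - 0.5), 2 / R)
  expect_equal(d, oracle_circle_count(half, c(21, 21), R) /
                    oracle_circle_count(matrix(TRUE, 41, 41), c(21, 21), R))
  expect_error(wrinkling_density(radial_profile(hm, c(21, 21), 10), 12), "range")
})

test_that("control normalization and the 0.2 low-wrinkler cutoff", {
  dens <- c(0.10, 0.015, 0.10, 0.30)
  norm <- normalize_to_controls(dens, control_positions = c(1, 3))
  expect_equal(norm, c(1.0, 0.15, 1.0, 3.0))
  lab <- classify_colonies(norm, low_cutoff = 0.2, high_cutoff = 2.0)
  expect_equal(as.character(lab), c("normal", "low", "normal", "high"))
  # homogeneous plate normalizes to all ones, controls are normal
  expect_equal(normalize_to_controls(rep(0.2, 5), 1:2), rep(1, 5))
  # a value exactly at the cutoff is not low (strict "<")
  expect_equal(as.character(classify_colonies(0.2)), "normal")
  expect_error(normalize_to_controls(c(0, 0, 0.5), 1:2), "calibration")
  expect_error(normalize_to_controls(numeric(0), integer(0)), "control")
  expect_error(classify_colonies(1, low_cutoff = 2, high_cutoff = 1))
})

test_that("mask is scale-invariant and keeps no component under the minimum", {
  syn <- synth_plate_image(synth_plate_spec(
    n_rows = 1, n_cols = 3, wrinkle_fraction = c(0, 0.1, 0.3), seed = 5,
    base_intensity = 0.3, background = 0.12, ridge_contrast = 0.12,
    frame_contrast = 0.15))
  x <- syn$image$pixels  # max well below 1/2 so scaling stays in range
  p <- wrinkle_params()
  m1 <- preprocess_to_mask(pim(x), p)$pixels
  m2 <- preprocess_to_mask(pim(2 * x), p)$pixels
  expect_identical(m1, m2)
  # post-condition: every surviving component has >= 50 px (oracle labeling)
  lab <- oracle_label(m1, 8)
  if (max(lab) > 0) expect_gte(min(tabulate(lab[lab > 0])), 50)
})

test_that("smooth illumination gradients barely change measured density", {
  base <- synth_plate_spec(n_rows = 1, n_cols = 3,
                           wrinkle_fraction = c(0.05, 0.15, 0.3),
                           gradient_amplitude = 0, noise_sd = 0, seed = 9)
  grad <- synth_plate_spec(n_rows = 1, n_cols = 3,
                           wrinkle_fraction = c(0.05, 0.15, 0.3),
                           gradient_amplitude = 0.08, noise_sd = 0, seed = 9)
  dens_of <- function(spec) {
    syn <- synth_plate_image(spec)
    mask <- preprocess_to_mask(syn$image)
    R <- floor(syn$truth$colony_radius_px)
    vapply(seq_len(3), function(k)
      wrinkling_density(radial_profile(mask, syn$grid$centers_px[k, ], R), R),
      numeric(1))
  }
  expect_true(all(abs(dens_of(grad) - dens_of(base)) < 0.02))
})

test_that("score_wrinkling runs the pipeline end to end", {
  fr <- c(0.2, 0, 0.2, 0.6)
  syn <- synth_plate_image(synth_plate_spec(n_rows = 2, n_cols = 2,
                                            wrinkle_fraction = fr, seed = 21))
  res <- score_wrinkling(syn$image, syn$grid,
                         colony_radius_px = floor(syn$truth$colony_radius_px),
                         control_positions = c(1, 3), high_cutoff = 2)
  expect_equal(nrow(res), 4L)
  expect_equal(as.character(res$label), c("normal", "low", "normal", "high"))
  expect_equal(mean(res$normalized_density[c(1, 3)]), 1)
})
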