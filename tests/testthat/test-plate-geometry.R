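# Plate image loading, rotation, grid inference, colony size and fluorescence.

test_that("image loading converts and rescales to [0,1] grayscale", {
  d <- withr::local_tempdir()
  # constant mid-gray
  f1 <- file.path(d, "gray.png")
  png::writePNG(matrix(0.5, 20, 30), f1)
  img <- load_plate_image(f1, mm_per_px = 0.1)
  expect_equal(dim(img$pixels), c(20L, 30L))
  expect_equal(max(img$pixels) - min(img$pixels), 0)
  # 8-bit endpoints map to 0 and 1
  f2 <- file.path(d, "bw.png")
  png::writePNG(matrix(c(0, 1), 2, 2), f2)
  img2 <- load_plate_image(f2, 0.1)
  expect_setequal(unique(as.numeric(img2$pixels)), c(0, 1))
  # RGB with R=G=B equals the grayscale load
  m <- matrix(runif(15 * 12), 15, 12)
  f3 <- file.path(d, "rgb.png"); f4 <- file.path(d, "g.png")
  png::writePNG(array(rep(m, 3), c(15, 12, 3)), f3)
  png::writePNG(m, f4)
  expect_equal(load_plate_image(f3, 0.1)$pixels,
               load_plate_image(f4, 0.1)$pixels, tolerance = 1e-6)
  # tiff path gives the same pixels as png
  f5 <- file.path(d, "g.tif")
  tiff::writeTIFF(m, f5, bits.per.sample = 16L)
  expect_equal(load_plate_image(f5, 0.1)$pixels,
               load_plate_image(f4, 0.1)$pixels, tolerance = 0.005)
  expect_error(load_plate_image(file.path(d, "missing.png"), 0.1), "cannot read")
  expect_error(load_plate_image(f1, -1), "mm_per_px")
})

test_that("rotation is exact at 0, invertible, and auto-recovers a known skew", {
  x <- matrix(0.1, 200, 200)
  x[80:120, 40:160] <- 0.9  # axis-aligned bright rectangle (the plate)
  img <- pim(x)
  expect_identical(rotate_to_axes(img, 0)$pixels, img$pixels)
  r7 <- rotate_to_axes(img, 7)
  auto <- rotate_to_axes(r7, "auto")
  expect_lt(abs(attr(auto, "angle_deg") - (-7)), 0.5)
  back <- rotate_to_axes(r7, -7)
  expect_lt(mean(abs(back$pixels - img$pixels)), 0.02)
  expect_error(rotate_to_axes(img, 60), "angle")
  # featureless image: auto falls back to 0 with a warning
  flat <- pim(matrix(0, 30, 30))
  expect_warning(auto0 <- rotate_to_axes(flat, "auto"), "falling back")
  expect_identical(attr(auto0, "angle_deg"), 0)
})

test_that("grid inference is exact lattice arithmetic", {
  img <- pim(matrix(0.5, 300, 300))
  g <- infer_grid(img, c(100, 100), 2, 2, spacing_mm = 5)  # 5 mm at 10 px/mm = 50 px
  expect_equal(g$centers_px,
               cbind(row = c(100, 100, 150, 150), col = c(100, 150, 100, 150)),
               ignore_attr = TRUE)
  # pitch from the 9 mm spacing at 10 px/mm
  g9 <- infer_grid(img, c(50, 50), 2, 2, spacing_mm = 9)
  expect_equal(g9$pitch_px, 90)
  # degenerate 1x1 grid
  g1 <- infer_grid(img, c(42, 17), 1, 1)
  expect_equal(g1$centers_px, cbind(row = 42, col = 17), ignore_attr = TRUE)
  # out-of-bounds centre names the offending grid position
  expect_error(infer_grid(img, c(250, 250), 2, 2, spacing_mm = 9),
               "\\(1, 2\\)")
  # corner recoverable from any inferred centre to machine precision
  gg <- infer_grid(img, c(13.25, 27.5), 3, 4, spacing_mm = 8.7)
  ij <- expand.grid(j = 1:4, i = 1:3)
  for (k in seq_len(12)) {
    corner <- gg$centers_px[k, ] - (c(ij$i[k], ij$j[k]) - 1) * gg$pitch_px
    expect_equal(unname(corner), c(13.25, 27.5), tolerance = 1e-12)
  }
})

test_that("diagonal diameter measurement matches the generated disc", {
  m <- draw_disc(matrix(0.1, 201, 201), c(101, 101), 40, 0.8)
  img <- pim(m)  # 10 px/mm
  d <- measure_colony_diameter(img, c(101, 101))
  expect_lt(abs(d - 8.0), 0.2)
  # invariant to a constant intensity offset (threshold is relative)
  expect_equal(measure_colony_diameter(pim(m + 0.1), c(101, 101)), d,
               tolerance = 1e-9)
  # symmetric under 90-degree rotation of the image (within 1 px = 0.1 mm)
  d_rot <- measure_colony_diameter(pim(t(m[, ncol(m):1])), c(101, 101))
  expect_lt(abs(d_rot - d), 0.1)
  # uniform background: nothing crosses the threshold
  expect_equal(measure_colony_diameter(pim(matrix(0.5, 50, 50)), c(25, 25)), 0)
  expect_error(measure_colony_diameter(img, c(1, 101)), "inside")
})

test_that("colony fluorescence normalization and per-area arithmetic", {
  m <- draw_disc(matrix(0.1, 101, 101), c(51, 51), 20, 0.6)
  img <- pim(m)
  # raw equal to blank -> 0; raw equal to reference -> 1
  expect_equal(colony_fluorescence(img, c(51, 51), 15, 0.6, 0.9), 0)
  expect_equal(colony_fluorescence(img, c(51, 51), 15, 0.1, 0.6), 1)
  # 20-fold lower expression measures 0.05 relative to the full reporter
  m2 <- draw_disc(matrix(0.1, 101, 101), c(51, 51), 20, 0.125)
  expect_equal(colony_fluorescence(pim(m2), c(51, 51), 15, 0.1, 0.6), 0.05)
  # per-area: constant disc, blank 0 -> value / mm_per_px^2
  v <- colony_fluorescence(img, c(51, 51), 15, 0, mode = "per_area")
  expect_equal(v, 0.6 / 0.1^2)
  expect_error(colony_fluorescence(img, c(51, 51), 15, 0.3, 0.3), "calibration")
  # invariance under affine rescaling when blank/reference come from the image
  a <- 0.8; b <- 0.05
  img_r <- pim(a * m + b)
  raw  <- colony_fluorescence(img,   c(51, 51), 15, 0, 1)
  rawr <- colony_fluorescence(img_r, c(51, 51), 15, 0, 1)
  norm  <- (raw - 0.1) / (0.6 - 0.1)           # blank/ref measured on img
  normr <- (rawr - (a * 0.1 + b)) / ((a * 0.6 + b) - (a * 0.1 + b))
  expect_equal(normr, norm, tolerance = 1e-12)
})

test_that("measure_plate returns one row per grid position", {
  m <- matrix(0.1, 260, 260)
  for (ctr in list(c(80, 80), c(80, 170), c(170, 80), c(170, 170)))
    m <- draw_disc(m, ctr, 25, 0.8)
  img <- pim(m)
  g <- infer_grid(img, c(80, 80), 2, 2, spacing_mm = 9,
                  well_labels = c("wt", "a", "b", "wt"))
  res <- measure_plate(img, g, radius_px = 30, blank_value = 0.1,
                       reference_value = 0.8)
  expect_equal(nrow(res), 4L)
  expect_equal(res$strain, c("wt", "a", "b", "wt"))
  expect_true(all(abs(res$diameter_mm - 5.0) < 0.3))
  expect_true(all(res$fluorescence > 0.5))
})
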