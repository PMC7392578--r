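test_that("Bruch detection is exact without noise and robust under speckle", {
  clean <- gen_bscan(small_truth(noise_sd = 0), small_geometry(),
                     blur_sigma = 0, speckle_sd = 0)
  det <- detect_bruch(clean$image)
  expect_true(all(abs(det - clean$bruch_rows) <= 1))
  expect_length(attr(det, "flagged"), 0)

  speckled <- gen_bscan(small_truth(noise_sd = 0), small_geometry(),
                        blur_sigma = 1, speckle_sd = 0.08, seed = 5)
  det2 <- detect_bruch(speckled$image)
  frac_ok <- mean(abs(det2 - speckled$bruch_rows) <= 2)
  expect_gte(frac_ok, 0.95)
})

test_that("a contrast-free image raises a segmentation failure", {
  flat <- bscan(matrix(0.5, 64, 64), 4, 20)
  expect_error(detect_bruch(flat), "segmentation failure")
  expect_error(segment_ilm(flat, reference_row = 48), "segmentation failure")
})

test_that("flattening is the identity when Bruch already sits at the reference", {
  sim <- gen_bscan(small_truth(noise_sd = 0), small_geometry(),
                   blur_sigma = 0, speckle_sd = 0)
  ref <- sim$bruch_rows[1]  # constant Bruch in the default geometry
  flat <- flatten_bscan(sim$image, sim$bruch_rows, reference_row = ref)
  expect_identical(flat$intensity, sim$image$intensity)
  expect_true(all(attr(flat, "shifts") == 0))
})

test_that("flattening a tilted Bruch leaves it constant within quantization", {
  geom <- small_geometry(bruch_tilt_px = 30, bruch_row = 100)
  sim <- gen_bscan(small_truth(noise_sd = 0), geom,
                   blur_sigma = 0, speckle_sd = 0)
  flat <- flatten_bscan(sim$image, sim$bruch_rows, reference_row = 120)
  redet <- detect_bruch(flat)
  expect_true(all(abs(redet - 120) <= 1))
  # idempotence: flattening the flattened image changes nothing
  flat2 <- flatten_bscan(flat, detect_bruch(flat), reference_row = 120)
  expect_true(all(abs(attr(flat2, "shifts")) <= 1))
})

test_that("a constant Bruch offset shifts every column by exactly that offset", {
  sim <- gen_bscan(small_truth(noise_sd = 0), small_geometry(),
                   blur_sigma = 0, speckle_sd = 0)
  ref <- sim$bruch_rows[1]
  flat <- flatten_bscan(sim$image, sim$bruch_rows + 5, reference_row = ref + 10)
  expect_true(all(attr(flat, "shifts") == 5))
})

test_that("ILM tracing recovers the ground truth contour", {
  geom <- small_geometry()
  sim <- gen_bscan(small_truth(noise_sd = 0), geom,
                   blur_sigma = 0, speckle_sd = 0)
  ref <- 130
  flat <- flatten_bscan(sim$image, sim$bruch_rows, reference_row = ref)
  prof <- segment_ilm(flat)
  truth_rows <- sim$ilm_rows + attr(flat, "shifts")
  truth_h <- ref - truth_rows
  rmse <- sqrt(mean((prof$h - truth_h)^2))
  expect_lte(rmse, 1)

  speckled <- gen_bscan(small_truth(noise_sd = 0), geom,
                        blur_sigma = 1, speckle_sd = 0.08, seed = 9)
  flat2 <- flatten_bscan(speckled$image, speckled$bruch_rows, reference_row = ref)
  prof2 <- segment_ilm(flat2)
  truth_h2 <- ref - (speckled$ilm_rows + attr(flat2, "shifts"))
  expect_lte(sqrt(mean((prof2$h - truth_h2)^2)), 2)
})

test_that("a flat contour is traced flat within a pixel", {
  tr <- profile_truth(baseline_height = 150,
                      nasal = list(pit_amplitude = 1e-6, pit_sigma = 300,
                                   para_amplitude = 0, para_sigma = 900),
                      noise_sd = 0, lateral_extent = 3000)
  sim <- gen_bscan(tr, small_geometry(), blur_sigma = 0, speckle_sd = 0)
  flat <- flatten_bscan(sim$image, sim$bruch_rows, reference_row = 120)
  prof <- segment_ilm(flat)
  expect_lte(diff(range(prof$h)), 1)
})

test_that("manual override corrections are applied after automatic tracing", {
  sim <- gen_bscan(small_truth(noise_sd = 0), small_geometry(),
                   blur_sigma = 0, speckle_sd = 0)
  flat <- flatten_bscan(sim$image, sim$bruch_rows, reference_row = 120)
  base <- segment_ilm(flat)
  fixed <- segment_ilm(flat, override = data.frame(column = 10, row = 33))
  expect_equal(fixed$h[10], 120 - 33)
  expect_equal(fixed$h[-10], base$h[-10])
})

test_that("the foveal slice is the deepest pit with enough context on each side", {
  vol <- gen_bscan_volume(small_truth(noise_sd = 0), small_geometry(),
                          n_slices = 15, pit_slice = 8, slice_sigma = 3,
                          blur_sigma = 0, speckle_sd = 0)
  expect_equal(as.integer(select_foveal_bscan(vol)), 8L)

  edge <- gen_bscan_volume(small_truth(noise_sd = 0), small_geometry(),
                           n_slices = 15, pit_slice = 3, slice_sigma = 2,
                           blur_sigma = 0, speckle_sd = 0)
  expect_error(select_foveal_bscan(edge), "insufficient context")
  expect_error(select_foveal_bscan(vol$slices[1:9]), "at least 11 slices")
})

test_that("equal-depth candidate slices resolve toward the central slice, then lower index", {
  vol <- gen_bscan_volume(small_truth(noise_sd = 0), small_geometry(),
                          n_slices = 15, pit_slice = 8, slice_sigma = 3,
                          blur_sigma = 0, speckle_sd = 0)
  # duplicate slice 7 into slice 9 so slices 7 and 9 tie exactly; both are
  # 1 slice from the central slice 8, so the lower index wins
  slices <- vol$slices
  slices[[9]] <- slices[[7]]
  slices[[8]] <- slices[[6]]   # displace the true optimum
  expect_equal(as.integer(select_foveal_bscan(slices)), 7L)
})

test_that("micrometre conversion scales, centers, and honours the lateral correction", {
  geom <- small_geometry()
  sim <- gen_bscan(small_truth(noise_sd = 0), geom,
                   blur_sigma = 0, speckle_sd = 0)
  flat <- flatten_bscan(sim$image, sim$bruch_rows, reference_row = 120)
  prof_px <- segment_ilm(flat)

  um1 <- to_micrometers(prof_px, geom$axial_um_per_px, geom$lateral_um_per_px,
                        lateral_correction = 1)
  expect_equal(unique(round(diff(um1$x), 9)), geom$lateral_um_per_px)
  # pit center at x = 0: the deepest samples straddle it
  deepest <- um1$x[um1$h <= min(um1$h) + 1e-9]
  expect_lte(min(abs(deepest)), 2 * geom$lateral_um_per_px)

  um05 <- to_micrometers(prof_px, geom$axial_um_per_px, geom$lateral_um_per_px,
                         lateral_correction = 0.5)
  expect_equal(um05$x, um1$x * 0.5, tolerance = 1e-12)
  expect_equal(um05$h, um1$h)

  # left-eye mirroring keeps x increasing and reverses the contour
  uml <- to_micrometers(prof_px, geom$axial_um_per_px, geom$lateral_um_per_px,
                        lateral_correction = 1, eye = "left")
  expect_true(all(diff(uml$x) > 0))
  expect_equal(uml$h, rev(um1$h))
})

test_that("lateral correction lookup is explicit: missing entries error, no silent default", {
  prof_px <- ilm_profile(1:120, rep(50, 120) + c(seq(30, 0, length.out = 60),
                                                 seq(0, 30, length.out = 60)),
                         units = "px")
  tab <- data.frame(pma = 34, ga = 27, factor = 0.82)
  um <- to_micrometers(prof_px, 2.5, 25, correction_table = tab,
                       pma = 34, ga = 27)
  expect_equal(median(diff(um$x)), 25 * 0.82, tolerance = 1e-9)
  expect_error(
    to_micrometers(prof_px, 2.5, 25, correction_table = tab, pma = 36, ga = 27),
    "no lateral correction entry"
  )
  expect_warning(to_micrometers(prof_px, 2.5, 25), "identity")
})

test_that("full preprocessing recovers the generating contour and is translation invariant", {
  geom <- small_geometry()
  sim <- gen_bscan(small_truth(noise_sd = 0), geom,
                   blur_sigma = 1, speckle_sd = 0.08, seed = 21)
  prof <- preprocess_bscan(sim$image, lateral_correction = 1)
  truth_h <- contour_oracle(200, 90, 350, 20, 900, abs(prof$x))
  rmse_px <- sqrt(mean((prof$h - truth_h)^2)) / geom$axial_um_per_px
  expect_lte(rmse_px, 2)

  # two pixel-grid contours differing by a 3-column lateral shift give the
  # same pit-centered profile after conversion
  f <- function(x_um) contour_oracle(150, 80, 350, 15, 900, abs(x_um)) / 2.5
  p1 <- ilm_profile(1:120, f((1:120 - 60) * 25), units = "px")
  p2 <- ilm_profile(1:120, f((1:120 - 63) * 25), units = "px")
  u1 <- to_micrometers(p1, 2.5, 25, lateral_correction = 1)
  u2 <- to_micrometers(p2, 2.5, 25, lateral_correction = 1)
  m1 <- compute_metrics(fit_dog(u1, dog_fit_config(multistart = 1)))
  m2 <- compute_metrics(fit_dog(u2, dog_fit_config(multistart = 1)))
  expect_equal(m1$width, m2$width, tolerance = 1e-3)
  expect_equal(m1$cft, m2$cft, tolerance = 1e-3)
})
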