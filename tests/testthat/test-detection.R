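test_that("bandpass removes constant background and slow gradients", {
  expect_true(all(bandpass(matrix(37, 40, 40)) == 0))
  # low-frequency gradient (period >> object scale) attenuated > 90%;
  # judged away from the image border, where reflective padding kinks the
  # sinusoid (the same margin the detector excludes)
  x <- outer(rep(1, 64), 0:127)
  grad <- 100 + 50 * sin(2 * pi * x / 128)
  bp <- bandpass(grad, 1, 7)
  expect_lt(max(bp[, 22:106]), 0.1 * 50)
})

test_that("bandpass keeps most of an isolated spot's mass", {
  img <- make_spot_image(64, 64, 30, 33, sigma_px = 0.72, photons = 2000)
  bp <- bandpass(img, 1, 7)
  f <- compute_features(bp, 30, 33, 3.5)
  expect_gt(f$mass, 0.8 * 2000)
})

test_that("a blank image yields no detections", {
  expect_equal(nrow(locate(matrix(5, 64, 64), 0.108)), 0)
  expect_equal(nrow(locate(matrix(0, 64, 64), 0.108)), 0)
})

test_that("sub-pixel centroid recovered within 0.1 px at SNR >= 10", {
  set.seed(42)
  img <- make_spot_image(64, 64, 20.30, 41.70, sigma_px = 0.72,
                         photons = 2000, bg = 10)
  noisy <- matrix(rpois(length(img), img), nrow(img)) +
    matrix(rnorm(length(img), 0, 2), nrow(img))
  noisy[noisy < 0] <- 0
  det <- locate(noisy, pixel_size_um = 1, min_mass = 0)
  expect_equal(nrow(det), 1)
  expect_lt(abs(det$x_um - 20.30), 0.1)
  expect_lt(abs(det$y_um - 41.70), 0.1)
})

test_that("separation suppression merges close peaks and keeps distant ones", {
  two <- function(dist_px) {
    make_spot_image(96, 96, 40, 48, photons = 2000) +
      make_spot_image(96, 96, 40 + dist_px, 48, photons = 1500)
  }
  expect_equal(nrow(locate(two(14), 1, min_mass = 0)), 2)  # 2 x separation
  expect_equal(nrow(locate(two(3.5), 1, min_mass = 0)), 1) # 0.5 x separation
})

test_that("mask features scale correctly and reflect spot symmetry", {
  img <- make_spot_image(64, 64, 31, 29, sigma_px = 1.2, photons = 3000,
                         bg = 5)
  f1 <- compute_features(img, 31, 29, 3.5, pixel_size_um = 0.108)
  expect_lt(f1$ecc, 0.1)           # circular spot
  expect_gt(f1$mass, 0)
  f2 <- compute_features(2 * img, 31, 29, 3.5, pixel_size_um = 0.108)
  expect_equal(f2$mass, 2 * f1$mass, tolerance = 1e-9)
  expect_equal(f2$size_um, f1$size_um, tolerance = 1e-9)
  expect_equal(f2$ecc, f1$ecc, tolerance = 1e-9)
  # degenerate all-zero mask
  f0 <- compute_features(matrix(0, 32, 32), 16, 16, 3.5)
  expect_equal(f0$mass, 0)
  expect_true(f0$degenerate)
})

test_that("detection is equivariant to integer-pixel translation", {
  base <- make_spot_image(100, 100, 30.3, 40.7, photons = 2000) +
    make_spot_image(100, 100, 60.1, 25.4, photons = 1500) +
    make_spot_image(100, 100, 45.6, 70.2, photons = 1800)
  shifted <- matrix(0, 100, 100)
  shifted[(1 + 5):100, (1 + 3):100] <- base[1:(100 - 5), 1:(100 - 3)]
  d0 <- locate(base, 1, min_mass = 0)
  d1 <- locate(shifted, 1, min_mass = 0)
  expect_equal(nrow(d0), 3)
  expect_equal(nrow(d1), 3)
  o0 <- order(d0$x_um); o1 <- order(d1$x_um)
  expect_equal(d1$x_um[o1], d0$x_um[o0] + 3, tolerance = 1e-3)
  expect_equal(d1$y_um[o1], d0$y_um[o0] + 5, tolerance = 1e-3)
})

test_that("filter_detections subsets and records provenance", {
  img <- make_spot_image(64, 64, 30, 30, photons = 2000) +
    make_spot_image(64, 64, 48, 20, photons = 200)
  det <- locate(img, 0.108, min_mass = 0)
  expect_equal(nrow(filter_detections(det)), nrow(det))      # identity
  expect_equal(nrow(filter_detections(det, min_mass = Inf)), 0)
  sub <- filter_detections(det, min_mass = 500)
  expect_equal(nrow(sub), 1)
  expect_length(attr(sub, "detect_params")$filters, 1)
})

test_that("full pipeline reaches recall/precision 0.95 and 0.05 um RMSE", {
  cm <- construct_model("Gag-IN-red", channel = "red")
  p <- field_params(512, 512, 5, particle_density = 0.02, seed = 7)
  sim <- simulate_field(p, list(cm), dual_label_fraction = 1)
  psf <- default_psf()
  dec <- richardson_lucy(get_channel(sim$field, "red"), psf, 15)
  det <- locate(max_project(dec), p$pixel_size_um, channel = "red")
  tr <- interior_truth(sim$truth[sim$truth$copies_red > 0, ], 512, 512,
                       p$pixel_size_um)
  m <- match_detections(tr, det, radius_um = 2 * p$pixel_size_um)
  expect_gte(m$recall, 0.95)
  expect_gte(m$precision, 0.95)
  expect_lte(m$rmse_um, 0.05)
})

test_that("locate validates its geometry parameters", {
  img <- make_spot_image(32, 32)
  expect_error(locate(img, 0.108, diameter_px = 6))       # even diameter
  expect_error(locate(img, 0.108, separation_px = 3))     # < diameter
})
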