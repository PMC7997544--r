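# Shared fixture builders and independent oracles, constructed in code.

# 2-D Gaussian spot at a sub-pixel center (0-based pixel coordinates),
# integrated flux = photons.
make_spot_image <- function(nx = 64, ny = 64, cx = nx / 2, cy = ny / 2,
                            sigma_px = 0.72, photons = 2000, bg = 0) {
  x <- outer(rep(1, ny), 0:(nx - 1))
  y <- outer(0:(ny - 1), rep(1, nx))
  g <- exp(-((x - cx)^2 + (y - cy)^2) / (2 * sigma_px^2))
  g / sum(g) * photons + bg
}

# 3-D spot stack [y, x, z].
make_spot_stack <- function(nx = 32, ny = 32, nz = 5, cx = nx / 2,
                            cy = ny / 2, cz = (nz - 1) / 2,
                            sigma_px = 0.72, sigma_z = 0.88,
                            photons = 2000, bg = 0) {
  arr <- array(0, c(ny, nx, nz))
  x <- outer(rep(1, ny), 0:(nx - 1))
  y <- outer(0:(ny - 1), rep(1, nx))
  lat <- exp(-((x - cx)^2 + (y - cy)^2) / (2 * sigma_px^2))
  zw <- exp(-((0:(nz - 1)) - cz)^2 / (2 * sigma_z^2))
  for (k in seq_len(nz)) arr[, , k] <- lat * zw[k]
  arr / sum(arr) * photons + bg
}

default_psf <- function(pixel_size_um = 0.108, z_step_um = 0.3)
  theoretical_psf(1.4, 0.6, pixel_size_um, z_step_um)

# O(n^2) exhaustive nearest-neighbour pairing oracle (reference-anchored,
# strict threshold), independent of the package's grid search.
exhaustive_pairs <- function(ref, query, threshold_um) {
  out <- NULL
  for (i in seq_len(nrow(ref))) {
    d <- sqrt((query$x_um - ref$x_um[i])^2 + (query$y_um - ref$y_um[i])^2)
    j <- which.min(d)
    if (length(j) && d[j] < threshold_um)
      out <- rbind(out, data.frame(ref_id = i, query_id = j,
                                   distance_um = d[j]))
  }
  out %||% data.frame(ref_id = integer(), query_id = integer(),
                      distance_um = numeric())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Direct triple-loop separable convolution oracle with symmetric reflection
# (independent of the compiled path).
ref_conv1d <- function(v, k) {
  r <- (length(k) - 1) / 2
  n <- length(v)
  refl <- function(i) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i
      if (i > n) i <- 2 * n + 1 - i
    }
    i
  }
  vapply(seq_len(n), function(i)
    sum(k * vapply(seq_along(k),
                   function(t) v[refl(i + t - r - 1)], 0)), 0)
}

# Truth rows away from the detector's edge-exclusion margin.
interior_truth <- function(truth, width_px, height_px, pixel_size_um,
                           margin_px = 3.5) {
  m <- margin_px * pixel_size_um
  truth[truth$x_um > m & truth$x_um < width_px * pixel_size_um - m &
          truth$y_um > m & truth$y_um < height_px * pixel_size_um - m, ,
        drop = FALSE]
}
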