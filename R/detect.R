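#' Bandpass filter for spot detection
#'
#' Difference-of-Gaussians preprocessing in the Crocker-Grier spirit: a
#' narrow Gaussian (sigma = `noise_scale_px`) suppresses pixel noise and a
#' wide Gaussian (sigma = `object_scale_px`) estimates the slowly varying
#' background, which is subtracted. Negative values are clipped to zero.
#' A constant image maps to all zeros.
#'
#' @param image 2-D matrix.
#' @param noise_scale_px Sigma of the smoothing Gaussian, pixels. Default 1.
#' @param object_scale_px Sigma of the background Gaussian, pixels; must
#'   exceed `noise_scale_px`. Default 7 (the nominal spot diameter).
#' @return Filtered non-negative matrix, same size.
#' @export
bandpass <- function(image, noise_scale_px = 1, object_scale_px = 7) {
  stopifnot(is.matrix(image), noise_scale_px < object_scale_px)
  ks <- gauss_kernel_1d(noise_scale_px)
  kb <- gauss_kernel_1d(object_scale_px)
  out <- sep_conv(image, ks, ks) - sep_conv(image, kb, kb)
  out[out < 0] <- 0
  out
}

#' Detect diffraction-limited particles with sub-pixel centroids
#'
#' Candidate peaks are local maxima of the bandpassed image above a
#' percentile threshold of its pixel values. Peaks closer than
#' `separation_px` are resolved greedily, keeping the brighter. Each kept
#' peak is refined by iterated intensity-weighted center of mass inside a
#' circular mask of radius `diameter_px / 2` (until the shift drops below
#' 0.005 px or 10 iterations). Mask features (mass, radius of gyration,
#' eccentricity) are measured on the bandpassed image; candidates below
#' `min_mass` and candidates within `diameter_px / 2` of the field edge are
#' discarded.
#'
#' Coordinates are zero-based with pixel centers at integer positions;
#' physical positions are `pixel * pixel_size_um` (micrometers).
#'
#' @param image 2-D matrix (typically deconvolved and max-projected).
#' @param pixel_size_um Lateral calibration, um/px.
#' @param diameter_px Odd integer spot diameter in pixels. Default 7.
#' @param separation_px Minimum allowed distance between detections;
#'   defaults to `diameter_px`.
#' @param min_mass Minimum integrated mass; NULL picks Otsu's threshold over
#'   candidate masses (skipped when there are fewer than 10 candidates).
#' @param threshold_percentile Percentile of the bandpassed pixel values a
#'   candidate peak must exceed. Default 99.7.
#' @param channel Channel name recorded in the table.
#' @param prefiltered Set TRUE if `image` is already bandpassed.
#' @param noise_scale_px Passed to [bandpass()] when `prefiltered = FALSE`.
#' @param photometry_image Optional second image (same size) on which mass,
#'   size and eccentricity are measured at the detected centroids, after the
#'   same bandpass. Use the flux-linear [sum_project()] of the deconvolved
#'   stack here when single-particle intensities are to be compared across
#'   preparations: iterative restoration sharpens bright spots faster than
#'   dim ones, so masses read off the maximum projection are not linear in
#'   photon flux. NULL (default) measures on the detection image.
#' @return A `detection_table`: data.frame with `channel`, `x_um`, `y_um`,
#'   `mass`, `size_um`, `ecc`, `raw_peak`, with calibration and the
#'   parameters used stored in attributes.
#' @export
locate <- function(image, pixel_size_um, diameter_px = 7,
                   separation_px = NULL, min_mass = NULL,
                   threshold_percentile = 99.7, channel = "ch",
                   prefiltered = FALSE, noise_scale_px = 1,
                   photometry_image = NULL) {
  stopifnot(is.matrix(image), pixel_size_um > 0,
            diameter_px %% 2 == 1, diameter_px >= 3)
  if (!is.null(photometry_image))
    stopifnot(identical(dim(photometry_image), dim(image)))
  separation_px <- separation_px %||% diameter_px
  if (separation_px < diameter_px)
    stop("separation_px must be >= diameter_px")
  params <- list(diameter_px = diameter_px, separation_px = separation_px,
                 min_mass = min_mass,
                 threshold_percentile = threshold_percentile,
                 noise_scale_px = noise_scale_px, prefiltered = prefiltered)
  bp <- if (prefiltered) image
        else bandpass(image, noise_scale_px, diameter_px)
  phot <- if (is.null(photometry_image)) bp
          else bandpass(photometry_image, noise_scale_px, diameter_px)
  params$photometry <- if (is.null(photometry_image)) "detection_image"
                       else "separate_image"
  empty <- detection_table(data.frame(), channel, pixel_size_um, params)

  if (!any(bp > 0)) return(empty)
  thr <- quantile(bp, min(threshold_percentile / 100, 1), names = FALSE)
  peaks <- local_maxima(bp, thr)
  if (!nrow(peaks)) return(empty)

  keep <- suppress_close(peaks, separation_px)
  peaks <- peaks[keep, , drop = FALSE]

  rm_px <- diameter_px / 2
  rows <- lapply(seq_len(nrow(peaks)), function(i) {
    ctr <- refine_centroid(bp, peaks$x[i], peaks$y[i], rm_px)
    if (is.null(ctr)) return(NULL)
    f <- compute_features(phot, ctr[1], ctr[2], rm_px, pixel_size_um)
    data.frame(x_px = ctr[1], y_px = ctr[2], mass = f$mass,
               size_um = f$size_um, ecc = f$ecc,
               raw_peak = image[round(ctr[2]) + 1, round(ctr[1]) + 1])
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows) || !nrow(rows)) return(empty)
  rows <- rows[rows$mass > 0, , drop = FALSE]
  if (!nrow(rows)) return(empty)

  # Re-apply separation on refined centroids (refinement can merge peaks).
  ord <- order(-rows$mass)
  keep <- suppress_close(data.frame(x = rows$x_px, y = rows$y_px,
                                    v = rows$mass)[ord, ], separation_px)
  rows <- rows[ord, , drop = FALSE][keep, , drop = FALSE]

  if (is.null(min_mass)) {
    # Otsu over candidate masses separates noise peaks from particles, but
    # on clean fields all candidates are real and Otsu would split the
    # particle population itself. Apply the cut only when the lower class
    # is consistent with the image's own noise floor, measured as the mask
    # mass at a fixed lattice of off-peak positions.
    min_mass <- 0
    if (nrow(rows) >= 10) {
      thr <- otsu_threshold(rows$mass)
      lo <- rows$mass[rows$mass < thr]
      hi <- rows$mass[rows$mass >= thr]
      null_mass <- null_mask_mass(phot, rm_px)
      if (length(lo) && length(hi) &&
          mean(lo) <= 4 * max(null_mass, .Machine$double.eps))
        min_mass <- thr
    }
    params$min_mass <- min_mass
  }
  rows <- rows[rows$mass >= min_mass, , drop = FALSE]
  edge <- diameter_px / 2
  inb <- rows$x_px >= edge & rows$x_px <= ncol(image) - 1 - edge &
         rows$y_px >= edge & rows$y_px <= nrow(image) - 1 - edge
  rows <- rows[inb, , drop = FALSE]
  if (!nrow(rows)) return(detection_table(data.frame(), channel,
                                          pixel_size_um, params))
  df <- data.frame(channel = channel,
                   x_um = rows$x_px * pixel_size_um,
                   y_um = rows$y_px * pixel_size_um,
                   mass = rows$mass, size_um = rows$size_um, ecc = rows$ecc,
                   raw_peak = rows$raw_peak)
  detection_table(df, channel, pixel_size_um, params)
}

detection_table <- function(df, channel, pixel_size_um, params) {
  if (!nrow(df))
    df <- data.frame(channel = character(), x_um = numeric(),
                     y_um = numeric(), mass = numeric(),
                     size_um = numeric(), ecc = numeric(),
                     raw_peak = numeric())
  rownames(df) <- NULL
  structure(df, pixel_size_um = pixel_size_um, channel = channel,
            detect_params = params,
            class = c("detection_table", "data.frame"))
}

# Median mask mass at a deterministic lattice of interior positions: the
# mass a candidate would carry if it sat on pure background.
null_mask_mass <- function(img, mask_radius_px, n_grid = 10) {
  r <- ceiling(mask_radius_px) + 2
  nx <- ncol(img); ny <- nrow(img)
  if (nx <= 2 * r + 2 || ny <= 2 * r + 2) return(0)
  gx <- seq(r + 1, nx - r - 2, length.out = n_grid)
  gy <- seq(r + 1, ny - r - 2, length.out = n_grid)
  vals <- vapply(seq_len(n_grid), function(i)
    vapply(seq_len(n_grid), function(j)
      compute_features(img, gx[i], gy[j], mask_radius_px)$mass, 0),
    numeric(n_grid))
  median(vals)
}

# Local maxima (8-neighborhood, >= to tolerate plateaus) above a threshold.
# Returns 0-based pixel coordinates with values, brightest first.
local_maxima <- function(bp, thr) {
  nr <- nrow(bp); nc <- ncol(bp)
  if (nr < 3 || nc < 3) return(data.frame(x = numeric(), y = numeric(),
                                          v = numeric()))
  core <- bp[2:(nr - 1), 2:(nc - 1)]
  is_max <- core > thr
  for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0) next
    is_max <- is_max & core >= bp[2:(nr - 1) + dy, 2:(nc - 1) + dx]
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (!nrow(idx)) return(data.frame(x = numeric(), y = numeric(),
                                    v = numeric()))
  out <- data.frame(x = idx[, 2], y = idx[, 1], v = core[is_max])
  out[order(-out$v), ]
}

# Greedy suppression: walk candidates from brightest down, keep one if no
# already-kept candidate lies within sep. Grid-bucketed for speed.
suppress_close <- function(peaks, sep) {
  n <- nrow(peaks)
  if (n <= 1) return(rep(TRUE, n))
  cell <- sep
  gx <- floor(peaks$x / cell); gy <- floor(peaks$y / cell)
  buckets <- new.env(hash = TRUE, parent = emptyenv())
  keep <- logical(n)
  for (i in seq_len(n)) {
    ok <- TRUE
    for (ax in -1:1) for (ay in -1:1) {
      key <- paste(gx[i] + ax, gy[i] + ay)
      js <- buckets[[key]]
      if (!is.null(js)) {
        d2 <- (peaks$x[js] - peaks$x[i])^2 + (peaks$y[js] - peaks$y[i])^2
        if (any(d2 < sep^2)) { ok <- FALSE; break }
      }
    }
    if (ok) {
      keep[i] <- TRUE
      key <- paste(gx[i], gy[i])
      buckets[[key]] <- c(buckets[[key]], i)
    }
  }
  keep
}

# Iterated intensity-weighted center of mass in a circular mask.
refine_centroid <- function(bp, x0, y0, radius_px, tol = 0.005,
                            max_iter = 10) {
  x <- x0; y <- y0
  r <- ceiling(radius_px)
  for (it in seq_len(max_iter)) {
    xi <- round(x); yi <- round(y)
    ix <- max(0, xi - r):min(ncol(bp) - 1, xi + r)
    iy <- max(0, yi - r):min(nrow(bp) - 1, yi + r)
    if (!length(ix) || !length(iy)) return(NULL)
    sub <- bp[iy + 1, ix + 1, drop = FALSE]
    dx <- outer(rep(1, length(iy)), ix) - x
    dy <- outer(iy, rep(1, length(ix))) - y
    msk <- (dx^2 + dy^2) <= radius_px^2
    w <- sub * msk
    tot <- sum(w)
    if (tot <= 0) return(NULL)
    nx <- sum(w * (dx + x)) / tot
    ny <- sum(w * (dy + y)) / tot
    shift <- sqrt((nx - x)^2 + (ny - y)^2)
    x <- nx; y <- ny
    if (shift < tol) break
  }
  c(x, y)
}

#' Mask-based particle features around a centroid
#'
#' Measures, inside a circular mask centred on a (sub-pixel) centroid:
#' `mass`, the background-corrected integrated intensity (local background is
#' the median of an annulus two pixels wide just outside the mask, and each
#' pixel's corrected value is floored at zero); `size_um`, the
#' intensity-weighted radius of gyration converted to micrometers; and
#' `ecc`, the eccentricity from second central moments (0 for a circularly
#' symmetric spot).
#'
#' @param image 2-D matrix.
#' @param cx_px,cy_px Centroid, zero-based pixels.
#' @param mask_radius_px Mask radius in pixels.
#' @param pixel_size_um Calibration for `size_um`. Default 1 (sizes in px).
#' @return list(mass, size_um, ecc, degenerate); an all-zero mask yields
#'   mass 0 with `degenerate = TRUE` and undefined (NA) size/ecc.
#' @export
compute_features <- function(image, cx_px, cy_px, mask_radius_px,
                             pixel_size_um = 1) {
  r <- ceiling(mask_radius_px + 2)
  xi <- round(cx_px); yi <- round(cy_px)
  ix <- max(0, xi - r):min(ncol(image) - 1, xi + r)
  iy <- max(0, yi - r):min(nrow(image) - 1, yi + r)
  sub <- image[iy + 1, ix + 1, drop = FALSE]
  dx <- outer(rep(1, length(iy)), ix) - cx_px
  dy <- outer(iy, rep(1, length(ix))) - cy_px
  d2 <- dx^2 + dy^2
  inner <- d2 <= mask_radius_px^2
  annulus <- d2 > mask_radius_px^2 & d2 <= (mask_radius_px + 2)^2
  bg <- if (any(annulus)) median(sub[annulus]) else 0
  corr <- pmax(sub - bg, 0)
  corr[!inner] <- 0
  mass <- sum(corr)
  if (mass <= 0)
    return(list(mass = 0, size_um = NA_real_, ecc = NA_real_,
                degenerate = TRUE))
  size_px <- sqrt(sum(corr * d2) / mass)
  mu20 <- sum(corr * dx^2) / mass
  mu02 <- sum(corr * dy^2) / mass
  mu11 <- sum(corr * dx * dy) / mass
  ecc <- sqrt((mu20 - mu02)^2 + 4 * mu11^2) / (mu20 + mu02)
  list(mass = mass, size_um = size_px * pixel_size_um,
       ecc = min(max(ecc, 0), 1), degenerate = FALSE)
}

#' Filter a detection table by feature ranges
#'
#' Subsets a [locate()] table by mass, size and eccentricity ranges; the
#' applied predicates are appended to the table's parameter provenance.
#'
#' @param table A `detection_table`.
#' @param min_mass,max_mass Mass bounds.
#' @param min_size_um,max_size_um Radius-of-gyration bounds (um).
#' @param max_ecc Maximum eccentricity.
#' @return The filtered `detection_table`.
#' @export
filter_detections <- function(table, min_mass = NULL, max_mass = NULL,
                              min_size_um = NULL, max_size_um = NULL,
                              max_ecc = NULL) {
  stopifnot(inherits(table, "detection_table"))
  keep <- rep(TRUE, nrow(table))
  if (!is.null(min_mass)) keep <- keep & table$mass >= min_mass
  if (!is.null(max_mass)) keep <- keep & table$mass <= max_mass
  if (!is.null(min_size_um)) keep <- keep & table$size_um >= min_size_um
  if (!is.null(max_size_um)) keep <- keep & table$size_um <= max_size_um
  if (!is.null(max_ecc)) keep <- keep & table$ecc <= max_ecc
  keep[is.na(keep)] <- FALSE
  out <- table[keep, , drop = FALSE]
  prm <- attr(table, "detect_params")
  prm$filters <- c(prm$filters,
                   list(list(min_mass = min_mass, max_mass = max_mass,
                             min_size_um = min_size_um,
                             max_size_um = max_size_um, max_ecc = max_ecc)))
  detection_table(as.data.frame(out), attr(table, "channel"),
                  attr(table, "pixel_size_um"), prm)
}
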