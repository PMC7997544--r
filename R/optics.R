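#' Theoretical point-spread function (Gaussian approximation)
#'
#' Builds a separable Gaussian approximation to the widefield PSF on the
#' voxel grid: `sigma_lateral = 0.21 * lambda / NA` and
#' `sigma_axial = 0.66 * lambda * n / NA^2` (n = refractive index of the
#' immersion medium), discretized at pixel centers and normalized to unit
#' sum. Adequate for diffraction-limited puncta and analytically checkable.
#'
#' @param numerical_aperture Objective NA (must be below the refractive
#'   index).
#' @param emission_wavelength_um Emission wavelength in micrometers,
#'   in (0.3, 0.8).
#' @param pixel_size_um Lateral pixel pitch (um/px).
#' @param z_step_um Axial step (um); NULL builds a single-plane (2-D) PSF.
#' @param refractive_index Immersion medium index, default 1.515 (oil).
#' @param truncate_sd Kernel support radius in sigmas. Default 3.
#' @return A `psf_model`: sigmas in um, separable 1-D kernels, and the dense
#'   normalized non-negative kernel array.
#' @export
#' @examples
#' psf <- theoretical_psf(1.4, 0.52, 0.108, 0.3)
#' psf$sigma_lateral_um  # 0.21 * 0.52 / 1.4 = 0.078
theoretical_psf <- function(numerical_aperture, emission_wavelength_um,
                            pixel_size_um, z_step_um = NULL,
                            refractive_index = 1.515, truncate_sd = 3) {
  stopifnot(numerical_aperture > 0,
            numerical_aperture < refractive_index,
            emission_wavelength_um > 0.3, emission_wavelength_um < 0.8,
            pixel_size_um > 0)
  sigma_lat <- 0.21 * emission_wavelength_um / numerical_aperture
  sigma_ax <- 0.66 * emission_wavelength_um * refractive_index /
    numerical_aperture^2
  kx <- gauss_kernel_1d(sigma_lat / pixel_size_um, truncate_sd)
  kz <- if (is.null(z_step_um)) 1
        else gauss_kernel_1d(sigma_ax / z_step_um, truncate_sd)
  kernel <- outer(kx, kx) %o% kz
  kernel <- kernel / sum(kernel)
  structure(list(numerical_aperture = numerical_aperture,
                 emission_wavelength_um = emission_wavelength_um,
                 pixel_size_um = pixel_size_um, z_step_um = z_step_um,
                 sigma_lateral_um = sigma_lat, sigma_axial_um = sigma_ax,
                 kx = kx, ky = kx, kz = kz, kernel = kernel),
            class = "psf_model")
}

# Blur an image (2-D or 3-D) with a PSF model or a plain kernel array.
psf_blur <- function(image, psf, flip = FALSE) {
  if (inherits(psf, "psf_model")) {
    k3 <- if (length(dim(image)) == 3) psf$kz else 1
    sep_conv(image, psf$ky, psf$kx, k3)
  } else {
    dense_conv(image, psf, flip = flip)
  }
}

#' Richardson-Lucy deconvolution
#'
#' Standard multiplicative-update restoration of a non-negative photon-count
#' image under a known PSF. The image is padded reflectively by one kernel
#' radius before iterating, which suppresses edge ringing; output is
#' non-negative and, for interior-dominated fields, conserves total flux to
#' within about 1%.
#'
#' @param image 2-D matrix or 3-D array of non-negative photon counts.
#' @param psf A [theoretical_psf()] model, or a plain non-negative kernel
#'   array with odd dimensions (normalized internally).
#' @param n_iter Number of iterations (>= 1). Default 15.
#' @param eps Small constant guarding divisions. Default 1e-12.
#' @return The deconvolved image, same dimensions as the input.
#' @export
richardson_lucy <- function(image, psf, n_iter = 15, eps = 1e-12) {
  stopifnot(n_iter >= 1)
  if (any(image < 0)) stop("image must be non-negative")
  if (!inherits(psf, "psf_model")) {
    s <- sum(psf)
    if (s <= 0) stop("PSF must have positive sum")
    psf <- psf / s
    kd <- dim(psf) %||% length(psf)
    di <- dim(image) %||% length(image)
    if (any(kd > c(di, rep(1L, max(0, length(kd) - length(di))))))
      stop("PSF support exceeds image size")
  }
  d <- dim(image)
  two_d <- length(d) == 2
  pad <- psf_pad_radius(psf, three_d = !two_d)
  obs <- pad_reflect(image, pad)
  est <- obs
  for (it in seq_len(n_iter)) {
    blur <- psf_blur(est, psf)
    ratio <- obs / pmax(blur, eps)
    est <- est * psf_blur(ratio, psf, flip = TRUE)
  }
  unpad(est, pad, d)
}

psf_pad_radius <- function(psf, three_d) {
  if (inherits(psf, "psf_model")) {
    r <- c(length(psf$ky) %/% 2, length(psf$kx) %/% 2,
           if (three_d) length(psf$kz) %/% 2 else 0L)
  } else {
    kd <- dim(psf) %||% c(length(psf), 1L, 1L)
    kd <- c(kd, rep(1L, 3 - length(kd)))
    r <- kd %/% 2
    if (!three_d) r <- r[1:2]
  }
  as.integer(r[seq_len(if (three_d) 3 else 2)])
}

# Reflective (half-sample symmetric) padding along each dimension.
pad_reflect <- function(x, pad) {
  d <- dim(x)
  idx <- lapply(seq_along(d), function(i) {
    n <- d[i]; p <- pad[i]
    if (p == 0) return(seq_len(n))
    pre <- pmin(pmax(rev(seq_len(p)), 1), n)
    post <- pmin(pmax(n + 1 - seq_len(p), 1), n)
    c(pre, seq_len(n), post)
  })
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

unpad <- function(x, pad, orig_dim) {
  idx <- lapply(seq_along(orig_dim),
                function(i) pad[i] + seq_len(orig_dim[i]))
  out <- do.call(`[`, c(list(x), idx, list(drop = FALSE)))
  dim(out) <- orig_dim
  out
}

#' Z sum projection
#'
#' Per-pixel sum across Z. Unlike the maximum projection this is linear in
#' the photon flux, so it is the projection of choice for photometry
#' (integrated single-particle intensities); detection uses [max_project()].
#'
#' @param stack 3-D array `[y, x, z]` (or a 2-D matrix, returned as-is).
#' @return 2-D matrix of per-pixel sums across Z.
#' @export
sum_project <- function(stack) {
  d <- dim(stack)
  if (length(d) == 2) return(stack)
  stopifnot(length(d) == 3, d[3] >= 1)
  out <- stack[, , 1]
  for (k in seq_len(d[3])[-1]) out <- out + stack[, , k]
  out
}

#' Z maximum-intensity projection
#'
#' @param stack 3-D array `[y, x, z]` (or a 2-D matrix, returned as-is).
#' @return 2-D matrix of per-pixel maxima across Z.
#' @export
max_project <- function(stack) {
  d <- dim(stack)
  if (length(d) == 2) return(stack)
  stopifnot(length(d) == 3, d[3] >= 1)
  out <- stack[, , 1]
  for (k in seq_len(d[3])[-1]) out <- pmax(out, stack[, , k])
  out
}
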