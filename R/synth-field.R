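#' Simulate a virus-on-glass image field with exact ground truth
#'
#' Draws particle positions from a uniform spatial Poisson process over the
#' field, assigns per-construct labeled-IN copy numbers with
#' [assign_labels()], flags a fraction of particles as mature (only those are
#' visible in the anti-capsid reference channel, emulating an antibody that
#' stains mature capsids only), renders every particle as a 3-D Gaussian PSF
#' at its sub-pixel position, and adds Poisson shot noise, constant
#' background and Gaussian read noise. Virions sit in a thin layer at the
#' coverslip: all particles lie near the central focal plane with a small
#' axial jitter.
#'
#' @param params A [field_params()] object.
#' @param constructs List of [construct_model()] objects (distinct channels).
#' @param dual_label_fraction Optional joint labeling probability passed to
#'   [assign_labels()].
#' @param mature_fraction Fraction of particles stained by the mature-capsid
#'   reference antibody. Default 0.9.
#' @param reference_channel Name of the immunostain reference channel.
#' @param reference_photons Expected integrated photons of the reference
#'   stain per mature particle. Default 4000.
#' @param gain_photons_per_copy Photons per labeled-IN copy, per channel; a
#'   single number or a vector named by channel. Default 2.
#' @param focus_jitter_um SD of the axial offset from the focal plane (um).
#' @param psf A [theoretical_psf()] model used to render particles; NULL uses
#'   NA 1.4, emission 0.6 um on the field's voxel grid.
#' @param max_particles Refuse to simulate if the expected particle count
#'   exceeds this cap (overlapping-field regime is out of scope).
#' @return A list with `field` (an `ImageField`: photon-count array
#'   `[y, x, z, channel]` plus calibration) and `truth` (a data.frame with
#'   positions in um, maturity flags, per-channel copies and photons).
#' @export
#' @examples
#' cm <- construct_model("Gag-mRuby3IN", channel = "red")
#' sim <- simulate_field(field_params(64, 64, seed = 1), list(cm))
#' dim(sim$field$data)
simulate_field <- function(params, constructs, dual_label_fraction = NULL,
                           mature_fraction = 0.9, reference_channel = "ref",
                           reference_photons = 4000,
                           gain_photons_per_copy = 2,
                           focus_jitter_um = 0.05, psf = NULL,
                           max_particles = 10000) {
  stopifnot(inherits(params, "field_params"),
            mature_fraction >= 0, mature_fraction <= 1)
  constructs <- as_construct_list(constructs)
  chans <- vapply(constructs, `[[`, "", "channel")
  if (reference_channel %in% chans)
    stop("constructs must not reuse the reference channel name")
  all_chans <- c(reference_channel, chans)
  gains <- rep(gain_photons_per_copy, length.out = length(chans))
  if (!is.null(names(gain_photons_per_copy)))
    gains <- gain_photons_per_copy[chans]
  names(gains) <- chans

  w_um <- params$width_px * params$pixel_size_um
  h_um <- params$height_px * params$pixel_size_um
  lambda <- params$particle_density * w_um * h_um
  if (lambda > max_particles)
    stop("expected particle count ", round(lambda),
         " exceeds max_particles = ", max_particles,
         "; overlapping-field densities are out of scope")

  ss <- derive_seeds(params$seed,
                     c("count", "position", "labels", "maturity", "noise"))
  n <- with_seed(ss$count, rpois(1, lambda))
  z_mid <- (params$n_z - 1) / 2 * params$z_step_um
  pos <- with_seed(ss$position, data.frame(
    x_um = runif(n, 0, w_um), y_um = runif(n, 0, h_um),
    z_um = z_mid + rnorm(n, 0, focus_jitter_um)))
  labels <- assign_labels(n, constructs, seed = ss$labels,
                          dual_label_fraction = dual_label_fraction)
  mature <- with_seed(ss$maturity,
                      as.logical(rbinom(n, 1, mature_fraction)))

  truth <- cbind(data.frame(particle_id = labels$particle_id),
                 pos, mature = mature,
                 labels[, setdiff(names(labels), "particle_id"),
                        drop = FALSE])
  truth[[paste0("copies_", reference_channel)]] <- rep(NA_real_, n)
  truth[[paste0("photons_", reference_channel)]] <-
    ifelse(mature, reference_photons, 0) + numeric(n)
  for (ch in chans)
    truth[[paste0("photons_", ch)]] <- truth[[paste0("copies_", ch)]] *
      gains[[ch]]

  if (is.null(psf))
    psf <- theoretical_psf(1.4, 0.6, params$pixel_size_um, params$z_step_um)
  stack <- array(0, dim = c(params$height_px, params$width_px, params$n_z,
                            length(all_chans)))
  for (ci in seq_along(all_chans)) {
    ph <- truth[[paste0("photons_", all_chans[ci])]]
    plane <- render_particles(params, pos, ph, psf)
    stack[, , , ci] <- plane
  }
  stack <- stack + params$background_level
  stack <- with_seed(ss$noise, {
    noisy <- array(rpois(length(stack), stack), dim = dim(stack))
    noisy <- noisy + rnorm(length(noisy), 0, params$read_noise_sd)
    noisy
  })
  stack[stack < 0] <- 0

  field <- new_image_field(stack, channels = all_chans,
                           pixel_size_um = params$pixel_size_um,
                           z_step_um = params$z_step_um)
  list(field = field, truth = truth)
}

# Render particles as 3-D Gaussians (separable outer product per particle,
# normalized over the window so integrated flux equals the photon count).
render_particles <- function(params, pos, photons, psf) {
  out <- array(0, dim = c(params$height_px, params$width_px, params$n_z))
  if (nrow(pos) == 0) return(out)
  sx <- psf$sigma_lateral_um / params$pixel_size_um
  sz <- psf$sigma_axial_um / params$z_step_um
  rxy <- max(2L, ceiling(4 * sx))
  rz <- max(1L, ceiling(4 * sz))
  for (i in seq_len(nrow(pos))) {
    if (photons[i] <= 0) next
    cx <- pos$x_um[i] / params$pixel_size_um
    cy <- pos$y_um[i] / params$pixel_size_um
    cz <- pos$z_um[i] / params$z_step_um
    ix <- max(0L, floor(cx) - rxy):min(params$width_px - 1L, ceiling(cx) + rxy)
    iy <- max(0L, floor(cy) - rxy):min(params$height_px - 1L, ceiling(cy) + rxy)
    iz <- max(0L, floor(cz) - rz):min(params$n_z - 1L, ceiling(cz) + rz)
    gx <- exp(-(ix - cx)^2 / (2 * sx^2))
    gy <- exp(-(iy - cy)^2 / (2 * sx^2))
    gz <- if (params$n_z == 1) 1 else exp(-(iz - cz)^2 / (2 * sz^2))
    w <- outer(gy, gx) %o% gz
    w <- w / sum(w) * photons[i]
    out[iy + 1L, ix + 1L, iz + 1L] <- out[iy + 1L, ix + 1L, iz + 1L] + w
  }
  out
}
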