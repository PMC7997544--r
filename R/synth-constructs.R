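#' Describe a fluorescent-integrase labeling construct
#'
#' A construct model captures how many labeled integrase (IN) copies a virion
#' carries in a given fluorescence channel. Gag-anchored fusions ride along
#' with Gag itself (>1500 copies per virion, one labeled IN per incorporated
#' labeled Gag), Gag-Pol-anchored fusions are packaged at the Pol:Gag ratio
#' (about 1:20), and Vpr-anchored fusions at a lower, Vpr-limited ratio. In
#' trans complementation the labeled construct is co-transfected with an
#' unlabeled backbone, so a particle carries the label only with probability
#' `incorporation_prob`; in cis configurations every particle is labeled.
#'
#' @param name Text label for the construct (e.g. "Gag-mRuby3IN").
#' @param channel Fluorescence channel this construct emits in (e.g. "red").
#' @param in_label_mode One of `"gag_anchored"`, `"pol_anchored"`,
#'   `"vpr_anchored"`, `"none"`; sets labeled-IN copies per particle.
#' @param gag_copy_mean Expected Gag copies per virion. Default 2000,
#'   consistent with the >1500 copies/virion packaged by HIV-1.
#' @param gag_copy_cv Coefficient of variation of the per-particle Gag copy
#'   number (log-normal law). Default 0.25.
#' @param pol_to_gag_ratio Anchor-to-Gag packaging ratio used for
#'   `pol_anchored` (default 1/20, the Pol:Gag ratio) and, as a generic
#'   anchor ratio, for `vpr_anchored`.
#' @param incorporation_prob Probability that a particle carries at least one
#'   labeled IN under trans complementation. Default 1 (cis: all labeled).
#' @return A `construct_model` object (list).
#' @export
#' @examples
#' construct_model("Gag-mRuby3IN", channel = "red")
construct_model <- function(name, channel,
                            in_label_mode = c("gag_anchored", "pol_anchored",
                                              "vpr_anchored", "none"),
                            gag_copy_mean = 2000, gag_copy_cv = 0.25,
                            pol_to_gag_ratio = 1 / 20,
                            incorporation_prob = 1) {
  in_label_mode <- match.arg(in_label_mode)
  stopifnot(gag_copy_mean > 0, gag_copy_cv >= 0,
            pol_to_gag_ratio > 0, pol_to_gag_ratio <= 1,
            incorporation_prob >= 0, incorporation_prob <= 1,
            nzchar(name), nzchar(channel))
  structure(list(name = name, channel = channel,
                 in_label_mode = in_label_mode,
                 gag_copy_mean = gag_copy_mean, gag_copy_cv = gag_copy_cv,
                 pol_to_gag_ratio = pol_to_gag_ratio,
                 incorporation_prob = incorporation_prob),
            class = "construct_model")
}

#' Imaging-field geometry and noise parameters
#'
#' Physical calibration and noise model for a simulated virus-on-glass (VOG)
#' field. The default pixel pitch of 0.108 um/px corresponds to a 60x
#' objective with 6.5 um camera pixels.
#'
#' @param width_px,height_px Field dimensions in pixels.
#' @param n_z Number of Z planes.
#' @param pixel_size_um Lateral pixel pitch in micrometers per pixel.
#' @param z_step_um Axial step between planes in micrometers.
#' @param particle_density Expected particles per square micrometer.
#' @param background_level Constant background, photons per pixel.
#' @param read_noise_sd Gaussian read noise standard deviation, photons.
#' @param seed Integer RNG seed, or NULL to use the current RNG state.
#' @return A `field_params` object (list).
#' @export
field_params <- function(width_px = 256L, height_px = 256L, n_z = 5L,
                         pixel_size_um = 0.108, z_step_um = 0.3,
                         particle_density = 0.02, background_level = 10,
                         read_noise_sd = 2, seed = NULL) {
  stopifnot(width_px >= 1, height_px >= 1, n_z >= 1,
            pixel_size_um > 0, z_step_um > 0,
            particle_density >= 0, background_level >= 0, read_noise_sd >= 0)
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px), n_z = as.integer(n_z),
                 pixel_size_um = pixel_size_um, z_step_um = z_step_um,
                 particle_density = particle_density,
                 background_level = background_level,
                 read_noise_sd = read_noise_sd, seed = seed),
            class = "field_params")
}

# Labeled-IN copies implied by a construct for given per-particle Gag copies.
construct_copies <- function(construct, gag_copies) {
  switch(construct$in_label_mode,
         gag_anchored = round(gag_copies),
         pol_anchored = round(gag_copies * construct$pol_to_gag_ratio),
         vpr_anchored = round(gag_copies * construct$pol_to_gag_ratio),
         none = rep(0, length(gag_copies)))
}

#' Assign per-particle label copy numbers
#'
#' Draws per-particle Gag copy numbers (log-normal around `gag_copy_mean`
#' with CV `gag_copy_cv`) and, for each construct, decides whether the
#' particle carries that construct's label (Bernoulli with
#' `incorporation_prob`, independently per construct) and how many labeled-IN
#' copies it then carries, according to the construct's anchoring mode.
#'
#' @param n_particles Number of particles (>= 0).
#' @param constructs List of [construct_model()] objects with distinct
#'   channels.
#' @param seed Integer seed or NULL.
#' @param dual_label_fraction Optional probability that a particle carries
#'   *all* constructs' labels; when given it overrides each construct's
#'   `incorporation_prob` with `dual_label_fraction^(1/k)` for k constructs,
#'   so that the joint labeling probability equals the requested value.
#' @return A data.frame with `particle_id`, `gag_copies`, and one
#'   `copies_<channel>` column per construct.
#' @export
assign_labels <- function(n_particles, constructs, seed = NULL,
                          dual_label_fraction = NULL) {
  stopifnot(n_particles >= 0)
  constructs <- as_construct_list(constructs)
  chans <- vapply(constructs, `[[`, "", "channel")
  if (anyDuplicated(chans)) stop("constructs must reference distinct channels")
  if (!is.null(dual_label_fraction)) {
    stopifnot(dual_label_fraction >= 0, dual_label_fraction <= 1)
    p <- dual_label_fraction^(1 / length(constructs))
    constructs <- lapply(constructs, function(cm) {
      cm$incorporation_prob <- p
      cm
    })
  }
  out <- data.frame(particle_id = seq_len(n_particles))
  gm <- if (length(constructs)) constructs[[1]]$gag_copy_mean else 2000
  gcv <- if (length(constructs)) constructs[[1]]$gag_copy_cv else 0.25
  with_seed(seed, {
    sdlog <- sqrt(log(1 + gcv^2))
    out$gag_copies <- if (n_particles)
      round(rlnorm(n_particles, log(gm) - sdlog^2 / 2, sdlog)) else numeric(0)
    for (cm in constructs) {
      carried <- if (cm$incorporation_prob >= 1) rep(TRUE, n_particles)
                 else as.logical(rbinom(n_particles, 1, cm$incorporation_prob))
      copies <- construct_copies(cm, out$gag_copies)
      copies[!carried] <- 0
      out[[paste0("copies_", cm$channel)]] <- copies
    }
  })
  out
}

as_construct_list <- function(constructs) {
  if (inherits(constructs, "construct_model")) constructs <- list(constructs)
  stopifnot(length(constructs) >= 1,
            all(vapply(constructs, inherits, TRUE, "construct_model")))
  constructs
}
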