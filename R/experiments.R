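#' Simulated virus-on-glass labeling-recovery experiment
#'
#' Runs the full analysis chain — field synthesis, per-channel
#' Richardson-Lucy deconvolution, Z maximum projection, particle detection,
#' and reference-anchored pairing at the 0.500 um rule — over a set of
#' independently seeded fields, pooling counts across fields the way
#' technical repeats are pooled in a VOG experiment. Reports, per
#' fluorescence channel, the fraction of mature-reference detections with a
#' colocalized partner, and the fraction paired in at least one channel
#' (the "either or both fluorophores" labeling frequency).
#'
#' @param constructs List of [construct_model()] objects.
#' @param n_fields Number of independent fields. Default 10.
#' @param field_px Field side length in pixels. Default 512.
#' @param n_z Z planes per field. Default 5.
#' @param particle_density Particles per square micrometer. Default 0.03
#'   (sub-confluent virions on glass).
#' @param dual_label_fraction Optional joint labeling probability (see
#'   [assign_labels()]).
#' @param mature_fraction Fraction of particles stained by the reference
#'   antibody. Default 0.9.
#' @param seed Integer seed; expanded to one sub-seed per field.
#' @param decon_iterations Richardson-Lucy iterations. Default 15.
#' @param threshold_um Colocalization cutoff. Default 0.5.
#' @param keep_masses Collect per-detection masses per channel (for
#'   intensity comparisons). Default FALSE.
#' @return list: `n_particles` (simulated), `n_reference` (pooled, after
#'   edge exclusion), `n_paired` (named per channel), `fraction` (named per
#'   channel), `n_paired_any`, `fraction_any`, and optionally `masses`.
#' @export
vog_label_experiment <- function(constructs, n_fields = 10, field_px = 512,
                                 n_z = 5, particle_density = 0.03,
                                 dual_label_fraction = NULL,
                                 mature_fraction = 0.9, seed = 1,
                                 decon_iterations = 15, threshold_um = 0.5,
                                 keep_masses = FALSE) {
  constructs <- as_construct_list(constructs)
  chans <- vapply(constructs, `[[`, "", "channel")
  seeds <- derive_seeds(seed, paste0("field", seq_len(n_fields)))
  n_particles <- 0L
  n_reference <- 0L
  n_paired <- setNames(integer(length(chans)), chans)
  n_paired_any <- 0L
  masses <- setNames(rep(list(numeric(0)), length(chans)), chans)
  for (fi in seq_len(n_fields)) {
    p <- field_params(field_px, field_px, n_z,
                      particle_density = particle_density,
                      seed = seeds[[fi]])
    sim <- simulate_field(p, constructs,
                          dual_label_fraction = dual_label_fraction,
                          mature_fraction = mature_fraction)
    n_particles <- n_particles + nrow(sim$truth)
    psf <- theoretical_psf(1.4, 0.6, p$pixel_size_um, p$z_step_um)
    dets <- lapply(sim$field$channels, function(ch) {
      dec <- richardson_lucy(get_channel(sim$field, ch),
                             psf, n_iter = decon_iterations)
      locate(max_project(dec), p$pixel_size_um, channel = ch,
             photometry_image = sum_project(dec))
    })
    names(dets) <- sim$field$channels
    rt <- dets$ref
    if (nrow(rt) == 0) next
    bounds <- c(field_px, field_px) * p$pixel_size_um
    paired_ids <- list()
    n_ref_field <- NULL
    for (ch in chans) {
      pr <- pair_to_reference(rt, dets[[ch]], threshold_um,
                              field_bounds = bounds)
      n_ref_field <- pr$n_reference
      n_paired[ch] <- n_paired[ch] + nrow(pr$pairs)
      paired_ids[[ch]] <- pr$pairs$ref_id
      if (keep_masses) masses[[ch]] <- c(masses[[ch]], dets[[ch]]$mass)
    }
    n_reference <- n_reference + n_ref_field
    n_paired_any <- n_paired_any + length(unique(unlist(paired_ids)))
  }
  out <- list(n_particles = n_particles, n_reference = n_reference,
              n_paired = n_paired,
              fraction = n_paired / max(n_reference, 1),
              n_paired_any = n_paired_any,
              fraction_any = n_paired_any / max(n_reference, 1))
  if (keep_masses) out$masses <- masses
  out
}

#' Simulated infection-readout experiment
#'
#' Generates a condition event table and a matched non-infected control,
#' gates singlets on both, anchors the GFP gate on the control, and reports
#' the percent-positive readout next to the ground truth.
#'
#' @param n_events Events per table. Default 50000.
#' @param infected_fraction True infected fraction of the condition table.
#' @param separation Infected-component shift in SD units. Default 4.
#' @param doublet_fraction Doublet contamination. Default 0.05.
#' @param seed Integer seed (control table uses a derived sub-seed).
#' @param gate_quantile Control quantile for the GFP gate. Default 0.999.
#' @param singlet_tolerance Robust band width for singlet gating. Default 3.
#' @return list: `percent_positive`, `true_percent`, `n_singlets`,
#'   `gate_value`.
#' @export
infection_experiment <- function(n_events = 50000, infected_fraction = 0.7,
                                 separation = 4, doublet_fraction = 0.05,
                                 seed = 1, gate_quantile = 0.999,
                                 singlet_tolerance = 3) {
  ss <- derive_seeds(seed, c("condition", "control"))
  ev <- simulate_flow_events(n_events, infected_fraction,
                             separation = separation, seed = ss$condition,
                             doublet_fraction = doublet_fraction)
  ctl <- simulate_flow_events(n_events, 0, separation = separation,
                              seed = ss$control,
                              doublet_fraction = doublet_fraction,
                              condition = "uninfected")
  gev <- gate_singlets(ev, tolerance = singlet_tolerance)
  gctl <- gate_singlets(ctl, tolerance = singlet_tolerance)
  res <- percent_positive(gev, gctl, gate_quantile = gate_quantile)
  list(percent_positive = res$percent_positive,
       true_percent = 100 * mean(gev$true_infected),
       n_singlets = res$n_singlets, gate_value = res$gate_value)
}
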