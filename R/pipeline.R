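#' Build a validated pipeline run configuration
#'
#' Collects every stage parameter of the VOG analysis in one flat list with
#' defaults, rejects unknown keys, and attaches a configuration hash that is
#' embedded in every output artifact. Any two configurations differing in
#' any parameter hash differently.
#'
#' @param ... Named overrides of the defaults listed below.
#' @return A `run_config` list with a `hash` attribute.
#' @section Parameters:
#' * `numerical_aperture` (1.4), `emission_wavelength_um` (0.6),
#'   `refractive_index` (1.515) — PSF model.
#' * `decon_iterations` (15) — Richardson-Lucy iterations.
#' * `diameter_px` (7), `separation_px` (7), `min_mass` (NULL = Otsu),
#'   `threshold_percentile` (99.7), `noise_scale_px` (1) — detection.
#' * `threshold_um` (0.5) — colocalization centroid rule.
#' * `reference_channel` ("ref") — mature-capsid immunostain channel.
#' * `gate_quantile` (0.999), `singlet_tolerance` (3),
#'   `dunn_correction` ("holm") — infectivity statistics.
#' * `seed` (NULL), `input_paths` (NULL), `output_dir` (NULL).
#' @export
run_config <- function(...) {
  defaults <- list(
    numerical_aperture = 1.4, emission_wavelength_um = 0.6,
    refractive_index = 1.515, decon_iterations = 15,
    diameter_px = 7, separation_px = 7, min_mass = NULL,
    threshold_percentile = 99.7, noise_scale_px = 1,
    threshold_um = 0.5, reference_channel = "ref",
    gate_quantile = 0.999, singlet_tolerance = 3,
    dunn_correction = "holm",
    seed = NULL, input_paths = NULL, output_dir = NULL)
  over <- list(...)
  if (length(over) && (is.null(names(over)) || any(!nzchar(names(over)))))
    stop("all configuration overrides must be named")
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- modifyList(defaults, over, keep.null = TRUE)
  structure(cfg, hash = rlang::hash(cfg), class = "run_config")
}

#' Run the full virus-on-glass analysis
#'
#' Chains the stages of the single-virion analysis over one or more
#' calibrated image fields: Richardson-Lucy deconvolution per channel with
#' the theoretical PSF, Z maximum-intensity projection, per-channel particle
#' detection, and reference-anchored colocalization of every non-reference
#' channel at the configured centroid threshold, with counts pooled across
#' fields. When `output_dir` is set, detection CSVs, a colocalization JSON,
#' and a plain-text run log (all parameters, seeds, per-stage particle
#' counts, config hash) are written there.
#'
#' @param config A [run_config()].
#' @param fields List of `ImageField` objects; NULL reads
#'   `config$input_paths` with [read_image()].
#' @return A `vog_report` list: per-field, per-channel `detections`,
#'   pooled `coloc` per query channel (n_reference, n_paired, fraction,
#'   binomial CI), the config and its hash.
#' @export
run_pipeline <- function(config, fields = NULL) {
  stopifnot(inherits(config, "run_config"))
  log_lines <- c(sprintf("vogq run, config hash %s", attr(config, "hash")),
                 sprintf("  %s = %s", names(config),
                         vapply(config, function(v)
                           paste(format(v), collapse = ","), "")))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  if (is.null(fields)) {
    if (is.null(config$input_paths)) stop("no fields and no input_paths")
    fields <- stage("read", lapply(config$input_paths, read_image))
  }
  if (inherits(fields, "ImageField")) fields <- list(fields)

  detections <- vector("list", length(fields))
  for (fi in seq_along(fields)) {
    fld <- fields[[fi]]
    psf <- stage("psf", theoretical_psf(
      config$numerical_aperture, config$emission_wavelength_um,
      fld$pixel_size_um, fld$z_step_um,
      refractive_index = config$refractive_index))
    per_ch <- lapply(fld$channels, function(ch) {
      dec <- stage("deconvolve",
                   richardson_lucy(get_channel(fld, ch), psf,
                                   n_iter = config$decon_iterations))
      prj <- stage("project", max_project(dec))
      stage("detect", locate(
        prj, fld$pixel_size_um, diameter_px = config$diameter_px,
        separation_px = config$separation_px, min_mass = config$min_mass,
        threshold_percentile = config$threshold_percentile,
        noise_scale_px = config$noise_scale_px, channel = ch,
        photometry_image = sum_project(dec)))
    })
    names(per_ch) <- fld$channels
    detections[[fi]] <- per_ch
    log_lines <- c(log_lines, sprintf(
      "field %d: %s", fi, paste(fld$channels, "=",
                                vapply(per_ch, nrow, 1L),
                                "detections", collapse = ", ")))
  }

  ref <- config$reference_channel
  query_channels <- setdiff(fields[[1]]$channels, ref)
  coloc <- lapply(query_channels, function(qc) {
    n_ref <- 0L; n_paired <- 0L
    for (fi in seq_along(fields)) {
      fld <- fields[[fi]]
      rt <- detections[[fi]][[ref]]
      qt <- detections[[fi]][[qc]]
      if (nrow(rt) == 0) next
      bounds <- c(dim(fld$data)[2], dim(fld$data)[1]) * fld$pixel_size_um
      pr <- stage("colocalize", pair_to_reference(
        rt, qt, threshold_um = config$threshold_um, field_bounds = bounds))
      n_ref <- n_ref + pr$n_reference
      n_paired <- n_paired + nrow(pr$pairs)
    }
    if (n_ref == 0) stop("pipeline stage 'colocalize' failed: ",
                         "no reference detections in any field")
    cf <- colocalized_fraction(data.frame(ref_id = seq_len(n_paired)),
                               n_reference = n_ref)
    c(list(query_channel = qc, reference_channel = ref,
           threshold_um = config$threshold_um), cf)
  })
  names(coloc) <- query_channels
  log_lines <- c(log_lines, vapply(coloc, function(cc) sprintf(
    "coloc %s vs %s: %d/%d = %.1f%%", cc$query_channel, ref,
    cc$n_paired, cc$n_reference, 100 * cc$fraction), ""))

  report <- structure(list(detections = detections, coloc = coloc,
                           config = config,
                           config_hash = attr(config, "hash"),
                           log = log_lines), class = "vog_report")
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    for (fi in seq_along(detections))
      for (ch in names(detections[[fi]]))
        write_detections(detections[[fi]][[ch]], file.path(
          config$output_dir, sprintf("detections_field%02d_%s.csv", fi, ch)))
    jsonlite::write_json(
      list(config_hash = attr(config, "hash"),
           coloc = lapply(coloc, function(cc)
             cc[c("query_channel", "reference_channel", "threshold_um",
                  "fraction", "n_paired", "n_reference", "conf_int")])),
      file.path(config$output_dir, "coloc.json"),
      auto_unbox = TRUE, digits = NA)
    writeLines(log_lines, file.path(config$output_dir, "run_log.txt"))
  }
  report
}

#' @export
print.vog_report <- function(x, ...) {
  cat("VOG analysis report (config ", x$config_hash, ")\n", sep = "")
  for (cc in x$coloc)
    cat(sprintf("  %s vs %s: %d/%d colocalized = %.1f%% (< %.3f um)\n",
                cc$query_channel, cc$reference_channel, cc$n_paired,
                cc$n_reference, 100 * cc$fraction, cc$threshold_um))
  invisible(x)
}
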