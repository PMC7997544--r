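#' Simulate flow-cytometry-like event tables
#'
#' Generates per-event forward/side scatter (log-normal, all positive) and a
#' GFP intensity drawn from a two-component log-normal mixture: the infected
#' component is shifted `separation` standard deviations (on the log scale)
#' above the uninfected one. A doublet subpopulation carries inflated
#' width-to-height scatter ratios, which the singlet gate is meant to
#' remove. Ground-truth infection status is recorded per event.
#'
#' @param n_events Number of events (>= 1).
#' @param infected_fraction True fraction of infected cells in `[0, 1]`.
#' @param separation Shift of the infected log-GFP component, in SD units.
#'   Default 4.
#' @param seed Integer seed or NULL.
#' @param doublet_fraction Fraction of events that are doublets. Default
#'   0.05.
#' @param doublet_width_factor Width inflation of doublets. Default 2.
#' @param condition Condition label recorded on every event.
#' @param gfp_log_mean,gfp_log_sd Uninfected log10-GFP location and scale.
#' @param infected_sd_ratio Spread of the infected log-GFP component
#'   relative to the uninfected one. Default 0.4: a reporter driven by an
#'   integrated provirus forms a tight bright population compared to the
#'   broad autofluorescence-plus-debris negative cloud, and a control gate
#'   at the 0.999 quantile then recovers the true infected fraction at
#'   component separations of about 4 SD.
#' @return A `flow_event_table` data.frame with columns `FSC-H`, `FSC-W`,
#'   `SSC-H`, `SSC-W`, `fluor`, `condition`, `true_infected`,
#'   `true_doublet`.
#' @export
simulate_flow_events <- function(n_events, infected_fraction,
                                 separation = 4, seed = NULL,
                                 doublet_fraction = 0.05,
                                 doublet_width_factor = 2,
                                 condition = "sample",
                                 gfp_log_mean = 2, gfp_log_sd = 0.25,
                                 infected_sd_ratio = 0.4) {
  stopifnot(n_events >= 1, infected_fraction >= 0, infected_fraction <= 1,
            doublet_fraction >= 0, doublet_fraction < 1)
  ss <- derive_seeds(seed, c("scatter", "doublet", "infect", "gfp"))
  sc <- with_seed(ss$scatter, list(fsc = rlnorm(n_events, log(5e4), 0.15),
                                   ssc = rlnorm(n_events, log(3e4), 0.2)))
  fsc_h <- sc$fsc
  ssc_h <- sc$ssc
  # width tracks height with small event-level jitter
  jit <- with_seed(ss$doublet, list(
    w1 = rlnorm(n_events, 0, 0.03), w2 = rlnorm(n_events, 0, 0.03),
    dbl = runif(n_events) < doublet_fraction))
  dbl <- jit$dbl
  fsc_w <- fsc_h * jit$w1 * ifelse(dbl, doublet_width_factor, 1)
  ssc_w <- ssc_h * jit$w2 * ifelse(dbl, doublet_width_factor, 1)
  inf <- with_seed(ss$infect, runif(n_events) < infected_fraction)
  lg <- with_seed(ss$gfp,
                  rnorm(n_events,
                        gfp_log_mean + ifelse(inf, separation * gfp_log_sd,
                                              0),
                        ifelse(inf, infected_sd_ratio * gfp_log_sd,
                               gfp_log_sd)))
  out <- data.frame(`FSC-H` = fsc_h, `FSC-W` = fsc_w,
                    `SSC-H` = ssc_h, `SSC-W` = ssc_w,
                    fluor = 10^lg, condition = condition,
                    true_infected = inf, true_doublet = dbl,
                    check.names = FALSE)
  class(out) <- c("flow_event_table", "data.frame")
  out
}

#' Simulate a luciferase (RLU) plate table
#'
#' Replicate relative-light-unit readouts per condition with multiplicative
#' log-normal noise around `rlu_per_p24 * p24_ng` plus a shared assay
#' background. Background conditions (uninfected, raltegravir-treated, or
#' catalytically dead integrase without rescue) are generated at background
#' level, i.e. with zero potency.
#'
#' @param conditions Data.frame with columns `condition`, `rlu_per_p24`
#'   (potency, RLU per ng p24; 0 for background conditions), `p24_ng`
#'   (viral input, > 0).
#' @param seed Integer seed or NULL.
#' @param n_replicates Replicates per condition. Default 3.
#' @param noise_cv Coefficient of variation of the multiplicative noise;
#'   0 gives exact replicates. Default 0.15.
#' @param background_rlu Assay background added to every well. Default 100.
#' @return Data.frame with `condition`, `replicate`, `rlu`.
#' @export
simulate_rlu_table <- function(conditions, seed = NULL, n_replicates = 3,
                               noise_cv = 0.15, background_rlu = 100) {
  stopifnot(is.data.frame(conditions),
            all(c("condition", "rlu_per_p24", "p24_ng") %in%
                  names(conditions)),
            all(conditions$p24_ng > 0), all(conditions$rlu_per_p24 >= 0),
            n_replicates >= 1, noise_cv >= 0)
  with_seed(seed, do.call(rbind, lapply(seq_len(nrow(conditions)),
    function(i) {
      mu <- conditions$rlu_per_p24[i] * conditions$p24_ng[i] +
        background_rlu
      fac <- if (noise_cv == 0) rep(1, n_replicates) else {
        sdlog <- sqrt(log(1 + noise_cv^2))
        rlnorm(n_replicates, -sdlog^2 / 2, sdlog)
      }
      data.frame(condition = conditions$condition[i],
                 replicate = seq_len(n_replicates), rlu = mu * fac)
    })))
}
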