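#' Gate singlet events by scatter width-to-height ratios
#'
#' Cell doublets carry inflated pulse-width-to-height ratios on forward and
#' side scatter. The gate keeps events whose `FSC-W/FSC-H` and `SSC-W/SSC-H`
#' ratios lie within a robust band fitted on all events: median +/-
#' `tolerance` times the MAD-scaled spread, per axis. A table that already
#' carries a singlet gate at the same tolerance is returned unchanged, so
#' gating is idempotent.
#'
#' @param events A `flow_event_table` (or data.frame with the four scatter
#'   columns).
#' @param tolerance Band half-width in robust SD units. Default 3.
#' @return The gated table, with the fitted band recorded in the
#'   `singlet_gate` attribute.
#' @export
gate_singlets <- function(events, tolerance = 3) {
  stopifnot(nrow(events) > 0, tolerance > 0)
  prev <- attr(events, "singlet_gate")
  if (!is.null(prev) && identical(prev$tolerance, tolerance)) return(events)
  band <- function(r) {
    m <- median(r); s <- mad(r)
    c(m - tolerance * s, m + tolerance * s)
  }
  r_f <- events[["FSC-W"]] / events[["FSC-H"]]
  r_s <- events[["SSC-W"]] / events[["SSC-H"]]
  b_f <- band(r_f); b_s <- band(r_s)
  keep <- r_f >= b_f[1] & r_f <= b_f[2] & r_s >= b_s[1] & r_s <= b_s[2]
  if (!any(keep)) stop("singlet gate rejected all events")
  out <- events[keep, , drop = FALSE]
  attr(out, "singlet_gate") <- list(tolerance = tolerance,
                                    fsc_band = b_f, ssc_band = b_s,
                                    n_in = nrow(events), n_kept = sum(keep))
  out
}

#' Percent GFP-positive against a non-infected control
#'
#' The GFP gate is the given quantile of the control (non-infected) events'
#' fluorescence; `percent_positive` is the percentage of condition events
#' strictly above it. Both tables should be singlet-gated first.
#'
#' @param events Gated condition events.
#' @param control_events Gated non-infected control events (set the gate).
#' @param gate_quantile Control quantile defining the gate. Default 0.999.
#' @return An `infection_result` list: condition, n_singlets,
#'   percent_positive, gate_value, control_condition.
#' @export
percent_positive <- function(events, control_events, gate_quantile = 0.999) {
  stopifnot(nrow(events) > 0, nrow(control_events) > 0,
            gate_quantile > 0, gate_quantile < 1)
  gate <- quantile(control_events$fluor, gate_quantile, names = FALSE)
  pct <- 100 * mean(events$fluor > gate)
  structure(list(condition = as.character(events$condition[1]),
                 n_singlets = nrow(events), percent_positive = pct,
                 gate_value = gate, gate_quantile = gate_quantile,
                 control_condition =
                   as.character(control_events$condition[1])),
            class = "infection_result")
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square p-value on k - 1 degrees
#' of freedom (delegates to [stats::kruskal.test()]). Identical values in
#' all groups give H = 0, p = 1.
#'
#' @param groups List of two or more non-empty numeric vectors.
#' @return list(H, p_value, df).
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2,
            all(lengths(groups) >= 1))
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(x)) == 1)
    return(list(H = 0, p_value = 1, df = length(groups) - 1))
  kt <- kruskal.test(x, g)
  list(H = unname(kt$statistic), p_value = kt$p.value,
       df = unname(kt$parameter))
}

#' Dunn's post-hoc multiple comparisons
#'
#' Pairwise z statistics from mean-rank differences on the pooled ranking,
#' with tie-corrected pooled variance
#' `(N(N+1)/12 - T/(12(N-1))) * (1/n_i + 1/n_j)` where
#' `T = sum(t^3 - t)` over tie groups, and p-values adjusted by the chosen
#' correction ([stats::p.adjust()]).
#'
#' @param groups Named (optionally) list of numeric vectors, all non-empty.
#' @param correction Adjustment method, default `"holm"`.
#' @return A `rank_test_result`: the Kruskal-Wallis H and p on the same
#'   pooled ranks, and a `pairwise` data.frame with z, raw and adjusted p.
#' @export
dunn_test <- function(groups, correction = "holm") {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(lengths(groups) == 0)) stop("all groups must be non-empty")
  nms <- names(groups) %||% as.character(seq_along(groups))
  nms[!nzchar(nms)] <- as.character(which(!nzchar(nms)))
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  n <- lengths(groups)
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties)
  var_base <- N * (N + 1) / 12 - tie_term / (12 * (N - 1))
  cmb <- utils::combn(length(groups), 2)
  pw <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(k) {
    i <- cmb[1, k]; j <- cmb[2, k]
    se <- sqrt(var_base * (1 / n[i] + 1 / n[j]))
    z <- if (se > 0) (rbar[i] - rbar[j]) / se else 0
    data.frame(group1 = nms[i], group2 = nms[j], z = unname(z),
               p_raw = 2 * stats::pnorm(-abs(z)))
  }))
  pw$p_adj <- pmin(p.adjust(pw$p_raw, method = correction), 1)
  kw <- kruskal_wallis(groups)
  structure(list(H = kw$H, p_value = kw$p_value, pairwise = pw,
                 correction = correction),
            class = "rank_test_result")
}

#' p24-normalized luciferase summary
#'
#' Subtracts the assay background (mean RLU of the designated background
#' wells) and divides by each condition's p24 input, yielding RLU per ng p24
#' with replicate mean and SD per condition.
#'
#' @param rlu_table Data.frame with `condition`, `rlu` (replicate rows).
#' @param p24_table Data.frame with `condition`, `p24_ng` (> 0); every
#'   non-background condition must appear.
#' @param background_condition Condition label(s) whose wells define the
#'   background (e.g. uninfected). Default "uninfected".
#' @return Data.frame with `condition`, `n`, `mean_rlu_per_p24`,
#'   `sd_rlu_per_p24`; background conditions are excluded from the output.
#' @export
rlu_normalize <- function(rlu_table, p24_table,
                          background_condition = "uninfected") {
  stopifnot(all(c("condition", "rlu") %in% names(rlu_table)),
            all(c("condition", "p24_ng") %in% names(p24_table)),
            all(p24_table$p24_ng > 0))
  bg_rows <- rlu_table$condition %in% background_condition
  bg <- if (any(bg_rows)) mean(rlu_table$rlu[bg_rows]) else 0
  conds <- setdiff(unique(rlu_table$condition), background_condition)
  missing_p24 <- setdiff(conds, p24_table$condition)
  if (length(missing_p24))
    stop("missing p24 input for condition(s): ",
         paste(missing_p24, collapse = ", "))
  do.call(rbind, lapply(conds, function(cd) {
    v <- rlu_table$rlu[rlu_table$condition == cd] - bg
    p24 <- p24_table$p24_ng[match(cd, p24_table$condition)]
    data.frame(condition = cd, n = length(v),
               mean_rlu_per_p24 = mean(v) / p24,
               sd_rlu_per_p24 = sd(v) / p24)
  }))
}
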