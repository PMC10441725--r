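# Partitioned-survival cohort trace: per-cycle occupancy of the three
# mutually exclusive health states (progression free, progressed disease,
# dead) read directly off the fitted PFS and OS curves. This reproduces
# the fitted curves exactly: PFS membership is S_PFS(t), death is
# 1 - S_OS(t), and progressed disease is the difference, clamped at zero
# where the extrapolated curves cross.

#' Cycle time grid
#'
#' Times (months) of cycle boundaries `k * cycle_length / 30.4375` for
#' `k = 0 ... ceil(horizon_years * 365.25 / cycle_length_days)`; the last
#' point is at or beyond the horizon.
#'
#' @param settings A [model_settings()].
#' @return Numeric vector of times in months.
#' @export
cycle_grid <- function(settings) {
  if (!inherits(settings, "model_settings"))
    stop_oncocea("'settings' must be a model_settings object",
                 "oncocea_invalid_argument")
  k_max <- ceiling(settings$horizon_years * 365.25 /
                     settings$cycle_length_days)
  (0:k_max) * settings$cycle_length_days / MONTH_DAYS
}

#' Discount factor
#'
#' Continuous-in-time convention \eqn{(1 + r)^{-t/12}} with `t` in months
#' and `r` the annual rate.
#'
#' @param t Time in months (>= 0).
#' @param rate Annual discount rate (>= 0).
#' @return Discount multipliers.
#' @export
discount_factor <- function(t, rate) {
  if (any(t < 0) || any(rate < 0))
    stop_oncocea("'t' and 'rate' must be non-negative",
                 "oncocea_domain_error")
  (1 + rate)^(-t / 12)
}

# Tolerated extrapolated PFS/OS curve crossing before a warning finding
# is attached to the trace.
CROSSING_TOLERANCE <- 0.02

#' Build the partitioned-survival cohort trace
#'
#' State occupancy at each cycle boundary: `pfs = min(S_pfs, S_os)`,
#' `dead = 1 - S_os`, `pd = S_os - pfs` (so the three always sum to 1).
#' Where the extrapolated PFS curve exceeds the OS curve the PD occupancy
#' is clamped at zero; if the excess exceeds 0.02 anywhere a warning
#' finding is attached (attribute `findings`), alongside the maximum
#' excess (attribute `crossing_max`).
#'
#' @param pfs,os [surv_spec()] objects for the arm's endpoints.
#' @param settings A [model_settings()].
#' @param discount_rate Annual discount rate used for the trace's
#'   `discount_factor` column.
#' @return A `cohort_trace` data frame with columns `cycle`,
#'   `time_months`, `pfs`, `pd`, `dead`, `incident_deaths`,
#'   `discount_factor`, and attributes `cycle_length_months`,
#'   `half_cycle_correction`, `crossing_max`, `findings`.
#' @export
partitioned_trace <- function(pfs, os, settings = model_settings(),
                              discount_rate = 0.03) {
  assert_surv_spec(pfs, "pfs"); assert_surv_spec(os, "os")
  tt <- cycle_grid(settings)
  s_pfs <- surv_prob(pfs, tt)
  s_os <- surv_prob(os, tt)
  crossing <- max(0, max(s_pfs - s_os))
  occ_pfs <- pmin(s_pfs, s_os)
  occ_pd <- s_os - occ_pfs
  occ_dead <- 1 - s_os
  tr <- data.frame(cycle = seq_along(tt) - 1L, time_months = tt,
                   pfs = occ_pfs, pd = occ_pd, dead = occ_dead,
                   incident_deaths = c(0, pmax(0, diff(occ_dead))),
                   discount_factor = discount_factor(tt, discount_rate))
  findings <- if (crossing > CROSSING_TOLERANCE)
    sprintf(paste0("extrapolated PFS exceeds OS by up to %.4f ",
                   "(tolerance %.2f); PD occupancy clamped at 0"),
            crossing, CROSSING_TOLERANCE) else character()
  structure(tr,
            class = c("cohort_trace", "data.frame"),
            cycle_length_months = settings$cycle_length_days / MONTH_DAYS,
            half_cycle_correction = settings$half_cycle_correction,
            discount_rate = discount_rate,
            crossing_max = crossing,
            findings = findings)
}

# Per-cycle discounted occupancy weights for accrual: with half-cycle
# correction the trapezoid (start + end of cycle)/2 of occ(t) * df(t),
# otherwise the end-of-cycle value. Returns one weight per cycle 1..K.
cycle_weights <- function(trace, column, discounted = TRUE) {
  x <- trace[[column]]
  d <- if (discounted) trace$discount_factor else 1
  v <- x * d
  if (isTRUE(attr(trace, "half_cycle_correction")))
    (v[-1] + v[-length(v)]) / 2
  else
    v[-1]
}

#' Export a cohort trace as CSV
#'
#' @param trace A `cohort_trace`.
#' @param path Output file path.
#' @export
write_trace <- function(trace, path) {
  if (!inherits(trace, "cohort_trace"))
    stop_oncocea("'trace' must be a cohort_trace", "oncocea_invalid_argument")
  write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
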