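# Cost, life-year and QALY accrual along a cohort trace, and incremental
# cost-effectiveness comparison of two strategies.

effective_u_pfs <- function(econ, arm) arm$utility_pfs %||% econ$utility_pfs

ae_qaly_decrement <- function(econ, arm, trace) {
  shared <- intersect(names(arm$ae_risks), names(econ$disutilities))
  if (length(shared) == 0) return(0)
  cyc_years <- attr(trace, "cycle_length_months") * MONTH_DAYS / 365.25
  # one-off decrement lasting one model cycle, discounted at first cycle
  sum(arm$ae_risks[shared] * econ$disutilities[shared]) * cyc_years *
    trace$discount_factor[2]
}

#' Accrue life-years and QALYs along a trace
#'
#' Life-years are the per-cycle discounted PFS + PD occupancy times the
#' cycle length; QALYs weight the two states by their utilities and
#' subtract a one-off adverse-event decrement
#' \eqn{\sum_{AE} \mathrm{risk} \times \mathrm{disutility}} lasting one
#' model cycle, applied at model entry.
#'
#' @param trace A [partitioned_trace()].
#' @param econ [economic_inputs()].
#' @param arm [arm_params()].
#' @return List with `ly`, `qaly` (discounted years) and
#'   `ly_undiscounted`, `qaly_undiscounted`.
#' @export
accrue_effects <- function(trace, econ, arm) {
  cyc_m <- attr(trace, "cycle_length_months")
  u_pfs <- effective_u_pfs(econ, arm)
  u_pd <- econ$utility_pd
  ae_dec <- ae_qaly_decrement(econ, arm, trace)
  one <- function(discounted) {
    w_pfs <- cycle_weights(trace, "pfs", discounted)
    w_pd <- cycle_weights(trace, "pd", discounted)
    list(ly = sum(w_pfs + w_pd) * cyc_m / 12,
         qaly = sum(u_pfs * w_pfs + u_pd * w_pd) * cyc_m / 12 -
           (if (discounted) ae_dec else ae_dec / trace$discount_factor[2]))
  }
  d <- one(TRUE); u <- one(FALSE)
  list(ly = d$ly, qaly = d$qaly,
       ly_undiscounted = u$ly, qaly_undiscounted = u$qaly)
}

# rolling sum of the last `dur` entries (including current), linear time
rolling_sum <- function(x, dur) {
  cs <- cumsum(x)
  cs - c(rep(0, min(dur, length(x))), utils::head(cs, -dur))
}

#' Accrue itemized costs along a trace
#'
#' Components (all USD, discounted unless `discounted = FALSE`):
#' * `maintenance_drugs`: olaparib (up to its cycle cap) and bevacizumab
#'   (up to its cap, rescaled by `body_weight / 70`), both weighted by
#'   PFS occupancy.
#' * `administration`: IV administration on bevacizumab cycles.
#' * `laboratory`, `imaging`: per-cycle monitoring while progression free.
#' * `testing`: one-off germline BRCA + HRD testing at model entry (both
#'   arms; disable by zeroing the test costs).
#' * `ae_management`: one-off adverse-event management at model entry.
#' * `second_line`: the arm's second-line proportion of each cycle's
#'   incident PD inflow receives carboplatin + paclitaxel (paclitaxel
#'   rescaled by `body_surface_area / 1.84`) plus administration for
#'   `second_line_duration_cycles` cycles from entry.
#' * `bsc`: best supportive care for PD occupancy not on second-line
#'   chemotherapy.
#' * `terminal_care`: one-off cost applied to each cycle's incident
#'   deaths.
#'
#' @inheritParams accrue_effects
#' @param patient [patient_profile()].
#' @param discounted Accrue with (default) or without discounting.
#' @return Named numeric vector of cost components.
#' @export
accrue_costs <- function(trace, econ, arm, patient = patient_profile(),
                         discounted = TRUE) {
  k <- seq_len(nrow(trace) - 1L)
  w_pfs <- cycle_weights(trace, "pfs", discounted)
  w_pd <- cycle_weights(trace, "pd", discounted)
  df_end <- if (discounted) trace$discount_factor[-1] else rep(1, length(k))
  bev_scale <- patient$body_weight / 70
  on_bev <- k <= arm$bevacizumab_max_cycles & arm$bevacizumab_cost_per_cycle > 0
  maintenance <-
    arm$olaparib_cost_per_cycle * sum(w_pfs[k <= arm$olaparib_max_cycles]) +
    arm$bevacizumab_cost_per_cycle * bev_scale * sum(w_pfs[on_bev])
  administration <- econ$admin_cost_per_cycle * sum(w_pfs[on_bev])
  laboratory <- econ$lab_cost_per_cycle * sum(w_pfs)
  imaging <- econ$imaging_cost_per_cycle * sum(w_pfs)
  testing <- econ$brca_test_cost + econ$hrd_test_cost
  ae_management <- arm$ae_management_cost
  # incident PD inflow = per-cycle decline of PFS occupancy, floored at 0
  inflow <- pmax(0, -diff(trace$pfs))
  sl_occ <- arm$second_line_proportion *
    rolling_sum(inflow, max(1L, econ$second_line_duration_cycles))
  if (econ$second_line_duration_cycles == 0L) sl_occ <- 0 * inflow
  sl_price <- econ$carboplatin_cost_per_cycle +
    econ$paclitaxel_cost_per_cycle * patient$body_surface_area / 1.84 +
    econ$admin_cost_per_cycle
  second_line <- sum(sl_occ * sl_price * df_end)
  bsc <- econ$bsc_cost_per_cycle * sum(pmax(0, w_pd - sl_occ * df_end))
  terminal_care <- econ$terminal_care_cost *
    sum(trace$incident_deaths[-1] * df_end)
  c(maintenance_drugs = maintenance, administration = administration,
    laboratory = laboratory, imaging = imaging, testing = testing,
    ae_management = ae_management, second_line = second_line,
    bsc = bsc, terminal_care = terminal_care)
}

#' Evaluate one strategy of an analysis
#'
#' Builds the arm's partitioned-survival trace and accrues discounted
#' (and undiscounted) costs, life-years and QALYs.
#'
#' @param inputs An [analysis_inputs()] object.
#' @param arm `"intervention"` or `"comparator"`.
#' @return A `strategy_outcome` list: `arm`, `name`, `total_cost`, `ly`,
#'   `qaly`, `cost_components`, undiscounted variants, and the trace's
#'   validation findings (if any) as attribute `findings`.
#' @export
evaluate_strategy <- function(inputs, arm = c("intervention", "comparator")) {
  arm <- match.arg(arm)
  a <- inputs$arms[[arm]]
  trace <- partitioned_trace(a$pfs, a$os, inputs$settings,
                             inputs$econ$discount_rate_annual)
  eff <- accrue_effects(trace, inputs$econ, a)
  comp <- accrue_costs(trace, inputs$econ, a, inputs$patient)
  comp_undisc <- accrue_costs(trace, inputs$econ, a, inputs$patient,
                              discounted = FALSE)
  structure(list(arm = arm, name = a$name,
                 total_cost = sum(comp), ly = eff$ly, qaly = eff$qaly,
                 cost_components = comp,
                 total_cost_undiscounted = sum(comp_undisc),
                 ly_undiscounted = eff$ly_undiscounted,
                 qaly_undiscounted = eff$qaly_undiscounted),
            class = "strategy_outcome",
            findings = attr(trace, "findings"))
}

#' @export
print.strategy_outcome <- function(x, ...) {
  cat(sprintf("<strategy_outcome> %s (%s)\n", x$arm, x$name))
  cat(sprintf("  total cost $%s   LYs %.3f   QALYs %.3f (discounted)\n",
              format(round(x$total_cost), big.mark = ","), x$ly, x$qaly))
  comp <- x$cost_components
  for (nm in names(comp))
    cat(sprintf("    %-18s $%s\n", nm,
                format(round(comp[[nm]]), big.mark = ",")))
  invisible(x)
}

#' Incremental cost-effectiveness comparison
#'
#' Deltas are intervention minus comparator. `status` is `"dominant"`
#' when the intervention is cheaper and more effective, `"dominated"`
#' when costlier and less effective, otherwise `"tradeoff"` with ICERs.
#' A zero QALY (LY) delta with a non-zero cost delta yields a signed
#' infinite ICER; identical outcomes yield `NaN`.
#'
#' @param intervention,comparator `strategy_outcome` objects from
#'   [evaluate_strategy()].
#' @return A `ce_comparison` list with `delta_cost`, `delta_ly`,
#'   `delta_qaly`, `icer_per_qaly`, `icer_per_ly`, `status`.
#' @export
compare <- function(intervention, comparator) {
  dc <- intervention$total_cost - comparator$total_cost
  dq <- intervention$qaly - comparator$qaly
  dl <- intervention$ly - comparator$ly
  status <- if (dc < 0 && dq > 0) "dominant"
            else if (dc > 0 && dq < 0) "dominated"
            else "tradeoff"
  ratio <- function(dx) {
    if (dx == 0) { if (dc == 0) NaN else sign(dc) * Inf } else dc / dx
  }
  structure(list(delta_cost = dc, delta_ly = dl, delta_qaly = dq,
                 icer_per_qaly = ratio(dq), icer_per_ly = ratio(dl),
                 status = status),
            class = "ce_comparison")
}

#' @export
print.ce_comparison <- function(x, ...) {
  cat("<ce_comparison>\n")
  cat(sprintf("  incremental cost  $%s\n",
              format(round(x$delta_cost), big.mark = ",")))
  cat(sprintf("  incremental LYs    %.3f   QALYs %.3f\n",
              x$delta_ly, x$delta_qaly))
  cat(sprintf("  ICER  $%s/QALY   $%s/LY   [%s]\n",
              format(round(x$icer_per_qaly), big.mark = ","),
              format(round(x$icer_per_ly), big.mark = ","), x$status))
  invisible(x)
}

#' Net monetary benefit
#'
#' \eqn{\mathrm{NMB} = \mathrm{WTP} \cdot \Delta\mathrm{QALY} - \Delta\mathrm{cost}};
#' positive means cost-effective at that willingness-to-pay.
#'
#' @param delta_cost Incremental cost, USD.
#' @param delta_qaly Incremental QALYs.
#' @param wtp Willingness-to-pay threshold, USD/QALY (>= 0).
#' @return NMB in USD.
#' @export
net_monetary_benefit <- function(delta_cost, delta_qaly, wtp) {
  if (any(wtp < 0))
    stop_oncocea("'wtp' must be non-negative", "oncocea_domain_error")
  wtp * delta_qaly - delta_cost
}

#' Run the full base case for one analysis
#'
#' @param inputs An [analysis_inputs()] object.
#' @return List with both `strategy_outcome`s and the `ce_comparison`.
#' @export
run_base_case <- function(inputs) {
  int <- evaluate_strategy(inputs, "intervention")
  cmp <- evaluate_strategy(inputs, "comparator")
  list(intervention = int, comparator = cmp, comparison = compare(int, cmp))
}
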