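# Typed model inputs: treatment arms, economic inputs, patient profile,
# model settings, PSA parameter specifications, and the assembled
# analysis_inputs bundle, plus structural validation.

#' Treatment-arm parameters
#'
#' @param name Arm label.
#' @param pfs,os [surv_spec()] objects for progression-free and overall
#'   survival.
#' @param olaparib_cost_per_cycle,bevacizumab_cost_per_cycle Drug
#'   acquisition cost per 3-week cycle, USD. Bevacizumab is dosed by body
#'   weight; its cost is rescaled by `body_weight / 70` at accrual time.
#' @param olaparib_max_cycles,bevacizumab_max_cycles Treatment caps in
#'   cycles (0 = agent not given).
#' @param ae_risks Named numeric vector of grade >= 3 adverse-event risks.
#' @param ae_management_cost One-off AE management cost at model entry, USD.
#' @param second_line_proportion Proportion of progressing patients who
#'   receive active second-line chemotherapy.
#' @param utility_pfs Optional arm-specific PFS utility override; when
#'   `NULL` the shared [economic_inputs()] PFS utility applies. Used by
#'   the sensitivity analyses, which vary the two arms' PFS utilities
#'   independently.
#' @return An `arm_params` object.
#' @export
arm_params <- function(name, pfs, os,
                       olaparib_cost_per_cycle = 0,
                       bevacizumab_cost_per_cycle = 0,
                       olaparib_max_cycles = 0,
                       bevacizumab_max_cycles = 0,
                       ae_risks = numeric(),
                       ae_management_cost = 0,
                       second_line_proportion = 0,
                       utility_pfs = NULL) {
  assert_surv_spec(pfs, "pfs"); assert_surv_spec(os, "os")
  structure(list(name = as.character(name), pfs = pfs, os = os,
                 olaparib_cost_per_cycle = olaparib_cost_per_cycle,
                 bevacizumab_cost_per_cycle = bevacizumab_cost_per_cycle,
                 olaparib_max_cycles = as.integer(olaparib_max_cycles),
                 bevacizumab_max_cycles = as.integer(bevacizumab_max_cycles),
                 ae_risks = ae_risks,
                 ae_management_cost = ae_management_cost,
                 second_line_proportion = second_line_proportion,
                 utility_pfs = utility_pfs),
            class = "arm_params")
}

#' Shared economic inputs
#'
#' Utilities, per-cycle and one-off costs, the discount rate and the
#' willingness-to-pay threshold. All costs are USD. Second-line
#' chemotherapy is carboplatin plus paclitaxel; its two drug prices are
#' kept separate so each can be varied in sensitivity analyses, and
#' paclitaxel (dosed by body surface area) is rescaled by
#' `body_surface_area / 1.84` at accrual time.
#'
#' @param utility_pfs,utility_pd Health-state utilities in \[0, 1\].
#' @param disutilities Named numeric vector of one-off AE disutility
#'   decrements.
#' @param admin_cost_per_cycle IV administration cost per cycle.
#' @param lab_cost_per_cycle,imaging_cost_per_cycle Routine monitoring
#'   costs per cycle, accrued while progression free.
#' @param brca_test_cost,hrd_test_cost One-off molecular testing costs,
#'   charged once per patient in both arms at model entry.
#' @param carboplatin_cost_per_cycle,paclitaxel_cost_per_cycle Second-line
#'   chemotherapy drug costs per cycle.
#' @param second_line_duration_cycles Cycles of second-line chemotherapy
#'   before transition to best supportive care.
#' @param bsc_cost_per_cycle Best-supportive-care cost per cycle in the
#'   progressed-disease state.
#' @param terminal_care_cost One-off terminal-care cost at death.
#' @param discount_rate_annual Annual discount rate (fraction per year).
#' @param wtp_per_qaly Willingness-to-pay threshold, USD per QALY.
#' @return An `economic_inputs` object.
#' @export
economic_inputs <- function(utility_pfs, utility_pd,
                            disutilities = numeric(),
                            admin_cost_per_cycle = 0,
                            lab_cost_per_cycle = 0,
                            imaging_cost_per_cycle = 0,
                            brca_test_cost = 0, hrd_test_cost = 0,
                            carboplatin_cost_per_cycle = 0,
                            paclitaxel_cost_per_cycle = 0,
                            second_line_duration_cycles = 6L,
                            bsc_cost_per_cycle = 0,
                            terminal_care_cost = 0,
                            discount_rate_annual = 0.03,
                            wtp_per_qaly = 150000) {
  structure(list(utility_pfs = utility_pfs, utility_pd = utility_pd,
                 disutilities = disutilities,
                 admin_cost_per_cycle = admin_cost_per_cycle,
                 lab_cost_per_cycle = lab_cost_per_cycle,
                 imaging_cost_per_cycle = imaging_cost_per_cycle,
                 brca_test_cost = brca_test_cost,
                 hrd_test_cost = hrd_test_cost,
                 carboplatin_cost_per_cycle = carboplatin_cost_per_cycle,
                 paclitaxel_cost_per_cycle = paclitaxel_cost_per_cycle,
                 second_line_duration_cycles =
                   as.integer(second_line_duration_cycles),
                 bsc_cost_per_cycle = bsc_cost_per_cycle,
                 terminal_care_cost = terminal_care_cost,
                 discount_rate_annual = discount_rate_annual,
                 wtp_per_qaly = wtp_per_qaly),
            class = "economic_inputs")
}

#' Reference patient profile
#'
#' Used to rescale weight-based (bevacizumab) and surface-area-based
#' (paclitaxel) drug costs relative to the reference 70 kg / 1.84 m2
#' patient the per-cycle prices were costed for.
#'
#' @param body_weight Body weight, kg.
#' @param body_surface_area Body surface area, m2.
#' @param serum_creatinine Serum creatinine, mg/dL (carried for carboplatin
#'   AUC dosing context; not used in cost scaling).
#' @return A `patient_profile` object.
#' @export
patient_profile <- function(body_weight = 70, body_surface_area = 1.84,
                            serum_creatinine = 1) {
  structure(list(body_weight = body_weight,
                 body_surface_area = body_surface_area,
                 serum_creatinine = serum_creatinine),
            class = "patient_profile")
}

#' Cohort-model settings
#'
#' @param cycle_length_days Model cycle length in days (default 21, a
#'   3-week cycle).
#' @param horizon_years Time horizon in years (default 15, by which point
#'   essentially the whole cohort is deceased under the bundled curves).
#' @param half_cycle_correction Apply trapezoidal half-cycle correction to
#'   all per-cycle accruals (default `TRUE`).
#' @return A `model_settings` object.
#' @export
model_settings <- function(cycle_length_days = 21, horizon_years = 15,
                           half_cycle_correction = TRUE) {
  if (cycle_length_days <= 0)
    stop_oncocea("'cycle_length_days' must be positive",
                 "oncocea_invalid_argument")
  if (horizon_years <= 0)
    stop_oncocea("'horizon_years' must be positive",
                 "oncocea_invalid_argument")
  structure(list(cycle_length_days = cycle_length_days,
                 horizon_years = horizon_years,
                 half_cycle_correction = isTRUE(half_cycle_correction)),
            class = "model_settings")
}

#' PSA parameter specification
#'
#' Distribution assignment for one input parameter of the probabilistic
#' sensitivity analysis. `name` is a parameter path resolvable by
#' [set_param()].
#'
#' @param name Parameter path (e.g. `"econ.utility_pfs"`).
#' @param family `"beta"`, `"gamma"`, `"normal"`, `"uniform"` or `"fixed"`.
#' @param mean Baseline (mean) value.
#' @param low,high Range; interpreted as a 95% interval for the
#'   moment-matched beta/gamma/normal families and as hard bounds for
#'   uniform and the normal truncation.
#' @return A `psa_param` object.
#' @export
psa_param <- function(name, family, mean, low = mean, high = mean) {
  family <- match.arg(family, PSA_FAMILIES)
  structure(list(name = name, family = family, mean = mean,
                 low = low, high = high),
            class = "psa_param")
}

#' Assembled analysis inputs
#'
#' @param subgroup One of `"overall"`, `"brca_mut"`, `"hrd_pos"`,
#'   `"hrd_pos_brca_wt"`.
#' @param intervention,comparator [arm_params()] for the two strategies.
#' @param econ [economic_inputs()].
#' @param patient [patient_profile()].
#' @param settings [model_settings()].
#' @param psa_specs List of [psa_param()] objects.
#' @return An `analysis_inputs` object.
#' @export
analysis_inputs <- function(subgroup, intervention, comparator, econ,
                            patient = patient_profile(),
                            settings = model_settings(),
                            psa_specs = list()) {
  subgroup <- match.arg(subgroup, SUBGROUP_IDS)
  for (a in list(intervention, comparator))
    if (!inherits(a, "arm_params"))
      stop_oncocea("both arms must be arm_params objects",
                   "oncocea_validation_error")
  x <- structure(list(subgroup = subgroup,
                      arms = list(intervention = intervention,
                                  comparator = comparator),
                      econ = econ, patient = patient, settings = settings,
                      psa_specs = psa_specs),
                 class = "analysis_inputs")
  f <- validate_inputs(x)
  if (any(f$severity == "error"))
    stop_oncocea(paste0("invalid analysis inputs:\n",
                        paste("-", f$message[f$severity == "error"],
                              collapse = "\n")),
                 "oncocea_validation_error")
  x
}

#' @export
print.analysis_inputs <- function(x, ...) {
  cat(sprintf("<analysis_inputs> subgroup '%s'\n", x$subgroup))
  for (nm in names(x$arms))
    cat(sprintf("  %s (%s): PFS %s(%g, %g), OS %s(%g, %g)\n",
                nm, x$arms[[nm]]$name,
                x$arms[[nm]]$pfs$family, x$arms[[nm]]$pfs$scale,
                x$arms[[nm]]$pfs$shape,
                x$arms[[nm]]$os$family, x$arms[[nm]]$os$scale,
                x$arms[[nm]]$os$shape))
  cat(sprintf("  utilities %.3f / %.3f, discount %.3f/yr, WTP %s/QALY, %d PSA parameters\n",
              x$econ$utility_pfs, x$econ$utility_pd,
              x$econ$discount_rate_annual,
              format(x$econ$wtp_per_qaly, big.mark = ","),
              length(x$psa_specs)))
  invisible(x)
}

finding <- function(severity, message)
  data.frame(severity = severity, message = message)

no_findings <- function()
  data.frame(severity = character(), message = character())

check_surv <- function(spec, label) {
  f <- no_findings()
  if (!is_surv_spec(spec))
    return(finding("error", paste(label, "is not a surv_spec")))
  if (spec$scale <= 0) f <- rbind(f, finding("error",
    paste(label, "scale must be positive")))
  if (spec$shape <= 0) f <- rbind(f, finding("error",
    paste(label, "shape must be positive")))
  if (isTRUE(all.equal(spec$scale, spec$shape)))
    f <- rbind(f, finding("warning", paste0(
      label, ": shape is numerically equal to scale (", spec$shape,
      "), which usually indicates a transcription error in the source ",
      "parameter table")))
  if (spec$shape < 0.1)
    f <- rbind(f, finding("warning", paste0(
      label, ": shape ", spec$shape, " < 0.1 implies an implausibly ",
      "heavy-tailed survival law")))
  f
}

#' Validate analysis inputs
#'
#' Structural invariants produce `error` findings; suspicious but
#' representable values (shape numerically equal to scale, extreme
#' shapes, sensitivity ranges that do not bracket the mean) produce
#' `warning` findings. The input object is never modified.
#'
#' @param inputs An `analysis_inputs`-shaped object.
#' @return Data frame with columns `severity` and `message` (zero rows if
#'   clean).
#' @export
validate_inputs <- function(inputs) {
  f <- no_findings()
  if (!is.list(inputs) || is.null(inputs$arms) || is.null(inputs$econ))
    return(finding("error", "inputs must contain 'arms' and 'econ'"))
  if (length(inputs$arms) != 2L ||
      !all(c("intervention", "comparator") %in% names(inputs$arms)))
    return(rbind(f, finding("error",
      "exactly two arms named 'intervention' and 'comparator' are required")))
  for (nm in names(inputs$arms)) {
    a <- inputs$arms[[nm]]
    f <- rbind(f, check_surv(a$pfs, paste(nm, "PFS")),
               check_surv(a$os, paste(nm, "OS")))
    costs <- c(olaparib_cost_per_cycle = a$olaparib_cost_per_cycle,
               bevacizumab_cost_per_cycle = a$bevacizumab_cost_per_cycle,
               ae_management_cost = a$ae_management_cost)
    bad <- names(costs)[!is.finite(costs) | costs < 0]
    for (b in bad) f <- rbind(f, finding("error",
      paste0(nm, " ", b, " must be a non-negative number")))
    if (a$olaparib_max_cycles < 0 || a$bevacizumab_max_cycles < 0)
      f <- rbind(f, finding("error",
        paste(nm, "treatment caps must be >= 0 cycles")))
    pr <- c(a$ae_risks, second_line_proportion = a$second_line_proportion)
    if (length(pr) && (any(!is.finite(pr)) || any(pr < 0) || any(pr > 1)))
      f <- rbind(f, finding("error",
        paste(nm, "probabilities (AE risks, second-line proportion) must lie in [0, 1]")))
    if (!is.null(a$utility_pfs) &&
        (a$utility_pfs < 0 || a$utility_pfs > 1))
      f <- rbind(f, finding("error",
        paste(nm, "utility_pfs override must lie in [0, 1]")))
  }
  e <- inputs$econ
  if (!is.finite(e$utility_pfs) || !is.finite(e$utility_pd) ||
      e$utility_pd < 0 || e$utility_pfs > 1 ||
      e$utility_pd > e$utility_pfs)
    f <- rbind(f, finding("error",
      "utilities must satisfy 0 <= utility_pd <= utility_pfs <= 1"))
  ec <- unlist(e[c("admin_cost_per_cycle", "lab_cost_per_cycle",
                   "imaging_cost_per_cycle", "brca_test_cost",
                   "hrd_test_cost", "carboplatin_cost_per_cycle",
                   "paclitaxel_cost_per_cycle", "bsc_cost_per_cycle",
                   "terminal_care_cost")])
  for (b in names(ec)[!is.finite(ec) | ec < 0])
    f <- rbind(f, finding("error", paste(b, "must be a non-negative number")))
  if (e$discount_rate_annual < 0 || e$discount_rate_annual > 1)
    f <- rbind(f, finding("error", "discount_rate_annual must lie in [0, 1]"))
  if (e$second_line_duration_cycles < 0)
    f <- rbind(f, finding("error",
      "second_line_duration_cycles must be >= 0"))
  p <- inputs$patient
  if (!is.null(p) && (p$body_weight <= 0 || p$body_surface_area <= 0 ||
                      p$serum_creatinine <= 0))
    f <- rbind(f, finding("error", "patient measurements must be positive"))
  for (ps in inputs$psa_specs) {
    if (!inherits(ps, "psa_param")) {
      f <- rbind(f, finding("error", "psa_specs entries must be psa_param objects"))
      next
    }
    ok <- tryCatch({ get_param(inputs, ps$name); TRUE },
                   error = function(e) FALSE)
    if (!ok) f <- rbind(f, finding("error", paste0(
      "PSA parameter '", ps$name, "' does not resolve to a model input")))
    if (!(ps$low <= ps$mean && ps$mean <= ps$high))
      f <- rbind(f, finding("warning", paste0(
        "PSA parameter '", ps$name, "': range [", ps$low, ", ", ps$high,
        "] does not bracket the mean ", ps$mean)))
    if (ps$family == "beta" && (ps$low < 0 || ps$high > 1 ||
                                ps$mean < 0 || ps$mean > 1))
      f <- rbind(f, finding("warning", paste0(
        "PSA parameter '", ps$name, "': beta distribution with range [",
        ps$low, ", ", ps$high, "] extending beyond [0, 1]; draws are ",
        "taken from the beta law itself and therefore stay within [0, 1]")))
  }
  f
}

# ---- parameter paths -------------------------------------------------------

# A parameter path addresses one scalar model input:
#   econ.<field>                  shared economic input
#   patient.<field>               patient profile field
#   intervention.<field>          arm field (likewise comparator.<field>)
#   intervention.ae_risks.<ae>    nested named entries (also disutilities)
#   drugs.bevacizumab_cost_per_cycle   agent price applied to BOTH arms
#   drugs.olaparib_cost_per_cycle      likewise
path_tokens <- function(name) strsplit(name, ".", fixed = TRUE)[[1]]

#' Read a model parameter by path
#'
#' @param inputs An `analysis_inputs` object.
#' @param name Parameter path, e.g. `"econ.utility_pfs"`,
#'   `"intervention.ae_risks.fatigue"`, `"drugs.olaparib_cost_per_cycle"`.
#' @return The scalar parameter value.
#' @export
get_param <- function(inputs, name) {
  tk <- path_tokens(name)
  bad <- function() stop_oncocea(
    paste0("unknown parameter path '", name, "'"),
    "oncocea_invalid_argument")
  root <- tk[1]
  if (root == "drugs") {
    if (length(tk) != 2 ||
        !tk[2] %in% c("olaparib_cost_per_cycle", "bevacizumab_cost_per_cycle"))
      bad()
    return(inputs$arms$intervention[[tk[2]]])
  }
  node <- switch(root,
                 econ = inputs$econ, patient = inputs$patient,
                 settings = inputs$settings,
                 intervention = inputs$arms$intervention,
                 comparator = inputs$arms$comparator, bad())
  for (t in tk[-1]) {
    if (is.null(node) || !t %in% names(node)) bad()
    node <- node[[t]]
  }
  # an unset arm-level PFS-utility override falls back to the shared value
  if (is.null(node) && root %in% c("intervention", "comparator") &&
      identical(tk[-1], "utility_pfs"))
    return(inputs$econ$utility_pfs)
  if (!is.numeric(node) || length(node) != 1L) bad()
  node
}

#' Set a model parameter by path
#'
#' Returns a modified copy; `drugs.*` paths write the agent price into
#' both arms so that a single sampled price moves them together.
#'
#' @inheritParams get_param
#' @param value New scalar value.
#' @return The modified `analysis_inputs`.
#' @export
set_param <- function(inputs, name, value) {
  get_param(inputs, name)  # validates the path
  tk <- path_tokens(name)
  if (tk[1] == "drugs") {
    inputs$arms$intervention[[tk[2]]] <- value
    inputs$arms$comparator[[tk[2]]] <- value
    return(inputs)
  }
  loc <- switch(tk[1],
                econ = c("econ"), patient = c("patient"),
                settings = c("settings"),
                intervention = c("arms", "intervention"),
                comparator = c("arms", "comparator"))
  inputs[[c(loc, tk[-1])]] <- value
  inputs
}
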