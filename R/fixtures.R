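# Bundled parameter sets for the four molecular subgroups, transcribed
# from the published model-input tables (2022 USD; survival time in
# months). These are the single source of truth; the YAML files under
# inst/extdata/ are serialized from them.

# Weibull scale/shape per subgroup, endpoint and arm. The HRD-positive
# PFS rows print shape equal to scale in the source table for both arms;
# they are carried verbatim and flagged by validate_inputs().
WEIBULL_PARAMS <- list(
  overall = list(
    intervention = list(os = c(0.0032233, 1.3412093),
                        pfs = c(0.03432, 0.900619)),
    comparator   = list(os = c(0.0025282, 1.427602),
                        pfs = c(0.041625, 0.984316))),
  brca_mut = list(
    intervention = list(os = c(0.0008312, 1.4656368),
                        pfs = c(0.005312, 1.20865)),
    comparator   = list(os = c(0.0016336, 1.4217268),
                        pfs = c(0.022464, 1.082455))),
  hrd_pos = list(
    intervention = list(os = c(0.0013868, 1.4043253),
                        pfs = c(0.014599, 0.014599)),
    comparator   = list(os = c(0.0014855, 1.500712),
                        pfs = c(0.021614, 0.021614))),
  hrd_pos_brca_wt = list(
    intervention = list(os = c(0.0017414, 1.4345009),
                        pfs = c(0.025081, 0.913035)),
    comparator   = list(os = c(0.0009159, 1.6748696),
                        pfs = c(0.033704, 0.913035))))

# Grade >= 3 AE risks. The published disutility table lists "leukopenia"
# 0.09; the corresponding observed AE in the combination arm is
# lymphopenia, so the decrement is keyed to it here (neutropenia, anemia
# and hypertension carry zero disutility).
AE_RISKS_INT <- c(fatigue = 0.050, neutropenia = 0.060,
                  lymphopenia = 0.070, anemia = 0.170,
                  hypertension = 0.190)
AE_RISKS_CMP <- c(hypertension = 0.300)
DISUTILITIES <- c(lymphopenia = 0.090, fatigue = 0.170,
                  neutropenia = 0, anemia = 0, hypertension = 0)

# name, family, mean, low, high
PSA_TABLE <- list(
  list("econ.utility_pfs", "beta", 0.840, 0.672, 1.008),
  list("econ.utility_pd", "beta", 0.790, 0.632, 0.948),
  list("econ.disutilities.lymphopenia", "beta", 0.090, 0.072, 0.108),
  list("econ.disutilities.fatigue", "beta", 0.170, 0.136, 0.204),
  list("intervention.ae_risks.fatigue", "beta", 0.050, 0.040, 0.060),
  list("intervention.ae_risks.neutropenia", "beta", 0.060, 0.048, 0.072),
  list("intervention.ae_risks.lymphopenia", "beta", 0.070, 0.056, 0.084),
  list("intervention.ae_risks.anemia", "beta", 0.170, 0.136, 0.204),
  list("intervention.ae_risks.hypertension", "beta", 0.190, 0.152, 0.228),
  list("comparator.ae_risks.hypertension", "beta", 0.300, 0.240, 0.360),
  list("intervention.second_line_proportion", "beta", 0.484, 0.387, 0.581),
  list("comparator.second_line_proportion", "beta", 0.610, 0.488, 0.732),
  list("patient.body_weight", "normal", 70, 56, 84),
  list("patient.body_surface_area", "normal", 1.84, 1.47, 2.21),
  list("econ.discount_rate_annual", "uniform", 0.03, 0, 0.05),
  list("drugs.olaparib_cost_per_cycle", "gamma", 3657, 2926, 4388),
  list("drugs.bevacizumab_cost_per_cycle", "gamma", 7326, 5861, 8791),
  list("econ.carboplatin_cost_per_cycle", "gamma", 23, 18, 28),
  list("econ.paclitaxel_cost_per_cycle", "gamma", 35, 28, 42),
  list("intervention.ae_management_cost", "gamma", 291, 233, 349),
  list("comparator.ae_management_cost", "gamma", 76, 61, 91),
  list("econ.lab_cost_per_cycle", "gamma", 4, 3, 5),
  list("econ.imaging_cost_per_cycle", "gamma", 105, 84, 126),
  list("econ.admin_cost_per_cycle", "gamma", 124, 99, 149),
  list("econ.brca_test_cost", "gamma", 2901, 2321, 3481),
  list("econ.hrd_test_cost", "gamma", 4682, 3746, 5618),
  list("econ.bsc_cost_per_cycle", "gamma", 4143, 3314, 4972),
  list("econ.terminal_care_cost", "gamma", 85904, 68723, 103085))

builtin_psa_specs <- function()
  lapply(PSA_TABLE, function(r) psa_param(r[[1]], r[[2]], r[[3]], r[[4]], r[[5]]))

#' Bundled model inputs for a molecular subgroup
#'
#' Returns the complete, validated parameter bundle for one of the four
#' molecular subgroups: Weibull PFS/OS curves for both arms, adverse-event
#' risks, utilities and disutilities, all unit costs, treatment caps
#' (olaparib 35 cycles, i.e. 2 years of 3-week cycles; bevacizumab 22
#' cycles, i.e. 15 months), the reference patient, model settings and the
#' full probabilistic-sensitivity-analysis distribution table.
#'
#' The HRD-positive subgroups carry PFS shape values numerically equal to
#' their scales, as printed in the source table; [validate_inputs()]
#' flags these with warnings since they imply degenerate, implausibly
#' heavy-tailed curves.
#'
#' @param subgroup `"overall"`, `"brca_mut"`, `"hrd_pos"` or
#'   `"hrd_pos_brca_wt"`.
#' @return An [analysis_inputs()] object; the intervention arm is
#'   olaparib plus bevacizumab, the comparator bevacizumab alone.
#' @examples
#' inp <- builtin_inputs("overall")
#' inp$arms$comparator$os
#' @export
builtin_inputs <- function(subgroup) {
  if (!is.character(subgroup) || length(subgroup) != 1L ||
      !subgroup %in% SUBGROUP_IDS)
    stop_oncocea(paste0("unknown subgroup; must be one of: ",
                        paste(SUBGROUP_IDS, collapse = ", ")),
                 "oncocea_invalid_argument")
  w <- WEIBULL_PARAMS[[subgroup]]
  spec2 <- function(v) surv_spec("weibull", v[1], v[2])
  slp <- c(intervention = 0.484, comparator = 0.610)
  intervention <- arm_params(
    name = "olaparib_bevacizumab",
    pfs = spec2(w$intervention$pfs), os = spec2(w$intervention$os),
    olaparib_cost_per_cycle = 3657, bevacizumab_cost_per_cycle = 7326,
    olaparib_max_cycles = 35L, bevacizumab_max_cycles = 22L,
    ae_risks = AE_RISKS_INT, ae_management_cost = 291,
    second_line_proportion = slp[["intervention"]])
  comparator <- arm_params(
    name = "bevacizumab",
    pfs = spec2(w$comparator$pfs), os = spec2(w$comparator$os),
    olaparib_cost_per_cycle = 0, bevacizumab_cost_per_cycle = 7326,
    olaparib_max_cycles = 0L, bevacizumab_max_cycles = 22L,
    ae_risks = AE_RISKS_CMP, ae_management_cost = 76,
    second_line_proportion = slp[["comparator"]])
  econ <- economic_inputs(
    utility_pfs = 0.840, utility_pd = 0.790, disutilities = DISUTILITIES,
    admin_cost_per_cycle = 124, lab_cost_per_cycle = 4,
    imaging_cost_per_cycle = 105, brca_test_cost = 2901,
    hrd_test_cost = 4682, carboplatin_cost_per_cycle = 23,
    paclitaxel_cost_per_cycle = 35, second_line_duration_cycles = 6L,
    bsc_cost_per_cycle = 4143, terminal_care_cost = 85904,
    discount_rate_annual = 0.03, wtp_per_qaly = 150000)
  analysis_inputs(subgroup = subgroup, intervention = intervention,
                  comparator = comparator, econ = econ,
                  patient = patient_profile(70, 1.84, 1),
                  settings = model_settings(21, 15, TRUE),
                  psa_specs = builtin_psa_specs())
}
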