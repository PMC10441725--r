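# Shared helpers: representative specs per family and a few input
# constructors used across test files.

family_specs <- function() list(
  exponential = surv_spec("exponential", scale = 0.05),
  weibull     = surv_spec("weibull", scale = 0.0025282, shape = 1.427602),
  loglogistic = surv_spec("loglogistic", scale = 0.01, shape = 1.5),
  lognormal   = surv_spec("lognormal", scale = 0.025, shape = 1.3),
  gompertz    = surv_spec("gompertz", scale = 0.004, shape = 0.05))

# inputs with effects-only accrual (no costs) for oracle comparisons
zero_cost_inputs <- function(base = builtin_inputs("overall")) {
  for (p in c("econ.admin_cost_per_cycle", "econ.lab_cost_per_cycle",
              "econ.imaging_cost_per_cycle", "econ.brca_test_cost",
              "econ.hrd_test_cost", "econ.carboplatin_cost_per_cycle",
              "econ.paclitaxel_cost_per_cycle", "econ.bsc_cost_per_cycle",
              "econ.terminal_care_cost", "drugs.olaparib_cost_per_cycle",
              "drugs.bevacizumab_cost_per_cycle",
              "intervention.ae_management_cost",
              "comparator.ae_management_cost"))
    base <- set_param(base, p, 0)
  base
}

# all-"fixed" PSA specs pinned at the current parameter values
fixed_psa_specs <- function(inputs) {
  lapply(inputs$psa_specs, function(s)
    psa_param(s$name, "fixed", get_param(inputs, s$name)))
}
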