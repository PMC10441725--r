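# YAML serialization of analysis inputs. One canonical schema whose key
# paths mirror the constructor fields; see inst/extdata/params_overall.yaml
# for a complete example.

surv_to_list <- function(s) list(family = s$family, scale = s$scale,
                                 shape = s$shape)
arm_to_list <- function(a) {
  out <- list(name = a$name, pfs = surv_to_list(a$pfs),
              os = surv_to_list(a$os),
              olaparib_cost_per_cycle = a$olaparib_cost_per_cycle,
              bevacizumab_cost_per_cycle = a$bevacizumab_cost_per_cycle,
              olaparib_max_cycles = a$olaparib_max_cycles,
              bevacizumab_max_cycles = a$bevacizumab_max_cycles,
              ae_risks = as.list(a$ae_risks),
              ae_management_cost = a$ae_management_cost,
              second_line_proportion = a$second_line_proportion)
  if (!is.null(a$utility_pfs)) out$utility_pfs <- a$utility_pfs
  out
}

#' Write analysis inputs to a YAML parameter file
#'
#' @param inputs An [analysis_inputs()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [load_inputs()]
#' @export
write_inputs <- function(inputs, path) {
  e <- inputs$econ
  doc <- list(
    subgroup = inputs$subgroup,
    settings = unclass(inputs$settings),
    patient = unclass(inputs$patient),
    econ = c(unclass(e)[setdiff(names(e), "disutilities")],
             list(disutilities = as.list(e$disutilities))),
    arms = list(intervention = arm_to_list(inputs$arms$intervention),
                comparator = arm_to_list(inputs$arms$comparator)),
    psa = lapply(inputs$psa_specs, unclass))
  yaml::write_yaml(doc, path, precision = 12L)
  invisible(path)
}

list_to_surv <- function(x, label) {
  need <- c("family", "scale", "shape")
  if (!is.list(x) || !all(need %in% names(x)))
    stop_oncocea(paste0("field '", label,
                        "' must provide family, scale and shape"),
                 "oncocea_format_error")
  surv_spec(x$family, x$scale, x$shape)
}

merge_fields <- function(target, src, fields) {
  for (f in intersect(fields, names(src))) target[[f]] <- src[[f]]
  target
}

#' Load analysis inputs from a YAML parameter file
#'
#' Reads the canonical parameter-file schema (see [write_inputs()] and
#' the bundled files under `inst/extdata/`). The `subgroup` key selects
#' which bundled parameter set supplies defaults for any optional field
#' the file omits; both arms' survival curves are required. All
#' invariants are checked on load and violations are reported together.
#'
#' @param path Path to a YAML parameter file.
#' @return A validated [analysis_inputs()] object.
#' @export
load_inputs <- function(path) {
  if (!file.exists(path))
    stop_oncocea(paste0("parameter file not found: ", path),
                 "oncocea_format_error")
  doc <- tryCatch(yaml::read_yaml(path), error = function(e)
    stop_oncocea(paste0("cannot parse '", path, "': ",
                        conditionMessage(e)), "oncocea_format_error"))
  if (!is.list(doc) || is.null(doc$subgroup))
    stop_oncocea("parameter file must contain a 'subgroup' key",
                 "oncocea_format_error")
  if (!doc$subgroup %in% SUBGROUP_IDS)
    stop_oncocea(paste0("unknown subgroup '", doc$subgroup, "'"),
                 "oncocea_format_error")
  base <- builtin_inputs(doc$subgroup)
  if (is.null(doc$arms) ||
      !all(c("intervention", "comparator") %in% names(doc$arms)))
    stop_oncocea(
      "parameter file must define arms 'intervention' and 'comparator'",
      "oncocea_validation_error")
  arms <- list()
  for (nm in c("intervention", "comparator")) {
    src <- doc$arms[[nm]]
    a <- base$arms[[nm]]
    for (ep in c("pfs", "os")) {
      if (is.null(src[[ep]]))
        stop_oncocea(paste0("arm '", nm, "' is missing its '", ep,
                            "' survival specification"),
                     "oncocea_validation_error")
      a[[ep]] <- list_to_surv(src[[ep]], paste(nm, ep))
    }
    a <- merge_fields(a, src, c(
      "name", "olaparib_cost_per_cycle", "bevacizumab_cost_per_cycle",
      "ae_management_cost", "second_line_proportion", "utility_pfs"))
    for (f in c("olaparib_max_cycles", "bevacizumab_max_cycles"))
      if (!is.null(src[[f]])) a[[f]] <- as.integer(src[[f]])
    if (!is.null(src$ae_risks)) a$ae_risks <- unlist(src$ae_risks)
    arms[[nm]] <- a
  }
  econ <- base$econ
  if (!is.null(doc$econ)) {
    econ <- merge_fields(econ, doc$econ, setdiff(names(econ), "disutilities"))
    econ$second_line_duration_cycles <-
      as.integer(econ$second_line_duration_cycles)
    if (!is.null(doc$econ$disutilities))
      econ$disutilities <- unlist(doc$econ$disutilities)
  }
  patient <- base$patient
  if (!is.null(doc$patient))
    patient <- merge_fields(patient, doc$patient, names(patient))
  settings <- base$settings
  if (!is.null(doc$settings)) {
    settings <- merge_fields(settings, doc$settings, names(settings))
    settings$half_cycle_correction <- isTRUE(settings$half_cycle_correction)
  }
  psa <- base$psa_specs
  if (!is.null(doc$psa))
    psa <- lapply(doc$psa, function(r) {
      need <- c("name", "family", "mean")
      if (!all(need %in% names(r)))
        stop_oncocea("each psa entry needs at least name, family and mean",
                     "oncocea_format_error")
      psa_param(r$name, r$family, r$mean, r$low %||% r$mean,
                r$high %||% r$mean)
    })
  analysis_inputs(subgroup = doc$subgroup,
                  intervention = arms$intervention,
                  comparator = arms$comparator,
                  econ = econ, patient = patient, settings = settings,
                  psa_specs = psa)
}

#' Path to a bundled subgroup parameter file
#'
#' @param subgroup One of the four subgroup ids.
#' @return Path to the installed YAML file.
#' @export
builtin_inputs_file <- function(subgroup) {
  if (!subgroup %in% SUBGROUP_IDS)
    stop_oncocea(paste0("unknown subgroup '", subgroup, "'"),
                 "oncocea_invalid_argument")
  system.file("extdata", paste0("params_", subgroup, ".yaml"),
              package = "oncocea", mustWork = TRUE)
}
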