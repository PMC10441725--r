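# Tabular report generation: CSV (canonical) + JSON mirrors, with a run
# manifest written alongside every output set. These functions back the
# command-line interface in inst/cli/oncocea.

resolve_inputs <- function(subgroup = NULL, config = NULL) {
  if (is.null(subgroup) == is.null(config))
    stop_oncocea("provide exactly one of 'subgroup' or 'config'",
                 "oncocea_invalid_argument")
  if (!is.null(config)) load_inputs(config) else builtin_inputs(subgroup)
}

log_inputs <- function(inputs, source) {
  message(sprintf("[oncocea] parameters: %s (subgroup '%s')",
                  source, inputs$subgroup))
  f <- validate_inputs(inputs)
  for (i in seq_len(nrow(f)))
    message(sprintf("[oncocea] %s: %s", f$severity[i], f$message[i]))
  invisible(f)
}

write_manifest <- function(out_dir, inputs, seed, outputs) {
  manifest <- list(
    subgroup = inputs$subgroup,
    settings = unclass(inputs$settings),
    seed = seed,
    package_version = as.character(packageVersion("oncocea")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = outputs)
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  path
}

ensure_dir <- function(out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  invisible(out_dir)
}

#' Base-case report
#'
#' Runs both strategies, prints the per-arm outcome table and the
#' incremental comparison, and writes `base_case.csv` (per-arm totals and
#' itemized cost components), `comparison.json` and a run manifest.
#'
#' @param subgroup Subgroup id for the bundled inputs, or `NULL` when
#'   `config` is given.
#' @param config Path to a YAML parameter file, or `NULL`.
#' @param out_dir Output directory (created if needed).
#' @return The [run_base_case()] result, invisibly.
#' @export
report_base_case <- function(subgroup = NULL, config = NULL,
                             out_dir = ".") {
  inputs <- resolve_inputs(subgroup, config)
  log_inputs(inputs, if (is.null(config)) "bundled fixture" else config)
  ensure_dir(out_dir)
  res <- run_base_case(inputs)
  arm_row <- function(o)
    cbind(data.frame(arm = o$arm, strategy = o$name,
                     total_cost_usd = o$total_cost, ly_years = o$ly,
                     qaly_years = o$qaly,
                     total_cost_undiscounted_usd = o$total_cost_undiscounted,
                     ly_undiscounted_years = o$ly_undiscounted,
                     qaly_undiscounted_years = o$qaly_undiscounted),
          as.data.frame(as.list(setNames(
            o$cost_components,
            paste0("cost_", names(o$cost_components), "_usd")))))
  tab <- rbind(arm_row(res$intervention), arm_row(res$comparator))
  csv <- file.path(out_dir, "base_case.csv")
  write.csv(tab, csv, row.names = FALSE)
  cmpj <- file.path(out_dir, "comparison.json")
  jsonlite::write_json(
    c(unclass(res$comparison),
      list(wtp_per_qaly_usd = inputs$econ$wtp_per_qaly,
           nmb_usd = net_monetary_benefit(res$comparison$delta_cost,
                                          res$comparison$delta_qaly,
                                          inputs$econ$wtp_per_qaly))),
    cmpj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_manifest(out_dir, inputs, NA, c(csv, cmpj))
  print(res$intervention); print(res$comparator); print(res$comparison)
  invisible(res)
}

#' Tornado-diagram report
#'
#' @inheritParams report_base_case
#' @param fraction Relative excursion for [one_way()]; default 0.20.
#' @return The tornado data frame, invisibly.
#' @export
report_tornado <- function(subgroup = NULL, config = NULL, out_dir = ".",
                           fraction = 0.20) {
  inputs <- resolve_inputs(subgroup, config)
  log_inputs(inputs, if (is.null(config)) "bundled fixture" else config)
  tor <- one_way(inputs, fraction = fraction)  # validates fraction
  ensure_dir(out_dir)
  names(tor) <- c("parameter", "low_value", "high_value",
                  "icer_at_low_usd_per_qaly", "icer_at_high_usd_per_qaly",
                  "span_usd_per_qaly")
  csv <- file.path(out_dir, "tornado.csv")
  write.csv(tor, csv, row.names = FALSE)
  write_manifest(out_dir, inputs, NA, csv)
  invisible(tor)
}

#' Two-way sensitivity report
#'
#' @inheritParams report_base_case
#' @param param_x,param_y Parameter paths, see [set_param()].
#' @param grid_x,grid_y Numeric value grids.
#' @param wtp Willingness-to-pay threshold.
#' @return The classification grid, invisibly.
#' @export
report_two_way <- function(subgroup = NULL, config = NULL, out_dir = ".",
                           param_x = "intervention.utility_pfs",
                           grid_x = seq(0.672, 1.0, by = 0.02),
                           param_y = "comparator.utility_pfs",
                           grid_y = seq(0.672, 1.0, by = 0.02),
                           wtp = NULL) {
  inputs <- resolve_inputs(subgroup, config)
  log_inputs(inputs, if (is.null(config)) "bundled fixture" else config)
  ensure_dir(out_dir)
  grid <- two_way(inputs, param_x, grid_x, param_y, grid_y,
                  wtp %||% inputs$econ$wtp_per_qaly)
  names(grid) <- c(param_x, param_y, "icer_usd_per_qaly", "cost_effective")
  csv <- file.path(out_dir, "two_way.csv")
  write.csv(grid, csv, row.names = FALSE)
  write_manifest(out_dir, inputs, NA, csv)
  invisible(grid)
}

#' Probabilistic sensitivity report
#'
#' Writes the PSA scatter (`psa_scatter.csv`: incremental cost and QALYs
#' per draw plus the sampled parameter values), the acceptability curve
#' (`ceac.csv`) and a manifest. Deterministic under `seed`.
#'
#' @inheritParams report_base_case
#' @param n Number of Monte Carlo iterations.
#' @param seed Integer seed.
#' @param wtp_grid Willingness-to-pay grid for the CEAC.
#' @return List with the draws and the CEAC, invisibly.
#' @export
report_psa <- function(subgroup = NULL, config = NULL, out_dir = ".",
                       n = 10000, seed = 1,
                       wtp_grid = seq(0, 300000, by = 2000)) {
  inputs <- resolve_inputs(subgroup, config)
  log_inputs(inputs, if (is.null(config)) "bundled fixture" else config)
  draws <- run_psa(inputs, n = n, seed = seed)  # validates n
  ensure_dir(out_dir)
  curve <- ceac(draws, wtp_grid)
  scatter <- as.data.frame(draws)
  names(scatter)[1:2] <- c("delta_cost_usd", "delta_qaly_years")
  csv1 <- file.path(out_dir, "psa_scatter.csv")
  write.csv(scatter, csv1, row.names = FALSE)
  csv2 <- file.path(out_dir, "ceac.csv")
  curve_out <- curve
  names(curve_out) <- c("wtp_usd_per_qaly", "probability_cost_effective")
  write.csv(curve_out, csv2, row.names = FALSE)
  write_manifest(out_dir, inputs, seed, c(csv1, csv2))
  p_wtp <- curve$probability_cost_effective[
    which.min(abs(curve$wtp - inputs$econ$wtp_per_qaly))]
  message(sprintf(
    "[oncocea] P(cost-effective) at $%s/QALY: %.3f over %d draws",
    format(inputs$econ$wtp_per_qaly, big.mark = ","), p_wtp, n))
  invisible(list(draws = draws, ceac = curve))
}
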