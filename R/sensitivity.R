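# One-way (tornado), two-way and probabilistic sensitivity analyses.

icer_at <- function(inputs) run_base_case(inputs)$comparison$icer_per_qaly

nmb_at <- function(inputs, wtp) {
  cmp <- run_base_case(inputs)$comparison
  net_monetary_benefit(cmp$delta_cost, cmp$delta_qaly, wtp)
}

cap_utility <- function(name, value) {
  if (grepl("utility", name, fixed = TRUE)) min(value, 1) else value
}

#' One-way sensitivity analysis (tornado)
#'
#' Re-runs the base case with each parameter at `mean * (1 - fraction)`
#' and `mean * (1 + fraction)`, all else held at baseline; utilities are
#' capped at 1 when the upper excursion exceeds it. Entries are sorted by
#' ICER span, the tornado-diagram order.
#'
#' @param inputs An [analysis_inputs()] object.
#' @param parameters Character vector of parameter paths; default: every
#'   non-fixed PSA parameter.
#' @param fraction Relative excursion, in (0, 1); default 0.20.
#' @return Data frame with columns `parameter`, `low_value`, `high_value`,
#'   `icer_at_low`, `icer_at_high`, `span`, sorted by `span` descending.
#' @export
one_way <- function(inputs, parameters = NULL, fraction = 0.20) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction >= 1)
    stop_oncocea("'fraction' must lie in (0, 1)", "oncocea_invalid_argument")
  if (is.null(parameters))
    parameters <- vapply(
      Filter(function(s) s$family != "fixed", inputs$psa_specs),
      `[[`, character(1), "name")
  rows <- lapply(parameters, function(p) {
    base <- get_param(inputs, p)   # errors for unresolvable names
    lo <- cap_utility(p, base * (1 - fraction))
    hi <- cap_utility(p, base * (1 + fraction))
    data.frame(parameter = p, low_value = lo, high_value = hi,
               icer_at_low = icer_at(set_param(inputs, p, lo)),
               icer_at_high = icer_at(set_param(inputs, p, hi)))
  })
  out <- do.call(rbind, rows)
  out$span <- abs(out$icer_at_high - out$icer_at_low)
  out <- out[order(-out$span, out$parameter), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Two-way sensitivity analysis
#'
#' Evaluates the base case over the Cartesian grid of two parameters and
#' classifies each cell as cost-effective (net monetary benefit >= 0 at
#' `wtp`) or not.
#'
#' @param inputs An [analysis_inputs()] object.
#' @param param_x,param_y Parameter paths.
#' @param grid_x,grid_y Numeric grids of values.
#' @param wtp Willingness-to-pay threshold; default the inputs' own.
#' @return Data frame with columns `x`, `y`, `icer_per_qaly`,
#'   `cost_effective`.
#' @export
two_way <- function(inputs, param_x, grid_x, param_y, grid_y,
                    wtp = inputs$econ$wtp_per_qaly) {
  get_param(inputs, param_x); get_param(inputs, param_y)
  cells <- expand.grid(x = grid_x, y = grid_y)
  res <- apply(cells, 1L, function(cell) {
    inp <- set_param(set_param(inputs, param_x, cell[["x"]]),
                     param_y, cell[["y"]])
    cmp <- run_base_case(inp)$comparison
    c(icer = cmp$icer_per_qaly,
      nmb = net_monetary_benefit(cmp$delta_cost, cmp$delta_qaly, wtp))
  })
  cells$icer_per_qaly <- res["icer", ]
  cells$cost_effective <- res["nmb", ] >= 0
  cells
}

# moment-matched samplers; SE of the ranged families is (high - low)/3.92,
# reading the published range as a 95% interval
psa_sample <- function(spec, n) {
  m <- spec$mean; se <- (spec$high - spec$low) / (2 * 1.96)
  switch(spec$family,
    fixed = rep(m, n),
    uniform = runif(n, spec$low, spec$high),
    normal = {  # truncated at [low, high]
      x <- rnorm(n, m, se)
      while (any(bad <- x < spec$low | x > spec$high))
        x[bad] <- rnorm(sum(bad), m, se)
      x
    },
    beta = {
      if (se^2 >= m * (1 - m))
        stop_oncocea(paste0(
          "PSA parameter '", spec$name, "': range too wide for a beta ",
          "distribution with mean ", m), "oncocea_spec_error")
      nu <- m * (1 - m) / se^2 - 1
      rbeta(n, m * nu, (1 - m) * nu)
    },
    gamma = {
      if (m <= 0 || se <= 0)
        stop_oncocea(paste0("PSA parameter '", spec$name,
                            "': gamma requires positive mean and range"),
                     "oncocea_spec_error")
      rgamma(n, shape = (m / se)^2, rate = m / se^2)
    })
}

#' Draw parameter values from their PSA distributions
#'
#' Beta and gamma are moment-matched to the mean and the standard error
#' `(high - low) / (2 * 1.96)`; normal draws are truncated at
#' `[low, high]`; uniform draws cover `[low, high]`; `fixed` always
#' returns the mean.
#'
#' @param specs List of [psa_param()] objects.
#' @param n Number of draws.
#' @param seed Optional seed.
#' @return Data frame, one column per parameter, `n` rows.
#' @export
draw_parameters <- function(specs, n = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cols <- lapply(specs, psa_sample, n = n)
  out <- as.data.frame(setNames(cols, vapply(specs, `[[`, character(1),
                                             "name")), check.names = FALSE)
  out
}

#' Probabilistic sensitivity analysis
#'
#' `n` Monte Carlo iterations; in each, every PSA parameter is drawn from
#' its distribution, written into the inputs and the full model is
#' re-evaluated for both arms. Survival-curve parameters are held fixed
#' (no sampling distribution is defined for them). Reproducible under
#' `seed`.
#'
#' @param inputs An [analysis_inputs()] object.
#' @param n Number of iterations (>= 1).
#' @param seed Integer seed.
#' @return A `psa_draws` data frame: `delta_cost`, `delta_qaly`, plus one
#'   audit column per sampled parameter.
#' @export
run_psa <- function(inputs, n = 10000, seed = 1) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1)
    stop_oncocea("'n' must be at least 1", "oncocea_invalid_argument")
  n <- as.integer(n)
  draws <- draw_parameters(inputs$psa_specs, n, seed = seed)
  dc <- dq <- numeric(n)
  for (i in seq_len(n)) {
    inp <- inputs
    for (p in names(draws)) inp <- set_param(inp, p, draws[[p]][i])
    cmp <- run_base_case(inp)$comparison
    dc[i] <- cmp$delta_cost; dq[i] <- cmp$delta_qaly
  }
  out <- cbind(data.frame(delta_cost = dc, delta_qaly = dq), draws)
  class(out) <- c("psa_draws", "data.frame")
  out
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay value, the fraction of PSA draws with
#' positive net monetary benefit.
#'
#' @param draws A `psa_draws` data frame from [run_psa()].
#' @param wtp_grid Willingness-to-pay grid, USD/QALY; default 0-300,000
#'   in steps of 2,000.
#' @return Data frame with columns `wtp`, `probability_cost_effective`.
#' @export
ceac <- function(draws, wtp_grid = seq(0, 300000, by = 2000)) {
  if (!is.data.frame(draws) || nrow(draws) == 0)
    stop_oncocea("'draws' must be a non-empty data frame",
                 "oncocea_invalid_argument")
  prob <- vapply(wtp_grid, function(w)
    mean(net_monetary_benefit(draws$delta_cost, draws$delta_qaly, w) > 0),
    numeric(1))
  data.frame(wtp = wtp_grid, probability_cost_effective = prob)
}

#' Willingness-to-pay at a target acceptability probability
#'
#' Linear interpolation between the bracketing grid points of the first
#' upward crossing of the target probability.
#'
#' @param curve A data frame from [ceac()].
#' @param target Probability in \[0, 1\].
#' @return WTP in USD/QALY.
#' @export
wtp_at_probability <- function(curve, target) {
  p <- curve$probability_cost_effective; w <- curve$wtp
  if (p[1] >= target) return(w[1])
  cross <- which(p[-1] >= target & p[-length(p)] < target)
  if (length(cross) == 0)
    stop_oncocea(sprintf(
      "acceptability curve never reaches probability %.3f (max %.3f)",
      target, max(p)), "oncocea_out_of_range")
  i <- cross[1]
  w[i] + (target - p[i]) / (p[i + 1] - p[i]) * (w[i + 1] - w[i])
}
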