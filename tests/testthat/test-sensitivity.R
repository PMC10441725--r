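test_that("PSA sampling honours each distribution family", {
  specs <- list(
    psa_param("econ.utility_pfs", "beta", 0.84, 0.672, 1.008),
    psa_param("econ.discount_rate_annual", "uniform", 0.03, 0, 0.05),
    psa_param("patient.body_weight", "normal", 70, 56, 84),
    psa_param("econ.bsc_cost_per_cycle", "gamma", 4143, 3314, 4972),
    psa_param("econ.utility_pd", "fixed", 0.79))
  d <- draw_parameters(specs, n = 10000, seed = 1)
  expect_true(all(d[["econ.utility_pd"]] == 0.79))
  expect_true(all(d[["econ.discount_rate_annual"]] >= 0 &
                    d[["econ.discount_rate_annual"]] <= 0.05))
  expect_true(all(d[["patient.body_weight"]] >= 56 &
                    d[["patient.body_weight"]] <= 84))
  expect_true(all(d[["econ.utility_pfs"]] <= 1))
  # moment matching: sample means within 3 standard errors
  se <- (1.008 - 0.672) / 3.92 / sqrt(10000)
  expect_lt(abs(mean(d[["econ.utility_pfs"]]) - 0.84), 3 * se)
  se_g <- (4972 - 3314) / 3.92 / sqrt(10000)
  expect_lt(abs(mean(d[["econ.bsc_cost_per_cycle"]]) - 4143), 3 * se_g)
  expect_identical(draw_parameters(specs, n = 100, seed = 9),
                   draw_parameters(specs, n = 100, seed = 9))
  # infeasible beta moment match is reported with the parameter name
  expect_error(draw_parameters(list(psa_param("econ.utility_pfs", "beta",
                                              0.5, -3, 4)), n = 2),
               "econ.utility_pfs", class = "oncocea_spec_error")
})

test_that("PSA with all-fixed specs reproduces the base case exactly", {
  inp <- builtin_inputs("overall")
  inp$psa_specs <- fixed_psa_specs(inp)
  draws <- run_psa(inp, n = 3, seed = 1)
  base <- run_base_case(inp)$comparison
  expect_true(all(draws$delta_cost == base$delta_cost))
  expect_true(all(draws$delta_qaly == base$delta_qaly))
})

test_that("PSA draws are reproducible under a seed", {
  inp <- builtin_inputs("overall")
  expect_identical(run_psa(inp, n = 25, seed = 11),
                   run_psa(inp, n = 25, seed = 11))
  expect_false(identical(run_psa(inp, n = 25, seed = 11)$delta_cost,
                         run_psa(inp, n = 25, seed = 12)$delta_cost))
  expect_error(run_psa(inp, n = 0), class = "oncocea_invalid_argument")
})

test_that("the acceptability curve follows its definition", {
  draws <- data.frame(delta_cost = c(-100, 200, 300, 400),
                      delta_qaly = c(0.001, 0.002, 0.004, 0.001))
  cv <- ceac(draws, wtp_grid = c(0, 1e5, 2e5, 4e5, 1e6))
  # at WTP 0, only cost-saving draws count
  expect_equal(cv$probability_cost_effective[1], 0.25)
  # all QALY gains positive: probability is non-decreasing in WTP
  expect_true(all(diff(cv$probability_cost_effective) >= 0))
  # and converges to the fraction with positive QALY gain (here all)
  expect_equal(max(cv$probability_cost_effective), 1)
})

test_that("WTP interpolation at a target probability brackets correctly", {
  cv <- data.frame(wtp = c(1e5, 2e5),
                   probability_cost_effective = c(0.4, 0.6))
  expect_equal(wtp_at_probability(cv, 0.5), 150000)
  expect_equal(wtp_at_probability(cv, 0.4), 100000)
  low <- data.frame(wtp = c(0, 1e5), probability_cost_effective = c(0.1, 0.2))
  expect_error(wtp_at_probability(low, 0.99), class = "oncocea_out_of_range")
})

test_that("tornado ranks parameters by ICER span with utilities on top", {
  inp <- set_param(builtin_inputs("overall"),
                   "comparator.ae_management_cost", 0)
  tor <- one_way(inp)
  expect_true(all(diff(tor$span) <= 0))
  expect_match(tor$parameter[1], "utility_pfs")
  # a zero-valued cost has no +/-20% effect and joins the span-0 tail
  # (together with AE risks whose disutility and one-off cost are zero)
  expect_identical(tor$span[tor$parameter == "comparator.ae_management_cost"],
                   0)
  expect_identical(tor$span[nrow(tor)], 0)
  # entries are invariant to the order the parameters are listed
  ps <- c("econ.utility_pfs", "drugs.olaparib_cost_per_cycle",
          "econ.bsc_cost_per_cycle")
  expect_equal(one_way(inp, ps), one_way(inp, rev(ps)))
  # raising the intervention drug price raises the ICER
  row <- one_way(inp, "drugs.olaparib_cost_per_cycle")
  base_icer <- run_base_case(inp)$comparison$icer_per_qaly
  expect_gt(row$icer_at_high, base_icer)
  expect_lt(row$icer_at_low, base_icer)
  expect_error(one_way(inp, fraction = 1.5),
               class = "oncocea_invalid_argument")
  expect_error(one_way(inp, "not.a.param"),
               class = "oncocea_invalid_argument")
})

test_that("utility excursions beyond 1 are capped in the tornado", {
  tor <- one_way(builtin_inputs("overall"), "econ.utility_pfs")
  expect_identical(tor$high_value, 1)
  expect_equal(tor$low_value, 0.84 * 0.8)
})

test_that("two-way classification is monotone in the intervention PFS utility", {
  inp <- builtin_inputs("overall")
  grid <- two_way(inp, "intervention.utility_pfs", seq(0.7, 1, by = 0.05),
                  "comparator.utility_pfs", c(0.76, 0.84, 0.92),
                  wtp = 150000)
  for (y in unique(grid$y)) {
    col <- grid[grid$y == y, ]
    col <- col[order(col$x), ]
    expect_true(all(diff(col$cost_effective) >= 0))
  }
  # at WTP 0 nothing is cost-effective (the intervention always costs more)
  g0 <- two_way(inp, "intervention.utility_pfs", c(0.8, 1),
                "comparator.utility_pfs", c(0.84), wtp = 0)
  expect_false(any(g0$cost_effective))
})
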