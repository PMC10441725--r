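test_that("QALYs equal LYs at unit utilities and zero disutilities", {
  inp <- builtin_inputs("overall")
  inp$econ$utility_pfs <- 1; inp$econ$utility_pd <- 1
  inp$econ$disutilities <- numeric()
  for (arm in c("intervention", "comparator")) {
    out <- evaluate_strategy(inp, arm)
    expect_equal(out$qaly, out$ly, tolerance = 1e-12)
    expect_gt(out$ly, 0)
  }
})

test_that("an immediately extinct cohort accrues almost nothing", {
  inp <- builtin_inputs("overall")
  dead <- surv_spec("weibull", scale = 100, shape = 1)
  inp$arms$comparator$pfs <- dead
  inp$arms$comparator$os <- dead
  out <- evaluate_strategy(inp, "comparator")
  expect_lt(out$ly, 0.05)
})

test_that("cost components sum to the total and zero prices zero components", {
  inp <- builtin_inputs("overall")
  out <- evaluate_strategy(inp, "intervention")
  expect_equal(sum(out$cost_components), out$total_cost, tolerance = 1e-6)
  expect_true(all(out$cost_components >= 0))
  # zeroing one unit price zeroes exactly that component
  inp2 <- set_param(inp, "econ.bsc_cost_per_cycle", 0)
  out2 <- evaluate_strategy(inp2, "intervention")
  expect_identical(out2$cost_components[["bsc"]], 0)
  others <- setdiff(names(out$cost_components), "bsc")
  expect_equal(out2$cost_components[others], out$cost_components[others])
  # zeroing everything zeroes the total
  out0 <- evaluate_strategy(zero_cost_inputs(), "intervention")
  expect_identical(out0$total_cost, 0)
})

test_that("undiscounted totals dominate discounted ones", {
  out <- evaluate_strategy(builtin_inputs("overall"), "intervention")
  expect_gt(out$total_cost_undiscounted, out$total_cost)
  expect_gt(out$ly_undiscounted, out$ly)
  expect_gt(out$qaly_undiscounted, out$qaly)
  expect_gte(out$ly, out$qaly)   # utilities are below 1
})

test_that("bevacizumab cost scales linearly with body weight", {
  inp <- builtin_inputs("overall")
  base <- evaluate_strategy(inp, "comparator")$cost_components
  inp$patient$body_weight <- 77
  heavier <- evaluate_strategy(inp, "comparator")$cost_components
  # the comparator's maintenance component is bevacizumab only
  expect_equal(heavier[["maintenance_drugs"]],
               1.1 * base[["maintenance_drugs"]], tolerance = 1e-12)
  expect_equal(heavier[["administration"]], base[["administration"]])
})

test_that("first-cycle maintenance price is the sum of the agents' prices", {
  inp <- builtin_inputs("overall")
  # a one-cycle horizon with (numerically) immortal patients isolates the
  # per-cycle price: 3,657 + 7,326 at the 70 kg reference weight
  alive <- surv_spec("weibull", scale = 1e-9, shape = 1)
  inp$arms$intervention$pfs <- alive
  inp$arms$intervention$os <- alive
  inp$settings <- model_settings(21, 21 / 365.25, half_cycle_correction = FALSE)
  inp <- set_param(inp, "econ.discount_rate_annual", 0)
  comp <- evaluate_strategy(inp, "intervention")$cost_components
  expect_equal(comp[["maintenance_drugs"]], 3657 + 7326, tolerance = 1e-6)
})

test_that("treatment caps stop drug accrual at 35 and 22 cycles", {
  inp <- builtin_inputs("overall")
  alive <- surv_spec("weibull", scale = 1e-9, shape = 1)
  inp$arms$intervention$pfs <- alive
  inp$arms$intervention$os <- alive
  inp <- set_param(inp, "econ.discount_rate_annual", 0)
  inp$settings <- model_settings(21, 15, half_cycle_correction = FALSE)
  comp <- evaluate_strategy(inp, "intervention")$cost_components
  expect_equal(comp[["maintenance_drugs"]], 35 * 3657 + 22 * 7326,
               tolerance = 1e-6)
  expect_equal(comp[["administration"]], 22 * 124, tolerance = 1e-6)
})

test_that("incremental comparison classifies dominance correctly", {
  so <- function(cost, qaly, ly = qaly) list(total_cost = cost, qaly = qaly,
                                             ly = ly)
  expect_identical(compare(so(100, 2), so(200, 1))$status, "dominant")
  expect_identical(compare(so(200, 1), so(100, 2))$status, "dominated")
  cmp <- compare(so(200, 2), so(100, 1))
  expect_identical(cmp$status, "tradeoff")
  expect_equal(cmp$icer_per_qaly, 100)
  same <- compare(so(100, 1), so(100, 1))
  expect_true(is.nan(same$icer_per_qaly))
  inf <- compare(so(200, 1), so(100, 1))
  expect_identical(inf$icer_per_qaly, Inf)
  expect_identical(inf$status, "tradeoff")
})

test_that("recomputed ICERs are internally consistent with printed totals", {
  # arithmetic on the published base-case table: delta-cost / delta-QALY
  # must match the published ICER to 0.5% for the two clean subgroups
  expect_lt(abs((293656 / 1.85) / 158729 - 1), 0.005)
  expect_lt(abs((265668 / 3.34) / 79434 - 1), 0.005)
})

test_that("net monetary benefit follows its definition", {
  expect_equal(net_monetary_benefit(293656, 1.85, 150000), -16156)
  icer <- 293656 / 1.85
  expect_equal(net_monetary_benefit(293656, 1.85, icer), 0, tolerance = 1e-9)
  expect_equal(net_monetary_benefit(500, 0, 100000), -500)
  expect_error(net_monetary_benefit(1, 1, -5), class = "oncocea_domain_error")
})

test_that("the ICER responds monotonically to utilities, prices and discounting", {
  inp <- builtin_inputs("overall")
  base <- run_base_case(inp)
  expect_gt(base$comparison$delta_qaly, 0)
  # higher shared PFS utility widens the QALY gap, lowering the ICER
  up_u <- run_base_case(set_param(inp, "econ.utility_pfs", 0.9))
  expect_lt(up_u$comparison$icer_per_qaly, base$comparison$icer_per_qaly)
  # a costlier intervention drug strictly raises it
  up_p <- run_base_case(set_param(inp, "drugs.olaparib_cost_per_cycle",
                                  3657 * 1.2))
  expect_gt(up_p$comparison$icer_per_qaly, base$comparison$icer_per_qaly)
  # removing discounting weakly increases both arms' effect totals
  no_d <- run_base_case(set_param(inp, "econ.discount_rate_annual", 0))
  for (arm in c("intervention", "comparator")) {
    expect_gte(no_d[[arm]]$ly, base[[arm]]$ly)
    expect_gte(no_d[[arm]]$qaly, base[[arm]]$qaly)
  }
})
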