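test_that("survival functions behave as proper survival laws in all families", {
  tgrid <- c(0, 0.1, 1, 5, 20, 60, 180, 600)
  for (nm in names(family_specs())) {
    sp <- family_specs()[[nm]]
    s <- surv_prob(sp, tgrid)
    expect_identical(s[1], 1)
    expect_true(all(diff(s) <= 0), info = nm)
    expect_true(all(s >= 0 & s <= 1), info = nm)
    expect_true(all(s[tgrid <= 60] > 0), info = nm)
    expect_lt(surv_prob(sp, 1e4), 1e-3)
    # median / survival consistency
    expect_lt(abs(surv_prob(sp, surv_median(sp)) - 0.5), 1e-9)
    # quantile inverts the CDF
    u <- c(0.05, 0.25, 0.5, 0.9, 0.99)
    expect_equal(1 - surv_prob(sp, surv_quantile(sp, u)), u,
                 tolerance = 1e-9)
  }
  expect_error(surv_prob(family_specs()$weibull, -1),
               class = "oncocea_domain_error")
  expect_error(surv_spec("weibull", scale = -1, shape = 1),
               class = "oncocea_invalid_argument")
  expect_error(surv_spec("exponential", scale = 1, shape = 2),
               class = "oncocea_invalid_argument")
})

test_that("exponential is the shape-1 Weibull and known medians reproduce", {
  ex <- surv_spec("exponential", scale = log(2))
  expect_equal(surv_prob(ex, 1), 0.5, tolerance = 1e-12)
  expect_equal(surv_median(ex), 1, tolerance = 1e-12)
  wb <- surv_spec("weibull", scale = log(2), shape = 1)
  expect_equal(surv_prob(wb, c(0.3, 1, 4)), surv_prob(ex, c(0.3, 1, 4)))
  # closed-form medians of the bundled curves (frozen oracle values)
  os_cmp <- surv_spec("weibull", 0.0025282, 1.427602)
  expect_equal(surv_median(os_cmp), 51.0233201993, tolerance = 1e-9)
  expect_equal(surv_prob(os_cmp, 51), 0.5002261632, tolerance = 1e-9)
  pfs_cmp_brca <- surv_spec("weibull", 0.022464, 1.082455)
  expect_equal(surv_median(pfs_cmp_brca), 23.7623511464, tolerance = 1e-9)
})

test_that("exponential fit matches the closed-form censored MLE", {
  set.seed(7)
  ipd <- simulate_ipd(surv_spec("exponential", 0.04), 800,
                      censoring_spec(admin_censor_time = 40))
  fit <- fit_parametric(ipd, "exponential")
  rate_mle <- sum(ipd$event) / sum(ipd$time)  # closed-form oracle
  expect_equal(fit$spec$scale, rate_mle, tolerance = 1e-6)
  expect_identical(fit$spec$shape, 1)
  expect_identical(fit$n_params, 1L)
  expect_equal(fit$aic, 2 * fit$n_params - 2 * fit$loglik)
  expect_equal(fit$bic, fit$n_params * log(fit$n_obs) - 2 * fit$loglik)
})

test_that("Weibull fit agrees with an independent fitter (survreg)", {
  set.seed(11)
  truth <- surv_spec("weibull", 0.0025282, 1.427602)
  ipd <- simulate_ipd(truth, 2000,
                      censoring_spec(admin_censor_time = surv_quantile(truth, 0.8)))
  fit <- fit_parametric(ipd, "weibull")
  sr <- survival::survreg(
    survival::Surv(time, event) ~ 1,
    data = data.frame(time = ipd$time, event = as.integer(ipd$event)),
    dist = "weibull")
  # survreg: S(t) = exp(-(t * exp(-mu))^(1/sigma))
  shape_sr <- 1 / sr$scale
  scale_sr <- exp(-coef(sr)[[1]] / sr$scale)
  expect_equal(fit$spec$shape, shape_sr, tolerance = 1e-4)
  expect_equal(fit$spec$scale, scale_sr, tolerance = 1e-3)
})

test_that("degenerate IPD is rejected", {
  expect_error(fit_parametric(data.frame(time = c(1, 2, 3),
                                         event = c(TRUE, TRUE, TRUE)),
                              "weibull"),
               class = "oncocea_degenerate_data")
  expect_error(fit_parametric(data.frame(time = 1:20,
                                         event = rep(FALSE, 20)),
                              "weibull"),
               class = "oncocea_degenerate_data")
})

test_that("model selection minimizes AIC with BIC tie-break", {
  fm <- function(aic, bic, k) structure(
    list(spec = family_specs()$weibull, loglik = 0, n_params = as.integer(k),
         n_obs = 100, aic = aic, bic = bic), class = "fitted_model")
  fits <- list(fm(100, 105, 2), fm(98, 103, 2), fm(103, 101, 2))
  expect_identical(select_best_model(fits)$aic, 98)
  # AIC tie resolved by BIC, then by parameter count
  fits2 <- list(fm(98, 104, 2), fm(98, 103, 3), fm(98, 103, 2))
  best <- select_best_model(fits2)
  expect_identical(best$bic, 103)
  expect_identical(best$n_params, 2L)
  expect_identical(select_best_model(fits[2]), fits[[2]])
  expect_error(select_best_model(list()),
               class = "oncocea_invalid_argument")
})

test_that("selection recovers the generating family on large samples", {
  set.seed(23)
  ipd <- simulate_ipd(surv_spec("weibull", 0.0025282, 1.427602), 3000,
                      censoring_spec(admin_censor_time = 120))
  fits <- lapply(c("weibull", "lognormal", "exponential", "loglogistic"),
                 function(f) fit_parametric(ipd, f))
  expect_identical(select_best_model(fits)$spec$family, "weibull")
})

test_that("IPD round-trips through the delimited text format", {
  ipd <- data.frame(time = c(1.5, 2.25, 10), event = c(TRUE, FALSE, TRUE))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ipd(ipd, path)
  expect_identical(readLines(path)[1], "time_months\tevent01")
  back <- read_ipd(path)
  expect_equal(back$time, ipd$time)
  expect_identical(back$event, ipd$event)
  writeLines(c("a\tb", "1\t1"), path)
  expect_error(read_ipd(path), class = "oncocea_format_error")
})
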