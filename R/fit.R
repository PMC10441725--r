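# Maximum-likelihood fitting of the five candidate survival families to
# right-censored individual patient data, and AIC/BIC model selection.
# Fitting is delegated to flexsurv::flexsurvreg(); the fitted parameters
# are re-expressed in the package's scale/shape parameterization (see
# ?surv_spec for the forms).

FLEXSURV_DIST <- c(exponential = "exp", weibull = "weibullPH",
                   loglogistic = "llogis", lognormal = "lnorm",
                   gompertz = "gompertz")

# flexsurv parameter vector -> surv_spec(scale, shape)
from_flexsurv <- function(family, res) {
  switch(family,
    exponential = list(scale = unname(res["rate"]), shape = 1),
    weibull     = list(scale = unname(res["scale"]),
                       shape = unname(res["shape"])),
    loglogistic = list(scale = unname(res["scale"])^(-unname(res["shape"])),
                       shape = unname(res["shape"])),
    lognormal   = list(scale = exp(-unname(res["meanlog"])),
                       shape = 1 / unname(res["sdlog"])),
    gompertz    = list(scale = unname(res["rate"]),
                       shape = unname(res["shape"])))
}

assert_ipd <- function(ipd) {
  if (!is.data.frame(ipd) || !all(c("time", "event") %in% names(ipd)))
    stop_oncocea("IPD must be a data frame with columns 'time' and 'event'",
                 "oncocea_invalid_argument")
  if (any(!is.finite(ipd$time)) || any(ipd$time <= 0))
    stop_oncocea("IPD times must be finite and positive",
                 "oncocea_invalid_argument")
  invisible(ipd)
}

#' Fit a parametric survival model to right-censored IPD
#'
#' Maximizes the right-censored log-likelihood
#' \eqn{\sum_{\mathrm{events}} \log f(t_i) + \sum_{\mathrm{censored}} \log S(t_i)}
#' for the requested family and returns the fit together with AIC and BIC.
#'
#' @param ipd Data frame with columns `time` (months, positive) and
#'   `event` (logical or 0/1; `TRUE` = event observed).
#' @param family One of the five supported families, see [surv_spec()].
#' @return A `fitted_model` list: `spec` ([surv_spec()]), `loglik`,
#'   `n_params`, `n_obs`, `aic`, `bic`.
#' @export
fit_parametric <- function(ipd, family) {
  family <- match.arg(family, SURV_FAMILIES)
  assert_ipd(ipd)
  n <- nrow(ipd)
  ev <- as.logical(ipd$event)
  if (n < 10)
    stop_oncocea("need at least 10 records to fit a survival model",
                 "oncocea_degenerate_data")
  if (!any(ev))
    stop_oncocea("all records are censored; cannot fit a survival model",
                 "oncocea_degenerate_data")
  dat <- data.frame(time = ipd$time, event = as.integer(ev))
  fs <- tryCatch(
    flexsurv::flexsurvreg(survival::Surv(time, event) ~ 1, data = dat,
                          dist = FLEXSURV_DIST[[family]]),
    error = function(e)
      stop_oncocea(paste0("survival model fit failed (", family, "): ",
                          conditionMessage(e)),
                   "oncocea_numerical_error"))
  if (!is.null(fs$opt$convergence) && fs$opt$convergence != 0)
    stop_oncocea(sprintf("optimizer did not converge for family '%s'",
                         family), "oncocea_numerical_error")
  est <- fs$res[, "est"]
  if (is.null(names(est))) names(est) <- rownames(fs$res)
  par <- from_flexsurv(family, est)
  if (par$shape <= 0 || par$scale <= 0)
    stop_oncocea(sprintf(
      "fitted %s parameters fall outside the supported space (scale %g, shape %g)",
      family, par$scale, par$shape), "oncocea_numerical_error")
  k <- fs$npars
  structure(list(spec = surv_spec(family, par$scale, par$shape),
                 loglik = fs$loglik, n_params = k, n_obs = n,
                 aic = 2 * k - 2 * fs$loglik,
                 bic = k * log(n) - 2 * fs$loglik),
            class = "fitted_model")
}

#' @export
print.fitted_model <- function(x, ...) {
  cat(sprintf(
    "<fitted_model> %s(scale = %g, shape = %g)  loglik %.2f  AIC %.2f  BIC %.2f  (n = %d)\n",
    x$spec$family, x$spec$scale, x$spec$shape, x$loglik, x$aic, x$bic,
    x$n_obs))
  invisible(x)
}

#' Select the best-fitting survival model
#'
#' Minimum AIC wins; ties are broken by minimum BIC, then by fewer
#' parameters.
#'
#' @param fits Non-empty list of `fitted_model` objects over the same data.
#' @return The selected `fitted_model`.
#' @export
select_best_model <- function(fits) {
  if (!is.list(fits) || length(fits) == 0 ||
      !all(vapply(fits, inherits, logical(1), "fitted_model")))
    stop_oncocea("'fits' must be a non-empty list of fitted_model objects",
                 "oncocea_invalid_argument")
  o <- order(vapply(fits, `[[`, numeric(1), "aic"),
             vapply(fits, `[[`, numeric(1), "bic"),
             vapply(fits, `[[`, numeric(1), "n_params"))
  fits[[o[1]]]
}

#' Read / write individual patient data
#'
#' The on-disk format is tab-delimited text with a mandatory header and
#' two columns: `time_months` (positive) and `event01` (1 = event,
#' 0 = right-censored).
#'
#' @param path File path.
#' @return `read_ipd()` returns a data frame with columns `time` and
#'   `event` (logical).
#' @export
read_ipd <- function(path) {
  d <- read.delim(path, header = TRUE)
  if (!all(c("time_months", "event01") %in% names(d)))
    stop_oncocea(
      "IPD file must have header columns 'time_months' and 'event01'",
      "oncocea_format_error")
  out <- data.frame(time = as.numeric(d$time_months),
                    event = as.integer(d$event01) == 1L)
  assert_ipd(out)
  out
}

#' @rdname read_ipd
#' @param ipd Data frame with columns `time` and `event`.
#' @export
write_ipd <- function(ipd, path) {
  assert_ipd(ipd)
  write.table(data.frame(time_months = ipd$time,
                         event01 = as.integer(as.logical(ipd$event))),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
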