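#' Parametric survival specification
#'
#' A `surv_spec` is a fully parameterized time-to-event law for one
#' endpoint (PFS or OS) of one treatment arm. Time is measured in months.
#' All five families are parameterized by a positive `scale` and a
#' positive `shape` so that published scale/shape pairs can be stored
#' verbatim:
#'
#' * `weibull`: \eqn{S(t) = \exp(-\mathrm{scale}\, t^{\mathrm{shape}})}
#' * `exponential`: Weibull with `shape = 1`,
#'   \eqn{S(t) = \exp(-\mathrm{scale}\, t)}
#' * `loglogistic`: \eqn{S(t) = 1/(1 + \mathrm{scale}\, t^{\mathrm{shape}})}
#' * `lognormal`: \eqn{S(t) = 1 - \Phi(\mathrm{shape}\cdot\log(\mathrm{scale}\, t))},
#'   i.e. `meanlog = -log(scale)`, `sdlog = 1/shape`
#' * `gompertz`: hazard \eqn{h(t) = \mathrm{scale}\cdot e^{\mathrm{shape}\, t}},
#'   \eqn{S(t) = \exp(-(\mathrm{scale}/\mathrm{shape})(e^{\mathrm{shape}\, t}-1))}
#'
#' @param family One of `"exponential"`, `"weibull"`, `"loglogistic"`,
#'   `"lognormal"`, `"gompertz"`.
#' @param scale Positive scale parameter (per-month hazard scale).
#' @param shape Positive shape parameter. Must be 1 for the exponential
#'   family (the default there).
#' @return An object of class `surv_spec`.
#' @examples
#' os <- surv_spec("weibull", scale = 0.0025282, shape = 1.427602)
#' surv_prob(os, c(0, 12, 51))
#' surv_median(os)
#' @export
surv_spec <- function(family, scale, shape = if (family == "exponential") 1) {
  family <- match.arg(family, SURV_FAMILIES)
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) ||
      scale <= 0)
    stop_oncocea("'scale' must be a single positive finite number",
                 "oncocea_invalid_argument")
  if (!is.numeric(shape) || length(shape) != 1L || !is.finite(shape) ||
      shape <= 0)
    stop_oncocea("'shape' must be a single positive finite number",
                 "oncocea_invalid_argument")
  if (family == "exponential" && shape != 1)
    stop_oncocea("exponential family requires shape = 1",
                 "oncocea_invalid_argument")
  structure(list(family = family, scale = scale, shape = shape),
            class = "surv_spec")
}

#' @export
print.surv_spec <- function(x, ...) {
  cat(sprintf("<surv_spec> %s(scale = %g, shape = %g), median %.2f months\n",
              x$family, x$scale, x$shape, surv_median(x)))
  invisible(x)
}

is_surv_spec <- function(x) inherits(x, "surv_spec")

assert_surv_spec <- function(x, what = "spec") {
  if (!is_surv_spec(x))
    stop_oncocea(sprintf("'%s' must be a surv_spec object", what),
                 "oncocea_invalid_argument")
  invisible(x)
}

#' Survival probability S(t)
#'
#' @param spec A [surv_spec()].
#' @param t Time in months, non-negative (vectorized).
#' @return Survival probabilities in (0, 1]; `S(0) = 1`.
#' @export
surv_prob <- function(spec, t) {
  assert_surv_spec(spec)
  if (any(!is.finite(t)) || any(t < 0))
    stop_oncocea("'t' must be finite and non-negative",
                 "oncocea_domain_error")
  sc <- spec$scale; sh <- spec$shape
  switch(spec$family,
    exponential = ,
    weibull     = exp(-sc * t^sh),
    loglogistic = 1 / (1 + sc * t^sh),
    lognormal   = ifelse(t == 0, 1, pnorm(-sh * log(sc * t))),
    gompertz    = exp(-(sc / sh) * expm1(sh * t)))
}

#' Density f(t) of a parametric survival law
#'
#' @inheritParams surv_prob
#' @return Density values; 0 at `t = 0` for families with `f(0) = 0`.
#' @export
surv_density <- function(spec, t) {
  assert_surv_spec(spec)
  if (any(!is.finite(t)) || any(t < 0))
    stop_oncocea("'t' must be finite and non-negative",
                 "oncocea_domain_error")
  sc <- spec$scale; sh <- spec$shape
  s <- surv_prob(spec, t)
  switch(spec$family,
    exponential = ,
    weibull     = ifelse(t == 0, if (sh < 1) Inf else if (sh == 1) sc else 0,
                         sc * sh * t^(sh - 1) * s),
    loglogistic = ifelse(t == 0, if (sh < 1) Inf else if (sh == 1) sc else 0,
                         sc * sh * t^(sh - 1) * s^2),
    lognormal   = ifelse(t == 0, 0, dnorm(sh * log(sc * t)) * sh / t),
    gompertz    = sc * exp(sh * t) * s)
}

#' Quantile of the event-time distribution
#'
#' Inverse of the cumulative distribution `F(t) = 1 - S(t)`; closed form
#' for every family.
#'
#' @param spec A [surv_spec()].
#' @param p Probabilities in \[0, 1).
#' @return Times in months with `F(t) = p`.
#' @export
surv_quantile <- function(spec, p) {
  assert_surv_spec(spec)
  if (any(p < 0) || any(p >= 1))
    stop_oncocea("'p' must lie in [0, 1)", "oncocea_domain_error")
  sc <- spec$scale; sh <- spec$shape
  switch(spec$family,
    exponential = ,
    weibull     = (-log1p(-p) / sc)^(1 / sh),
    loglogistic = (p / ((1 - p) * sc))^(1 / sh),
    lognormal   = ifelse(p == 0, 0, exp(qnorm(p) / sh) / sc),
    gompertz    = log1p(-sh * log1p(-p) / sc) / sh)
}

#' Median survival time
#'
#' Time `t` with `S(t) = 0.5`, in months. Closed form for all families
#' (Weibull: \eqn{(\ln 2/\mathrm{scale})^{1/\mathrm{shape}}}).
#'
#' @param spec A [surv_spec()].
#' @return Median survival in months.
#' @export
surv_median <- function(spec) surv_quantile(spec, 0.5)
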