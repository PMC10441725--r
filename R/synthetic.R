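# Synthetic right-censored individual patient data: the statistical
# structure that pseudo-IPD reconstructed from published Kaplan-Meier
# curves carries, generated here directly from a parametric law so the
# fitting and model-selection stage can be exercised end to end.

#' Censoring mechanism for synthetic IPD
#'
#' Administrative censoring at a fixed study cutoff combined with random
#' dropout following an exponential law.
#'
#' @param admin_censor_time Study cutoff in months (`Inf` = none).
#' @param dropout_rate Per-month exponential dropout hazard (0 = none).
#' @return A `censoring_spec` object.
#' @export
censoring_spec <- function(admin_censor_time = Inf, dropout_rate = 0) {
  if (!is.numeric(admin_censor_time) || length(admin_censor_time) != 1L ||
      is.na(admin_censor_time) || admin_censor_time <= 0)
    stop_oncocea("'admin_censor_time' must be positive",
                 "oncocea_invalid_argument")
  if (!is.numeric(dropout_rate) || length(dropout_rate) != 1L ||
      is.na(dropout_rate) || dropout_rate < 0)
    stop_oncocea("'dropout_rate' must be non-negative",
                 "oncocea_invalid_argument")
  structure(list(admin_censor_time = admin_censor_time,
                 dropout_rate = dropout_rate),
            class = "censoring_spec")
}

#' Simulate right-censored individual patient data
#'
#' Event times are drawn by inverse-transform sampling from the closed-form
#' quantile function of `spec` (see [surv_quantile()]); each record is
#' censored at the minimum of the administrative cutoff and an exponential
#' dropout time.
#'
#' @param spec A [surv_spec()].
#' @param n Number of patients (>= 1).
#' @param censoring A [censoring_spec()]; default: no censoring.
#' @param seed Optional integer seed for reproducibility.
#' @return Data frame with columns `time` (months) and `event` (logical).
#' @export
simulate_ipd <- function(spec, n, censoring = censoring_spec(), seed = NULL) {
  assert_surv_spec(spec)
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1)
    stop_oncocea("'n' must be at least 1", "oncocea_invalid_argument")
  if (!inherits(censoring, "censoring_spec"))
    stop_oncocea("'censoring' must be a censoring_spec object",
                 "oncocea_invalid_argument")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  t_event <- surv_quantile(spec, runif(n))
  t_drop <- if (censoring$dropout_rate > 0)
    rexp(n, censoring$dropout_rate) else rep(Inf, n)
  t_cens <- pmin(censoring$admin_censor_time, t_drop)
  data.frame(time = pmin(t_event, t_cens), event = t_event <= t_cens)
}

#' Kaplan-Meier estimate of a survival curve
#'
#' Product-limit estimator (via [survival::survfit()]); events at a tied
#' time are processed before censorings, the standard convention.
#'
#' @param ipd Data frame with columns `time` and `event`.
#' @return A `km_curve` data frame with columns `time`, `surv`, `n_risk`.
#' @export
km_estimate <- function(ipd) {
  assert_ipd(ipd)
  if (nrow(ipd) == 0)
    stop_oncocea("IPD is empty", "oncocea_invalid_argument")
  fit <- survival::survfit(
    survival::Surv(time, event) ~ 1,
    data = data.frame(time = ipd$time, event = as.integer(as.logical(ipd$event))))
  structure(data.frame(time = fit$time, surv = fit$surv,
                       n_risk = fit$n.risk),
            class = c("km_curve", "data.frame"))
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' Right-continuous step interpolation; 1 before the first event time.
#'
#' @param km A `km_curve` from [km_estimate()].
#' @param t Times in months.
#' @return Estimated survival probabilities.
#' @export
km_surv_at <- function(km, t) {
  if (!inherits(km, "km_curve"))
    stop_oncocea("'km' must be a km_curve", "oncocea_invalid_argument")
  vapply(t, function(ti) {
    i <- which(km$time <= ti)
    if (length(i) == 0) 1 else km$surv[max(i)]
  }, numeric(1))
}

#' Export a Kaplan-Meier curve as CSV
#'
#' @param km A `km_curve`.
#' @param path Output file path.
#' @export
write_km <- function(km, path) {
  if (!inherits(km, "km_curve"))
    stop_oncocea("'km' must be a km_curve", "oncocea_invalid_argument")
  write.csv(data.frame(time_months = km$time, survival = km$surv,
                       n_at_risk = km$n_risk),
            path, row.names = FALSE)
  invisible(path)
}
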