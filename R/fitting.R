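#' Survival record tables
#'
#' Pseudo-individual-patient data (IPD) are plain data frames with columns
#' `time_cycles` (non-negative event or censoring time in 21-day cycles) and
#' `event` (1 = event observed, 0 = right-censored). `as_survival_records()`
#' validates and normalises such a table.
#'
#' @param data A data frame with columns `time_cycles` and `event`.
#' @return The validated data frame.
#' @export
as_survival_records <- function(data) {
  data <- as.data.frame(data)
  if (!all(c("time_cycles", "event") %in% names(data))) {
    stop("survival records need columns `time_cycles` and `event`", call. = FALSE)
  }
  if (nrow(data) == 0L) stop("empty survival record table", call. = FALSE)
  if (any(!is.finite(data$time_cycles)) || any(data$time_cycles < 0)) {
    stop("`time_cycles` must be finite and >= 0", call. = FALSE)
  }
  if (!all(data$event %in% c(0, 1))) {
    stop("`event` must be 0 (censored) or 1 (event)", call. = FALSE)
  }
  data[c("time_cycles", "event")]
}

#' Kaplan-Meier curve container
#'
#' @param times Non-decreasing event times (cycles).
#' @param survival Survival probabilities in `[0, 1]`, non-increasing.
#' @param at_risk Non-negative numbers at risk just before each time.
#' @return A `km_curve` object (also a data frame).
#' @export
km_curve <- function(times, survival, at_risk) {
  stopifnot(length(times) == length(survival), length(times) == length(at_risk))
  if (length(times) == 0L) stop("empty KM curve", call. = FALSE)
  if (is.unsorted(times)) stop("KM `times` must be non-decreasing", call. = FALSE)
  if (any(survival < 0 | survival > 1)) stop("KM `survival` outside [0, 1]", call. = FALSE)
  if (any(diff(survival) > 1e-12)) stop("KM `survival` must be non-increasing", call. = FALSE)
  if (any(at_risk < 0)) stop("negative `at_risk`", call. = FALSE)
  structure(data.frame(time_cycles = times, survival = survival, at_risk = at_risk),
            class = c("km_curve", "data.frame"))
}

#' Product-limit (Kaplan-Meier) estimate from survival records
#'
#' Thin wrapper around [survival::survfit()] with ties handled
#' event-before-censor (the estimator's standard convention).
#'
#' @param data Survival records (see [as_survival_records()]).
#' @return A [km_curve()] with one row per distinct observed time.
#' @examples
#' km_estimate(data.frame(time_cycles = 1:3, event = 1))
#' @export
km_estimate <- function(data) {
  data <- as_survival_records(data)
  fit <- survival::survfit(survival::Surv(time_cycles, event) ~ 1, data = data)
  km_curve(fit$time, fit$surv, fit$n.risk)
}

# supported parametric families and their flexsurv names / free-parameter counts
.families <- list(
  loglogistic = list(flexsurv = "llogis", k = 2L),
  weibull     = list(flexsurv = "weibull", k = 2L),
  exponential = list(flexsurv = "exp", k = 1L),
  lognormal   = list(flexsurv = "lnorm", k = 2L)
)

#' Maximum-likelihood parametric survival fit
#'
#' Fits one of four candidate families (log-logistic, Weibull, exponential,
#' log-normal) to right-censored survival records by maximum likelihood via
#' [flexsurv::flexsurvreg()]: events contribute the density, censored records
#' the survival function. For the log-logistic family the natural
#' `(shape, scale)` estimates are mapped to this model's `(theta, kappa)`
#' parameterisation through `kappa = shape`, `theta = -shape * log(scale)`.
#'
#' @param data Survival records with at least two distinct observed event times.
#' @param family One of `"loglogistic"`, `"weibull"`, `"exponential"`,
#'   `"lognormal"`.
#' @return A `parametric_fit` with elements `family`, `params`
#'   ([llogis_params()] for the log-logistic, a named coefficient list
#'   otherwise), `coefs` (natural parameters), `loglik`, `aic`, `bic`,
#'   `k` (free parameters), `n` (records) and `n_events`.
#' @export
fit_parametric <- function(data, family = "loglogistic") {
  data <- as_survival_records(data)
  family <- match.arg(family, names(.families))
  n_events <- sum(data$event == 1)
  if (n_events == 0L) {
    stop("all records censored: parameters unidentifiable", call. = FALSE)
  }
  if (n_events < 2L || length(unique(data$time_cycles[data$event == 1])) < 2L) {
    stop("degenerate data: need >= 2 distinct observed event times", call. = FALSE)
  }
  if (any(data$time_cycles == 0 & data$event == 1)) {
    # zero event times have no density under these families; nudge by half of
    # the smallest positive time so the likelihood is defined
    eps <- min(data$time_cycles[data$time_cycles > 0], 1) / 2
    data$time_cycles[data$time_cycles == 0 & data$event == 1] <- eps
  }
  fam <- .families[[family]]
  fit <- flexsurv::flexsurvreg(
    survival::Surv(time_cycles, event) ~ 1, data = data, dist = fam$flexsurv)
  coefs <- stats::setNames(as.list(fit$res[, "est"]), rownames(fit$res))
  n <- nrow(data)
  ll <- fit$loglik
  params <- if (family == "loglogistic") {
    llogis_params(theta = -coefs$shape * log(coefs$scale), kappa = coefs$shape)
  } else coefs
  structure(list(family = family, params = params, coefs = coefs,
                 loglik = ll, aic = -2 * ll + 2 * fam$k,
                 bic = -2 * ll + fam$k * log(n),
                 k = fam$k, n = n, n_events = n_events),
            class = "parametric_fit")
}

#' @export
print.parametric_fit <- function(x, ...) {
  cat(sprintf("parametric fit: %s (n = %d, events = %d)\n",
              x$family, x$n, x$n_events))
  cat("  ", paste(names(x$coefs), signif(unlist(x$coefs), 5),
                  sep = " = ", collapse = ", "), "\n")
  cat(sprintf("  loglik %.3f  AIC %.3f  BIC %.3f\n", x$loglik, x$aic, x$bic))
  invisible(x)
}

#' Predicted survival from a parametric fit
#'
#' @param fit A `parametric_fit`.
#' @param t Non-negative times in cycles.
#' @return Survival probabilities.
#' @export
fitted_survival <- function(fit, t) {
  stopifnot(inherits(fit, "parametric_fit"))
  if (any(t < 0)) stop("negative time in `t`", call. = FALSE)
  cf <- fit$coefs
  switch(fit$family,
    loglogistic = llogis_survival(fit$params, t),
    weibull     = stats::pweibull(t, cf$shape, cf$scale, lower.tail = FALSE),
    exponential = stats::pexp(t, cf$rate, lower.tail = FALSE),
    lognormal   = stats::plnorm(t, cf$meanlog, cf$sdlog, lower.tail = FALSE))
}

#' Adjusted R-squared of a parametric fit against a Kaplan-Meier curve
#'
#' Residuals are taken on the survival-probability scale at the KM time
#' points: `R2 = 1 - SS_res / SS_tot`, then adjusted as
#' `1 - (1 - R2) (n - 1) / (n - k - 1)` with `n` KM points and `k` free model
#' parameters.
#'
#' @param fit A `parametric_fit`.
#' @param km A [km_curve()].
#' @return Adjusted R-squared (at most 1).
#' @export
adjusted_r2_vs_km <- function(fit, km) {
  stopifnot(inherits(fit, "parametric_fit"), inherits(km, "km_curve"))
  n <- nrow(km)
  k <- fit$k
  if (n <= k + 1L) {
    stop("adjusted R2 undefined: need more KM points than parameters + 1",
         call. = FALSE)
  }
  pred <- fitted_survival(fit, km$time_cycles)
  ss_res <- sum((km$survival - pred)^2)
  ss_tot <- sum((km$survival - mean(km$survival))^2)
  if (ss_tot == 0) {
    # flat KM curve: perfect iff residual-free
    return(if (ss_res == 0) 1 else -Inf)
  }
  r2 <- 1 - ss_res / ss_tot
  1 - (1 - r2) * (n - 1) / (n - k - 1)
}

#' Read / write pseudo-IPD and KM curve CSV files
#'
#' `read_ipd()`/`write_ipd()` use the dialect `time_cycles,event`;
#' `read_km()`/`write_km()` use `time_cycles,survival,at_risk`. All files are
#' UTF-8, `.`-decimal, comma-separated with a header row.
#'
#' @param path File path.
#' @param data Survival records, for `write_ipd()`.
#' @param km A [km_curve()], for `write_km()`.
#' @return The records or curve (readers); the path, invisibly (writers).
#' @export
read_ipd <- function(path) {
  as_survival_records(utils::read.csv(path))
}

#' @rdname read_ipd
#' @export
write_ipd <- function(data, path) {
  utils::write.csv(as_survival_records(data), path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_ipd
#' @export
read_km <- function(path) {
  d <- utils::read.csv(path)
  km_curve(d$time_cycles, d$survival, d$at_risk)
}

#' @rdname read_ipd
#' @export
write_km <- function(km, path) {
  stopifnot(inherits(km, "km_curve"))
  utils::write.csv(as.data.frame(km), path, row.names = FALSE)
  invisible(path)
}

#' Write a fit-report CSV
#'
#' One row per fit with columns `arm,endpoint,family,theta,kappa,shape,scale,
#' rate,meanlog,sdlog,loglik,aic,bic,adj_r2`; parameters that a family does
#' not have are `NA`.
#'
#' @param fits List of `parametric_fit` objects.
#' @param arm,endpoint Character vectors recycled against `fits`.
#' @param adj_r2 Optional numeric vector of adjusted R-squared values.
#' @param path File path.
#' @return The report data frame, invisibly.
#' @export
write_fit_report <- function(fits, arm, endpoint, path, adj_r2 = NA_real_) {
  stopifnot(all(vapply(fits, inherits, logical(1), "parametric_fit")))
  arm <- rep_len(arm, length(fits))
  endpoint <- rep_len(endpoint, length(fits))
  adj_r2 <- rep_len(adj_r2, length(fits))
  row1 <- function(i) {
    f <- fits[[i]]
    cf <- f$coefs
    get <- function(nm) if (!is.null(cf[[nm]])) cf[[nm]] else NA_real_
    data.frame(
      arm = arm[i], endpoint = endpoint[i], family = f$family,
      theta = if (f$family == "loglogistic") f$params$theta else NA_real_,
      kappa = if (f$family == "loglogistic") f$params$kappa else NA_real_,
      shape = get("shape"), scale = get("scale"), rate = get("rate"),
      meanlog = get("meanlog"), sdlog = get("sdlog"),
      loglik = f$loglik, aic = f$aic, bic = f$bic, adj_r2 = adj_r2[i])
  }
  report <- do.call(rbind, lapply(seq_along(fits), row1))
  utils::write.csv(report, path, row.names = FALSE)
  invisible(report)
}
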