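#' Log-logistic survival parameters
#'
#' Constructs the parameter pair of the log-logistic survival curve used
#' throughout the model,
#' \deqn{S(t) = \frac{1}{1 + e^{\theta} t^{\kappa}},}
#' with `t` measured in model cycles of 21 days (one chemotherapy cycle).
#' `theta` is a log-scale location parameter (the curve's median is
#' `exp(-theta/kappa)` cycles) and `kappa > 0` is the shape.
#'
#' @param theta Real location parameter (dimensionless, log scale).
#' @param kappa Positive shape parameter.
#' @return An object of class `llogis_params`.
#' @examples
#' p <- llogis_params(theta = -3.2726, kappa = 1.4703)
#' llogis_survival(p, 0:10)
#' llogis_median(p)
#' @export
llogis_params <- function(theta, kappa) {
  stopifnot(is.numeric(theta), length(theta) == 1L, is.finite(theta),
            is.numeric(kappa), length(kappa) == 1L, is.finite(kappa))
  if (kappa <= 0) {
    stop("`kappa` must be > 0 (got ", kappa, ")", call. = FALSE)
  }
  structure(list(theta = theta, kappa = kappa), class = "llogis_params")
}

#' @export
print.llogis_params <- function(x, ...) {
  cat(sprintf("log-logistic survival: theta = %.4f, kappa = %.4f\n",
              x$theta, x$kappa))
  cat(sprintf("  median %.2f cycles (%.1f months at 21 d/cycle)\n",
              llogis_median(x), llogis_median(x) * 21 / 30.4375))
  invisible(x)
}

#' Survival probability of the log-logistic curve
#'
#' Evaluates `S(t) = 1 / (1 + exp(theta) * t^kappa)` at times `t` (cycles).
#' `S(0) = 1` and the curve is strictly decreasing for `t > 0`.
#'
#' @param params A [llogis_params()] object.
#' @param t Non-negative vector of times in 21-day cycles.
#' @return Vector of survival probabilities in `(0, 1]`.
#' @export
llogis_survival <- function(params, t) {
  stopifnot(inherits(params, "llogis_params"), is.numeric(t))
  if (any(t < 0)) stop("negative time in `t`", call. = FALSE)
  1 / (1 + exp(params$theta) * t^params$kappa)
}

#' Density of the log-logistic event-time distribution
#'
#' @inheritParams llogis_survival
#' @return Vector of densities (per cycle).
#' @export
llogis_density <- function(params, t) {
  stopifnot(inherits(params, "llogis_params"), is.numeric(t))
  if (any(t < 0)) stop("negative time in `t`", call. = FALSE)
  th <- params$theta; k <- params$kappa
  s <- 1 / (1 + exp(th) * t^k)
  exp(th) * k * t^(k - 1) * s^2
}

#' Median of the log-logistic curve (closed form)
#'
#' `exp(-theta/kappa)` cycles; `llogis_survival(params, llogis_median(params))`
#' equals 0.5 by construction.
#'
#' @inheritParams llogis_survival
#' @return Median survival time in cycles.
#' @export
llogis_median <- function(params) {
  stopifnot(inherits(params, "llogis_params"))
  exp(-params$theta / params$kappa)
}

#' Mean of the log-logistic event-time distribution (closed form)
#'
#' Finite only for `kappa > 1`: `alpha * (pi/kappa) / sin(pi/kappa)` with
#' scale `alpha = exp(-theta/kappa)`.
#'
#' @inheritParams llogis_survival
#' @return Mean survival time in cycles.
#' @export
llogis_mean <- function(params) {
  stopifnot(inherits(params, "llogis_params"))
  k <- params$kappa
  if (k <= 1) stop("mean is infinite for kappa <= 1", call. = FALSE)
  b <- pi / k
  llogis_median(params) * b / sin(b)
}

#' Quantile function (inverse CDF) of the log-logistic distribution
#'
#' Solves `1 - S(t) = p`, giving `t = (p/(1-p))^(1/kappa) * exp(-theta/kappa)`.
#'
#' @inheritParams llogis_survival
#' @param p Vector of probabilities in `[0, 1)`.
#' @return Vector of times in cycles.
#' @export
llogis_quantile <- function(params, p) {
  stopifnot(inherits(params, "llogis_params"), is.numeric(p))
  if (any(p < 0 | p >= 1)) stop("`p` must be in [0, 1)", call. = FALSE)
  (p / (1 - p))^(1 / params$kappa) * llogis_median(params)
}
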