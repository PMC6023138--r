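#' Probabilistic-sensitivity-analysis parameter distribution
#'
#' A `(family, median, low, high)` quadruple defining how one uncertain
#' parameter is drawn in the probabilistic sensitivity analysis. The printed
#' range is treated as a 95% interval and the point value as the mean for
#' moment matching (see [build_sampler()]).
#'
#' @param param_id Parameter label.
#' @param family `"lognormal"`, `"gamma"`, `"beta"`, or `"fixed"` (never
#'   drawn).
#' @param median Point (base-case) value.
#' @param low,high Range bounds, `low <= median <= high`. Beta requires all
#'   three in `[0, 1]`; lognormal and gamma require positive values.
#' @return A `param_distribution`.
#' @export
param_distribution <- function(param_id, family, median, low, high) {
  family <- match.arg(family, c("lognormal", "gamma", "beta", "fixed"))
  if (!(low <= median && median <= high)) {
    stop("`", param_id, "`: need low <= median <= high", call. = FALSE)
  }
  if (family %in% c("lognormal", "gamma") && low <= 0 && low < high) {
    stop("`", param_id, "`: ", family, " requires positive values",
         call. = FALSE)
  }
  if (family == "beta" && (low < 0 || high > 1)) {
    stop("`", param_id, "`: beta requires values in [0, 1]", call. = FALSE)
  }
  structure(list(param_id = param_id, family = family, median = median,
                 low = low, high = high), class = "param_distribution")
}

#' Build a random-value source for a parameter distribution
#'
#' Mapping conventions (the literature rarely states how a point value and
#' range define a distribution; this one is centralised here so alternatives
#' are one function away):
#'
#' * lognormal: `meanlog = log(median)`, `sdlog = (log(high) - log(low)) /
#'   (2 * 1.96)` -- the median is reproduced exactly.
#' * gamma: moment-matched to mean `median` and `sd = (high - low) / (2 *
#'   1.96)`.
#' * beta: moment-matched the same way; infeasible moments
#'   (`sd^2 >= mean (1 - mean)`) raise an error naming the parameter.
#' * a degenerate range (`low == high`) or the `fixed` family yields a
#'   constant sampler.
#'
#' The returned sampler is a function of `n` drawing from R's global RNG
#' stream, so a joint [set.seed()] governs reproducibility across parameters;
#' pass `seed` to fix the stream here instead.
#'
#' @param dist A [param_distribution()].
#' @param seed Optional integer seed applied before each call.
#' @return `function(n)` returning `n` draws.
#' @export
build_sampler <- function(dist, seed = NULL) {
  stopifnot(inherits(dist, "param_distribution"))
  wrap <- function(f) {
    if (is.null(seed)) f
    else function(n) { set.seed(seed); f(n) }
  }
  if (dist$family == "fixed" || dist$low == dist$high) {
    return(wrap(function(n) rep(dist$median, n)))
  }
  z95 <- 2 * stats::qnorm(0.975)
  if (dist$family == "lognormal") {
    meanlog <- log(dist$median)
    sdlog <- (log(dist$high) - log(dist$low)) / z95
    return(wrap(function(n) stats::rlnorm(n, meanlog, sdlog)))
  }
  m <- dist$median
  s <- (dist$high - dist$low) / z95
  if (dist$family == "gamma") {
    shape <- m^2 / s^2
    rate <- m / s^2
    return(wrap(function(n) stats::rgamma(n, shape = shape, rate = rate)))
  }
  # beta
  if (s^2 >= m * (1 - m)) {
    stop("`", dist$param_id, "`: beta moment-matching infeasible (sd^2 = ",
         signif(s^2, 4), " >= mean(1-mean) = ", signif(m * (1 - m), 4), ")",
         call. = FALSE)
  }
  nu <- m * (1 - m) / s^2 - 1
  shape1 <- m * nu
  shape2 <- (1 - m) * nu
  wrap(function(n) stats::rbeta(n, shape1, shape2))
}

#' Distribution table of a configuration
#'
#' One [param_distribution()] per parameter flagged for the PSA.
#'
#' @param config A `model_config`.
#' @return Named list of `param_distribution` objects.
#' @export
config_distributions <- function(config) {
  p <- config$parameters[config$parameters$psa, ]
  out <- lapply(seq_len(nrow(p)), function(i) {
    param_distribution(p$id[i], p$family[i], p$value[i], p$low[i], p$high[i])
  })
  names(out) <- p$id
  out
}
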