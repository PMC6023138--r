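#' Simulate pseudo-individual patient data from a log-logistic curve
#'
#' Inverse-CDF sampling: for `u ~ Uniform(0,1)` the event time is
#' `t = (u/(1-u))^(1/kappa) * exp(-theta/kappa)` cycles. Optional
#' administrative right-censoring truncates times at `censor_time` and marks
#' them censored. Reproducible under `seed`.
#'
#' @param params A [llogis_params()] object.
#' @param n Number of patients (>= 1).
#' @param censor_time Administrative censoring time in cycles, or `NULL` for
#'   no censoring.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return Survival records (`time_cycles`, `event`).
#' @examples
#' ipd <- simulate_ipd(llogis_params(-3.2726, 1.4703), n = 100, seed = 1)
#' @export
simulate_ipd <- function(params, n, censor_time = NULL, seed = NULL) {
  stopifnot(inherits(params, "llogis_params"))
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("`n` must be a count >= 1", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  u <- stats::runif(n)
  t <- (u / (1 - u))^(1 / params$kappa) * exp(-params$theta / params$kappa)
  event <- rep(1, n)
  if (!is.null(censor_time)) {
    stopifnot(is.numeric(censor_time), censor_time >= 0)
    cens <- t > censor_time
    t[cens] <- censor_time
    event[cens] <- 0
  }
  data.frame(time_cycles = t, event = event)
}

#' Emulate a digitized Kaplan-Meier curve
#'
#' Simulates `n` patients from the curve, forms the product-limit estimate and
#' samples the resulting step function on a regular time grid -- the shape of
#' data a graph digitizer produces from a published KM figure. Optional
#' bounded jitter (off by default) perturbs the grid survival values by at
#' most `jitter`, then restores monotonicity and the `[0, 1]` range, mimicking
#' digitizer read-off error.
#'
#' @inheritParams simulate_ipd
#' @param grid_step Positive grid spacing in cycles.
#' @param max_time Upper end of the grid; defaults to the largest simulated
#'   time.
#' @param jitter Non-negative bound of the uniform perturbation (default 0).
#' @return A [km_curve()] sampled on the grid (`at_risk` is the number of
#'   simulated patients still at risk at each grid time).
#' @export
digitized_km_fixture <- function(params, n, grid_step, seed = NULL,
                                 max_time = NULL, jitter = 0) {
  if (!is.numeric(grid_step) || grid_step <= 0) {
    stop("`grid_step` must be > 0", call. = FALSE)
  }
  stopifnot(jitter >= 0)
  ipd <- simulate_ipd(params, n, seed = seed)
  km <- km_estimate(ipd)
  if (is.null(max_time)) max_time <- max(ipd$time_cycles)
  grid <- seq(0, max_time, by = grid_step)
  # step-function value: last KM point at or before each grid time (1 before
  # the first event)
  idx <- findInterval(grid, km$time_cycles)
  surv <- c(1, km$survival)[idx + 1L]
  at_risk <- vapply(grid, function(g) sum(ipd$time_cycles >= g), numeric(1))
  if (jitter > 0) {
    surv <- surv + stats::runif(length(surv), -jitter, jitter)
    surv <- pmin(pmax(surv, 0), 1)
    surv <- cummin(surv)  # restore the non-increasing KM shape
    surv[1] <- min(1, max(surv[1], surv[2]))
  }
  km_curve(grid, surv, at_risk)
}

#' Two-arm trial fixture mirroring the study conditions
#'
#' Default parameterisation of the source trial: arms X (capecitabine
#' monotherapy, n = 26) and XELOX (capecitabine + oxaliplatin, n = 24), with
#' the fitted log-logistic progression-free and overall survival parameters of
#' each arm. All defaults can be overridden.
#'
#' @param seed Integer seed stored in the fixture and used by
#'   [simulate_trial()].
#' @param arm_names Pair of arm labels.
#' @param n_per_arm Pair of per-arm sample sizes.
#' @param pfs_params,os_params Named lists (one [llogis_params()] per arm).
#' @return A `trial_fixture` object.
#' @export
make_trial_fixture <- function(seed = 1L,
                               arm_names = c("X", "XELOX"),
                               n_per_arm = c(X = 26L, XELOX = 24L),
                               pfs_params = list(
                                 X = llogis_params(-3.0531, 2.1872),
                                 XELOX = llogis_params(-3.9836, 1.6494)),
                               os_params = list(
                                 X = llogis_params(-3.2726, 1.4703),
                                 XELOX = llogis_params(-4.5714, 1.4960))) {
  stopifnot(length(arm_names) == 2L, length(n_per_arm) == 2L)
  names(n_per_arm) <- arm_names
  for (a in arm_names) {
    if (llogis_median(pfs_params[[a]]) > llogis_median(os_params[[a]])) {
      stop("fixture arm ", a, ": PFS median exceeds OS median", call. = FALSE)
    }
  }
  structure(list(arm_names = arm_names, n_per_arm = n_per_arm,
                 pfs_params = pfs_params, os_params = os_params,
                 seed = as.integer(seed)),
            class = "trial_fixture")
}

#' @export
print.trial_fixture <- function(x, ...) {
  cat("two-arm trial fixture (seed ", x$seed, ")\n", sep = "")
  for (a in x$arm_names) {
    cat(sprintf(
      "  %s (n = %d): PFS median %.2f cycles, OS median %.2f cycles\n",
      a, x$n_per_arm[[a]],
      llogis_median(x$pfs_params[[a]]), llogis_median(x$os_params[[a]])))
  }
  invisible(x)
}

#' Simulate pseudo-IPD for every arm and endpoint of a fixture
#'
#' @param fixture A [make_trial_fixture()] object.
#' @param censor_time Optional administrative censoring time (cycles).
#' @return Named list `arm -> list(pfs = records, os = records)`.
#' @export
simulate_trial <- function(fixture, censor_time = NULL) {
  stopifnot(inherits(fixture, "trial_fixture"))
  set.seed(fixture$seed)
  out <- list()
  for (a in fixture$arm_names) {
    out[[a]] <- list(
      pfs = simulate_ipd(fixture$pfs_params[[a]], fixture$n_per_arm[[a]],
                         censor_time = censor_time),
      os = simulate_ipd(fixture$os_params[[a]], fixture$n_per_arm[[a]],
                        censor_time = censor_time))
  }
  out
}

#' Inject a trial fixture into a model configuration
#'
#' Serializes the fixture's arms and survival parameters into the declarative
#' config format, so a simulated trial can drive the full economic pipeline
#' (and be written out with [save_config()]).
#'
#' @param fixture A [make_trial_fixture()] object.
#' @param base Configuration to start from (default [default_config()]).
#' @return A validated `model_config`.
#' @export
fixture_config <- function(fixture, base = default_config()) {
  stopifnot(inherits(fixture, "trial_fixture"))
  base$arms <- fixture$arm_names
  base$survival <- stats::setNames(lapply(fixture$arm_names, function(a) {
    list(pfs = list(theta = fixture$pfs_params[[a]]$theta,
                    kappa = fixture$pfs_params[[a]]$kappa),
         os = list(theta = fixture$os_params[[a]]$theta,
                   kappa = fixture$os_params[[a]]$kappa))
  }), fixture$arm_names)
  validate_config(base)
}
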