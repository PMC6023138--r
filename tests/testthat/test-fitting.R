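test_that("KM estimate matches the hand-computed product limit", {
  km <- km_estimate(data.frame(time_cycles = 1:3, event = 1))
  expect_s3_class(km, "km_curve")
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(km$at_risk, c(3, 2, 1))
  # all-censored data give a flat curve at 1
  flat <- km_estimate(data.frame(time_cycles = c(2, 5, 9), event = 0))
  expect_true(all(flat$survival == 1))
  expect_error(km_estimate(data.frame(time_cycles = c(-1, 2), event = 1)),
               ">= 0")
})

test_that("KM estimate converges to the generating curve", {
  ipd <- simulate_ipd(x_os, n = 5000, seed = 7)
  km <- km_estimate(ipd)
  sup <- max(abs(km$survival - llogis_survival(x_os, km$time_cycles)))
  expect_lt(sup, 0.05)
})

test_that("MLE recovers log-logistic parameters and its information criteria", {
  ipd <- simulate_ipd(llogis_params(-3.27, 1.47), n = 5000, seed = 3)
  fit <- fit_parametric(ipd, "loglogistic")
  expect_equal(fit$params$theta, -3.27, tolerance = 0.05)
  expect_equal(fit$params$kappa, 1.47, tolerance = 0.05)
  # AIC/BIC identities hold exactly for every returned fit
  for (fam in c("loglogistic", "weibull", "exponential", "lognormal")) {
    f <- fit_parametric(ipd[1:300, ], fam)
    expect_equal(f$aic, -2 * f$loglik + 2 * f$k)
    expect_equal(f$bic, -2 * f$loglik + f$k * log(f$n))
  }
})

test_that("fits are consistent: error shrinks with sample size", {
  truth <- c(-3.27, 1.47)
  mare <- function(n, seeds) {
    errs <- vapply(seeds, function(s) {
      f <- fit_parametric(simulate_ipd(llogis_params(truth[1], truth[2]),
                                       n, seed = s), "loglogistic")
      mean(abs(c(f$params$theta, f$params$kappa) - truth) / abs(truth))
    }, numeric(1))
    stats::median(errs)
  }
  expect_lt(mare(5000, 1:5), mare(200, 1:5))
})

test_that("right-censoring is handled in the likelihood", {
  # heavy administrative censoring should not wreck parameter recovery
  ipd <- simulate_ipd(llogis_params(-3.27, 1.47), n = 5000,
                      censor_time = 15, seed = 5)
  expect_gt(mean(ipd$event == 0), 0.2)
  fit <- fit_parametric(ipd, "loglogistic")
  expect_equal(fit$params$theta, -3.27, tolerance = 0.1)
  expect_equal(fit$params$kappa, 1.47, tolerance = 0.1)
})

test_that("model selection prefers the generating family", {
  # data simulated from an exponential: AIC should favour it over the
  # log-logistic in the majority of replicates
  wins <- vapply(1:5, function(s) {
    set.seed(100 + s)
    ipd <- data.frame(time_cycles = stats::rexp(1000, rate = 0.2), event = 1)
    fit_parametric(ipd, "exponential")$aic < fit_parametric(ipd, "loglogistic")$aic
  }, logical(1))
  expect_gte(sum(wins), 3)
})

test_that("degenerate and unidentifiable inputs are rejected", {
  expect_error(fit_parametric(data.frame(time_cycles = numeric(), event = numeric())),
               "empty")
  expect_error(fit_parametric(data.frame(time_cycles = c(3, 5), event = 0)),
               "censored")
  expect_error(fit_parametric(data.frame(time_cycles = rep(4, 30), event = 1)),
               "degenerate")
})

test_that("adjusted R2 vs KM behaves as a goodness-of-fit measure", {
  ipd <- simulate_ipd(x_os, n = 200, seed = 2)
  fit <- fit_parametric(ipd, "loglogistic")
  # KM generated exactly from the fitted curve -> 1
  t <- 1:40
  exact <- km_curve(t, llogis_survival(fit$params, t), rep(100, 40))
  expect_equal(adjusted_r2_vs_km(fit, exact), 1)
  # perturbation strictly lowers it
  warped <- km_curve(t, llogis_survival(fit$params, t)^3, rep(100, 40))
  expect_lt(adjusted_r2_vs_km(fit, warped), 1)
  # trial-scale KM (n = 26) fits its own MLE well in most replicates
  r2 <- vapply(1:10, function(s) {
    small <- simulate_ipd(x_os, n = 26, seed = 200 + s)
    f <- fit_parametric(small, "loglogistic")
    adjusted_r2_vs_km(f, km_estimate(small))
  }, numeric(1))
  expect_gte(sum(r2 >= 0.85 & r2 <= 1), 7)
  # undefined when KM points do not exceed parameters + 1
  tiny <- km_curve(c(1, 2, 3), c(0.9, 0.5, 0.2), c(10, 5, 2))
  expect_error(adjusted_r2_vs_km(fit, tiny), "undefined")
})

test_that("IPD, KM and fit-report CSV dialects round-trip", {
  tmp <- withr::local_tempdir()
  ipd <- simulate_ipd(x_pfs, n = 50, censor_time = 8, seed = 9)
  p1 <- file.path(tmp, "ipd.csv")
  write_ipd(ipd, p1)
  expect_equal(readLines(p1, n = 1), "\"time_cycles\",\"event\"")
  expect_equal(read_ipd(p1), ipd)
  km <- km_estimate(ipd)
  p2 <- file.path(tmp, "km.csv")
  write_km(km, p2)
  expect_equal(readLines(p2, n = 1), "\"time_cycles\",\"survival\",\"at_risk\"")
  expect_equal(as.data.frame(read_km(p2)), as.data.frame(km))
  fits <- list(fit_parametric(ipd, "loglogistic"),
               fit_parametric(ipd, "exponential"))
  p3 <- file.path(tmp, "report.csv")
  rep <- write_fit_report(fits, arm = "X", endpoint = "pfs", path = p3)
  back <- utils::read.csv(p3)
  expect_equal(back$family, c("loglogistic", "exponential"))
  expect_true(is.na(back$theta[2]) && !is.na(back$rate[2]))
  expect_equal(back$theta[1], fits[[1]]$params$theta)
})
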