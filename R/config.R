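#' Default model configuration
#'
#' Builds the packaged base-case configuration of the two-arm model: the
#' log-logistic survival parameters fitted to each arm's progression-free and
#' overall survival curves, the Chinese-healthcare-perspective cost table
#' (2016 US$), grade 3/4 adverse-event risks, second-line-chemotherapy risks,
#' health-state utilities (0.797 progression-free, 0.577 progressed, 0 dead),
#' dosing (capecitabine 1000 mg/m2 twice daily on days 1-14, oxaliplatin
#' 110 mg/m2 on day 1 in the XELOX arm, 21-day cycles), 3% annual discounting,
#' a 260-cycle (15-year) horizon, the willingness-to-pay threshold of
#' $26,598/QALY (3x 2016 Chinese per-capita GDP), and the accrual conventions
#' frozen by [calibrate_conventions()].
#'
#' Each uncertain parameter carries its point value, one-way range and
#' probabilistic-sensitivity-analysis distribution family in the
#' `parameters` table; the discount rate is varied one-way (0-5%) but not in
#' the PSA.
#'
#' @return A `model_config` object.
#' @export
default_config <- function() {
  parameters <- data.frame(
    id = c("cost_capecitabine", "cost_oxaliplatin", "cost_laboratory",
           "cost_administration", "cost_supportive_care", "cost_second_line",
           "cost_abdominal_ct", "cost_abdominal_mri", "cost_chest_xray",
           "cost_ae_diarrhea", "cost_ae_anemia", "cost_ae_fatigue",
           "cost_ae_anorexia", "cost_ae_thrombocytopenia",
           "risk_ae_diarrhea_x", "risk_ae_anemia_x", "risk_ae_fatigue_x",
           "risk_ae_anorexia_x", "risk_ae_thrombocytopenia_x",
           "risk_ae_diarrhea_xelox", "risk_ae_anemia_xelox",
           "risk_ae_fatigue_xelox", "risk_ae_anorexia_xelox",
           "risk_ae_thrombocytopenia_xelox",
           "risk_second_line_x", "risk_second_line_xelox",
           "utility_pfs", "utility_pd", "discount_rate"),
    value = c(4.8, 371.9, 129.5, 18.5, 1415.4, 5300.4, 60.2, 123.3, 6.0,
              44.3, 531.7, 115.4, 115.4, 3551.7,
              0.08, 0.15, 0.08, 0.08, 0.04,
              0.04, 0.08, 0.13, 0.13, 0.04,
              0.38, 0.58, 0.797, 0.577, 0.03),
    low = c(3.8, 297.5, 103.6, 16.6, 1022.8, 4240.3, 30.1, 61.7, 3.0,
            39.9, 478.5, 103.8, 103.8, 3196.5,
            0.064, 0.12, 0.064, 0.064, 0.032,
            0.032, 0.064, 0.104, 0.104, 0.032,
            0.304, 0.464, 0.638, 0.462, 0.0),
    high = c(5.8, 446.3, 155.4, 20.3, 2021.5, 6360.5, 90.3, 185.0, 9.0,
             48.7, 584.9, 126.9, 126.9, 3906.9,
             0.096, 0.18, 0.096, 0.096, 0.048,
             0.048, 0.096, 0.156, 0.156, 0.048,
             0.456, 0.696, 0.956, 0.692, 0.05),
    family = c(rep("lognormal", 6), rep("gamma", 3), rep("lognormal", 5),
               rep("beta", 14), "fixed"),
    psa = c(rep(TRUE, 28), FALSE),
    stringsAsFactors = FALSE)

  cfg <- list(
    schema_version = 1L,
    currency = "2016 USD",
    horizon_cycles = 260L,
    days_per_cycle = 21,
    days_per_year = 365,
    wtp = 26598,
    bsa = 1.72,
    arms = c("X", "XELOX"),
    survival = list(
      X = list(pfs = list(theta = -3.0531, kappa = 2.1872),
               os = list(theta = -3.2726, kappa = 1.4703)),
      XELOX = list(pfs = list(theta = -3.9836, kappa = 1.6494),
                   os = list(theta = -4.5714, kappa = 1.4960))),
    dosing = list(
      capecitabine_mg_m2 = 1000, capecitabine_admin_per_day = 2,
      capecitabine_days = 14, capecitabine_pack_mg = 500,
      oxaliplatin_mg_m2 = 110, oxaliplatin_vial_mg = 50,
      oxaliplatin_arms = "XELOX"),
    conventions = list(
      trace_method = "markov",
      accrual_timing = "start",
      capecitabine_rounding = "per_cycle",
      capecitabine_dose_reading = "full",
      admin_cost_in_x = TRUE,
      second_line_application = "exclusive",
      followup_every_cycles = 3L),
    psa = list(n_iter = 1000L, seed = 20180628L),
    parameters = parameters)
  class(cfg) <- "model_config"
  validate_config(cfg)
}

.allowed_top <- c("schema_version", "currency", "horizon_cycles",
                  "days_per_cycle", "days_per_year", "wtp", "bsa", "arms",
                  "survival", "dosing", "conventions", "psa", "parameters")
.allowed_conventions <- list(
  trace_method = c("markov", "partitioned"),
  accrual_timing = c("start", "end", "half"),
  capecitabine_rounding = c("per_cycle", "per_admin"),
  capecitabine_dose_reading = c("full", "half"),
  admin_cost_in_x = c(TRUE, FALSE),
  second_line_application = c("exclusive", "additive", "one_off"),
  followup_every_cycles = NULL)  # any count, 0 = never

#' Validate a model configuration
#'
#' Rejects unknown keys and checks every numeric range before any run:
#' positive horizon and cycle length, non-negative discount rate and costs,
#' probabilities and utilities in `[0, 1]`, `low <= value <= high` for every
#' parameter, valid convention flags and survival parameters.
#'
#' @param config A `model_config` (or plain list with the same shape).
#' @return The validated config, invisibly classed `model_config`.
#' @export
validate_config <- function(config) {
  config <- unclass(config)
  unknown <- setdiff(names(config), .allowed_top)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(.allowed_top, names(config))
  if (length(missing)) {
    stop("missing config key(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  with(config, {
    stopifnot(horizon_cycles >= 1, days_per_cycle > 0, days_per_year > 0,
              wtp >= 0, bsa > 0, length(arms) == 2L)
  })
  for (a in config$arms) {
    sv <- config$survival[[a]]
    if (is.null(sv)) stop("no survival parameters for arm ", a, call. = FALSE)
    for (ep in c("pfs", "os")) {
      llogis_params(sv[[ep]]$theta, sv[[ep]]$kappa)  # errors if invalid
    }
  }
  cv <- config$conventions
  for (nm in names(.allowed_conventions)) {
    allowed <- .allowed_conventions[[nm]]
    if (is.null(cv[[nm]])) stop("missing convention `", nm, "`", call. = FALSE)
    if (!is.null(allowed) && !cv[[nm]] %in% allowed) {
      stop("convention `", nm, "` must be one of: ",
           paste(allowed, collapse = ", "), call. = FALSE)
    }
  }
  if (cv$followup_every_cycles < 0) {
    stop("`followup_every_cycles` must be >= 0", call. = FALSE)
  }
  p <- config$parameters <- as.data.frame(config$parameters)
  need <- c("id", "value", "low", "high", "family", "psa")
  if (!all(need %in% names(p))) {
    stop("`parameters` table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(p$id)) stop("duplicate parameter ids", call. = FALSE)
  bad <- p$id[!(p$low <= p$value & p$value <= p$high)]
  if (length(bad)) {
    stop("parameter range violated (need low <= value <= high): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  probs <- grepl("^(risk_|utility_)", p$id)
  bad <- p$id[probs & (p$low < 0 | p$high > 1)]
  if (length(bad)) {
    stop("probability/utility outside [0, 1]: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  bad <- p$id[grepl("^cost_", p$id) & p$low < 0]
  if (length(bad)) {
    stop("negative cost: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!all(p$family %in% c("lognormal", "gamma", "beta", "fixed"))) {
    stop("unknown distribution family in `parameters`", call. = FALSE)
  }
  if (config$psa$n_iter < 1) stop("`psa$n_iter` must be >= 1", call. = FALSE)
  structure(config, class = "model_config")
}

#' Look up / override parameter values
#'
#' `param_values()` returns the named vector of base-case parameter values;
#' `set_param()` overrides one value. A value outside the parameter's one-way
#' range widens the range to include it (the ranges describe sensitivity
#' intervals, not hard bounds, but the config must stay self-consistent).
#'
#' @param config A `model_config`.
#' @param id Parameter id.
#' @param value New value.
#' @return Named numeric vector, or the modified config.
#' @export
param_values <- function(config) {
  stats::setNames(config$parameters$value, config$parameters$id)
}

#' @rdname param_values
#' @export
set_param <- function(config, id, value) {
  i <- match(id, config$parameters$id)
  if (is.na(i)) stop("unknown parameter id: ", id, call. = FALSE)
  config$parameters$value[i] <- value
  config$parameters$low[i] <- min(config$parameters$low[i], value)
  config$parameters$high[i] <- max(config$parameters$high[i], value)
  config
}

#' Read / write a model configuration as YAML
#'
#' The packaged default lives at
#' `system.file("extdata", "default_config.yaml", package = "ceagc")` and
#' reproduces the base case. Loaded files are fully validated; schema
#' violations name the offending key.
#'
#' @param path File path.
#' @param config A `model_config`, for `save_config()`.
#' @return A validated `model_config` (loader); the path, invisibly (writer).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$parameters)) {
    raw$parameters <- as.data.frame(raw$parameters, stringsAsFactors = FALSE)
  }
  if (!is.null(raw$arms)) raw$arms <- as.character(raw$arms)
  validate_config(raw)
}

#' @rdname load_config
#' @export
save_config <- function(config, path) {
  config <- validate_config(config)
  out <- unclass(config)
  out$parameters <- as.list(out$parameters)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.model_config <- function(x, ...) {
  cat("model_config:", x$currency, "|", x$horizon_cycles, "cycles of",
      x$days_per_cycle, "days | discount",
      sprintf("%.1f%%/yr", 100 * param_values(x)[["discount_rate"]]),
      "| WTP", format(x$wtp, big.mark = ","), "\n")
  cat("  arms:", paste(x$arms, collapse = " vs "), " bsa:", x$bsa, "m2\n")
  cv <- x$conventions
  cat("  conventions:", paste(names(cv), unlist(cv), sep = "=",
                              collapse = ", "), "\n")
  cat("  ", nrow(x$parameters), "parameters (",
      sum(x$parameters$psa), "in PSA )\n")
  invisible(x)
}

#' Hash of a configuration (provenance tag for outputs)
#'
#' A short deterministic fingerprint of the serialized config, logged with
#' every CLI output so result files can be traced to the exact configuration.
#'
#' @param config A `model_config`.
#' @return A character scalar.
#' @export
config_hash <- function(config) {
  txt <- paste(utils::capture.output(utils::str(unclass(config), digits.d = 10)),
               collapse = "\n")
  # FNV-1a-style 32-bit hash over the serialized text, kept in double
  # arithmetic (R's bitwXor is 32-bit signed); dependency-free and stable
  h <- 2166136261
  for (b in utf8ToInt(txt) %% 256) {
    low <- h %% 256
    h <- h - low + bitwXor(low, b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
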