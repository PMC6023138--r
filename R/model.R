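#' Evaluate the economic model for one arm
#'
#' Builds the arm's cohort trace from its survival parameters (under the
#' configured trace method and horizon) and accrues discounted costs and
#' QALYs under the configured conventions.
#'
#' @param config A `model_config`.
#' @param arm Arm label.
#' @param values Optional named vector of parameter values overriding the
#'   base case (as used by the sensitivity analyses).
#' @return An `econ_outcome`.
#' @export
evaluate_arm <- function(config, arm, values = NULL) {
  if (is.null(values)) values <- param_values(config)
  sv <- config$survival[[arm]]
  trace <- build_trace(
    llogis_params(sv$pfs$theta, sv$pfs$kappa),
    llogis_params(sv$os$theta, sv$os$kappa),
    config$horizon_cycles,
    method = config$conventions$trace_method)
  accrue_outcomes(
    trace,
    arm_inputs(config, arm, values),
    utility_set(u_pfs = unname(values[["utility_pfs"]]),
                u_pd = unname(values[["utility_pd"]])),
    discount_spec(annual_rate = unname(values[["discount_rate"]]),
                  days_per_cycle = config$days_per_cycle,
                  days_per_year = config$days_per_year))
}

#' Run the base case
#'
#' Evaluates both arms at the base-case parameter values and compares them
#' (second arm vs first).
#'
#' @param config A `model_config`.
#' @param values Optional parameter override vector.
#' @return A `base_case` object: per-arm `econ_outcome`s, the
#'   `ce_comparison`, and the conventions in force.
#' @examples
#' bc <- run_base_case(default_config())
#' print(bc)
#' @export
run_base_case <- function(config, values = NULL) {
  config <- validate_config(config)
  outcomes <- lapply(config$arms, evaluate_arm, config = config,
                     values = values)
  names(outcomes) <- config$arms
  structure(list(
    outcomes = outcomes,
    comparison = compare_arms(outcomes[[1]], outcomes[[2]]),
    conventions = config$conventions,
    currency = config$currency),
    class = "base_case")
}

#' @export
print.base_case <- function(x, ...) {
  arms <- names(x$outcomes)
  cat("Base-case cost-effectiveness results (", x$currency, ")\n", sep = "")
  cat("  conventions: ", paste(names(x$conventions), unlist(x$conventions),
                               sep = "=", collapse = ", "), "\n", sep = "")
  f <- function(v) formatC(v, format = "f", digits = 2, big.mark = ",")
  q <- function(v) formatC(v, format = "f", digits = 2)
  w <- max(nchar(arms)) + 2
  pad <- function(s) formatC(s, width = w)
  cat(sprintf("  %-22s %12s %12s\n", "Outcome", arms[1], arms[2]))
  o1 <- x$outcomes[[1]]; o2 <- x$outcomes[[2]]
  rows <- list(
    c("Costs in PFS ($)", f(o1$cost_pfs), f(o2$cost_pfs)),
    c("Costs in PD ($)", f(o1$cost_pd), f(o2$cost_pd)),
    c("Total costs ($)", f(o1$cost_total), f(o2$cost_total)),
    c("QALYs in PFS", q(o1$qaly_pfs), q(o2$qaly_pfs)),
    c("QALYs in PD", q(o1$qaly_pd), q(o2$qaly_pd)),
    c("Total QALYs", q(o1$qaly_total), q(o2$qaly_total)),
    c("Cost/effectiveness", f(x$comparison$ce_ratio_ref),
      f(x$comparison$ce_ratio_alt)))
  for (r in rows) cat(sprintf("  %-22s %12s %12s\n", r[1], r[2], r[3]))
  cat(sprintf("  %-22s %12s %12s\n", "Incremental cost ($)", "-",
              f(x$comparison$delta_cost)))
  cat(sprintf("  %-22s %12s %12s\n", "Incremental QALYs", "-",
              q(x$comparison$delta_qaly)))
  if (x$comparison$dominance == "none" && !is.na(x$comparison$icer)) {
    cat(sprintf("  %-22s %12s %12s\n", "ICER ($/QALY)", "-",
                f(x$comparison$icer)))
  } else {
    cat(sprintf("  %-22s %12s %12s\n", "ICER", "-", x$comparison$dominance))
  }
  invisible(x)
}

#' Export base-case outcomes as CSV
#'
#' Columns `arm,cost_pfs,cost_pd,cost_total,qaly_pfs,qaly_pd,qaly_total`.
#'
#' @param base_case A [run_base_case()] result.
#' @param path File path.
#' @return The data frame, invisibly.
#' @export
write_outcomes <- function(base_case, path) {
  stopifnot(inherits(base_case, "base_case"))
  df <- do.call(rbind, lapply(base_case$outcomes, function(o) {
    data.frame(arm = o$arm, cost_pfs = o$cost_pfs, cost_pd = o$cost_pd,
               cost_total = o$cost_total, qaly_pfs = o$qaly_pfs,
               qaly_pd = o$qaly_pd, qaly_total = o$qaly_total)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Per-state cost/QALY cells of a configuration
#'
#' The eight summary cells of the base case (costs and QALYs in the
#' progression-free and progressed states, for both arms), as used by the
#' convention calibration.
#'
#' @param config A `model_config`.
#' @param values Optional parameter override vector.
#' @return Named numeric vector
#'   `<arm>.cost_pfs, <arm>.cost_pd, <arm>.qaly_pfs, <arm>.qaly_pd`.
#' @export
model_cells <- function(config, values = NULL) {
  out <- c()
  for (arm in config$arms) {
    o <- evaluate_arm(config, arm, values)
    v <- c(cost_pfs = o$cost_pfs, cost_pd = o$cost_pd,
           qaly_pfs = o$qaly_pfs, qaly_pd = o$qaly_pd)
    names(v) <- paste(arm, names(v), sep = ".")
    out <- c(out, v)
  }
  out
}
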