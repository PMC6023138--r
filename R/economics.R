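#' Utility set for the three health states
#'
#' Preference weights per state: progression-free, progressed disease and
#' death (fixed at 0). Defaults are the base-case values 0.797 and 0.577.
#'
#' @param u_pfs,u_pd Utilities in `[0, 1]`.
#' @return A `utility_set`.
#' @export
utility_set <- function(u_pfs = 0.797, u_pd = 0.577) {
  stopifnot(is.numeric(u_pfs), is.numeric(u_pd))
  if (u_pfs < 0 || u_pfs > 1 || u_pd < 0 || u_pd > 1) {
    stop("utilities must lie in [0, 1]", call. = FALSE)
  }
  structure(list(u_pfs = u_pfs, u_pd = u_pd, u_dead = 0),
            class = "utility_set")
}

#' Discounting specification
#'
#' Continuous-compounding-free per-cycle discounting from an annual rate:
#' cycle `t` is weighted by `(1 + rate)^(-t * days_per_cycle / days_per_year)`.
#'
#' @param annual_rate Annual discount rate (default 0.03).
#' @param days_per_cycle,days_per_year Calendar conversion (21 and 365).
#' @return A `discount_spec`.
#' @export
discount_spec <- function(annual_rate = 0.03, days_per_cycle = 21,
                          days_per_year = 365) {
  stopifnot(annual_rate >= 0, days_per_cycle > 0, days_per_year > 0)
  structure(list(annual_rate = annual_rate, days_per_cycle = days_per_cycle,
                 days_per_year = days_per_year), class = "discount_spec")
}

discount_factors <- function(discount, t) {
  (1 + discount$annual_rate)^(-t * discount$days_per_cycle /
                                discount$days_per_year)
}

.ae_types <- c("diarrhea", "anemia", "fatigue", "anorexia", "thrombocytopenia")

#' Economic inputs for one treatment arm
#'
#' Assembles the per-arm cost, risk and dosing inputs from a configuration and
#' (optionally) an overriding vector of parameter values, as used by the
#' sensitivity analyses. Arm-specific parameters are looked up with the
#' lower-cased arm name as suffix (e.g. `risk_second_line_xelox`).
#'
#' @param config A `model_config`.
#' @param arm Arm label (one of `config$arms`).
#' @param values Named vector of parameter values; defaults to
#'   [param_values()] of the config.
#' @return An `arm_inputs` object.
#' @export
arm_inputs <- function(config, arm, values = NULL) {
  if (!arm %in% config$arms) {
    stop("unknown arm `", arm, "`; config arms: ",
         paste(config$arms, collapse = ", "), call. = FALSE)
  }
  if (is.null(values)) values <- param_values(config)
  v <- function(id) {
    if (!id %in% names(values)) stop("missing parameter: ", id, call. = FALSE)
    unname(values[[id]])
  }
  sfx <- tolower(arm)
  has_oxa <- arm %in% config$dosing$oxaliplatin_arms
  structure(list(
    arm = arm,
    bsa = config$bsa,
    dosing = config$dosing,
    conventions = config$conventions,
    unit_costs = list(
      capecitabine = v("cost_capecitabine"),
      oxaliplatin = v("cost_oxaliplatin"),
      laboratory = v("cost_laboratory"),
      administration = v("cost_administration"),
      supportive_care = v("cost_supportive_care"),
      second_line = v("cost_second_line"),
      abdominal_ct = v("cost_abdominal_ct"),
      abdominal_mri = v("cost_abdominal_mri"),
      chest_xray = v("cost_chest_xray")),
    ae_costs = vapply(.ae_types, function(a) v(paste0("cost_ae_", a)),
                      numeric(1)),
    ae_risks = vapply(.ae_types, function(a) v(paste0("risk_ae_", a, "_", sfx)),
                      numeric(1)),
    p_second_line = v(paste0("risk_second_line_", sfx)),
    has_oxaliplatin = has_oxa,
    admin_applies = has_oxa || isTRUE(config$conventions$admin_cost_in_x)),
    class = "arm_inputs")
}

#' First-line drug acquisition cost per 21-day cycle
#'
#' Capecitabine: `dose_mg_m2 * bsa` mg per administration, two administrations
#' per day for 14 days; rounded up to whole 500 mg units either per
#' administration (`per_admin`) or over the cycle total (`per_cycle`,
#' default), then priced per unit. Under the `half` dose reading the printed
#' 1000 mg/m2 daily dose is split across the two administrations.
#' Oxaliplatin (oxaliplatin arms only): `110 * bsa` mg on day 1, rounded up to
#' whole 50 mg vials.
#'
#' @param inputs An [arm_inputs()] object.
#' @return List with `capecitabine`, `oxaliplatin` and `total` cost per cycle.
#' @export
regimen_drug_cost_per_cycle <- function(inputs) {
  stopifnot(inherits(inputs, "arm_inputs"))
  if (inputs$bsa <= 0) stop("`bsa` must be > 0", call. = FALSE)
  dd <- inputs$dosing
  cv <- inputs$conventions
  mg_m2 <- dd$capecitabine_mg_m2
  if (identical(cv$capecitabine_dose_reading, "half")) mg_m2 <- mg_m2 / 2
  dose_mg <- mg_m2 * inputs$bsa
  n_admin <- dd$capecitabine_admin_per_day * dd$capecitabine_days
  pack <- dd$capecitabine_pack_mg
  units <- if (identical(cv$capecitabine_rounding, "per_admin")) {
    ceiling(dose_mg / pack) * n_admin
  } else {
    ceiling(dose_mg * n_admin / pack)
  }
  cape <- units * inputs$unit_costs$capecitabine
  oxa <- 0
  if (inputs$has_oxaliplatin) {
    vials <- ceiling(dd$oxaliplatin_mg_m2 * inputs$bsa / dd$oxaliplatin_vial_mg)
    oxa <- vials * inputs$unit_costs$oxaliplatin
  }
  list(capecitabine = cape, oxaliplatin = oxa, total = cape + oxa)
}

#' Cost accrued per cycle spent in a health state
#'
#' Progression-free cycles accrue first-line drug acquisition,
#' administration (always in the intravenous XELOX arm; in the oral-only X arm
#' only when the `admin_cost_in_x` convention is on) and laboratory costs.
#' Progressed-disease cycles accrue a follow-up package (abdominal CT,
#' abdominal MRI, chest radiograph and laboratory evaluation) once every
#' `followup_every_cycles` cycles, plus second-line treatment costs under the
#' configured application rule: `exclusive` (the fraction `p_second_line`
#' accrues second-line chemotherapy instead of supportive care), `additive`
#' (supportive care for all plus `p_second_line` weighted chemotherapy) or
#' `one_off` (supportive care only here; a single weighted second-line cost is
#' charged on entry into the state by [accrue_outcomes()]). Death accrues
#' nothing.
#'
#' @param inputs An [arm_inputs()] object.
#' @param state `"pfs"`, `"pd"` or `"dead"`.
#' @param cycle Ignored (state costs are cycle-constant); kept for interface
#'   stability.
#' @return Cost per cycle (money).
#' @export
state_cost_per_cycle <- function(inputs, state, cycle = NULL) {
  stopifnot(inherits(inputs, "arm_inputs"))
  uc <- inputs$unit_costs
  cv <- inputs$conventions
  switch(state,
    pfs = {
      regimen_drug_cost_per_cycle(inputs)$total +
        (if (inputs$admin_applies) uc$administration else 0) +
        uc$laboratory
    },
    pd = {
      fu_every <- cv$followup_every_cycles
      fu <- if (fu_every > 0) {
        (uc$abdominal_ct + uc$abdominal_mri + uc$chest_xray + uc$laboratory) /
          fu_every
      } else 0
      p2 <- inputs$p_second_line
      sl <- switch(cv$second_line_application,
        exclusive = (1 - p2) * uc$supportive_care + p2 * uc$second_line,
        additive = uc$supportive_care + p2 * uc$second_line,
        one_off = uc$supportive_care)
      fu + sl
    },
    dead = 0,
    stop("unknown health state: ", state, call. = FALSE))
}

#' One-off grade 3/4 adverse-event cost
#'
#' Sum over the five main adverse events (diarrhea, anemia, fatigue, anorexia,
#' thrombocytopenia) of per-patient risk times cost per episode, charged once
#' at model start (the risks are per-patient trial incidences, not per-cycle
#' rates).
#'
#' @param inputs An [arm_inputs()] object.
#' @return Money.
#' @export
one_off_ae_cost <- function(inputs) {
  stopifnot(inherits(inputs, "arm_inputs"))
  if (any(inputs$ae_risks < 0 | inputs$ae_risks > 1)) {
    stop("adverse-event risks must lie in [0, 1]", call. = FALSE)
  }
  sum(inputs$ae_risks * inputs$ae_costs)
}

#' Discounted cost and QALY accrual over a cohort trace
#'
#' Per cycle `t`, each state contributes `occupancy * state_cost * d(t)` to
#' costs and `occupancy * utility * cycle_years * d(t)` to QALYs, with
#' `d(t) = (1 + rate)^(-t * days_per_cycle / days_per_year)`. Occupancy is
#' taken at cycle start, cycle end or the midpoint average (half-cycle
#' correction) per the `accrual_timing` convention. The one-off adverse-event
#' cost enters undiscounted at cycle 0 (progression-free bucket); under the
#' `one_off` second-line rule the weighted second-line cost is charged on
#' entry into progressed disease, discounted at the entry cycle.
#'
#' @param trace A `cohort_trace`.
#' @param inputs An [arm_inputs()] object.
#' @param utilities A [utility_set()].
#' @param discount A [discount_spec()].
#' @return An `econ_outcome`: `cost_pfs`, `cost_pd`, `cost_total`,
#'   `qaly_pfs`, `qaly_pd`, `qaly_total`, with discounted person-cycles per
#'   state as attribute `person_cycles`.
#' @export
accrue_outcomes <- function(trace, inputs, utilities, discount) {
  stopifnot(inherits(trace, "cohort_trace"), inherits(inputs, "arm_inputs"),
            inherits(utilities, "utility_set"),
            inherits(discount, "discount_spec"))
  H <- attr(trace, "n_cycles")
  timing <- inputs$conventions$accrual_timing
  if (timing == "start") {
    w_pfs <- trace$pfs[1:H]; w_pd <- trace$pd[1:H]; td <- 0:(H - 1)
  } else if (timing == "end") {
    w_pfs <- trace$pfs[2:(H + 1)]; w_pd <- trace$pd[2:(H + 1)]; td <- 1:H
  } else {
    w_pfs <- (trace$pfs[1:H] + trace$pfs[2:(H + 1)]) / 2
    w_pd <- (trace$pd[1:H] + trace$pd[2:(H + 1)]) / 2
    td <- 1:H - 0.5
  }
  d <- discount_factors(discount, td)
  pc_pfs <- sum(w_pfs * d)
  pc_pd <- sum(w_pd * d)
  cycle_years <- discount$days_per_cycle / discount$days_per_year

  cost_pfs <- pc_pfs * state_cost_per_cycle(inputs, "pfs") +
    one_off_ae_cost(inputs)
  cost_pd <- pc_pd * state_cost_per_cycle(inputs, "pd")
  if (identical(inputs$conventions$second_line_application, "one_off")) {
    inflow <- pmax(trace$pfs[1:H] - trace$pfs[2:(H + 1)], 0)
    d_entry <- discount_factors(discount, 0:(H - 1))
    cost_pd <- cost_pd + sum(inflow * d_entry) * inputs$p_second_line *
      inputs$unit_costs$second_line
  }
  qaly_pfs <- pc_pfs * utilities$u_pfs * cycle_years
  qaly_pd <- pc_pd * utilities$u_pd * cycle_years
  structure(list(
    arm = inputs$arm,
    cost_pfs = cost_pfs, cost_pd = cost_pd, cost_total = cost_pfs + cost_pd,
    qaly_pfs = qaly_pfs, qaly_pd = qaly_pd, qaly_total = qaly_pfs + qaly_pd),
    person_cycles = c(pfs = pc_pfs, pd = pc_pd),
    class = "econ_outcome")
}

#' @export
print.econ_outcome <- function(x, ...) {
  cat(sprintf("arm %s: cost %0.2f (PFS %0.2f + PD %0.2f), QALY %0.4f (PFS %0.4f + PD %0.4f)\n",
              x$arm, x$cost_total, x$cost_pfs, x$cost_pd,
              x$qaly_total, x$qaly_pfs, x$qaly_pd))
  invisible(x)
}

#' Incremental comparison of two arms
#'
#' Computes `alt - ref` increments, the ICER (`delta_cost / delta_qaly`) when
#' the QALY increment is non-zero, each arm's cost-effectiveness ratio, and a
#' dominance verdict: the alternative dominates when it is cheaper and more
#' effective, is dominated in the mirror case; otherwise the ICER is the
#' decision quantity.
#'
#' @param ref,alt `econ_outcome` objects (reference first).
#' @return A `ce_comparison` with `delta_cost`, `delta_qaly`, `icer` (`NA`
#'   when undefined or dominance applies), `dominance` flag and the two C/E
#'   ratios.
#' @export
compare_arms <- function(ref, alt) {
  stopifnot(inherits(ref, "econ_outcome"), inherits(alt, "econ_outcome"))
  dc <- alt$cost_total - ref$cost_total
  dq <- alt$qaly_total - ref$qaly_total
  dominance <- if (dc < 0 && dq > 0) "alt_dominant"
    else if (dc > 0 && dq < 0) "ref_dominant"
    else "none"
  icer <- if (dq != 0 && dominance == "none") dc / dq else NA_real_
  icer_flag <- if (dq == 0 && dc != 0) "undefined_zero_qaly_increment"
    else if (dominance != "none") "dominance"
    else "ok"
  structure(list(
    ref_arm = ref$arm, alt_arm = alt$arm,
    delta_cost = dc, delta_qaly = dq, icer = icer, icer_flag = icer_flag,
    dominance = dominance,
    ce_ratio_ref = ref$cost_total / ref$qaly_total,
    ce_ratio_alt = alt$cost_total / alt$qaly_total),
    class = "ce_comparison")
}

#' @export
print.ce_comparison <- function(x, ...) {
  cat(sprintf("%s vs %s: dCost %0.2f, dQALY %0.4f\n",
              x$alt_arm, x$ref_arm, x$delta_cost, x$delta_qaly))
  if (x$dominance != "none") {
    cat("  dominance:", x$dominance, "(no finite ICER reported)\n")
  } else if (!is.na(x$icer)) {
    cat(sprintf("  ICER %0.2f per QALY\n", x$icer))
  } else {
    cat("  ICER undefined:", x$icer_flag, "\n")
  }
  cat(sprintf("  C/E ratios: %s %0.2f, %s %0.2f\n",
              x$ref_arm, x$ce_ratio_ref, x$alt_arm, x$ce_ratio_alt))
  invisible(x)
}
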