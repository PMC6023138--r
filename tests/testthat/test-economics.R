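cfg <- default_config()

test_that("oxaliplatin acquisition rounds up to whole 50 mg vials", {
  # 110 mg/m2 * 1.72 m2 = 189.2 mg -> 4 vials at $371.9
  dc <- regimen_drug_cost_per_cycle(arm_inputs(cfg, "XELOX"))
  expect_equal(dc$oxaliplatin, 4 * 371.9)
  expect_equal(dc$oxaliplatin, 1487.60)
  # the oral-only arm buys no oxaliplatin
  expect_equal(regimen_drug_cost_per_cycle(arm_inputs(cfg, "X"))$oxaliplatin, 0)
})

test_that("capecitabine rounding conventions count 500 mg units correctly", {
  # 1000 mg/m2 * 1.72 = 1720 mg per administration, 28 administrations
  v <- param_values(cfg)
  inp <- arm_inputs(cfg, "X", v)
  expect_equal(regimen_drug_cost_per_cycle(inp)$capecitabine,
               ceiling(1720 * 28 / 500) * 4.8)  # per-cycle total: 97 units
  cfg2 <- cfg
  cfg2$conventions$capecitabine_rounding <- "per_admin"
  expect_equal(regimen_drug_cost_per_cycle(arm_inputs(cfg2, "X"))$capecitabine,
               4 * 28 * 4.8)  # 4 units per administration
  cfg3 <- cfg
  cfg3$conventions$capecitabine_dose_reading <- "half"
  expect_equal(regimen_drug_cost_per_cycle(arm_inputs(cfg3, "X"))$capecitabine,
               ceiling(860 * 28 / 500) * 4.8)
  # zero unit price -> zero drug cost
  v0 <- v; v0[["cost_capecitabine"]] <- 0
  expect_equal(regimen_drug_cost_per_cycle(arm_inputs(cfg, "X", v0))$capecitabine, 0)
  # degenerate body surface area is rejected
  cfg4 <- cfg; cfg4$bsa <- 0
  expect_error(regimen_drug_cost_per_cycle(arm_inputs(cfg4, "X")), "bsa")
})

test_that("one-off adverse-event cost is the risk-weighted episode sum", {
  # X arm at base case: 0.15*531.7 + 0.08*44.3 + 0.08*115.4 + 0.08*115.4
  #                     + 0.04*3551.7 = 243.831
  expect_equal(one_off_ae_cost(arm_inputs(cfg, "X")), 243.831)
  v <- param_values(cfg)
  v[grep("^risk_ae_.*_x$", names(v))] <- 0
  expect_equal(one_off_ae_cost(arm_inputs(cfg, "X", v)), 0)
  v[grep("^risk_ae_.*_x$", names(v))] <- 1
  expect_equal(one_off_ae_cost(arm_inputs(cfg, "X", v)),
               44.3 + 531.7 + 115.4 + 115.4 + 3551.7)
})

test_that("state costs follow the configured conventions", {
  inp <- arm_inputs(cfg, "X")
  expect_equal(state_cost_per_cycle(inp, "dead"), 0)
  # progression-free: drugs + administration + laboratory, cycle-constant
  c_pfs <- state_cost_per_cycle(inp, "pfs")
  expect_equal(c_pfs,
               regimen_drug_cost_per_cycle(inp)$total + 18.5 + 129.5)
  expect_equal(state_cost_per_cycle(inp, "pfs", cycle = 7), c_pfs)
  # progressed disease, exclusive second-line rule + follow-up every 3 cycles
  expect_equal(state_cost_per_cycle(inp, "pd"),
               (60.2 + 123.3 + 6.0 + 129.5) / 3 +
                 0.62 * 1415.4 + 0.38 * 5300.4)
  # with everything that costs anything in PD switched off it accrues nothing
  v <- param_values(cfg)
  v[["risk_second_line_x"]] <- 0
  v[["cost_supportive_care"]] <- 0
  cfg_nofu <- cfg
  cfg_nofu$conventions$followup_every_cycles <- 0L
  expect_equal(state_cost_per_cycle(arm_inputs(cfg_nofu, "X", v), "pd"), 0)
  expect_error(state_cost_per_cycle(inp, "limbo"), "unknown health state")
})

test_that("a single undiscounted progression-free cycle accrues u * 21/365", {
  sure <- llogis_params(-30, 1)  # survival ~ 1 over the first cycle
  tr <- build_partitioned_trace(sure, sure, 1)
  v <- param_values(cfg)
  v[grepl("^cost_|^risk_", names(v))] <- 0
  inp <- arm_inputs(cfg, "X", v)
  out <- accrue_outcomes(tr, inp, utility_set(0.797, 0.577),
                         discount_spec(annual_rate = 0))
  expect_equal(out$qaly_pfs, 0.797 * 21 / 365, tolerance = 1e-9)
  expect_equal(out$cost_total, 0)
})

test_that("accrual is additive, linear in unit costs, and zero at zero", {
  o <- evaluate_arm(cfg, "XELOX")
  expect_equal(o$cost_total, o$cost_pfs + o$cost_pd)
  expect_equal(o$qaly_total, o$qaly_pfs + o$qaly_pd)
  # tripling every unit cost triples all cost outputs, leaves QALYs alone
  v <- param_values(cfg)
  v3 <- v
  v3[grepl("^cost_", names(v3))] <- v3[grepl("^cost_", names(v3))] * 3
  o3 <- evaluate_arm(cfg, "XELOX", v3)
  expect_equal(o3$cost_pfs, 3 * o$cost_pfs)
  expect_equal(o3$cost_pd, 3 * o$cost_pd)
  expect_equal(o3$qaly_total, o$qaly_total)
  # zero utilities give zero QALYs, zeroed cost table gives zero costs
  v0 <- v
  v0[c("utility_pfs", "utility_pd")] <- 0
  expect_equal(evaluate_arm(cfg, "XELOX", v0)$qaly_total, 0)
  v0 <- v
  v0[grepl("^cost_", names(v0))] <- 0
  expect_equal(evaluate_arm(cfg, "XELOX", v0)$cost_total, 0)
})

test_that("positive discounting strictly shrinks totals", {
  v <- param_values(cfg)
  v[["discount_rate"]] <- 0
  o0 <- evaluate_arm(cfg, "X", v)
  o3 <- evaluate_arm(cfg, "X")  # 3% base case
  expect_lt(o3$cost_total, o0$cost_total)
  expect_lt(o3$qaly_total, o0$qaly_total)
})

test_that("undiscounted PFS person-time approaches the analytic mean", {
  # with half-cycle (trapezoid) accrual, no discounting and no curve
  # crossing, discounted person-cycles in PFS converge to the closed-form
  # log-logistic mean within half a cycle
  cfg2 <- cfg
  cfg2$conventions$trace_method <- "partitioned"
  cfg2$conventions$accrual_timing <- "half"
  v <- param_values(cfg2)
  v[["discount_rate"]] <- 0
  o <- evaluate_arm(cfg2, "X", v)
  pc_pfs <- o$qaly_pfs / (0.797 * 21 / 365)
  expect_equal(pc_pfs, llogis_mean(x_pfs), tolerance = 0.5 / llogis_mean(x_pfs))
})

test_that("one-off second-line rule charges entrants once, at entry", {
  cfg2 <- cfg
  cfg2$conventions$second_line_application <- "one_off"
  o <- evaluate_arm(cfg2, "X")
  # manual recomputation from the trace
  tr <- build_markov_trace(x_pfs, x_os, 260)
  H <- 260
  d <- (1.03)^(-(0:(H - 1)) * 21 / 365)
  inflow <- pmax(tr$pfs[1:H] - tr$pfs[2:(H + 1)], 0)
  inp <- arm_inputs(cfg2, "X")
  manual <- sum(tr$pd[1:H] * d) * state_cost_per_cycle(inp, "pd") +
    sum(inflow * d) * 0.38 * 5300.4
  expect_equal(o$cost_pd, manual, tolerance = 1e-9)
})

test_that("arm comparison computes increments, ICER and dominance", {
  mk <- function(cost, qaly, arm = "A") {
    structure(list(arm = arm, cost_pfs = cost, cost_pd = 0, cost_total = cost,
                   qaly_pfs = qaly, qaly_pd = 0, qaly_total = qaly),
              class = "econ_outcome")
  }
  cmp <- compare_arms(mk(100, 1), mk(200, 3, "B"))
  expect_equal(cmp$delta_cost, 100)
  expect_equal(cmp$delta_qaly, 2)
  expect_equal(cmp$icer, 50)
  expect_equal(cmp$dominance, "none")
  # cheaper and more effective alternative dominates; no finite ICER
  dom <- compare_arms(mk(100, 1), mk(90, 1.5, "B"))
  expect_equal(dom$dominance, "alt_dominant")
  expect_true(is.na(dom$icer))
  # zero QALY increment with a cost difference: ICER undefined and flagged
  und <- compare_arms(mk(100, 1), mk(150, 1, "B"))
  expect_true(is.na(und$icer))
  expect_equal(und$icer_flag, "undefined_zero_qaly_increment")
})
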