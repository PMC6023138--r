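cfg <- default_config()

test_that("one-way analysis pins a parameter and recomputes the ICER", {
  e <- one_way(cfg, "utility_pd")
  expect_s3_class(e, "tornado_entry")
  expect_equal(e$bar_width, abs(e$icer_high - e$icer_low))
  # base-case ICER lies inside the bar for this monotone-influence parameter
  expect_true(min(e$icer_low, e$icer_high) <= e$icer &&
                e$icer <= max(e$icer_low, e$icer_high))
  expect_error(one_way(cfg, "not_a_param"), "unknown parameter")
})

test_that("a parameter without model influence produces a flat bar", {
  # an adverse-event episode cost whose risks are zero in both arms
  cfg0 <- set_param(cfg, "risk_ae_diarrhea_x", 0)
  cfg0 <- set_param(cfg0, "risk_ae_diarrhea_xelox", 0)
  base <- run_base_case(cfg0)$comparison$icer
  e <- one_way(cfg0, "cost_ae_diarrhea")
  expect_equal(e$icer_low, base)
  expect_equal(e$icer_high, base)
  expect_equal(e$bar_width, 0)
})

test_that("tornado covers all 29 parameters, sorted by influence", {
  tor <- tornado(cfg)
  expect_equal(nrow(tor), 29L)
  expect_true("discount_rate" %in% tor$param_id)
  expect_true(all(diff(tor$bar_width) <= 0))
  # the XELOX second-line risk is the single most influential parameter
  expect_equal(tor$param_id[1], "risk_second_line_xelox")
  # single-parameter call yields a single entry
  expect_equal(nrow(tornado(cfg, "utility_pfs")), 1L)
  # all-degenerate ranges: every bar collapses to zero width
  tor0 <- tornado(degenerate_config())
  expect_true(all(tor0$bar_width == 0))
})

test_that("PSA stores one draw per iteration and is seed-reproducible", {
  p1 <- run_psa(cfg, n_iter = 40, seed = 77)
  expect_equal(nrow(p1$draws), 40L)
  p2 <- run_psa(cfg, n_iter = 40, seed = 77)
  expect_identical(p1$draws, p2$draws)
  p3 <- run_psa(cfg, n_iter = 40, seed = 78)
  expect_false(identical(p1$draws, p3$draws))
})

test_that("a degenerate PSA reproduces the base case in every draw", {
  dcfg <- degenerate_config()
  psa <- run_psa(dcfg, n_iter = 5, seed = 1)
  bc <- run_base_case(dcfg)
  expect_equal(psa$draws$delta_cost, rep(bc$comparison$delta_cost, 5))
  expect_equal(psa$draws$delta_qaly, rep(bc$comparison$delta_qaly, 5))
})

test_that("cost-effectiveness probability uses net monetary benefit", {
  psa <- run_psa(cfg, n_iter = 60, seed = 5)
  # at WTP 0 the NMB reduces to -cost: probability X is strictly cheaper
  expect_equal(prob_cost_effective(psa, 0),
               mean(psa$draws$cost_ref < psa$draws$cost_alt))
  p <- prob_cost_effective(psa, 26598)
  expect_gte(p, 0)
  expect_lte(p, 1)
})

test_that("CEAC probabilities are complementary at every grid point", {
  psa <- run_psa(cfg, n_iter = 60, seed = 6)
  cc <- ceac(psa, wtp_grid = seq(0, 2e5, by = 2e4))
  expect_equal(cc$prob_ref + cc$prob_alt, rep(1, nrow(cc)))
  # the reference arm's curve is non-increasing in WTP here (the alternative
  # gains more QALYs in essentially all draws)
  expect_true(all(diff(cc$prob_ref) <= 0))
  expect_equal(nrow(ceac(psa, wtp_grid = 26598)), 1L)
  expect_error(ceac(psa, numeric()), "empty")
})

test_that("sensitivity exports use the documented CSV dialects", {
  tmp <- withr::local_tempdir()
  psa <- run_psa(cfg, n_iter = 10, seed = 2)
  f1 <- file.path(tmp, "psa.csv")
  write_psa(psa, f1)
  expect_equal(readLines(f1, n = 1), "\"iter\",\"delta_cost\",\"delta_qaly\"")
  cc <- ceac(psa, wtp_grid = c(0, 26598))
  f2 <- file.path(tmp, "ceac.csv")
  write_ceac(cc, f2, "X", "XELOX")
  expect_equal(readLines(f2, n = 1), "\"wtp\",\"prob_x\",\"prob_xelox\"")
  tor <- tornado(cfg, c("utility_pfs", "utility_pd"))
  f3 <- file.path(tmp, "tornado.csv")
  write_tornado(tor, f3)
  expect_equal(readLines(f3, n = 1),
               "\"param_id\",\"icer_low\",\"icer_high\",\"bar_width\"")
})

test_that("figures build without error", {
  psa <- run_psa(cfg, n_iter = 10, seed = 3)
  expect_s3_class(plot_ce_plane(psa), "ggplot")
  expect_s3_class(plot_ceac(ceac(psa, c(0, 5e4, 1e5))), "ggplot")
  tor <- tornado(cfg, c("utility_pfs", "risk_second_line_xelox"))
  expect_s3_class(plot_tornado(tor), "ggplot")
})
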