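# Cost/QALY accrual and incremental comparison.

test_that("drug cost per administration resolves each dose rule", {
  pt <- patient(body_surface_area = 1.82, body_weight = 74)
  tdxd <- regimen_component("tdxd", 5.4, "per_kg", 1, 21, 29.68)
  expect_equal(drug_cost_per_admin(tdxd, pt), 5.4 * 74 * 29.68)  # 11860.13
  m2 <- regimen_component("x", 100, "per_m2", 1, 21, 1)
  expect_equal(drug_cost_per_admin(m2, pt), 182)
  flat0 <- regimen_component("y", 0, "flat", 1, 21, 10)
  expect_equal(drug_cost_per_admin(flat0, pt), 0)
})

test_that("adverse-event burden aggregates by frequency weighting", {
  expect_equal(aggregate_ae_burden(data.frame(frequency = numeric(0),
                                              cost = numeric(0),
                                              disutility = numeric(0))),
               c(cost = 0, disutility = 0))
  ev <- data.frame(frequency = c(0.5, 0.25), cost = c(1000, 2000),
                   disutility = c(0.02, 0.04))
  expect_equal(aggregate_ae_burden(ev), c(cost = 1000, disutility = 0.02))
  # a synthetic itemization calibrated to the published per-arm aggregate
  items <- data.frame(frequency = c(0.139, 0.051, 0.05, 0.30),
                      cost = c(20000, 15000, 12000, 1470),
                      disutility = c(0.129, 0.05, 0.04, 0.015))
  agg <- aggregate_ae_burden(items)
  expect_equal(unname(agg["cost"]), 4586, tolerance = 1e-9)
  expect_lt(abs(agg[["disutility"]] - 0.027), 1e-4)
  expect_error(aggregate_ae_burden(data.frame(frequency = 1.5, cost = 1,
                                              disutility = 0)), "frequencies")
})

test_that("zero costs and unit utilities give QALY = horizon and zero cost", {
  alive <- surv_model("exponential", c(rate = 1e-12))
  tr <- build_trace(alive, alive, time_grid(discount_rate = 0))
  econ <- zero_cost_econ(utility_pf = 1, utility_pd = 1)
  res <- accrue_strategy(tr, free_regimen(), econ)
  expect_equal(res$qaly, 10, tolerance = 1e-9)
  expect_equal(res$cost_total, 0)
  expect_equal(res$ly_total, 10, tolerance = 1e-9)
})

test_that("terminal-care accrual conserves the one-time cost at r = 0", {
  # everyone dead well before the horizon
  os <- surv_model("exponential", c(rate = 0.05))
  tr <- build_trace(os, os, time_grid(discount_rate = 0))
  econ <- zero_cost_econ(terminal_care_cost = 20409)
  res <- accrue_strategy(tr, free_regimen(), econ)
  dead_end <- tr$dead[nrow(tr)]
  expect_equal(res$cost_terminal, 20409 * dead_end, tolerance = 1e-9)
  expect_equal(res$cost_terminal, 20409, tolerance = 1e-3)  # >99.99% dead
})

test_that("QALYs equal life-years when utilities are 1 and disutilities 0", {
  cfg <- scenario_config("all")
  cfg$grid$discount_rate <- 0
  cfg <- set_config_param(cfg, "utility_pf", 1)
  cfg <- set_config_param(cfg, "utility_pd", 1)
  cfg <- set_config_param(cfg, "ae_disutility_tdxd", 0)
  cfg <- set_config_param(cfg, "ae_disutility_chemo", 0)
  pipe <- psmcea:::run_pipeline(cfg)
  for (s in pipe$strategies) expect_equal(s$qaly, s$ly_total, tolerance = 1e-9)
})

test_that("cost components sum to the total and scale linearly in unit costs", {
  cfg <- scenario_config("all")
  pipe <- psmcea:::run_pipeline(cfg)
  comp_names <- c("cost_drug", "cost_admin", "cost_monitoring", "cost_bsc",
                  "cost_ae", "cost_terminal")
  for (s in pipe$strategies) {
    expect_equal(sum(unlist(s[comp_names])), s$cost_total, tolerance = 1e-6)
    expect_lte(s$ly_pf, s$ly_total)
  }
  # double every unit cost -> exactly double total cost, QALYs unchanged
  cfg2 <- cfg
  for (nm in c("price_trastuzumab_deruxtecan", "price_capecitabine",
               "price_eribulin", "price_gemcitabine", "price_paclitaxel",
               "price_nab_paclitaxel", "terminal_care_cost", "ct_scan_cost",
               "bsc_cost_per_cycle", "ae_cost_tdxd", "ae_cost_chemo",
               "admin_first_hour", "admin_addl_hour", "follow_up_cost")) {
    sp <- Filter(function(s) s$name == nm, cfg$param_specs)[[1]]
    cfg2 <- set_config_param(cfg2, nm, 2 * sp$base)
  }
  pipe2 <- psmcea:::run_pipeline(cfg2)
  for (arm in c("tdxd", "chemo")) {
    expect_equal(pipe2$strategies[[arm]]$cost_total,
                 2 * pipe$strategies[[arm]]$cost_total, tolerance = 1e-9)
    expect_equal(pipe2$strategies[[arm]]$qaly, pipe$strategies[[arm]]$qaly)
  }
})

test_that("net-benefit identities hold for arbitrary comparisons", {
  set.seed(4)
  for (i in 1:25) {
    a <- structure(list(qaly = runif(1, 0.5, 3), ly_total = runif(1, 1, 4),
                        cost_total = runif(1, 1e4, 3e5)),
                   class = "strategy_result")
    b <- structure(list(qaly = runif(1, 0.5, 3), ly_total = runif(1, 1, 4),
                        cost_total = runif(1, 1e4, 3e5)),
                   class = "strategy_result")
    l <- runif(1, 2e4, 2e5)
    cc <- compare_strategies(a, b, l)
    expect_equal(cc$inhb * l, cc$inmb, tolerance = 1e-9)
    if (cc$delta_effect != 0) {
      expect_equal(cc$icer_per_qaly, cc$delta_cost / cc$delta_effect)
    }
  }
})

test_that("identical strategies compare to zero increments with flagged ICER", {
  a <- structure(list(qaly = 1.5, ly_total = 2, cost_total = 1e5),
                 class = "strategy_result")
  cc <- compare_strategies(a, a, 1e5)
  expect_equal(cc$delta_cost, 0)
  expect_equal(cc$delta_effect, 0)
  expect_equal(cc$inmb, 0)
  expect_true(is.na(cc$icer_per_qaly))
  expect_equal(cc$dominance, "equal_effect")
})

test_that("regimen and econ validation reject bad inputs", {
  expect_error(regimen("bad", list(
    regimen_component("a", 1, "flat", 1, 21, 1, share = 0.5))), "sum to 1")
  expect_error(econ_inputs(utility_pf = 0.4, utility_pd = 0.5), ">=")
  expect_error(econ_inputs(utility_pf = 1.2), "\\[0, 1\\]")
  expect_error(regimen_component("a", 1, "oral", 1, 21, 1), "arg")
})
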