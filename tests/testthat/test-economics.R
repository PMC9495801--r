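base_summary <- function() annualize(run_flowsheet(plant_config()))

test_that("raw-material cost matches the published line and is affine in prices", {
  summ <- base_summary()
  cost <- raw_material_cost(summ)
  expect_equal(cost / 1e6, 1.79, tolerance = 0.005)
  # all prices zero
  zero <- econ_config(sludge_price = 0, enzyme_price = 0,
                      caoh2_price_t = 0, h2so4_price_t = 0)
  expect_equal(raw_material_cost(summ, zero), 0)
  # affine in each price with slope = annual consumption (finite-difference
  # oracle)
  d <- 0.1
  slope_sludge <- (raw_material_cost(summ, econ_config(sludge_price = 0.5 + d)) -
                     cost) / d
  expect_equal(slope_sludge, summ$sludge_t * 1000, tolerance = 1e-6)
  slope_enz <- (raw_material_cost(summ, econ_config(enzyme_price = 20 + d)) -
                  cost) / d
  expect_equal(slope_enz, summ$enzyme_prep_t * 1000, tolerance = 1e-6)
})

test_that("operating-cost breakdown has raw materials above 40 percent", {
  summ <- base_summary()
  ox <- opex_breakdown(summ)
  expect_equal(ox$total, sum(ox$items), tolerance = 1e-9)
  expect_equal(sum(ox$percent), 100, tolerance = 0.05)
  expect_gt(ox$percent[["raw_materials"]], 40)
  # each computed line lands near its published counterpart
  ref <- ref_opex_breakdown()
  expect_equal(ox$items[["raw_materials"]], ref[["raw_materials"]],
               tolerance = 0.01 * ref[["raw_materials"]])
  expect_equal(ox$items[["utilities"]], ref[["utilities"]],
               tolerance = 0.05 * ref[["utilities"]])
  expect_equal(ox$items[["labor"]], ref[["labor"]],
               tolerance = 0.05 * ref[["labor"]])
  expect_equal(ox$items[["depreciation"]], ref[["depreciation"]])
})

test_that("published operating-cost lines sum to 4.23 against a rounded 4.22 total", {
  # decimal summation oracle on the printed breakdown
  expect_equal(sum(ref_opex_breakdown()) / 1e6,
               1.79 + 0.30 + 0.58 + 0.06 + 0.15 + 0.32 + 0.26 + 0.77)
  expect_equal(round(sum(ref_opex_breakdown()) / 1e6, 2), 4.23)
})

test_that("degenerate factor set reduces the operating cost to depreciation", {
  summ <- base_summary()
  cfg <- econ_config(sludge_price = 0, enzyme_price = 0,
                     caoh2_price_t = 0, h2so4_price_t = 0,
                     electricity_price = 0, water_price = 0,
                     other_utilities_eur = 0, operator_hours = 0,
                     supervisor_hours = 0, maintenance_frac_capex = 0,
                     operating_frac_labor = 0,
                     contingency_frac_direct = 0,
                     admin_frac_labor_maint = 0)
  ox <- opex_breakdown(summ, config = cfg)
  expect_equal(ox$total, cfg$depreciation_eur)
})

test_that("NPV and IRR satisfy their closed-form identities", {
  # one year, invest 100, receive 110: NPV at 0 is 10 and IRR is 10%
  expect_equal(npv(0, 110, 100), 10)
  expect_equal(irr(110, 100), 0.10, tolerance = 1e-8)
  # constant flows: annuity closed form vs explicit summation
  set.seed(3)
  for (i in 1:20) {
    r <- stats::runif(1, 0.01, 0.3)
    n <- sample(2:25, 1)
    f <- stats::runif(1, 10, 1000)
    C <- stats::runif(1, 10, 1000)
    expect_equal(npv(r, rep(f, n), C),
                 -C + f * (1 - (1 + r)^(-n)) / r, tolerance = 1e-9)
  }
})

test_that("cash-flow indicators are internally consistent for the base case", {
  tea <- evaluate_tea()
  cf <- tea$cashflow
  # NPV evaluated at the IRR vanishes
  expect_lt(abs(npv(cf$irr, cf$flows, capex_total()$total)), 1)
  expect_equal(cf$pi, cf$npv / capex_total()$total, tolerance = 1e-12)
  expect_equal(sign(cf$pi), sign(cf$npv))
  expect_gt(cf$npv, 0)
  # discounted payback is no shorter than simple payback at r > 0
  simple <- capex_total()$total / cf$flows[1]
  expect_gte(cf$payback, simple)
})

test_that("NPV moves the right way with each price", {
  d <- 0.01
  base <- evaluate_tea()$cashflow$npv
  up_sale <- evaluate_tea(econ = econ_config(sale_price = 3.5 + d))
  up_sludge <- evaluate_tea(econ = econ_config(sludge_price = 0.5 + d))
  up_enz <- evaluate_tea(econ = econ_config(enzyme_price = 20 + d))
  expect_gt(up_sale$cashflow$npv, base)
  expect_lt(up_sludge$cashflow$npv, base)
  expect_lt(up_enz$cashflow$npv, base)
  # slope in the sale price = discounted annual product tonnage after tax
  summ <- annualize(run_flowsheet(plant_config()))
  r <- 0.05; n <- 10
  annuity <- (1 - (1 + r)^(-n)) / r
  expect_equal((up_sale$cashflow$npv - base) / d,
               summ$biofertilizer_t * 1000 * (1 - 0.25) * annuity,
               tolerance = 1e-6 * abs(base))
})

test_that("IRR is invariant to currency rescaling", {
  tea <- evaluate_tea()
  r1 <- irr(tea$cashflow$flows, capex_total()$total)
  r2 <- irr(tea$cashflow$flows * 1e3, capex_total()$total * 1e3)
  expect_equal(r1, r2, tolerance = 1e-9)
})

test_that("IRR is absent when the cash flows never repay the investment", {
  expect_true(is.na(irr(rep(-5, 10), 100)))
  cf <- cash_flows(0, opex_breakdown(base_summary()),
                   capex_total()$total)
  expect_lt(cf$npv, 0)
  expect_true(is.na(cf$payback))
})

test_that("by-product sales would add about 29,000 EUR per year", {
  summ <- base_summary()
  expect_equal(byproduct_revenue(summ), 29000, tolerance = 100)
  expect_equal(byproduct_revenue(summ, 0), 0)
  # linear in tonnage
  expect_equal(byproduct_revenue(summ, 120), 2 * byproduct_revenue(summ))
  # excluded from the base cash flow unless toggled
  with_bp <- evaluate_tea(econ = econ_config(include_byproduct_revenue = TRUE))
  without <- evaluate_tea()
  expect_equal(with_bp$revenue - without$revenue,
               byproduct_revenue(summ), tolerance = 1e-6)
})

test_that("profitability index from the published NPV/investment pair is 0.95", {
  expect_equal(round(profitability_index(9.17e6, 9648523.33), 2), 0.95)
})
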