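contrast_coef <- function(x, y) {
  # orthogonal-contrast oracle for Box-Behnken linear terms
  (sum(y[x == 1]) - sum(y[x == -1])) / 8
}

test_that("the design lays out the 13 published scenarios in order", {
  d <- bb_design()
  expect_equal(nrow(d), 13)
  expect_equal(unlist(d[1, c("A", "B", "C")]),
               c(A = 1.0, B = 17.5, C = 2.5))
  # the center run appears exactly once, as row 5
  center <- d$xA == 0 & d$xB == 0 & d$xC == 0
  expect_equal(which(center), 5L)
  # every edge run has exactly one factor at mid level
  expect_true(all(rowSums(d[!center, c("xA", "xB", "xC")] == 0) == 1))
  expect_error(bb_design(levels = list(A = c(1, 0.6, 0.2),
                                       B = c(10, 17.5, 25),
                                       C = c(2.5, 5, 7.5))), "increasing")
})

test_that("coded columns are centred and mutually orthogonal", {
  d <- bb_design()
  X <- as.matrix(d[, c("xA", "xB", "xC")])
  expect_equal(colSums(X), c(xA = 0, xB = 0, xC = 0))
  expect_equal(sum(X[, 1] * X[, 2]), 0)
  expect_equal(sum(X[, 1] * X[, 3]), 0)
  expect_equal(sum(X[, 2] * X[, 3]), 0)
})

test_that("scenario engine reproduces the published profitability pattern", {
  res <- run_scenarios()
  expect_equal(nrow(res), 13)
  # negative NPV with absent payback and IRR exactly for scenarios 1, 9, 11
  neg <- res$scenario[res$npv_meur < 0]
  expect_equal(sort(neg), c(1, 9, 11))
  expect_true(all(is.na(res$irr_pct[res$scenario %in% neg])))
  expect_true(all(is.na(res$pp_years[res$scenario %in% neg])))
  expect_true(all(!is.na(res$irr_pct[!res$scenario %in% neg])))
  # NPV increases with the sale price at fixed costs (published ordering
  # of runs 3 vs 11, 12 vs 7, 10 vs 1, 13 vs 9)
  pairs <- list(c(3, 11), c(12, 7), c(10, 1), c(13, 9))
  for (p in pairs) {
    expect_gt(res$npv_meur[res$scenario == p[1]],
              res$npv_meur[res$scenario == p[2]])
  }
  # PI sign equals NPV sign everywhere
  expect_equal(sign(res$pi), sign(res$npv_meur))
})

test_that("identical prices in every run give identical indicators", {
  d <- bb_design()
  d$A[] <- 0.6; d$B[] <- 17.5; d$C[] <- 5.0
  d$xA[] <- 0; d$xB[] <- 0; d$xC[] <- 0
  res <- run_scenarios(d)
  expect_equal(length(unique(round(res$npv_meur, 9))), 1)
  expect_equal(length(unique(round(res$pi, 9))), 1)
})

test_that("quadratic fit to the published NPV column matches the contrast oracle", {
  d <- bb_design()
  y <- ref_scenario_indicators()$npv_meur
  fit <- fit_quadratic(d, y)
  expect_equal(fit$coded[["a1"]], contrast_coef(d$xA, y),
               tolerance = 1e-10)
  expect_equal(fit$coded[["a2"]], contrast_coef(d$xB, y),
               tolerance = 1e-10)
  expect_equal(fit$coded[["a3"]], contrast_coef(d$xC, y),
               tolerance = 1e-10)
  # sale price dominates: almost 5x the sludge and ~14x the enzyme effect
  expect_gt(abs(fit$coded[["a3"]]), abs(fit$coded[["a1"]]))
  expect_gt(abs(fit$coded[["a1"]]), abs(fit$coded[["a2"]]))
  expect_gt(abs(fit$coded[["a3"]] / fit$coded[["a1"]]), 4)
  expect_lt(abs(fit$coded[["a3"]] / fit$coded[["a1"]]), 5.5)
  expect_gt(abs(fit$coded[["a3"]] / fit$coded[["a2"]]), 13)
  expect_lt(abs(fit$coded[["a3"]] / fit$coded[["a2"]]), 15)
  expect_gte(fit$r_squared, 0.99)
  expect_equal(fit$df_residual, 3)
})

test_that("contrast and least-squares linear coefficients agree on any response", {
  set.seed(17)
  d <- bb_design()
  for (i in 1:10) {
    y <- stats::rnorm(13, sd = 10)
    fit <- fit_quadratic(d, y)
    expect_equal(fit$coded[["a1"]], contrast_coef(d$xA, y),
                 tolerance = 1e-8)
    expect_equal(fit$coded[["a2"]], contrast_coef(d$xB, y),
                 tolerance = 1e-8)
    expect_equal(fit$coded[["a3"]], contrast_coef(d$xC, y),
                 tolerance = 1e-8)
  }
})

test_that("exactly quadratic responses are recovered to 1e-8", {
  set.seed(23)
  d <- bb_design()
  for (i in 1:10) {
    a <- stats::rnorm(10, sd = 5)
    y <- a[1] + a[2] * d$xA + a[3] * d$xB + a[4] * d$xC +
      a[5] * d$xA * d$xB + a[6] * d$xA * d$xC + a[7] * d$xB * d$xC +
      a[8] * d$xA^2 + a[9] * d$xB^2 + a[10] * d$xC^2
    fit <- fit_quadratic(d, y)
    expect_equal(unname(fit$coded), a, tolerance = 1e-8)
  }
  # constant response: intercept only
  flat <- fit_quadratic(d, rep(7.5, 13))
  expect_equal(flat$coded[["a0"]], 7.5, tolerance = 1e-9)
  expect_equal(unname(flat$coded[-1]), rep(0, 9), tolerance = 1e-9)
})

test_that("runs with missing responses are dropped and counted", {
  d <- bb_design()
  y <- ref_scenario_indicators()$irr_pct  # NA for scenarios 1, 9, 11
  fit <- fit_quadratic(d, y)
  expect_equal(fit$n_used, 10)
  expect_equal(fit$n_dropped, 3)
  expect_error(fit_quadratic(d, c(y[1:12], NA)), "at least 10")
})

test_that("coded and real parameterizations predict identically", {
  fit <- fit_quadratic(bb_design(), ref_scenario_indicators()$npv_meur)
  pts <- bb_design()[, c("A", "B", "C")]
  expect_equal(predict(fit, pts, units = "real"),
               predict(fit, pts, units = "coded"), tolerance = 1e-8)
  # prediction at the center point is the coded intercept
  center <- data.frame(A = 0.6, B = 17.5, C = 5.0)
  expect_equal(predict(fit, center), fit$coded[["a0"]],
               tolerance = 1e-8)
})

test_that("surface grid brackets the break-even sale price", {
  fit <- fit_quadratic(bb_design(), ref_scenario_indicators()$npv_meur)
  grid <- surface_grid(fit, fixed = c(B = 17.5), n = 41)
  # NPV crosses zero between sale prices of 2.5 and 5.0 at center sludge cost
  slice <- grid[abs(grid$A - 0.6) < 1e-9, ]
  slice <- slice[order(slice$C), ]
  signs <- sign(slice$prediction)
  crossing <- slice$C[which(diff(signs) > 0)]
  expect_true(length(crossing) == 1 && crossing > 2.5 && crossing < 5.0)
  expect_false(any(grid$extrapolated))
  # holding a factor outside its range flags extrapolation
  expect_warning(surface_grid(fit, fixed = c(B = 30)), "extrapolate")
})
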