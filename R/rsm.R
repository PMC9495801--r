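#' Box-Behnken design over the three price factors
#'
#' The 13-run, three-level Box-Behnken design used for the price
#' sensitivity analysis: factor A is the sludge cost, B the enzyme cost and
#' C the biofertilizer sale price (all EUR/kg).  The twelve edge runs place
#' two factors at their extremes with the third at its mid level, plus one
#' center run; run order matches the published scenario table so results
#' can be compared row for row.
#'
#' Coding is the standard one: `x = (value - center) / half-range`, which
#' makes the coded columns mutually orthogonal with zero sums, so the
#' linear coefficients of a quadratic fit equal simple orthogonal
#' contrasts.
#'
#' @param levels Named list of three sorted numeric level triplets `A`,
#'   `B`, `C` (low / mid / high); defaults 0.2/0.6/1.0, 10/17.5/25 and
#'   2.5/5.0/7.5 EUR/kg.
#' @return An object of class `bb_design`: a data.frame with columns
#'   `scenario`, real-unit `A`, `B`, `C` and coded `xA`, `xB`, `xC`;
#'   attribute `levels` stores the factor levels.
#' @export
#' @examples
#' bb_design()[1, ]  # scenario 1: A = 1.0, B = 17.5, C = 2.5
bb_design <- function(levels = list(A = c(0.2, 0.6, 1.0),
                                    B = c(10, 17.5, 25),
                                    C = c(2.5, 5.0, 7.5))) {
  if (!setequal(names(levels), c("A", "B", "C")))
    stop("'levels' must name exactly A, B and C")
  for (f in c("A", "B", "C")) {
    if (length(levels[[f]]) != 3 || any(diff(levels[[f]]) <= 0))
      stop("factor ", f, " needs three strictly increasing levels")
  }
  coded <- matrix(c(
    +1,  0, -1,
    +1, +1,  0,
     0, -1, +1,
    -1, +1,  0,
     0,  0,  0,
    -1, -1,  0,
    -1,  0, -1,
    +1, -1,  0,
     0, +1, -1,
    +1,  0, +1,
     0, -1, -1,
    -1,  0, +1,
     0, +1, +1), ncol = 3, byrow = TRUE,
    dimnames = list(NULL, c("xA", "xB", "xC")))
  real <- vapply(c(A = "A", B = "B", C = "C"), function(f) {
    lv <- levels[[f]]
    center <- lv[2]
    half <- (lv[3] - lv[1]) / 2
    center + coded[, paste0("x", f)] * half
  }, numeric(nrow(coded)))
  df <- data.frame(scenario = seq_len(nrow(coded)), real, coded)
  attr(df, "levels") <- levels
  class(df) <- c("bb_design", "data.frame")
  df
}

#' Code real factor values onto the design scale
#'
#' @param design A [bb_design()].
#' @param values Data.frame or named list with columns/elements `A`, `B`,
#'   `C` in real units.
#' @return Data.frame of coded `xA`, `xB`, `xC`.
#' @export
code_factors <- function(design, values) {
  levels <- attr(design, "levels")
  out <- lapply(c(A = "A", B = "B", C = "C"), function(f) {
    lv <- levels[[f]]
    (values[[f]] - lv[2]) / ((lv[3] - lv[1]) / 2)
  })
  stats::setNames(as.data.frame(out), c("xA", "xB", "xC"))
}

#' Published profitability indicators of the 13 scenarios
#'
#' The NPV (million EUR), payback period (years), IRR (percent) and
#' profitability index reported for the 13 design scenarios of the
#' reference study.  Scenarios 1, 9 and 11 have negative NPV, so their
#' payback and IRR are undefined (`NA`).
#'
#' @return A data.frame with columns `scenario`, `npv_meur`, `pp_years`,
#'   `irr_pct`, `pi`.
#' @export
ref_scenario_indicators <- function() {
  data.frame(
    scenario = 1:13,
    npv_meur = c(-9.82, 17.19, 54.97, 28.94, 25.09, 32.99, 3.11, 21.24,
                 -4.99, 47.07, -0.74, 58.82, 50.92),
    pp_years = c(NA, 5.02, 2.58, 3.65, 4.01, 3.35, 8.92, 4.44, NA, 2.88,
                 NA, 2.46, 2.72),
    irr_pct = c(NA, 27.46, 71.01, 42.70, 37.62, 48.18, 9.96, 32.64, NA,
                60.29, NA, 76.53, 65.42),
    pi = c(-1.02, 1.78, 5.70, 3.00, 2.60, 3.42, 0.32, 2.20, -0.52, 4.88,
           -0.08, 6.10, 5.28)
  )
}

#' Evaluate the TEA over every design scenario
#'
#' Runs one techno-economic evaluation per design row, varying only the
#' three prices (scenario prices do not alter the mass balance, so the
#' flowsheet is solved once).  IRR and payback are reported as absent
#' (`NA`) when the NPV is negative: a project that never recovers its
#' investment has no payback, and a below-zero return is not a meaningful
#' rate.
#'
#' @param design A [bb_design()].
#' @param plant A [plant_config()].
#' @param econ An [econ_config()] supplying everything except the three
#'   scenario prices.
#' @param capex Total investment, EUR.
#' @return A data.frame with `scenario`, `A`, `B`, `C`, `npv_meur`,
#'   `pp_years`, `irr_pct`, `pi`.
#' @export
#' @examples
#' \donttest{
#' run_scenarios(bb_design())
#' }
run_scenarios <- function(design = bb_design(), plant = plant_config(),
                          econ = econ_config(),
                          capex = capex_total()$total) {
  stopifnot(inherits(design, "bb_design"))
  fs <- run_flowsheet(plant)
  summ <- annualize(fs)
  rows <- lapply(seq_len(nrow(design)), function(i) {
    ec <- econ
    ec$sludge_price <- design$A[i]
    ec$enzyme_price <- design$B[i]
    ec$sale_price <- design$C[i]
    ox <- opex_breakdown(summ, capex, ec)
    revenue <- summ$biofertilizer_t * 1000 * ec$sale_price
    if (isTRUE(ec$include_byproduct_revenue))
      revenue <- revenue + byproduct_revenue(summ, ec$byproduct_price_t)
    cf <- cash_flows(revenue, ox, capex, ec)
    negative <- cf$npv < 0
    data.frame(scenario = design$scenario[i],
               A = design$A[i], B = design$B[i], C = design$C[i],
               npv_meur = cf$npv / 1e6,
               pp_years = if (negative) NA_real_ else cf$payback,
               irr_pct = if (negative || is.na(cf$irr)) NA_real_
                         else 100 * cf$irr,
               pi = cf$pi)
  })
  do.call(rbind, rows)
}

#' Fit the full quadratic response-surface model
#'
#' Ordinary least squares of
#' `Y = a0 + a1 A + a2 B + a3 C + a4 AB + a5 AC + a6 BC +
#'  a7 A^2 + a8 B^2 + a9 C^2`
#' in coded units, with the real-unit parameterization fitted alongside.
#' Rows with missing responses (scenarios whose indicator is undefined) are
#' dropped and counted.  On a Box-Behnken design the coded linear
#' coefficients equal the orthogonal contrasts
#' `(sum of Y at +1 - sum of Y at -1) / 8`.
#'
#' @param design A [bb_design()].
#' @param y Numeric response vector, one value per design row (`NA`
#'   allowed).
#' @return An object of class `rsm_fit` with `coded` and `real` coefficient
#'   vectors (a0..a9), `r_squared`, `df_residual`, `n_used`, `n_dropped`
#'   and the underlying `lm` fits.
#' @export
#' @examples
#' fit <- fit_quadratic(bb_design(), ref_scenario_indicators()$npv_meur)
#' fit$coded[c("a1", "a2", "a3")]
fit_quadratic <- function(design, y) {
  stopifnot(inherits(design, "bb_design"))
  if (length(y) != nrow(design))
    stop("'y' must have one response per design row")
  keep <- !is.na(y)
  if (sum(keep) < 10)
    stop("at least 10 complete runs are needed to fit the 10-term model")
  build <- function(a, b, c_) {
    data.frame(A = a, B = b, C = c_,
               AB = a * b, AC = a * c_, BC = b * c_,
               A2 = a^2, B2 = b^2, C2 = c_^2)
  }
  dat_c <- cbind(y = y[keep],
                 build(design$xA[keep], design$xB[keep], design$xC[keep]))
  dat_r <- cbind(y = y[keep],
                 build(design$A[keep], design$B[keep], design$C[keep]))
  form <- y ~ A + B + C + AB + AC + BC + A2 + B2 + C2
  fit_c <- stats::lm(form, data = dat_c)
  fit_r <- stats::lm(form, data = dat_r)
  if (any(is.na(stats::coef(fit_c))))
    stop("design is rank deficient for the quadratic model")
  nm <- paste0("a", 0:9)
  tss <- sum((dat_c$y - mean(dat_c$y))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit_c)^2) / tss else 1
  structure(list(
    coded = stats::setNames(unname(stats::coef(fit_c)), nm),
    real = stats::setNames(unname(stats::coef(fit_r)), nm),
    r_squared = r2,
    df_residual = fit_c$df.residual,
    n_used = sum(keep),
    n_dropped = sum(!keep),
    lm_coded = fit_c,
    lm_real = fit_r,
    design = design), class = "rsm_fit")
}

#' @export
print.rsm_fit <- function(x, ...) {
  cat("<rsm_fit> quadratic response surface\n")
  cat("  coded coefficients:\n")
  print(round(x$coded, 4))
  cat(sprintf("  R-squared %.4f on %d runs (%d dropped), %d residual df\n",
              x$r_squared, x$n_used, x$n_dropped, x$df_residual))
  invisible(x)
}

#' Predict from a fitted response surface
#'
#' @param object An [fit_quadratic()] result.
#' @param newdata Data.frame with real-unit columns `A`, `B`, `C`.
#' @param units `"real"` (default) or `"coded"`: which parameterization to
#'   evaluate (they agree to rounding; both take real-unit `newdata`).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.rsm_fit <- function(object, newdata, units = c("real", "coded"),
                            ...) {
  units <- match.arg(units)
  if (units == "real") {
    a <- newdata$A; b <- newdata$B; c_ <- newdata$C
    fit <- object$lm_real
  } else {
    xc <- code_factors(object$design, newdata)
    a <- xc$xA; b <- xc$xB; c_ <- xc$xC
    fit <- object$lm_coded
  }
  nd <- data.frame(A = a, B = b, C = c_, AB = a * b, AC = a * c_,
                   BC = b * c_, A2 = a^2, B2 = b^2, C2 = c_^2)
  unname(stats::predict(fit, newdata = nd))
}

#' Gridded response-surface predictions
#'
#' Predictions over a rectangular grid of two factors with the third held
#' fixed, the layout behind the usual surface/contour panels (e.g. NPV
#' over sludge cost and sale price at enzyme cost 10 or 25 EUR/kg).
#' Cells outside the coded \[-1, +1\] cube are flagged as extrapolation.
#'
#' @param fit An [fit_quadratic()] result.
#' @param fixed Single named value of the factor to hold, real units,
#'   e.g. `c(B = 10)`.
#' @param n Grid points per free factor (default 21).
#' @return A data.frame with the two free-factor columns, the fixed factor,
#'   `prediction` and logical `extrapolated`.
#' @export
surface_grid <- function(fit, fixed, n = 21) {
  stopifnot(inherits(fit, "rsm_fit"))
  if (length(fixed) != 1 || is.null(names(fixed)) ||
      !names(fixed) %in% c("A", "B", "C"))
    stop("'fixed' must be a single named value among A, B, C")
  levels <- attr(fit$design, "levels")
  free <- setdiff(c("A", "B", "C"), names(fixed))
  grid <- expand.grid(
    seq(levels[[free[1]]][1], levels[[free[1]]][3], length.out = n),
    seq(levels[[free[2]]][1], levels[[free[2]]][3], length.out = n))
  names(grid) <- free
  grid[[names(fixed)]] <- unname(fixed)
  grid <- grid[, c("A", "B", "C")]
  coded <- code_factors(fit$design, grid)
  extrapolated <- apply(abs(coded) > 1 + 1e-9, 1, any)
  if (any(extrapolated))
    warning("some grid cells extrapolate beyond the coded design cube")
  cbind(grid, prediction = predict(fit, grid),
        extrapolated = extrapolated)
}
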