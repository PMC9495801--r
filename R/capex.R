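#' Reference equipment list with packaged costs
#'
#' The seventeen equipment items of the reference plant design with their
#' sizes and purchased costs.  The costs come from the commercial
#' cost-estimation database used in the original design study (vendor
#' budgets for the packaging machine and solar collectors) and are treated
#' as data: the correlations behind them are proprietary and are not
#' re-derived here.
#'
#' Note: the per-item cells sum to 1,085,950 EUR while the published
#' equipment total carried into the investment breakdown is 1,088,448.80
#' EUR (rounding inside the estimation tool).  Both are retained; see
#' [ref_capex_breakdown()].
#'
#' @return A data.frame with columns `name`, `description`, `units`,
#'   `size`, `size_unit`, `unit_cost`, `total_cost` (EUR).
#' @export
ref_equipment_costs <- function() {
  df <- data.frame(
    name = c("BI-T1", "H1", "P-6", "R", "P-7", "P-4", "HE", "CaOH2",
             "H2SO4", "CENTRIF", "CO-T1", "CO-P1", "PACKAG", "CA-T1",
             "CA-P1", "CA-P2", "COLLECTO"),
    description = c(
      "Carbon steel storage tank",
      "SS316 high-pressure positive displacement pump",
      "SS304 centrifugal pump",
      "SS304 jacketed stirred tank reactor",
      "SS304 centrifugal pump",
      "Carbon steel centrifugal pump",
      "Carbon steel counterflow shell-and-tube heat exchanger",
      "Fiber-reinforced polymer storage tank",
      "Fiber-reinforced polymer storage tank",
      "Carbon steel high-speed disc centrifuge",
      "Carbon steel storage tank",
      "Carbon steel centrifugal pump",
      "Liquid packaging machine (containers up to 20 L)",
      "Carbon steel storage tank",
      "Carbon steel centrifugal pump",
      "Carbon steel centrifugal pump",
      "Flat solar thermal collector"),
    units = c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 5, 1, 1, 1, 1, 1, 7),
    size = c(8.06, 106, 1, 1.11, 1, 1, 0.47, 3.8, 3.8, 254, 39.6, 1, 120,
             11.4, 1, 1, 1.9),
    size_unit = c("m3", "kW", "kW", "m3", "kW", "kW", "m2", "m3", "m3",
                  "mm", "m3", "kW", "bpm", "m3", "kW", "kW", "m2"),
    unit_cost = c(24300, 229100, 5700, 78200, 5700, 4500, 8200, 43100,
                  43100, 219100, 60000, 4500, 80000, 26900, 4500, 4500,
                  650),
    stringsAsFactors = FALSE
  )
  df$total_cost <- df$units * df$unit_cost
  df
}

#' Reference investment (CAPEX) line items
#'
#' The factor-based investment breakdown of the reference design:
#' installed-equipment cost plus the bulk and indirect items, in EUR.
#'
#' @return Named numeric vector of line items.
#' @export
ref_capex_breakdown <- function() {
  c(equipment = 1088448.80,
    piping = 542566.50,
    civil = 405450.50,
    instrumentation = 1035617.10,
    electrical = 1301905.00,
    design_engineering_procurement = 3208042.43,
    administrative_taxes = 576675.40,
    contingencies = 1489817.60)
}

#' Total investment from CAPEX line items
#'
#' @param items Named numeric vector of investment line items, EUR (default
#'   the reference breakdown).
#' @return An object of class `capex_breakdown` with `items`, `total` and
#'   `percent` (shares summing to 100).
#' @export
#' @examples
#' capex_total()$total  # 9648523.33
capex_total <- function(items = ref_capex_breakdown()) {
  if (length(items) == 0) stop("'items' must be non-empty")
  if (is.null(names(items)) || any(!nzchar(names(items))))
    stop("'items' must be a named vector")
  if (any(items < 0)) stop("investment line items must be non-negative")
  total <- sum(items)
  structure(list(items = items,
                 total = total,
                 percent = 100 * items / total),
            class = "capex_breakdown")
}

#' @export
print.capex_breakdown <- function(x, ...) {
  cat("<capex_breakdown>\n")
  for (nm in names(x$items))
    cat(sprintf("  %-32s %14.2f EUR %6.2f%%\n", nm, x$items[nm],
                x$percent[nm]))
  cat(sprintf("  %-32s %14.2f EUR\n", "TOTAL", x$total))
  invisible(x)
}

#' Scale an equipment cost to a new size
#'
#' Six-tenths power law `cost * (new/old)^exponent`, the standard
#' order-of-magnitude scaling for process equipment; enables what-if
#' costing at plant scales other than the reference one.
#'
#' @param cost Base cost, EUR.
#' @param old_size,new_size Equipment sizes in a common unit; positive.
#' @param exponent Scaling exponent (default 0.6).
#' @return Scaled cost, EUR.
#' @export
#' @examples
#' scale_equipment_cost(78200, 1.11, 2.22)  # 2x reactor volume
scale_equipment_cost <- function(cost, old_size, new_size,
                                 exponent = 0.6) {
  if (old_size <= 0 || new_size <= 0)
    stop("equipment sizes must be positive")
  if (cost < 0) stop("cost must be non-negative")
  cost * (new_size / old_size)^exponent
}
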