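#' Write a plant/economic configuration pair to YAML
#'
#' Serializes the tunable scalar parameters of the two configurations so a
#' scenario can be stored, edited and re-read; nested rule objects are
#' flattened into named blocks.
#'
#' @param config A list with `plant` ([plant_config()]) and `econ`
#'   ([econ_config()]), e.g. from [base_case()] or [sample_configs()].
#' @param path Output YAML file path.
#' @return Invisibly, `path`.
#' @export
write_config_yaml <- function(config, path) {
  stopifnot(inherits(config$plant, "plant_config"),
            inherits(config$econ, "econ_config"))
  p <- config$plant
  strip <- function(x) lapply(unclass(x), function(v)
    if (is.numeric(v) && !is.null(names(v))) as.list(v) else v)
  out <- list(
    plant = c(
      list(sludge_rate = p$sludge_rate,
           operating_hours = p$operating_hours,
           dry_matter_fraction = p$dry_matter_fraction,
           composition = as.list(p$composition),
           sludge_density = p$sludge_density,
           feed_temperature = p$feed_temperature,
           hydrolysis_temperature = p$hydrolysis_temperature,
           homog_pressure = p$homog_pressure,
           homog_efficiency = p$homog_efficiency),
      list(dosing = strip(p$dosing),
           reaction = list(conversion = p$reaction$conversion),
           centrifuge = strip(p$centrifuge),
           solar = strip(p$solar))),
    econ = unclass(config$econ))
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Read a plant/economic configuration pair from YAML
#'
#' Inverse of [write_config_yaml()]; unspecified fields fall back to the
#' package defaults.
#'
#' @param path YAML file path.
#' @return A list with `plant` and `econ` configurations.
#' @export
read_config_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  pl <- raw$plant
  plant_args <- pl[setdiff(names(pl),
                           c("composition", "dosing", "reaction",
                             "centrifuge", "solar"))]
  if (!is.null(pl$composition))
    plant_args$composition <- unlist(pl$composition)
  if (!is.null(pl$dosing)) {
    d <- pl$dosing
    if (!is.null(d$enzyme_prep_fractions))
      d$enzyme_prep_fractions <- unlist(d$enzyme_prep_fractions)
    plant_args$dosing <- do.call(dosing_rule, d)
  }
  if (!is.null(pl$reaction))
    plant_args$reaction <- do.call(reaction_spec, pl$reaction)
  if (!is.null(pl$centrifuge))
    plant_args$centrifuge <- do.call(centrifuge_spec, pl$centrifuge)
  if (!is.null(pl$solar))
    plant_args$solar <- do.call(solar_spec, pl$solar)
  plant <- do.call(plant_config, plant_args)
  econ <- do.call(econ_config,
                  raw$econ[names(raw$econ) %in%
                             names(formals(econ_config))])
  list(plant = plant, econ = econ)
}

#' Write a techno-economic report to JSON
#'
#' One JSON document with the annual totals, the sizing results, the OPEX
#' breakdown and the four profitability indicators of an [evaluate_tea()]
#' result.
#'
#' @param tea An [evaluate_tea()] result.
#' @param path Output JSON path.
#' @return Invisibly, the report list.
#' @export
write_tea_report <- function(tea, path) {
  report <- list(
    annual = unclass(tea$summary),
    sizing = tea$flowsheet$sizing,
    opex_eur = as.list(tea$opex$items),
    opex_total_eur = tea$opex$total,
    revenue_eur = tea$revenue,
    indicators = list(npv_eur = tea$cashflow$npv,
                      irr = tea$cashflow$irr,
                      payback_years = tea$cashflow$payback,
                      pi = tea$cashflow$pi))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(report)
}
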