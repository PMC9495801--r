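#' Plant configuration
#'
#' Collects every design parameter of the six-stage plant: sludge feed rate
#' and composition, dosing and reaction rules, centrifuge split, solar
#' sizing constants and operating temperatures.  The defaults are the
#' 2062.5 t/year reference design: 260.42 kg/h of microalgal sludge at
#' 19.42 percent dry matter, dry biomass composed of 49.5 percent protein,
#' 17.5 percent lipids, 26.0 percent carbohydrates and 7.0 percent ash,
#' operated 7920 h/year.
#'
#' @param sludge_rate Sludge feed, kg/h (default 260.42).
#' @param operating_hours Annual operation, h/year (default 7920).
#' @param dry_matter_fraction Biomass (dry matter) mass fraction of the
#'   sludge (default 50.57/260.42).
#' @param composition Named fractions of the dry matter over `protein`,
#'   `lipids`, `carbohydrates`, `ash`; must sum to 1.
#' @param sludge_density Sludge density, kg/L (default 1.03).
#' @param feed_temperature Sludge feed temperature, degC (default 25).
#' @param hydrolysis_temperature Reactor temperature, degC (default 50).
#' @param homog_pressure Homogenization pressure rise, bar (default 200).
#' @param homog_efficiency Homogenizer dissipation efficiency
#'   (default 0.35).
#' @param dosing A [dosing_rule()].
#' @param reaction A [reaction_spec()].
#' @param centrifuge A [centrifuge_spec()].
#' @param solar A [solar_spec()].
#' @param cpm A [cp_model()].
#' @param sludge_storage_days,product_storage_days,reagent_storage_days
#'   Residence times of the buffer tanks, days (defaults 1, 30, 30).
#' @return An object of class `plant_config`.
#' @export
#' @examples
#' cfg <- plant_config()
#' cfg$sludge_rate
plant_config <- function(sludge_rate = 260.42,
                         operating_hours = 7920,
                         dry_matter_fraction = 50.57 / 260.42,
                         composition = c(protein = 0.495,
                                         lipids = 0.175,
                                         carbohydrates = 0.260,
                                         ash = 0.070),
                         sludge_density = 1.03,
                         feed_temperature = 25,
                         hydrolysis_temperature = 50,
                         homog_pressure = 200,
                         homog_efficiency = 0.35,
                         dosing = dosing_rule(),
                         reaction = reaction_spec(),
                         centrifuge = centrifuge_spec(),
                         solar = solar_spec(),
                         cpm = cp_model(),
                         sludge_storage_days = 1,
                         product_storage_days = 30,
                         reagent_storage_days = 30) {
  if (sludge_rate <= 0) stop("sludge_rate must be positive")
  if (operating_hours <= 0 || operating_hours > 8760)
    stop("operating_hours must lie in (0, 8760]")
  if (dry_matter_fraction <= 0 || dry_matter_fraction >= 1)
    stop("dry_matter_fraction must lie in (0, 1)")
  req <- c("protein", "lipids", "carbohydrates", "ash")
  if (!setequal(names(composition), req))
    stop("composition must name exactly: ", paste(req, collapse = ", "))
  if (any(composition < 0) || abs(sum(composition) - 1) > 1e-9)
    stop("composition fractions must be non-negative and sum to 1")
  structure(list(sludge_rate = sludge_rate,
                 operating_hours = operating_hours,
                 dry_matter_fraction = dry_matter_fraction,
                 composition = composition[req],
                 sludge_density = sludge_density,
                 feed_temperature = feed_temperature,
                 hydrolysis_temperature = hydrolysis_temperature,
                 homog_pressure = homog_pressure,
                 homog_efficiency = homog_efficiency,
                 dosing = dosing,
                 reaction = reaction,
                 centrifuge = centrifuge,
                 solar = solar,
                 cpm = cpm,
                 sludge_storage_days = sludge_storage_days,
                 product_storage_days = product_storage_days,
                 reagent_storage_days = reagent_storage_days),
            class = "plant_config")
}

#' Solve the plant flowsheet
#'
#' Runs the six stages in their fixed feed-forward order (the flowsheet has
#' no recycles): sludge storage (1) -> homogenizer (3), reagent dosing
#' (4, 5, 6), adiabatic mixing and heating to the hydrolysis temperature,
#' stoichiometric reactor (7), disc centrifuge (8 product / 9 cake),
#' product storage (10) and packaging (11).  Storage and packaging are
#' mass-transparent.  Streams CA-1/CA-2 are the solar hot-water loop that
#' delivers the exchanger duty.
#'
#' @param config A [plant_config()].
#' @return An object of class `flowsheet_result`: a named list of streams
#'   (`s1` to `s11`, `ca1`, `ca2`), plus `duty` (kJ/h), `mixed_feed` (the
#'   cold reactor feed before heating) and `sizing` (solar field and
#'   storage-tank sizes).
#' @export
#' @examples
#' fs <- run_flowsheet(plant_config())
#' stream_total(fs$streams$s8)  # biofertilizer product, kg/h
run_flowsheet <- function(config = plant_config()) {
  stopifnot(inherits(config, "plant_config"))
  dm <- config$sludge_rate * config$dry_matter_fraction
  s1 <- process_stream(config$feed_temperature, 1.01, c(
    water = config$sludge_rate - dm,
    protein = dm * config$composition[["protein"]],
    lipids = dm * config$composition[["lipids"]],
    carbohydrates = dm * config$composition[["carbohydrates"]],
    ash = dm * config$composition[["ash"]]))
  s2 <- s1  # buffer tank, mass-transparent

  s3 <- tryCatch(
    homogenize(s2, config$homog_pressure, config$homog_efficiency,
               config$sludge_density, config$cpm),
    error = function(e) stop("homogenizer: ", conditionMessage(e)))

  dosed <- tryCatch(
    dose_reagents(s3, config$dosing, config$sludge_density),
    error = function(e) stop("reagent dosing: ", conditionMessage(e)))
  s4 <- dosed$enzyme
  s5 <- dosed$h2so4
  s6 <- dosed$caoh2

  mixed <- mix_streams(list(s3, s4, s5, s6), config$cpm)
  he <- tryCatch(
    exchanger_duty(mixed, config$hydrolysis_temperature,
                   config$solar$hot_supply, config$solar$hot_return,
                   config$cpm),
    error = function(e) stop("heat exchanger: ", conditionMessage(e)))

  s7 <- tryCatch(
    hydrolyze_and_neutralize(mixed, config$reaction,
                             config$hydrolysis_temperature),
    error = function(e) stop("hydrolysis reactor: ", conditionMessage(e)))

  split <- tryCatch(
    centrifuge(s7, config$centrifuge),
    error = function(e) stop("centrifuge: ", conditionMessage(e)))
  s8 <- split$centrate
  s9 <- split$cake
  s10 <- s8  # concentrate storage
  s11 <- s10 # packaging

  ca1 <- process_stream(config$solar$hot_supply, 1.01,
                        c(water = he$hot_water_flow))
  ca2 <- process_stream(config$solar$hot_return, 1.01,
                        c(water = he$hot_water_flow))

  sizing <- c(
    size_solar(he$duty, config$solar, config$cpm),
    list(sludge_tank_m3 = size_storage_tank(
           stream_total(s1), config$sludge_storage_days,
           config$sludge_density),
         product_tank_m3 = size_storage_tank(
           stream_total(s10), config$product_storage_days, 1.03)))

  structure(list(
    streams = list(s1 = s1, s2 = s2, s3 = s3, s4 = s4, s5 = s5, s6 = s6,
                   s7 = s7, s8 = s8, s9 = s9, s10 = s10, s11 = s11,
                   ca1 = ca1, ca2 = ca2),
    duty = he$duty,
    hot_water_flow = he$hot_water_flow,
    mixed_feed = mixed,
    sizing = sizing,
    config = config), class = "flowsheet_result")
}

#' @export
print.flowsheet_result <- function(x, ...) {
  cat("<flowsheet_result>\n")
  cat(sprintf("  feed:        %8.2f kg/h sludge\n",
              stream_total(x$streams$s1)))
  cat(sprintf("  product:     %8.2f kg/h (%.2f%% free amino acids)\n",
              stream_total(x$streams$s8),
              100 * stream_fraction(x$streams$s8, "amino_acids")$fraction))
  cat(sprintf("  by-product:  %8.2f kg/h solids cake\n",
              stream_total(x$streams$s9)))
  cat(sprintf("  heat duty:   %8.1f kJ/h\n", x$duty))
  invisible(x)
}

#' Overall mass-balance closure of a solved flowsheet
#'
#' Relative gap between total inlet (sludge plus the three reagent streams)
#' and total outlet (product plus cake) mass flows.
#'
#' @param result A [run_flowsheet()] result.
#' @return Relative imbalance (dimensionless).
#' @export
mass_balance_gap <- function(result) {
  stopifnot(inherits(result, "flowsheet_result"))
  s <- result$streams
  inflow <- sum(vapply(s[c("s1", "s4", "s5", "s6")], stream_total,
                       numeric(1)))
  outflow <- sum(vapply(s[c("s8", "s9")], stream_total, numeric(1)))
  abs(inflow - outflow) / inflow
}

#' Annual production and consumption totals
#'
#' Multiplies the steady-state flows by the operating hours:
#' tonnes = kg/h x h / 1000; heating energy in kJ.
#'
#' @param result A [run_flowsheet()] result.
#' @param hours Operating hours per year (defaults to the config value).
#' @return An object of class `annual_summary` with fields
#'   `biofertilizer_t`, `solid_byproduct_t`, `sludge_t`, `enzyme_prep_t`,
#'   `caoh2_prep_t`, `h2so4_prep_t`, `heating_kJ`.
#' @export
#' @examples
#' annualize(run_flowsheet(plant_config()))$biofertilizer_t
annualize <- function(result, hours = NULL) {
  stopifnot(inherits(result, "flowsheet_result"))
  if (is.null(hours)) hours <- result$config$operating_hours
  if (hours < 0) stop("hours must be non-negative")
  s <- result$streams
  t_per_year <- function(stream) stream_total(stream) * hours / 1000
  structure(list(
    biofertilizer_t = t_per_year(s$s10),
    solid_byproduct_t = t_per_year(s$s9),
    sludge_t = t_per_year(s$s1),
    enzyme_prep_t = t_per_year(s$s4),
    caoh2_prep_t = t_per_year(s$s6),
    h2so4_prep_t = t_per_year(s$s5),
    heating_kJ = result$duty * hours,
    hours = hours), class = "annual_summary")
}

#' @export
print.annual_summary <- function(x, ...) {
  cat("<annual_summary>\n")
  cat(sprintf("  biofertilizer   %10.2f t/year\n", x$biofertilizer_t))
  cat(sprintf("  solid by-product%10.2f t/year\n", x$solid_byproduct_t))
  cat(sprintf("  sludge consumed %10.2f t/year\n", x$sludge_t))
  cat(sprintf("  enzyme prep     %10.2f t/year\n", x$enzyme_prep_t))
  cat(sprintf("  Ca(OH)2 prep    %10.2f t/year\n", x$caoh2_prep_t))
  cat(sprintf("  H2SO4 prep      %10.2f t/year\n", x$h2so4_prep_t))
  cat(sprintf("  heating energy  %10.3e kJ/year\n", x$heating_kJ))
  invisible(x)
}

#' Reference stream table of the 2062.5 t/year design
#'
#' The published steady-state balance of the reference plant, solved with a
#' commercial process simulator: temperature, pressure and per-component
#' flows of the thirteen flowsheet streams, plus the supplied heat duty.
#' Used as the comparison target for [run_flowsheet()] and as printed-value
#' input where an operation is exercised in isolation.
#'
#' @return A data.frame with one column per stream (`s1` to `s11`, `ca1`,
#'   `ca2`) and rows for temperature, pressure, total flow and component
#'   flows; attribute `supplied_heat_kJ_h` carries the hot-loop duty
#'   (10336.50 kJ/h).
#' @export
ref_stream_table <- function() {
  rows <- c("temperature_C", "pressure_bar", "total_kg_h",
            paste0(component_names(), "_kg_h"))
  put <- function(temp, total, flows) {
    col <- stats::setNames(c(temp, 1.01, total,
                             numeric(length(component_names()))), rows)
    col[paste0(names(flows), "_kg_h")] <- flows
    col
  }
  s1 <- put(25, 260.42, c(water = 209.85, protein = 25.03, lipids = 8.85,
                          carbohydrates = 13.15, ash = 3.54))
  s3 <- s1; s3[["temperature_C"]] <- 40.04
  s8 <- put(50, 207.82, c(water = 194.03, sucrose = 1.31,
                          amino_acids = 12.48))
  cols <- list(
    s1 = s1, s2 = s1, s3 = s3,
    s4 = put(25, 4.79, c(water = 2.40, enzymes = 0.94, sucrose = 1.44)),
    s5 = put(25, 0.88, c(water = 0.02, h2so4 = 0.86)),
    s6 = put(25, 2.79, c(water = 1.39, caoh2 = 1.40)),
    s7 = put(50, 268.87, c(water = 213.98, protein = 11.26,
                           lipids = 8.85, carbohydrates = 13.15,
                           ash = 3.54, enzymes = 0.94, sucrose = 1.44,
                           caoh2 = 0.75, amino_acids = 13.77,
                           caso4 = 1.2)),
    s8 = s8,
    s9 = put(50, 61.05, c(water = 19.95, protein = 11.26, lipids = 8.85,
                          carbohydrates = 13.15, ash = 3.54,
                          enzymes = 0.94, sucrose = 0.13, caoh2 = 0.75,
                          amino_acids = 1.28, caso4 = 1.2)),
    s10 = s8, s11 = s8,
    ca1 = put(85, 118.20, c(water = 118.20)),
    ca2 = put(65, 118.20, c(water = 118.20)))
  df <- as.data.frame(do.call(cbind, cols))
  rownames(df) <- rows
  structure(df, supplied_heat_kJ_h = 10336.50)
}

#' Build a process_stream from a reference stream-table column
#'
#' @param id Stream identifier, e.g. `"s3"`.
#' @return A [process_stream()] with the printed temperature and component
#'   flows of that column.
#' @export
ref_stream <- function(id) {
  df <- ref_stream_table()
  if (!id %in% colnames(df)) stop("unknown stream id: ", id)
  col <- df[[id]]
  names(col) <- rownames(df)
  comps <- component_names()
  flows <- col[paste0(comps, "_kg_h")]
  names(flows) <- comps
  process_stream(col[["temperature_C"]], col[["pressure_bar"]],
                 flows[flows > 0])
}
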