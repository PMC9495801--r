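#' Reagent and enzyme dosing rule
#'
#' Dosing is volumetric, on the sludge volumetric flow for the pH-control
#' reagents and on the dry biomass mass for the enzyme preparations, as is
#' usual practice for liquid protease products:
#' \itemize{
#'   \item enzymes: `enzyme_dose` percent (v/w) of liquid preparation per kg
#'     of dry biomass, applied once per preparation (an endoprotease and an
#'     exoprotease added sequentially, hence `n_preparations = 2`);
#'   \item Ca(OH)2 suspension at 70 percent (w/v): `caoh2_ratio` percent
#'     (v/v) of the sludge flow;
#'   \item 98 wt percent sulfuric acid: `h2so4_ratio` percent (v/v) of the
#'     sludge flow.
#' }
#' The enzyme preparation is a liquid product: besides the active enzyme it
#' carries water and a sucrose stabiliser; `enzyme_prep_fractions` gives its
#' mass composition.
#'
#' @param enzyme_dose Enzyme preparation dose, percent v/w on dry biomass
#'   (default 4).
#' @param n_preparations Number of sequential enzyme preparations dosed at
#'   `enzyme_dose` each (default 2).
#' @param caoh2_ratio Ca(OH)2 suspension to sludge ratio, percent v/v
#'   (default 0.79).
#' @param h2so4_ratio Sulfuric acid to sludge ratio, percent v/v
#'   (default 0.19).
#' @param caoh2_strength Ca(OH)2 suspension strength, percent w/v
#'   (default 70).
#' @param h2so4_strength Sulfuric acid strength, wt percent (default 98).
#' @param enzyme_density,caoh2_density,h2so4_density Reagent densities,
#'   kg/L.
#' @param enzyme_prep_fractions Mass fractions (water, enzymes, sucrose) of
#'   the liquid enzyme preparation; must sum to 1.
#' @return An object of class `dosing_rule`.
#' @export
dosing_rule <- function(enzyme_dose = 4,
                        n_preparations = 2,
                        caoh2_ratio = 0.79,
                        h2so4_ratio = 0.19,
                        caoh2_strength = 70,
                        h2so4_strength = 98,
                        enzyme_density = 1.183,
                        caoh2_density = 1.396,
                        h2so4_density = 1.8305,
                        enzyme_prep_fractions = c(water = 2.40 / 4.78,
                                                  enzymes = 0.94 / 4.78,
                                                  sucrose = 1.44 / 4.78)) {
  ratios <- c(enzyme_dose, caoh2_ratio, h2so4_ratio,
              caoh2_strength, h2so4_strength)
  if (any(ratios <= 0) || any(ratios > 100))
    stop("dosing ratios and strengths must lie in (0, 100]")
  if (any(c(enzyme_density, caoh2_density, h2so4_density) <= 0))
    stop("reagent densities must be positive")
  if (abs(sum(enzyme_prep_fractions) - 1) > 1e-9)
    stop("enzyme preparation mass fractions must sum to 1")
  structure(list(enzyme_dose = enzyme_dose,
                 n_preparations = n_preparations,
                 caoh2_ratio = caoh2_ratio,
                 h2so4_ratio = h2so4_ratio,
                 caoh2_strength = caoh2_strength,
                 h2so4_strength = h2so4_strength,
                 enzyme_density = enzyme_density,
                 caoh2_density = caoh2_density,
                 h2so4_density = h2so4_density,
                 enzyme_prep_fractions = enzyme_prep_fractions),
            class = "dosing_rule")
}

#' Hydrolysis and neutralization reaction specification
#'
#' Two reactions run in the stirred hydrolysis reactor:
#' \enumerate{
#'   \item enzymatic protein hydrolysis, `conversion` of the feed protein
#'     transferred 1:1 by mass to free amino acids (the degree of
#'     hydrolysis after the 3 h batch; no net hydrolytic water uptake, so
#'     the step is mass-closed);
#'   \item complete neutralization of the dosed acid,
#'     H2SO4 + Ca(OH)2 -> CaSO4 + 2 H2O, tracked through fixed mass ratios
#'     per kg of H2SO4 derived from the molar masses (98.08, 74.09, 136.14,
#'     18.02 g/mol).
#' }
#'
#' @param conversion Degree of protein hydrolysis, fraction in \[0, 1\]
#'   (default 0.55).
#' @return An object of class `reaction_spec` carrying the conversion and
#'   the stoichiometric mass ratios `caoh2_per_h2so4`, `caso4_per_h2so4`,
#'   `water_per_h2so4`.
#' @export
reaction_spec <- function(conversion = 0.55) {
  if (conversion < 0 || conversion > 1)
    stop("conversion must lie in [0, 1]")
  ratios <- list(caoh2_per_h2so4 = 74.09 / 98.08,
                 caso4_per_h2so4 = 136.14 / 98.08,
                 water_per_h2so4 = 36.03 / 98.08)
  # mass closure of the neutralization: reactants = products
  stopifnot(abs(1 + ratios$caoh2_per_h2so4 -
                  ratios$caso4_per_h2so4 - ratios$water_per_h2so4) < 1e-4)
  structure(c(list(conversion = conversion), ratios),
            class = "reaction_spec")
}

#' Disc-centrifuge split specification
#'
#' @param cake_liquid_fraction Mass fraction of entrained mother liquor
#'   (water plus dissolved solutes) in the solids stream -- the "humidity"
#'   of the cake (default 0.35).
#' @param solids_recovery Fraction of insoluble solids reporting to the
#'   cake (default 1, i.e. complete retention).
#' @return An object of class `centrifuge_spec`.
#' @export
centrifuge_spec <- function(cake_liquid_fraction = 0.35,
                            solids_recovery = 1.0) {
  if (cake_liquid_fraction < 0 || cake_liquid_fraction >= 1)
    stop("cake_liquid_fraction must lie in [0, 1)")
  if (solids_recovery <= 0 || solids_recovery > 1)
    stop("solids_recovery must lie in (0, 1]")
  structure(list(cake_liquid_fraction = cake_liquid_fraction,
                 solids_recovery = solids_recovery),
            class = "centrifuge_spec")
}

#' Solar thermal collection system specification
#'
#' The collector field is sized to capture, during `collection_hours` of
#' sun per day, the whole daily heat demand plus a `loss_margin`; the flat
#' collectors are rated by a collection capacity per unit area and degree
#' of driving temperature difference, of which at least `delta_T_min` is
#' guaranteed.  The hot-water storage tank holds `storage_autonomy` days of
#' demand over the 85/65 degC loop swing.
#'
#' @param loss_margin Fractional heat-loss oversizing of the capture field
#'   (default 0.20).
#' @param collection_hours Useful collection time, h/day (default 8).
#' @param delta_T_min Minimum temperature rise in the collectors, degC
#'   (default 10).
#' @param collector_capacity Collector rating, kJ/(h m2 degC)
#'   (default 350.22).
#' @param collector_area Absorber area per collector, m2 (default 1.9).
#' @param spare_collectors Installed spare units beyond the rounded-up
#'   requirement (default 1).
#' @param storage_autonomy Hot-water storage autonomy, days (default 3).
#' @param storage_oversize Volumetric oversizing factor of the storage tank
#'   (default 1.25).
#' @param hot_supply,hot_return Loop supply and return temperatures, degC
#'   (defaults 85 and 65).
#' @return An object of class `solar_spec`.
#' @export
solar_spec <- function(loss_margin = 0.20,
                       collection_hours = 8,
                       delta_T_min = 10,
                       collector_capacity = 350.22,
                       collector_area = 1.9,
                       spare_collectors = 1,
                       storage_autonomy = 3,
                       storage_oversize = 1.25,
                       hot_supply = 85,
                       hot_return = 65) {
  vals <- c(loss_margin, collection_hours, delta_T_min, collector_capacity,
            collector_area, storage_autonomy, storage_oversize)
  if (any(vals <= 0) && loss_margin < 0)
    stop("solar specification values must be positive")
  if (any(c(collection_hours, delta_T_min, collector_capacity,
            collector_area, storage_autonomy, storage_oversize) <= 0))
    stop("solar specification values must be positive")
  if (hot_supply <= hot_return)
    stop("hot_supply must exceed hot_return")
  structure(list(loss_margin = loss_margin,
                 collection_hours = collection_hours,
                 delta_T_min = delta_T_min,
                 collector_capacity = collector_capacity,
                 collector_area = collector_area,
                 spare_collectors = spare_collectors,
                 storage_autonomy = storage_autonomy,
                 storage_oversize = storage_oversize,
                 hot_supply = hot_supply,
                 hot_return = hot_return),
            class = "solar_spec")
}

#' High-pressure homogenization
#'
#' The sludge is pumped to `delta_P` bar and flashed back to ambient
#' pressure to rupture the microalgal cells.  Composition is unchanged; the
#' pumping work dissipates into the stream, raising its temperature by
#' `dT = dP / (rho * cp_mix * efficiency)` where `efficiency` is the
#' overall electric-to-heat efficiency of the pump-valve pair (its default
#' of 0.35 reproduces the roughly 40 degC outlet of the reference balance).
#'
#' @param feed Inlet [process_stream()].
#' @param delta_P Pressure rise before the let-down valve, bar
#'   (default 200).
#' @param efficiency Overall dissipation efficiency in (0, 1\]
#'   (default 0.35).
#' @param density Feed density, kg/L (default 1.03 for the 20 percent
#'   sludge).
#' @param cpm A [cp_model()].
#' @return Outlet [process_stream()] at ambient pressure.
#' @export
#' @examples
#' s <- process_stream(25, flows = c(water = 209.85, protein = 25.03,
#'   lipids = 8.85, carbohydrates = 13.15, ash = 3.54))
#' homogenize(s)$temperature
homogenize <- function(feed, delta_P = 200, efficiency = 0.35,
                       density = 1.03, cpm = cp_model()) {
  stopifnot(inherits(feed, "process_stream"))
  if (delta_P < 0) stop("delta_P must be non-negative")
  if (efficiency <= 0 || efficiency > 1)
    stop("efficiency must lie in (0, 1]")
  if (density <= 0) stop("density must be positive")
  if (delta_P == 0) return(process_stream(feed$temperature, 1.01,
                                          feed$flows))
  cp_mix <- mixture_cp(feed, cpm)
  # 1 bar = 100 kJ/m3 of displaced volume; rho in kg/m3
  dT <- (delta_P * 100) / (density * 1000 * cp_mix * efficiency)
  process_stream(feed$temperature + dT, 1.01, feed$flows)
}

#' Reagent and enzyme dosing streams
#'
#' Builds the three feed streams to the hydrolysis reactor from the sludge
#' flow and a [dosing_rule()]: the liquid enzyme preparation (dosed v/w on
#' the dry biomass), the 98 wt percent sulfuric acid and the 70 percent w/v
#' Ca(OH)2 suspension (both dosed v/v on the sludge volumetric flow).  All
#' reagent streams enter at 25 degC.
#'
#' @param sludge Sludge [process_stream()] (water plus biomass fractions).
#' @param rule A [dosing_rule()].
#' @param sludge_density Sludge density, kg/L (default 1.03); required to
#'   convert the mass flow to the volumetric dosing basis.
#' @return A list of streams `enzyme`, `h2so4`, `caoh2`.
#' @export
dose_reagents <- function(sludge, rule = dosing_rule(),
                          sludge_density = 1.03) {
  stopifnot(inherits(sludge, "process_stream"),
            inherits(rule, "dosing_rule"))
  if (is.null(sludge_density) || !is.finite(sludge_density) ||
      sludge_density <= 0)
    stop("sludge density is required for volumetric dosing")
  total <- stream_total(sludge)
  sludge_vol <- total / sludge_density                      # L/h
  dry_mass <- total - sludge$flows[["water"]]               # kg/h biomass

  # enzyme preparation: v/w per preparation on dry biomass
  enz_vol <- rule$n_preparations * (rule$enzyme_dose / 100) * dry_mass
  enz_mass <- enz_vol * rule$enzyme_density
  fr <- rule$enzyme_prep_fractions
  enzyme <- process_stream(25, 1.01, c(
    water = enz_mass * fr[["water"]],
    enzymes = enz_mass * fr[["enzymes"]],
    sucrose = enz_mass * fr[["sucrose"]]))

  # sulfuric acid: v/v on sludge, split by wt strength
  acid_mass <- sludge_vol * (rule$h2so4_ratio / 100) * rule$h2so4_density
  h2so4 <- process_stream(25, 1.01, c(
    h2so4 = acid_mass * rule$h2so4_strength / 100,
    water = acid_mass * (1 - rule$h2so4_strength / 100)))

  # lime suspension: v/v on sludge, strength is w/v (kg active per L)
  lime_vol <- sludge_vol * (rule$caoh2_ratio / 100)
  lime_active <- lime_vol * rule$caoh2_strength / 100
  lime_mass <- lime_vol * rule$caoh2_density
  if (lime_active > lime_mass)
    stop("Ca(OH)2 strength inconsistent with suspension density")
  caoh2 <- process_stream(25, 1.01, c(
    caoh2 = lime_active,
    water = lime_mass - lime_active))

  list(enzyme = enzyme, h2so4 = h2so4, caoh2 = caoh2)
}

#' Hydrolysis reactor with in-situ neutralization
#'
#' Applies the two stoichiometric reactions of a [reaction_spec()] to the
#' mixed reactor feed: protein to free amino acids at the specified degree
#' of hydrolysis, and complete consumption of the dosed sulfuric acid by
#' Ca(OH)2 forming gypsum and water.  The outlet leaves at the controlled
#' hydrolysis temperature.  Total mass is conserved exactly.
#'
#' @param feed Mixed reactor feed [process_stream()].
#' @param spec A [reaction_spec()].
#' @param T_out Reactor temperature, degC (default 50).
#' @return Outlet [process_stream()].
#' @export
hydrolyze_and_neutralize <- function(feed, spec = reaction_spec(),
                                     T_out = 50) {
  stopifnot(inherits(feed, "process_stream"),
            inherits(spec, "reaction_spec"))
  fl <- feed$flows
  acid <- fl[["h2so4"]]
  need <- acid * spec$caoh2_per_h2so4
  if (fl[["caoh2"]] < need - 1e-9)
    stop(sprintf(
      "insufficient Ca(OH)2: %.4f kg/h present, %.4f kg/h required (deficit %.4f)",
      fl[["caoh2"]], need, need - fl[["caoh2"]]))
  reacted <- fl[["protein"]] * spec$conversion
  fl[["protein"]] <- fl[["protein"]] - reacted
  fl[["amino_acids"]] <- fl[["amino_acids"]] + reacted
  fl[["caoh2"]] <- max(fl[["caoh2"]] - need, 0)  # guard rounding residue
  fl[["caso4"]] <- fl[["caso4"]] + acid * spec$caso4_per_h2so4
  fl[["water"]] <- fl[["water"]] + acid * spec$water_per_h2so4
  fl[["h2so4"]] <- 0
  process_stream(T_out, feed$pressure, fl)
}

#' Heat-exchanger duty and hot-loop flow
#'
#' Duty to bring a cold stream to its target temperature with the
#' constant-cp model, and the hot-water loop flow that delivers it over the
#' supply/return swing of the solar loop.  The countercurrent exchanger
#' requires a minimum approach between the hot-side outlet and the
#' cold-side inlet.
#'
#' @param cold_in Cold-side inlet [process_stream()].
#' @param T_target Cold-side outlet temperature, degC (default 50).
#' @param hot_supply,hot_return Hot-water loop temperatures, degC
#'   (defaults 85 / 65).
#' @param cpm A [cp_model()] (its `cp_hot` is used for the loop).
#' @param approach_min Minimum approach temperature, degC (default 10).
#' @return A list with `duty` (kJ/h) and `hot_water_flow` (kg/h).
#' @export
exchanger_duty <- function(cold_in, T_target = 50, hot_supply = 85,
                           hot_return = 65, cpm = cp_model(),
                           approach_min = 10) {
  stopifnot(inherits(cold_in, "process_stream"))
  if (T_target < cold_in$temperature)
    stop("T_target must not be below the cold inlet temperature")
  if (hot_supply <= hot_return)
    stop("hot_supply must exceed hot_return")
  if (hot_return - cold_in$temperature < approach_min - 1e-9)
    stop(sprintf(
      "approach temperature violated: hot return %.2f degC vs cold inlet %.2f degC (minimum %.1f degC)",
      hot_return, cold_in$temperature, approach_min))
  duty <- stream_total(cold_in) * mixture_cp(cold_in, cpm) *
    (T_target - cold_in$temperature)
  list(duty = duty,
       hot_water_flow = duty / (cpm$cp_hot * (hot_supply - hot_return)))
}

#' Disc-centrifuge solid-liquid split
#'
#' All insoluble solids (times `solids_recovery`) report to the cake; the
#' cake is brought to its specified liquid fraction by entraining mother
#' liquor -- water plus dissolved solutes -- at the liquor's own
#' composition.  The centrate is the remainder.  Both outlets leave at the
#' feed temperature.
#'
#' @param feed Feed [process_stream()].
#' @param spec A [centrifuge_spec()].
#' @return A list of streams `centrate` (liquid product) and `cake`
#'   (solid by-product).
#' @export
centrifuge <- function(feed, spec = centrifuge_spec()) {
  stopifnot(inherits(feed, "process_stream"),
            inherits(spec, "centrifuge_spec"))
  insol <- components_of_class("insoluble-solid")
  liq <- setdiff(component_names(), insol)

  cake_fl <- stats::setNames(numeric(length(feed$flows)),
                             names(feed$flows))
  cake_fl[insol] <- feed$flows[insol] * spec$solids_recovery
  S <- sum(cake_fl[insol])
  L <- sum(feed$flows[liq])
  r <- spec$cake_liquid_fraction
  entrained <- S * r / (1 - r)
  if (entrained > L + 1e-12)
    stop("not enough mother liquor to reach the specified cake humidity")
  if (L > 0) cake_fl[liq] <- feed$flows[liq] * (entrained / L)

  centrate_fl <- feed$flows - cake_fl
  centrate_fl[abs(centrate_fl) < 1e-12] <- 0
  list(centrate = process_stream(feed$temperature, feed$pressure,
                                 centrate_fl),
       cake = process_stream(feed$temperature, feed$pressure, cake_fl))
}

#' Size the solar collection field and its hot-water storage
#'
#' Capture area follows the daily-energy rule
#' `area = duty * 24 * (1 + loss_margin) /
#'   (collection_hours * collector_capacity * delta_T_min)`;
#' the installed collector count is the area divided by the per-collector
#' absorber area, rounded up, plus the installed spares.  Storage volume
#' holds the autonomy days of demand over the loop temperature swing, with
#' a volumetric oversize.
#'
#' @param duty Process heat demand, kJ/h.
#' @param spec A [solar_spec()].
#' @param cpm A [cp_model()] (its `cp_hot` and water density 1000 kg/m3
#'   size the storage).
#' @return A list with `capture_area` (m2), `collectors_required`
#'   (fractional), `collectors_installed` (count), `storage_volume` (m3).
#' @export
#' @examples
#' size_solar(10336.50)
size_solar <- function(duty, spec = solar_spec(), cpm = cp_model()) {
  stopifnot(inherits(spec, "solar_spec"))
  if (duty < 0) stop("duty must be non-negative")
  area <- duty * 24 * (1 + spec$loss_margin) /
    (spec$collection_hours * spec$collector_capacity * spec$delta_T_min)
  raw <- area / spec$collector_area
  installed <- ceiling(raw) + spec$spare_collectors
  storage <- spec$storage_autonomy * 24 * duty /
    (1000 * cpm$cp_hot * (spec$hot_supply - spec$hot_return)) *
    spec$storage_oversize
  list(capture_area = area,
       collectors_required = raw,
       collectors_installed = installed,
       storage_volume = storage)
}

#' Size a liquid storage tank
#'
#' @param flow Stream mass flow, kg/h.
#' @param residence Residence (storage) time, days.
#' @param density Stored liquid density, kg/L.
#' @param oversize Volumetric oversizing factor (default 1.33, the usual
#'   75 percent working-volume rule).
#' @return Tank volume, m3.
#' @export
#' @examples
#' size_storage_tank(260.42, 1, 1.03)  # ~8.07 m3 sludge buffer
size_storage_tank <- function(flow, residence, density, oversize = 1.33) {
  if (flow < 0 || residence < 0)
    stop("flow and residence must be non-negative")
  if (density <= 0 || oversize <= 0)
    stop("density and oversize must be positive")
  flow * 24 * residence / density / 1000 * oversize
}
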