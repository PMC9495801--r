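#' Randomized plant/economics scenario sampler
#'
#' Draws plant and economic configurations with the structure the analysis
#' assumes, so every stage of the pipeline can be exercised without
#' external data.  Per draw: the dry-biomass macromolecular composition is
#' uniform on the simplex with the protein fraction constrained to its
#' plausible range for protein-rich microalgae; dry matter, degree of
#' hydrolysis and feed scale vary around the reference design; the three
#' prices are uniform on the sensitivity-analysis ranges (sludge 0.2-1.0,
#' enzymes 10-25, sale price 2.5-7.5 EUR/kg).
#'
#' @param seed Integer RNG seed; the same seed reproduces the same
#'   configuration list.
#' @param protein_range,dry_matter_range,conversion_range,scale_range
#'   Two-element ranges for the protein fraction of dry matter, the
#'   dry-matter fraction of the sludge, the degree of hydrolysis, and the
#'   feed-rate multiplier on the reference 260.42 kg/h.
#' @param sludge_price_range,enzyme_price_range,sale_price_range Price
#'   ranges, EUR/kg.
#' @return An object of class `scenario_sampler`.
#' @export
scenario_sampler <- function(seed = 1,
                             protein_range = c(0.3, 0.6),
                             dry_matter_range = c(0.15, 0.25),
                             conversion_range = c(0.3, 0.8),
                             scale_range = c(0.5, 1.5),
                             sludge_price_range = c(0.2, 1.0),
                             enzyme_price_range = c(10, 25),
                             sale_price_range = c(2.5, 7.5)) {
  ranges <- list(protein = protein_range,
                 dry_matter = dry_matter_range,
                 conversion = conversion_range,
                 scale = scale_range,
                 sludge_price = sludge_price_range,
                 enzyme_price = enzyme_price_range,
                 sale_price = sale_price_range)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2 || r[1] > r[2])
      stop("invalid range for ", nm)
  }
  if (protein_range[1] < 0 || protein_range[2] > 1 ||
      dry_matter_range[1] <= 0 || dry_matter_range[2] >= 1 ||
      conversion_range[1] < 0 || conversion_range[2] > 1)
    stop("fraction ranges must lie inside [0, 1]")
  structure(c(list(seed = as.integer(seed)), ranges),
            class = "scenario_sampler")
}

runif_range <- function(n, range) stats::runif(n, range[1], range[2])

#' Sample random plant and economic configurations
#'
#' @param sampler A [scenario_sampler()].
#' @param n Number of configurations (>= 1).
#' @return A list of `n` elements, each a list with `plant`
#'   ([plant_config()]) and `econ` ([econ_config()]).
#' @export
#' @examples
#' cfgs <- sample_configs(scenario_sampler(seed = 42), 3)
#' cfgs[[1]]$plant$composition
sample_configs <- function(sampler, n) {
  stopifnot(inherits(sampler, "scenario_sampler"))
  if (n < 1) stop("n must be at least 1")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv()))
  set.seed(sampler$seed)

  lapply(seq_len(n), function(i) {
    protein <- runif_range(1, sampler$protein)
    # remaining mass uniformly on the 3-simplex (ordered-uniform gaps),
    # scaled to 1 - protein
    cuts <- sort(stats::runif(2))
    rest <- (1 - protein) * c(cuts[1], cuts[2] - cuts[1], 1 - cuts[2])
    plant <- plant_config(
      sludge_rate = 260.42 * runif_range(1, sampler$scale),
      dry_matter_fraction = runif_range(1, sampler$dry_matter),
      composition = c(protein = protein,
                      lipids = rest[1],
                      carbohydrates = rest[2],
                      ash = rest[3]),
      reaction = reaction_spec(runif_range(1, sampler$conversion)))
    econ <- econ_config(
      sludge_price = runif_range(1, sampler$sludge_price),
      enzyme_price = runif_range(1, sampler$enzyme_price),
      sale_price = runif_range(1, sampler$sale_price))
    list(plant = plant, econ = econ)
  })
}

#' Reference base-case configuration
#'
#' The packaged reference design: the 2062.5 t/year plant of
#' [plant_config()] defaults with base prices of 0.5 EUR/kg sludge,
#' 20 EUR/kg enzymes and 3.5 EUR/kg biofertilizer.
#'
#' @return A list with `plant` and `econ` configurations.
#' @export
#' @examples
#' base_case()$econ$sale_price
base_case <- function() {
  list(plant = plant_config(), econ = econ_config())
}
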