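#' Chemical component registry
#'
#' Every stream in the plant is described by the mass flows of eleven
#' components: water, the four macromolecular fractions of the microalgal
#' biomass (protein, lipids, carbohydrates, ash), the liquid enzyme
#' preparation solids (enzymes, sucrose stabiliser), the pH-control reagents
#' (H2SO4, Ca(OH)2), and the reaction products (free amino acids, gypsum).
#' The registry records, per component, its solubility class -- which drives
#' the centrifuge split -- together with the constant specific heat capacity
#' used by the enthalpy model, and molar masses where the neutralization
#' stoichiometry needs them.
#'
#' Solubility classes:
#' \describe{
#'   \item{water}{the continuous liquid phase}
#'   \item{dissolved-solute}{follows the liquor through the centrifuge
#'     (sucrose, free amino acids, H2SO4)}
#'   \item{insoluble-solid}{reports to the centrifuge cake (biomass
#'     fractions, enzymes, Ca(OH)2, CaSO4)}
#' }
#' Enzymes are classed insoluble because the solid by-product carries the
#' full enzyme flow in the reference balance.
#'
#' @return A data.frame with columns `name`, `class`, `cp` (kJ/(kg K)),
#'   `molar_mass` (g/mol, `NA` where stoichiometry never needs it).
#' @export
#' @examples
#' component_registry()
component_registry <- function() {
  data.frame(
    name = c("water", "protein", "lipids", "carbohydrates", "ash",
             "enzymes", "sucrose", "h2so4", "caoh2", "amino_acids",
             "caso4"),
    class = c("water", "insoluble-solid", "insoluble-solid",
              "insoluble-solid", "insoluble-solid", "insoluble-solid",
              "dissolved-solute", "dissolved-solute", "insoluble-solid",
              "dissolved-solute", "insoluble-solid"),
    # Constant-cp enthalpy model.  Organics take Choi-Okos-like values
    # clipped to 1.4-1.6; ash and the inorganic salts sit lower.
    cp = c(4.18, 1.60, 1.60, 1.55, 0.84,
           1.55, 1.55, 1.10, 1.10, 1.55,
           1.10),
    molar_mass = c(18.02, NA, NA, NA, NA,
                   NA, NA, 98.08, 74.09, NA,
                   136.14),
    stringsAsFactors = FALSE
  )
}

#' Component names recognised by the plant model
#' @return Character vector of the eleven component identifiers.
#' @export
component_names <- function() component_registry()$name

#' Components of a given solubility class
#' @param class One of `"water"`, `"dissolved-solute"`, `"insoluble-solid"`.
#' @return Character vector of component names.
#' @export
components_of_class <- function(class) {
  reg <- component_registry()
  class <- match.arg(class, unique(reg$class))
  reg$name[reg$class == class]
}

#' Constant heat-capacity model
#'
#' A mixture's enthalpy is computed with constant per-component specific
#' heats: the mixture cp is the mass-weighted mean of the component cps.
#' The hot-water heating loop carries its own cp (default 4.372 kJ/(kg K)
#' over the 85 to 65 degC swing, calibrated so the loop flow matches the
#' reference balance; plain water would be 4.18).
#'
#' @param overrides Named numeric vector of per-component cp values
#'   (kJ/(kg K)) replacing the registry defaults.
#' @param cp_hot Specific heat of the solar hot-water loop, kJ/(kg K).
#' @return An object of class `cp_model`.
#' @export
#' @examples
#' cp_model()
#' cp_model(overrides = c(water = 4.2))
cp_model <- function(overrides = NULL, cp_hot = 4.372) {
  reg <- component_registry()
  cps <- stats::setNames(reg$cp, reg$name)
  if (!is.null(overrides)) {
    bad <- setdiff(names(overrides), reg$name)
    if (length(bad))
      stop("unknown component(s) in cp overrides: ",
           paste(bad, collapse = ", "))
    cps[names(overrides)] <- overrides
  }
  if (any(cps <= 0) || cp_hot <= 0)
    stop("all heat capacities must be strictly positive")
  structure(list(cp = cps, cp_hot = cp_hot), class = "cp_model")
}

#' Mass-weighted mixture heat capacity of a stream
#'
#' @param stream A [process_stream()].
#' @param cpm A [cp_model()].
#' @return Mixture cp in kJ/(kg K).
#' @export
mixture_cp <- function(stream, cpm = cp_model()) {
  stopifnot(inherits(stream, "process_stream"), inherits(cpm, "cp_model"))
  total <- sum(stream$flows)
  if (total <= 0) stop("mixture cp undefined for a zero-flow stream")
  sum(stream$flows * cpm$cp[names(stream$flows)]) / total
}
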