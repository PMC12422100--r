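#' Chemical state of a culture for thermodynamic calculations
#'
#' @param aqueous named numeric vector of aqueous concentrations (mol/L).
#' @param gas named numeric vector of partial pressures (atm).
#' @param temperature_k temperature (K); 298.15 by default, matching the
#'   standard transformed Gibbs energies in the catalogue.
#' @return list of class `sf_state`.
#' @export
chemical_state <- function(aqueous = numeric(0), gas = numeric(0),
                           temperature_k = T_STANDARD) {
  if (any(aqueous < 0) || any(gas < 0)) stop("activities must be nonnegative")
  if (temperature_k <= 0) stop("temperature must be positive")
  structure(list(aqueous = aqueous, gas = gas, temperature_k = temperature_k),
            class = "sf_state")
}

activity_of <- function(met_id, catalogue, state) {
  phase <- catalogue$metabolites$phase[match(met_id, catalogue$metabolites$id)]
  if (phase %in% c("solid", "biomass")) return(1)
  pool <- if (phase == "gas") state$gas else state$aqueous
  if (!met_id %in% names(pool)) {
    stop("state is missing activity for '", met_id, "'")
  }
  unname(pool[[met_id]])
}

#' Reaction quotient at a chemical state
#'
#' `Q = prod(activity ^ coefficient)` with aqueous activities in mol/L, gas
#' activities in atm, and solids/biomass at unit activity (water and protons
#' are implicit in the pH-7 convention). A zero-activity reactant gives
#' `Q = +Inf` (flagged via attribute `zero_reactant`).
#'
#' @param reaction a catalogue reaction entry.
#' @param catalogue an `sf_catalogue`.
#' @param state an [chemical_state()].
#' @return numeric Q (unitless).
#' @export
reaction_quotient <- function(reaction, catalogue, state) {
  st <- reaction$stoich
  st <- st[catalogue$metabolites$phase[match(names(st), catalogue$metabolites$id)] !=
             "biomass"]
  acts <- vapply(names(st), activity_of, numeric(1),
                 catalogue = catalogue, state = state)
  if (any(acts == 0 & st < 0)) {
    q <- Inf
    attr(q, "zero_reactant") <- names(st)[acts == 0 & st < 0]
    return(q)
  }
  prod(acts^st)
}

#' Transformed Gibbs energy at a chemical state
#'
#' `dG' = dG0' + R T ln(Q) / 1000` (kJ per unit reaction extent), with
#' `R = 8.314` J/mol/K and `T` taken from the state (298.15 K by default).
#'
#' @inheritParams reaction_quotient
#' @return list with `dg_prime` (kJ/mol), `dg0_prime`, `q`, `temperature_k`.
#' @examples
#' cat <- read_catalogue()
#' st <- chemical_state(aqueous = c(acetate = 0.01),
#'                      gas = c(CH4 = 0.1, CO2 = 0.1))
#' delta_g_prime(cat$reactions$acetoclastic_methanogenesis, cat, st)
#' @export
delta_g_prime <- function(reaction, catalogue, state) {
  q <- reaction_quotient(reaction, catalogue, state)
  if (!is.finite(q) || q <= 0) {
    stop("reaction quotient of '", reaction$id,
         "' is not positive and finite (Q = ", q, ")")
  }
  t_k <- state$temperature_k
  dg <- reaction$dg0_prime + R_GAS * t_k * log(q) / 1000
  list(dg_prime = dg, dg0_prime = reaction$dg0_prime, q = q,
       temperature_k = t_k)
}

#' Gibbs energies of all active reactions of an assembly
#'
#' @param assembly assembly label or `sf_assembly`.
#' @param catalogue an `sf_catalogue`.
#' @param state an [chemical_state()].
#' @return data.frame `assembly`, `reaction`, `dg0_prime`, `q`, `dg_prime`.
#' @export
thermo_table <- function(assembly, catalogue, state) {
  if (is.character(assembly)) assembly <- assembly(assembly)
  reactions <- active_reactions(assembly, catalogue)
  out <- do.call(rbind, lapply(reactions, function(r) {
    res <- delta_g_prime(r, catalogue, state)
    data.frame(assembly = assembly$label, reaction = r$id,
               dg0_prime = res$dg0_prime, q = res$q, dg_prime = res$dg_prime,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
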