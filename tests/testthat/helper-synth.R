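# Shared fixtures: the default catalogue, the measured product set, and a
# generator of random feasible ground-truth extents (consumer extents drawn
# within the supply their producers provide, so daily in-vessel amounts stay
# nonnegative under uniform daily rates).

test_cat <- read_catalogue()
PRODUCTS <- c("lactate", "acetate", "ethanol", "H2", "CO2", "CH4")

# assemblies whose active stoichiometry has full column rank over PRODUCTS
# (Rc and Dv together make lactate oxidation collinear with acetogenesis
# minus lactate fermentation)
FULL_RANK_ASSEMBLIES <- c("Rc", "Rc&Mc", "Rc&Mh", "Rc&Mc&Mh")

random_feasible_extents <- function(label) {
  members <- assembly(label)$members
  lf <- stats::runif(1, 0.2, 0.8)
  ha <- stats::runif(1, 0.2, 0.8)
  maf <- stats::runif(1, 0.2, 0.8)
  out <- c(lactate_fermentation = lf, hydrogenic_acetogenesis = ha,
           mixed_acid_fermentation = maf)
  hlo <- 0
  if ("Dv" %in% members) {
    hlo <- stats::runif(1, 0.1, 0.6) * 2 * lf
    out["hydrogenic_lactate_oxidation"] <- hlo
  }
  if ("Mc" %in% members) {
    out["acetoclastic_methanogenesis"] <-
      stats::runif(1, 0.1, 0.6) * (2 * ha + maf + hlo)
  }
  if ("Mh" %in% members) {
    out["hydrogenotrophic_methanogenesis"] <-
      stats::runif(1, 0.1, 0.6) * (4 * ha + 2 * maf + 2 * hlo) / 4
  }
  out
}

product_matrix <- function(label, catalogue = test_cat) {
  build_matrix(active_reactions(label, catalogue),
               catalogue$metabolites$id)[PRODUCTS, , drop = FALSE]
}
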