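#' syntroflux: stoichiometric flux and cross-feeding analysis for synthetic
#' anaerobic communities
#'
#' Fits per-species overall-reaction extents to cumulative metabolite
#' measurements from fed-batch co-cultures, infers interspecies exchange
#' fluxes, computes reaction thermodynamics and carbon/electron transfer to
#' CH4 and CO2, and provides the comparison statistics used to contrast
#' community assemblies.
#'
#' @keywords internal
"_PACKAGE"

# Physical constants (SI); R in J/mol/K, pressures in atm throughout.
R_GAS <- 8.314
ATM_PA <- 101325
T_STANDARD <- 298.15

#' Parse a CHO molecular formula into element counts
#'
#' @param formula character like `"C6H12O6"`, `"H2"`, `"CO2"`.
#' @return named numeric vector with entries `C`, `H`, `O`.
#' @examples
#' parse_formula("C6H12O6")
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  m <- gregexpr("([CHO])([0-9]*)", formula, perl = TRUE)[[1]]
  if (m[1] == -1L || sum(attr(m, "match.length")) != nchar(formula)) {
    stop("cannot parse formula (C, H, O only): '", formula, "'")
  }
  parts <- regmatches(formula, gregexpr("([CHO])([0-9]*)", formula, perl = TRUE))[[1]]
  out <- c(C = 0, H = 0, O = 0)
  for (p in parts) {
    el <- substr(p, 1, 1)
    n <- substr(p, 2, nchar(p))
    out[el] <- out[el] + if (nzchar(n)) as.numeric(n) else 1
  }
  out
}

#' Degree of reduction of a CHO compound
#'
#' Electron equivalents available per mole on full oxidation to CO2 and H2O:
#' `4*C + H - 2*O`. CO2 has degree of reduction 0 by construction.
#'
#' @param formula character molecular formula (C, H, O only).
#' @return numeric electron equivalents per mole.
#' @examples
#' gamma_from_formula("CH4")  # 8
#' gamma_from_formula("CO2")  # 0
#' @export
gamma_from_formula <- function(formula) {
  el <- parse_formula(formula)
  unname(4 * el["C"] + el["H"] - 2 * el["O"])
}

#' Path of the default reaction catalogue shipped with the package
#' @return file path to the YAML catalogue.
#' @export
default_catalogue_path <- function() {
  system.file("extdata", "catalogue.yaml", package = "syntroflux", mustWork = TRUE)
}

#' Read a reaction catalogue from a YAML config
#'
#' The catalogue defines the metabolites (formula, phase, carbon count,
#' degree of reduction), the four species, and the species-attributed overall
#' reactions with signed stoichiometry, ATP yield and standard transformed
#' Gibbs energy. The default catalogue holds the six-reaction model of the
#' cellulolytic community (three Rc fermentations, Dv lactate oxidation, and
#' the two methanogeneses); all values are user-editable.
#'
#' @param path YAML file; defaults to the shipped catalogue.
#' @param validate check carbon/electron balance of every reaction (default
#'   `TRUE`); an unbalanced reaction is an error.
#' @return an object of class `sf_catalogue`: list with `metabolites`
#'   (data.frame), `species` (data.frame), `reactions` (named list), `y_atp`.
#' @examples
#' cat <- read_catalogue()
#' names(cat$reactions)
#' @export
read_catalogue <- function(path = default_catalogue_path(), validate = TRUE) {
  raw <- yaml::read_yaml(path)
  for (field in c("metabolites", "species", "reactions")) {
    if (is.null(raw[[field]])) stop("catalogue is missing '", field, "'")
  }
  mets <- data.frame(
    id = names(raw$metabolites),
    formula = vapply(raw$metabolites, function(m) {
      if (is.null(m$formula)) NA_character_ else as.character(m$formula)
    }, character(1)),
    phase = vapply(raw$metabolites, function(m) as.character(m$phase), character(1)),
    carbon = vapply(raw$metabolites, function(m) as.numeric(m$carbon), numeric(1)),
    gamma = vapply(raw$metabolites, function(m) as.numeric(m$gamma), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  bad_phase <- setdiff(mets$phase, c("aqueous", "gas", "solid", "biomass"))
  if (length(bad_phase)) stop("unknown phase(s): ", paste(bad_phase, collapse = ", "))
  if (any(mets$carbon < 0) || any(mets$gamma < 0)) {
    stop("carbon and gamma must be nonnegative")
  }
  # gamma must agree with the formula for every CHO compound
  for (i in seq_len(nrow(mets))) {
    f <- mets$formula[i]
    if (!is.na(f)) {
      g <- gamma_from_formula(f)
      if (abs(g - mets$gamma[i]) > 1e-9) {
        stop("gamma of '", mets$id[i], "' (", mets$gamma[i],
             ") disagrees with formula ", f, " (", g, ")")
      }
    }
  }
  species <- data.frame(
    id = names(raw$species),
    description = vapply(raw$species, as.character, character(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  if (anyDuplicated(species$id)) stop("duplicate species ids")
  reactions <- lapply(names(raw$reactions), function(rid) {
    r <- raw$reactions[[rid]]
    st <- unlist(r$stoich)
    unknown <- setdiff(names(st), mets$id)
    if (length(unknown)) {
      stop("reaction '", rid, "' references unknown metabolite(s): ",
           paste(unknown, collapse = ", "))
    }
    if (!r$species %in% species$id) {
      stop("reaction '", rid, "' has unknown species '", r$species, "'")
    }
    if (as.numeric(r$atp_yield) < 0) stop("reaction '", rid, "' has negative atp_yield")
    list(id = rid, species = as.character(r$species),
         stoich = st, atp_yield = as.numeric(r$atp_yield),
         dg0_prime = as.numeric(r$dg0_prime))
  })
  names(reactions) <- names(raw$reactions)
  cat <- structure(
    list(metabolites = mets, species = species, reactions = reactions,
         y_atp = if (is.null(raw$y_atp)) 10.5 else as.numeric(raw$y_atp)),
    class = "sf_catalogue"
  )
  if (validate) {
    for (r in cat$reactions) {
      bal <- validate_balance(r, cat)
      if (!bal$ok) {
        stop("reaction '", r$id, "' is unbalanced (carbon residual ",
             bal$carbon_residual, ", electron residual ", bal$electron_residual, ")")
      }
    }
  }
  cat
}

#' @export
print.sf_catalogue <- function(x, ...) {
  cat("Reaction catalogue:", nrow(x$metabolites), "metabolites,",
      length(x$reactions), "reactions,", nrow(x$species), "species\n")
  for (r in x$reactions) {
    lhs <- r$stoich[r$stoich < 0]
    rhs <- r$stoich[r$stoich > 0]
    fmt <- function(v) paste(ifelse(abs(v) == 1, names(v),
                                    paste0(abs(v), " ", names(v))), collapse = " + ")
    cat(sprintf("  %-30s [%s] %s -> %s\n", r$id, r$species, fmt(lhs), fmt(rhs)))
  }
  invisible(x)
}

#' Check carbon and electron balance of one reaction
#'
#' Residuals are computed over non-biomass metabolites (water and protons are
#' implicit); a balanced reaction has both residuals exactly zero.
#'
#' @param reaction a reaction entry from an [read_catalogue()] catalogue.
#' @param catalogue an `sf_catalogue`.
#' @return list with `carbon_residual`, `electron_residual`, `ok`.
#' @export
validate_balance <- function(reaction, catalogue) {
  st <- reaction$stoich
  unknown <- setdiff(names(st), catalogue$metabolites$id)
  if (length(unknown)) {
    stop("reaction '", reaction$id, "' references unknown metabolite(s): ",
         paste(unknown, collapse = ", "))
  }
  idx <- match(names(st), catalogue$metabolites$id)
  keep <- catalogue$metabolites$phase[idx] != "biomass"
  carbon <- sum(st[keep] * catalogue$metabolites$carbon[idx][keep])
  electron <- sum(st[keep] * catalogue$metabolites$gamma[idx][keep])
  list(carbon_residual = carbon, electron_residual = electron,
       ok = carbon == 0 && electron == 0)
}

#' Build the stoichiometric matrix
#'
#' @param reactions list of reaction entries (catalogue order is preserved in
#'   the columns).
#' @param metabolites character vector of metabolite ids giving the row order.
#' @return numeric matrix, metabolites x reactions; entries are the signed
#'   coefficients (negative = consumed), zero where a metabolite is not
#'   referenced.
#' @examples
#' cat <- read_catalogue()
#' S <- build_matrix(cat$reactions, cat$metabolites$id)
#' @export
build_matrix <- function(reactions, metabolites) {
  S <- matrix(0, nrow = length(metabolites), ncol = length(reactions),
              dimnames = list(metabolites,
                              vapply(reactions, function(r) r$id, character(1))))
  for (r in reactions) {
    unknown <- setdiff(names(r$stoich), metabolites)
    if (length(unknown)) {
      stop("reaction '", r$id, "' references metabolite(s) absent from the row list: ",
           paste(unknown, collapse = ", "))
    }
    S[names(r$stoich), r$id] <- r$stoich
  }
  S
}

#' Couple biomass production to ATP yield
#'
#' Adds a biomass coefficient `y_atp * atp_yield` (g dry weight per mol
#' extent, i.e. mg per mmol) to every reaction, making biomass an explicit
#' product. Biomass is excluded from carbon/electron balance checks.
#'
#' @param catalogue an `sf_catalogue`.
#' @param y_atp g biomass per mol ATP (default from the catalogue, 10.5).
#' @return the modified catalogue.
#' @export
add_biomass <- function(catalogue, y_atp = catalogue$y_atp) {
  if (!"biomass" %in% catalogue$metabolites$id) {
    stop("catalogue has no 'biomass' metabolite")
  }
  catalogue$reactions <- lapply(catalogue$reactions, function(r) {
    r$stoich <- c(r$stoich[names(r$stoich) != "biomass"],
                  biomass = y_atp * r$atp_yield)
    r
  })
  catalogue
}

CANONICAL_SPECIES <- c("Rc", "Mc", "Mh", "Dv")

#' Construct a community assembly
#'
#' @param members character vector of species ids, or a label like
#'   `"Rc&Mc&Dv"`.
#' @return object of class `sf_assembly` with `members` (canonical order) and
#'   `label`.
#' @examples
#' assembly("Rc&Mc")$members
#' @export
assembly <- function(members) {
  if (length(members) == 1L && grepl("&", members)) {
    members <- strsplit(members, "&", fixed = TRUE)[[1]]
  }
  members <- unique(members)
  unknown <- setdiff(members, CANONICAL_SPECIES)
  if (length(unknown)) stop("unknown species id(s): ", paste(unknown, collapse = ", "))
  if (!length(members)) stop("assembly must be non-empty")
  members <- CANONICAL_SPECIES[CANONICAL_SPECIES %in% members]
  structure(list(members = members, label = paste(members, collapse = "&")),
            class = "sf_assembly")
}

#' The eight default community assemblies
#'
#' One mono-culture (Rc), three bi-cultures, three tri-cultures and the
#' quad-culture; the cellulolytic fermenter Rc is present in all of them.
#'
#' @return character vector of assembly labels.
#' @export
default_assemblies <- function() {
  c("Rc", "Rc&Mc", "Rc&Mh", "Rc&Dv",
    "Rc&Mc&Mh", "Rc&Mc&Dv", "Rc&Mh&Dv", "Rc&Mc&Mh&Dv")
}

#' Reactions active in an assembly
#'
#' @param assembly an `sf_assembly` or a label string.
#' @param catalogue an `sf_catalogue`.
#' @return the reactions whose species is a member, in catalogue order.
#' @examples
#' cat <- read_catalogue()
#' names(active_reactions("Rc&Mh", cat))
#' @export
active_reactions <- function(assembly, catalogue) {
  if (is.character(assembly)) assembly <- assembly(assembly)
  Filter(function(r) r$species %in% assembly$members, catalogue$reactions)
}
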