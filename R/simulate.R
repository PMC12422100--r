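# Run expr with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Default true reaction extents per assembly (mmol over the 7-day run)
#'
#' Presets mirror the qualitative regimes of the cellulolytic community:
#' the mono-culture consumes about 1.14 mmol glucose-equivalent (184 mg
#' cellulose), the Rc&Mc bi-culture runs acetoclastic methanogenesis at
#' 0.32 mmol, Rc&Dv runs lactate oxidation at 0.18 mmol, Rc&Mh runs
#' hydrogenotrophic methanogenesis at 0.42 mmol, mixed-acid fermentation
#' vanishes when Mh and Dv co-occur, and the quad-culture routes about
#' 1.36 mmol carbon to CH4. All presets keep daily in-vessel amounts
#' nonnegative under the default fed-batch geometry.
#'
#' @param assembly assembly label or `sf_assembly`.
#' @return named numeric vector of total extents for the active reactions.
#' @export
preset_extents <- function(assembly) {
  if (is.character(assembly)) assembly <- assembly(assembly)
  presets <- list(
    "Rc" = c(lactate_fermentation = 0.50, hydrogenic_acetogenesis = 0.35,
             mixed_acid_fermentation = 0.29),
    "Rc&Mc" = c(lactate_fermentation = 0.50, hydrogenic_acetogenesis = 0.35,
                mixed_acid_fermentation = 0.29,
                acetoclastic_methanogenesis = 0.32),
    "Rc&Mh" = c(lactate_fermentation = 0.45, hydrogenic_acetogenesis = 0.45,
                mixed_acid_fermentation = 0.25,
                hydrogenotrophic_methanogenesis = 0.42),
    "Rc&Dv" = c(lactate_fermentation = 0.55, hydrogenic_acetogenesis = 0.35,
                mixed_acid_fermentation = 0.25,
                hydrogenic_lactate_oxidation = 0.18),
    "Rc&Mc&Mh" = c(lactate_fermentation = 0.50,
                   hydrogenic_acetogenesis = 0.35,
                   mixed_acid_fermentation = 0.05,
                   hydrogenotrophic_methanogenesis = 0.088,
                   acetoclastic_methanogenesis = 0.32),
    "Rc&Mc&Dv" = c(lactate_fermentation = 0.50,
                   hydrogenic_acetogenesis = 0.30,
                   mixed_acid_fermentation = 0.29,
                   hydrogenic_lactate_oxidation = 0.019,
                   acetoclastic_methanogenesis = 0.23),
    "Rc&Mh&Dv" = c(lactate_fermentation = 0.45,
                   hydrogenic_acetogenesis = 0.556,
                   mixed_acid_fermentation = 0,
                   hydrogenic_lactate_oxidation = 0.064,
                   hydrogenotrophic_methanogenesis = 0.55),
    "Rc&Mc&Mh&Dv" = c(lactate_fermentation = 0.06,
                      hydrogenic_acetogenesis = 0.566,
                      mixed_acid_fermentation = 0,
                      hydrogenic_lactate_oxidation = 0.018,
                      hydrogenotrophic_methanogenesis = 0.55,
                      acetoclastic_methanogenesis = 0.81)
  )
  p <- presets[[assembly$label]]
  if (is.null(p)) stop("no preset for assembly '", assembly$label, "'")
  p
}

#' Configuration for the synthetic culture generator
#'
#' @param assembly assembly label or `sf_assembly`.
#' @param days run length (default 7).
#' @param true_extents named total extents (mmol) for the active reactions;
#'   default [preset_extents()]. Extents for inactive reactions are a
#'   config error.
#' @param noise_cv coefficient of variation of the multiplicative Gaussian
#'   measurement noise on concentrations/pressures (default 0.05).
#' @param replicates number of culture replicates (default 3).
#' @param volumes a [culture_volumes()] object.
#' @param initial_gas named initial partial pressures (atm); default 3% H2.
#' @param protein_markers marker proteins per active reaction (default 2).
#' @param protein_noise_cv noise CV for protein abundances (default 0.05).
#' @param background_proteins uncorrelated background proteins (default 20).
#' @param seed integer seed; the single source of randomness.
#' @param catalogue an `sf_catalogue`.
#' @return list of class `sf_genconfig`.
#' @export
generator_config <- function(assembly, days = 7, true_extents = NULL,
                             noise_cv = 0.05, replicates = 3,
                             volumes = culture_volumes(),
                             initial_gas = c(H2 = 0.03),
                             protein_markers = 2, protein_noise_cv = 0.05,
                             background_proteins = 20, seed = 1,
                             catalogue = read_catalogue()) {
  if (is.character(assembly)) assembly <- assembly(assembly)
  if (is.null(true_extents)) true_extents <- preset_extents(assembly)
  active <- vapply(active_reactions(assembly, catalogue),
                   function(r) r$id, character(1))
  extra <- setdiff(names(true_extents), active)
  if (length(extra)) {
    stop("extents given for reaction(s) inactive in ", assembly$label, ": ",
         paste(extra, collapse = ", "))
  }
  if (any(true_extents < 0)) stop("extents must be nonnegative")
  if (noise_cv < 0 || protein_noise_cv < 0) stop("noise CV must be nonnegative")
  full <- stats::setNames(rep(0, length(active)), active)
  full[names(true_extents)] <- true_extents
  structure(list(assembly = assembly, days = days, true_extents = full,
                 noise_cv = noise_cv, replicates = replicates,
                 volumes = volumes, initial_gas = initial_gas,
                 protein_markers = protein_markers,
                 protein_noise_cv = protein_noise_cv,
                 background_proteins = background_proteins,
                 seed = seed, catalogue = catalogue),
            class = "sf_genconfig")
}

#' Simulate a fed-batch culture
#'
#' Ground-truth per-day metabolite increments are `S %*% (daily extents)`
#' (extents spread uniformly over the run); vessel bookkeeping inverts
#' [cumulative_production()]: each day the in-vessel amounts are updated,
#' a reading (concentration in mM or partial pressure in atm) is taken with
#' multiplicative Gaussian noise truncated at zero, and the daily liquid and
#' headspace samples remove their proportional share (replenishment medium
#' carries no analyte). Identical seeds give identical output.
#'
#' @param config a [generator_config()].
#' @return list with `readings` (tidy data.frame `culture`, `replicate`,
#'   `day`, `analyte`, `value`, `unit`), `truth` (noise-free cumulative
#'   net production per analyte/day), `true_extents`, `daily_extents`.
#' @export
simulate_culture <- function(config) {
  stopifnot(inherits(config, "sf_genconfig"))
  cat_ <- config$catalogue
  vol <- config$volumes
  analytes <- c("lactate", "acetate", "ethanol", "H2", "CO2", "CH4")
  analytes <- analytes[analytes %in% cat_$metabolites$id]
  phase <- cat_$metabolites$phase[match(analytes, cat_$metabolites$id)]
  reactions <- active_reactions(config$assembly, cat_)
  S <- build_matrix(reactions, cat_$metabolites$id)[analytes, , drop = FALSE]
  n_d <- config$days
  daily_extents <- matrix(config$true_extents / n_d, ncol(S), n_d,
                          dimnames = list(colnames(S), NULL))
  delta <- S %*% daily_extents  # mmol produced per analyte per day
  # initial in-vessel amounts (mmol)
  a0 <- stats::setNames(rep(0, length(analytes)), analytes)
  for (g in names(config$initial_gas)) {
    if (g %in% analytes) {
      a0[g] <- gas_mmol(config$initial_gas[[g]], vol$headspace_ml,
                        vol$temperature_k)
    }
  }
  keep_liq <- 1 - vol$sampled_liquid_ml / vol$liquid_ml
  keep_gas <- 1 - vol$sampled_gas_ml / vol$headspace_ml
  keep <- ifelse(phase == "gas", keep_gas, keep_liq)
  # true in-vessel trajectory: amount measured on day d (before sampling)
  amounts <- matrix(0, length(analytes), n_d + 1,
                    dimnames = list(analytes, 0:n_d))
  amounts[, 1] <- a0
  a <- a0
  for (d in seq_len(n_d)) {
    a <- a * keep + delta[, d]
    if (any(a < -1e-9)) {
      stop("infeasible extents: in-vessel amount of ",
           paste(analytes[a < -1e-9], collapse = ", "),
           " becomes negative on day ", d)
    }
    a <- pmax(a, 0)
    amounts[, d + 1] <- a
  }
  to_reading <- function(amount) {
    ifelse(phase == "gas",
           amount / 1000 * R_GAS * vol$temperature_k /
             (vol$headspace_ml * 1e-6) / ATM_PA,
           amount * 1000 / vol$liquid_ml)
  }
  true_values <- apply(amounts, 2, to_reading)
  truth_cum <- t(apply(delta, 1, cumsum))
  if (n_d == 1) truth_cum <- matrix(delta, ncol = 1, dimnames = dimnames(delta))
  truth <- data.frame(
    culture = config$assembly$label,
    analyte = rep(analytes, n_d + 1),
    day = rep(0:n_d, each = length(analytes)),
    mmol = as.numeric(cbind(0, truth_cum)),
    stringsAsFactors = FALSE
  )
  readings <- with_seed(config$seed, {
    do.call(rbind, lapply(seq_len(config$replicates), function(rep_id) {
      noise <- matrix(stats::rnorm(length(true_values), 0, config$noise_cv),
                      nrow(true_values), ncol(true_values))
      vals <- pmax(true_values * (1 + noise), 0)
      data.frame(
        culture = config$assembly$label, replicate = rep_id,
        day = rep(0:n_d, each = length(analytes)),
        analyte = rep(analytes, n_d + 1),
        value = as.numeric(vals),
        unit = rep(ifelse(phase == "gas", "atm", "mM"), n_d + 1),
        stringsAsFactors = FALSE
      )
    }))
  })
  rownames(readings) <- NULL
  list(readings = readings, truth = truth,
       true_extents = config$true_extents, daily_extents = daily_extents)
}

#' Simulate a matched protein-abundance table
#'
#' Each active reaction gets `protein_markers` marker proteins whose
#' abundance is proportional to the reaction's total extent (with
#' multiplicative noise); reactions with zero extent sit at a small
#' background level, as do the uncorrelated background proteins. Abundances
#' are normalized per species so that each species' proteins sum to 1,
#' mirroring normalization against each species' total proteome.
#'
#' @param config a [generator_config()].
#' @param background_level abundance floor for inactive markers and
#'   background proteins (default 1e-3).
#' @return list with `abundance` (matrix, proteins x 1 culture column) and
#'   `mapping` (data.frame `protein`, `reaction`, `species`; background
#'   proteins have `NA` reaction).
#' @export
simulate_proteins <- function(config, background_level = 1e-3) {
  stopifnot(inherits(config, "sf_genconfig"))
  reactions <- active_reactions(config$assembly, config$catalogue)
  members <- config$assembly$members
  with_seed(config$seed + 1L, {
    rows <- list()
    for (r in reactions) {
      xi <- config$true_extents[[r$id]]
      for (k in seq_len(config$protein_markers)) {
        base <- if (xi > 0) xi else background_level
        ab <- max(base * (1 + stats::rnorm(1, 0, config$protein_noise_cv)), 0)
        rows[[length(rows) + 1]] <- data.frame(
          protein = paste0(r$id, "_marker", k), reaction = r$id,
          species = r$species, abundance = ab, stringsAsFactors = FALSE)
      }
    }
    for (k in seq_len(config$background_proteins)) {
      sp <- members[(k - 1) %% length(members) + 1]
      ab <- max(background_level *
                  (1 + stats::rnorm(1, 0, config$protein_noise_cv)), 0)
      rows[[length(rows) + 1]] <- data.frame(
        protein = paste0("background_", k), reaction = NA_character_,
        species = sp, abundance = ab, stringsAsFactors = FALSE)
    }
    tab <- do.call(rbind, rows)
    # per-species normalization to a total of 1
    for (sp in members) {
      idx <- tab$species == sp
      tot <- sum(tab$abundance[idx])
      if (tot > 0) tab$abundance[idx] <- tab$abundance[idx] / tot
    }
    abundance <- matrix(tab$abundance, ncol = 1,
                        dimnames = list(tab$protein, config$assembly$label))
    list(abundance = abundance,
         mapping = tab[, c("protein", "reaction", "species")])
  })
}

#' End-to-end parameter-recovery check
#'
#' Simulates a culture, rebuilds cumulative production from the readings,
#' refits extents, and compares them with the generator's truth.
#'
#' @param config a [generator_config()].
#' @param mode,lambda passed to [fit_culture()].
#' @param use_prior build a proteomics prior from [simulate_proteins()]
#'   (ATP scaling `"none"`, matching the generator's abundance model) and
#'   use it with the given `lambda`; needed for identifiability whenever the
#'   active stoichiometry is rank-deficient (Rc and Dv together).
#' @return list with `max_rel_error` and `median_rel_error` (over reactions
#'   with positive true extent), `max_abs_error_zero` (reactions with zero
#'   truth), `r_squared`, `nrmse`, `extents`, `true_extents`, `fit`.
#' @export
round_trip_check <- function(config, mode = "endpoint", lambda = 0,
                             use_prior = FALSE) {
  sim <- simulate_culture(config)
  cum <- cumulative_production(sim$readings, config$catalogue, config$volumes)
  prior <- NULL
  if (use_prior) {
    pr <- simulate_proteins(config)
    prior <- proteomics_prior(pr$abundance, pr$mapping, config$catalogue,
                              culture = config$assembly$label,
                              total_scale = sum(config$true_extents),
                              atp_scaling = "none")
  }
  fit <- fit_culture(cum, config$assembly, config$catalogue, mode = mode,
                     lambda = lambda, prior = prior)
  est <- fit$extent_mean[names(config$true_extents)]
  truth <- config$true_extents
  pos <- truth > 0
  rel <- abs(est[pos] - truth[pos]) / truth[pos]
  list(max_rel_error = if (any(pos)) max(rel) else 0,
       median_rel_error = if (any(pos)) stats::median(rel) else 0,
       max_abs_error_zero = if (any(!pos)) max(abs(est[!pos])) else 0,
       r_squared = fit$r_squared, nrmse = fit$nrmse,
       extents = est, true_extents = truth, fit = fit)
}
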