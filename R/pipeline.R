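#' Assemble a pipeline run configuration
#'
#' @param measurements path to a tidy measurement CSV/TSV (see
#'   [read_measurements()]) or a data.frame of readings.
#' @param out_dir output directory (created if needed).
#' @param catalogue catalogue YAML path or an `sf_catalogue`.
#' @param proteins optional list with `abundance` (path or table) and
#'   `mapping` (path or data.frame `protein`, `reaction`); engaged when
#'   `lambda > 0`.
#' @param mode fit mode, `"endpoint"` or `"trajectory"`.
#' @param lambda shrinkage weight toward the proteomics prior.
#' @param convention exchange-edge convention (see [infer_exchanges()]).
#' @param products products for the element ledger.
#' @param default_activities named list with optional `aqueous` (mol/L) and
#'   `gas` (atm) activities for reaction participants that are not measured
#'   (the default supplies a nominal 1 mM glucose for the fermentation
#'   quotients).
#' @param volumes a [culture_volumes()] object.
#' @param seed integer seed recorded in every output and used for any
#'   stochastic step.
#' @return list of class `sf_runconfig`.
#' @export
run_config <- function(measurements, out_dir, catalogue = NULL,
                       proteins = NULL, mode = "endpoint", lambda = 0,
                       convention = "consumer_extent",
                       products = c("CH4", "CO2"),
                       default_activities = list(aqueous = c(glucose = 1e-3)),
                       volumes = culture_volumes(), seed = 1) {
  structure(list(measurements = measurements, out_dir = out_dir,
                 catalogue = catalogue, proteins = proteins, mode = mode,
                 lambda = lambda, convention = convention,
                 products = products,
                 default_activities = default_activities,
                 volumes = volumes, seed = seed),
            class = "sf_runconfig")
}

stage_run <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("[", stage, "] ", conditionMessage(e), call. = FALSE)
  })
}

# Mean final-day chemical state of one culture from its raw readings.
# Activities are floored at a detection-limit value so that an analyte
# reported as zero (below detection) does not make a reaction quotient
# degenerate.
state_from_readings <- function(readings, catalogue, defaults,
                                floor = 1e-6) {
  final_day <- max(readings$day)
  d <- readings[readings$day == final_day, ]
  agg <- stats::aggregate(value ~ analyte + unit, data = d, FUN = mean)
  aqueous <- defaults$aqueous
  gas <- defaults$gas
  for (i in seq_len(nrow(agg))) {
    if (agg$unit[i] == "atm") {
      gas[agg$analyte[i]] <- max(agg$value[i], floor)
    } else {
      aqueous[agg$analyte[i]] <- max(agg$value[i] / 1000, floor)  # mM -> mol/L
    }
  }
  chemical_state(aqueous = if (is.null(aqueous)) numeric(0) else aqueous,
                 gas = if (is.null(gas)) numeric(0) else gas)
}

#' Run the full analysis pipeline
#'
#' Executes measurements -> fit -> exchange -> thermo -> elements -> stats
#' for every culture in the input, writing CSV tables and a JSON report to
#' the output directory. Fold-change comparisons are computed for every
#' pair of cultures that differ by the addition of a single species. All
#' outputs embed the seed and a hash of the effective configuration; any
#' stage failure raises an error tagged with the stage name.
#'
#' @param config an [run_config()] (or a list coercible to one).
#' @return invisibly, the report bundle (list of all tables and fits).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "sf_runconfig")) config <- do.call(run_config, config)
  cat_ <- stage_run("catalogue", {
    if (inherits(config$catalogue, "sf_catalogue")) config$catalogue
    else if (is.null(config$catalogue)) read_catalogue()
    else read_catalogue(config$catalogue)
  })
  readings <- stage_run("measurements", {
    if (is.data.frame(config$measurements)) config$measurements
    else read_measurements(config$measurements, cat_)
  })
  cum <- stage_run("measurements",
                   cumulative_production(readings, cat_, config$volumes))
  cultures <- unique(cum$culture)
  prior_for <- function(culture) {
    if (is.null(config$proteins) || config$lambda <= 0) return(NULL)
    ab <- config$proteins$abundance
    if (is.character(ab)) {
      ab <- utils::read.table(ab, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE, check.names = FALSE)
    }
    mp <- config$proteins$mapping
    if (is.character(mp)) {
      mp <- utils::read.table(mp, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
    }
    proteomics_prior(ab, mp, cat_, culture)
  }
  fits <- stage_run("fit", {
    out <- lapply(cultures, function(cu) {
      fit_culture(cum[cum$culture == cu, ], cu, cat_, mode = config$mode,
                  lambda = config$lambda, prior = prior_for(cu))
    })
    names(out) <- cultures
    out
  })
  exchanges <- stage_run("exchange", {
    tabs <- lapply(cultures, function(cu) {
      e <- infer_exchanges(fits[[cu]], catalogue = cat_,
                           convention = config$convention)
      if (nrow(e)) cbind(culture = cu, e) else NULL
    })
    do.call(rbind, tabs)
  })
  thermo <- stage_run("thermo", {
    tabs <- lapply(cultures, function(cu) {
      st <- state_from_readings(readings[readings$culture == cu, ], cat_,
                                config$default_activities)
      thermo_table(cu, cat_, st)
    })
    do.call(rbind, tabs)
  })
  elements <- stage_run("elements", {
    tabs <- lapply(cultures, function(cu) {
      transfer_to_products(cum[cum$culture == cu, ], config$products, cat_)
    })
    do.call(rbind, tabs)
  })
  comparisons <- stage_run("stats", {
    tabs <- list()
    for (a in cultures) {
      for (b in cultures) {
        ma <- assembly(a)$members; mb <- assembly(b)$members
        if (length(mb) == length(ma) + 1 && all(ma %in% mb)) {
          tabs[[paste(a, b)]] <- flux_fold_changes(
            fits[[a]]$extents, fits[[b]]$extents, label_a = a, label_b = b)
        }
      }
    }
    if (length(tabs)) do.call(rbind, tabs) else NULL
  })
  extents_tab <- do.call(rbind, lapply(cultures, function(cu) {
    f <- fits[[cu]]
    data.frame(culture = cu, reaction = f$reactions,
               extent_mmol = unname(f$extent_mean),
               sd = unname(f$extent_sd), stringsAsFactors = FALSE)
  }))
  bundle <- list(cumulative = cum, fits = fits, extents = extents_tab,
                 exchanges = exchanges, thermo = thermo, elements = elements,
                 comparisons = comparisons)
  stage_run("report", {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, name) {
      if (!is.null(df)) {
        utils::write.csv(df, file.path(config$out_dir, name), row.names = FALSE)
      }
    }
    wr(cum, "cumulative.csv")
    wr(extents_tab, "extents.csv")
    wr(exchanges, "exchanges.csv")
    wr(thermo, "thermo.csv")
    wr(elements, "elements.csv")
    wr(comparisons, "comparisons.csv")
    cfg_echo <- config[c("mode", "lambda", "convention", "products", "seed")]
    cfg_file <- tempfile(fileext = ".json")
    jsonlite::write_json(cfg_echo, cfg_file, auto_unbox = TRUE, digits = NA)
    report <- list(
      package_version = as.character(utils::packageVersion("syntroflux")),
      seed = config$seed,
      config = cfg_echo,
      config_hash = unname(tools::md5sum(cfg_file)),
      fit_quality = lapply(fits, function(f) {
        list(r_squared = f$r_squared, nrmse = f$nrmse,
             rank_deficient = f$rank_deficient)
      })
    )
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })
  invisible(bundle)
}
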