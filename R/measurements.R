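#' Vessel and sampling geometry of the fed-batch cultures
#'
#' Defaults follow the culture design: 160 ml bottles with 20 ml liquid
#' (140 ml headspace), 2 ml liquid sampled and replenished daily with fresh
#' medium, 5 ml headspace gas sampled daily, incubation at 34 degrees C
#' (307.15 K) for gas bookkeeping.
#'
#' @param liquid_ml liquid volume (ml).
#' @param headspace_ml headspace volume (ml).
#' @param sampled_liquid_ml liquid removed per day (ml); replenished with
#'   analyte-free medium.
#' @param sampled_gas_ml headspace gas removed per day (ml).
#' @param temperature_k incubation temperature used for gas mole conversion.
#' @return list of class `sf_volumes`.
#' @export
culture_volumes <- function(liquid_ml = 20, headspace_ml = 140,
                            sampled_liquid_ml = 2, sampled_gas_ml = 5,
                            temperature_k = 307.15) {
  stopifnot(liquid_ml > 0, headspace_ml > 0,
            sampled_liquid_ml >= 0, sampled_gas_ml >= 0, temperature_k > 0)
  structure(list(liquid_ml = liquid_ml, headspace_ml = headspace_ml,
                 sampled_liquid_ml = sampled_liquid_ml,
                 sampled_gas_ml = sampled_gas_ml,
                 temperature_k = temperature_k),
            class = "sf_volumes")
}

#' Moles of an ideal gas from partial pressure
#'
#' @param pressure_atm partial pressure (atm).
#' @param headspace_ml gas volume (ml).
#' @param temperature_k temperature (K).
#' @return mmol of gas (`n = P V / (R T)`).
#' @examples
#' gas_mmol(1, 140, 298.15)  # about 5.72 mmol
#' @export
gas_mmol <- function(pressure_atm, headspace_ml, temperature_k) {
  if (any(temperature_k <= 0)) stop("temperature must be positive")
  if (any(pressure_atm < 0) || any(headspace_ml < 0)) {
    stop("pressure and volume must be nonnegative")
  }
  pressure_atm * ATM_PA * headspace_ml * 1e-6 / (R_GAS * temperature_k) * 1000
}

#' Cumulative net production from daily fed-batch readings
#'
#' Converts per-day concentration (mM, aqueous) or partial-pressure (atm,
#' gas) readings into cumulative net production since day 0 (mmol),
#' correcting for the daily sampling: the amount removed with each sample is
#' credited back, and the daily medium replenishment contributes no analyte.
#' For an aqueous analyte at volume V with daily sample v,
#' `cumulative[d] = (V*C_d + sum_{k<d} v*C_k - V*C_0) / 1000`;
#' gas analytes use the same bookkeeping with amounts from [gas_mmol()].
#'
#' @param readings data.frame with columns `culture`, `replicate`, `day`,
#'   `analyte`, `value` (one culture/replicate/analyte series, or several;
#'   they are split internally). Days must be contiguous from 0.
#' @param catalogue an `sf_catalogue` (determines phase of each analyte).
#' @param volumes a [culture_volumes()] object.
#' @return data.frame `culture`, `replicate`, `analyte`, `day`, `mmol`
#'   (cumulative net production; 0 at day 0).
#' @examples
#' cat <- read_catalogue()
#' r <- data.frame(culture = "Rc", replicate = 1, day = 0:2,
#'                 analyte = "acetate", value = c(0, 1, 2))
#' cumulative_production(r, cat)
#' @export
cumulative_production <- function(readings, catalogue,
                                  volumes = culture_volumes()) {
  req <- c("culture", "replicate", "day", "analyte", "value")
  missing_cols <- setdiff(req, names(readings))
  if (length(missing_cols)) {
    stop("readings are missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  unknown <- setdiff(unique(readings$analyte), catalogue$metabolites$id)
  if (length(unknown)) {
    stop("unknown analyte(s): ", paste(unknown, collapse = ", "))
  }
  if (any(readings$value < 0)) stop("negative concentration/pressure reading")
  key <- interaction(readings$culture, readings$replicate, readings$analyte,
                     drop = TRUE)
  out <- lapply(split(readings, key), function(d) {
    d <- d[order(d$day), ]
    days <- d$day
    if (days[1] != 0 || any(diff(days) != 1)) {
      stop("days must be contiguous from 0 for ", d$culture[1], "/",
           d$replicate[1], "/", d$analyte[1])
    }
    phase <- catalogue$metabolites$phase[match(d$analyte[1], catalogue$metabolites$id)]
    if (phase == "gas") {
      amount <- gas_mmol(d$value, volumes$headspace_ml, volumes$temperature_k)
      removed <- gas_mmol(d$value, volumes$sampled_gas_ml, volumes$temperature_k)
    } else {
      amount <- volumes$liquid_ml * d$value / 1000
      removed <- volumes$sampled_liquid_ml * d$value / 1000
    }
    cum <- amount + c(0, cumsum(removed)[-length(removed)]) - amount[1]
    data.frame(culture = d$culture, replicate = d$replicate,
               analyte = d$analyte, day = days, mmol = cum,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$culture, res$replicate, res$analyte, res$day), , drop = FALSE]
}

#' Read a tidy measurement table
#'
#' Expects a CSV or TSV with header `culture, replicate, day, analyte,
#' value, unit`. Units are normalized to mM (aqueous: `mM`, `uM`/`µM`, `M`)
#' and atm (gas: `atm`, `kPa`, `bar`). Unknown analytes (when a catalogue is
#' supplied) and duplicate (culture, replicate, day, analyte) keys are
#' rejected.
#'
#' @param path file path; delimiter inferred from the extension (`.tsv` =
#'   tab, otherwise comma).
#' @param catalogue optional `sf_catalogue` used to reject unknown analytes.
#' @return data.frame of typed readings with values in mM / atm.
#' @export
read_measurements <- function(path, catalogue = NULL) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = TRUE)
  req <- c("culture", "replicate", "day", "analyte", "value", "unit")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("measurement file is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0) return(df[, req])
  bad <- which(is.na(suppressWarnings(as.numeric(df$value))) |
                 is.na(suppressWarnings(as.integer(df$day))))
  if (length(bad)) {
    stop("malformed row(s) at line(s) ",
         paste(bad + 1L, collapse = ", "), " of ", path)
  }
  df$value <- as.numeric(df$value)
  df$day <- as.integer(df$day)
  conv <- c(mM = 1, uM = 1e-3, M = 1e3, atm = 1, kPa = 1 / 101.325,
            bar = 1 / 1.01325)
  unit <- df$unit
  unit[unit == "µM"] <- "uM"
  unknown_units <- setdiff(unique(unit), names(conv))
  if (length(unknown_units)) {
    stop("unknown unit(s): ", paste(unknown_units, collapse = ", "))
  }
  df$value <- df$value * conv[unit]
  df$unit <- ifelse(unit %in% c("mM", "uM", "M"), "mM", "atm")
  if (!is.null(catalogue)) {
    unknown <- setdiff(unique(df$analyte), catalogue$metabolites$id)
    if (length(unknown)) {
      stop("unknown analyte(s): ", paste(unknown, collapse = ", "))
    }
  }
  key <- paste(df$culture, df$replicate, df$day, df$analyte, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- df[duplicated(key), , drop = FALSE][1, ]
    stop("duplicate reading for (", dup$culture, ", ", dup$replicate, ", day ",
         dup$day, ", ", dup$analyte, ")")
  }
  df[, req]
}
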