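#' Carbon and electron content of an amount of metabolite
#'
#' Linear scaling of the amount by the catalogue's carbon count and degree
#' of reduction (electron equivalents per mole).
#'
#' @param metabolite metabolite id.
#' @param amount_mmol amount (mmol, nonnegative).
#' @param catalogue an `sf_catalogue`.
#' @return list with `carbon_mmol` and `electron_mmol`.
#' @examples
#' cat <- read_catalogue()
#' element_content("CH4", 1, cat)  # 1 mmol C, 8 mmol e-
#' @export
element_content <- function(metabolite, amount_mmol, catalogue) {
  i <- match(metabolite, catalogue$metabolites$id)
  if (is.na(i)) stop("unknown metabolite '", metabolite, "'")
  if (any(amount_mmol < 0)) stop("amount must be nonnegative")
  list(carbon_mmol = amount_mmol * catalogue$metabolites$carbon[i],
       electron_mmol = amount_mmol * catalogue$metabolites$gamma[i])
}

#' Carbon and electron transfer ledger to products
#'
#' Computes, per product, the carbon (mmol C) and electron equivalents
#' (mmol e-) contained in the final cumulative net production, either from
#' a cumulative measurement table or from a fitted model's predicted
#' production (`S %*% extents`).
#'
#' @param x a cumulative data.frame from [cumulative_production()] (columns
#'   `culture`, `replicate`, `analyte`, `day`, `mmol`) or an `sf_fit`.
#' @param products character vector of product metabolite ids (e.g.
#'   `c("CH4", "CO2")`).
#' @param catalogue an `sf_catalogue`.
#' @return data.frame `culture`, `product`, `amount_mmol`, `carbon_mmol`,
#'   `electron_mmol` (replicate-averaged final cumulative amounts), with a
#'   `totals` attribute summing across products.
#' @export
transfer_to_products <- function(x, products, catalogue) {
  if (inherits(x, "sf_fit")) {
    pred <- as.numeric(x$S %*% x$extent_mean)
    names(pred) <- rownames(x$S)
    culture <- x$assembly$label
    amounts <- vapply(products, function(p) {
      if (!p %in% names(pred)) 0 else max(pred[[p]], 0)
    }, numeric(1))
  } else {
    culture <- as.character(unique(x$culture))
    if (length(culture) != 1L) stop("expected a single culture")
    final_day <- max(x$day)
    amounts <- vapply(products, function(p) {
      v <- x$mmol[x$analyte == p & x$day == final_day]
      if (!length(v)) 0 else max(mean(v), 0)
    }, numeric(1))
  }
  rows <- do.call(rbind, lapply(seq_along(products), function(i) {
    ec <- element_content(products[i], amounts[i], catalogue)
    data.frame(culture = culture, product = products[i],
               amount_mmol = amounts[i],
               carbon_mmol = ec$carbon_mmol, electron_mmol = ec$electron_mmol,
               stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  attr(rows, "totals") <- c(carbon_mmol = sum(rows$carbon_mmol),
                            electron_mmol = sum(rows$electron_mmol))
  rows
}
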