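# Per-species net production/consumption of each metabolite, with
# intra-species recycling (a species consuming its own product) netted out.
species_net_flows <- function(extents, assembly, catalogue) {
  if (is.character(assembly)) assembly <- assembly(assembly)
  reactions <- active_reactions(assembly, catalogue)
  rids <- vapply(reactions, function(r) r$id, character(1))
  missing_r <- setdiff(rids, names(extents))
  if (length(missing_r)) {
    stop("extents missing for active reaction(s): ",
         paste(missing_r, collapse = ", "))
  }
  mets <- setdiff(catalogue$metabolites$id[catalogue$metabolites$phase != "biomass"],
                  character(0))
  prod <- cons <- matrix(0, length(assembly$members), length(mets),
                         dimnames = list(assembly$members, mets))
  for (r in reactions) {
    xi <- extents[[r$id]]
    for (m in names(r$stoich)) {
      if (!m %in% mets) next
      coef <- r$stoich[[m]]
      if (coef > 0) prod[r$species, m] <- prod[r$species, m] + coef * xi
      if (coef < 0) cons[r$species, m] <- cons[r$species, m] - coef * xi
    }
  }
  net_prod <- pmax(prod - cons, 0)
  net_cons <- pmax(cons - prod, 0)
  list(prod = prod, cons = cons, net_prod = net_prod, net_cons = net_cons,
       assembly = assembly, reactions = reactions)
}

#' Infer the interspecies exchange network from fitted extents
#'
#' For every shared metabolite, each species' net production and net intake
#' are computed from extents times stoichiometric coefficients
#' (intra-species recycling is netted out first), and each receiver's intake
#' is allocated to donors in proportion to their production shares. Two edge
#' amount conventions are available: `"consumer_extent"` reports the extent
#' of the receiving reaction(s) attributed to the donor (so a bi-culture
#' edge whose consuming coefficient is -1 equals the consuming reaction's
#' extent), `"metabolite_total"` reports the summed mmol of the transferred
#' metabolites. Edges with zero amount are dropped.
#'
#' @param fit an `sf_fit` (its mean extents are used) or a named vector of
#'   extents (mmol).
#' @param assembly assembly label or `sf_assembly`; defaults to the fit's.
#' @param catalogue an `sf_catalogue`.
#' @param convention `"consumer_extent"` (default) or `"metabolite_total"`.
#' @return data.frame with columns `donor`, `receiver`, `metabolites`
#'   (comma-separated), `amount` (mmol), `convention`. Mono-cultures yield
#'   zero rows.
#' @export
infer_exchanges <- function(fit, assembly = NULL, catalogue,
                            convention = c("consumer_extent", "metabolite_total")) {
  convention <- match.arg(convention)
  if (inherits(fit, "sf_fit")) {
    if (is.null(assembly)) assembly <- fit$assembly
    extents <- fit$extent_mean
  } else {
    extents <- fit
    if (is.null(assembly)) stop("assembly required when passing raw extents")
  }
  if (is.character(assembly)) assembly <- assembly(assembly)
  empty <- data.frame(donor = character(0), receiver = character(0),
                      metabolites = character(0), amount = numeric(0),
                      convention = character(0), stringsAsFactors = FALSE)
  if (length(assembly$members) < 2) return(empty)
  fl <- species_net_flows(extents, assembly, catalogue)
  mets <- colnames(fl$net_prod)
  # donor production share per metabolite
  share <- matrix(0, nrow(fl$net_prod), length(mets),
                  dimnames = dimnames(fl$net_prod))
  for (m in mets) {
    tot <- sum(fl$net_prod[, m])
    if (tot > 0) share[, m] <- fl$net_prod[, m] / tot
  }
  # mmol transferred donor -> receiver per metabolite
  transfer <- array(0, c(nrow(share), nrow(share), length(mets)),
                    dimnames = list(rownames(share), rownames(share), mets))
  for (m in mets) {
    for (rcv in rownames(share)) {
      intake <- fl$net_cons[rcv, m]
      if (intake <= 0) next
      avail <- sum(fl$net_prod[, m])
      if (avail <= 0) next  # supplied from initial conditions, no donor edge
      intake <- min(intake, avail)
      transfer[, rcv, m] <- intake * share[, m]
      transfer[rcv, rcv, m] <- 0
    }
  }
  rows <- list()
  for (donor in rownames(share)) {
    for (rcv in rownames(share)) {
      if (donor == rcv) next
      moved <- transfer[donor, rcv, ]
      met_set <- mets[moved > 0]
      if (!length(met_set)) next
      if (convention == "metabolite_total") {
        amount <- sum(moved)
      } else {
        # extent of the receiving reactions attributed to this donor:
        # weight each consuming reaction's extent by the externally supplied,
        # donor-attributed fraction of the metabolites it consumes
        amount <- 0
        for (r in fl$reactions) {
          if (r$species != rcv) next
          consumed <- -r$stoich[r$stoich < 0]
          consumed <- consumed[names(consumed) %in% mets]
          if (!length(consumed)) next
          xi <- extents[[r$id]]
          if (xi <= 0) next
          w <- consumed * xi  # mmol of each metabolite this reaction consumes
          frac <- vapply(names(consumed), function(m) {
            if (fl$cons[rcv, m] <= 0) return(0)
            # fraction of the receiver's consumption of m supplied by donor
            transfer[donor, rcv, m] / fl$cons[rcv, m]
          }, numeric(1))
          amount <- amount + xi * sum(w * frac) / sum(w)
        }
      }
      if (amount > 0) {
        rows[[length(rows) + 1]] <- data.frame(
          donor = donor, receiver = rcv,
          metabolites = paste(met_set, collapse = ","),
          amount = amount, convention = convention, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  # long per-metabolite transfer table (mmol), useful for conservation checks
  tl <- which(transfer > 0, arr.ind = TRUE)
  attr(out, "transfers") <- data.frame(
    donor = rownames(share)[tl[, 1]], receiver = rownames(share)[tl[, 2]],
    metabolite = mets[tl[, 3]], mmol = transfer[tl], stringsAsFactors = FALSE)
  out
}

#' Compare two exchange networks edge by edge
#'
#' Edges are keyed by (donor, receiver, metabolite set). An edge present in
#' only one network is flagged `"emergent"` (only in B) or `"lost"` (only in
#' A) with the absent side treated as 0.
#'
#' @param edges_a,edges_b edge tables from [infer_exchanges()].
#' @return data.frame with `donor`, `receiver`, `metabolites`, `amount_a`,
#'   `amount_b`, `difference`, `pct_change` (100 * (B - A) / A; `NA` for
#'   emergent edges), `status` in `{"shared", "emergent", "lost"}`.
#' @export
compare_exchanges <- function(edges_a, edges_b) {
  key <- function(e) paste(e$donor, e$receiver, e$metabolites, sep = "|")
  ka <- key(edges_a); kb <- key(edges_b)
  all_keys <- union(ka, kb)
  out <- do.call(rbind, lapply(all_keys, function(k) {
    ia <- match(k, ka); ib <- match(k, kb)
    a <- if (is.na(ia)) 0 else edges_a$amount[ia]
    b <- if (is.na(ib)) 0 else edges_b$amount[ib]
    src <- if (is.na(ia)) edges_b[ib, ] else edges_a[ia, ]
    status <- if (is.na(ia)) "emergent" else if (is.na(ib)) "lost" else "shared"
    data.frame(donor = src$donor, receiver = src$receiver,
               metabolites = src$metabolites,
               amount_a = a, amount_b = b, difference = b - a,
               pct_change = if (a > 0) 100 * (b - a) / a else NA_real_,
               status = status, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
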