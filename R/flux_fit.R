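# Per-analyte scales used both as fit weights and for range-normalized
# goodness of fit: the observed range of each analyte, floored at 1% of the
# largest range so that a flat analyte cannot get infinite weight.
analyte_scales <- function(observed, analyte) {
  rng <- tapply(observed, analyte, function(v) diff(range(v)))
  mx <- max(rng)
  if (mx == 0) return(rng * 0 + 1)
  pmax(rng, 0.01 * mx)
}

#' Nonnegative least-squares fit of reaction extents
#'
#' Solves `argmin_{xi >= 0} ||W (S xi - y)||^2 + lambda ||xi - a||^2` with
#' the deterministic Lawson-Hanson active-set algorithm
#' ([pracma::lsqnonneg()]). With `y` a matrix (analytes x days, days 1..D of
#' cumulative production) a trajectory fit is performed: per-day extents are
#' constrained nonnegative and their running sums are fitted to each day's
#' cumulative vector; reported extents are the per-day sums.
#'
#' @param S stoichiometric matrix (analytes x reactions), e.g. a row subset
#'   of [build_matrix()].
#' @param y observed cumulative net production: numeric vector (endpoint
#'   mode, one value per row of `S`) or matrix (trajectory mode, one column
#'   per day).
#' @param weights per-analyte weights (default all 1); row `a` of the system
#'   is multiplied by `weights[a]`.
#' @param prior named numeric vector of prior extents `a` (mmol), e.g. from
#'   [proteomics_prior()]; required when `lambda > 0`.
#' @param lambda nonnegative shrinkage weight toward the prior; 0 = pure
#'   nonnegative least squares.
#' @return list of class `sf_nnls`: `extents` (named, mmol), `fitted`
#'   (same shape as `y`), `residuals`, `objective`, `rank_deficient`
#'   (TRUE when `S` lacks full column rank and `lambda == 0`, in which case
#'   the reported solution is the deterministic active-set representative of
#'   a non-unique optimum), `daily` (per-day extent matrix, trajectory mode).
#' @examples
#' cat <- read_catalogue()
#' S <- build_matrix(active_reactions("Rc&Mc", cat), cat$metabolites$id)
#' S <- S[c("lactate", "acetate", "ethanol", "H2", "CO2", "CH4"), ]
#' y <- as.numeric(S %*% c(0.5, 0.35, 0.29, 0.32))
#' fit_extents(S, y)$extents
#' @export
fit_extents <- function(S, y, weights = NULL, prior = NULL, lambda = 0) {
  stopifnot(is.matrix(S), lambda >= 0)
  n_r <- ncol(S)
  if (is.null(weights)) weights <- rep(1, nrow(S))
  weights <- as.numeric(weights)
  if (length(weights) != nrow(S)) stop("weights must have one entry per row of S")
  if (lambda > 0 && is.null(prior)) stop("lambda > 0 requires a prior")
  a <- rep(0, n_r)
  if (!is.null(prior)) {
    pv <- if (is.list(prior)) prior$a else prior
    if (!is.null(names(pv)) && !is.null(colnames(S))) {
      missing_r <- setdiff(colnames(S), names(pv))
      if (length(missing_r)) stop("prior is missing reaction(s): ",
                                  paste(missing_r, collapse = ", "))
      a <- unname(pv[colnames(S)])
    } else {
      stopifnot(length(pv) == n_r)
      a <- unname(pv)
    }
  }
  WS <- S * weights
  trajectory <- is.matrix(y)
  if (trajectory) {
    if (nrow(y) != nrow(S)) stop("y must have one row per row of S")
    n_d <- ncol(y)
    # block system: day d sees the running sum of per-day extents
    A <- matrix(0, nrow(S) * n_d, n_r * n_d)
    for (d in seq_len(n_d)) {
      for (k in seq_len(d)) {
        A[(d - 1) * nrow(S) + seq_len(nrow(S)),
          (k - 1) * n_r + seq_len(n_r)] <- WS
      }
    }
    b <- as.numeric(y * weights)
    if (lambda > 0) {
      A <- rbind(A, sqrt(lambda) * do.call(cbind, rep(list(diag(n_r)), n_d)))
      b <- c(b, sqrt(lambda) * a)
    }
    sol <- pracma::lsqnonneg(A, b)
    daily <- matrix(sol$x, nrow = n_r, ncol = n_d,
                    dimnames = list(colnames(S), NULL))
    extents <- rowSums(daily)
    cum_ext <- daily
    if (n_d > 1) for (d in 2:n_d) cum_ext[, d] <- cum_ext[, d - 1] + daily[, d]
    fitted <- S %*% cum_ext
    dimnames(fitted) <- dimnames(y)
    rank_def <- qr(A)$rank < ncol(A)
  } else {
    if (length(y) != nrow(S)) stop("y must have one value per row of S")
    A <- WS
    b <- as.numeric(y) * weights
    if (lambda > 0) {
      A <- rbind(A, sqrt(lambda) * diag(n_r))
      b <- c(b, sqrt(lambda) * a)
    }
    sol <- pracma::lsqnonneg(A, b)
    extents <- stats::setNames(sol$x, colnames(S))
    daily <- NULL
    fitted <- as.numeric(S %*% extents)
    names(fitted) <- rownames(S)
    rank_def <- qr(A)$rank < n_r
  }
  res <- y - fitted
  obj <- sum((weights * res)^2) + lambda * sum((extents - a)^2)
  out <- list(extents = extents, fitted = fitted, residuals = res,
              objective = obj, lambda = lambda, rank_deficient = rank_def,
              daily = daily)
  if (rank_def && lambda == 0) {
    out$warning <- paste("S lacks full column rank with lambda = 0;",
                         "extents are one representative of a non-unique optimum")
  }
  class(out) <- "sf_nnls"
  out
}

#' Range-normalized goodness of fit
#'
#' Each analyte's observations and fitted values are divided by that
#' analyte's observed range (making mmol-scale gases commensurate with
#' smaller fermentation products), then pooled:
#' `R^2 = 1 - SSres/SStot` and `NRMSE = sqrt(mean(normalized residual^2))`.
#'
#' @param observed,fitted numeric vectors of equal length (>= 2 values).
#' @param analyte optional factor/character of the same length giving the
#'   analyte of each observation; default treats all values as one analyte.
#' @param scales optional named per-analyte scales to normalize by (e.g. the
#'   observed range of the full cumulative series); computed from `observed`
#'   when missing.
#' @return list with `r_squared` and `nrmse`. When the observations have
#'   zero variance R-squared is undefined and returned as `NA` with an
#'   `explanation` element.
#' @examples
#' goodness_of_fit(c(0, 1, 2, 3), c(0.5, 1.5, 1.5, 2.5))  # R2 0.8, NRMSE 1/6
#' @export
goodness_of_fit <- function(observed, fitted, analyte = NULL, scales = NULL) {
  stopifnot(length(observed) == length(fitted), length(observed) >= 2)
  if (is.null(analyte)) analyte <- rep("all", length(observed))
  if (is.null(scales)) scales <- analyte_scales(observed, analyte)
  s <- as.numeric(scales[as.character(analyte)])
  z_obs <- observed / s
  z_fit <- fitted / s
  ss_res <- sum((z_obs - z_fit)^2)
  ss_tot <- sum((z_obs - mean(z_obs))^2)
  nrmse <- sqrt(mean((z_obs - z_fit)^2))
  if (ss_tot == 0) {
    return(list(r_squared = NA_real_, nrmse = nrmse,
                explanation = "observations have zero variance; R-squared undefined"))
  }
  list(r_squared = 1 - ss_res / ss_tot, nrmse = nrmse)
}

#' Proteomics-derived prior reaction activities
#'
#' Marker-protein abundances are averaged per reaction in the given culture,
#' optionally scaled by the reaction's ATP yield, and rescaled so the priors
#' sum to `total_scale`. Reactions without any mapped marker receive the mean
#' of the covered reactions' priors. Zero abundance yields a zero prior, and
#' the rescaling makes the prior invariant to a global rescaling of the
#' abundance table.
#'
#' @param abundance protein-by-culture table: matrix with protein rownames,
#'   or data.frame with a `protein` column plus one numeric column per
#'   culture.
#' @param mapping data.frame with columns `protein`, `reaction` (background
#'   proteins may carry `NA` reaction).
#' @param catalogue an `sf_catalogue`.
#' @param culture column name of the culture to use.
#' @param total_scale the priors are rescaled to this total extent (mmol;
#'   default 1).
#' @param atp_scaling `"multiply"` (default: abundance x ATP yield),
#'   `"divide"`, or `"none"`. The direction appropriate for a given
#'   proteomics pipeline depends on how abundances relate to reaction
#'   turnover; see the methods vignette.
#' @return list of class `sf_prior`: `a` (named prior extents, mmol) and
#'   `source = "proteomics"`.
#' @export
proteomics_prior <- function(abundance, mapping, catalogue, culture,
                             total_scale = 1,
                             atp_scaling = c("multiply", "divide", "none")) {
  atp_scaling <- match.arg(atp_scaling)
  if (is.data.frame(abundance)) {
    if (!"protein" %in% names(abundance)) {
      stop("abundance data.frame needs a 'protein' column")
    }
    rn <- abundance$protein
    abundance <- as.matrix(abundance[, setdiff(names(abundance), "protein"),
                                     drop = FALSE])
    rownames(abundance) <- rn
  }
  if (!culture %in% colnames(abundance)) {
    stop("culture '", culture, "' not found in abundance table")
  }
  ab <- abundance[, culture]
  a <- vapply(catalogue$reactions, function(r) {
    markers <- mapping$protein[!is.na(mapping$reaction) & mapping$reaction == r$id]
    markers <- intersect(markers, names(ab))
    if (!length(markers)) return(NA_real_)
    m <- mean(ab[markers])
    switch(atp_scaling,
           multiply = m * r$atp_yield,
           divide = if (r$atp_yield > 0) m / r$atp_yield else m,
           none = m)
  }, numeric(1))
  if (all(is.na(a))) stop("mapping covers no reaction in the catalogue")
  a[is.na(a)] <- mean(a, na.rm = TRUE)
  tot <- sum(a)
  if (tot > 0) a <- a * total_scale / tot
  structure(list(a = a, source = "proteomics"), class = "sf_prior")
}

#' Uniform prior activities
#'
#' @param reactions reaction list (e.g. [active_reactions()]).
#' @param total_scale total prior extent to spread uniformly (mmol).
#' @return `sf_prior` with equal prior extents.
#' @export
uniform_prior <- function(reactions, total_scale = 1) {
  ids <- vapply(reactions, function(r) r$id, character(1))
  structure(list(a = stats::setNames(rep(total_scale / length(ids),
                                         length(ids)), ids),
                 source = "uniform"),
            class = "sf_prior")
}

#' Fit reaction extents for one culture from cumulative measurements
#'
#' Replicates are fitted separately and summarized as mean and SD; fit
#' weights default to the inverse observed range of each analyte (shared
#' with the NRMSE normalization). Endpoint mode (default) fits the final
#' cumulative vector of each replicate; trajectory mode stacks days 1..D
#' with nonnegative per-day extents.
#'
#' @param cumulative data.frame from [cumulative_production()] for one
#'   culture (columns `culture`, `replicate`, `analyte`, `day`, `mmol`).
#' @param assembly assembly label or `sf_assembly`.
#' @param catalogue an `sf_catalogue`.
#' @param mode `"endpoint"` or `"trajectory"`.
#' @param lambda shrinkage weight toward `prior` (default 0).
#' @param prior an `sf_prior` or named vector (see [fit_extents()]).
#' @param analytes analytes to fit on; default all measured analytes known
#'   to the catalogue, in catalogue order.
#' @return object of class `sf_fit`: per-replicate `extents` matrix,
#'   `extent_mean`, `extent_sd`, pooled `r_squared` and `nrmse`, `fitted`
#'   data.frame of observed vs fitted values, the active `S`, and flags.
#' @export
fit_culture <- function(cumulative, assembly, catalogue,
                        mode = c("endpoint", "trajectory"),
                        lambda = 0, prior = NULL, analytes = NULL) {
  mode <- match.arg(mode)
  if (is.character(assembly)) assembly <- assembly(assembly)
  if (length(unique(cumulative$culture)) != 1L) {
    stop("fit_culture expects measurements of a single culture")
  }
  if (is.null(analytes)) {
    analytes <- intersect(catalogue$metabolites$id, unique(cumulative$analyte))
  }
  if (!length(analytes)) stop("no fit analytes available")
  reactions <- active_reactions(assembly, catalogue)
  if (!length(reactions)) stop("assembly has no active reactions")
  S_full <- build_matrix(reactions, catalogue$metabolites$id)
  S <- S_full[analytes, , drop = FALSE]
  obs <- cumulative[cumulative$analyte %in% analytes, ]
  scales <- analyte_scales(obs$mmol, obs$analyte)[analytes]
  w <- 1 / scales
  reps <- sort(unique(obs$replicate))
  fits <- lapply(reps, function(rep_id) {
    d <- obs[obs$replicate == rep_id, ]
    days <- sort(unique(d$day))
    final_day <- max(days)
    if (mode == "endpoint") {
      y <- vapply(analytes, function(a) d$mmol[d$analyte == a & d$day == final_day],
                  numeric(1))
    } else {
      fit_days <- days[days > 0]
      y <- vapply(fit_days, function(dd) {
        vapply(analytes, function(a) d$mmol[d$analyte == a & d$day == dd],
               numeric(1))
      }, numeric(length(analytes)))
      dimnames(y) <- list(analytes, fit_days)
    }
    fit_extents(S, y, weights = w, prior = prior, lambda = lambda)
  })
  names(fits) <- reps
  extents <- t(vapply(fits, function(f) f$extents, numeric(ncol(S))))
  rownames(extents) <- reps
  fitted_df <- do.call(rbind, lapply(reps, function(rep_id) {
    f <- fits[[as.character(rep_id)]]
    if (mode == "endpoint") {
      # endpoint extents accrue uniformly over the run when compared with
      # the daily cumulative series
      days <- sort(unique(obs$day[obs$replicate == rep_id]))
      days <- days[days > 0]
      final_day <- max(days)
      do.call(rbind, lapply(days, function(dd) {
        d <- obs[obs$replicate == rep_id & obs$day == dd, ]
        y_obs <- stats::setNames(d$mmol[match(analytes, d$analyte)], analytes)
        data.frame(replicate = rep_id, analyte = analytes, day = dd,
                   observed = unname(y_obs),
                   fitted = unname(f$fitted) * dd / final_day,
                   stringsAsFactors = FALSE)
      }))
    } else {
      do.call(rbind, lapply(colnames(f$fitted), function(dd) {
        d <- obs[obs$replicate == rep_id & obs$day == as.integer(dd), ]
        y_obs <- stats::setNames(d$mmol[match(analytes, d$analyte)], analytes)
        data.frame(replicate = rep_id, analyte = analytes, day = as.integer(dd),
                   observed = unname(y_obs), fitted = unname(f$fitted[, dd]),
                   stringsAsFactors = FALSE)
      }))
    }
  }))
  gof <- goodness_of_fit(fitted_df$observed, fitted_df$fitted,
                         fitted_df$analyte, scales = scales)
  structure(list(
    assembly = assembly, mode = mode, lambda = lambda,
    reactions = colnames(S), analytes = analytes, S = S,
    extents = extents,
    extent_mean = colMeans(extents),
    extent_sd = apply(extents, 2, stats::sd),
    fitted = fitted_df,
    r_squared = gof$r_squared, nrmse = gof$nrmse,
    scales = scales,
    rank_deficient = any(vapply(fits, function(f) f$rank_deficient, logical(1))),
    replicate_fits = fits
  ), class = "sf_fit")
}

#' @export
print.sf_fit <- function(x, ...) {
  cat("Stoichiometric fit:", x$assembly$label, "(", x$mode, "mode, lambda =",
      x$lambda, ")\n")
  cat(sprintf("  R^2 = %.4f, NRMSE = %.4f over %d replicates\n",
              x$r_squared, x$nrmse, nrow(x$extents)))
  if (x$rank_deficient && x$lambda == 0) {
    cat("  note: active stoichiometry is rank-deficient; extents are one\n",
        "  representative of a non-unique optimum (consider a prior)\n")
  }
  tab <- data.frame(extent_mmol = round(x$extent_mean, 4),
                    sd = round(x$extent_sd, 4))
  print(tab)
  invisible(x)
}

#' Bootstrap uncertainty of fitted extents
#'
#' Resamples replicates with replacement, refits each resampled set, and
#' reports the mean and SD of the resampled mean extents. Deterministic for
#' a fixed seed.
#'
#' @inheritParams fit_culture
#' @param n_boot number of bootstrap draws (>= 2).
#' @param seed integer seed.
#' @param ... passed to [fit_culture()].
#' @return list with `mean`, `sd` (named by reaction), `draws` matrix.
#' @export
bootstrap_extents <- function(cumulative, assembly, catalogue, n_boot = 200,
                              seed = 1, ...) {
  if (n_boot < 2) stop("n_boot must be at least 2")
  reps <- unique(cumulative$replicate)
  if (length(reps) < 2) stop("bootstrap requires at least 2 replicates")
  base_fit <- fit_culture(cumulative, assembly, catalogue, ...)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  draws <- t(vapply(seq_len(n_boot), function(b) {
    take <- sample(as.character(reps), length(reps), replace = TRUE)
    colMeans(base_fit$extents[take, , drop = FALSE])
  }, numeric(length(base_fit$reactions))))
  list(mean = colMeans(draws), sd = apply(draws, 2, stats::sd), draws = draws)
}
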