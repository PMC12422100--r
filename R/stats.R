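#' Two-sample t-test with degenerate-case handling
#'
#' Pooled-variance (Student's) by default, Welch optionally. When both
#' groups have zero variance the test is degenerate: equal means give
#' `t = 0, p = 1`; different means give `p = 0` flagged `degenerate`.
#'
#' @param a,b numeric vectors (each >= 2 values).
#' @param variant `"pooled"` or `"welch"`.
#' @return list with `t`, `df`, `p`, and logical `degenerate`.
#' @examples
#' two_sample_t(c(1, 2, 3), c(2, 3, 4))  # t = -1.2247, p ~ 0.288
#' @export
two_sample_t <- function(a, b, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  stopifnot(length(a) >= 2, length(b) >= 2, all(is.finite(c(a, b))))
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) {
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1,
                  degenerate = TRUE))
    }
    return(list(t = sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2, p = 0, degenerate = TRUE))
  }
  ht <- stats::t.test(a, b, var.equal = (variant == "pooled"))
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, degenerate = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with enforced monotonicity;
#' stable under input permutation and ties.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return q-values in input order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.04))  # 0.03 0.03 0.04
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Pearson correlation with two-sided p-value
#'
#' @param x,y numeric vectors (n >= 3, finite). Zero variance in either
#'   vector makes r undefined (`NA` with an explanation).
#' @return list with `r`, `p`, `n`.
#' @examples
#' pearson_cor(c(1, 2, 3, 4), c(2, 1, 4, 3))  # r = 0.6
#' @export
pearson_cor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3, all(is.finite(c(x, y))))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = length(x),
                explanation = "zero variance; correlation undefined"))
  }
  ht <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), p = ht$p.value, n = length(x))
}

#' Fold changes of fitted extents between two cultures
#'
#' For each shared reaction the fold change of mean extent (B vs A) is
#' reported in magnitude form (`max(ratio, 1/ratio)`) with a direction
#' arrow, capped at `ceiling` (reported as `"> ceiling"`), together with a
#' t-test on the replicate extents and BH q-values across the family.
#'
#' @param extents_a,extents_b replicate-by-reaction extent matrices (e.g.
#'   `fit$extents` from [fit_culture()], or bootstrap draws).
#' @param label_a,label_b assembly labels for the output.
#' @param ceiling fold-change cap (default 100).
#' @param variant t-test variant, see [two_sample_t()].
#' @return data.frame with `reaction`, `group_a`, `group_b`, `mean_a`,
#'   `mean_b`, `fold_change`, `capped`, `display` (e.g. `"> 100"`),
#'   `direction` (`"up"` when B > A, `"down"` otherwise, `"ns"` if equal),
#'   `p_value`, `q_value`.
#' @export
flux_fold_changes <- function(extents_a, extents_b, label_a = "A",
                              label_b = "B", ceiling = 100,
                              variant = "pooled") {
  shared <- intersect(colnames(extents_a), colnames(extents_b))
  if (!length(shared)) stop("no shared reactions between the two cultures")
  rows <- lapply(shared, function(r) {
    va <- extents_a[, r]; vb <- extents_b[, r]
    ma <- mean(va); mb <- mean(vb)
    if (ma == 0 && mb == 0) {
      fc <- 1; dir <- "ns"
    } else if (ma == 0 || mb == 0) {
      fc <- Inf; dir <- if (mb > ma) "up" else "down"
    } else {
      ratio <- mb / ma
      fc <- max(ratio, 1 / ratio)
      dir <- if (ratio > 1) "up" else if (ratio < 1) "down" else "ns"
    }
    capped <- fc > ceiling
    tt <- two_sample_t(va, vb, variant = variant)
    data.frame(reaction = r, group_a = label_a, group_b = label_b,
               mean_a = ma, mean_b = mb,
               fold_change = min(fc, ceiling), capped = capped,
               display = if (capped) paste0("> ", ceiling)
                         else sprintf("%.2f", fc),
               direction = dir, p_value = tt$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_adjust(out$p_value)
  rownames(out) <- NULL
  out
}
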