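# Independent brute-force oracle for the nonnegative least-squares fit:
# grid search over the extent box [0, upper]^n minimizing the weighted SSE.
# `steps` gives the refinement schedule; a single step is an exhaustive
# search at that resolution, several steps refine a window of +/- 2 previous
# steps around the coarse minimizer (valid because the objective is a convex
# quadratic, so the continuous minimizer lies near the coarse grid optimum).
grid_nnls <- function(S, y, weights = NULL, upper = 0.5,
                      steps = c(0.025, 0.005, 0.001)) {
  if (is.null(weights)) weights <- rep(1, nrow(S))
  A <- S * as.numeric(weights)
  b <- as.numeric(y) * as.numeric(weights)
  n <- ncol(S)
  lo <- rep(0, n)
  hi <- rep(upper, n)
  best <- NULL
  for (st in steps) {
    grids <- lapply(seq_len(n), function(j) {
      seq(max(0, lo[j]), min(upper, hi[j]), by = st)
    })
    G <- as.matrix(expand.grid(grids))
    E <- A %*% t(G) - b
    sse <- colSums(E^2)
    k <- which.min(sse)
    best <- list(x = as.numeric(G[k, ]), sse = sse[[k]])
    lo <- best$x - 2 * st
    hi <- best$x + 2 * st
  }
  best
}
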