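# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Brute-force DTW: plain recursion over all monotone alignment paths
# (match / insert / delete). Only feasible for short series.
bruteForceDTW <- function(a, b) {
  a <- if (is.matrix(a)) a else matrix(a, ncol = 1L)
  b <- if (is.matrix(b)) b else matrix(b, ncol = 1L)
  cost <- function(i, j) sqrt(sum((a[i, ] - b[j, ])^2))
  rec <- function(i, j) {
    if (i == 1L && j == 1L) return(cost(1L, 1L))
    best <- Inf
    if (i > 1L && j > 1L) best <- min(best, rec(i - 1L, j - 1L))
    if (i > 1L) best <- min(best, rec(i - 1L, j))
    if (j > 1L) best <- min(best, rec(i, j - 1L))
    best + cost(i, j)
  }
  rec(nrow(a), nrow(b))
}

# Numeric root-finder for the lognormal shape with a requested IQR of the
# factor distribution (median 1): solves exp(s*q) - exp(-s*q) = iqr.
sigmaFromIqrNumeric <- function(iqr) {
  if (iqr == 0) return(0)
  q <- qnorm(0.75)
  uniroot(function(s) exp(s * q) - exp(-s * q) - iqr,
          c(0, 50), tol = 1e-14)$root
}

# Tiny constant-derivative system for hand-integrable cases. rate=0 gives
# the zero-RHS system of the piecewise-noise oracle.
constantRateSystem <- function(rate = 0) {
  new("OdeSystem", name = "const", variables = "u", parameters = "k",
      rhs = function(y, t, theta) rate + 0 * y,
      defaultCenters = c(u = 1, k = 1), nonneg = FALSE)
}

# Shared small SIR fixtures for forecasting tests.
sirCenters <- function() defaultCenters(getOdeSystem("sir"))

sirTrajectory <- function(grid = 0:39) {
  cen <- sirCenters()
  sys <- getOdeSystem("sir")
  simulateTrajectory(sys, cen[kineticParameters(sys)],
                     cen[stateVariables(sys)], grid)
}
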