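#' @include AllClasses.R generate.R
NULL

#' Multivariate dynamic time warping distance
#'
#' Dependent multivariate DTW: dynamic program over the \code{Ta x Tb} cost
#' matrix with local cost the Euclidean distance across variables and steps
#' match / insert / delete; the full (unnormalized) optimal path sum is
#' returned. No warping-window constraint is applied by default (series are
#' short); a Sakoe-Chiba radius can be set via \code{window}.
#'
#' Callers are expected to z-normalize per variable beforehand (DTW is
#' scale-sensitive); [assessCoherence()] does this with pooled synthetic
#' statistics.
#'
#' @param a,b numeric matrices (time x variables) with equal variable
#'   dimension; plain vectors are treated as one-variable series.
#' @param window optional Sakoe-Chiba radius (in time steps).
#' @return nonnegative distance; 0 iff the series align at zero cost.
#' @examples
#' dtwDistance(c(1, 2, 3), c(1, 2, 2, 3))  # 0: the repeated 2 is absorbed
#' @export
dtwDistance <- function(a, b, window = NULL) {
  a <- rbind2mat(a); b <- rbind2mat(b)
  if (ncol(a) != ncol(b)) stop("variable dimension mismatch")
  Ta <- nrow(a); Tb <- nrow(b)
  if (Ta == 0L || Tb == 0L) stop("empty series")
  sq <- outer(rowSums(a^2), rep(1, Tb)) +
    outer(rep(1, Ta), rowSums(b^2)) - 2 * a %*% t(b)
  sq[sq < 0] <- 0  # guard tiny negative round-off before the square root
  local <- sqrt(sq)
  D <- matrix(Inf, Ta + 1L, Tb + 1L)
  D[1L, 1L] <- 0
  for (i in seq_len(Ta)) {
    jr <- if (is.null(window)) seq_len(Tb)
          else seq(max(1L, i - window), min(Tb, i + window))
    for (j in jr)
      D[i + 1L, j + 1L] <- local[i, j] +
        min(D[i, j], D[i, j + 1L], D[i + 1L, j])
  }
  D[Ta + 1L, Tb + 1L]
}

rbind2mat <- function(x) {
  if (is.matrix(x)) x else matrix(as.numeric(x), ncol = 1L)
}

#' Estimated first-derivative transform for derivative DTW
#'
#' Per variable, the interior-point derivative estimate
#' \deqn{d_i = ((q_i - q_{i-1}) + (q_{i+1} - q_{i-1})/2) / 2,}
#' i.e. the average of the backward difference and the centred half
#' difference, which is robust to single-point noise. The first and last
#' points are dropped, so a \code{T x n} series maps to \code{(T-2) x n}.
#'
#' @param series numeric matrix (time x variables) or vector; \code{T >= 3}.
#' @return the transformed series.
#' @examples
#' derivativeTransform(c(0, 1, 0))  # 0.5
#' @export
derivativeTransform <- function(series) {
  q <- rbind2mat(series)
  Tn <- nrow(q)
  if (Tn < 3L) stop("derivative transform needs at least 3 time points")
  i <- 2L:(Tn - 1L)
  ((q[i, , drop = FALSE] - q[i - 1L, , drop = FALSE]) +
     (q[i + 1L, , drop = FALSE] - q[i - 1L, , drop = FALSE]) / 2) / 2
}

#' Screen the coherence of synthetic dynamics against a target series
#'
#' Samples \code{nPairs} synthetic series and computes their DTW and DDTW
#' distances to the target, plus a baseline sample of distances between
#' \code{nPairs} disjoint synthetic pairs. All series are z-normalized per
#' variable with pooled synthetic-dataset statistics first. The shift
#' statistic is the probability (over all cross comparisons, ties counted
#' half) that a random target distance exceeds a random baseline distance:
#' about 0.5 when the target is exchangeable with the synthetic series,
#' approaching 1 when the target's shapes lie outside the synthetic
#' distribution. The report ranks configurations; it deliberately issues no
#' absolute coherent/incoherent verdict.
#'
#' @param synthetic a [TimeSeriesDataset-class] with at least 2 series.
#' @param target a [Trajectory-class] on the same variables.
#' @param nPairs sample size per distance distribution.
#' @param seed RNG seed.
#' @param window optional Sakoe-Chiba radius passed to [dtwDistance()].
#' @return a [CoherenceReport-class].
#' @export
assessCoherence <- function(synthetic, target, nPairs = 50L, seed = 1L,
                            window = NULL) {
  stopifnot(is(synthetic, "TimeSeriesDataset"), is(target, "Trajectory"))
  n <- nSeries(synthetic)
  if (n < 2L)
    stop("coherence baseline unavailable for a single-series dataset; ",
         "generate a larger synthetic dataset")
  vars <- synthetic@variables
  if (!all(vars %in% colnames(target@values)))
    stop("target does not carry the synthetic dataset's variables")
  pooled <- do.call(rbind, lapply(synthetic@trajectories,
                                  function(t) t@values))
  ctr <- colMeans(pooled)
  scl <- apply(pooled, 2L, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  zn <- function(v) sweep(sweep(v[, vars, drop = FALSE], 2L, ctr, `-`),
                          2L, scl, `/`)
  zSyn <- lapply(synthetic@trajectories, function(t) zn(t@values))
  zTar <- zn(target@values)

  set.seed(.deriveSeed(seed, 41L))
  tgtIdx <- sample.int(n, nPairs, replace = nPairs > n)
  basePairs <- matrix(0L, nPairs, 2L)
  for (k in seq_len(nPairs)) basePairs[k, ] <- sample.int(n, 2L)

  distPair <- function(a, b, deriv) {
    if (deriv) {
      a <- derivativeTransform(a); b <- derivativeTransform(b)
    }
    dtwDistance(a, b, window = window)
  }
  report1 <- function(deriv) {
    tgt <- vapply(tgtIdx, function(i)
      distPair(zSyn[[i]], zTar, deriv), numeric(1L))
    base <- vapply(seq_len(nPairs), function(k)
      distPair(zSyn[[basePairs[k, 1L]]], zSyn[[basePairs[k, 2L]]], deriv),
      numeric(1L))
    cmp <- outer(tgt, base, `-`)
    list(target = tgt, baseline = base,
         shift = mean(cmp > 0) + 0.5 * mean(cmp == 0))
  }
  new("CoherenceReport", dtw = report1(FALSE), ddtw = report1(TRUE),
      nPairs = as.numeric(nPairs), seed = as.numeric(seed))
}
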