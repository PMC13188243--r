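#' @include simulate.R intervals.R
NULL

# Deterministic derived seeds, kept well below 2^31.
.deriveSeed <- function(base, ...) {
  ix <- c(...)
  s <- as.double(base) %% 1000003
  for (k in seq_along(ix)) s <- (s * 7919 + as.double(ix[k]) * 104729 + k) %%
      2147483629
  as.integer(s)
}

#' Generate a synthetic dataset of ODE trajectories
#'
#' Draws \code{nSeries} independent (kinetic parameter, initial condition)
#' configurations from the diversity intervals, simulates each on the shared
#' grid with the requested noise, and collects the results. Trajectories
#' whose simulation fails, or that contain non-finite or (for nonnegative
#' systems) negative values, are discarded and re-drawn up to
#' \code{maxRetries} times per slot; retry counts are recorded in the
#' dataset config. The whole dataset is reproducible from \code{seed}.
#'
#' @param system an [OdeSystem-class] or its registered name.
#' @param diversity a [DiversityConfig-class] covering the system.
#' @param noise a [NoiseConfig-class]; measurement noise is applied to each
#'   clean trajectory after simulation, environmental noise inside the
#'   solver (see [simulateTrajectory()]).
#' @param nSeries number of trajectories (the studied sizes are 1, 10, 100,
#'   1000, but any positive integer works).
#' @param grid shared strictly increasing time grid.
#' @param seed master seed.
#' @param maxRetries retry cap per slot before generation fails.
#' @return a [TimeSeriesDataset-class].
#' @examples
#' sys <- getOdeSystem("sir")
#' div <- diversityConfig(sys, icClass = "S", kpClass = "M")
#' ds <- generateDataset(sys, div, noiseConfig("none"), nSeries = 5,
#'                       grid = 0:30, seed = 1)
#' @export
generateDataset <- function(system, diversity, noise = noiseConfig("none"),
                            nSeries = 10L, grid, seed = 1L,
                            maxRetries = 10L) {
  if (is.character(system)) system <- getOdeSystem(system)
  stopifnot(is(system, "OdeSystem"), nSeries >= 1L)
  .checkGrid(grid)
  .checkCoverage(diversity, system)
  trajs <- vector("list", nSeries)
  retries <- integer(nSeries)
  for (k in seq_len(nSeries)) {
    done <- FALSE
    for (attempt in 0:maxRetries) {
      slotSeed <- .deriveSeed(seed, k, attempt)
      cfg <- sampleConfiguration(diversity, system, seed = slotSeed)
      tr <- tryCatch({
        tr <- simulateTrajectory(system, cfg$theta, cfg$ics, grid,
                                 noise = noise,
                                 seed = .deriveSeed(seed, k, attempt, 1L),
                                 seriesId = sprintf("series_%04d", k))
        if (noise@kind == "measurement" && noise@level > 0)
          tr <- applyMeasurementNoise(tr, noise,
                                      seed = .deriveSeed(seed, k, attempt, 2L))
        tr
      }, simulationFailure = function(e) NULL)
      bad <- is.null(tr) || any(!is.finite(tr@values)) ||
        (system@nonneg && min(tr@values) < -1e-8)
      if (!bad) {
        prov <- tr@provenance
        prov$slotSeed <- slotSeed
        prov$retries <- attempt
        tr@provenance <- prov
        trajs[[k]] <- tr
        retries[k] <- attempt
        done <- TRUE
        break
      }
    }
    if (!done)
      stop("generation failure for series ", k, " after ", maxRetries,
           " retries (system '", system@name, "', noise kind '",
           noise@kind, "', operation '", noise@operation, "', level ",
           noise@level, "): simulations infeasible or negative states")
  }
  new("TimeSeriesDataset",
      systemName = system@name, time = as.numeric(grid),
      variables = system@variables, trajectories = trajs,
      config = list(noise = list(kind = noise@kind,
                                 operation = noise@operation,
                                 level = noise@level),
                    nSeries = nSeries,
                    icClasses = vapply(diversity@icSpecs,
                                       function(s) s@widthClass, ""),
                    kpClasses = vapply(diversity@kpSpecs,
                                       function(s) s@widthClass, ""),
                    retries = retries),
      seed = as.numeric(seed))
}

#' Generate a pseudo-real target series fixture
#'
#' Stands in for an observed target dataset so the whole pipeline can be
#' exercised without external downloads (synthetic fixture, labelled as
#' such). A coherent fixture is one trajectory of the same system at the
#' true parameters with multiplicative lognormal observation noise of the
#' given interquartile range. An incoherent fixture comes from a
#' structurally different generator: the same system with one kinetic
#' parameter scaled by a large factor, plus a phase-shifted additive
#' sinusoid per variable (amplitude a fraction of each variable's clean sd),
#' with the same observation noise.
#'
#' @param system an [OdeSystem-class] or registered name.
#' @param theta,ics true kinetic parameters and initial state.
#' @param grid time grid.
#' @param observationNoiseIQR interquartile range of the multiplicative
#'   lognormal observation noise (0 = exact clean trajectory).
#' @param coherent logical flag selecting the generator.
#' @param seed integer seed.
#' @param scaledParameter name of the parameter perturbed in the incoherent
#'   case (default: the system's first kinetic parameter).
#' @param scaleFactor multiplier applied to that parameter (default 5).
#' @param sineAmplitude sinusoid amplitude as a fraction of each variable's
#'   clean sd (default 0.75).
#' @return a [Trajectory-class] flagged in its provenance.
#' @export
generateFixtureTarget <- function(system, theta = NULL, ics = NULL, grid,
                                  observationNoiseIQR = 0.05,
                                  coherent = TRUE, seed = 1L,
                                  scaledParameter = NULL, scaleFactor = 5,
                                  sineAmplitude = 0.75) {
  if (is.character(system)) system <- getOdeSystem(system)
  cen <- system@defaultCenters
  if (is.null(theta)) theta <- cen[system@parameters]
  if (is.null(ics)) ics <- cen[system@variables]
  .checkGrid(grid)
  if (coherent) {
    tr <- simulateTrajectory(system, theta, ics, grid,
                             seriesId = "target_coherent")
  } else {
    if (is.null(scaledParameter)) scaledParameter <- system@parameters[1L]
    th2 <- theta
    th2[[scaledParameter]] <- th2[[scaledParameter]] * scaleFactor
    tr <- simulateTrajectory(system, th2, ics, grid,
                             seriesId = "target_incoherent")
    v <- tr@values
    span <- diff(range(grid))
    set.seed(.deriveSeed(seed, 17L))
    phases <- stats::runif(ncol(v), 0, 2 * pi)
    for (j in seq_len(ncol(v))) {
      amp <- sineAmplitude * stats::sd(v[, j])
      v[, j] <- v[, j] + amp * sin(2 * pi * 3 * (grid - grid[1L]) / span +
                                     phases[j])
      if (system@nonneg) v[, j] <- pmax(v[, j], 0)
    }
    tr@values <- v
  }
  if (observationNoiseIQR > 0)
    tr <- applyMeasurementNoise(
      tr, noiseConfig("measurement", "multiplicative", observationNoiseIQR),
      seed = .deriveSeed(seed, 23L))
  prov <- tr@provenance
  prov$fixture <- list(coherent = coherent, seed = seed,
                       observationNoiseIQR = observationNoiseIQR)
  tr@provenance <- prov
  tr
}

#' Restrict a trajectory to a set of time indices
#'
#' @param traj a [Trajectory-class].
#' @param idx integer vector of (1-based) time indices, contiguous.
#' @return the restricted [Trajectory-class].
#' @export
subsetTrajectory <- function(traj, idx) {
  stopifnot(is(traj, "Trajectory"), all(idx >= 1L),
            all(idx <= length(traj@time)))
  new("Trajectory", seriesId = traj@seriesId, time = traj@time[idx],
      values = traj@values[idx, , drop = FALSE],
      provenance = c(traj@provenance, list(subset = range(idx))))
}
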