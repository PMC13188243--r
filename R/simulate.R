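#' @include AllClasses.R ode-systems.R noise.R
NULL

# Condition signalled when the solver fails or produces non-finite states;
# generateDataset() catches it and re-draws the configuration.
.simulationFailure <- function(msg) {
  stop(structure(class = c("simulationFailure", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

.desolveFunc <- function(system, theta) {
  function(t, y, parms) list(system@rhs(y, t, theta))
}

.solveClean <- function(system, theta, ics, times,
                        rtol = 1e-8, atol = 1e-10) {
  out <- try(deSolve::ode(y = ics, times = times,
                          func = .desolveFunc(system, theta), parms = NULL,
                          method = "lsoda", rtol = rtol, atol = atol),
             silent = TRUE)
  if (inherits(out, "try-error"))
    .simulationFailure(paste("ODE solver error:", attr(out, "condition")$message))
  m <- unclass(out)[, system@variables, drop = FALSE]
  if (nrow(m) != length(times) || any(!is.finite(m)))
    .simulationFailure("ODE solver returned incomplete or non-finite states")
  rownames(m) <- NULL
  m
}

#' Validate a time grid
#'
#' @param grid numeric vector of time points.
#' @return the grid, invisibly, or an error.
#' @keywords internal
.checkGrid <- function(grid) {
  if (length(grid) < 2L || any(!is.finite(grid)) || any(diff(grid) <= 0))
    stop("time grid must have >= 2 finite, strictly increasing points")
  invisible(grid)
}

#' Simulate one trajectory of an ODE system
#'
#' Clean runs (\code{kind = "none"} or \code{"measurement"}) use a single
#' adaptive solve with output at the grid points; measurement noise, if any,
#' is applied afterwards via [applyMeasurementNoise()] (by
#' [generateDataset()]). Environmental noise is realised piecewise: on each
#' interval \code{[t_i, t_{i+1})} one noise value per variable is drawn and
#' the perturbed system \code{dy/dt + e} (additive) or \code{dy/dt * e}
#' (multiplicative) is integrated with state continuity at the interval
#' boundaries, so the perturbation propagates through the dynamics.
#'
#' Additive environmental draws are Gaussian with standard deviation
#' \code{level} times the per-variable scale of the clean derivative (the sd
#' of the clean trajectory's finite-difference slopes); multiplicative draws
#' are lognormal with median 1 and shape [sigmaFromIQR()] of the level.
#' At \code{level = 0} both distributions are degenerate at the identity and
#' the clean single-solve path is taken, so the result is bit-identical to
#' the noiseless simulation.
#'
#' @param system an [OdeSystem-class].
#' @param theta named kinetic parameter vector.
#' @param ics named initial state vector.
#' @param grid strictly increasing time grid.
#' @param noise a [NoiseConfig-class]; default none.
#' @param seed optional integer seed for the environmental draws.
#' @param seriesId identifier stored on the trajectory.
#' @param envDraws optional \code{(N-1) x n} matrix of explicit environmental
#'   draws (one row per interval, one column per variable) overriding the
#'   random draws; intended for controlled experiments.
#' @return a [Trajectory-class] with full provenance.
#' @examples
#' sys <- getOdeSystem("sir")
#' cen <- defaultCenters(sys)
#' tr <- simulateTrajectory(sys, cen[kineticParameters(sys)],
#'                          cen[stateVariables(sys)], 0:30)
#' @export
simulateTrajectory <- function(system, theta, ics, grid,
                               noise = noiseConfig("none"), seed = NULL,
                               seriesId = "sim", envDraws = NULL) {
  stopifnot(is(system, "OdeSystem"), is(noise, "NoiseConfig"))
  .checkGrid(grid)
  theta <- theta[system@parameters]
  ics <- ics[system@variables]
  if (any(is.na(theta)) || any(is.na(ics)))
    stop("theta/ics must cover all system parameters and variables")
  n <- length(system@variables)
  N <- length(grid)

  environmental <- noise@kind == "environmental" &&
    (noise@level > 0 || !is.null(envDraws))
  if (!environmental) {
    vals <- .solveClean(system, theta, ics, grid)
  } else {
    clean <- .solveClean(system, theta, ics, grid)
    if (is.null(envDraws)) {
      if (!is.null(seed)) set.seed(seed)
      if (noise@operation == "additive") {
        derivScale <- apply(apply(clean, 2L, diff) / diff(grid), 2L,
                            stats::sd)
        derivScale[derivScale == 0] <- 1  # flat variable: unit scale
        envDraws <- vapply(seq_len(n), function(j)
          stats::rnorm(N - 1L, 0, noise@level * derivScale[j]),
          numeric(N - 1L))
      } else {
        sig <- sigmaFromIQR(noise@level)
        envDraws <- matrix(stats::rlnorm((N - 1L) * n, 0, sig),
                           nrow = N - 1L)
      }
    }
    envDraws <- as.matrix(envDraws)
    if (nrow(envDraws) != N - 1L || ncol(envDraws) != n)
      stop("envDraws must be an (N-1) x n matrix")
    vals <- matrix(NA_real_, N, n)
    vals[1L, ] <- as.numeric(ics)
    state <- ics
    for (i in seq_len(N - 1L)) {
      e <- envDraws[i, ]
      pert <- if (noise@operation == "additive")
        function(t, y, parms) list(system@rhs(y, t, theta) + e)
      else
        function(t, y, parms) list(system@rhs(y, t, theta) * e)
      out <- try(deSolve::ode(y = state, times = grid[i:(i + 1L)],
                              func = pert, parms = NULL, method = "lsoda",
                              rtol = 1e-8, atol = 1e-10), silent = TRUE)
      if (inherits(out, "try-error") || nrow(out) < 2L ||
          any(!is.finite(unclass(out)[2L, -1L])))
        .simulationFailure(sprintf(
          "environmental-noise integration failed on interval %d", i))
      state <- unclass(out)[2L, system@variables]
      vals[i + 1L, ] <- as.numeric(state)
    }
  }
  colnames(vals) <- system@variables
  new("Trajectory", seriesId = as.character(seriesId), time = as.numeric(grid),
      values = vals,
      provenance = list(system = system@name, theta = theta, ics = ics,
                        noise = list(kind = noise@kind,
                                     operation = noise@operation,
                                     level = noise@level),
                        seed = seed,
                        environmental = environmental))
}
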