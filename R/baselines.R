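#' @include forecast.R simulate.R
NULL

#' Train the uninformed deep-learning baseline
#'
#' The same training loop as [pretrain()] (early stopping, best-checkpoint
#' by validation loss) applied to the target training region with a randomly
#' initialized model and a scaler fitted on the target training split. Built
#' with the same seed as the corresponding transfer-learning run, the two
#' arms differ only in the initial parameters (random vs pre-trained),
#' making comparisons paired.
#'
#' @param architecture model architecture (see [buildModel()]).
#' @param targetTrain a [Trajectory-class] restricted to the training region.
#' @param cfg a [trainConfig()].
#' @param targetVars forecast target variables.
#' @param hyper hyperparameter overrides for [buildModel()].
#' @return a trained [ForecastModel-class].
#' @export
trainDLBaseline <- function(architecture, targetTrain, cfg = trainConfig(),
                            targetVars = NULL, hyper = list()) {
  stopifnot(is(targetTrain, "Trajectory"))
  vars <- colnames(targetTrain@values)
  if (is.null(targetVars)) targetVars <- vars
  model <- buildModel(architecture, inputLen = 5L, nVars = length(vars),
                      horizon = 5L, nTargets = length(targetVars),
                      targetVars = targetVars, hyper = hyper,
                      seed = cfg$seed)
  trainDLBaselineFromModel(model, targetTrain, cfg)
}

#' @rdname trainDLBaseline
#' @param model a freshly built [ForecastModel-class] (paired with the TL
#'   arm's initialization).
#' @export
trainDLBaselineFromModel <- function(model, targetTrain,
                                     cfg = trainConfig()) {
  stopifnot(is(model, "ForecastModel"), is(targetTrain, "Trajectory"))
  model@scaler <- .fitScaler(list(targetTrain@values),
                             colnames(targetTrain@values))
  if (cfg$maxEpochs == 0L) return(model)
  sp <- .targetSplitWindows(model, targetTrain, cfg)
  .trainLoop(model, .scaledXY(model, sp$train), .scaledXY(model, sp$val),
             cfg, headOnly = FALSE, phase = "dl_baseline")
}

#' Calibrate an ODE system to observations
#'
#' Minimises the weighted sum of squared differences between the simulated
#' trajectory (started at the first observed state) and the observations
#' over all observed variables, using bounded Levenberg-Marquardt least
#' squares ([minpack.lm::nls.lm]) with a small multi-start: the supplied
#' \code{theta0} plus \code{nStarts - 1} log-uniform perturbations of it.
#' Per-variable \code{1/sd} weights make variables of different scales
#' contribute comparably. Returns the best restart.
#'
#' @param system an [OdeSystem-class] or registered name.
#' @param observations a [Trajectory-class] covering the training and
#'   validation region (at least \code{2 * nParameters} time points).
#' @param theta0 named initial kinetic parameter vector (default: system
#'   centers).
#' @param lower,upper named positivity bounds (defaults: \code{theta0/1e3}
#'   and \code{theta0*1e3}).
#' @param nStarts number of seeded restarts.
#' @param perturbation half-width of the log-uniform restart perturbation
#'   (in natural-log units; default \code{log(2)}, i.e. factors in
#'   [1/2, 2]).
#' @param fitICs also fit the initial state? (default \code{FALSE}: the
#'   first observed values are used as-is).
#' @param seed RNG seed for the restarts.
#' @return a [CalibrationResult-class].
#' @export
calibrateODE <- function(system, observations, theta0 = NULL, lower = NULL,
                         upper = NULL, nStarts = 10L,
                         perturbation = log(2), fitICs = FALSE, seed = 1L) {
  if (is.character(system)) system <- getOdeSystem(system)
  stopifnot(is(observations, "Trajectory"))
  obs <- observations@values[, system@variables, drop = FALSE]
  times <- observations@time
  np <- length(system@parameters)
  if (nrow(obs) < 2L * np)
    stop("calibration needs at least ", 2L * np, " observed time points")
  if (is.null(theta0)) theta0 <- system@defaultCenters[system@parameters]
  theta0 <- theta0[system@parameters]
  if (is.null(lower)) lower <- theta0 / 1e3
  if (is.null(upper)) upper <- theta0 * 1e3
  w <- 1 / apply(obs, 2L, stats::sd)
  w[!is.finite(w)] <- 1
  ics0 <- obs[1L, ]
  names(ics0) <- system@variables

  residFun <- function(par) {
    theta <- par[system@parameters]
    ics <- if (fitICs) par[paste0("ic_", system@variables)] else ics0
    names(ics) <- system@variables
    sim <- tryCatch(.solveClean(system, theta, ics, times),
                    simulationFailure = function(e) NULL)
    if (is.null(sim)) return(rep(1e6, length(obs)))
    as.numeric(sweep(sim - obs, 2L, w, `*`))
  }

  par0 <- theta0
  lo <- lower[system@parameters]; up <- upper[system@parameters]
  if (fitICs) {
    icp <- ics0; names(icp) <- paste0("ic_", system@variables)
    par0 <- c(theta0, icp)
    lo <- c(lo, pmax(icp / 1e3, 1e-9)); up <- c(up, pmax(icp * 1e3, 1))
  }

  set.seed(.deriveSeed(seed, 31L))
  starts <- list(par0)
  for (k in seq_len(max(0L, nStarts - 1L))) {
    p <- par0 * exp(stats::runif(length(par0), -perturbation, perturbation))
    starts[[k + 1L]] <- pmin(pmax(p, lo), up)
  }

  rows <- list()
  best <- NULL
  for (k in seq_along(starts)) {
    fit <- try(minpack.lm::nls.lm(
      par = starts[[k]], lower = lo, upper = up, fn = residFun,
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error")) {
      rows[[k]] <- data.frame(start = k, residual = NA_real_,
                              converged = FALSE, nIter = NA_integer_)
      next
    }
    rss <- sum(fit$fvec^2)
    conv <- fit$info %in% c(1L, 2L, 3L, 4L)
    rows[[k]] <- data.frame(start = k, residual = rss, converged = conv,
                            nIter = fit$niter)
    if (conv && (is.null(best) || rss < best$rss))
      best <- list(fit = fit, rss = rss, k = k)
  }
  restarts <- do.call(rbind, rows)
  if (is.null(best))
    stop("calibration failure: no restart converged; trace:\n",
         paste(utils::capture.output(print(restarts)), collapse = "\n"))
  par <- best$fit$par
  theta <- par[system@parameters]
  ics <- if (fitICs) {
    v <- par[paste0("ic_", system@variables)]; names(v) <- system@variables; v
  } else ics0
  new("CalibrationResult", systemName = system@name, theta = theta,
      ics = ics, time = times, weights = w, residual = best$rss,
      converged = TRUE, nIter = as.numeric(best$fit$niter),
      restarts = restarts)
}

#' Forecast by simulating a calibrated ODE
#'
#' One deterministic simulation of the fitted system, continued from the
#' state at the end of the calibration window over the future grid. For
#' nonnegative systems started positive the mechanistic forecast stays
#' positive.
#'
#' @param system an [OdeSystem-class] or registered name.
#' @param calibration a converged [CalibrationResult-class].
#' @param gridFuture strictly increasing future time points (all beyond the
#'   calibration window). A zero-length grid yields a zero-row trajectory
#'   value matrix wrapped in a plain list.
#' @return a [Trajectory-class] on \code{gridFuture} (or an empty list for a
#'   zero-length grid).
#' @export
forecastODE <- function(system, calibration, gridFuture) {
  if (is.character(system)) system <- getOdeSystem(system)
  stopifnot(is(calibration, "CalibrationResult"), calibration@converged)
  if (length(gridFuture) == 0L)
    return(list(time = numeric(0),
                values = matrix(0, 0L, length(system@variables),
                                dimnames = list(NULL, system@variables))))
  if (any(gridFuture <= max(calibration@time)))
    stop("gridFuture must lie strictly beyond the calibration window")
  fullGrid <- c(calibration@time, gridFuture)
  sim <- .solveClean(system, calibration@theta, calibration@ics, fullGrid)
  idx <- length(calibration@time) + seq_along(gridFuture)
  new("Trajectory", seriesId = "ode_forecast",
      time = as.numeric(gridFuture),
      values = sim[idx, , drop = FALSE],
      provenance = list(system = system@name, theta = calibration@theta,
                        calibrated = TRUE))
}
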