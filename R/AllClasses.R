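#' @import methods
NULL

#' Ordinary differential equation system
#'
#' An \code{OdeSystem} bundles everything the generator and the calibration
#' baseline need to know about a dynamical system: the ordered state
#' variables, the ordered kinetic parameters, a deterministic right-hand-side
#' function, strictly positive default interval centers for every variable
#' and parameter, and whether states are constrained to stay nonnegative.
#'
#' @slot name identifier of the system (e.g. \code{"sir"}).
#' @slot variables ordered character vector of state variable names.
#' @slot parameters ordered character vector of kinetic parameter names.
#' @slot rhs function \code{(state, t, theta) -> derivative vector}; must be
#'   deterministic and return one finite value per state variable.
#' @slot defaultCenters named numeric vector of strictly positive interval
#'   centers covering every variable and parameter. These are documented,
#'   editable configuration values, not calibrated constants.
#' @slot nonneg logical; if \code{TRUE} trajectories with negative values are
#'   rejected during dataset generation.
#'
#' @seealso [getOdeSystem()], [registerOdeSystem()]
#' @export
setClass("OdeSystem", representation(
  name = "character",
  variables = "character",
  parameters = "character",
  rhs = "function",
  defaultCenters = "numeric",
  nonneg = "logical"
))

setValidity("OdeSystem", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "name must be a single non-empty string")
  if (length(object@variables) < 1L)
    msg <- c(msg, "at least one state variable required")
  need <- c(object@variables, object@parameters)
  if (!all(need %in% names(object@defaultCenters)))
    msg <- c(msg, "defaultCenters must cover every variable and parameter")
  cen <- object@defaultCenters[need]
  if (any(!is.finite(cen)) || any(cen <= 0))
    msg <- c(msg, "all default centers must be strictly positive and finite")
  if (length(msg)) msg else TRUE
})

#' Uniform sampling interval around a center value
#'
#' Intervals are symmetric and relative: \code{[center*(1-w), center*(1+w)]}
#' with \code{w} the half width fraction resolved from a width class
#' (S, M, L, XL). The lower bound must stay positive, so \code{w < 1}.
#'
#' @slot center strictly positive center value.
#' @slot widthClass one of \code{"S"}, \code{"M"}, \code{"L"}, \code{"XL"}
#'   (or \code{"custom"} when constructed from a raw fraction).
#' @slot halfWidthFraction half width as a fraction of the center, in [0, 1).
#'
#' @seealso [intervalSpec()], [resolveInterval()]
#' @export
setClass("IntervalSpec", representation(
  center = "numeric",
  widthClass = "character",
  halfWidthFraction = "numeric"
))

setValidity("IntervalSpec", function(object) {
  msg <- character()
  if (length(object@center) != 1L || !is.finite(object@center) ||
      object@center <= 0)
    msg <- c(msg, "center must be a single strictly positive value")
  w <- object@halfWidthFraction
  if (length(w) != 1L || !is.finite(w) || w < 0 || w >= 1)
    msg <- c(msg, "halfWidthFraction must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' Diversity configuration: sampling intervals for ICs and KPs
#'
#' Maps every state variable of a system to an initial-condition sampling
#' interval and every kinetic parameter to a parameter sampling interval.
#' Interval widths control the diversity of the generated dataset.
#'
#' @slot icSpecs named list of [IntervalSpec-class] objects, one per state
#'   variable.
#' @slot kpSpecs named list of [IntervalSpec-class] objects, one per kinetic
#'   parameter.
#'
#' @seealso [diversityConfig()], [sampleConfiguration()]
#' @export
setClass("DiversityConfig", representation(
  icSpecs = "list",
  kpSpecs = "list"
))

setValidity("DiversityConfig", function(object) {
  ok <- function(l) length(l) == 0L ||
    (!is.null(names(l)) && all(vapply(l, is, TRUE, "IntervalSpec")))
  if (!ok(object@icSpecs)) return("icSpecs must be a named list of IntervalSpec")
  if (!ok(object@kpSpecs)) return("kpSpecs must be a named list of IntervalSpec")
  TRUE
})

#' Noise configuration
#'
#' Exactly one (kind, operation) combination is active at a time.
#' \code{kind = "measurement"} perturbs observed values after simulation;
#' \code{kind = "environmental"} perturbs the ODE right-hand side itself with
#' a draw held constant between consecutive grid points, so its effect
#' propagates through the dynamics. For multiplicative noise \code{level} is
#' the interquartile range of the lognormal factor distribution (median 1);
#' for additive noise it is the ratio of the noise standard deviation to the
#' per-variable scale of the clean signal. \code{level = 0} is the identity.
#'
#' @slot kind one of \code{"none"}, \code{"measurement"}, \code{"environmental"}.
#' @slot operation one of \code{"additive"}, \code{"multiplicative"}.
#' @slot level nonnegative noise level.
#'
#' @seealso [noiseConfig()], [sigmaFromIQR()], [applyMeasurementNoise()]
#' @export
setClass("NoiseConfig", representation(
  kind = "character",
  operation = "character",
  level = "numeric"
))

setValidity("NoiseConfig", function(object) {
  msg <- character()
  if (!object@kind %in% c("none", "measurement", "environmental"))
    msg <- c(msg, "kind must be one of none/measurement/environmental")
  if (!object@operation %in% c("additive", "multiplicative"))
    msg <- c(msg, "operation must be additive or multiplicative")
  if (length(object@level) != 1L || !is.finite(object@level) ||
      object@level < 0)
    msg <- c(msg, "level must be a single nonnegative number")
  if (length(msg)) msg else TRUE
})

#' A single (simulated or observed) trajectory
#'
#' Values live on a shared strictly increasing time grid; one column per
#' state variable. The provenance list records everything needed to
#' regenerate a simulated trajectory exactly (sampled parameters, sampled
#' initial conditions, noise summary, seed).
#'
#' @slot seriesId identifier.
#' @slot time strictly increasing numeric time grid.
#' @slot values numeric matrix, \code{length(time)} rows, one column per
#'   variable (column names are the variable names).
#' @slot provenance list of generation metadata.
#'
#' @export
setClass("Trajectory", representation(
  seriesId = "character",
  time = "numeric",
  values = "matrix",
  provenance = "list"
))

setValidity("Trajectory", function(object) {
  msg <- character()
  n <- length(object@time)
  if (n < 2L) msg <- c(msg, "time grid needs at least 2 points")
  if (any(!is.finite(object@time)) || any(diff(object@time) <= 0))
    msg <- c(msg, "time grid must be finite and strictly increasing")
  if (nrow(object@values) != n)
    msg <- c(msg, "values must have one row per time point")
  if (is.null(colnames(object@values)))
    msg <- c(msg, "values must carry variable names as column names")
  if (any(!is.finite(object@values)))
    msg <- c(msg, "values must be finite")
  if (length(msg)) msg else TRUE
})

#' Collection of trajectories on a shared grid
#'
#' @slot systemName name of the generating system (or \code{"observed"}).
#' @slot time the shared time grid.
#' @slot variables shared variable order.
#' @slot trajectories list of [Trajectory-class] objects.
#' @slot config generation configuration snapshot.
#' @slot seed master seed the dataset was generated from.
#'
#' @seealso [generateDataset()]
#' @export
setClass("TimeSeriesDataset", representation(
  systemName = "character",
  time = "numeric",
  variables = "character",
  trajectories = "list",
  config = "list",
  seed = "numeric"
))

setValidity("TimeSeriesDataset", function(object) {
  for (tr in object@trajectories) {
    if (!is(tr, "Trajectory")) return("trajectories must be Trajectory objects")
    if (!isTRUE(all.equal(tr@time, object@time, tolerance = 1e-12)))
      return("all trajectories must share the dataset time grid")
    if (!identical(colnames(tr@values), object@variables))
      return("all trajectories must share the dataset variable order")
  }
  TRUE
})

#' Neural forecaster with a body/head parameter partition
#'
#' The body is an architecture-specific feature extractor (LSTM, GRU, CNN or
#' DNN); the head is always a two-layer perceptron emitting
#' \code{horizon x nTargets} values. Fine-tuning trains the head only; the
#' body is frozen bit-for-bit. The scaler (per-variable location/scale) is
#' fitted once on the training data and stored with the model.
#'
#' @slot architecture one of \code{"lstm"}, \code{"gru"}, \code{"cnn"},
#'   \code{"dnn"}.
#' @slot inputLen input window length. @slot nVars number of input variables.
#' @slot horizon forecast horizon (steps). @slot nTargets number of target
#'   variables.
#' @slot targetVars names of the target variables.
#' @slot hyper hyperparameter list (units, hidden size, ...).
#' @slot body named list of body parameter arrays.
#' @slot head named list of head parameter arrays (W1, b1, W2, b2).
#' @slot scaler list with \code{center}, \code{scale} per variable and
#'   \code{fitted} flag.
#' @slot log training log data frame (epoch, phase, train and validation loss).
#' @slot seed initialization seed.
#'
#' @seealso [buildModel()], [pretrain()], [finetune()]
#' @export
setClass("ForecastModel", representation(
  architecture = "character",
  inputLen = "numeric",
  nVars = "numeric",
  horizon = "numeric",
  nTargets = "numeric",
  targetVars = "character",
  hyper = "list",
  body = "list",
  head = "list",
  scaler = "list",
  log = "data.frame",
  seed = "numeric"
))

setValidity("ForecastModel", function(object) {
  msg <- character()
  if (!object@architecture %in% c("lstm", "gru", "cnn", "dnn"))
    msg <- c(msg, "unknown architecture")
  if (!all(c("W1", "b1", "W2", "b2") %in% names(object@head)))
    msg <- c(msg, "head must have exactly the two-layer parameters W1,b1,W2,b2")
  if (length(msg)) msg else TRUE
})

#' Result of calibrating an ODE system to observations
#'
#' @slot systemName calibrated system.
#' @slot theta fitted kinetic parameter vector.
#' @slot ics initial state used for simulation (first observed values by
#'   default).
#' @slot time observation time grid used for fitting.
#' @slot weights per-variable residual weights.
#' @slot residual final weighted residual sum of squares (>= 0).
#' @slot converged logical convergence flag of the best restart.
#' @slot nIter optimizer trace length (iterations of the best restart).
#' @slot restarts data frame summarising all restarts.
#'
#' @seealso [calibrateODE()], [forecastODE()]
#' @export
setClass("CalibrationResult", representation(
  systemName = "character",
  theta = "numeric",
  ics = "numeric",
  time = "numeric",
  weights = "numeric",
  residual = "numeric",
  converged = "logical",
  nIter = "numeric",
  restarts = "data.frame"
))

setValidity("CalibrationResult", function(object) {
  if (length(object@residual) != 1L || object@residual < 0)
    return("residual must be a single nonnegative number")
  TRUE
})

#' Paired blocked-bootstrap comparison of two forecast error sets
#'
#' @slot estimate point estimate of the metric difference (arm A minus arm B).
#' @slot lower,upper percentile confidence bounds.
#' @slot level confidence level (default 0.95).
#' @slot blockLen moving-block length used on the time axis.
#' @slot nBoot number of bootstrap replicates.
#' @slot seed RNG seed.
#'
#' @seealso [blockedBootstrapDiffCI()], [significanceFlag()]
#' @export
setClass("BootstrapResult", representation(
  estimate = "numeric",
  lower = "numeric",
  upper = "numeric",
  level = "numeric",
  blockLen = "numeric",
  nBoot = "numeric",
  seed = "numeric"
))

setValidity("BootstrapResult", function(object) {
  if (object@lower > object@upper) return("lower bound exceeds upper bound")
  if (object@level <= 0 || object@level >= 1) return("level must be in (0,1)")
  TRUE
})

#' Coherence screening report
#'
#' For each distance variant (DTW on z-normalized values, DDTW on the
#' estimated first derivative) the report holds a sample of
#' synthetic-to-target distances, a baseline sample of synthetic-to-synthetic
#' distances, and the shift statistic: the probability that a random target
#' distance exceeds a random baseline distance (0.5 under exchangeability,
#' near 1 for incoherent targets). The report is comparative only; it never
#' issues an absolute coherent/incoherent verdict.
#'
#' @slot dtw list with \code{target}, \code{baseline} distance vectors and
#'   \code{shift} statistic.
#' @slot ddtw same for derivative DTW.
#' @slot nPairs sample size per distribution.
#' @slot seed RNG seed.
#'
#' @seealso [assessCoherence()]
#' @export
setClass("CoherenceReport", representation(
  dtw = "list",
  ddtw = "list",
  nPairs = "numeric",
  seed = "numeric"
))

setValidity("CoherenceReport", function(object) {
  for (m in list(object@dtw, object@ddtw)) {
    if (!all(c("target", "baseline", "shift") %in% names(m)))
      return("each metric entry needs target, baseline and shift")
    if (any(c(m$target, m$baseline) < 0)) return("distances must be >= 0")
    if (m$shift < 0 || m$shift > 1) return("shift statistic must be in [0,1]")
  }
  TRUE
})

#' Grid experiment result table
#'
#' @slot cells long data frame with one row per attempted
#'   (size, icClass, kpClass, architecture, seed) cell: transfer-learning,
#'   DL-baseline and ODE-baseline metrics plus a status column. Failed cells
#'   are recorded with their failure reason, never dropped.
#' @slot summary per-configuration aggregate: seed-mean metrics, relative
#'   changes versus the baselines, bootstrap confidence intervals and
#'   significance flags.
#' @slot config configuration snapshot.
#'
#' @seealso [runGrid()], [selectBest()], [runNoiseStudy()]
#' @export
setClass("GridResult", representation(
  cells = "data.frame",
  summary = "data.frame",
  config = "list"
))
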