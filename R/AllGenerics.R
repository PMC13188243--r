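#' @include AllClasses.R
NULL

#' Accessors for odetransfer objects
#'
#' Small generic accessors so user code never touches slots directly.
#'
#' @param object an odetransfer S4 object.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("systemName", function(object) standardGeneric("systemName"))

#' @rdname accessors
#' @export
setGeneric("stateVariables", function(object) standardGeneric("stateVariables"))

#' @rdname accessors
#' @export
setGeneric("kineticParameters",
           function(object) standardGeneric("kineticParameters"))

#' @rdname accessors
#' @export
setGeneric("defaultCenters", function(object) standardGeneric("defaultCenters"))

#' @rdname accessors
#' @export
setGeneric("timePoints", function(object) standardGeneric("timePoints"))

#' @rdname accessors
#' @export
setGeneric("trajValues", function(object) standardGeneric("trajValues"))

#' @rdname accessors
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))

#' @rdname accessors
#' @export
setGeneric("trajectories", function(object) standardGeneric("trajectories"))

#' @rdname accessors
#' @export
setGeneric("nSeries", function(object) standardGeneric("nSeries"))

#' @rdname accessors
#' @export
setGeneric("architecture", function(object) standardGeneric("architecture"))

#' @rdname accessors
#' @export
setGeneric("bodyParameters", function(object) standardGeneric("bodyParameters"))

#' @rdname accessors
#' @export
setGeneric("headParameters", function(object) standardGeneric("headParameters"))

#' @rdname accessors
#' @export
setGeneric("trainingLog", function(object) standardGeneric("trainingLog"))

#' @rdname accessors
#' @export
setGeneric("fittedParameters",
           function(object) standardGeneric("fittedParameters"))

#' @rdname accessors
#' @export
setGeneric("shiftStatistic", function(object, ...)
  standardGeneric("shiftStatistic"))

#' @rdname accessors
#' @export
setGeneric("gridCells", function(object) standardGeneric("gridCells"))

#' @rdname accessors
#' @export
setGeneric("gridSummary", function(object) standardGeneric("gridSummary"))

# ---- methods -------------------------------------------------------------

#' @rdname accessors
setMethod("systemName", "OdeSystem", function(object) object@name)
#' @rdname accessors
setMethod("systemName", "TimeSeriesDataset", function(object) object@systemName)
#' @rdname accessors
setMethod("systemName", "CalibrationResult", function(object) object@systemName)

#' @rdname accessors
setMethod("stateVariables", "OdeSystem", function(object) object@variables)
#' @rdname accessors
setMethod("stateVariables", "TimeSeriesDataset",
          function(object) object@variables)
#' @rdname accessors
setMethod("stateVariables", "Trajectory",
          function(object) colnames(object@values))

#' @rdname accessors
setMethod("kineticParameters", "OdeSystem", function(object) object@parameters)

#' @rdname accessors
setMethod("defaultCenters", "OdeSystem", function(object) object@defaultCenters)

#' @rdname accessors
setMethod("timePoints", "Trajectory", function(object) object@time)
#' @rdname accessors
setMethod("timePoints", "TimeSeriesDataset", function(object) object@time)

#' @rdname accessors
setMethod("trajValues", "Trajectory", function(object) object@values)

#' @rdname accessors
setMethod("provenance", "Trajectory", function(object) object@provenance)

#' @rdname accessors
setMethod("trajectories", "TimeSeriesDataset",
          function(object) object@trajectories)

#' @rdname accessors
setMethod("nSeries", "TimeSeriesDataset",
          function(object) length(object@trajectories))

#' @rdname accessors
setMethod("architecture", "ForecastModel", function(object) object@architecture)

#' @rdname accessors
setMethod("bodyParameters", "ForecastModel", function(object) object@body)

#' @rdname accessors
setMethod("headParameters", "ForecastModel", function(object) object@head)

#' @rdname accessors
setMethod("trainingLog", "ForecastModel", function(object) object@log)

#' @rdname accessors
setMethod("fittedParameters", "CalibrationResult", function(object)
  object@theta)

#' @rdname accessors
#' @param metric \code{"dtw"} or \code{"ddtw"}.
#' @param ... passed on to methods.
setMethod("shiftStatistic", "CoherenceReport",
          function(object, metric = c("dtw", "ddtw"), ...) {
  metric <- match.arg(metric)
  slot(object, metric)$shift
})

#' @rdname accessors
setMethod("gridCells", "GridResult", function(object) object@cells)

#' @rdname accessors
setMethod("gridSummary", "GridResult", function(object) object@summary)

# ---- show methods --------------------------------------------------------

setMethod("show", "OdeSystem", function(object) {
  cat("OdeSystem \"", object@name, "\": ",
      length(object@variables), " variables (",
      paste(object@variables, collapse = ", "), "), ",
      length(object@parameters), " kinetic parameters (",
      paste(object@parameters, collapse = ", "), ")\n", sep = "")
  invisible(object)
})

setMethod("show", "Trajectory", function(object) {
  cat("Trajectory \"", object@seriesId, "\": ", length(object@time),
      " time points x ", ncol(object@values), " variables [",
      paste(colnames(object@values), collapse = ", "), "]\n", sep = "")
  invisible(object)
})

setMethod("show", "TimeSeriesDataset", function(object) {
  cat("TimeSeriesDataset (", object@systemName, "): ",
      length(object@trajectories), " series x ", length(object@time),
      " time points, variables: ",
      paste(object@variables, collapse = ", "), "\n", sep = "")
  invisible(object)
})

setMethod("show", "NoiseConfig", function(object) {
  cat("NoiseConfig: kind=", object@kind, ", operation=", object@operation,
      ", level=", object@level, "\n", sep = "")
  invisible(object)
})

setMethod("show", "ForecastModel", function(object) {
  nb <- sum(vapply(object@body, length, 1L))
  nh <- sum(vapply(object@head, length, 1L))
  cat("ForecastModel [", toupper(object@architecture), "]: input ",
      object@inputLen, " x ", object@nVars, " -> horizon ", object@horizon,
      " x ", object@nTargets, " (", nb, " body + ", nh,
      " head parameters)\n", sep = "")
  invisible(object)
})

setMethod("show", "CalibrationResult", function(object) {
  cat("CalibrationResult (", object@systemName, "): residual=",
      format(object@residual, digits = 4), ", converged=",
      object@converged, "\n  theta: ",
      paste(names(object@theta), "=", signif(object@theta, 4),
            collapse = ", "), "\n", sep = "")
  invisible(object)
})

setMethod("show", "BootstrapResult", function(object) {
  cat(sprintf(
    "BootstrapResult: diff=%.4g, %d%% CI [%.4g, %.4g], block=%d, n_boot=%d\n",
    object@estimate, round(100 * object@level), object@lower, object@upper,
    as.integer(object@blockLen), as.integer(object@nBoot)))
  invisible(object)
})

setMethod("show", "CoherenceReport", function(object) {
  cat(sprintf(
    "CoherenceReport (n_pairs=%d): shift DTW=%.3f, DDTW=%.3f\n",
    as.integer(object@nPairs), object@dtw$shift, object@ddtw$shift))
  invisible(object)
})

setMethod("show", "GridResult", function(object) {
  cat("GridResult: ", nrow(object@cells), " cells (",
      sum(object@cells$status == "ok"), " ok), ",
      nrow(object@summary), " summarised configurations\n", sep = "")
  invisible(object)
})
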