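#' @include AllClasses.R
NULL

#' Default half-width fractions of the four interval width classes
#'
#' Classes of increasing length used to control dataset diversity. The
#' fractions are documented, editable defaults; any run can override them.
#'
#' @return named numeric vector \code{c(S=0.05, M=0.20, L=0.50, XL=0.80)}.
#' @export
widthClassDefaults <- function() c(S = 0.05, M = 0.20, L = 0.50, XL = 0.80)

#' Construct a sampling interval specification
#'
#' @param center strictly positive interval center.
#' @param widthClass one of \code{"S"}, \code{"M"}, \code{"L"}, \code{"XL"};
#'   ignored when \code{halfWidthFraction} is given directly.
#' @param halfWidthFraction optional explicit half width as a fraction of the
#'   center, in [0, 1).
#' @param widths named vector resolving classes to fractions (defaults to
#'   [widthClassDefaults()]).
#' @return an [IntervalSpec-class] object.
#' @examples
#' intervalSpec(0.3, "M")              # [0.24, 0.36]
#' intervalSpec(2, halfWidthFraction = 0)  # degenerate [2, 2]
#' @export
intervalSpec <- function(center, widthClass = "M", halfWidthFraction = NULL,
                         widths = widthClassDefaults()) {
  if (is.null(halfWidthFraction)) {
    if (!widthClass %in% names(widths))
      stop("unknown width class '", widthClass, "'; available: ",
           paste(names(widths), collapse = ", "))
    halfWidthFraction <- unname(widths[[widthClass]])
  } else {
    widthClass <- "custom"
  }
  obj <- new("IntervalSpec", center = as.numeric(center),
             widthClass = widthClass,
             halfWidthFraction = as.numeric(halfWidthFraction))
  validObject(obj)
  obj
}

#' Resolve an interval specification to numeric bounds
#'
#' \code{lower = center*(1-w)}, \code{upper = center*(1+w)}; the lower bound
#' is guaranteed positive because \code{w < 1} and \code{center > 0}.
#'
#' @param spec an [IntervalSpec-class] object.
#' @return numeric vector \code{c(lower, upper)}.
#' @examples
#' resolveInterval(intervalSpec(1, halfWidthFraction = 0.2))  # c(0.8, 1.2)
#' @export
resolveInterval <- function(spec) {
  stopifnot(is(spec, "IntervalSpec"))
  validObject(spec)
  w <- spec@halfWidthFraction
  c(lower = spec@center * (1 - w), upper = spec@center * (1 + w))
}

#' Build a diversity configuration for a system
#'
#' Assigns every state variable an initial-condition sampling interval and
#' every kinetic parameter a parameter sampling interval, centered on the
#' system's default centers (or user-supplied centers).
#'
#' @param system an [OdeSystem-class] object.
#' @param icClass,kpClass width class applied to all ICs / all KPs.
#' @param centers optional named numeric vector overriding the system's
#'   default centers.
#' @param widths named class-to-fraction map (see [widthClassDefaults()]).
#' @return a [DiversityConfig-class] object.
#' @examples
#' diversityConfig(getOdeSystem("sir"), icClass = "S", kpClass = "M")
#' @export
diversityConfig <- function(system, icClass = "M", kpClass = "M",
                            centers = NULL, widths = widthClassDefaults()) {
  stopifnot(is(system, "OdeSystem"))
  cen <- system@defaultCenters
  if (!is.null(centers)) cen[names(centers)] <- centers
  mk <- function(nms, cls) {
    out <- lapply(nms, function(nm) intervalSpec(cen[[nm]], cls,
                                                 widths = widths))
    names(out) <- nms
    out
  }
  obj <- new("DiversityConfig",
             icSpecs = mk(system@variables, icClass),
             kpSpecs = mk(system@parameters, kpClass))
  validObject(obj)
  obj
}

.checkCoverage <- function(diversity, system) {
  miss_ic <- setdiff(system@variables, names(diversity@icSpecs))
  miss_kp <- setdiff(system@parameters, names(diversity@kpSpecs))
  if (length(miss_ic) || length(miss_kp))
    stop("diversity config does not cover the system: missing ",
         paste(c(miss_ic, miss_kp), collapse = ", "))
  invisible(TRUE)
}

#' Draw one (kinetic parameters, initial conditions) configuration
#'
#' Each value is drawn independently and uniformly from its resolved
#' interval. Reproducible: the caller controls the RNG state (pass
#' \code{seed} or seed the session).
#'
#' @param diversity a [DiversityConfig-class] object covering the system.
#' @param system the target [OdeSystem-class].
#' @param seed optional integer seed (set before drawing when given).
#' @return list with named numeric vectors \code{theta} and \code{ics}.
#' @export
sampleConfiguration <- function(diversity, system, seed = NULL) {
  stopifnot(is(diversity, "DiversityConfig"))
  .checkCoverage(diversity, system)
  if (!is.null(seed)) set.seed(seed)
  draw <- function(specs, nms) {
    v <- vapply(nms, function(nm) {
      b <- resolveInterval(specs[[nm]])
      stats::runif(1L, b[["lower"]], b[["upper"]])
    }, numeric(1L))
    names(v) <- nms
    v
  }
  list(theta = draw(diversity@kpSpecs, system@parameters),
       ics = draw(diversity@icSpecs, system@variables))
}
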