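#' @include AllClasses.R
NULL

#' Construct a noise configuration
#'
#' @param kind \code{"none"}, \code{"measurement"} (i.i.d. perturbation of
#'   each observed value) or \code{"environmental"} (perturbation of the ODE
#'   right-hand side, held constant between consecutive grid points).
#' @param operation \code{"additive"} or \code{"multiplicative"}. Only one
#'   (kind, operation) combination is active at a time.
#' @param level nonnegative noise level. Multiplicative: target interquartile
#'   range of the lognormal factor distribution (median 1). Additive: ratio
#'   of the noise standard deviation to the per-variable scale of the clean
#'   signal, so the noise is scaled to fit the measured quantity.
#'   \code{level = 0} is the identity.
#' @return a [NoiseConfig-class] object.
#' @examples
#' noiseConfig("measurement", "multiplicative", 0.1)
#' noiseConfig("none")
#' @export
noiseConfig <- function(kind = c("none", "measurement", "environmental"),
                        operation = c("multiplicative", "additive"),
                        level = 0) {
  kind <- match.arg(kind)
  operation <- match.arg(operation)
  if (!is.finite(level) || level < 0)
    stop("invalid noise level: must be a nonnegative number")
  obj <- new("NoiseConfig", kind = kind, operation = operation,
             level = as.numeric(level))
  validObject(obj)
  obj
}

#' Default noise levels of the noise study
#'
#' Six levels of increasing strength (interquartile range for multiplicative
#' noise, sd-fraction for additive noise); documented, overridable defaults.
#'
#' @return numeric vector of six levels.
#' @export
defaultNoiseLevels <- function() c(0.01, 0.05, 0.1, 0.2, 0.5, 1.0)

#' Lognormal shape parameter from a target interquartile range
#'
#' For a lognormal with log-scale median 1 (log-mean 0) and shape
#' \eqn{\sigma}, the quartiles are \eqn{\exp(\pm\sigma q_{75})} with
#' \eqn{q_{75}} the standard-normal 0.75 quantile, so the interquartile
#' range is \eqn{2\sinh(\sigma q_{75})}. Inverting gives the closed form
#' \deqn{\sigma = \mathrm{asinh}(\mathrm{iqr}/2) / q_{75}.}
#'
#' @param iqr requested nonnegative interquartile range of the factor
#'   distribution.
#' @return the lognormal shape \eqn{\sigma \ge 0}.
#' @examples
#' sigmaFromIQR(0)    # 0
#' sigmaFromIQR(0.1)  # ~0.0741
#' @export
sigmaFromIQR <- function(iqr) {
  if (!is.finite(iqr) || iqr < 0)
    stop("invalid noise level: iqr must be nonnegative")
  asinh(iqr / 2) / stats::qnorm(0.75)
}

#' Apply measurement noise to a trajectory
#'
#' Multiplicative: each value is multiplied by an i.i.d. lognormal factor
#' with median 1 and shape [sigmaFromIQR()] of the level. Additive: each
#' value receives i.i.d. Gaussian noise with standard deviation
#' \code{level} times the per-variable standard deviation of the clean
#' trajectory. Draws are independent per variable and per time point.
#'
#' @param traj a clean [Trajectory-class].
#' @param noise a [NoiseConfig-class] with \code{kind = "measurement"}.
#' @param seed optional integer seed.
#' @return the perturbed [Trajectory-class] (provenance records the noise).
#' @export
applyMeasurementNoise <- function(traj, noise, seed = NULL) {
  stopifnot(is(traj, "Trajectory"), is(noise, "NoiseConfig"))
  if (noise@kind != "measurement")
    stop("applyMeasurementNoise requires noise kind 'measurement', got '",
         noise@kind, "'")
  if (noise@level == 0) return(traj)
  if (!is.null(seed)) set.seed(seed)
  v <- traj@values
  if (noise@operation == "multiplicative") {
    sig <- sigmaFromIQR(noise@level)
    fac <- matrix(stats::rlnorm(length(v), meanlog = 0, sdlog = sig),
                  nrow = nrow(v))
    v <- v * fac
  } else {
    sds <- apply(traj@values, 2L, stats::sd)
    eps <- vapply(seq_len(ncol(v)), function(j)
      stats::rnorm(nrow(v), 0, noise@level * sds[j]),
      numeric(nrow(v)))
    v <- v + eps
  }
  prov <- traj@provenance
  prov$measurementNoise <- list(operation = noise@operation,
                                level = noise@level, seed = seed)
  new("Trajectory", seriesId = traj@seriesId, time = traj@time,
      values = v, provenance = prov)
}
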