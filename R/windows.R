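#' @include AllClasses.R
NULL

#' Build sliding forecast windows from a trajectory
#'
#' Enumerates all maximal stride-1 sliding windows: each window pairs
#' \code{inputLen} consecutive observations of all variables with the
#' following \code{horizon} observations of the target variables. With
#' \code{N} time points there are \code{max(0, N - inputLen - horizon + 1)}
#' windows. When \code{targetRegion} (a vector of 1-based time indices) is
#' given, only windows whose target region lies entirely inside it are kept;
#' inputs may extend before the region.
#'
#' @param traj a [Trajectory-class].
#' @param inputLen input window length (>= 1).
#' @param horizon forecast horizon (>= 1).
#' @param targetVars names of the forecast target variables (default: all).
#' @param targetRegion optional integer vector of admissible target time
#'   indices.
#' @return a list of class \code{"WindowSet"} with \code{inputs}
#'   (K x inputLen x nVars), \code{targets} (K x horizon x nTargets),
#'   \code{origins} (data frame: seriesId, t0Index = last input index),
#'   \code{lastInputs} (K x nTargets matrix of forecast-origin values) and
#'   \code{targetVars}. A series too short to window yields an empty set
#'   with a warning, so short series are skippable in aggregation.
#' @examples
#' sys <- getOdeSystem("lv")
#' cen <- defaultCenters(sys)
#' tr <- simulateTrajectory(sys, cen[kineticParameters(sys)],
#'                          cen[stateVariables(sys)], seq(0, 4.4, 0.4))
#' ws <- makeWindows(tr, inputLen = 5, horizon = 5, targetVars = "y")
#' nrow(ws$origins)  # 12 - 5 - 5 + 1 = 3
#' @export
makeWindows <- function(traj, inputLen, horizon, targetVars = NULL,
                        targetRegion = NULL) {
  stopifnot(is(traj, "Trajectory"), inputLen >= 1L, horizon >= 1L)
  v <- traj@values
  N <- nrow(v)
  vars <- colnames(v)
  if (is.null(targetVars)) targetVars <- vars
  if (!all(targetVars %in% vars))
    stop("unknown target variables: ",
         paste(setdiff(targetVars, vars), collapse = ", "))
  t0 <- seq.int(inputLen, N - horizon)
  if (N < inputLen + horizon) t0 <- integer(0)
  if (!is.null(targetRegion))
    t0 <- t0[vapply(t0, function(p)
      all((p + 1L):(p + horizon) %in% targetRegion), TRUE)]
  K <- length(t0)
  if (K == 0L) {
    warning("series '", traj@seriesId, "' yields no windows (N=", N,
            ", need >= ", inputLen + horizon, " points in region)")
    return(structure(list(
      inputs = array(0, c(0L, inputLen, length(vars))),
      targets = array(0, c(0L, horizon, length(targetVars))),
      origins = data.frame(seriesId = character(), t0Index = integer()),
      lastInputs = matrix(0, 0L, length(targetVars),
                          dimnames = list(NULL, targetVars)),
      targetVars = targetVars), class = "WindowSet"))
  }
  inputs <- array(0, c(K, inputLen, length(vars)),
                  dimnames = list(NULL, NULL, vars))
  targets <- array(0, c(K, horizon, length(targetVars)),
                   dimnames = list(NULL, NULL, targetVars))
  for (k in seq_len(K)) {
    p <- t0[k]
    inputs[k, , ] <- v[(p - inputLen + 1L):p, , drop = FALSE]
    targets[k, , ] <- v[(p + 1L):(p + horizon), targetVars, drop = FALSE]
  }
  structure(list(
    inputs = inputs, targets = targets,
    origins = data.frame(seriesId = traj@seriesId, t0Index = t0),
    lastInputs = matrix(v[t0, targetVars], K, length(targetVars),
                        dimnames = list(NULL, targetVars)),
    targetVars = targetVars), class = "WindowSet")
}

# Concatenate window sets along the window axis.
.bindWindows <- function(sets) {
  sets <- Filter(function(s) nrow(s$origins) > 0L, sets)
  if (length(sets) == 0L) return(NULL)
  if (length(sets) == 1L) return(sets[[1L]])
  abind_k <- function(arrs) {
    d <- dim(arrs[[1L]])
    out <- array(0, c(sum(vapply(arrs, function(a) dim(a)[1L], 1L)),
                      d[2L], d[3L]))
    at <- 0L
    for (a in arrs) {
      if (dim(a)[1L] > 0L) out[at + seq_len(dim(a)[1L]), , ] <- a
      at <- at + dim(a)[1L]
    }
    out
  }
  structure(list(
    inputs = abind_k(lapply(sets, `[[`, "inputs")),
    targets = abind_k(lapply(sets, `[[`, "targets")),
    origins = do.call(rbind, lapply(sets, `[[`, "origins")),
    lastInputs = do.call(rbind, lapply(sets, `[[`, "lastInputs")),
    targetVars = sets[[1L]]$targetVars), class = "WindowSet")
}
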