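#' @include AllClasses.R
NULL

.asErr <- function(pred, obs) {
  if (inherits(pred, "ForecastSet")) {
    obs <- pred$obs; pred <- pred$pred
  }
  if (length(pred) != length(obs) ||
      (!is.null(dim(pred)) && !is.null(dim(obs)) &&
         !identical(dim(pred), dim(obs))))
    stop("pred and obs must have the same shape")
  if (length(pred) == 0L) stop("empty input")
  as.numeric(pred) - as.numeric(obs)
}

#' Forecast error metrics
#'
#' \code{mae} is the mean absolute elementwise error and \code{rmse} the
#' root mean squared elementwise error over all (window, step, target
#' variable) cells; \code{rmse >= mae} always (Jensen).
#'
#' @param pred predictions: an array or a \code{"ForecastSet"} from
#'   [predictSeries()].
#' @param obs observations with the same shape (ignored if \code{pred} is a
#'   ForecastSet).
#' @return a nonnegative scalar.
#' @examples
#' mae(c(1, 2, 3, 5), c(2, 1, 4, 4))  # 1
#' rmse(c(0, 0, 0, 2), c(0, 0, 0, 0)) # 1
#' @export
mae <- function(pred, obs = NULL) mean(abs(.asErr(pred, obs)))

#' @rdname mae
#' @export
rmse <- function(pred, obs = NULL) sqrt(mean(.asErr(pred, obs)^2))

#' Prediction trend accuracy
#'
#' A multi-step variant of mean directional accuracy: over all (window,
#' horizon step, target variable) triples, the fraction where the sign of
#' the predicted change from the forecast origin (the last input value)
#' matches the sign of the observed change. Zero changes match only zero
#' changes, so flat forecasts get no credit for moves. Reported as
#' \code{1 - PTA} in comparisons so that lower is better.
#'
#' @param pred K x H x nTargets prediction array or a \code{"ForecastSet"}.
#' @param obs matching observation array.
#' @param lastInputs K x nTargets matrix of forecast-origin values.
#' @return PTA in [0, 1].
#' @examples
#' # origin 10, observed (12, 9), predicted (11, 11): up/up then up-vs-down
#' pta(array(c(11, 11), c(1, 2, 1)), array(c(12, 9), c(1, 2, 1)),
#'     matrix(10))  # 0.5
#' @export
pta <- function(pred, obs = NULL, lastInputs = NULL) {
  if (inherits(pred, "ForecastSet")) {
    obs <- pred$obs; lastInputs <- pred$lastInputs; pred <- pred$pred
  }
  if (is.null(lastInputs)) stop("missing forecast origins (lastInputs)")
  K <- dim(pred)[1L]; H <- dim(pred)[2L]; Tn <- dim(pred)[3L]
  if (!identical(dim(obs), dim(pred)) || nrow(lastInputs) != K)
    stop("pred, obs and lastInputs shapes do not align")
  if (K == 0L) stop("empty input")
  origin <- array(rep(lastInputs, each = 1L), c(K, Tn, H))
  origin <- aperm(origin, c(1L, 3L, 2L))  # K x H x Tn
  mean(sign(pred - origin) == sign(obs - origin))
}

#' Relative change of a metric versus a baseline
#'
#' \code{100 * (tl - baseline) / baseline}; negative values mean the
#' transfer-learning arm improves on the baseline.
#'
#' @param tlMetric metric of the transfer-learning arm.
#' @param baselineMetric strictly positive baseline metric.
#' @return signed percent change.
#' @export
relativeChange <- function(tlMetric, baselineMetric) {
  if (!is.finite(baselineMetric) || baselineMetric <= 0)
    stop("relative change undefined: baseline metric must be positive")
  100 * (tlMetric - baselineMetric) / baselineMetric
}

#' Spread per-window forecast errors onto the time axis
#'
#' Defines "error at time point t" for overlapping windows as the mean
#' absolute (or squared, or trend-mismatch) error over all (window, step)
#' cells whose target falls on t. This is the per-time-point error vector
#' the blocked bootstrap resamples.
#'
#' @param fs a \code{"ForecastSet"} from [predictSeries()].
#' @param timeIndices evaluation-region time indices (1-based, same
#'   convention as the origins); default: all covered indices.
#' @param type \code{"abs"} for MAE-style errors or \code{"trend"} for
#'   1-PTA-style mismatch indicators.
#' @return named numeric vector of per-time-point errors.
#' @export
perTimepointErrors <- function(fs, timeIndices = NULL,
                               type = c("abs", "trend")) {
  type <- match.arg(type)
  stopifnot(inherits(fs, "ForecastSet"))
  K <- dim(fs$pred)[1L]; H <- dim(fs$pred)[2L]; Tn <- dim(fs$pred)[3L]
  if (K == 0L) stop("empty forecast set")
  cellTime <- outer(fs$origins$t0Index, seq_len(H), `+`)  # K x H
  if (is.null(timeIndices)) timeIndices <- sort(unique(as.integer(cellTime)))
  if (type == "abs") {
    cellErr <- abs(fs$pred - fs$obs)  # K x H x Tn
  } else {
    origin <- aperm(array(fs$lastInputs, c(K, Tn, H)), c(1L, 3L, 2L))
    cellErr <- (sign(fs$pred - origin) != sign(fs$obs - origin)) * 1
  }
  out <- vapply(timeIndices, function(tt) {
    m <- cellTime == tt
    if (!any(m)) return(NA_real_)
    mean(cellErr[array(rep(m, Tn), c(K, H, Tn))])
  }, numeric(1L))
  names(out) <- timeIndices
  out[!is.na(out)]
}

#' Paired blocked-bootstrap confidence interval for a metric difference
#'
#' Moving-block bootstrap over the time axis: contiguous blocks of
#' \code{blockLen} time indices are sampled with replacement until the
#' resampled length reaches \code{N}, then truncated. The same resampled
#' time indices are applied to both arms (paired over time), and the seed
#' rows are simultaneously resampled with replacement, identically in both
#' arms (paired over seeds). The aggregated metric is recomputed per arm on
#' each replicate and the percentile confidence interval of the difference
#' (A minus B) is returned.
#'
#' @param errorsA,errorsB numeric seed x time-point error matrices of equal
#'   shape (e.g. from [perTimepointErrors()] stacked over seeds).
#' @param metric aggregator mapping a matrix to a scalar (default: mean, the
#'   MAE/1-PTA aggregation of per-time-point errors).
#' @param blockLen moving-block length; default \code{ceiling(N^(1/3))}.
#' @param nBoot number of replicates.
#' @param level confidence level.
#' @param seed RNG seed.
#' @return a [BootstrapResult-class].
#' @export
blockedBootstrapDiffCI <- function(errorsA, errorsB, metric = mean,
                                   blockLen = NULL, nBoot = 1000L,
                                   level = 0.95, seed = 1L) {
  errorsA <- rbind(errorsA); errorsB <- rbind(errorsB)
  if (!identical(dim(errorsA), dim(errorsB)))
    stop("error matrices must share shape (seeds x time points)")
  S <- nrow(errorsA); N <- ncol(errorsA)
  if (N < 1L || S < 1L) stop("empty error matrices")
  if (is.null(blockLen)) blockLen <- ceiling(N^(1 / 3))
  if (blockLen < 1L) stop("blockLen must be >= 1")
  blockLen <- min(blockLen, N)
  est <- metric(errorsA) - metric(errorsB)
  set.seed(seed)
  nStarts <- N - blockLen + 1L
  nBlocks <- ceiling(N / blockLen)
  diffs <- numeric(nBoot)
  for (b in seq_len(nBoot)) {
    starts <- sample.int(nStarts, nBlocks, replace = TRUE)
    tIdx <- as.integer(outer(0:(blockLen - 1L), starts, `+`))[seq_len(N)]
    sIdx <- sample.int(S, S, replace = TRUE)
    diffs[b] <- metric(errorsA[sIdx, tIdx, drop = FALSE]) -
      metric(errorsB[sIdx, tIdx, drop = FALSE])
  }
  alpha <- (1 - level) / 2
  qs <- stats::quantile(diffs, c(alpha, 1 - alpha), names = FALSE,
                        type = 7)
  new("BootstrapResult", estimate = est, lower = qs[1L], upper = qs[2L],
      level = level, blockLen = as.numeric(blockLen),
      nBoot = as.numeric(nBoot), seed = as.numeric(seed))
}

#' Does a bootstrap interval indicate a significant difference?
#'
#' \code{TRUE} iff the confidence interval excludes zero; a boundary
#' exactly at zero counts as non-exclusion.
#'
#' @param result a [BootstrapResult-class].
#' @return logical flag.
#' @export
significanceFlag <- function(result) {
  stopifnot(is(result, "BootstrapResult"))
  result@lower > 0 || result@upper < 0
}
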