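#' @include forecast.R baselines.R evaluation.R coherence.R io.R
NULL

#' Assemble and validate an experiment configuration
#'
#' Bundles the target series, the split convention, the window spec, the
#' (size x IC class x KP class x architecture x seed) grid, the noise-study
#' spec and the training/bootstrap settings. Defaults follow the studied
#' grid: sizes 1/10/100/1000, width classes S/M/L/XL for ICs and KPs, four
#' architectures, five seeds, and six noise levels per (kind, operation)
#' pair.
#'
#' @param system an [OdeSystem-class] or registered name.
#' @param target the observed (or fixture) [Trajectory-class].
#' @param trainEnd 0-based index of the last training time point
#'   (inclusive; the convention "time steps 0-18 train" means
#'   \code{trainEnd = 18}).
#' @param window list with \code{inputLen}, \code{horizon},
#'   \code{targetVars}.
#' @param sizes synthetic dataset sizes.
#' @param icClasses,kpClasses diversity width classes.
#' @param architectures model architectures.
#' @param seeds seed vector (one paired TL/DL run per seed).
#' @param noiseKinds,noiseOperation,noiseLevels noise-study enumeration
#'   (one kind and operation combination at a time).
#' @param train a [trainConfig()].
#' @param bootstrap list with \code{nBoot}, \code{level},
#'   optional \code{blockLen}.
#' @param centers optional named overrides of the system's interval centers.
#' @param hyper model hyperparameter overrides.
#' @param outDir optional directory for incremental per-cell results
#'   (makes grid runs resumable).
#' @return a validated list of class \code{"ExperimentConfig"}.
#' @export
experimentConfig <- function(system, target, trainEnd,
                             window = list(inputLen = 5L, horizon = 5L,
                                           targetVars = NULL),
                             sizes = c(1L, 10L, 100L, 1000L),
                             icClasses = c("S", "M", "L", "XL"),
                             kpClasses = c("S", "M", "L", "XL"),
                             architectures = c("lstm", "gru", "cnn", "dnn"),
                             seeds = 1:5,
                             noiseKinds = c("measurement", "environmental"),
                             noiseOperation = "multiplicative",
                             noiseLevels = defaultNoiseLevels(),
                             train = trainConfig(),
                             bootstrap = list(nBoot = 1000L, level = 0.95),
                             centers = NULL, hyper = list(),
                             outDir = NULL) {
  if (is.character(system)) system <- getOdeSystem(system)
  stopifnot(is(system, "OdeSystem"), is(target, "Trajectory"))
  window <- utils::modifyList(list(inputLen = 5L, horizon = 5L,
                                   targetVars = NULL), window)
  if (is.null(window$targetVars))
    window$targetVars <- colnames(target@values)
  if (!all(window$targetVars %in% colnames(target@values)))
    stop("targetVars not present in the target series")
  cls <- names(widthClassDefaults())
  if (!all(icClasses %in% cls) || !all(kpClasses %in% cls))
    stop("width classes must be among ", paste(cls, collapse = ", "))
  if (!all(architectures %in% c("lstm", "gru", "cnn", "dnn")))
    stop("unknown architecture in grid spec")
  if (!all(noiseKinds %in% c("measurement", "environmental")))
    stop("noise kinds must be measurement/environmental")
  stopifnot(all(sizes >= 1), length(seeds) >= 1, inherits(train, "TrainConfig"))
  # validate the split up front
  splitTarget(target, trainEnd, valFraction = train$valFraction,
              horizon = window$horizon)
  structure(list(system = system, target = target, trainEnd = trainEnd,
                 window = window, sizes = as.integer(sizes),
                 icClasses = icClasses, kpClasses = kpClasses,
                 architectures = architectures, seeds = as.integer(seeds),
                 noiseKinds = noiseKinds, noiseOperation = noiseOperation,
                 noiseLevels = noiseLevels, train = train,
                 bootstrap = utils::modifyList(
                   list(nBoot = 1000L, level = 0.95, blockLen = NULL),
                   bootstrap),
                 centers = centers, hyper = hyper, outDir = outDir),
            class = "ExperimentConfig")
}

#' Split a target series into train / validation / test regions
#'
#' Indices follow the convention that a stated boundary like "time steps
#' 0-18 for training" is 0-based and inclusive: the training region (used
#' for deep-learning training) spans points 1..(trainEnd+1) in R's 1-based
#' indexing, its last \code{valFraction} is the validation tail, and the
#' test region is everything after. ODE calibration uses the combined
#' train+validation region; evaluation windows target the test region only.
#' The three regions partition the series without overlap.
#'
#' @param target a [Trajectory-class].
#' @param trainEnd 0-based inclusive index of the last training point.
#' @param valFraction validation fraction of the training region.
#' @param horizon forecast horizon (the test region must be at least this
#'   long).
#' @return list with integer index vectors \code{train} (excluding the
#'   validation tail), \code{validation}, \code{trainFull} (train +
#'   validation), \code{test}.
#' @examples
#' tr <- generateFixtureTarget("sir", grid = 0:59, observationNoiseIQR = 0,
#'                             seed = 1)
#' sp <- splitTarget(tr, 18, horizon = 5)
#' range(sp$trainFull)  # 1 19
#' range(sp$test)       # 20 60
#' @export
splitTarget <- function(target, trainEnd, valFraction = 0.10, horizon = 5L) {
  stopifnot(is(target, "Trajectory"))
  N <- length(target@time)
  nTrain <- trainEnd + 1L  # 0-based inclusive boundary
  if (nTrain < 2L || nTrain >= N)
    stop("invalid split: trainEnd must leave a nonempty train and test region")
  if (N - nTrain < horizon)
    stop("test region shorter than the forecast horizon (", horizon, ")")
  nVal <- max(1L, ceiling(valFraction * nTrain))
  list(train = seq_len(nTrain - nVal),
       validation = (nTrain - nVal + 1L):nTrain,
       trainFull = seq_len(nTrain),
       test = (nTrain + 1L):N)
}

#' Enumerate the grid cells of an experiment configuration
#'
#' @param cfg an [experimentConfig()].
#' @return data frame with one row per (size, icClass, kpClass,
#'   architecture, seed) cell.
#' @export
enumerateGrid <- function(cfg) {
  stopifnot(inherits(cfg, "ExperimentConfig"))
  expand.grid(size = cfg$sizes, icClass = cfg$icClasses,
              kpClass = cfg$kpClasses, architecture = cfg$architectures,
              seed = cfg$seeds, stringsAsFactors = FALSE)
}

#' Enumerate the noise-study cells
#'
#' One (kind, operation) combination at a time, each at every level.
#'
#' @param cfg an [experimentConfig()].
#' @return data frame with one row per (noiseKind, noiseOperation,
#'   noiseLevel, seed) cell.
#' @export
enumerateNoiseStudy <- function(cfg) {
  stopifnot(inherits(cfg, "ExperimentConfig"))
  expand.grid(noiseKind = cfg$noiseKinds,
              noiseOperation = cfg$noiseOperation,
              noiseLevel = cfg$noiseLevels, seed = cfg$seeds,
              stringsAsFactors = FALSE)
}

# Metrics of one forecast set, plus per-time-point error vectors.
.forecastMetrics <- function(fs) {
  list(mae = mae(fs), rmse = rmse(fs), pta = pta(fs),
       ptErrAbs = perTimepointErrors(fs, type = "abs"),
       ptErrTrend = perTimepointErrors(fs, type = "trend"))
}

# ODE-baseline metrics on the test region: single simulated series, origin
# for the trend metric is the last calibrated value per target variable.
.odeMetrics <- function(system, calib, target, split, targetVars) {
  fc <- forecastODE(system, calib, target@time[split$test])
  pred <- fc@values[, targetVars, drop = FALSE]
  obs <- target@values[split$test, targetVars, drop = FALSE]
  origin <- target@values[max(split$trainFull), targetVars]
  originM <- matrix(origin, nrow(obs), length(targetVars), byrow = TRUE)
  ptErr <- rowMeans(abs(pred - obs))
  names(ptErr) <- split$test
  list(mae = mae(pred, obs), rmse = rmse(pred, obs),
       pta = mean(sign(pred - originM) == sign(obs - originM)),
       ptErrAbs = ptErr)
}

# One paired TL/DL cell: same seed -> same initialization, data order and
# batching; the arms differ only in pre-training.
.runCell <- function(cfg, dataset, archId, seed, split) {
  target <- cfg$target
  trainTraj <- subsetTrajectory(target, split$trainFull)
  w <- cfg$window
  cellCfg <- cfg$train
  cellCfg$seed <- .deriveSeed(cellCfg$seed, seed)
  nVars <- ncol(target@values)
  init <- buildModel(archId, inputLen = w$inputLen, nVars = nVars,
                     horizon = w$horizon, nTargets = length(w$targetVars),
                     targetVars = w$targetVars, hyper = cfg$hyper,
                     seed = cellCfg$seed)
  tl <- pretrain(init, dataset, cellCfg)
  tl <- finetune(tl, trainTraj, cellCfg)
  dl <- trainDLBaselineFromModel(init, trainTraj, cellCfg)
  tlFs <- predictSeries(tl, target, split$test)
  dlFs <- predictSeries(dl, target, split$test)
  list(tl = .forecastMetrics(tlFs), dl = .forecastMetrics(dlFs))
}

#' Run the synthetic-dataset characteristics grid
#'
#' For every (size, IC class, KP class) a noise-free synthetic dataset is
#' generated (noise enters only the dedicated noise study); for every
#' architecture and seed a transfer-learning run (pre-train, head-only
#' fine-tune) and a paired DL baseline are trained and evaluated on the
#' test region; one ODE calibration serves all cells of a target. Cell
#' failures are recorded with their reason and the run continues. With
#' \code{cfg$outDir} set, per-cell results are written incrementally and
#' reused on a rerun.
#'
#' @param cfg an [experimentConfig()].
#' @param verbose print per-cell progress?
#' @return a [GridResult-class].
#' @export
runGrid <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "ExperimentConfig"))
  system <- cfg$system
  target <- cfg$target
  split <- splitTarget(target, cfg$trainEnd,
                       valFraction = cfg$train$valFraction,
                       horizon = cfg$window$horizon)
  ode <- tryCatch({
    calib <- calibrateODE(system,
                          subsetTrajectory(target, split$trainFull),
                          seed = cfg$train$seed)
    .odeMetrics(system, calib, target, split, cfg$window$targetVars)
  }, error = function(e) {
    warning("ODE baseline failed: ", conditionMessage(e))
    NULL
  })
  if (!is.null(cfg$outDir))
    dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)

  rows <- list()
  ptStore <- list()
  for (size in cfg$sizes) for (ic in cfg$icClasses) for (kp in cfg$kpClasses) {
    div <- diversityConfig(system, icClass = ic, kpClass = kp,
                           centers = cfg$centers)
    dsSeed <- .deriveSeed(cfg$train$seed, size,
                          match(ic, c("S", "M", "L", "XL")),
                          match(kp, c("S", "M", "L", "XL")))
    dataset <- tryCatch(
      generateDataset(system, div, noiseConfig("none"), nSeries = size,
                      grid = target@time, seed = dsSeed),
      error = function(e) e)
    for (arch in cfg$architectures) for (sd in cfg$seeds) {
      key <- sprintf("size%d_ic%s_kp%s_%s_seed%d", size, ic, kp, arch, sd)
      cellFile <- if (!is.null(cfg$outDir))
        file.path(cfg$outDir, paste0("cell_", key, ".json")) else NULL
      if (!is.null(cellFile) && file.exists(cellFile)) {
        row <- as.data.frame(jsonlite::read_json(cellFile,
                                                 simplifyVector = TRUE)$row)
        rows[[key]] <- row
        pt <- jsonlite::read_json(cellFile, simplifyVector = TRUE)$pt
        if (!is.null(pt)) ptStore[[key]] <- pt
        next
      }
      if (inherits(dataset, "error")) {
        rows[[key]] <- .failRow(size, ic, kp, arch, sd,
                                conditionMessage(dataset), ode)
        next
      }
      res <- tryCatch(.runCell(cfg, dataset, arch, sd, split),
                      error = function(e) e)
      if (inherits(res, "error")) {
        rows[[key]] <- .failRow(size, ic, kp, arch, sd,
                                conditionMessage(res), ode)
        next
      }
      row <- data.frame(
        size = size, icClass = ic, kpClass = kp, architecture = arch,
        seed = sd,
        tl_mae = res$tl$mae, tl_rmse = res$tl$rmse, tl_pta = res$tl$pta,
        dl_mae = res$dl$mae, dl_rmse = res$dl$rmse, dl_pta = res$dl$pta,
        ode_mae = if (is.null(ode)) NA_real_ else ode$mae,
        ode_rmse = if (is.null(ode)) NA_real_ else ode$rmse,
        ode_pta = if (is.null(ode)) NA_real_ else ode$pta,
        status = "ok", reason = "")
      rows[[key]] <- row
      ptStore[[key]] <- list(tlAbs = res$tl$ptErrAbs,
                             dlAbs = res$dl$ptErrAbs,
                             tlTrend = res$tl$ptErrTrend,
                             dlTrend = res$dl$ptErrTrend)
      if (!is.null(cellFile))
        jsonlite::write_json(list(row = row, pt = ptStore[[key]]), cellFile,
                             auto_unbox = TRUE, digits = NA)
      if (verbose)
        message(key, ": TL MAE=", signif(res$tl$mae, 4),
                " DL MAE=", signif(res$dl$mae, 4))
    }
  }
  cells <- do.call(rbind, rows)
  rownames(cells) <- NULL
  summary <- .summariseGrid(cells, ptStore, cfg, ode)
  new("GridResult", cells = cells, summary = summary,
      config = list(trainEnd = cfg$trainEnd, sizes = cfg$sizes,
                    icClasses = cfg$icClasses, kpClasses = cfg$kpClasses,
                    architectures = cfg$architectures, seeds = cfg$seeds,
                    system = system@name, baseSeed = cfg$train$seed))
}

.failRow <- function(size, ic, kp, arch, sd, reason, ode) {
  data.frame(size = size, icClass = ic, kpClass = kp, architecture = arch,
             seed = sd, tl_mae = NA_real_, tl_rmse = NA_real_,
             tl_pta = NA_real_, dl_mae = NA_real_, dl_rmse = NA_real_,
             dl_pta = NA_real_,
             ode_mae = if (is.null(ode)) NA_real_ else ode$mae,
             ode_rmse = if (is.null(ode)) NA_real_ else ode$rmse,
             ode_pta = if (is.null(ode)) NA_real_ else ode$pta,
             status = "failed", reason = as.character(reason))
}

# Aggregate cells over seeds per configuration; attach relative changes and
# paired blocked-bootstrap CIs (TL vs DL on abs and trend errors).
.summariseGrid <- function(cells, ptStore, cfg, ode) {
  keyCols <- c("size", "icClass", "kpClass", "architecture")
  ok <- cells[cells$status == "ok", , drop = FALSE]
  if (nrow(ok) == 0L)
    return(data.frame())
  keys <- unique(ok[keyCols])
  out <- list()
  for (i in seq_len(nrow(keys))) {
    kk <- keys[i, ]
    sel <- ok$size == kk$size & ok$icClass == kk$icClass &
      ok$kpClass == kk$kpClass & ok$architecture == kk$architecture
    sub <- ok[sel, , drop = FALSE]
    ptKeys <- sprintf("size%d_ic%s_kp%s_%s_seed%d", kk$size, kk$icClass,
                      kk$kpClass, kk$architecture, sub$seed)
    pts <- ptStore[ptKeys]
    haveAll <- all(!vapply(pts, is.null, TRUE))
    ciL <- ciU <- NA_real_; sig <- NA
    if (haveAll && length(pts) >= 1L) {
      A <- do.call(rbind, lapply(pts, function(p) unlist(p$tlAbs)))
      B <- do.call(rbind, lapply(pts, function(p) unlist(p$dlAbs)))
      bs <- blockedBootstrapDiffCI(A, B,
                                   blockLen = cfg$bootstrap$blockLen,
                                   nBoot = cfg$bootstrap$nBoot,
                                   level = cfg$bootstrap$level,
                                   seed = .deriveSeed(cfg$train$seed, 71L, i))
      ciL <- bs@lower; ciU <- bs@upper; sig <- significanceFlag(bs)
    }
    row <- data.frame(
      kk, nSeeds = nrow(sub),
      tl_mae = mean(sub$tl_mae), tl_rmse = mean(sub$tl_rmse),
      tl_one_minus_pta = mean(1 - sub$tl_pta),
      dl_mae = mean(sub$dl_mae),
      dl_one_minus_pta = mean(1 - sub$dl_pta),
      rel_mae_vs_dl = relativeChange(mean(sub$tl_mae), mean(sub$dl_mae)),
      rel_pta_vs_dl = if (mean(1 - sub$dl_pta) > 0)
        relativeChange(mean(1 - sub$tl_pta), mean(1 - sub$dl_pta))
      else NA_real_,
      rel_mae_vs_ode = if (!is.null(ode))
        relativeChange(mean(sub$tl_mae), ode$mae) else NA_real_,
      ci_mae_diff_lower = ciL, ci_mae_diff_upper = ciU,
      significant_vs_dl = sig)
    out[[i]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Select the best grid configuration
#'
#' Configurations (size, IC class, KP class, architecture) are ranked by
#' seed-mean MAE; ties are broken by mean 1-PTA, then by smaller dataset
#' size.
#'
#' @param results a [GridResult-class].
#' @return one-row data frame with the winning configuration key.
#' @export
selectBest <- function(results) {
  stopifnot(is(results, "GridResult"))
  s <- results@summary
  if (nrow(s) == 0L) stop("all grid cells failed; nothing to select")
  ord <- order(s$tl_mae, s$tl_one_minus_pta, s$size)
  s[ord[1L], c("size", "icClass", "kpClass", "architecture", "tl_mae",
               "tl_one_minus_pta")]
}

#' Run the noise study at a fixed best configuration
#'
#' For each allowed (noise kind, operation) pair and each level, the
#' synthetic dataset is regenerated at the best (size, diversity) with that
#' noise and the transfer-learning runs are repeated across seeds (the DL
#' baseline needs no regeneration: it never sees synthetic data).
#' Infeasible combinations (generation failures, e.g. environmental noise
#' destabilising a stiff system) are recorded with their reason and
#' skipped.
#'
#' @param cfg an [experimentConfig()].
#' @param best one-row configuration key as returned by [selectBest()].
#' @param verbose print progress?
#' @return a [GridResult-class] whose cells carry noise columns.
#' @export
runNoiseStudy <- function(cfg, best, verbose = FALSE) {
  stopifnot(inherits(cfg, "ExperimentConfig"))
  system <- cfg$system
  target <- cfg$target
  split <- splitTarget(target, cfg$trainEnd,
                       valFraction = cfg$train$valFraction,
                       horizon = cfg$window$horizon)
  div <- diversityConfig(system, icClass = best$icClass,
                         kpClass = best$kpClass, centers = cfg$centers)
  arch <- best$architecture
  rows <- list()
  for (kind in cfg$noiseKinds) for (op in cfg$noiseOperation) {
    for (lev in cfg$noiseLevels) {
      noise <- noiseConfig(kind, op, lev)
      dsSeed <- .deriveSeed(cfg$train$seed, best$size, match(kind,
                            c("measurement", "environmental")),
                            round(1e6 * lev))
      dataset <- tryCatch(
        generateDataset(system, div, noise, nSeries = best$size,
                        grid = target@time, seed = dsSeed),
        error = function(e) e)
      for (sd in cfg$seeds) {
        key <- sprintf("%s_%s_lev%g_seed%d", kind, op, lev, sd)
        if (inherits(dataset, "error")) {
          row <- .failRow(best$size, best$icClass, best$kpClass, arch, sd,
                          conditionMessage(dataset), NULL)
        } else {
          res <- tryCatch(.runCell(cfg, dataset, arch, sd, split),
                          error = function(e) e)
          row <- if (inherits(res, "error"))
            .failRow(best$size, best$icClass, best$kpClass, arch, sd,
                     conditionMessage(res), NULL)
          else
            data.frame(size = best$size, icClass = best$icClass,
                       kpClass = best$kpClass, architecture = arch,
                       seed = sd, tl_mae = res$tl$mae,
                       tl_rmse = res$tl$rmse, tl_pta = res$tl$pta,
                       dl_mae = res$dl$mae, dl_rmse = res$dl$rmse,
                       dl_pta = res$dl$pta, ode_mae = NA_real_,
                       ode_rmse = NA_real_, ode_pta = NA_real_,
                       status = "ok", reason = "")
        }
        row$noiseKind <- kind; row$noiseOperation <- op; row$noiseLevel <- lev
        rows[[key]] <- row
        if (verbose) message(key, ": status ", row$status)
      }
    }
  }
  cells <- do.call(rbind, rows)
  rownames(cells) <- NULL
  new("GridResult", cells = cells, summary = .summariseNoise(cells),
      config = list(best = best, noiseKinds = cfg$noiseKinds,
                    noiseOperation = cfg$noiseOperation,
                    noiseLevels = cfg$noiseLevels))
}

.summariseNoise <- function(cells) {
  ok <- cells[cells$status == "ok", , drop = FALSE]
  if (nrow(ok) == 0L) return(data.frame())
  agg <- stats::aggregate(
    cbind(tl_mae, dl_mae, tl_pta) ~ noiseKind + noiseOperation + noiseLevel,
    data = ok, FUN = mean)
  agg$rel_mae_vs_dl <- 100 * (agg$tl_mae - agg$dl_mae) / agg$dl_mae
  agg
}

#' Write a grid result to disk
#'
#' Cells and summary as CSV, config snapshot as JSON.
#'
#' @param results a [GridResult-class].
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeGridResult <- function(results, dir) {
  stopifnot(is(results, "GridResult"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(results@cells, file.path(dir, "cells.csv"),
                   row.names = FALSE)
  utils::write.csv(results@summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(results@config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
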