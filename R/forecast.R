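#' @include nn.R windows.R generate.R
NULL

#' Training configuration
#'
#' @param maxEpochs maximum pre-training epochs (early stopping usually
#'   terminates sooner). \code{maxEpochs = 0} returns the initial model
#'   unchanged.
#' @param patience epochs without validation improvement before stopping.
#' @param batch minibatch size.
#' @param lr Adam learning rate.
#' @param valFraction fraction of training series (or time points, for
#'   single-series data) held out for validation.
#' @param fineTuneEpochs number of head-only fine-tuning epochs.
#' @param seed seed governing initial shuffling and batching.
#' @return a validated list of class \code{"TrainConfig"}.
#' @export
trainConfig <- function(maxEpochs = 200L, patience = 5L, batch = 32L,
                        lr = 1e-3, valFraction = 0.10, fineTuneEpochs = 5L,
                        seed = 1L) {
  stopifnot(maxEpochs >= 0, patience >= 1, batch >= 1, lr > 0,
            valFraction > 0, valFraction < 1, fineTuneEpochs >= 1)
  structure(list(maxEpochs = as.integer(maxEpochs),
                 patience = as.integer(patience),
                 batch = as.integer(batch), lr = lr,
                 valFraction = valFraction,
                 fineTuneEpochs = as.integer(fineTuneEpochs),
                 seed = as.integer(seed)),
            class = "TrainConfig")
}

#' Build a randomly initialized forecast model
#'
#' Architectures: \code{"lstm"} and \code{"gru"} (one recurrent layer,
#' default 64 units, last hidden state as feature), \code{"cnn"} (two 1-D
#' convolutions, kernel 3, default 32 channels, zero same-padding, global
#' mean pooling), \code{"dnn"} (flatten plus one dense layer, default 64
#' units). Every body feeds the same two-layer perceptron head (default 32
#' hidden units) emitting \code{horizon x nTargets} values. Initialization
#' is reproducible from \code{seed}.
#'
#' @param architecture one of \code{"lstm"}, \code{"gru"}, \code{"cnn"},
#'   \code{"dnn"}.
#' @param inputLen input window length.
#' @param nVars number of input variables.
#' @param horizon forecast horizon.
#' @param nTargets number of target variables.
#' @param targetVars names of target variables (defaults to
#'   \code{paste0("y", 1:nTargets)} until training data names them).
#' @param hyper optional hyperparameter overrides: \code{units},
#'   \code{channels}, \code{dnnUnits}, \code{headHidden}.
#' @param seed initialization seed.
#' @return a [ForecastModel-class].
#' @examples
#' m <- buildModel("dnn", inputLen = 5, nVars = 2, horizon = 5,
#'                 nTargets = 1, seed = 1)
#' @export
buildModel <- function(architecture = c("lstm", "gru", "cnn", "dnn"),
                       inputLen, nVars, horizon, nTargets,
                       targetVars = NULL, hyper = list(), seed = 1L) {
  architecture <- match.arg(architecture)
  stopifnot(inputLen >= 1, nVars >= 1, horizon >= 1, nTargets >= 1)
  h <- utils::modifyList(list(units = 64L, channels = 32L, dnnUnits = 64L,
                              headHidden = 32L), hyper)
  set.seed(seed)
  body <- .initBody(architecture, inputLen, nVars, h)
  fd <- .featureDim(architecture, h)
  hh <- h$headHidden
  head <- list(W1 = matrix(.unif(fd * hh, fd), fd, hh),
               b1 = numeric(hh),
               W2 = matrix(.unif(hh * horizon * nTargets, hh), hh,
                           horizon * nTargets),
               b2 = numeric(horizon * nTargets))
  if (is.null(targetVars)) targetVars <- paste0("y", seq_len(nTargets))
  new("ForecastModel", architecture = architecture,
      inputLen = as.numeric(inputLen), nVars = as.numeric(nVars),
      horizon = as.numeric(horizon), nTargets = as.numeric(nTargets),
      targetVars = targetVars, hyper = h, body = body, head = head,
      scaler = list(fitted = FALSE),
      log = data.frame(), seed = as.numeric(seed))
}

# ---- scaling ------------------------------------------------------------

# Per-variable standardization, fitted once on the (pre-)training data and
# reused unchanged for fine-tuning and inference.
.fitScaler <- function(valuesList, vars) {
  pooled <- do.call(rbind, valuesList)[, vars, drop = FALSE]
  center <- colMeans(pooled)
  scale <- apply(pooled, 2L, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  list(center = center, scale = scale, vars = vars, fitted = TRUE)
}

#' Apply / invert the model's per-variable scaler
#'
#' @param model a [ForecastModel-class] with a fitted scaler.
#' @param values numeric matrix with variable column names.
#' @param invert map scaled values back to original units?
#' @return the transformed matrix.
#' @export
applyScaler <- function(model, values, invert = FALSE) {
  sc <- model@scaler
  if (!isTRUE(sc$fitted)) stop("model scaler has not been fitted yet")
  vars <- colnames(values)
  ctr <- sc$center[vars]; scl <- sc$scale[vars]
  if (anyNA(ctr)) stop("scaler does not cover variables: ",
                       paste(vars[is.na(ctr)], collapse = ", "))
  if (invert) sweep(sweep(values, 2L, scl, `*`), 2L, ctr, `+`)
  else sweep(sweep(values, 2L, ctr, `-`), 2L, scl, `/`)
}

# Scale a WindowSet into (X, Y) training arrays using the model scaler.
.scaledXY <- function(model, ws) {
  sc <- model@scaler
  vars <- dimnames(ws$inputs)[[3L]]
  X <- ws$inputs
  for (j in seq_along(vars))
    X[, , j] <- (X[, , j] - sc$center[[vars[j]]]) / sc$scale[[vars[j]]]
  Yarr <- ws$targets
  for (j in seq_along(ws$targetVars))
    Yarr[, , j] <- (Yarr[, , j] - sc$center[[ws$targetVars[j]]]) /
      sc$scale[[ws$targetVars[j]]]
  K <- dim(Yarr)[1L]
  list(X = X, Y = matrix(Yarr, K, dim(Yarr)[2L] * dim(Yarr)[3L]))
}

# ---- training loop ------------------------------------------------------

.valLoss <- function(model, X, Y) {
  out <- .modelForward(model, X)$out
  mean((out - Y)^2)
}

# Shared minibatch loop. headOnly freezes the body; exactEpochs disables
# early stopping (fine-tuning). Checkpoints the parameters with minimal
# validation loss over epochs 1..E.
.trainLoop <- function(model, trainXY, valXY, cfg, headOnly = FALSE,
                       exactEpochs = NULL, phase = "train") {
  nEpochs <- if (is.null(exactEpochs)) cfg$maxEpochs else exactEpochs
  logRows <- list()
  if (nEpochs == 0L) return(model)
  set.seed(.deriveSeed(cfg$seed, 101L))
  K <- dim(trainXY$X)[1L]
  # body and head can share parameter names (e.g. W1); namespace them
  pack <- function(body, head)
    c(stats::setNames(body, paste0("body.", names(body))),
      stats::setNames(head, paste0("head.", names(head))))
  adam <- .adamInit(pack(model@body, model@head))
  best <- list(loss = Inf, body = model@body, head = model@head)
  sinceBest <- 0L
  for (ep in seq_len(nEpochs)) {
    idx <- sample.int(K)
    epochLoss <- 0
    nbatch <- 0L
    for (start in seq(1L, K, by = cfg$batch)) {
      bi <- idx[start:min(start + cfg$batch - 1L, K)]
      Xb <- trainXY$X[bi, , , drop = FALSE]
      Yb <- trainXY$Y[bi, , drop = FALSE]
      fw <- .modelForward(model, Xb)
      loss <- mean((fw$out - Yb)^2)
      dOut <- 2 * (fw$out - Yb) / length(Yb)
      gr <- .modelBackward(model, fw, dOut, headOnly = headOnly)
      grads <- c(
        if (!headOnly) stats::setNames(gr$body,
                                       paste0("body.", names(gr$body))),
        stats::setNames(gr$head, paste0("head.", names(gr$head))))
      params <- pack(model@body, model@head)
      upd <- .adamStep(params[names(grads)], grads,
                       .subAdam(adam, names(grads)), cfg$lr)
      adam <- .mergeAdam(adam, upd$state, names(grads))
      for (nm in names(upd$params)) {
        bare <- sub("^(body|head)\\.", "", nm)
        if (startsWith(nm, "body.")) model@body[[bare]] <- upd$params[[nm]]
        else model@head[[bare]] <- upd$params[[nm]]
      }
      epochLoss <- epochLoss + loss
      nbatch <- nbatch + 1L
    }
    vl <- .valLoss(model, valXY$X, valXY$Y)
    logRows[[ep]] <- data.frame(phase = phase, epoch = ep,
                                train_loss = epochLoss / nbatch,
                                val_loss = vl)
    if (vl < best$loss) {
      best <- list(loss = vl, body = model@body, head = model@head)
      sinceBest <- 0L
    } else sinceBest <- sinceBest + 1L
    if (is.null(exactEpochs) && sinceBest >= cfg$patience) break
  }
  model@body <- best$body
  model@head <- best$head
  model@log <- rbind(model@log, do.call(rbind, logRows))
  model
}

.subAdam <- function(adam, nms)
  list(m = adam$m[nms], v = adam$v[nms], t = adam$t)

.mergeAdam <- function(adam, sub, nms) {
  adam$m[nms] <- sub$m; adam$v[nms] <- sub$v; adam$t <- sub$t
  adam
}

# ---- user-facing training ------------------------------------------------

#' Pre-train a model on a synthetic dataset
#'
#' Holds out a validation fraction of whole series (default 10%; a
#' single-series dataset falls back to a time-tail split with a notice),
#' fits the per-variable scaler on the training portion, minimises mean
#' squared error on scaled targets, and returns the checkpoint with minimal
#' validation loss (early stopping with \code{cfg$patience}). The per-epoch
#' train/validation losses are appended to the model's training log.
#'
#' @param model a freshly built [ForecastModel-class].
#' @param dataset a [TimeSeriesDataset-class].
#' @param cfg a [trainConfig()].
#' @param targetVars forecast target variables (default: model's, or all
#'   dataset variables).
#' @return the pre-trained [ForecastModel-class].
#' @export
pretrain <- function(model, dataset, cfg = trainConfig(),
                     targetVars = NULL) {
  stopifnot(is(model, "ForecastModel"), is(dataset, "TimeSeriesDataset"))
  if (is.null(targetVars)) targetVars <- model@targetVars
  if (!all(targetVars %in% dataset@variables))
    targetVars <- dataset@variables[seq_len(model@nTargets)]
  model@targetVars <- targetVars
  n <- nSeries(dataset)
  L <- model@inputLen; H <- model@horizon
  if (length(dataset@time) < L + H)
    stop("dataset series too short to window; need at least ", L + H,
         " time points")
  if (n >= 2L) {
    set.seed(.deriveSeed(cfg$seed, 7L))
    nVal <- max(1L, round(cfg$valFraction * n))
    valIdx <- sample.int(n, nVal)
    trainTr <- dataset@trajectories[-valIdx]
    valTr <- dataset@trajectories[valIdx]
    model@scaler <- .fitScaler(lapply(trainTr, function(t) t@values),
                               dataset@variables)
    trWS <- .bindWindows(lapply(trainTr, makeWindows, inputLen = L,
                                horizon = H, targetVars = targetVars))
    vaWS <- .bindWindows(lapply(valTr, makeWindows, inputLen = L,
                                horizon = H, targetVars = targetVars))
  } else {
    message("single-series dataset: validation falls back to a time-tail split")
    tr <- dataset@trajectories[[1L]]
    N <- length(tr@time)
    tail <- max(1L, ceiling(cfg$valFraction * N))
    model@scaler <- .fitScaler(list(tr@values), dataset@variables)
    sp <- .tailSplit(makeWindows(tr, L, H, targetVars), N, H, tail)
    trWS <- sp$train
    vaWS <- sp$val
  }
  .trainLoop(model, .scaledXY(model, trWS), .scaledXY(model, vaWS), cfg,
             headOnly = FALSE, phase = "pretrain")
}

# Assign windows whose target region reaches into the last `tail` time
# points to validation; guarantee both splits are nonempty (a single-window
# series uses its one window for both).
.tailSplit <- function(all, N, H, tail) {
  inTail <- all$origins$t0Index + H > N - tail
  if (all(inTail) && length(inTail) > 1L) inTail[-length(inTail)] <- FALSE
  if (!any(inTail)) inTail[length(inTail)] <- TRUE
  if (all(inTail)) return(list(train = all, val = all))
  list(train = .sliceWindows(all, !inTail), val = .sliceWindows(all, inTail))
}

.sliceWindows <- function(ws, keep) {
  structure(list(inputs = ws$inputs[keep, , , drop = FALSE],
                 targets = ws$targets[keep, , , drop = FALSE],
                 origins = ws$origins[keep, , drop = FALSE],
                 lastInputs = ws$lastInputs[keep, , drop = FALSE],
                 targetVars = ws$targetVars), class = "WindowSet")
}

# Split a target training region into head windows and a validation tail:
# validation windows are those whose target region reaches into the last
# ceil(valFraction * N) time points.
.targetSplitWindows <- function(model, targetTrain, cfg) {
  L <- model@inputLen; H <- model@horizon
  N <- length(targetTrain@time)
  if (N < L + H)
    stop("target series too short to window; minimum length is ", L + H,
         " (inputLen + horizon)")
  all <- makeWindows(targetTrain, L, H, model@targetVars)
  tail <- max(1L, ceiling(cfg$valFraction * N))
  .tailSplit(all, N, H, tail)
}

#' Fine-tune the head of a pre-trained model on target data
#'
#' Trains only the two-layer perceptron head for exactly
#' \code{cfg$fineTuneEpochs} epochs on the target training region; the body
#' parameters are frozen bit-for-bit. The returned parameters are the
#' checkpoint with minimal loss on the target's validation tail. The scaler
#' fitted at pre-training is reused unchanged.
#'
#' @param model a pre-trained (or freshly initialized) [ForecastModel-class].
#' @param targetTrain a [Trajectory-class] restricted to the training region
#'   (including its validation tail).
#' @param cfg a [trainConfig()].
#' @return the fine-tuned [ForecastModel-class].
#' @export
finetune <- function(model, targetTrain, cfg = trainConfig()) {
  stopifnot(is(model, "ForecastModel"), is(targetTrain, "Trajectory"))
  if (!isTRUE(model@scaler$fitted))
    model@scaler <- .fitScaler(list(targetTrain@values),
                               colnames(targetTrain@values))
  sp <- .targetSplitWindows(model, targetTrain, cfg)
  .trainLoop(model, .scaledXY(model, sp$train), .scaledXY(model, sp$val),
             cfg, headOnly = TRUE, exactEpochs = cfg$fineTuneEpochs,
             phase = "finetune")
}

#' Forecast all windows targeting an evaluation region
#'
#' Emits one \code{horizon x nTargets} forecast, in original units, for
#' every window whose target region lies entirely inside
#' \code{evalRegion}; input windows may extend into the training region.
#'
#' @param model a trained [ForecastModel-class].
#' @param context the full observed [Trajectory-class].
#' @param evalRegion integer vector of (1-based) time indices forming the
#'   evaluation region.
#' @return list of class \code{"ForecastSet"}: \code{pred} and \code{obs}
#'   (K x horizon x nTargets arrays), \code{origins}, \code{lastInputs},
#'   \code{targetVars}. Empty (with a warning) if no window fits.
#' @export
predictSeries <- function(model, context, evalRegion) {
  stopifnot(is(model, "ForecastModel"), is(context, "Trajectory"))
  # makeWindows' own empty-set warning is superseded by the message below
  ws <- withCallingHandlers(
    makeWindows(context, model@inputLen, model@horizon, model@targetVars,
                targetRegion = evalRegion),
    warning = function(w) invokeRestart("muffleWarning"))
  K <- nrow(ws$origins)
  if (K == 0L) {
    warning("no forecast windows fit inside the evaluation region")
    return(structure(list(pred = ws$targets, obs = ws$targets,
                          origins = ws$origins, lastInputs = ws$lastInputs,
                          targetVars = ws$targetVars), class = "ForecastSet"))
  }
  sc <- model@scaler
  X <- ws$inputs
  vars <- dimnames(X)[[3L]]
  for (j in seq_along(vars))
    X[, , j] <- (X[, , j] - sc$center[[vars[j]]]) / sc$scale[[vars[j]]]
  out <- .modelForward(model, X)$out
  pred <- array(out, c(K, model@horizon, model@nTargets))
  for (j in seq_along(model@targetVars))
    pred[, , j] <- pred[, , j] * sc$scale[[model@targetVars[j]]] +
      sc$center[[model@targetVars[j]]]
  dimnames(pred) <- dimnames(ws$targets)
  structure(list(pred = pred, obs = ws$targets, origins = ws$origins,
                 lastInputs = ws$lastInputs, targetVars = ws$targetVars),
            class = "ForecastSet")
}
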