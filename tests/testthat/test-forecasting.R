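test_that("sliding windows enumerate all maximal stride-1 slices", {
  tr <- sirTrajectory(0:11)  # N = 12
  ws <- makeWindows(tr, 5, 5, "I")
  expect_equal(nrow(ws$origins), 3)  # 12 - 5 - 5 + 1
  # window contents are contiguous slices of the source
  v <- trajValues(tr)
  for (k in seq_len(3)) {
    p <- ws$origins$t0Index[k]
    expect_equal(ws$inputs[k, , ], v[(p - 4):p, ])
    expect_equal(as.numeric(ws$targets[k, , 1]), v[(p + 1):(p + 5), "I"])
    expect_equal(ws$lastInputs[k, "I"], v[p, "I"])
  }
  # N = 10: exactly one window covering the whole series
  ws1 <- makeWindows(sirTrajectory(0:9), 5, 5, "I")
  expect_equal(nrow(ws1$origins), 1)
  expect_equal(ws1$origins$t0Index, 5)
  # N = 9: too short -> empty set with a warning, not an error
  expect_warning(ws0 <- makeWindows(sirTrajectory(0:8), 5, 5, "I"),
                 "no windows")
  expect_equal(nrow(ws0$origins), 0)
})

test_that("model construction is seeded, shaped and counted correctly", {
  for (arch in c("lstm", "gru", "cnn", "dnn")) {
    a <- buildModel(arch, 5, 2, 5, 1, seed = 42)
    b <- buildModel(arch, 5, 2, 5, 1, seed = 42)
    expect_identical(bodyParameters(a), bodyParameters(b))
    expect_identical(headParameters(a), headParameters(b))
    X <- array(rnorm(3 * 5 * 2), c(3, 5, 2))
    out <- odetransfer:::.modelForward(a, X)$out
    expect_equal(dim(out), c(3L, 5L))
    expect_true(all(is.finite(out)))
  }
  expect_error(buildModel("transformer", 5, 2, 5, 1), "arg")
  # head parameter count: (featureDim+1)*hidden + (hidden+1)*H*nTargets
  m <- buildModel("dnn", 5, 2, 5, 1, seed = 1)
  hp <- headParameters(m)
  fd <- nrow(hp$W1); hh <- ncol(hp$W1)
  expect_equal(sum(lengths(hp)), (fd + 1) * hh + (hh + 1) * 5 * 1)
})

test_that("pretraining learns, checkpoints the best epoch and is deterministic", {
  sys <- getOdeSystem("sir")
  div <- diversityConfig(sys, icClass = "S", kpClass = "M")
  ds <- generateDataset(sys, div, noiseConfig("none"), 10, 0:29, seed = 4)
  cfg <- trainConfig(maxEpochs = 8, seed = 9)
  m <- buildModel("dnn", 5, 3, 5, 1, targetVars = "I", seed = 9)
  mt <- pretrain(m, ds, cfg)
  log <- trainingLog(mt)
  expect_gt(nrow(log), 0)
  expect_lt(log$train_loss[nrow(log)], log$train_loss[1])
  # the returned parameters are the checkpoint with minimal validation loss:
  # rebuild the validation split pretrain used and recompute its loss
  set.seed(odetransfer:::.deriveSeed(cfg$seed, 7L))
  valIdx <- sample.int(nSeries(ds), max(1L, round(0.1 * nSeries(ds))))
  vaWS <- odetransfer:::.bindWindows(
    lapply(trajectories(ds)[valIdx], makeWindows, inputLen = 5, horizon = 5,
           targetVars = "I"))
  vaXY <- odetransfer:::.scaledXY(mt, vaWS)
  expect_equal(odetransfer:::.valLoss(mt, vaXY$X, vaXY$Y),
               min(log$val_loss), tolerance = 1e-12)
  # determinism under matched seed and data
  mt2 <- pretrain(buildModel("dnn", 5, 3, 5, 1, targetVars = "I", seed = 9),
                  ds, cfg)
  expect_identical(bodyParameters(mt), bodyParameters(mt2))
  expect_identical(headParameters(mt), headParameters(mt2))
  # single-series dataset: time-tail validation fallback with a notice
  ds1 <- generateDataset(sys, div, noiseConfig("none"), 1, 0:29, seed = 5)
  expect_message(pretrain(m, ds1, trainConfig(maxEpochs = 2, seed = 1)),
                 "time-tail")
})

test_that("fine-tuning changes the head only and helps on matched dynamics", {
  sys <- getOdeSystem("sir")
  div <- diversityConfig(sys, icClass = "S", kpClass = "M")
  ds <- generateDataset(sys, div, noiseConfig("none"), 20, 0:39, seed = 6)
  cfg <- trainConfig(maxEpochs = 15, seed = 1)
  target <- generateFixtureTarget("sir", grid = 0:39,
                                  observationNoiseIQR = 0, seed = 8)
  sp <- splitTarget(target, 18, horizon = 5)
  trainTraj <- subsetTrajectory(target, sp$trainFull)
  pre <- pretrain(buildModel("gru", 5, 3, 5, 1, targetVars = "I", seed = 1),
                  ds, cfg)
  ft <- finetune(pre, trainTraj, cfg)
  # frozen body, bit for bit; head moved
  expect_identical(bodyParameters(ft), bodyParameters(pre))
  expect_false(identical(headParameters(ft), headParameters(pre)))
  # exactly fineTuneEpochs epochs of fine-tuning in the log
  expect_equal(sum(trainingLog(ft)$phase == "finetune"), cfg$fineTuneEpochs)
  # fine-tuning on matched dynamics reduces target validation loss
  spw <- odetransfer:::.targetSplitWindows(pre, trainTraj, cfg)
  valXY <- odetransfer:::.scaledXY(pre, spw$val)
  expect_lte(odetransfer:::.valLoss(ft, valXY$X, valXY$Y),
             odetransfer:::.valLoss(pre, valXY$X, valXY$Y))
  # too-short target names the minimum length
  expect_error(finetune(pre, subsetTrajectory(target, 1:8), cfg),
               "minimum length is 10")
})

test_that("prediction emits one forecast per admissible window, in original units", {
  sys <- getOdeSystem("sir")
  div <- diversityConfig(sys, icClass = "S", kpClass = "S")
  ds <- generateDataset(sys, div, noiseConfig("none"), 10, 0:39, seed = 3)
  cfg <- trainConfig(maxEpochs = 5, seed = 4)
  m <- pretrain(buildModel("dnn", 5, 3, 5, 1, targetVars = "I", seed = 4),
                ds, cfg)
  target <- sirTrajectory(0:39)
  # evaluation region of exactly horizon length with preceding context
  fs <- predictSeries(m, target, 31:35)
  expect_equal(nrow(fs$origins), 1)
  expect_true(all(is.finite(fs$pred)))
  # all windows with targets inside the test region
  fs2 <- predictSeries(m, target, 20:40)
  expect_equal(nrow(fs2$origins), 17)  # t0 from 19 to 35
  expect_true(all(fs2$origins$t0Index + 5 <= 40 &
                    fs2$origins$t0Index >= 19))
  # scaler round-trip is the identity
  v <- trajValues(target)
  expect_equal(applyScaler(m, applyScaler(m, v), invert = TRUE), v,
               tolerance = 1e-10)
  expect_warning(predictSeries(m, target, 1:3), "no forecast windows")
})
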