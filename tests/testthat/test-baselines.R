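test_that("the DL baseline shares the training contract and pairing", {
  target <- generateFixtureTarget("sir", grid = 0:39,
                                  observationNoiseIQR = 0.05, seed = 2)
  sp <- splitTarget(target, 18, horizon = 5)
  trainTraj <- subsetTrajectory(target, sp$trainFull)
  init <- buildModel("dnn", 5, 3, 5, 1, targetVars = "I", seed = 5)
  # zero epochs returns the random initialization unchanged
  frozen <- trainDLBaselineFromModel(init, trainTraj,
                                     trainConfig(maxEpochs = 0, seed = 5))
  expect_identical(bodyParameters(frozen), bodyParameters(init))
  expect_identical(headParameters(frozen), headParameters(init))
  # same seed twice -> identical trained models
  cfg <- trainConfig(maxEpochs = 10, seed = 5)
  a <- trainDLBaselineFromModel(init, trainTraj, cfg)
  b <- trainDLBaselineFromModel(init, trainTraj, cfg)
  expect_identical(bodyParameters(a), bodyParameters(b))
  expect_identical(headParameters(a), headParameters(b))
  # training helps over the untrained model on abundant low-noise data
  fsTrained <- predictSeries(a, target, sp$test)
  frozen@scaler <- a@scaler
  fsInit <- predictSeries(frozen, target, sp$test)
  expect_lt(mae(fsTrained), mae(fsInit))
})

test_that("ODE calibration recovers generating parameters", {
  lv <- getOdeSystem("lv")
  thTrue <- defaultCenters(lv)[kineticParameters(lv)]
  ics <- defaultCenters(lv)[stateVariables(lv)]
  obs <- simulateTrajectory(lv, thTrue, ics, seq(0, 19.6, 0.4))  # 50 points
  # optimum-at-start: residual ~ 0 and theta unchanged
  c0 <- calibrateODE(lv, obs, theta0 = thTrue, nStarts = 1, seed = 1)
  expect_lt(c0@residual, 1e-10)
  expect_equal(fittedParameters(c0), thTrue, tolerance = 1e-6)
  # noiseless recovery from a +/-20% perturbed start, within 1%
  th0 <- thTrue * c(1.2, 0.8, 1.2, 0.8)
  cr <- calibrateODE(lv, obs, theta0 = th0, nStarts = 3, seed = 1)
  expect_lt(max(abs(fittedParameters(cr) / thTrue - 1)), 0.01)
  expect_true(cr@converged)
  # objective of the reported best restart is nonnegative and minimal
  expect_true(all(cr@restarts$residual[cr@restarts$converged] >=
                    cr@residual - 1e-9))
  # too few observations
  expect_error(calibrateODE(lv, subsetTrajectory(obs, 1:5)),
               "at least 8")
})

test_that("calibration flags degenerate all-zero observations", {
  sys <- getOdeSystem("sir")
  flat <- new("Trajectory", seriesId = "zero", time = 0:19,
              values = matrix(0, 20, 3,
                              dimnames = list(NULL, c("S", "I", "R"))),
              provenance = list())
  res <- tryCatch(calibrateODE(sys, flat, nStarts = 2, seed = 1),
                  error = function(e) e)
  if (is(res, "CalibrationResult")) {
    # a zero series is fit exactly by zero dynamics: residual must be ~ 0
    expect_lt(res@residual, 1e-8)
  } else {
    expect_match(conditionMessage(res), "calibration failure")
  }
})

test_that("ODE forecasting continues the fitted trajectory deterministically", {
  lv <- getOdeSystem("lv")
  thTrue <- defaultCenters(lv)[kineticParameters(lv)]
  ics <- defaultCenters(lv)[stateVariables(lv)]
  grid <- seq(0, 30, 0.4)
  full <- simulateTrajectory(lv, thTrue, ics, grid)
  obs <- subsetTrajectory(full, 1:50)
  cr <- calibrateODE(lv, obs, theta0 = thTrue * c(1.2, 0.8, 1.2, 0.8),
                     nStarts = 3, seed = 1)
  fc <- forecastODE(lv, cr, grid[51:length(grid)])
  # noiseless recovery reproduces the held-out tail within 1%
  tail <- trajValues(full)[51:length(grid), ]
  expect_lt(max(abs(trajValues(fc) - tail)) / max(abs(tail)), 0.01)
  # positivity of the mechanistic forecast
  expect_true(all(trajValues(fc) > 0))
  # determinism and zero-length future grid
  fc2 <- forecastODE(lv, cr, grid[51:length(grid)])
  expect_identical(trajValues(fc), trajValues(fc2))
  empty <- forecastODE(lv, cr, numeric(0))
  expect_equal(nrow(empty$values), 0)
})

test_that("parameter recovery stays accurate under observation noise", {
  # median relative error < 5% over noisy replicate datasets
  lv <- getOdeSystem("lv")
  thTrue <- defaultCenters(lv)[kineticParameters(lv)]
  ics <- defaultCenters(lv)[stateVariables(lv)]
  grid <- seq(0, 19.6, 0.4)
  errs <- vapply(1:8, function(k) {
    obs <- simulateTrajectory(lv, thTrue, ics, grid)
    obs <- applyMeasurementNoise(obs,
                                 noiseConfig("measurement", "multiplicative",
                                             0.05), seed = 100 + k)
    cr <- calibrateODE(lv, obs, theta0 = thTrue, nStarts = 2,
                       seed = 200 + k)
    median(abs(fittedParameters(cr) / thTrue - 1))
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})
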