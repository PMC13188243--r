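test_that("interval resolution is symmetric, relative and positivity-safe", {
  expect_equal(resolveInterval(intervalSpec(2, halfWidthFraction = 0)),
               c(lower = 2, upper = 2))
  expect_equal(resolveInterval(intervalSpec(1, halfWidthFraction = 0.2)),
               c(lower = 0.8, upper = 1.2))
  expect_error(intervalSpec(1, halfWidthFraction = 1), "\\[0, 1\\)")
  expect_error(intervalSpec(-1, "M"), "positive")
  # width classes are strictly ordered in length
  w <- widthClassDefaults()
  expect_true(all(diff(w[c("S", "M", "L", "XL")]) > 0))
})

test_that("configuration sampling is uniform on the intervals and seeded", {
  sys <- getOdeSystem("lv")
  # zero widths collapse to the centers
  div0 <- diversityConfig(sys, widths = c(S = 0, M = 0, L = 0, XL = 0))
  cfg <- sampleConfiguration(div0, sys, seed = 1)
  cen <- defaultCenters(sys)
  expect_equal(cfg$theta, cen[kineticParameters(sys)])
  expect_equal(cfg$ics, cen[stateVariables(sys)])
  # uniform-sampling oracle on (0.8, 1.2): moments and range
  sysC <- constantRateSystem()
  divC <- new("DiversityConfig",
              icSpecs = list(u = intervalSpec(1, halfWidthFraction = 0.2)),
              kpSpecs = list(k = intervalSpec(1, halfWidthFraction = 0.2)))
  set.seed(99)
  draws <- replicate(1e4, sampleConfiguration(divC, sysC)$theta[["k"]])
  expect_gte(min(draws), 0.8)
  expect_lte(max(draws), 1.2)
  mcse <- sqrt(0.4^2 / 12 / 1e4)
  expect_lt(abs(mean(draws) - 1), 3 * mcse)
  # determinism under a shared seed
  expect_identical(sampleConfiguration(divC, sysC, seed = 7),
                   sampleConfiguration(divC, sysC, seed = 7))
})

test_that("sigmaFromIQR matches its definition and the sampled IQR", {
  expect_identical(sigmaFromIQR(0), 0)
  expect_equal(sigmaFromIQR(0.1), 0.0741, tolerance = 1e-3)
  expect_error(sigmaFromIQR(-0.1), "nonnegative")
  # closed form vs an independent numeric root-find
  for (iqr in c(0.01, 0.05, 0.2, 1.0))
    expect_equal(sigmaFromIQR(iqr), sigmaFromIqrNumeric(iqr),
                 tolerance = 1e-10)
  set.seed(11)
  x <- rlnorm(1e5, 0, sigmaFromIQR(0.3))
  expect_equal(unname(diff(quantile(x, c(0.25, 0.75)))), 0.3,
               tolerance = 0.02)
})

test_that("environmental noise follows the piecewise-constant semantics", {
  zero <- constantRateSystem(0)
  # hand integration: slopes 0.5 then -0.2 on unit intervals from 0
  tr <- simulateTrajectory(zero, c(k = 1), c(u = 0), 0:2,
                           noise = noiseConfig("environmental", "additive", 1),
                           envDraws = matrix(c(0.5, -0.2), 2, 1))
  expect_equal(as.numeric(trajValues(tr)), c(0, 0.5, 0.3), tolerance = 1e-10)
  # multiplicative with factors held at 1 reproduces the clean solution
  sys <- getOdeSystem("sir")
  cen <- defaultCenters(sys)
  clean <- simulateTrajectory(sys, cen[kineticParameters(sys)],
                              cen[stateVariables(sys)], 0:20)
  noisy0 <- simulateTrajectory(sys, cen[kineticParameters(sys)],
                               cen[stateVariables(sys)], 0:20,
                               noise = noiseConfig("environmental",
                                                   "multiplicative", 0))
  expect_identical(trajValues(clean), trajValues(noisy0))
  # clean SIR conserves mass
  sums <- rowSums(trajValues(clean))
  expect_lt(max(abs(sums / sums[1] - 1)), 1e-6)
})

test_that("measurement noise has the stated distributional properties", {
  tr <- sirTrajectory(0:39)
  n0 <- noiseConfig("measurement", "multiplicative", 0)
  expect_identical(trajValues(applyMeasurementNoise(tr, n0, seed = 1)),
                   trajValues(tr))
  expect_error(applyMeasurementNoise(tr, noiseConfig("none"), 1),
               "measurement")
  # multiplicative: median of noisy/clean ratios near 1
  long <- sirTrajectory(seq(0, 39, length.out = 4000))
  nm <- applyMeasurementNoise(long,
                              noiseConfig("measurement", "multiplicative",
                                          0.2), seed = 2)
  ratios <- trajValues(nm) / trajValues(long)
  expect_equal(median(ratios), 1, tolerance = 0.01)
  # additive: sd of residuals = level * clean per-variable sd
  na <- applyMeasurementNoise(long,
                              noiseConfig("measurement", "additive", 0.5),
                              seed = 3)
  res <- trajValues(na) - trajValues(long)
  cleanSd <- apply(trajValues(long), 2, sd)
  for (j in 1:3)
    expect_equal(sd(res[, j]), 0.5 * unname(cleanSd[j]), tolerance = 0.05)
})

test_that("dataset generation is reproducible, finite and diverse", {
  sys <- getOdeSystem("lv")
  # degenerate widths + no noise give the deterministic center simulation
  div0 <- diversityConfig(sys, widths = c(S = 0, M = 0, L = 0, XL = 0))
  ds0 <- generateDataset(sys, div0, noiseConfig("none"), nSeries = 1,
                         grid = seq(0, 10, 0.5), seed = 1)
  cen <- defaultCenters(sys)
  ref <- simulateTrajectory(sys, cen[kineticParameters(sys)],
                            cen[stateVariables(sys)], seq(0, 10, 0.5))
  expect_equal(trajValues(trajectories(ds0)[[1]]), trajValues(ref),
               tolerance = 1e-12)
  # byte-identical regeneration from the same master seed
  div <- diversityConfig(sys, icClass = "M", kpClass = "L")
  dsA <- generateDataset(sys, div, noiseConfig("none"), 20,
                         seq(0, 10, 0.5), seed = 7)
  dsB <- generateDataset(sys, div, noiseConfig("none"), 20,
                         seq(0, 10, 0.5), seed = 7)
  expect_identical(lapply(trajectories(dsA), trajValues),
                   lapply(trajectories(dsB), trajValues))
  # wide KP intervals: all trajectories finite, pairwise distinct
  vals <- lapply(trajectories(dsA), trajValues)
  expect_true(all(vapply(vals, function(v) all(is.finite(v)), TRUE)))
  for (i in 1:5) for (j in seq_len(i - 1))
    expect_gt(max(abs(vals[[i]] - vals[[j]])), 0)
  # provenance allows exact regeneration of a single trajectory
  tr <- trajectories(dsA)[[3]]
  pv <- provenance(tr)
  re <- simulateTrajectory(sys, pv$theta, pv$ics, timePoints(tr))
  expect_equal(trajValues(re), trajValues(tr), tolerance = 1e-12)
})

test_that("averaging noisy replicates converges to the clean trajectory", {
  # mean-zero additive environmental draws on a constant-rate system:
  # the error of the M-replicate average shrinks like 1/sqrt(M)
  sys <- constantRateSystem(0.5)
  grid <- 0:20
  clean <- simulateTrajectory(sys, c(k = 1), c(u = 0), grid)
  noisyMean <- function(M, seed) {
    acc <- 0
    for (m in seq_len(M)) {
      tr <- simulateTrajectory(sys, c(k = 1), c(u = 0), grid,
                               noise = noiseConfig("environmental",
                                                   "additive", 0.5),
                               seed = 1000 * seed + m)
      acc <- acc + trajValues(tr)
    }
    acc / M
  }
  errs <- vapply(c(4, 64), function(M)
    max(abs(noisyMean(M, M) - trajValues(clean))), numeric(1))
  expect_lt(errs[2], errs[1])
})

test_that("the noisy trajectory approaches the clean one as level shrinks", {
  sys <- getOdeSystem("lv")
  cen <- defaultCenters(sys)
  grid <- seq(0, 10, 0.5)
  clean <- trajValues(simulateTrajectory(sys, cen[kineticParameters(sys)],
                                         cen[stateVariables(sys)], grid))
  dev <- vapply(c(1e-1, 1e-2, 1e-3), function(lev) {
    tr <- simulateTrajectory(sys, cen[kineticParameters(sys)],
                             cen[stateVariables(sys)], grid,
                             noise = noiseConfig("environmental",
                                                 "multiplicative", lev),
                             seed = 5)
    max(abs(trajValues(tr) - clean))
  }, numeric(1))
  expect_true(all(diff(dev) < 0))
  expect_lt(dev[3], 0.05 * max(abs(clean)))
})

test_that("fixture targets behave as labelled", {
  grid <- 0:39
  # coherent with zero observation noise is the exact clean trajectory
  coh0 <- generateFixtureTarget("sir", grid = grid,
                                observationNoiseIQR = 0, seed = 3)
  expect_equal(trajValues(coh0), trajValues(sirTrajectory(grid)),
               tolerance = 1e-12)
  # the incoherent fixture departs from the coherent one at most points
  inc <- generateFixtureTarget("sir", grid = grid,
                               observationNoiseIQR = 0, coherent = FALSE,
                               seed = 3)
  cleanSd <- apply(trajValues(coh0), 2, sd)
  frac <- mean(abs(trajValues(inc) - trajValues(coh0)) >
                 rep(cleanSd, each = length(grid)))
  expect_gt(frac, 0.5)
  # reproducible from seed
  incB <- generateFixtureTarget("sir", grid = grid,
                                observationNoiseIQR = 0, coherent = FALSE,
                                seed = 3)
  expect_identical(trajValues(inc), trajValues(incB))
})
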