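test_that("MAE and RMSE match hand arithmetic and satisfy Jensen", {
  expect_equal(mae(c(1, 2), c(1, 2)), 0)
  expect_equal(rmse(c(1, 2), c(1, 2)), 0)
  pred <- c(1, -1, 1, -1); obs <- c(0, 0, 0, 0)
  expect_equal(mae(pred, obs), 1)
  expect_equal(rmse(pred, obs), 1)
  expect_equal(mae(c(0, 0, 0, 2), c(0, 0, 0, 0)), 0.5)
  expect_equal(rmse(c(0, 0, 0, 2), c(0, 0, 0, 0)), 1)
  expect_error(mae(1:3, 1:4), "same shape")
  expect_error(mae(numeric(0), numeric(0)), "empty")
  set.seed(3)
  for (k in 1:20) {
    e <- rnorm(17)
    expect_gte(rmse(e, 0 * e), mae(e, 0 * e))
  }
})

test_that("prediction trend accuracy counts origin-anchored sign matches", {
  # exact forecast: every trend right
  obs <- array(c(12, 9), c(1, 2, 1))
  expect_equal(pta(obs, obs, matrix(10)), 1)
  # origin 10, obs (12, 9) = up/down, pred (11, 11) = up/up -> one of two
  expect_equal(pta(array(c(11, 11), c(1, 2, 1)), obs, matrix(10)), 0.5)
  # mirrored forecast flips every nonzero move
  set.seed(8)
  o <- array(rnorm(3 * 4 * 2), c(3, 4, 2))
  y0 <- matrix(rnorm(6), 3, 2)
  origin <- aperm(array(y0, c(3, 2, 4)), c(1, 3, 2))
  mirrored <- 2 * origin - o
  expect_equal(pta(mirrored, o, y0), 0)
  expect_error(pta(o, o, NULL), "origins")
  # invariance under increasing origin-preserving rescaling (sign-preserving)
  rescale <- function(x) 3 * x
  p <- o + 0.3
  expect_equal(pta(rescale(p), rescale(o), rescale(y0)), pta(p, o, y0))
  # zero moves only match zero moves
  flatObs <- array(5, c(1, 2, 1))
  flatPred <- array(c(5, 6), c(1, 2, 1))
  expect_equal(pta(flatPred, flatObs, matrix(5)), 0.5)
})

test_that("relative change is a signed percent with a positive baseline", {
  expect_equal(relativeChange(1, 1), 0)
  expect_equal(relativeChange(0.05, 1), -95)
  expect_equal(relativeChange(1.076, 1), 7.6)
  expect_error(relativeChange(1, 0), "positive")
})

test_that("the paired blocked bootstrap has the stated degenerate behaviour", {
  set.seed(1)
  e <- matrix(abs(rnorm(3 * 30)), 3, 30)
  # identical arms: every replicate difference is 0
  bs <- blockedBootstrapDiffCI(e, e, nBoot = 200, seed = 2)
  expect_identical(c(bs@lower, bs@upper), c(0, 0))
  expect_false(significanceFlag(bs))
  # N <= blockLen with one seed: single full block, degenerate CI at the
  # point difference
  a <- matrix(abs(rnorm(6)), 1); b <- matrix(abs(rnorm(6)), 1)
  bs1 <- blockedBootstrapDiffCI(a, b, blockLen = 10, nBoot = 50, seed = 3)
  expect_equal(bs1@lower, bs1@estimate)
  expect_equal(bs1@upper, bs1@estimate)
  expect_error(blockedBootstrapDiffCI(a, b[, 1:3, drop = FALSE]),
               "share shape")
  expect_error(blockedBootstrapDiffCI(a, b, blockLen = 0), ">= 1")
})

test_that("a planted difference is detected and pairing is respected", {
  set.seed(42)
  base <- matrix(rnorm(5 * 100), 5, 100)
  shifted <- base + 0.5
  bs <- blockedBootstrapDiffCI(shifted, base, nBoot = 2000, seed = 7)
  expect_equal(bs@estimate, 0.5, tolerance = 1e-12)  # paired: exact shift
  expect_true(significanceFlag(bs))
  expect_gt(bs@lower, 0)
  # significance flag conventions
  mk <- function(lo, hi) new("BootstrapResult", estimate = (lo + hi) / 2,
                             lower = lo, upper = hi, level = 0.95,
                             blockLen = 3, nBoot = 10, seed = 1)
  expect_true(significanceFlag(mk(-0.9, -0.3)))
  expect_false(significanceFlag(mk(-0.2, 0.1)))
  expect_false(significanceFlag(mk(0, 0)))
})

test_that("per-time-point errors average the windows covering each point", {
  fs <- structure(list(
    pred = array(c(1, 2, 2, 4), c(2, 2, 1)),  # windows x steps x targets
    obs = array(c(1, 2, 4, 2), c(2, 2, 1)),
    origins = data.frame(seriesId = "s", t0Index = c(5, 6)),
    lastInputs = matrix(c(0, 0), 2, 1),
    targetVars = "v"), class = "ForecastSet")
  # window 1 covers t 6,7 with abs errors 0,2; window 2 covers t 7,8 with 0,2
  pe <- perTimepointErrors(fs)
  expect_equal(unname(pe), c(0, 1, 2))
  expect_equal(names(pe), c("6", "7", "8"))
})
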