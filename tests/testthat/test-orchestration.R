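test_that("target splitting follows the 0-based inclusive boundary convention", {
  tr <- generateFixtureTarget("sir", grid = 0:59, observationNoiseIQR = 0,
                              seed = 1)
  sp <- splitTarget(tr, 18, horizon = 5)
  # "time steps 0-18" -> train+validation = points 1..19, test = 20..60
  expect_equal(sp$trainFull, 1:19)
  expect_equal(sp$test, 20:60)
  # regions partition the series without overlap
  expect_equal(sort(c(sp$train, sp$validation, sp$test)), 1:60)
  expect_length(intersect(sp$trainFull, sp$test), 0)
  # validation is the tail of the training region
  expect_equal(max(sp$validation), 19)
  expect_equal(sp$validation, (19 - length(sp$validation) + 1):19)
  expect_error(splitTarget(tr, 80, horizon = 5), "train and test")
  expect_error(splitTarget(tr, 57, horizon = 5), "shorter than")
})

test_that("time-series CSV round-trips and rejects malformed input", {
  sys <- getOdeSystem("lv")
  div <- diversityConfig(sys, icClass = "M", kpClass = "M")
  ds <- generateDataset(sys, div, noiseConfig("none"), 3, seq(0, 5, 0.5),
                        seed = 9)
  path <- file.path(tempdir(), "lv_ds.csv")
  writeTimeSeriesCSV(ds, path)
  back <- readTimeSeriesCSV(path)
  expect_equal(nSeries(back), 3)
  expect_equal(stateVariables(back), stateVariables(ds))
  for (k in 1:3)
    expect_equal(trajValues(trajectories(back)[[k]]),
                 trajValues(trajectories(ds)[[k]]), tolerance = 1e-12)
  # provenance sidecar exists and holds the seed
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$seed, 9)
  # shuffled rows are sorted by (series, time) on read
  df <- utils::read.csv(path, check.names = FALSE)
  shuffled <- df[sample.int(nrow(df)), ]
  path2 <- file.path(tempdir(), "lv_shuffled.csv")
  utils::write.csv(shuffled, path2, row.names = FALSE)
  back2 <- readTimeSeriesCSV(path2)
  expect_equal(trajValues(trajectories(back2)[[1]]),
               trajValues(trajectories(back)[[1]]), tolerance = 1e-12)
  # missing time column is a parse error naming the column
  path3 <- file.path(tempdir(), "bad.csv")
  utils::write.csv(df[, setdiff(names(df), "time")], path3,
                   row.names = FALSE)
  expect_error(readTimeSeriesCSV(path3), "'time'")
  # non-numeric cells are named with their rows
  df4 <- df; df4$x[3] <- "oops"
  path4 <- file.path(tempdir(), "bad2.csv")
  utils::write.csv(df4, path4, row.names = FALSE)
  expect_error(readTimeSeriesCSV(path4), "non-numeric")
})

test_that("grid enumeration matches the studied design", {
  tgt <- generateFixtureTarget("sir", grid = 0:39,
                               observationNoiseIQR = 0.05, seed = 1)
  cfg <- experimentConfig("sir", tgt, trainEnd = 18,
                          window = list(targetVars = "I"))
  cells <- enumerateGrid(cfg)
  # 16 diversity configurations per size, 4 sizes, 4 architectures, 5 seeds
  expect_equal(nrow(unique(cells[, c("icClass", "kpClass")])), 16)
  expect_equal(nrow(cells), 4 * 16 * 4 * 5)
  expect_equal(length(unique(cells$seed)), 5)
  noise <- enumerateNoiseStudy(cfg)
  # six levels per (kind, operation) pair, five seeds each
  expect_equal(nrow(noise), 2 * 6 * 5)
  for (kind in c("measurement", "environmental"))
    expect_equal(length(unique(noise$noiseLevel[noise$noiseKind == kind])),
                 6)
})

test_that("a smoke grid runs, pairs arms, summarises and selects", {
  tgt <- generateFixtureTarget("sir", grid = 0:39,
                               observationNoiseIQR = 0.05, seed = 21)
  cfg <- experimentConfig(
    "sir", tgt, trainEnd = 18, window = list(targetVars = "I"),
    sizes = c(1L, 10L), icClasses = "M", kpClasses = c("S", "XL"),
    architectures = "dnn", seeds = 1:2,
    train = trainConfig(maxEpochs = 6, seed = 3),
    bootstrap = list(nBoot = 100, level = 0.95))
  res <- suppressMessages(runGrid(cfg))
  cells <- gridCells(res)
  # one row per enumerated cell: 2 sizes x 2 KP classes x 1 arch x 2 seeds
  expect_equal(nrow(cells), 8)
  expect_true(all(cells$status %in% c("ok", "failed")))
  ok <- cells[cells$status == "ok", ]
  expect_gt(nrow(ok), 0)
  expect_true(all(ok$tl_mae >= 0 & ok$dl_mae >= 0))
  expect_true(all(ok$tl_pta >= 0 & ok$tl_pta <= 1))
  # ODE baseline metrics attached to every row
  expect_true(all(is.finite(ok$ode_mae)))
  s <- gridSummary(res)
  expect_equal(nrow(s), 4)
  expect_true(all(is.finite(s$rel_mae_vs_dl)))
  best <- selectBest(res)
  expect_equal(best$tl_mae, min(s$tl_mae))
  # rerunning with the same seeds reproduces the table
  res2 <- suppressMessages(runGrid(cfg))
  expect_equal(gridCells(res2)$tl_mae, cells$tl_mae, tolerance = 1e-12)
})

test_that("best-configuration selection applies the stated tie-breaks", {
  mk <- function(...) {
    s <- data.frame(...)
    new("GridResult", cells = data.frame(status = "ok"), summary = s,
        config = list())
  }
  # plain MAE ranking
  r <- mk(size = c(10, 100), icClass = "M", kpClass = "M",
          architecture = "gru", tl_mae = c(0.9, 1.0),
          tl_one_minus_pta = c(0.5, 0.5))
  expect_equal(selectBest(r)$size, 10)
  # MAE tie broken by 1-PTA
  r2 <- mk(size = c(10, 100), icClass = "M", kpClass = "M",
           architecture = "gru", tl_mae = c(1, 1),
           tl_one_minus_pta = c(0.3, 0.2))
  expect_equal(selectBest(r2)$size, 100)
  # full tie broken by smaller size
  r3 <- mk(size = c(1000, 10), icClass = "M", kpClass = "M",
           architecture = "gru", tl_mae = c(1, 1),
           tl_one_minus_pta = c(0.2, 0.2))
  expect_equal(selectBest(r3)$size, 10)
  expect_error(selectBest(new("GridResult", cells = data.frame(),
                              summary = data.frame(), config = list())),
               "failed")
})

test_that("the noise study enumerates levels and records failures", {
  tgt <- generateFixtureTarget("sir", grid = 0:39,
                               observationNoiseIQR = 0.05, seed = 22)
  cfg <- experimentConfig(
    "sir", tgt, trainEnd = 18, window = list(targetVars = "I"),
    sizes = 10L, icClasses = "M", kpClasses = "M",
    architectures = "dnn", seeds = 1L,
    noiseKinds = "measurement", noiseLevels = c(0, 0.1),
    train = trainConfig(maxEpochs = 4, seed = 3))
  best <- data.frame(size = 10L, icClass = "M", kpClass = "M",
                     architecture = "dnn")
  ns <- suppressMessages(runNoiseStudy(cfg, best))
  cells <- gridCells(ns)
  expect_equal(nrow(cells), 2)  # 2 levels x 1 seed
  expect_true(all(c("noiseKind", "noiseLevel") %in% names(cells)))
  expect_true(all(cells$status == "ok"))
  expect_gt(nrow(gridSummary(ns)), 0)
})
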