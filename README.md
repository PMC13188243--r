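# odetransfer

Simulation-based transfer learning for dynamical-system time series.

## What problem this solves

Forecasting biological dynamics — epidemic waves, predator–prey cycles,
chemostat populations — is usually a small-data problem: a deep-learning
model sees only the observed part of the dynamics (say, the rising flank of
an infection wave) and cannot extrapolate behaviour it has never been shown,
while a mechanistic ODE model extrapolates but only within its structural
assumptions. `odetransfer` implements and instruments the middle road for
researchers in epidemiological and ecological forecasting:

1. **Simulate** a synthetic dataset of trajectories from a registered ODE
   system (SIR epidemic, Lotka–Volterra predator–prey, substrate–algae–
   rotifers chemostat, or your own), with controlled
   * *size* — number of series (1 / 10 / 100 / 1000),
   * *diversity* — kinetic parameters and initial conditions drawn uniformly
     from relative intervals `[c(1−w), c(1+w)]` with width classes
     S/M/L/XL (w = 0.05/0.2/0.5/0.8),
   * *noise* — measurement (i.i.d. per observation) or environmental
     (`dŷ/dt = dy/dt + e_t` or `(dy/dt)·e_t`, one draw per variable held
     constant per grid interval), additive or multiplicative; multiplicative
     levels are the IQR of a lognormal factor with median 1.
2. **Pre-train** a small forecaster (LSTM / GRU / CNN / DNN + two-layer
   head) on the synthetic windows, then **fine-tune only the head** on the
   target series (the body is frozen bit-for-bit).
3. **Compare** against two baselines — the identical network trained on the
   target data alone from the same random initialization (paired seeds),
   and ODE calibration (bounded least-squares fit of the kinetic
   parameters, then simulation) — using MAE, RMSE and 1−PTA (prediction
   trend accuracy, a multi-step variant of mean directional accuracy),
   with paired moving-block bootstrap confidence intervals over time points
   and seeds.
4. **Screen coherence** between synthetic and target dynamics with
   multivariate DTW and derivative DTW against a synthetic-vs-synthetic
   baseline distance distribution — incoherent source data is the classic
   cause of negative transfer.

## Worked example

A coherent pseudo-real target: an SIR wave observed on t = 0..39 with 5%
multiplicative observation noise, where training data end at t = 18 —
before the wave peaks near t = 26, so the decline is unseen.

```r
library(odetransfer)

target <- generateFixtureTarget("sir", grid = 0:39,
                                observationNoiseIQR = 0.05,
                                coherent = TRUE, seed = 11)
sp <- splitTarget(target, trainEnd = 18, horizon = 5)
trainRegion <- subsetTrajectory(target, sp$trainFull)

sys <- getOdeSystem("sir")
synth <- generateDataset(sys, diversityConfig(sys, icClass = "M", kpClass = "M"),
                         noiseConfig("none"), nSeries = 100,
                         grid = 0:39, seed = 100)
#> TimeSeriesDataset (sir): 100 series x 40 time points, variables: S, I, R

cfg  <- trainConfig(maxEpochs = 60, seed = 1)
init <- buildModel("gru", inputLen = 5, nVars = 3, horizon = 5,
                   nTargets = 1, targetVars = "I", seed = 1)
tl <- finetune(pretrain(init, synth, cfg), trainRegion, cfg)  # transfer arm
dl <- trainDLBaselineFromModel(init, trainRegion, cfg)        # paired baseline

tlFs <- predictSeries(tl, target, sp$test)
dlFs <- predictSeries(dl, target, sp$test)
```

This prints (output from the code above):

```
TL  test MAE: 48.0   1-PTA: 0.388
DL  test MAE: 188.0   1-PTA: 0.459
relative MAE change: -74.5%
ODE test MAE: 10.5
```

The transfer-learning arm, having seen simulated wave declines during
pre-training, tracks the unseen downswing and cuts the test MAE of the
uninformed network by ~75%; the ODE baseline is even better here because
this fixture *is* an SIR system — on real data with structural mismatch
that advantage disappears. The paired blocked bootstrap confirms the TL–DL
difference:

```r
blockedBootstrapDiffCI(perTimepointErrors(tlFs), perTimepointErrors(dlFs),
                       nBoot = 2000, seed = 1)
#> BootstrapResult: diff=-136, 95% CI [-150.8, -123.7], block=3, n_boot=2000

assessCoherence(synth, target, nPairs = 50, seed = 1)
#> CoherenceReport (n_pairs=50): shift DTW=0.294, DDTW=0.812
```

A shift statistic near 0.5 or below means the target sits inside the
synthetic distance distribution (coherent); values near 1 flag incoherence.

For full designs use `experimentConfig()` + `runGrid()` (sizes × 16
diversity configurations × architectures × seeds), `selectBest()` and
`runNoiseStudy()` (six levels per noise kind at the best configuration).
A thin CLI over these functions is in
`inst/scripts/odetransfer-cli.R` (`generate`, `coherence`, `grid`
subcommands; wide CSV in, JSON/CSV reports out).

## Package layout

* `R/ode-systems.R` — registry of SIR / LV / SAR right-hand sides.
* `R/intervals.R`, `R/noise.R`, `R/simulate.R`, `R/generate.R` — the
  synthetic-dataset generator.
* `R/nn.R`, `R/forecast.R` — the neural engine and the
  pretrain/finetune/predict protocol.
* `R/baselines.R` — uninformed DL and ODE-calibration baselines.
* `R/evaluation.R` — MAE/RMSE/PTA, relative changes, blocked bootstrap.
* `R/coherence.R` — DTW/DDTW screening.
* `R/orchestration.R`, `R/io.R` — experiment grid, noise study, CSV/JSON I/O.
* `vignettes/simulation-transfer-learning.Rmd` — model, assumptions,
  design decisions, limitations.
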