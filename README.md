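# fishcut

Automatic identification of the ideal head-cut position of spindle-shaped
fish (e.g. crucian carp) on a processing line, from line-laser triangulation
scans of the upper body surface.

On an industrial line, a line laser mounted above a conveyor belt sweeps the
passing fish and yields one *radial profile* (height vs lateral position)
per frame. The curve of per-frame maximum heights — the **ventral–dorsal
demarcation line** — tracks the thickness of the body along its length and
carries enough shape information to predict the *head length* (mouth to
trailing gill-cover edge, in mm), which is where the cutting blade should
strike. `fishcut` implements the full chain:

1. **Simulation** — a parametric spindle-shaped fish generator with
   allometrically coupled dimensions, scanned by a virtual line laser
   (640 points/line by default) with Gaussian noise, impulse outliers and
   conveyor vibration, so the whole pipeline is testable against analytic
   ground truth.
2. **Preprocessing** — threshold segmentation of belt vs body points by
   adjacent-point height jumps (`|Δh| > T`), then constant-position Kalman
   filtering and asymmetric sliding-median filtering along each profile.
3. **Features** — demarcation-line extraction, resampling to a fixed length
   `p = 60`, Z-score standardization, and correlation-matrix PCA
   (`D = Z'Z/(n−1)`), retaining the components that reach 95% cumulative
   explained variance (three, in practice).
4. **Models** — three head-length regressors built from first principles:
   * **LS-SVM** — RBF-kernel least-squares SVM; training is one exact solve
     of the bordered Gram system `[[0, 1'], [1, K + I/γ]] [b; α] = [0; y]`,
     with `(σ², γ)` tuned by particle swarm search over cross-validated RMSE;
   * **PSO-BP** — a 3–10–1 sigmoid network whose 51 weights are first located
     by particle swarm optimization (positions in [−2, 2], velocities in
     [−1, 1]), then refined by full-batch gradient descent;
   * **LSTM** — a single-layer LSTM that consumes the three principal
     component scores as a 3-step sequence, trained by
     backpropagation-through-time with global-norm gradient clipping.
5. **Evaluation** — random 154/50 train/test splits and the four standard
   indicators: R², RMSE, MAE and the residual predictive deviation
   RPD = SD(y)/RMSE (RPD > 2.5 ⇒ "accurate and reliable"; R² > 0.82 ⇒
   practical; R² > 0.9 ⇒ excellent).

## Worked example

```r
library(fishcut)

# simulate a study population of 204 fish and run the whole pipeline
dataset <- generate_dataset(204, scan_config(), seed = 1)
report  <- evaluate_pipeline(dataset, n_train = 154, n_test = 50, seed = 1)
print(report)
```

```
<fishcut_report> 204 fish (154 train / 50 test)
  lssvm  test R2 0.9422 RMSE 0.4750 MAE 0.3498 RPD 4.2013  [excellent, accurate and reliable]
  psobp  test R2 0.9362 RMSE 0.4991 MAE 0.3479 RPD 3.9984  [excellent, accurate and reliable]
  lstm   test R2 0.9336 RMSE 0.5089 MAE 0.3602 RPD 3.9213  [excellent, accurate and reliable]
```

All three regressors recover the head-cut position to about half a
millimetre RMSE on held-out fish, with RPD near 4 — comfortably inside the
"accurate and reliable" band. The PCA stage keeps 3 components:

```r
glance(report)$cumulative_variance   # 0.954 — three components suffice
tidy(report)                         # full metrics tibble, train + test
autoplot(report)                     # predicted vs observed, per model
```

Individual stages are ordinary tibble-in / tibble-out functions that
compose with the pipe:

```r
cloud <- simulate_scan(sample_fish_params(1, seed = 7), scan_config())
line  <- cloud |>
  preprocess_cloud(threshold = 5) |>
  extract_demarcation_line(belt_height = 250.32)
autoplot(line)
```

A command-line front end mirrors the library
(`inst/exec/fishcut simulate|preprocess|extract|pca|train|predict|run`).

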