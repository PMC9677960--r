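# adawin

Adaptive-window segmentation and classification of animal behavior from
wearable inertial sensors.

## What this solves, and for whom

Precision-livestock researchers monitor animals with body-mounted
accelerometer/gyroscope nodes (here: 10 Hz, two triaxial sensors) and
classify behaviors — eating, lying, walking, standing — from windowed
features of the stream. A single fixed window size (WS) cannot suit every
behavior: eating and lying bouts last minutes, so long windows give stable
features; walking and standing bouts last only seconds, so long windows
straddle bout boundaries and degrade exactly the minority classes one most
wants to detect.

`adawin` implements the full pipeline around *adaptive windowing*:

1. **Stream validation** from the logger's timestamp and counter channels.
2. **Cleaning**: interquartile-fence outlier censoring combined with the
   sensors' physical ranges (16 g, 2000 °/s), linear-interpolation gap
   filling, per-animal min–max normalization to [0, 1].
3. **Segmentation**: sliding windows `[start, start + ws)` every `ss`
   samples (`floor((n − ws)/ss) + 1` windows), majority-label assignment
   with a purity gate (default 0.8).
4. **Features**: 14 statistics × 8 channels (6 axes + 2 magnitudes) ×
   {time, frequency} = 224 features per window, plus accelerometer pitch
   and roll.
5. **Classification**: SVM (linear, one-vs-all), KNN (k = 8), decision tree
   (Gini, unlimited depth), Gaussian naive Bayes, random forest (100
   trees), evaluated with a stratified 70/30 holdout and per-class
   precision / recall / F1, where F1 = 2PR/(P + R).
6. **Window optimization**: for each behavior class *c*, sweep the grid and
   select

       (WS_c, SS_c) = argmax_{(ws, ss)} F1_c(ws, ss),

   ties toward larger WS then smaller SS. Because each class's argmax is
   taken over a grid containing the global sliding optimum, adaptive
   per-class F1 ≥ sliding-optimum F1 under the same seed — the minority
   short-bout classes gain by construction.
7. **Feature selection**: recursive elimination by random-forest Gini
   importance, dropping the bottom 10% per iteration down to the top 25%.
8. **Synthetic data**: a labeled IMU simulator reproducing the study's
   structure (class imbalance 49.40 : 33.33 : 7.87 : 1.76, long/short
   bout-duration contrast, 10 Hz) for end-to-end testing without any
   downloads.

## Worked example

```r
library(adawin)

# a labeled 100-minute stream with the default study conditions
sim   <- simulate_stream(sim_config(duration_s = 6000), seed = 1)
raw   <- inject_artifacts(sim$stream, outlier_rate = 0.002,
                          missing_rate = 0.002, seed = 1)
clean <- preprocess_stream(raw)

fit <- adawin(clean, sim$track,
              ws_s = c(2, 3, 5, 7), ss_s = c(0.1, 0.3, 0.5, 1.5, 3),
              algorithms = "rf", seed = 1, max_windows = 600)
print(fit)
```

```
Adaptive-window behavior classifier
  algorithm: rf; seed: 1
  sliding optimum: ws 7 s, ss 0.5 s (mean F1 1.000)
  adaptive plan:
    eating    ws 7 s, ss 0.1 s (F1 1.000)
    lying     ws 7 s, ss 0.5 s (F1 1.000)
    standing  ws 7 s, ss 0.5 s (F1 1.000)
    walking   ws 7 s, ss 0.1 s (F1 1.000)
```

Reading the output: the sliding optimum is the single (WS, SS) with the
best mean F1 across classes; the plan rows are each behavior's own optimum.
On this short, cleanly separable simulation every class already saturates
F1 = 1 and ties resolve toward the largest window; the packaged checks
verify the structural property that the long-bout behaviors' selected
windows are never shorter than the short-bout behaviors', and that each
class's adaptive F1 is at least its F1 at the sliding optimum — the
mechanism by which adaptive windows recover minority-class performance on
real recordings. `coef(fit)` returns the per-class (WS, SS)
matrix, `predict(fit, stream)` a fused per-sample label timeline, and
`plot(fit)` the F1 surface. On this synthetic stream the per-class F1
values are near 1 by design; they say nothing about field performance (see
the vignette's simulator caveats).

The same pipeline is scriptable from a shell via the installed CLI:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/adawin", package="adawin"))')" \
  simulate --duration 600 --seed 7 --out raw.csv --labels labels.csv
```

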