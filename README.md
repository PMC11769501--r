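# harshift

Robustness of deep human activity recognition (HAR) models under sensor
variability, explained through distribution shift.

## The problem

Wrist-worn IMU-based HAR models are usually trained and tested on data from
one carefully placed sensor. In the real world the same model meets
*variability*: the device sits on the other wrist (position), at a rotated
angle (orientation), or is different hardware with another sampling rate and
noise floor (device) — and every subject moves differently. Each factor
shifts the test distribution away from the training distribution and can
silently destroy performance.

`harshift` is a complete, tested harness for studying these effects in
isolation, for researchers evaluating HAR architectures and practitioners
deciding whether a model trained on one device/placement will survive
another. It provides:

* a **synthetic multi-sensor accelerometer generator** — a 16-subject
  treadmill-walking cohort recorded by five simultaneous wrist sensors
  (100 Hz vs 64 Hz devices, left/right wrist, 45° rotation), with
  per-subject gait parameters and "sidebar holders" whose damped walking
  makes them hard subjects;
* the **preprocessing pipeline**: leak-free standardization, 2 s sliding
  windows (128 samples at 64 Hz, 200 at 100 Hz), class-weighted sampling,
  per-window linear resampling across device rates;
* three **hybrid CNN-recurrent architectures** — a shallow DeepConvLSTM
  (227,138 parameters), TinyHAR (24,864) and Attend-and-Discriminate
  (297,412) — implemented from scratch (including reverse-mode gradients
  and Adam) with exact parameter accounting and MAC estimates;
* the **training regime**: batch 256, cross-entropy, early stopping,
  learning-rate annealing, best-epoch restoration;
* an **iterative multiscale-kernel MMD** for distribution shift: the
  squared MMD between random contiguous 100-sample windows, averaged over
  many iterations, computed per activity class,

      MMD²(X, Y) = mean K_XX + mean K_YY − 2 mean K_XY,
      k(d²) = Σ_a a⁴ / (a² + d²),   a ∈ {0.2, 0.5, 0.9, 1.3, 1.5, 1.6};

* the **evaluation protocol**: leave-one-subject-out folds over paired
  baseline/variability settings that share the identical test sensor,
  paired t-tests with the */**/*** convention, and the per-fold MMD–F1
  correlation;
* **compounding-variability scenarios** (ideal/ideal, self/ideal,
  self/self, ideal/self placements) in the style of the REALDISP dataset,
  with a `.log` reader for the real data and a synthetic stand-in
  generator.

## A worked example

Simulate a small cohort, run one position-variability experiment
(train on the right-wrist 64 Hz sensor, test on the left-wrist one) against
its baseline, and connect the F1 drop to the distribution shift:

```r
library(harshift)

cohort <- simulate_cohort(make_cohort(6, sidebar_ids = 2, seed = 7),
                          harvar_sensors(),
                          walk_min_per_speed = 0.1, nonwalk_min = 1)

base <- run_experiment(experiment_spec("exp1", "position", "EL", "EL", "baseline"),
                       cohort, arch = "tinyhar",
                       train_cfg = fast_train_config(max_epochs = 6, batch_size = 64),
                       mmd_cfg = mmd_config(iterations = 200), seed = 1)
vari <- run_experiment(experiment_spec("exp1", "position", "ER", "EL", "variability"),
                       cohort, arch = "tinyhar",
                       train_cfg = fast_train_config(max_epochs = 6, batch_size = 64),
                       mmd_cfg = mmd_config(iterations = 200), seed = 1)
base
#> <experiment_result> exp1 [tinyhar] train EL -> test EL (baseline): F1 0.878 +- 0.233, MMD 1.124
vari
#> <experiment_result> exp1 [tinyhar] train ER -> test EL (variability): F1 0.845 +- 0.218, MMD 1.470

paired_ttest(base$per_fold$f1, vari$per_fold$f1)
#> <stat_result> t = 3.331 (df 5), p = 0.0208 (*)
mmd_f1_correlation(rbind(base$per_fold, vari$per_fold))
#> <stat_result> r = -0.808, p = 0.00149 (**)
```

Read: training on the other wrist costs about 0.03 mean F1 across the LOSO
folds — small on average but consistent fold by fold, which is why the
paired t-test still stars it. The variability setting's mean MMD (1.47) is
clearly above the baseline's (1.12), and across folds larger shifts go with
lower F1 (Pearson r = -0.81). The fold for subject 2 — a sidebar holder
whose walking oscillation is damped to 25% — is the weak fold behind the
large standard deviations in both settings.

The full study (all eight sensor-pair experiments, three architectures,
full-length sessions and 50,000 MMD iterations) runs through the same
functions with the default configurations via `run_study()`; the reduced
sizes above are the quick profile documented in the methods vignette
(`vignettes/harshift-methods.Rmd`).

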