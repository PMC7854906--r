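# tdann

Cross-day and cross-subject transfer learning for EEG-based emotion
decoding in R.

EEG patterns that discriminate emotional states are carried by band
power with a characteristic scalp topography, but the measured signal
drifts between recording days and differs between subjects (electrode
impedance, cap placement, background physiology). A classifier trained
on some days or subjects therefore degrades on new ones. `tdann`
implements a two-level domain adaptation pipeline that learns a
representation aligned across recording *domains* (days or subjects)
while staying discriminative for the emotion classes:

1. **Features.** Continuous EEG is cut into 2-s windows (50% overlap)
   and, per window, channel and canonical band (Delta 1–3, Theta 4–7,
   Alpha 8–13, Beta 14–30, Gamma 31–50 Hz), reduced to the Gaussian
   differential entropy `h = ½·log(2πeσ²)` — a monotone transform of
   band power.
2. **Topographic images.** Electrode positions are projected to the
   plane by the azimuthal equidistant ("polar") projection and the
   per-band DE values are interpolated with the Clough–Tocher C1
   scheme into min–max standardized 32 × 32 × 5 images, preserving
   scalp topology.
3. **Two-level adaptation.** A compact CNN feature generator `G_f`
   feeds a softmax classifier `G_c` and a domain discriminator `G_d`.
   Training minimizes

   `L_G = L_C + λ_d·L_D + λ_m·L_MMD + λ_z·‖W‖²`,

   where `L_C` is the source classification cross-entropy, `L_MMD` the
   multi-kernel RBF maximum mean discrepancy between source and target
   features (first level, together with adaptive batch normalization —
   per-domain statistics, shared affine), and `L_D = −H` rewards
   confusing the adversarial domain discriminator (second level). The
   discriminator itself minimizes `H + λ_L·(‖∇_x G_d(x)‖₂ − 1)²`, a
   gradient-penalty Lipschitz constraint. Defaults are the reference
   cross-day settings: λ_d = 0.1, λ_m = 0.1, λ_z = 0.01, λ_L = 10,
   batch 160 (80 source / 80 target), Adam at 5e-4.

Evaluation is leave-one-domain-out: each day or subject serves once as
the unlabeled target/test domain. Since suitable emotional-EEG corpora are
typically unavailable or access-restricted, the package ships a synthetic EEG
generator (band-structured classes, per-channel gain / offset / noise
domain shifts) on which the full pipeline, its ablations (MMD-only,
DANN-only, source-only) and all numeric contracts are exercised.

The CNN forward/backward passes (im2col convolutions, AdaBN, dropout,
Adam), the Clough–Tocher interpolation and the zero-phase Butterworth
filter bank are implemented natively (R + a small set of Rcpp kernels),
with analytic gradients throughout — including the exact input
gradients the penalty term requires.

## Worked example

A miniature cross-day experiment on synthetic data — two classes that
differ in posterior Alpha and frontal Beta power, two "days" that differ
by a smooth electrode-gain field, a DC offset and noise level:

```r
library(tdann)

base <- matrix(1, 5, 3)          # bands x {frontal, central, posterior}
cls2 <- base
cls2[3, 3] <- 1.8                # Alpha, posterior: amplitude x1.8
cls2[4, 1] <- 1.5                # Beta, frontal: x1.5
spec <- synthetic_spec(
  n_channels = 32, fs = 128, duration_s = 30, n_trials = 2,
  classes = list(base, cls2),
  domains = list(list(gain_spatial_sd = 0.6, noise_mult = 1),
                 list(gain_spatial_sd = 0.6, offset = 3, noise_mult = 2)),
  seed = 1)
gen <- generate_synthetic_eeg(spec)
ep  <- synthetic_epochs(gen)                 # 2-s windows, 50% overlap
de  <- extract_de_features(ep)               # per-band DE in nats
img <- minmax_standardize(render_image_stack(de, gen$montage))
ds  <- as_image_dataset(img)

cfg <- adaptation_config(batch_source = 40, batch_target = 40,
                         max_epochs = 4, patience = 4, seed = 1)
res <- leave_one_domain_out(ds, cfg, verbose = TRUE)
round(res$summary, 3)
```

which prints

```
<synthetic_eeg> 8 trials x 32 channels x 3840 samples @ 128 Hz
<epoched_eeg> 232 windows x 32 channels x 256 samples @ 128 Hz
<de_features> 232 windows x 32 channels x 5 bands (nats)
<topo_images> 232 windows x 32 x 32 x 5 bands (min-max standardized)
fold 1 (domain 1): accuracy 0.974
fold 2 (domain 2): accuracy 0.974
 mean    sd
0.974 0.000
```

Each fold trains on the labelled windows of one domain plus the
*unlabeled* windows of the other (transductive protocol), adapts the
per-domain normalization statistics to the held-out domain, and scores
accuracy there: 97.4% on both held-out days, where a source-only
classifier on the same data is substantially worse (see the benchmark
below). `run_transfer_benchmark()` scales this to the packaged
61-channel fixture and the full ablation grid.

A thin CLI wraps the same functions (`exec/tdann`):

```sh
tdann simulate  --difficulty easy --seed 1 --out raw.rds
tdann features  --input raw.rds --out feats.rds
tdann images    --features feats.rds --resolution 32 --out imgs.rds
tdann loocv     --data imgs.rds --out results/
tdann benchmark --difficulty easy --seeds 1,2,3 --epochs 2 --out results/
```

`features` also accepts continuous EDF recordings
(`--input recording.edf --montage montage.tsv`).

## Package layout

- `R/features.R`, `R/filters.R` — windowing, Butterworth filter bank, DE.
- `R/montage.R`, `R/topomap.R` — 10–20 montage construction, azimuthal
  projection, Delaunay + Clough–Tocher rendering.
- `R/network.R` — CNN presets, AdaBN, forward/backward.
- `R/losses.R` — MMD, kernels, adversarial losses, gradient penalty.
- `R/train.R`, `R/benchmark.R` — two-level training loop, LOOCV,
  ablation benchmark.
- `R/synthetic.R` — synthetic EEG generator and packaged fixtures.
- `vignettes/two-level-adaptation.Rmd` — the model, its assumptions,
  parameter choices and limitations.
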