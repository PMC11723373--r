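# seizcast

EEG-based epileptic seizure prediction and detection from band-power
spectral images, for researchers building or benchmarking probabilistic
deep models on clinical-style EEG.

Two tasks are covered end to end:

* **Prediction** — binary classification of 2-second EEG windows as
  *preictal* (the hour before a seizure onset) versus *interictal*
  (baseline), with per-event seizure prediction times and false-alarm
  rates per monitored hour.
* **Detection** — four-way classification over interictal, PreI, PreII
  (earlier/later halves of the preictal hour) and ictal windows.

## The model

Raw multichannel EEG (23 bipolar channels, 256 Hz) is windowed (2 s),
Fourier-transformed, low-passed at 30 Hz, and summarized as theta/alpha/beta
band power per channel. Each band's channel powers are laid out on a 5×5
scalp grid and cubically interpolated to 64×64, giving 3×64×64 spectral
images that are standardized and ZCA-whitened.

The feature extractor is a stack of **contractive spike-and-slab
convolutional RBMs** (CssCRBM). Each layer couples visible maps v to binary
spike units h and continuous slab units s via shared kernels w:

    E(v,s,h) = - Σ (v*w)_ij h_ij s_ij  -  Σ b h  +  Σ (v-c)²/2σ²  +  ½ Σ a s²

with exact conditionals: spikes logistic in z = (v*w)²/(2a) + b, slabs
Gaussian N(Ch/a, 1/a), visible units Gaussian around the transposed
convolution of h⊙s. **Dual-variable probabilistic max-pooling** allows at
most one active spike per pooling block and pools spikes and slabs jointly
(their product is the pooled output). Layers are trained greedily by
contrastive divergence (CD-5) with a contractive penalty (the Frobenius
norm of the spike-activation Jacobian) and stacked 36/64/128/128 kernels
deep, shrinking 64×64 inputs to 31, 15, 7, then 3.

For classification the stack runs as a special CNN (relu spikes, linear
slabs, max-pooled hybrid maps), feeds 9 tokens of width 128 into a
single-head transformer-encoder block, and classifies the mean-pooled
token. Fine-tuning is **dual-task**: cross-entropy plus a Siamese
contrastive verification loss (weight 0.11, margin 1 on unit-normalized
features) that shrinks intra-class and stretches inter-class distances,
optimized with Adam.

A fully seeded synthetic EEG generator (1/f background plus class-dependent
band oscillations, ictal 3–5 Hz bursts) reproduces both study designs at
full scale — 10,800 images per patient and 108,000 total for prediction,
9,000 per class for detection — so everything here runs without any
clinical recordings. Exact-enumeration oracles for tiny models verify the
closed-form conditionals and the CD gradient.

## Worked example

```r
library(seizcast)

# simulate a small cohort and build the binary prediction dataset
spec <- synth_spec(seed = 42)
cohort <- gen_cohort(spec, n_patients = 1, database = "I",
                     minutes = list(preictal = 2, interictal = 2))
db <- build_database_one(cohort, minutes_per_class = 2)
db
#> <spectral_dataset> 120 images, classes: interictal, preictal
#>
#> interictal   preictal
#>         60         60

# the full reduced pipeline: whiten -> CD pretrain -> dual-task finetune -> eval
pl <- run_synthetic_pipeline(seed = 42)
pl$report
#> <eval_report> n = 60, accuracy 0.867
#>   sensitivity 1.000, FPR 0.267/sample, 60.000/h, mean prediction time 1.6 min
tail(pl$history, 2)
#>    epoch loss_main   loss_ver     total  accuracy
#> 9      9 0.2801577 0.06510153 0.2873189 0.9428571
#> 10    10 0.1810374 0.04550367 0.1860428 0.9785714
```

Every preictal test window's positive call counts toward sensitivity; the
per-hour FPR merges consecutive interictal positives within a 2-minute
refractory window into alarm events (at this toy scale only a minute of
interictal data is monitored, so the per-hour figure is dominated by small
numbers). Prediction time runs from the first positive preictal sample to
the event's onset — with 2-minute synthetic event windows the ceiling is
2 minutes.

Lower-level entry points: `band_power()`, `to_spectral_image()`,
`fit_zca()`, `csscrbm_params()` / `cd_update()` / `train_csscrbm()`,
`pretrain_stack()`, `forward_deterministic()`, `finetune()`,
`evaluate_model()`, and `gen_tiny_rbm()` with the enumeration oracles
`enumerate_spike_conditional()` / `exact_nll_grad()`. A thin CLI
(`exec/seizcast`) wraps simulate / preprocess / pretrain / finetune /
evaluate over EDF inputs with CSV annotation sidecars.

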