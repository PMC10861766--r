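---
title: "Decoding motor-imagery EEG with an attention-based feature-pyramid TCN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding motor-imagery EEG with an attention-based feature-pyramid TCN}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The decoding problem

Motor imagery (MI) — the mental rehearsal of a movement — produces
band-limited power changes (event-related desynchronization and
synchronization) in the mu (8–12 Hz) and beta (13–30 Hz) rhythms over
sensorimotor cortex. Decoding which movement a subject imagined from a
few seconds of multichannel EEG is the core task of non-invasive
brain–computer interfaces. The signal is weak: trials are short, the
signal-to-noise ratio is low, and the informative features are joint
spectral–spatial patterns rather than anything visible in the raw
time course.

`bfatcnet` implements a convolutional classifier for epoched MI-EEG
trials (trials × channels × samples) built from four blocks:

1. **Temporal feature block.** An EEGNet-style front end: `F1` temporal
   filters of length `F_s/4` (rounded to the nearest power of two —
   64 samples at 250 Hz) applied per electrode, batch-normalized;
   a depthwise electrode convolution with `D` spatial filters per
   temporal map that collapses the electrode axis into
   `d = F1 · D = 32` feature maps, followed by ELU and (1, 8) average
   pooling; then two further temporal stages (kernel 16, batch norm,
   sigmoid, (1, 2) pooling). A convolutional block attention module
   (CBAM) re-weights channels and time steps after the depthwise stage,
   and a bidirectional feature pyramid (Bi-FPN) fuses the three stage
   outputs. The result is three time series `z_j ∈ R^{T_c × d}` at
   nominal bands 4–32, 4–16 and 4–8 Hz with lengths `floor(T/8)`,
   `floor(T/16)` and `floor(T/32)` — 140, 70 and 35 for a 4.5 s trial
   at 250 Hz.
2. **Sliding windows.** Each band series is cut into `n` overlapping
   windows of length `T_w = T_c − n + 1` (window `w` starts at offset
   `w − 1`), a crop-style augmentation of the sequence dimension.
3. **Attention + TCN branch.** Every window passes through multi-head
   scaled-dot-product self-attention
   (`s = softmax(q kᵀ / √d_k)`, `z_a = Σ_b s_ab v_b`) with a residual
   connection and dropout, then a temporal convolutional network of `L`
   residual blocks, each two dilated causal convolutions (dilation
   `2^(l−1)` in block `l`) with batch norm, ELU and dropout and an
   elementwise skip `F(x) + x`. The receptive field is
   `RFS = 1 + 2 (K_T − 1)(2^L − 1)` — 19 elements for the default
   `K_T = 4, L = 2`. Adaptive average pooling compresses each window to
   a 32-dimensional summary.
4. **Classifier head.** The `3 × n × 32` window summaries are
   concatenated and passed through three fully connected layers with
   batch norm and dropout, ending in a softmax over the MI classes.

Training uses AdamW (decoupled weight decay) on the categorical
cross-entropy, with weights initialized from N(0, 0.01²), and optional
online augmentation per batch: convex mixing of same-label trials
(`x ← w·x1 + (1−w)·x2`), additive Gaussian noise
(`x ← x + noise_level·n`) and amplitude scaling (`x ← scale·x`), each
parameter drawn uniformly from its range.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `f1`, `depth_mult` | 16, 2 | filters | temporal maps × spatial filters; product fixes `d = 32` |
| `temporal_kernel` | `F_s/4 → 64` | samples | span of the first conv; keeps ≥ 4 Hz activity inside one kernel |
| `spatial_kernel` | 16 | samples | later temporal stages |
| `pool_sizes` | 8, 2, 2 | samples | total ×32 downsampling; fixes branch lengths |
| `cbam_reduction` | 8 | — | channel-MLP bottleneck (must divide 32) |
| `bifpn_eps` | 1e-4 | — | fast-normalized fusion stabilizer |
| `n_windows` | 5 | windows | `T_w = T_c − n + 1`; at `T_c = 35` leaves `T_w = 31 > RFS = 19` |
| `n_heads`, `head_dim` | 2, 32 | — | attention geometry |
| `n_blocks`, `kernel`, `filters` | 2, 4, 32 | — | TCN stack; receptive field 19 |
| `dropout` | 0.12 | prob. | attention, TCN and head |
| `lr`, `weight_decay` | 1.795e-3, 5.015e-8 | — | AdamW recipe |
| `batch_size`, `epochs` | 128, 50 | — | training loop (30 epochs suffice for the synthetic benchmark) |
| `init_std` | 0.01 | — | weight draw N(0, std²) |

## Design choices where the architecture was open

Several wiring details admit more than one reasonable reading; the
package fixes them as follows and exposes each as configuration.

* **Filter counts.** Only the fused width `d = 32` is a hard
  constraint; `F1 = 16` with `D = 2` satisfies it and keeps the front
  end EEGNet-shaped.
* **Layer-1 activation.** The first convolution is linear
  (conv + batch norm only), as in the EEGNet lineage where the
  nonlinearity enters after the depthwise spatial filter; stage 2 uses
  ELU, stages 3–4 use sigmoid. Keeping layer 1 linear also lets the
  implementation fold stages 1–2 into one fused compiled operator (see
  *Numerical choices*).
* **CBAM placement and geometry.** CBAM is applied once, right after
  the depthwise stage's pooling, where the electrode axis is gone and
  channel attention is most meaningful. The channel MLP uses reduction
  8 with no biases; the time-attention convolution uses the CBAM
  default kernel of 7 restricted to the time axis, acting on the
  stacked channel-mean and channel-max descriptors.
* **Bi-FPN internals.** One pyramid layer over the three levels with
  the standard top-down then bottom-up topology, fast-normalized fusion
  `O = Σ relu(w_i) I_i / (eps + Σ relu(w_j))`, linear interpolation for
  upsampling, (1, 2) average pooling for downsampling, and a 1×1
  convolution + batch norm at each fusion node. Fused outputs replace
  the raw level outputs.
* **Attention wiring.** Two heads of width 32 (the explicit
  hyperparameter statement wins over any larger head enumeration); the
  concatenated heads are projected back to `d = 32`; residual
  connection plus dropout, no layer normalization. Branches do not
  share parameters — the three bands have different lengths and
  semantics — though the window count is shared.
* **Per-window summary.** Adaptive average pooling to length 1, i.e.
  32 features per window; the head input is `3 · n · 32 = 480`.
* **Head widths.** `480 → 128 → 64 → n_classes` with batch norm, ELU
  and dropout between layers.
* **Windows.** `n = 5` balances window length against the shortest
  branch (`T_w = 31` at `T_c = 35`, comfortably above the TCN
  receptive field of 19).
* **Epoch window.** 4.5 s (1125 samples at 250 Hz), which reproduces
  the 140/70/35 branch lengths; a strict 4.0 s cue-to-end reading
  is available through the reader's `window_seconds`.
* **Schedule.** Constant learning rate, 50 default epochs, no early
  stopping.

## Numerical choices

* **Power-of-two kernel rounding** breaks ties upward (a 48-sample
  quarter second selects 64, not 32).
* **Same padding** on all encoder temporal convolutions, so the printed
  branch lengths arise purely from pooling floors; **causal left
  padding** `(K_T − 1)·dilation` inside the TCN.
* **Batch norm** uses biased batch variance with `eps = 1e-5`. After
  the last optimizer step, `train_model()` re-estimates every layer's
  running statistics with one exact sweep over the training set
  (batch statistics, dropout inactive). With only tens of updates, an
  exponential moving average initialized at (0, 1) lags far behind the
  trained weights and evaluation-mode forwards would be mis-scaled;
  the recalibration sweep removes that mismatch exactly.
* **Fusion scalars** are initialized to 1 (the standard choice for
  fast-normalized fusion). Drawing them from N(0, 0.01²) would zero
  entire pyramid nodes with probability ½ per weight after the relu,
  blocking gradient flow through the pyramid; all other weights follow
  the N(0, 0.01²) recipe exactly, biases and batch-norm shifts start
  at 0, scales at 1.
* **Softmax stability**: scores are shifted by their maximum before
  exponentiation; the cross-entropy works on logits and clamps
  probabilities at 1e-12.
* **Degenerate inputs**: window counts must satisfy `1 ≤ n < T_c`;
  trials shorter than the temporal kernel, empty datasets, labels
  outside `[0, n_classes)` and non-finite losses raise errors rather
  than propagating silently.
* **Determinism.** All randomness (initialization, shuffling, dropout,
  augmentation, synthesis) flows through R's RNG under a single seed;
  two runs with one seed on one machine are bit-identical. The
  compiled kernels use fixed summation orders.
* **Engine.** No autograd framework is assumed: layers run on a small
  reverse-mode tape written for this package, with compiled (Rcpp)
  kernels for the convolutions, batch norm and ELU. The first two
  encoder stages are fused into a single compiled operator that
  recomputes per-electrode intermediates in cache instead of
  materializing the `F1 × C × T × batch` tensor, which keeps training
  compute-bound; its backward pass is the exact hand-derived adjoint
  (finite-difference tests in `test-autograd.R` verify the whole graph
  to ~1e-5 relative error).

## The synthetic benchmark

The generator (`synth_spec()` / `simulate_mi_eeg()`) emulates the
physiology the architecture targets: each trial is per-electrode
1/f-colored background noise (unit variance, spectral slope 1), and
each class adds a narrow-band amplitude-modulated sinusoid — random
carrier frequency inside the class band, random carrier and envelope
phases, modulation depth 0.5 at ~1 Hz — on a class-specific electrode
subset, at amplitude `snr` times the noise standard deviation. Class
signatures default to distinct mu/beta-style (band, electrode-group)
pairs, mimicking the lateralized ERD/ERS contrasts of left-hand,
right-hand, foot and tongue imagery. Random phases make the classes
indistinguishable in the time-domain mean while band power separates
them — so a model can only succeed by learning spectral–spatial
features, matching the architecture's premise.

What the generator does **not** emulate: inter-subject and inter-trial
covariate shift, artifacts (EMG, EOG, line noise), volume-conduction
channel correlations, non-stationary band power drift, and genuine ERD
(power *decrease* relative to a baseline — the generator uses additive
class power). Passing the synthetic benchmark therefore demonstrates
that the pipeline can learn band-limited spatial contrasts end to end;
it does not certify performance on competition recordings, which
require the GDF reader and full-length training.

The benchmark conditions are the generator defaults: 4 classes ×
60 trials, 22 channels, 250 Hz, 4.5 s, snr 2.0, seed 7, with 25 % of
trials held out per class, the default model configuration and
30 training epochs. A control at snr 0 (label-independent noise) must
score at chance. Unit tests use scaled-down geometries (4–8 channels,
0.6–2 s trials, 8-map encoders) chosen to exercise every code path in
seconds; the capacity and oracle checks state their sizes inline.

## Known limitations

* CPU-only, double precision; batches of 128 full-size trials use on
  the order of 1 GB of working memory.
* The GDF reader delegates container parsing to the MNE backend via
  `python`; without it, only the fixture format is available.
* Cohen's κ is reported in its standard global form (the per-class
  averaged variant collapses to it when agreement terms are global),
  and the class-balanced accuracy is macro-averaged recall — equal to
  plain accuracy on balanced sets; both micro and macro forms are
  reported.
* The across-subject standard deviation in `subject_summary()` is the
  population (divide-by-n) form.
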