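---
title: "Multirate ECG beat classification: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multirate ECG beat classification: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrecg)
```

## The processing model

`mrecg` classifies single-lead ECG beats with a deliberately cheap,
multirate front end. A digitised stream `x_n` (360 Hz, millivolts) is
band-pass filtered to `xf_n`, decimated to `xd_n`, tiled into beat
windows `xs_n`, decomposed into wavelet subbands, reduced to 16
statistics per beat, and classified by k-nearest neighbours. The point of
the design is that decimation before the wavelet stage divides the
arithmetic of everything downstream by the decimation factor, while the
feature reduction divides the data volume to be stored or transmitted by
more than twenty-fold; the accompanying cost functions make both claims
auditable.

### Denoising

The clinically useful ECG band is taken as [0.5, 50] Hz: baseline wander
(respiration, electrode motion) lives below 0.5 Hz and power-line
interference at 50/60 Hz and above. The filter is a linear-phase FIR of
fixed order 122 designed by the windowed-sinc method with a Hamming
window (`signal::fir1`), and its coefficient vector is explicitly
symmetrised so the linear-phase identity `b_i = b_{order-i}` holds
exactly. Applying it shifts the output by the integer group delay
`order/2 = 61` samples, which `apply_filter()` compensates so beat peaks
stay aligned; edges are implicitly zero-padded.

One honest limitation: at order 122 and 360 Hz the transition width of a
Hamming windowed-sinc is roughly 10 Hz, far wider than the 0.5 Hz lower
edge. The filter therefore attenuates true DC only mildly (gain ≈ 0.88)
even though the passband nominally excludes it; slow baseline wander at
0.3 Hz is likewise only partially suppressed at this order. The passband
(unity ± 5 % at 10 Hz) and the upper stopband (< 5 % at 120 Hz) behave as
specified, and the tests assert exactly that achievable contract. A much
higher order or an IIR design would fix DC rejection but is outside this
front end's fixed budget.

### Decimation

For a signal band-limited to `fmax`, plain subsampling by `D` is
alias-free when `D <= fs / (2 * fmax)`; with `fs = 360` and
`fmax = 50` the bound is 3.6, so the pipeline default is `D = 3`
(120 Hz effective rate). `decimate_signal()` enforces the bound and
reports it in the error message; `force = TRUE` deliberately bypasses it,
both because alias studies need the unsafe path and because the cost
model's printed multirate coefficient corresponds to `D = 4`
(`0.875 = 3.5/4`). Both factors are therefore first-class: the alias-safe
default is 3, and the cost functions parameterise `D` so either
configuration is reproducible. The decimation phase is fixed at offset
0 (samples 1, 1+D, 1+2D, ...).

### Segmentation

Records are tiled with consecutive non-overlapping 0.9-s rectangular
windows (`round(0.9 * fs)` samples: 108 at 120 Hz, 81 at 90 Hz), the
trailing partial window discarded, the window centre time kept as
metadata. No R-peak detection is attempted: the synthetic generator
centres one beat per window by construction, and windowing rules for
real recordings are an alignment concern deliberately out of scope.

### Wavelet decomposition

Each window is decomposed by a three-level Daubechies filter bank. The
orthonormal scaling coefficients `g` are computed at load time by
spectral factorization of the Daubechies half-band polynomial
(`polyroot` plus Newton polishing; accurate to ~1e-12 for orders 1–10,
verified against the db2 closed form and a reference wavelet library),
and the high-pass is the quadrature-mirror `h_k = (-1)^k g_{Kg-1-k}`
(0-based). Analysis convolves with `g`/`h` and keeps every second output
(the `2n - k` stencil), with **periodic** boundary extension and a
circular shift of `Kg/2 - 1` that cancels the half-band group delay; this
makes the transform exactly orthonormal (energy preserved, perfect
reconstruction) and bit-compatible with the widely used "periodization"
mode of reference DWT implementations, which the oracle tests exploit.

Windows are zero-padded to the next multiple of 2³ before the cascade so
each level halves the length exactly: 108 → 112 → d1 = 56, d2 = 28,
d3 = 14, a3 = 14. Nominal band edges are the dyadic halving of
`[0, fs_effective/2]` — at 120 Hz: a3 [0, 7.5], d3 [7.5, 15],
d2 [15, 30], d1 [30, 60] Hz. These are computed from the effective rate
rather than fixed, because a printed table of edges only matches one
specific rate. The default order is db4 (8 taps), a common ECG choice;
all code is order-parametric over db1–db10.

### Features

Four statistics per subband, 16 per beat, in fixed subband-major order
(`d1_E … a3_NV`):

* **E** — the sum of absolute coefficient values, Σ|c|. Note this is an
  L1 sum, kept deliberately as the pipeline's definition; the
  conventional quadratic energy is available via `energy = "l2"`.
* **K** — Pearson (non-excess) kurtosis `m4/m2²` with population
  moments; 3 for Gaussian coefficients, lower bound 1. A zero-variance
  subband returns 0 with a warning rather than NaN.
* **PV / NV** — the largest positive and most negative coefficient, with
  0 when no coefficient of that sign exists, so `PV >= 0 >= NV` always.

### Classification and evaluation

KNN with `k = 5` and Euclidean distance in the raw 16-dimensional feature
space (no scaling by default, since the feature definitions themselves
carry the discriminative magnitudes; per-fold z-scoring is available via
`scale = TRUE`). Ties are resolved deterministically: majority vote,
then smallest summed distance among tied classes, then lexicographic
class name. Cross-validation is stratified 10-fold: each class is
shuffled by the seeded generator and dealt round-robin, so folds are
balanced and the whole report is reproducible bit-for-bit from the seed.

Scoring aggregates the confusion matrix over folds and derives per-class
one-vs-rest counts. Accuracy is `(TP+TN)/(TP+TN+FP+FN) * 100` and
specificity `TN/(TN+FP)`; `average_*` are arithmetic means over the three
classes. Because one-vs-rest accuracy counts true negatives, its chance
level for three balanced classes is 5/9, not 1/3 — the report therefore
also exposes `overall_accuracy` (plain percent correct, chance 1/3) and
per-class recall, and the suite's chance-level test asserts on the
overall rate.

## The cost model

`compression_ratio(Nr, P)` is the data reduction of transmitting `P`
features instead of `Nr` window samples. With the one-second reference
window at 360 Hz this is 360/16 = 22.5; with the pipeline's own 0.9-s
window it is 324/16 = 20.25. Both are reported rather than silently
choosing one, since the headline figure assumes the 1-s reference.

The wavelet cascade's arithmetic: a `Kg`-tap half-band filter costs `Kg`
additions and `Kg` multiplications per input sample; two branches per
level over three levels at halving rates give the factor
`2·(1 + 1/2 + 1/4) = 3.5`, i.e. `3.5·Kg·Nr` additions and the same count
of multiplications at fixed rate, and `(3.5/D)·Kg·Nr` after decimation
(`0.875` at `D = 4`). The gain is algebraically `D`, independent of `Kg`
and `Nr` — the tests verify that identity over a grid, and the fixed-rate
coefficient against an explicit per-level operation counter. The
denoising FIR's own cost can be reported as an optional extension but is
kept out of the fixed-vs-multirate comparison, which concerns the
decomposition stage only.

## The synthetic generator

There is no bundled beat archive, so the generator stands in for one.
Each beat is a sum of Gaussian deflections (P, Q, R, S, T) over 0.9 s;
RBBB adds a widened QRS with a secondary R′ bump and a discordant T, and
WPW a delta wave sliding into R with a shortened PR interval. Records
are contaminated with a power-line sinusoid (default 0.2 mV at 50 Hz,
configurable to 60 Hz), baseline wander (0.3 mV at 0.3 Hz) and white
Gaussian noise (default sigma 0.05 mV), with per-record jitter (5 %
relative) of amplitudes and widths. These defaults were chosen once as
plausible ambulatory contamination relative to a ~1 mV R wave. Seeding
is hierarchical: one master stream draws one sub-seed per record index,
so a record's samples never depend on how many other records are
generated around it.

What the generator emulates: beat-scale morphology differences, realistic
spectral content (smooth, band-limited below ~50 Hz), the standard noise
types, and class-balanced labelled sampling at 360 Hz. What it does not
emulate: rhythm-level (inter-beat) dynamics, morphology drift within a
recording, electrode artefacts, multi-lead correlation, or clinically
validated waveshapes. Consequently, a perfect cross-validated score on
the zero-noise synthetic classes demonstrates that the chain preserves
separable morphology end-to-end — not that comparable accuracy would be
reached on clinical archives, where published figures for this type of
chain are in the low-90 % range. The noise-sweep test (accuracy
degrading monotonically over white-noise sigma 0, 0.25, 1.0, 2.5 mV)
probes the realistic direction of that gap.

## Numerical choices and degenerate inputs

* Filter coefficients are symmetrised `(b + rev(b))/2`, making the
  linear-phase test exact rather than tolerance-based.
* Wavelet padding is zeros (not reflection): it keeps the length
  contract exact and orthonormality trivially true; the padded tail is
  part of the analysed window.
* Kurtosis of a constant subband: 0 with a warning (a degenerate subband
  carries no shape information).
* PV/NV of single-signed subbands: 0 by definition.
* Records shorter than one window segment to an empty list with a
  warning, not an error, so batch runs skip short tails gracefully.
* KNN distance ties: stable order (distance, then index); class-vote
  ties: summed distance, then class name.
* All randomness flows through an internal seeded-evaluation helper that
  restores the caller's RNG state.

## Problem sizes used by the test suite

The study-scale checks run the full chain at 150 beats per class
(450 instances, the 450 × 16 matrix), 10-fold cross-validation, and the
noise sweep over 20 seeds × 4 noise levels; oracle comparisons use 100
random 108-sample segments against a reference periodized DWT and
exhaustive KNN checks up to 50 training instances. A single study-scale
pipeline run takes well under a second, and the whole suite a few tens
of seconds on one core.
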