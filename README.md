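# mrecg — multirate ECG processing and arrhythmia classification

`mrecg` implements a computationally efficient multirate front end for
single-lead ECG beat classification, aimed at settings where every
operation and every transmitted byte counts (wearable and implantable
cardiac monitors). The chain is:

1. **Denoising** — an offline-designed 122nd-order linear-phase band-pass
   FIR (windowed-sinc, Hamming) with cut-offs [0.5, 50] Hz at
   F<sub>S</sub> = 360 Hz, suppressing baseline wander and power-line
   interference.
2. **Decimation** — subsampling by an integer factor D without an extra
   anti-aliasing stage, justified by the band limit: aliasing-free whenever
   D ≤ F<sub>S</sub> / (2·f<sub>max</sub>) = 360 / 100 = 3.6, so D = 3 is
   the largest safe factor (D = 4 requires an explicit override).
3. **Segmentation** — consecutive 0.9-s rectangular windows, one beat per
   window.
4. **Wavelet decomposition** — a three-level Daubechies filter bank
   (half-band quadrature-mirror pair g, h with h<sub>k</sub> =
   (−1)<sup>k</sup> g<sub>Kg−1−k</sub>, periodic boundary handling),
   yielding subbands d1, d2, d3, a3.
5. **Features** — per subband: energy E = Σ|c|, Pearson kurtosis
   K = m₄/m₂², peak positive value PV and peak negative value NV — 16
   features per beat.
6. **Classification** — k-nearest neighbours (k = 5, Euclidean distance,
   majority vote) under stratified 10-fold cross-validation, scored with
   per-class one-vs-rest accuracy (TP+TN)/(TP+TN+FP+FN)·100 and
   specificity TN/(TN+FP).

Alongside the pipeline, the package does the cost accounting that
motivates the multirate design: the compression ratio
R<sub>COMP</sub> = N<sub>r</sub>/P (360 samples → 16 features = 22.5×) and
the fixed-rate vs multirate wavelet operation counts
(3.5·Kg·N<sub>r</sub> vs (3.5/D)·Kg·N<sub>r</sub> additions and
multiplications, a D-fold gain — 4× at D = 4).

Because no public beat archive is bundled, the package ships a seeded
synthetic generator of three beat morphologies — normal sinus rhythm (N),
right bundle branch block (RBBB, widened QRS with an R′ bump) and
Wolff-Parkinson-White (WPW, delta wave with a short PR interval) — built
from sums of Gaussian deflections and contaminated with power-line
interference, baseline wander and white noise. Every stage is testable
offline with it.

## Worked example

```r
library(mrecg)
cfg <- pipeline_config(n_per_class = 20, folds = 5, seed = 7, out_dir = tempfile())
s <- run_pipeline(cfg)
print(s)
```

```
[mrecg] input: 60 records @ 360 Hz
[mrecg] denoised with 123-tap band-pass [0.5, 50] Hz
[mrecg] decimated by D=3 -> 120 Hz
[mrecg] segmented into 60 windows of 0.9 s
[mrecg] feature matrix: 60 x 16 (+ label)
[mrecg] KNN k=5, 5-fold CV: average accuracy 100.00%, overall 100.00% correct
[mrecg] costs: R_COMP = 20.25, gain = 3
<pipeline_summary> config 3770d418: 60 records -> 60 segments
<classification_report> KNN k=5, 5-fold CV, seed 7
 class accuracy specificity recall
     N      100           1      1
  RBBB      100           1      1
   WPW      100           1      1
average accuracy 100.00%, average specificity 1.000, overall 100.00% correct
<cost_report> Nr=324, P=16, Kg=8, D=3
  compression ratio R_COMP = 20.25
  fixed-rate: 9072 additions + 9072 multiplications
  multirate:  3024 additions + 3024 multiplications
  gain = 3
```

Reading the output: 60 synthetic beats (20 per class) pass through the
filter, the D = 3 decimator and the 0.9-s windower, giving one
108-sample segment per beat and a 60 × 16 feature matrix. The default
synthetic morphologies are cleanly separable, so cross-validated KNN is
perfect here. The cost report uses this run's own sizes: a 0.9-s window
at 360 Hz is N<sub>r</sub> = 324 samples, so the feature front end
transmits 324/16 = 20.25× less data, and the decimated wavelet cascade
does 3× fewer additions and multiplications than its fixed-rate
counterpart (9072 → 3024). With the one-second reference window
(N<sub>r</sub> = 360) the compression ratio is the headline 22.5, and at
D = 4 the gain is 4.

A thin command-line front end over the same functions is installed under
`inst/cli/mrecg` (subcommands `synth`, `preprocess`, `features`,
`classify`, `costs`, `run`).

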