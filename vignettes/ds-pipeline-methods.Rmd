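---
title: "Methods: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the processing of two-photon calcium recordings into direction-tuning
statistics, the population decomposition that compares genotypes, the
intrinsic-signal retinotopy pipeline, and the synthetic-data generator
that every stage is validated against. It also records the numerical
choices and the decisions made where the methodology left the design
open.

## Trace processing

Raw per-ROI fluorescence is converted to a baseline-normalized signal
$\Delta F/F_0 = (F - F_0)/F_0$. The baseline $F_0$ is a rolling 10th
percentile over a 60-s window followed by a zero-phase second-order
Butterworth low-pass at 0.01 Hz. Numerical choices:

* **Window edges.** The percentile window is truncated at the trace
  boundaries; no samples are fabricated by padding.
* **Filter order and phase.** The Butterworth order is not dictated by
  the method description; order 2 applied forward-backward (zero phase)
  is the standard minimal-ripple choice. Because the filter is applied
  with zero initial conditions, the series is edge-reflected and
  demeaned before filtering; otherwise the start-up transient (time
  constant ~100 s at the 0.01-Hz cutoff) would corrupt a large fraction
  of the trace.
* **Stride.** `compute_baseline_f0(..., stride = n)` evaluates the
  percentile on a subgrid and interpolates. The subsequent 0.01-Hz
  low-pass makes a 1-s stride numerically indistinguishable from the
  exact per-frame filter (tested to 1%); the multi-ROI pipeline uses it
  for speed.
* **Known bias.** A rolling low percentile is a biased estimator: with
  white noise of relative standard deviation $\sigma$ it sits about
  $1.28\sigma$ below the true baseline, and on sloped segments it lags
  by roughly $0.4 \times \mathrm{window} \times \mathrm{slope}$. At the
  default generator conditions (gentle drift, periods > 120 s) the
  estimated baseline stays within 1% of the generator's true $F_0$ at
  zero noise; the residual stimulus decay tail contributes about 0.5%
  of the typical response amplitude. Consequences for DSI are discussed
  under *Synthetic data*.

Trial amplitudes are extracted from the trace downsampled to 15.4 Hz by
block averaging; the amplitude of a trial is the mean of the largest
50% of samples in the 3-s drift window (top $\lceil n/2 \rceil$ sorted
samples, so odd windows are never empty). Responsiveness is gated at a
preferred-direction trial-mean amplitude above 0.06 (cortical mode;
the gate is applied to the trial mean, not single trials) or at any
amplitude above the cell's $\Delta F/F_0$ mean + 2 SD computed over the
stimulus-free samples (retinal mode; the method statement does not name
the segment, so the gray-screen and pre-stimulus frames are used).

## Tuning metrics

For each temporal frequency (TF) the per-direction mean amplitudes
$R_i \ge 0$ (negative values floored) define:

* the **preferred direction** $\theta$, the angle of the vector sum
  $\sum_i R_i (\cos d_i, \sin d_i)$ taken with the full-quadrant
  arctangent (the single-argument arctangent in the printed formula is
  quadrant-ambiguous; every standard implementation resolves it this
  way);
* **DSI** $= (R_\mathrm{pref} - R_\mathrm{opp}) /
  (R_\mathrm{pref} + R_\mathrm{opp})$, with $R_\mathrm{pref}$ read at
  the sampled direction nearest $\theta$ and $R_\mathrm{opp}$ 180° away
  — the vector sum defines preference, and the two coincide for
  unimodal curves;
* **OSI** $= (R_\mathrm{pref} - R_\mathrm{orth}) /
  (R_\mathrm{pref} + R_\mathrm{orth})$ with axis means (preferred
  direction and its opposite vs the orthogonal pair).

Degenerate inputs: an all-zero curve has no preferred direction
($\theta$ reported missing, DSI = 0); a perfectly symmetric curve has a
numerically zero resultant, and the preferred sampled direction falls
back to the amplitude maximum — a deterministic tie-break exercised
only by constructed fixtures. For arbitrary multimodal curves the
nearest-to-$\theta$ reading can yield DSI < 0; for unimodal tuning
DSI lies in [0, 1].

A cell is **direction-selective (DS)** when it is responsive and DSI
strictly exceeds 0.3 in at least one TF. The **preferred TF** maximizes
the preferred-direction amplitude, with ties broken toward the lower TF
(each TF uses its own best direction). The **ON-OFF index** per spot
size is $(R_\mathrm{ON} - R_\mathrm{OFF})/(R_\mathrm{ON} +
R_\mathrm{OFF})$; a cell is ON-OFF when the mean of $|OOI|$ over the
five sizes is below 0.3. The absolute value is a deliberate
interpretation: the signed reading would classify pure-OFF cells
(OOI $\approx -1$) as ON-OFF. Axis classification assigns angles within
45° of the posterior–anterior axis to "horizontal", with the 45°
boundary itself horizontal (deterministic tie rule). Directions use
0° = posterior (temporal-to-nasal motion on the screen), increasing
counter-clockwise; retinal data are reported in the same convention
with nasal motion on the retina corresponding to posterior motion in
the visual field.

## Population decomposition and grid comparison

DS cells enter a response matrix with eight columns — peak amplitude
and DSI at each of the four TFs — z-scored per column (amplitudes and
DSI live on different scales; the source description does not state a
scaling, and unscaled PCA would be dominated by amplitude variance) and
projected onto the top two principal components. Component signs are
fixed so the loading of the highest-TF amplitude is non-negative, making
the embedding reproducible.

The pooled embedding's bounding box is split into $n \times n$
half-open grids (default 8; points on the top/right boundary belong to
the last bin). The grid partition is computed from both groups pooled —
per-group fractions are only comparable on a common partition. Each
grid is tested with a two-sided Yates-corrected chi-square on the 2×2
table *in-grid vs out-of-grid × group*; this is the only 2×2
construction consistent with comparing one grid's fraction between
groups. Grids are classed *decreased*/*increased* (p < 0.05 with the
mutant fraction below/above control) or *unchanged*. No minimum-count
filter and no multiple-testing correction are applied, matching the
reported per-grid P < 0.05 usage; `p_adjust = "fdr"` enables an
optional BH correction. The per-grid mutation index
$(F_\mathrm{control} - F_\mathrm{mutant}) /
(F_\mathrm{control} + F_\mathrm{mutant})$ and projection-target index
$(F_\mathrm{RLp} - F_\mathrm{PMp})/(F_\mathrm{RLp} + F_\mathrm{PMp})$
take 0/0 as 0.

The Rayleigh test uses the small-sample-corrected p-value of the
standard circular-statistics toolboxes,
$p = \exp\!\big(\sqrt{1 + 4n + 4(n^2 - R^2)} - (1 + 2n)\big)$ with
$R = n\bar{r}$; the exact approximation variant of the cited toolbox is
not printed anywhere, and this is the formulation its documentation
gives. Its empirical type-I error at $\alpha = 0.05$ is about 0.05
(checked over 2000 uniform simulations). Kolmogorov–Smirnov comparisons
of preferred-direction distributions linearize angles on [0°, 360°)
with the cut at 0° = posterior.

## Intrinsic-signal retinotopy

Each pixel's time course yields a complex Fourier coefficient at the
DFT bin nearest the sweep frequency (0.067 Hz azimuth, 0.088 Hz
elevation for the default 134.46° and 102.75° extents at 9°/s). All
phase arithmetic is circular (wrapped to $[-\pi, \pi)$). Opposing
sweeps measure $\theta + \delta$ and $-\theta + \delta$; the
hemodynamic delay $\delta$ is the circular half-sum, resolved by taking
the candidate nearest zero (valid for delays under a quarter stimulus
period, ~3.7 s here), and the retinotopic phase $\theta = \phi_{fwd} -
\delta$ retains the full $[-\pi,\pi)$ range. Phases map linearly onto
visual degrees over the sweep extent.

The visual-field sign is the sine of the angle between the retinotopic
gradients, $I = \sin(\angle\nabla\mathrm{el} -
\angle\nabla\mathrm{az})$ — the de-facto definition behind published
sign-map code, with the order chosen so that an azimuth map increasing
along x with elevation increasing along y gives $I = +1$. Gradients are
central differences after Gaussian pre-smoothing (σ = 2 px default;
raw maps are too noisy for pixelwise gradients), with missing-aware
normalized convolution so unresponsive pixels (Fourier magnitude below
10% of the image maximum) do not bleed into area borders. Thresholding
keeps $|I| \ge \overline{|I|} + \mathrm{SD}(|I|)$: the printed
threshold is ambiguous for signed maps whose mean is near zero, and the
signed reading would discard all negative-sign areas. A constant map
(zero spread) yields an empty mask. The mask is cleaned by a 3×3
median filter, then the 8-neighbor rule: retain pixels with more than
four non-zero neighbors, and fill gaps adjacent to retained pixels —
the retain pass and the fill pass run once each, in that order (the
description does not fix the order; a single sweep keeps the operator
idempotent on solid blocks). Borders come from a Sobel edge detector on
the binarized mask; connected components are labeled (8-connectivity),
sizes converted to mm², and centroids re-expressed relative to the
largest area's centroid (V1 by construction). Components under 9 px are
discarded as specks.

Areal response strength for episodic gratings normalizes each pixel's
time course to its mean over the ≥10-s pre-stimulus segment, then takes
the peak spectral power in 0.05–0.1 Hz; the per-area strength is the
ROI maximum. Normalizing the time course (rather than the power) makes
the strength invariant to a global gain on the stack.

## Synthetic data: what it emulates and what it does not

The generator produces ground-truth-labeled recordings under the study
protocols: 12 directions × 4 TFs (0.3/0.75/1.2/1.8 Hz) × 6 trials of
3 s drift + 3 s gray at 30.9 Hz (cortex); 8 directions × 3 trials at
8 Hz (retina); 2-s flash spots of 50–800 µm; sinusoidal sweep stacks
for retinotopy; 20-s episodic grating stacks for areal responses.

The tuning model is a baseline-plus-von-Mises curve normalized so the
noiseless curve's DSI equals `dsi_true` exactly: with
$b = (1-\mathrm{dsi})/(1+\mathrm{dsi})$,
$R(d) = A_{tf}\,[\,b + (1-b)\,\tilde{v}_\kappa(d-\theta)\,]$, where
$\tilde v$ is the von Mises density rescaled to [0, 1]. Traces convolve
the per-event expected amplitude with a single-exponential
calcium-indicator kernel (τ = 0.6 s, GCaMP6f-like; no kernel is stated
in the methods, and this is the standard minimal model), superimpose a
slow multiplicative drift (sum of sinusoids with periods 137–307 s and
3% total amplitude, chosen so the 60-s percentile baseline must
actively remove it), and add white Gaussian noise. Flash responses are
transient (0.3-s onset and offset drives, peak-normalized): a sustained
ON drive would leak its decay tail into the OFF window and destroy
ON-OFF-index recoverability, and real ON-OFF cells respond transiently.

Two noise entry points are distinguished deliberately:

* `synthesize_recording` adds **frame-level** noise to the raw trace.
  At zero noise the full pipeline reproduces the closed-form expected
  amplitudes within 1% (the kernel onset contributes a deterministic
  attack factor, `kernel_attack_factor()`, about 0.97 at the default
  rates). With frame noise present, the percentile baseline's
  $-1.28\sigma$ bias propagates into a *downward* DSI bias of order
  0.05–0.1 at realistic amplitudes — a property of the baseline method
  itself, reproduced faithfully, not corrected.
* `sample_tuning_curves` draws **trial-level** amplitude noise
  (Gaussian, floored at zero) around the closed-form expectations.
  Parameter-recovery and population benchmarks use this path: it models
  trial-to-trial variability directly (the magnitudes are not stated in
  the source and are free parameters of the spec) and keeps the
  benchmark about the estimators rather than about the percentile
  filter.

The recovery benchmark (2000 cells, κ ∈ [2, 6], trial noise 0.05,
6 trials) draws preferred directions on the stimulus grid, where
`dsi_true` is exactly recoverable by construction; off-grid preferred
directions add a discretization bias of up to ~0.03 (the nearest
sampled direction sits up to 15° off-peak), characterized separately by
the noiseless recovery test (< 5°, < 0.05). Median recovery errors are
about 3° in θ and 0.047 in DSI, dominated by trial noise at the chosen
amplitude scale (log-normal, median 0.35 ΔF/F₀, a typical peak
amplitude for virally expressed GCaMP6f somata).

The genotype benchmark uses two-class mixtures: a posterior-preferring,
high-DSI class whose amplitude rises with TF (1.2/0.3 Hz ratio ≈ 2)
and a generic class with uniform directions and a falling TF profile.
Control carries 45% posterior-class mass, the mutant 20% — the only
difference between groups, emulating the selective loss of the
retina-dependent posterior high-TF channel. With 1000 cells per group
the decreased grids, their TF-increasing amplitude signature, their
posterior Rayleigh bias at 1.2 Hz, and positive mutation indices are
stable across 6×6, 8×8 and 10×10 grids.

The retinotopy generator lays out six rectangular areas (largest = V1)
with linear gradients of 1.2°/px and alternating mirror polarity,
separated by unresponsive gaps, on a 96×96 grid at 0.02 mm/px; stacks
span an integer number of sweep periods so the stimulus frequency falls
exactly on a DFT bin (no spectral leakage), three sweeps at 6 Hz for
the benchmarks. The hemodynamic delay is a constant phase offset
identical in forward and reverse sweeps — precisely the assumption the
subtraction method needs.

**What passing tests do not show about real data**: the generator has
no motion artifacts, no neuropil contamination, no bleaching, additive
Gaussian noise only, perfectly rectangular areas with exactly linear
retinotopy, and von Mises tuning with a single preferred direction per
cell. Results on real recordings additionally depend on motion
correction and ROI segmentation, which are upstream of this package's
scope.

## Problem sizes

Default benchmark sizes were chosen so each stage completes in seconds
on a single core while keeping estimator errors well inside their
tolerances: 2000 cells for parameter recovery, 1000 cells per group for
the genotype comparison, 96×96×~270-frame stacks for retinotopy, and
2000 simulations of n = 50 for the Rayleigh level check. All
generators and analyses are deterministic given a seed.
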