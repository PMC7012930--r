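# dsstream

Analysis of direction-selective visual responses, from single-cell
calcium-imaging traces to population-level comparisons between
genotypes, plus intrinsic-signal retinotopic mapping of visual cortical
areas.

## The scientific problem

Retinal direction-selective (DS) cells encode motion direction before
any cortical processing. When retinal horizontal direction selectivity
is genetically disrupted, which cortical populations inherit the
deficit? Answering this requires a chain of quantitative analyses:

1. **Trace processing** — convert raw two-photon fluorescence into
   ΔF/F₀ (60-s 10th-percentile baseline + 0.01-Hz Butterworth low-pass)
   and trial-resolved response amplitudes (mean of the larger 50% of
   samples in each 3-s drift window, at 15.4 Hz).
2. **Tuning metrics** — per cell and temporal frequency (TF):
   preferred direction θ = atan2(Σᵢ Rᵢ sin dᵢ, Σᵢ Rᵢ cos dᵢ),
   DSI = (R_pref − R_opp)/(R_pref + R_opp),
   OSI = (R_pref − R_orth)/(R_pref + R_orth), preferred TF, ON-OFF
   index OOI = (R_ON − R_OFF)/(R_ON + R_OFF). Cells are responsive if
   the preferred-direction amplitude exceeds 0.06 ΔF/F₀ at some TF, and
   DS if additionally DSI > 0.3.
3. **Population decomposition** — an n×8 response matrix (peak
   amplitude and DSI at 4 TFs) is decomposed by PCA, segmented by 8×8
   grids, and per-grid cell fractions are compared between groups with
   two-sided Yates-corrected χ² tests; normalized-difference indices
   summarize the changes: MI = (F_ctrl − F_mut)/(F_ctrl + F_mut) and
   PTI = (F_RLp − F_PMp)/(F_RLp + F_PMp). Circular statistics
   (Rayleigh test) quantify population direction biases.
4. **Intrinsic-signal retinotopy** — per-pixel Fourier phase at the
   sweep frequency (speed/extent, ≈0.067 Hz azimuth and 0.088 Hz
   elevation), hemodynamic-delay subtraction from opposing sweeps,
   visual-field sign maps I = sin(∠∇el − ∠∇az), and a three-step
   border detection (threshold at mean|I| + SD|I| with a 3×3 median
   filter; 8-neighbor isolation/gap-filling; Sobel edges + connected
   components) yielding area sizes, centroids and per-area response
   strengths.

A synthetic-data generator produces ground-truth-labeled recordings
under the study's stimulus protocols (12 directions × 4 TFs × 6 trials
of drifting gratings; flash spots; retinotopy sweeps; episodic
gratings), so the whole pipeline is testable end-to-end without any
experimental data. See `vignettes/ds-pipeline-methods.Rmd` for the
models, parameter choices and limitations.

## Worked example

```r
library(dsstream)

protocol <- cortical_grating_protocol(order_seed = 1)
truth <- sample_population(cortical_population_spec("control", n = 5),
                           seed = 1)
rec <- synthesize_recording(truth, protocol, seed = 1)   # raw traces
pr  <- process_recording(rec, mode = "cortical")          # dF/F0 + curves
s   <- summarize_cells(pr$curves, responsive = pr$responsive,
                       group = "control")
truth[1, c("class", "theta_true", "dsi_true")]
#>    class theta_true  dsi_true
#>  generic   234.6026 0.7218145
round(s[1, c("preferred_tf", "tf_ratio", "dsi_1.2", "theta_1.2")], 3)
#>  preferred_tf tf_ratio dsi_1.2 theta_1.2
#>           0.3    0.639    0.51   233.447
```

The preferred direction is recovered to ~1° (233.4 vs 234.6). The DSI
estimate (0.51 vs 0.72) sits below truth because frame-level noise
biases the percentile baseline low — an inherent property of the
baseline method that the package reproduces and documents in the
methods vignette; the trial-level generator (`sample_tuning_curves`)
recovers DSI to ~0.05.

The full population comparison runs in one call:

```r
cfg <- default_config()
cfg$n_cells_per_group <- 400L
res <- run_pipeline(cfg)
#> generated: 800; responsive: 800; DS: 753
#> grids decreased/increased: 1/0
subset(res$grid_comparison$grids, class == "decreased")[,
  c("grid", "count_control", "count_mutant", "chisq", "p", "mi")]
#>  grid count_control count_mutant  chisq      p mi
#>    38             6            0 4.0291 0.0447  1
```

Grid 38 of the PCA embedding loses its cells in the mutant group
(6 control vs 0 mutant, p = 0.045, mutation index 1): the synthetic
mutant population was generated with reduced posterior-preferring
high-TF mass, and the grid comparison localizes exactly that
subpopulation.

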