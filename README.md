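# speckleflow

Analysis and simulation toolkit for **multi-distance speckle contrast
optical spectroscopy (SCOS)** recordings of scalp and cerebral
hemodynamics.

## The problem

Optical measurements of cerebral blood flow through the intact head are
contaminated by scalp and skull blood dynamics.  A seven-channel SCOS
instrument addresses this by imaging laser speckle collected at
source–detector (S–D) distances from 0.6 to 2.6 cm — short channels see
mostly scalp, long channels gain brain sensitivity — while a brief
occlusion of the superficial temporal artery (which supplies scalp, not
brain) provides a controlled perturbation that suppresses only the
superficial signal.  Comparing pre/during/post-occlusion statistics
across distances quantifies how scalp-sensitive each channel is.

`speckleflow` implements the full analysis for such recordings, and —
because no public data set exists for this protocol — a seeded synthetic
two-layer (scalp/brain) speckle-camera simulator with closed-form ground
truth so that every stage is testable.

## The model

Per channel and frame, the squared speckle contrast over the pixel
ensemble is corrected for instrumental variance (all in counts):

    K²_raw = σ²(I) / μ²(I)
    K²_adj = K²_raw − γ/μ − 1/(12 μ²) − σ²_dark/μ²        (γ = gain/CF ≈ 2.17)

and converted to hemodynamic indices

    BFI  = 1 / K²_adj                      (relative blood flow)
    nBFI = min–max normalized BFI ∈ [0,1]
    BVI  = log10(I₀ / μ(t))                (blood volume, Beer–Lambert)

The record is segmented around the occlusion window (a = pre, b =
during, c = post); per channel the pipeline reports ⟨nBFI⟩ and σ per
segment, the ratios b/a and c/a, group means ± across-subject SD (after
excluding subject-channels with frequency-domain SNR < 10 dB),
convergence distance of the occlusion curve to the control curve, and
beat-averaged cardiac waveform amplitudes for flow and volume.

The simulator draws pixel intensities from a gamma distribution with
shape 1/K²_true, where K²_true follows the integrated speckle visibility
function `K² = β (e^(−2x) − 1 + 2x)/(2x²)`, `x = T/τ_c`, with `1/τ_c`
proportional to a pulsatile two-layer composite flow, then adds Poisson
photodetection, read noise, quantization and 16-bit clipping — emulating
a 65 frame/s, 8 ms-exposure acquisition.  See the methods vignette
(`vignettes/speckleflow-methods.Rmd`) for every stated parameter.

## Worked example

Simulate a 3-subject occlusion cohort (24 s at 65 fps, occlusion 8–16 s),
calibrate from dark frames, process every stack and aggregate:

```r
library(speckleflow)

cfg   <- synth_config(n_subjects = 3, seed = 1, region_px = 32,
                      heart_rate_hz = c(0.95, 1.05, 1.2))
study <- run_synthetic_study(cfg)   # dark calibration + per-subject series
ana   <- analyze_study(study)       # segments, ratios, SNR, waveforms

study$calib
#> camera_calibration: gain 1, CF 0.46 e-/count, gamma 2.1739, offset 99.9999, dark var 4.08971
```

The dark-frame calibration recovers γ = 1/0.46 ≈ 2.17, the offset
(100 counts) and the read variance (4 counts² plus quantization).  The
group ratio curve shows the depth-graded occlusion dip — strong at short
S–D distances, nearly gone by 2.6 cm:

```r
g <- ana$group
data.frame(channel = g$channel, sd_cm = g$sd_distance_cm,
           ba = round(g$ratio_mean_ba_mean, 3),
           ba_sd = round(g$ratio_mean_ba_sd, 3),
           ca = round(g$ratio_mean_ca_mean, 3))
#>  channel sd_cm    ba ba_sd    ca
#>        1   0.6 0.187 0.003 1.000
#>        2   1.0 0.250 0.012 0.991
#>        3   1.3 0.362 0.022 0.986
#>        4   1.6 0.590 0.022 0.991
#>        5   2.0 0.829 0.024 0.980
#>        6   2.3 0.923 0.001 0.973
#>        7   2.6 0.956 0.036 0.992
```

`ba` is ⟨nBFI_b⟩/⟨nBFI_a⟩ (during/pre): channel 1 collapses to 0.19
because it is scalp-dominated and the normalized trace bottoms out during
the occlusion, while channel 7 stays near 1.  `ca` ≈ 1 everywhere — flow
recovers after release.  The closed-form generator oracle for the
unnormalized BFI ratios is available for comparison:

```r
expected_segment_ratios(cfg, metric = "bfi")$ratio_mean_ba
#> 0.483 0.595 0.737 0.869 0.958 0.982 0.990

unique(round(spectral_summary(study)$heart_rate_hz, 3))
#> 0.958 1.042 1.208     # configured: 0.95, 1.05, 1.20 (FFT bin = 0.042 Hz)
```

`run_pipeline(cfg, "out/")` executes the same flow end to end — including
a matched control cohort, the occlusion-vs-control convergence distance,
and CBF/CBV waveform amplitude-ratio curves — and writes tidy CSV tables
plus a manifest (config hash, seed, exclusion counts) to `out/`.  A CLI
wrapper with `simulate / calibrate / process / analyze / report`
subcommands lives in `inst/cli/speckleflow`.

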