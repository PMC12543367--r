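---
title: "Methods: speckle contrast analysis and the synthetic two-layer cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: speckle contrast analysis and the synthetic two-layer cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The measurement model

Speckle contrast optical spectroscopy (SCOS) infers relative blood flow
from the blurring of a time-integrated laser speckle pattern.  A camera
with exposure $T$ images a speckle field whose decorrelation time
$\tau_c$ shortens as scatterers (red blood cells) move faster.  Over a
pixel ensemble the squared speckle contrast is

$$K^2_\mathrm{raw}(t) \;=\; \frac{\sigma^2(I(t))}{\mu^2(I(t))},$$

with $\sigma^2$ the unbiased spatial variance of the raw counts and $\mu$
the ensemble mean *after dark-offset subtraction* (an offset shifts the
mean but not the variance, and the shot-noise correction below needs
$\mu$ in signal counts).  Measured contrast carries instrumental variance
on top of the speckle physics, removed term by term, all in
analog-to-digital units:

$$K^2_\mathrm{adj} = K^2_\mathrm{raw}
  - \underbrace{\gamma/\mu}_{\text{shot}}
  - \underbrace{1/(12\mu^2)}_{\text{quantization}}
  - \underbrace{\sigma^2_\mathrm{dark}/\mu^2}_{\text{read/dark}},$$

where $\gamma = \mathrm{gain}/CF$ converts Poisson electron variance to
count units ($CF = 0.46\,e^-/\mathrm{count}$ and gain 1 give
$\gamma \approx 2.17$) and $\sigma^2_\mathrm{dark}$ is measured from dark
frames rather than taken from the data sheet.  Quantization is disabled
by default: at 16-bit depth it is orders of magnitude below the other
terms.  Adjusted values at or below `floor_epsilon` ($10^{-6}$) are
flagged invalid — this happens when the photon count approaches the
camera noise floor — and downstream statistics skip invalid frames
rather than propagate garbage.

The blood flow index is $\mathrm{BFI} = 1/K^2_\mathrm{adj}$ (relative
units; absolute flow quantification is explicitly out of scope), min–max
normalized over the full record to $\mathrm{nBFI} \in [0,1]$.  Blood
volume is tracked through absorption: with $I_0$ the mean channel
intensity over a baseline window (default the first 7 s),
$\mathrm{BVI}(t) = \log_{10}(I_0 / \mu(t))$.  A linearized form
$c\,(I_0-\mu)/I_0$ is provided; the first-order Taylor coefficient of the
log form is $1/\ln 10 \approx 0.434$, which is the default, while the
coefficient 2 that also circulates in the literature can be requested
explicitly (`coefficient = 2`).  We deliberately do not adjudicate
between the two.

# The synthetic two-layer world

No public recordings exist for this kind of seven-channel occlusion
protocol, so the package states a synthetic world precise enough that
every pipeline stage has a closed-form oracle.

**Layers and mixing.**  A scalp flow and a brain flow share the subject's
cardiac waveform.  During the occlusion window (default 8–16 s of a 24 s
record; the 8–17 s variant used in part of the original protocol is one
config edit away) the scalp flow is multiplied by `scalp_suppression`
(default 0.35) with 0.5 s raised-cosine ramps — a manual arterial press
is not instantaneous, and hard edges would ring through the segment
statistics.  The brain trace is untouched: the superficial temporal
artery supplies scalp, not brain.  Channel $i$ sees the linear mixture
$w_i\,\mathrm{scalp} + (1-w_i)\,\mathrm{brain}$ with
$w_i = 1/(1+e^{(d_i-1.25)/0.28})$ on the source–detector grid
$d = 0.6 \ldots 2.6$ cm — a logistic stand-in for the photon-transport
"banana" that we do not simulate (sensitivities are parameters, not
derived quantities).

**Flow to contrast.**  The decorrelation rate is proportional to the
composite flow, scaled so $\tau_c = 1$ ms at baseline — comfortably
inside the 1–10 ms regime where an 8 ms exposure integrates many
decorrelation events.  The forward visibility function is
$K^2 = \beta\,(e^{-2x}-1+2x)/(2x^2)$, $x = T/\tau_c$, with coherence
factor $\beta = 0.2$ reflecting the dense speckle sampling of the
emulated system ($s/p = 0.3$, about 0.1 speckle per pixel).

**Speckle and camera noise.**  Pixels are drawn independently from a
gamma distribution with shape $1/K^2$ — the spatial speckle correlation
is folded into $\beta$ rather than simulated as a correlated field, which
reproduces the first two ensemble moments exactly, and the pipeline uses
nothing else.  Photodetection adds Poisson noise (the stage the
$\gamma/\mu$ term corrects; it can be disabled to test the gamma ensemble
in isolation), then Gaussian read noise (2 counts), a dark offset
(100 counts), rounding, and clipping to the 16-bit range.  Mean counts
decay exponentially with distance (decay length 0.55 cm, channel 1 at
3000 counts), placing channel 7 near — but above — the noise floor, so
the invalid-frame machinery gets exercised.

**Volume.**  Blood volume pulses with a smaller amplitude (0.08 vs 0.3
for flow) and is suppressed less by the occlusion (factor 0.6 vs 0.35):
vessels drain incompletely.  Detected intensity follows
$\mu(t) = \mu_0\,10^{-\mathrm{BVI}_\mathrm{true}(t)}$ with
$\mathrm{BVI}_\mathrm{true} = 0.15\,(v(t)-1)$.  Volume mixing weights are
derived from the flow weights by shrinking the brain:scalp odds by
$2.5/6$ — grey matter carries roughly six times the scalp's blood *flow*
but only two to three times its haemoglobin content — which is what makes
the flow signal converge to brain-dominated behaviour at a shorter
source–detector distance than the volume signal, the qualitative ordering
reported for human cohorts.

**Cardiac waveform.**  Two wrapped Gaussians per period (systolic peak at
phase 0.18, width 0.12; dicrotic bump at 0.55, width 0.12, relative
amplitude 0.25), shifted to zero mean and scaled to unit peak-to-trough
span, so `pulsatility` *is* the fractional span.  The widths matter: a
narrower systolic peak pushes power into the second harmonic, and the
plain FFT peak picker the pipeline uses (maximum in 0.7–3 Hz, ties to the
lower frequency) would lock onto $2f_0$ for non-integer cycle counts.
The defaults keep the fundamental 3–4× stronger in power, as in
physiological pulses.  Heart rates default to an even spread over
0.9–1.25 Hz across subjects.

**Reproducibility.**  One integer seed per cohort; subject $i$ draws from
a stream seeded by `(seed + 7919 i) mod (2^31 - 1)`.  Identical
`(config, seed)` gives bit-identical stacks.

# Segmentation, ratios and the oracle

The record splits into pre (a), during (b) and post (c) half-open
segments at the occlusion boundaries; a sample at exactly 8 s belongs to
segment b.  Per channel the pipeline reports
$\langle \mathrm{nBFI}_s\rangle$ and $\sigma_s$ and the ratios b/a and
c/a, aggregated across subjects as mean ± across-subject (unbiased)
standard deviation, after dropping subject–channels whose
frequency-domain SNR falls below 10 dB.

`expected_segment_ratios()` is the independent oracle: it integrates the
generator's composite-flow formula directly (no frames, no noise).  Three
metrics are offered because they answer different questions:

* `"flow"` — the composite itself; in the ramp-free limit the during/pre
  ratio is exactly $1 - w(1-s)$.
* `"bfi"` — the flow mapped through the exact visibility function to
  $1/K^2_\mathrm{true}$.  BFI is *affine*, not proportional, to flow at
  finite $T/\tau_c$ (at $x = 8$, $\beta\,\mathrm{BFI} \approx x + 0.5$),
  so BFI ratios differ from flow ratios by up to ~0.03 at strongly
  suppressed channels.  This is the metric used when checking pipeline
  output against the oracle, since it is what the pipeline estimates.
* `"nbfi"` — additionally min–max normalized, matching the reported
  group curves.  Not used for oracle comparisons: the normalization
  anchors to the trace extremes, which finite-pixel contrast noise
  inflates, making the comparison needlessly fragile.

Convergence of an occlusion ratio curve to the control curve is declared
at the smallest source–detector distance where the absolute difference is
within tolerance (default 0.05) *and stays within tolerance at all larger
distances*.

# Waveform analytics

Heart rate comes from the periodogram peak in 0.7–3.0 Hz (covering
resting adult rates with margin).  The frequency-domain SNR — the
usability criterion with its 10 dB threshold — is spec'd here because the
original supplementary definition was not available: total power within
±0.2 Hz of the cardiac peak over the noise floor, estimated as the median
periodogram level in 3–10 Hz divided by $\ln 2$ (the median of an
exponential distribution is $\ln 2$ times its mean, so white noise scores
0 dB) and scaled to the signal bandwidth.

Beats are detected once per record on a zero-phase FFT band-pass
($[0.5, 3] \times$ HR): local maxima separated by at least $0.6/\mathrm{HR}$,
each preceded by a local-minimum onset.  A first peak closer than one
period to the record start is dropped — its onset is unobservable, and
keeping the phase-misaligned partial beat was measured to bias
pre-occlusion amplitudes low by ~5%.  Each beat between consecutive
onsets (duration-gated to 0.5–1.5 periods) is resampled to a 100-bin
phase grid and averaged per segment; the average is harmonic-limited to
10 harmonics — physiological pulses carry little power beyond that —
and the amplitude $I$ is its peak-to-trough span.  Amplitudes are
computed on normalized traces, so the b/a and c/a amplitude ratios are
dimensionless and offset-invariant.

# What a green test does and does not establish

The generator reproduces: per-channel ensemble statistics of integrated
speckle with realistic shot/read/quantization noise; depth-graded
scalp/brain mixing; pulsatile flow and volume with an occlusion
perturbation; intensity decay with distance down to the noise floor.  It
does **not** reproduce: spatially correlated speckle, motion artifacts,
fiber-bundle optics, photon-transport sensitivity profiles,
post-occlusion hyperaemic overshoot (available but off by default so the
post/pre oracle stays exactly 1), or inter-subject anatomical
variability.  Green tests therefore establish correctness of the
*analysis* under the stated model, not physiological fidelity; in
particular the default `scalp_suppression = 0.35` is a modelling choice,
not an estimate of what a manual occlusion achieves.

# Numerical and scale choices

* **Finite-pixel noise floor.**  A per-frame contrast estimate over $N$
  pixels has relative sampling error $\approx \sqrt{2/N}$ even with all
  camera noise off.  The emulated instrument images $\sim 10^5$ pixels
  per channel (5.5 Mpx sensor, 7 fibers), where this floor is below 1%;
  simulating that for 40 subject-records would need ~$10^9$ gamma draws
  per cohort, so the package default is a 48×48 px region (floor ≈ 3%)
  and cohort-scale acceptance runs use 32×32 (≈ 4.4%).  Segment-mean
  ratios average ~520 frames and are insensitive to this (measured
  oracle error < 0.005 against a 0.02 tolerance), but beat-amplitude
  estimates are not: per-subject amplitude-ratio scatter at desk scale is
  0.06–0.15, so a 20-subject group mean moves 3–5% by sampling alone.
  The segment-logic amplitude check (ratios = 1 ± 2% on control) is
  therefore run on the generator's exact traces (`truth_series()`),
  which is the high-SNR limit the criterion describes; the full-noise
  numbers are still reported, unasserted, by the acceptance script.
* **Variance convention.**  Unbiased ($N-1$) sample variance everywhere:
  ensembles are finite samples and the tests need one fixed convention.
* **One contrast value per channel-frame**, over the whole rectangular
  region; no sub-windowing.
* **Dark calibration** is global by default (pooled over all dark
  pixels); per-channel dark variance is accepted wherever a calibration
  is consumed.
* **BVI per channel.**  When a layout is supplied, the volume index uses
  the channel-region mean, not the full-sensor mean: per-channel volume
  curves are the object of interest, and the channels sit at different
  intensities.
* **Degenerate inputs.**  Non-positive offset-subtracted means flag the
  frame invalid (no exception); a constant trace cannot be normalized
  (error); an empty segment is an error naming the segment; a tie in the
  heart-rate search resolves to the lower frequency.

# Known limitations

Beat onsets from band-passed minima are adequate for the stated world but
would need refinement for arrhythmic or low-SNR human data; the SNR
definition stands in for an unavailable original; channel sensitivities
are parameters, so the synthetic convergence distances (2.0 cm for flow
vs 2.3 cm for volume amplitude with the defaults) reproduce the *ordering*
reported for humans, not the printed distances; and ratios computed on
normalized traces compress strongly suppressed channels toward zero, so
cross-study comparisons should fix the normalization convention first.
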