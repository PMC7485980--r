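---
title: "Methods: calcium-transient analysis of fly visual interneurons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calcium-transient analysis of fly visual interneurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flytrace)
```

## What the pipeline measures

`flytrace` analyses two-photon GCaMP recordings of *Drosophila* lamina
monopolar terminals (L1/L2 in medulla layer M2) under two designs:

* **Bath mode.** A drug (e.g. 100 µM serotonin) or saline is perfused
  onto the exposed optic lobe while fluorescence is recorded at 10–20
  frames/s. The quantity of interest is the slow change in *basal*
  intracellular calcium, expressed as ΔF/F = (F~t~ − F~0~)/F~0~ with F~0~
  the mean fluorescence over the first 60 s (before the perfusion
  change reaches the tissue — the line dead time is ~105 s on the
  gravity rig and ~45 s on the valve rig).

* **Visual mode.** Full-field 100-ms light or dark flashes are shown
  every 5 s on an LED arena, recorded at 25–30 frames/s. Each 60-s
  epoch contains 12 flashes, 6 of each polarity in shuffled order; six
  epochs make an experiment, with the perfusion switched after epoch 1.
  Here F~0~ is the mean over 30 s of non-consecutive inter-stimulus
  baseline during epoch 1, and the objects of interest are the
  stimulus-locked transients: dark flashes drive a fast calcium rise
  that decays within about a second; light flashes drive a transient
  dip followed by a secondary rise.

## ROI discovery

Segmentation follows a threshold → cluster → split chain:

1. **Global median threshold.** The median over *every* pixel of every
   frame separates dim background from tissue; pixels whose temporal
   mean is below it are discarded. Ties are kept (retain at `>=`),
   which only matters for synthetic movies with exactly repeated
   values.
2. **k-means activity clustering** (k = 3, 10 restarts, seeded) on the
   z-scored per-pixel time series. z-scoring makes the feature
   brightness-invariant so that "similar activity" means similar
   *dynamics*, not similar intensity; zero-variance pixels get an
   all-zero feature. The largest cluster is retained (ties go to the
   lowest cluster index). Distinct feature rows are clustered once and
   members mapped back, which makes the result invariant to pixel
   order; if fewer distinct rows than k exist the cluster count
   degrades gracefully.
3. **Watershed split** (visual mode only). The surface is the
   Gaussian-smoothed (σ = 1 px) temporal-mean image restricted to the
   retained set; seeds are its local maxima with ≥ 3 px separation, and
   basins are grown by geodesic propagation. ROIs below `min_roi_px`
   (default 4 px — suppresses single-pixel noise) are dropped. In bath
   mode the whole retained set is one pooled ROI.

The registration step that precedes segmentation is phase correlation
against the temporal-mean image with parabolic sub-pixel refinement,
applied by bilinear interpolation; out-of-frame pixels are filled with
the frame median so the global-median threshold is not biased. The
spectral whitening is regularised (ε = 1% of the peak cross-power)
because smooth, low-noise microscopy images carry no shift information
at high spatial frequencies. Registration runs before the threshold is
computed (declared order; both orders are available by calling the
stages directly). Out-of-plane motion cannot be corrected in a single
plane; the pipeline reports an RMS motion score per recording and never
discards anything automatically.

## Filtering

All filters are second-order IIR notches designed from a center
frequency and a −3 dB bandwidth (unit DC gain, zeros exactly on the
unit circle), applied forward–backward so the net phase is zero and
kinetic timings are not shifted. Edge effects are handled by odd
reflection padding of three filter lengths (length ≡ fs/bandwidth
samples), and the DC component is routed around the filter state so
constant traces pass through exactly.

* **Brain-motion notch**: 0.04 Hz, bandwidth 0.005 Hz. Roughly half of
  bath recordings show this slow multiplicative oscillation; filtering
  is always an explicit per-recording choice, supported by an advisory
  detector (smoothed periodogram peak at 0.04 ± 0.01 Hz exceeding 5×
  the median density) that flags but never filters.
* **Stimulus bands**: the flash responses occupy 0.19–0.21 Hz and
  0.38–0.42 Hz; these are realised as two cascaded notches centered at
  0.20 Hz (bw 0.02) and 0.40 Hz (bw 0.04), i.e. band edges map to
  center ± bw/2. The cascade is used only for the basal-calcium
  readout in visual experiments. A train of ~1-s transients repeated
  every 5 s also has harmonics above 0.4 Hz which these two bands do
  not touch; the recovered basal trace therefore retains some fast
  ripple, while its slow component — the object of interest — is
  unbiased. The tests assert exactly that: ≥ 20 dB removal inside the
  stated bands, unbiased drift recovery, and no attenuation at DC or at
  5× the center frequencies.

Because ΔF/F is affine in F~t~ and the notches have unit DC gain,
filtering before or after the ΔF/F conversion commutes exactly for a
fixed F~0~ (asserted numerically); the pipeline filters the raw trace.

## Baselines and epoch averaging

The 30-s visual baseline is assembled from the gap before each of the
12 epoch-1 flashes: the 2.5-s segment ending 0.5 s before the onset.
Late-gap samples avoid the previous flash's transient; the first onset
of each epoch is placed 3 s into the epoch so all segments and all
pre-stimulus windows fit inside epoch 1. Only the total — 30 s,
non-consecutive, between stimulus presentations — is fixed by the
protocol; which sub-segments to use is the package's concrete choice.

Epoch responses are built per flash from windows spanning −0.5 s to
+4.9 s around the onset, linearly interpolated onto a common time base
at the recording's native frame rate (rates vary between 25 and 30
frames/s across flies), each shifted by its own mean over the 0.5 s
preceding the onset, then averaged. A flash whose window runs past the
end of the trace is dropped with a logged warning. Metrics are measured
on the averaged epoch response (average-then-measure), not averaged
per-flash metrics.

## Transient metrics

With the response aligned to 0 before the flash:

* **Peak size** (dark) — maximum over (0, 2] s. **Trough size**
  (light) — magnitude of the minimum over the same window. 2 s bounds
  the primary response because transients return to basal levels within
  about a second; the window is a parameter.
* **Decay / rise time** — the post-stimulus peak-to-peak span (max −
  min over (0, 4.9] s) defines the 90% and 10% levels; crossing times
  are found by linear interpolation searching forward from the primary
  extremum, and the metric is the 90→10 (dark) or 10→90 (light) span.
* **Exponential constant** — ΔF/F(t) = c·e^kt^ fitted by least squares
  on the log of the values between the two crossings, offset by the
  post-stimulus minimum (decays) or subtracted from the maximum
  (rises) with a floor of 1% of the peak-to-peak span to keep the log
  defined. k < 0 for decays, k > 0 for rises by convention. The
  log-linear estimator is validated against nonlinear least squares in
  the tests; for pure exponentials |k| = ln 9 / (90–10 span) to within
  1%.
* **Secondary response** — the magnitude of the reversal beyond
  baseline after the primary extremum (undershoot after the dark peak,
  overshoot after the light trough), searched to the end of the window;
  a monophasic response scores a valid 0.
* **Epoch-1 normalisation** — every metric is reported as
  epoch~n~ − epoch~1~, so epoch 1 is exactly 0; an invalid epoch-1
  value invalidates the whole series rather than silently producing
  zeros.

## Statistics

Group comparisons use the tests the designs call for: a two-tailed
Wilcoxon rank-sum for two-group bath comparisons (exact by full
enumeration when the combined n ≤ 12 with no ties — at most 924
assignments — otherwise the normal approximation with tie and
continuity corrections), and a two-way repeated-measures ANOVA
(between: group, within: epoch) for the per-epoch metric deltas, with
Šidák-adjusted per-epoch pairwise tests, 1 − (1 − p)^m^. Sphericity
handling in the original Prism analyses is unreported, so the primary
p-values use the classical uncorrected decomposition and a
Greenhouse–Geisser-corrected p is emitted alongside as an auxiliary
column.

## The synthetic generator

Every stage is tested against simulated data whose ground truth is
exported, so oracles are exact. The generator's defaults are the study
conditions: 6 epochs × 60 s with 12 shuffled flashes each; 15 frames/s
(bath) and 27 frames/s (visual), inside the stated acquisition ranges;
dark kernels peaking at 0.8 ΔF/F with a 2.2 s⁻¹ decay (90–10 span
≈ 1 s) and a 20% undershoot; light kernels dipping to 0.25 ΔF/F with a
1.8 s⁻¹ recovery and a 60% overshoot; a serotonin basal ramp beginning
at the perfusion arrival (105/45 s) and rising to a 1.73 ΔF/F plateau
(the scale reported for serotonin-driven basal rises in L2 terminals)
over 180 s, saline flat; a 0.04 Hz
multiplicative motion oscillation and integer rigid jitter when
enabled; Gaussian noise with σ ∝ √intensity as a photon-noise
surrogate, parameterised by an SNR dial (peak transient amplitude over
noise σ at a terminal center; ∞ disables noise).

Kernels are closed-form and piecewise smooth: a raised-cosine limb to
the extremum joined to an *exactly* exponential decay/recovery limb,
plus a delayed alpha-function secondary lobe. The exact exponential
limb is deliberate — it makes 90–10 spans and fitted rate constants
analytic (ln 9 / rate) so kinetic code is tested against closed forms
rather than against itself. The join at the extremum has a kink; no
analysis step differentiates the kernel, so nothing depends on
smoothness there.

Terminals are super-Gaussian spots, exp(−(r²/2σ²)²) with σ = 3.5 px on
a 48 × 48 field: a fairly uniform bright interior with a soft edge and
a single intensity maximum, like a filled terminal in cross-section.
This matters for fidelity of the segmentation test: with a plain
Gaussian profile the pixel SNR forms a continuum and k-means splits
terminals into concentric shells, which real, more plateau-like
terminals do not show. The default 6-terminal ring has inter-center
spacing of about 4σ.

What the generator does **not** emulate: neuropil contamination,
bleaching, indicator nonlinearity and saturation, non-rigid warping,
and out-of-plane motion. Passing tests therefore demonstrate
correctness of the algorithms under the declared signal model, not
robustness to every artefact of real recordings.

## Numerical and design notes

* The end-to-end zero-noise identity (pipeline ΔF/F ≡ programmed ΔF/F
  to < 10⁻³) is run at zero additive background: background
  fluorescence inside an ROI scales extracted ΔF/F by S/(S+B), so exact
  identity is only defined at B = 0. With the default dim background
  the dilution is a few percent, visible in the movie-backed pipeline
  test.
* Problem sizes in tests and the acceptance script are chosen for
  desk-scale runs: 48 × 48 px movies, 60-s single-epoch movies for
  segmentation sweeps (50 seeded runs), 8 flies per group for the bath
  simulation, 1000 replicates for the rank-sum calibration.
* All randomness flows through explicit integer seeds; the RNG state of
  the caller is never touched. Identical seeds give bit-identical
  movies, protocols and result tables.
* Manual steps of the original workflow (ROI curation by layer
  position, discarding recordings with out-of-plane motion) are
  represented by explicit configuration — an ROI include/exclude choice
  and the advisory motion score — never by silent automation.
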