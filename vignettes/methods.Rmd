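---
title: "Models and methods behind cthair"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cthair}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cthair)
```

cthair quantifies how C-tactile (CT) afferents — unmyelinated,
slowly conducting (< 2 m/s) low-threshold mechanoreceptors of human hairy
skin — respond to deflection and removal of individual hairs, and how
small the accompanying skin deformation is. It implements four
quantification stacks (spike trains, OCT M-mode micro-displacement, dense
optical flow, instrument tip tracking) together with synthetic-data
generators that emulate the corresponding acquisitions with known ground
truth. This vignette records the models, the tunable parameters and the
design decisions, so that what the tests do and do not demonstrate is
explicit.

## Spike trains and unit classification

**Generative model.** A simulated afferent fires as a gamma renewal
process during each stimulus epoch and is silent otherwise. Inter-spike
intervals (ISIs) are Gamma with shape $k = 4$: regular enough that the
mean of reciprocal ISIs is finite and controlled (a Poisson process was
excluded because the mean reciprocal ISI diverges). Since
$E[1/\mathrm{ISI}] = r\,k/(k-1)$ at renewal rate $r$, the generator uses
$r = \frac{k-1}{k}\, m$ to hit a target mean instantaneous frequency
(IF) $m$. Per-unit targets are drawn from population presets calibrated
to the recorded populations: brushing $21 \pm 6$ spikes/s, single-hair
deflection $12 \pm 5$ spikes/s, with a floor at 2 spikes/s (draws below
it are resampled). Each spike inserts a 3 ms biphasic waveform whose
leading phase dominates; polarity encodes fibre class (downward-leading
for C, upward for A-beta). Additive Gaussian noise gives a per-sample
SNR of 8 at the defaults (40 uV peak, 5 uV noise).

**After-discharge.** Hair plucking is followed, in CT units only, by
continued firing whose duration is drawn from Normal(7.1 s, 3.2 s) with
non-positive draws resampled. Firing decays linearly from 12 to
3 spikes/s over the drawn duration (time-rescaled renewal process), and
the discharge is modelled as ending with its final action potential at
the drawn duration — which makes the drawn duration directly comparable
with the detector's last-spike definition. The final rate of 3 spikes/s
keeps spontaneous within-discharge gaps far below the detector's 2 s gap
rule.

**Detection and metrics.** Spike detection is threshold crossing of
either polarity (default five robust noise SDs), a 2 ms refractory
merge, and template matching by normalized cross-correlation (default
acceptance 0.8). The template is the mean candidate waveform inside
brush epochs; when a trace has no brush epoch the pipelines reuse the
unit's template from its brush characterisation trace, mirroring the
convention of confirming spike morphology against brushing trials — a
single noisy candidate waveform is otherwise too unreliable a template
at SNR 8. Mean IF is the arithmetic mean of reciprocal ISIs in the
window and peak IF their maximum; with fewer than two spikes both are
reported absent (the minimum-two-spikes rule). The alternative reading
of a mean frequency, $(n-1)/\mathrm{span}$, remains available as
`method = "span"`; by Jensen's inequality the reciprocal-ISI mean always
dominates it, and the two agree exactly on regular trains.

**Classification.** C fibres: downward spikes with conduction velocity
below 2 m/s, or a mechanical response delay of at least 100 ms; A-beta:
upward spikes above 30 m/s. CT units are C fibres with mechanical
threshold at or below 4 mN (the threshold phrase is read as $\le 4$ mN)
that respond to soft brushing; HFAs are rapidly adapting A-beta units
responding to hair deflection. The monofilament threshold follows the
50% criterion over the standard Semmes-Weinstein force set
(0.08–3000 mN; intermediate forces are rejected): the lowest force with
responses on at least half its trials, confirmed on re-test (two or more
positive trials; single-trial candidates are flagged low-confidence).
The simulated staircase first secures a suprathreshold response
(escalating if the starting force misses, as an experimenter would),
then descends until a force fails the criterion. True thresholds are
drawn from {0.4, 0.7, 1.6, 4} mN with weights 6:6:2:1, the composition
that reproduces the reported population mean of 0.92 mN over 15 units
within the discrete force set.

## OCT M-mode displacement

**Generator.** A trial is a depth-by-time intensity matrix (10 kHz
A-line rate over 3 s, 5.5 um depth sampling by default): dark air above
a bright skin band whose surface follows a condition-specific
trajectory — linear drift (idle, calibrated so the two consecutive
500 ms window means differ by the condition's true displacement), a step
at the 1.5 s contact with a 500 ms hold (monofilaments), or a bending
ramp reaching maximum at 1.2 s with a release back to rest at 1.5 s
(hair). The surface edge is rendered as a linear intensity ramp three
depth samples wide so that threshold crossing with linear interpolation
recovers the surface exactly (to machine precision) on noiseless
trials — this is what makes the deterministic recovery tests exact
rather than approximate. Per-trial true displacements are drawn from
Normal(condition mean, condition SD) where the means are the reported
group means (2.04, 8.14, 17.09, 25.28, 60.93, 79.18 um) and the SDs are
implied by their 95% confidence intervals; the draws are keyed by
(condition, location, replicate) only, so changing the top-level seed
changes the noise but never the ground truth. Artefacts (a beam-crossing
occlusion band, a 6 um 1.2 Hz heartbeat, 20 um/s motion drift) are
injected into 23% of trials.

**Estimation.** Surface segmentation takes, per A-line, the first depth
sample above background mean + 5 background SDs (fallback: the
background/peak midpoint on effectively noiseless data, which sits
mid-ramp), refined by linear interpolation and median-filtered over
1 ms. Events are located by the extremum of a two-sided 10 ms
window-mean derivative — a plain adjacent-sample derivative lets single
noisy A-lines outrank genuine steps of a few um — with the sign chosen
by event kind (contact deepens the surface; release restores it).
Displacement is the absolute difference of 200 ms window means before
and after the event, excluding a 20 ms guard gap around it (the guard is
a convention; it avoids transition contamination). The idle condition
uses two consecutive 500 ms windows at the start of the recording (the
placement within the 3 s recording is unspecified in the source design;
the start is the least stimulus-contaminated span). The hair condition
reuses the 200 ms windows around the release event (window lengths for
release are an assumption). Artefact screening works on the
pre-stimulus 0.8 s span: occlusion (> 5% invalid A-lines), heartbeat
(fitted 0.8–2 Hz sinusoid amplitude > 3 um; a direct projection on a
frequency grid, because FFT bins leak badly on sub-second spans), motion
(> 15 um/s fitted drift — above the steepest plausible idle drift but
below the injected motion artefact). After rejection the 10 largest
displacements per condition are kept (deterministic tie-break by
location then trial), then compared by one-way ANOVA with Tukey's HSD at
family-wise alpha 0.05 and per-condition t-based 95% CIs.

**What the synthetic protocol does not emulate.** Top-10 selection from
noisy per-trial truths inflates selected-group means above the
population means — an order-statistics effect the real study shares but
that makes selected synthetic means sit above the calibrated condition
means; the pipeline tests therefore compare each trial's estimate with
its own ground truth. More importantly, with groups drawn at the
reported means and CI-implied SDs ($n = 10$), the exact significance
pattern (every pair separated except idle vs hair deflection)
replicates in only about a third of seeds: the pattern's binding pair,
0.4 vs 0.7 mN, sits almost exactly at the Tukey critical value
(observed studentized range ≈ 4.22 vs critical ≈ 4.18 at these group
statistics), and the idle–hair gap that must stay non-significant is
close to the gap that must be significant. No within-group spread in
(4.6, 6.2) um pooled changes this materially. The corresponding
acceptance property is left failing deliberately rather than weakening
the calibration or the pattern definition.

## Dense optical flow

The two-frame estimator is the polynomial-expansion method: each frame
is approximated per pixel by a local quadratic
$f(\mathbf{x}) \approx \mathbf{x}^\top A \mathbf{x} + \mathbf{b}^\top
\mathbf{x} + c$ under a Gaussian applicability (neighbourhood 5 px,
sigma 1.5), and the displacement satisfying
$A\,\mathbf{d} = -\tfrac12(\mathbf{b}_2 - \mathbf{b}_1)$ is solved per
pixel after averaging the normal equations over a 7 px window, within a
coarse-to-fine pyramid (scale 0.6, four levels, up to eight iterations
per level with bilinear warping of the second frame). Expansion uses
separable correlations with replicate borders; pyramid construction
Gaussian-smooths before resampling; pixels within one neighbourhood of
the border are flagged low-confidence. The returned flow is the motion
of content from the first to the second frame in px/frame. Cumulative
fields sum increments at fixed pixel locations (Eulerian); this matches
the cumulative-field definition used for visualisation but does not
follow material points, so a uniform dark object under-reports its own
interior motion (aperture effect) while textured regions accumulate
their full displacement — the quantitative accumulation test therefore
uses a textured moving patch. Cross-validation uses scikit-image's
iterative Lucas–Kanade dense flow (via the installed Python) as an
independent implementation on pure translations, where both estimators
target the same ground-truth field; no independent polynomial-expansion
reference exists in the environment.

## Tip tracking

Frames are thresholded by between-class variance maximisation (the
high-contrast dark-instrument-on-light-skin regime makes a learned
segmentation front end unnecessary here; an externally supplied mask can
be substituted), the largest component is kept, refined by optional
opening and a radius-1 closing (opening is off by default because it
erodes a sharp apex by several pixels; the open–close filter is
idempotent), and the outer boundary is traced and simplified by
maximum-deviation reduction (tolerance 1 px). The tip is the vertex of
maximal discrete curvature — turning angle over a ±3-vertex span,
normalised by the longer arm so that a vertex straddling a corner cannot
outrank the corner — restricted to a 30 px radius around the previous
tip (≈ 0.65 mm at 465 px/cm; the first frame is unconstrained, and a
lost track re-seeds unconstrained with a flag). The vertex is then
refined to sub-pixel precision by intersecting straight lines fitted to
the two contour flanks, each offset half a pixel outward to undo the
boundary-pixel-centre bias; without this the apex of a thresholded
narrow wedge is systematically eroded by 1–2 px. Raw speed is the
per-frame Euclidean step scaled by fps/calibration; smoothing is a
Gaussian of sigma 5 frames (sigma is taken to be in frames) with
reflective ends, which preserves the series mean to well under 2%.

The synthetic videos render an anti-aliased dark wedge (default apex
angle 40 degrees) over a lightly textured background at 60 fps and
465 px/cm, moving at 0.8 cm/s (6.2 px/frame) by default. They emulate
contrast and motion, not specular reflections, shadows, defocus or hair
occlusion of the tip; passing tests show the geometric pipeline is
accurate under the stated contrast regime, not that segmentation is
robust to real-world imaging artefacts.

## Problem sizes, randomness and reproducibility

All randomness flows from one integer seed through a documented
multiplicative split (`child_seed()`), so every generator is
bit-reproducible and independent streams never collide. The test suite
runs reduced problem sizes chosen to keep each check statistically
decisive: OCT protocol tests use a 2 kHz A-line rate and 2x2 grids
(window geometry unchanged — the estimators' exactness does not depend
on the rate), flow tests use 64–96 px frames, population-recovery
checks use 60 units x 4 trials (brush/deflection IF), 500 pluck trials
and 400 staircase units — the same sizes the acceptance script uses.
The full-rate default protocol (270 trials at 10 kHz) is processed
streaming by `run_oct_pipeline()` so memory stays modest.
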