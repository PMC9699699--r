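---
title: "Methods: chronic calcium-imaging quantification with catrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chronic calcium-imaging quantification with catrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catrace)
```

## What this package quantifies

Chronic imaging of cultured cortical neurons expressing a genetically
encoded calcium indicator produces, per field of view, a matrix of raw
fluorescence traces (cells x time) and fluorescence images of the same
neurons. From these, the analysis derives the quantities that
characterise network maturation and indicator toxicity:

* spontaneous event frequency (mHz), amplitude (dF/F0), and waveform
  metrics (FWHM, 50% rise/decay times) per cell;
* network synchrony per view (mean pairwise Spearman rank correlation);
* the frequency content of the oscillations (one-sided FFT amplitude,
  integrated over ultra-slow < 10 mHz, slow 10-100 mHz and fast
  100-300 mHz bands);
* morphometry: nuclear/cytosolic intensity ratio with a 0.8
  nuclear-filling cutoff, soma area, skeleton-based total neurite length,
  Sholl profiles, and an image-contrast index;
* longitudinal statistics: per-stage (DIV) profiles, growth rates as
  first derivatives, profile-level correlations, and two-tailed t /
  one-way ANOVA + Bonferroni group comparisons.

Because chronic culture experiments are not desk-reproducible, the package
ships a synthetic-data generator whose per-stage presets encode the
published summary statistics; every pipeline stage is validated by
recovering known ground truth from that generator.

## Signal model and extraction

A raw trace is modelled as
$F(t) = F_{bg} + F_{base}\,(1 + \textstyle\sum_i g_i(t)) + \epsilon(t)$,
where each spontaneous event contributes a unit-peak kernel

$$g(t) \;=\; A \cdot \frac{(1 - e^{-t/\tau_r})\, e^{-\max(0,\,t-p)/\tau_d}}{\max_s (1 - e^{-s/\tau_r})\, e^{-\max(0,\,s-p)/\tau_d}}$$

with rise constant $\tau_r$, decay constant $\tau_d$ and an optional
plateau $p$ (zero for healthy transients). The kernel is normalised to
unit peak so the amplitude parameter *is* the peak dF/F0 an isolated
event reaches — without the normalisation the same parameter would reach
only ~50% of its nominal value for typical $\tau_r/\tau_d$, making truth
amplitudes incomparable to measured ones.

Extraction follows the standard sequence: subtract a per-view scalar
background; find F0 as the mean of the contiguous 5-sample window with
the minimal mean ("five data points at rest" — the searched window is a
deterministic, transient-avoiding reading of "at rest"; the first-5
convention is available as an option); convert to
$\Delta F/F_0 = ((F - F_{bg}) - F_0)/F_0$. For in-vivo-style ROI traces,
`neuropil_correct()` applies
$F_{cell}(t) = F_{meas}(t) - r\,F_{neuropil}(t)$ with the conventional
$r = 0.7$. Because dF/F0 is an affine transform of F, event detection
(thresholds are medians plus SD multiples) is exactly invariant to errors
in the F0 scale; F0 bias only rescales reported amplitudes.

## Event detection: the 3-SD rule made operational

The published rule — peaks exceeding three standard deviations — leaves
open what "SD" is measured on and how peaks are delimited. The detector
uses, per trace:

1. **Noise SD**: the scaled median absolute deviation of the first
   difference divided by $\sqrt2$. This estimates the white-noise SD
   robustly even when events occupy a sizeable fraction of samples
   (events inflate a plain SD; `sd_mode = "raw"` provides that reading
   too). Threshold: `median + k * SD`, `k = 3`.
2. **Candidates**: strict local maxima of the raw trace above threshold,
   *corroborated* on a 3-sample boxcar-smoothed copy (whose noise SD is
   $SD/\sqrt{w}$). The literal per-sample rule admits ~4 single-sample
   noise spikes per 3000 samples at 3 SD; the corroboration removes
   nearly all of them while costing no temporal resolution, because
   candidates are still raw-trace maxima.
3. **Separation at half maximum**: two candidates are distinct events
   only if the trace dips below half of the smaller peak height (above
   baseline) between them; otherwise they merge into the higher peak.
   This is the same semantics as the FWHM: events whose half-maximum
   regions are not separated are one event. It is what keeps a
   12-second plateaued toxic transient from being split into dozens of
   noise wiggles.
4. **Prominence**: each event must rise at least `k * SD` above the
   deeper of the valleys separating it from its neighbours, suppressing
   threshold-level bumps riding on slow decay tails.
5. **Minimum separation** (default `2/fs`): closer peaks keep the higher.

All five parts are deterministic and configurable, and the test suite
pins the composite behaviour to an exhaustive brute-force scan
implemented independently of the package code.

**Known bias.** At the study sampling rate (5 Hz) and the first-week
event rate (150 mHz), ~6% of Poisson event pairs arrive closer than the
two-sample local-maximum resolution and merge; together with the
half-maximum separation rule the detector recovers roughly 90-95% of
events at 150 mHz (and essentially all events at 20 mHz). This is a
resolution limit of peak counting on sampled data, not a tunable; the
recovery tests therefore compare view means within three standard errors,
with the SE computed for the shared/private Poisson design (below).

Waveform metrics interpolate the two half-maximum crossings linearly
between samples; overlapping events are split at the inter-event minimum,
and a transient riding on a neighbour's tail is measured against its own
pedestal (the larger flanking minimum). A flank is only used when a
neighbouring event exists on that side — at trace edges the baseline
median is the reference, and events whose crossings run off the trace
keep `NA` metrics.

## Synchrony and spectra

Synchrony per view is the mean over all unordered pairs of the Spearman
rank correlation (average ranks for ties); constant traces have no
defined rank correlation and are excluded with a warning. Note that rank
correlations of *sparse* event traces are diluted by baseline noise:
with ~3% of samples inside events, even a perfectly shared event train
yields view synchrony of order 0.1. Absolute values therefore depend
strongly on event density and noise; the monotone increase across
maturation (and in the generator's shared fraction) is the meaningful
readout, and with zero noise and identical event trains the measure is
exactly 1.

The amplitude spectrum removes the mean, applies the DFT, and reports
$2\sqrt{\mathrm{Re}^2 + \mathrm{Im}^2}/n$ per bin on the one-sided grid
$k\,f_s/n$ (DC and, for even $n$, the Nyquist bin are not doubled) — no
detrending beyond mean removal and no taper, keeping the printed formula
literal. Band fractions integrate the amplitude by trapezoid over
[0,10), [10,100) and [100,300] mHz and report shares of the three-band
total; energy above 300 mHz is reported separately. Per-view spectra are
computed per cell and averaged (a view-mean-trace mode is available).

A caveat the tests encode: a *Poisson* event train low-pass filtered by a
second-scale kernel is spectrally broad, so the 200-mHz-wide fast band
retains a large share of the three-band total at every stage; the
recoverable maturation signature is the growth of the slow-band share as
events slow and widen, not outright slow-band dominance (which in real
recordings reflects the quasi-periodicity of network oscillations — a
feature the generator deliberately does not model).

## Morphometry

The N/C ratio is the nuclear over cytosolic mask-mean intensity; strictly
greater than 0.8 classifies a neuron nucleus-filled (the chronic
toxicity hallmark). Soma area is mask pixel count times pixel area.
Total neurite length skeletonizes the mask with Zhang–Suen thinning and
sums adjacency steps (1 axial, $\sqrt2$ diagonal, with corner-shortcut
diagonals not double-counted) — a 2-D replacement for commercial 3-D
filament tracing, stated as a simplification. Sholl profiles count
8-connected runs of skeleton pixels in annuli of half-width
$\sqrt2/2$ px (so no 8-connected path can cross a circle unseen), one
run per crossing. The contrast index is read as
$1 - 2/(F/F_{bg} + 1)$: the only reading of the printed formula that is
bounded in $(-1, 1)$, zero at $F = F_{bg}$ and increasing in
$F/F_{bg}$ — i.e. that behaves like a contrast.

## The synthetic generator and its presets

`build_stage_presets()` fixes the study conditions at seven stages
(DIV3–DIV28) under two conditions. The anchors that are printed numbers
are encoded exactly: healthy event rate 150 mHz at DIV3 declining
log-linearly in DIV to the 20 mHz plateau at DIV28; toxic presets equal
healthy through DIV10 and then diverge (collapsed rate and amplitude,
plateaued kernels reaching exactly 10x the healthy kernel FWHM at DIV28,
with plateau durations solved numerically from the kernel and frozen in
the preset table). Trajectories that exist only as figures — amplitude,
synchrony/shared-fraction, per-stage kernel constants — are relative,
monotone choices: amplitude 0.5 to 2.0 dF/F0, shared fraction 0.15 to
0.80, rise/decay constants growing from 0.10/0.35 s to 0.30/1.00 s
(brief, frequent events early; larger, slower events late). Late toxic
kernels end their plateau with a sharp 0.5 s decay, as toxic example
traces do; this also keeps slow tails from hovering at threshold level.
Noise SD is 0.05 dF/F0, a typical epifluorescence culture figure.

Events are the union of a network-shared Poisson train (identical times
across cells; rate `event_rate * shared_fraction`) and per-cell private
trains. One RNG stream drives the shared train and each cell derives its
own stream from the seed and cell index, so per-cell output survives a
change in `n_cells`. Amplitudes are Gaussian, truncated below at a
quarter of the mean.

Because the shared train moves every cell together, the view-mean event
frequency has standard error
$SE = \frac{1000}{T}\sqrt{s\lambda T + (1-s)\lambda T / n_{cells}}$ mHz
(shared fraction $s$, rate $\lambda$, duration $T$): the naive SEM
across cells would understate it badly at high $s$. Recovery tests and
the acceptance analysis use this SE.

`build_morph_presets()` encodes late-stage soma areas of 300 um^2
(healthy) vs 200 um^2 (toxic), logistic-like length growth (so the
growth-rate curve is bell-shaped), and an N/C ratio that climbs past the
0.8 cutoff only in the toxic branch after DIV10. Rendered images place a
soma disk and concentric nucleus (intensity ratio = sampled N/C) on a
512 px canvas with a random tree of polyline neurites. Headings are
quantized to multiples of 45 degrees and vertices to the pixel lattice,
which makes the rasterized skeleton length *exactly* the recorded
Euclidean truth (1 and $\sqrt2$ steps); border reflections never turn
more than 90 degrees and children leave their parent at 45-90 degrees,
so walks cannot double back adjacent to themselves (which thinning would
fuse and shorten). Mean length recovery is within ~2%, individual trees
within ~10% (residual branch crossings).

What the generator deliberately does **not** emulate: bleaching trends,
motion, correlated (neuropil) noise, bursty/quasi-periodic network
rhythms, cell-to-cell rate heterogeneity beyond the shared/private split,
3-D morphology and overlapping cells. Passing recovery tests therefore
demonstrates the correctness of the measurement chain under the stated
noise model, not robustness to all real-data artifacts.

## Problem sizes and determinism

The recovery analyses use the protocol sizes throughout: 30 cells x
600 s at 5 Hz per view for frequency/FWHM recovery, 50 rendered images
per condition for morphometry, and smaller views (2-15 cells, 20-600 s)
in unit tests — all chosen so the whole suite runs in well under a
minute per module on one core. All randomness flows from explicit seeds;
identical (preset, seed) pairs give bit-identical traces, images and
pipeline tables, and `run_pipeline()` refuses configs with unknown keys
so a typo cannot silently change an analysis.

## Known limitations

* Peak counting at 5 Hz under-detects by ~5-10% at 150 mHz (see above);
  frequencies at or below ~50 mHz are recovered essentially unbiased.
* Spearman synchrony values are event-density dependent (dilution by
  baseline ranks); compare within, not across, acquisition protocols.
* Band fractions depend on recording length through the frequency grid;
  below ~100 s at 5 Hz the ultra-slow band has no interior bin and is
  reported 0% with a warning.
* The skeleton length estimator assumes neurites thin relative to the
  soma; heavily overlapping arbors shorten the skeleton at junctions.
* Group comparisons implement exactly the published repertoire (Student's
  t, one-way ANOVA + Bonferroni); no mixed-effects modelling of repeated
  views.
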