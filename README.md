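# catrace — chronic calcium-imaging quantification for cultured neurons

Long-term (days-to-weeks) calcium imaging of cultured cortical neurons
with genetically encoded indicators (GCaMP-family GECIs) is the standard
way to follow network maturation — and to detect the chronic toxicity an
unprotected CaM-based sensor inflicts on its host cell (nuclear filling,
stalled growth, collapsed and slowed Ca²⁺ oscillations). `catrace` is an
R implementation of the full quantification chain such experiments need,
for imaging labs and analysts who have trace matrices and ROI-masked
images and want reproducible numbers:

* **Trace conditioning** — background subtraction, rest-window baseline
  F₀ ("five data points at rest"), ΔF/F₀ = ((F − F_bg) − F₀)/F₀, and
  neuropil correction F_cell(t) = F_meas(t) − r·F_neuropil(t) with
  r = 0.7.
* **Event detection** — the three-standard-deviations rule
  (threshold = median + 3·SD with a robust noise SD =
  MAD(ΔF)/√2), made operational with a smoothed-corroboration step,
  separation-at-half-maximum, and a prominence criterion; waveform
  metrics per event: amplitude, FWHM between the two half-maximum
  crossings, and 50% rise/decay times; event frequency in mHz;
  stimulus-trial success rate and SNR
  (F_max/F₀ over the SD of the filtered 1-s pre-stimulus baseline).
* **Synchrony & spectra** — per-view synchrony as the mean pairwise
  Spearman rank correlation; one-sided FFT amplitude
  2·√(Re² + Im²)/n with band shares for <10 mHz (ultra-slow),
  10–100 mHz (slow) and 100–300 mHz (fast).
* **Morphometry** — nuclear/cytosolic intensity ratio with the 0.8
  nuclear-filling cutoff, soma area, skeleton-based total neurite
  length, Sholl profiles, image contrast 1 − 2/(F/F_bg + 1).
* **Longitudinal statistics** — per-DIV profiles (mean ± SEM), growth
  rates as first derivatives, profile-level OLS correlations (R²), and
  two-tailed unpaired t-tests / one-way ANOVA with Bonferroni post hoc
  (star-coded).
* **A synthetic-data generator** — per-stage presets (DIV3…DIV28,
  healthy vs toxic) that encode the published summary statistics
  (150 mHz first-week event rate declining to a 20 mHz plateau;
  ~300 vs ~200 µm² late somas; 10-fold toxic FWHM; N/C ratio crossing
  0.8 after DIV10) and emit traces, stimulus trials and neuron images
  with exact ground truth, so every stage of the pipeline is testable.

## Worked example

```r
library(catrace)

presets <- build_stage_presets()
p <- get_preset(presets, "DIV28", "healthy")
v <- simulate_view(p, n_cells = 10, duration_s = 600, fs = 5, seed = 42)

x   <- v$traces[1, ] - p$background_F
dff <- to_dff(x, f0 = compute_f0(x), fs = 5)
events <- waveform_metrics(dff, detect_events(dff))
head(events[, c("t_peak", "amplitude", "fwhm", "t_on50", "t_off50")], 3)
#>   t_peak amplitude     fwhm    t_on50   t_off50
#> 1   81.2  2.538895 1.272095 0.2677144 1.0043811
#> 2  153.8  1.955031 1.365080 0.4396446 0.9254353
#> 3  172.2  2.592937 1.303210 0.4257274 0.8774829
event_frequency_mHz(events)
#> [1] 23.33333
view_synchrony(v)
#> <synchrony_result>  10 cells, mean pairwise Spearman 0.233
```

A mature healthy cell fires ~20 mHz events of ~2 ΔF/F₀ with ~1.3 s FWHM,
and the network-shared event train produces measurable pairwise rank
correlation. The same chain on a toxic-preset image cohort:

```r
img <- render_neuron_image(get_preset(build_morph_presets(), "DIV28", "toxic"),
                           seed = 7)
nc_ratio_and_class(img$pixels, img$masks$nucleus, img$masks$cytosol)$nuclear_class
#> [1] "nucleus_filled"
soma_area(img$masks$soma, img$pixel_size)
#> [1] 237.25
```

— a nucleus-filled neuron with a stalled soma, drawn from the
200 ± 16 µm² toxic late-stage preset.

## The analysis workflow

`analysis/01_simulate.R` … `05_longitudinal.R` run the complete
two-condition longitudinal experiment (7 stages × 2 conditions) as thin
narrative drivers over the package functions, writing their tables under
`results/run/`. Stage 5 ends with the study-level readouts: bell-shaped
neurite growth rate peaking near DIV12, amplitude–length profile
correlation R² ≈ 0.98 (frequency–length R² ≈ 0.96 with negative slope),
and healthy-vs-toxic DIV28 comparisons significant at *** for frequency,
FWHM, soma area, neurite length and N/C ratio.

`run_pipeline()` exposes the same simulate → analyze → report chain as a
single YAML-configured call with fail-fast config validation, caching
(`resume: true`) and byte-identical reruns for a fixed seed.

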