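---
title: "zoneQuant: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{zoneQuant: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zoneQuant)
```

# The assay and the measurement model

An exclusion-zone migration assay stamps a circular cell-free area of nominal
diameter $d$ into a confluent monolayer; here the reference insert has a 5 mm
foot, so the theoretical zone area is $\pi d^2/4 = 19.63\ \mathrm{mm^2}$. The
well is imaged in brightfield at fixed cadence and the cell-free area $A(t)$
is extracted from each frame; the readout is the self-normalized percent area

$$P(t) = 100 \cdot \frac{A(t)}{A(t_0)}.$$

Self-normalization to each well's own first frame, rather than to the
theoretical area, is essential: under migration inhibitors the monolayer edge
relaxes outward slightly and $P(t) > 100$ is a real, reportable state. For the
same reason percent values are never clamped at 100.

# Segmentation chain

`runPipeline()` composes, in fixed order:

1. **Grayscale**: unweighted channel mean truncated to integer — the default
   conversion of common image-analysis tools when channel weighting is not
   enabled.
2. **Crop**: centered square of fractional side 0.8 by default. The crop
   geometry of the original batch workflow is not prescribed anywhere, so it
   is a plain parameter; the only requirement is that the zone plus a ring of
   monolayer stays inside.
3. **Sobel edges**: $\sqrt{G_x^2+G_y^2}$ with 3×3 kernels, replicated
   borders, clipped to [0, 255] and truncated. The convolution is computed
   directly in the spatial domain (padded shifted sums) rather than by FFT:
   the outputs are integer-quantized, and an FFT result that lands at
   $249.9999\ldots$ where the exact sum is 250 would floor to the wrong
   level.
4. **Maximum-entropy (Kapur) threshold** on the 256-bin histogram of the edge
   image: choose $T$ maximizing $\psi(T) = H_{\le T} + H_{>T}$, each class
   entropy over its occupied bins after within-class renormalization.
   Candidates leaving a class empty are skipped; with fewer than two occupied
   bins the threshold is undefined and the pipeline downgrades the frame to a
   zero-area result with a flag. Ties are broken toward the lowest level, and
   a candidate only displaces the incumbent when its criterion is larger by
   more than $10^{-12}$ — algebraically tied plateaus (e.g. any threshold
   inside an empty gap between two histogram modes) therefore resolve
   deterministically to the lowest level regardless of floating-point noise.
5. **Binarize with explicit polarity**: pixels above the threshold are edge
   pixels ("dark background" convention); the returned mask is their
   complement, under the module-wide contract *foreground = cell-free*. The
   original interactive workflow expressed this as a display-level LUT
   inversion; making it an explicit complement removes hidden state, and the
   simulator's truth masks arbitrate that this polarity is the correct one.
6. **Erode** (one 3×3 full-element iteration by default) with borders treated
   as background, then **fill holes** (background components not 4-connected
   to the border become foreground). Erosion detaches thin bridges between
   the zone and low-gradient specks inside cell interiors; hole filling
   absorbs the edge rings that debris specks leave inside the zone.
7. **Particle analysis**: 8-connected components, areas calibrated as
   $\mathrm{count}/s^2$ with $s$ the pixel scale in px/µm, kept when inside
   the fixed range $[10^5, 7\times10^8]\ \mathrm{µm^2}$ and unioned. The
   bounds are interpreted in calibrated µm² (0.1–700 mm²): only calibrated
   units make the printed range physically sensible, and at 0.3525 px/µm the
   minimum corresponds to ≈ 12 426 px. Survivors are unioned rather than
   reduced to the largest, matching particle-analysis semantics of summing
   in-range areas.

All stages preserve the pixel scale, every intermediate is retrievable with
`keepStages = TRUE`, and the pipeline is fully deterministic.

# Synthetic assay: what it emulates, and what it does not

The simulator exists so that every downstream stage can be validated against
exact ground truth. A frame is composed of:

- a **monolayer texture**: a seeded jittered-grid Voronoi mosaic with
  per-cell shading and bright polygonal boundary lines ~1.5 px wide. This
  reproduces the one property the segmentation chain actually exploits — the
  monolayer has high local intensity variance (edge-rich cell borders) while
  the cell-free zone is smooth;
- a **front** at radius $r(t) = \max\!\big(0,\ r_0 - v\,\max(0,\,t -
  t_{\mathrm{lag}})\big)$, with signed velocity $v$ (positive = closure). The
  texture contrast ramps in over two cell diameters *outward* from $r(t)$, so
  the truth mask (the disc of radius $r(t)$, exactly) remains the honest
  boundary while the leading cells fade in gradually — segmentation is
  neither artificially perfect nor biased by construction;
- **debris**: sparse bright specks (3–8 µm radius, far below the 0.1 mm²
  size-filter minimum) inside the zone, overgrown as the front passes them,
  exercising the erode and size-filter steps;
- a mild multiplicative **illumination gradient** and additive Gaussian
  **noise**, then quantization to 8-bit and replication to three channels.

All randomness flows from the single integer `rngSeed`; the texture and
debris fields are static across a series, and identical configurations give
bit-identical frames.

Default parameters and why:

| parameter | default | rationale |
|---|---|---|
| `zoneDiameterMm` | 5 | nominal foot diameter of the reference insert |
| `pixelScale` | 0.3525 px/µm | whole-well scan calibration at 4× |
| `frameIntervalH`, `durationH` | 3 h, 96 h | reference imaging cadence and horizon (33 frames) |
| `frontLagH` | 24 h | observed quiescent phase: treatments do not separate within the first day (cells spread/recover before directed migration) |
| `textureCellDiameterUm` | 30 µm | typical spread epithelial cell |
| `textureContrast` | 0.5 | distinct but not saturated brightfield cell borders |
| `debrisDensityPerMm2` | 0.5 | occasional specks, as in washed wells |
| `illuminationGradient` | 0.1 | mild lateral shading typical of whole-well scans |
| `noiseSd` | 2 gray levels | 8-bit camera noise |
| `imageMarginMm` | 0.75 | keeps a monolayer ring inside the default 0.8 crop |

`treatmentPresets()` maps the five reference treatments to signed front
velocities by inverting the endpoint model: with $r_0 = 2500$ µm, a 24 h lag
and a 96 h horizon, $v = r_0\,(1-\sqrt{P_{96}/100})/72\,\mathrm{h}$ for
endpoint percent areas of 88.8 (medium alone), 78.1 (serum), 48.9 (EGF),
103.3 (colchicine) and 110.7 (doxorubicin), giving 2.00, 4.04, 10.44, −0.57
and −1.81 µm/h. The lag field is the one structural addition to the front
model: without it, a constant-velocity front would separate promoter from
inhibitor within hours, contradicting the observed pattern in which no
treatment differs significantly during the first 24 h.

What the simulator deliberately does **not** reproduce: phase-contrast
optics, cell division and death, front roughness/fingering, drift, or
non-circular zones. Passing the end-to-end tests therefore demonstrates that
the measurement chain is correct and calibrated on edge-textured imagery with
known truth — not that segmentation will be this accurate on any particular
microscope's real data, where front morphology and contrast vary.

## Known degenerate regime

With `noiseSd = 0` the smooth illumination ramp quantizes into faint
intensity bands; the Kapur threshold on the edge image then lands at 0 and
the band boundaries slice the cell-free disc into a few large strips. The
*total* extracted area and equivalent diameter remain within tolerance (the
cut lines are pixels-thin), but the component count exceeds one. Any nonzero
sensor noise dithers the quantization away; the regime exists only in the
idealized noise-free render used for calibration checks.

# Statistics

`pairedTTest`, `oneWayAnova` and `twoWayAnova` wrap the standard R fitting
machinery (`t.test`, `aov`) rather than reimplementing it; the package layer
adds the contracts the assay needs:

- exact-tie limits (identical paired vectors give $t = 0, p = 1$; zero
  between-group variation gives $F = 0, p = 1$) instead of errors;
- numerically-zero guards in the two-way layout: a sum of squares below
  $10^{-10}$ of the total variation counts as zero, a non-zero effect over a
  zero residual reports a capped $F = 10^{300}$ with $p = 0$ (relevant only
  for noise-free synthetic layouts);
- balanced-only two-way design, enforced: with equal cell sizes the Type-I
  decomposition is unambiguous and the per-timepoint pairwise comparisons can
  use the pooled residual mean square, $t = (\bar y_a - \bar y_b)\,/\,
  \sqrt{2\,\mathrm{MS_E}/r}$;
- family-wise adjustment per timepoint family of $\binom{k}{2}$ treatment
  pairs, Šidák by default ($1-(1-p)^m$) with Bonferroni as the alternative.
  The post-hoc procedure of the original analysis is not documented anywhere,
  so it is a configuration option rather than an inference.

# Tracking

The tracker is deliberately simple: greedy nearest-neighbour linking between
consecutive frames, distance-sorted, one detection per track per frame, with
a hard displacement gate. This is adequate exactly when cells are well
separated relative to per-frame motion — the regime of the velocity analysis
it supports — and the tests verify agreement with a brute-force optimal
assignment oracle in that regime. Velocity is **path length over elapsed
time** (the convention of common tracking tools for "average cell
velocity"), with net displacement over time available as an option.
Positional jitter adds a positive bias to path-length speed (each frame
contributes an extra noise step); at jitter ≤ 0.2× the per-step displacement
the bias stays under 10%, and the working point of the velocity validation
(0.15 µm steps, 0.01 µm jitter) makes it negligible.

# Numerical conventions and problem sizes

- Dimensions are millimetres everywhere in the geometry layer; conversion to
  µm happens only at the image boundary. Areas are reported in both µm² and
  mm².
- Masks are logical matrices with the fixed polarity foreground = cell-free;
  labelled components are 8-connected (4-connected labelling plus diagonal
  merge), hole filling uses 4-connected background reachability from the
  border.
- Batch CSV output is UTF-8 with '.' decimal separator, times in hours; one
  shared parameter set per batch, per-well overrides intentionally
  unsupported to protect comparability.
- Truth masks are written as 8-bit 0/255 TIFF (the TIFF writer used does not
  emit 1-bit files); readers should threshold at > 0.
- The validation suite scales its imagery to keep runtimes short while
  preserving the physics: calibration checks run at the full 5 mm zone and
  0.3525 px/µm; the 33-frame kinetics-fidelity series uses a 2 mm zone and
  the end-to-end 5-treatment × 3-replicate plate a 1.2 mm zone (9 frames per
  well at 12 h cadence), with preset velocities scaled by zone radius so the
  closure fractions match the full-size assay. These sizes are the package's
  own choices for its test battery; all parameters remain free for users.

# Limitations

- The segmentation chain assumes edge-textured monolayers on a smooth
  background; fluorescence imagery, heavy vignetting or confluent debris
  fields are out of scope.
- Centroid *detection* from real images is intentionally not provided; the
  tracking module consumes detection tables (from the simulator or external
  detectors), keeping the velocity analysis testable and honest about what it
  does.
- The two-way ANOVA is balanced-only; unbalanced or mixed-effect designs need
  dedicated modelling.
- The measured-vs-theoretical gap of physical inserts (printed feet run
  slightly under nominal diameter) is not modelled; the simulator's zone is
  exactly nominal.
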