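# zoneQuant

Quantification of **exclusion-zone (insert-based) cell migration assays**
from brightfield time-lapse images.

In an exclusion-zone assay a removable insert blocks cell attachment in a
defined region of the well; lifting it leaves a reproducible circular
cell-free area inside a confluent monolayer, without the mechanical damage of
a scratch assay. Collective migration is then read out as the **percent
cell-free area over time**: promoters (serum, EGF) close the zone, inhibitors
(colchicine, doxorubicin) leave it open or let it grow slightly. zoneQuant is
for cell biologists running such assays on plate scanners who need calibrated,
batch-scale image quantification plus the associated statistics.

## What it computes

The core is the segmentation chain that turns one 24-bit RGB frame into a
calibrated cell-free area:

1. 8-bit grayscale conversion (unweighted channel mean) and centered crop;
2. Sobel edge enhancement, |∇I| = √(Gx² + Gy²), which converts monolayer
   texture into signal;
3. **maximum-entropy (Kapur) thresholding**: the gray level T maximizing
   ψ(T) = H(≤T) + H(>T), the sum of Shannon entropies of the two histogram
   classes;
4. polarity normalization (foreground = cell-free), one round of 3×3 binary
   erosion, and hole filling;
5. particle analysis: 8-connected components, calibrated by the pixel scale
   (px/µm) as area = count / scale², kept within a fixed size range
   (default 1e5–7e8 µm²) and unioned.

Around it sit: the insert geometry model (a 5 mm foot stamps a theoretical
zone of π·d²/4 = 19.6 mm²), migration kinetics (per-well normalization to
the first frame, replicate mean ± SEM, paired t, one-way and balanced two-way
ANOVA with Šidák/Bonferroni per-timepoint comparisons), a greedy
nearest-neighbour centroid tracker with path-length velocity estimation, and
a **synthetic assay simulator** — a seeded Voronoi-mosaic monolayer around a
disc whose front moves at a configurable signed velocity — that provides
exact ground truth (masks, areas, tracks) for end-to-end validation.

## Worked example

Simulate a closing 2 mm zone under a strong-promoter front velocity and
quantify it with the full pipeline:

```r
library(zoneQuant)

insertGeometry()
#> InsertGeometry (mm):
#>   top    16 x 3 (plus-sign span x height)
#>   middle d=9 h=10
#>   bottom d=5 h=4 (zone diameter 5 mm)
#>   total height 17 mm; theoretical zone area 19.63 mm^2

cfg <- simConfig(zoneDiameterMm = 2, imageMarginMm = 0.4,
                 frontVelocityUmPerH = treatmentPresets()[["egf"]],
                 durationH = 24, frameIntervalH = 12, frontLagH = 0)
sim <- simulateTimelapse(cfg, wellId = "A1")
res <- lapply(sim$series@frames, runPipeline)
df  <- data.frame(well_id = "A1", time_h = sim$series@timesH,
                  area_mm2 = vapply(res, areaMm2, numeric(1)))
percentArea(df)
#>  well_id treatment time_h area_mm2 percent_area
#>       A1      <NA>      0 3.152783    100.00000
#>       A1      <NA>     12 2.410647     76.46093
#>       A1      <NA>     24 1.773166     56.24131
```

The measured percent areas (100, 76.5, 56.2) track the simulator's ground
truth (100, 76.5, 56.2) to a fraction of a percentage point: the front at
10.44 µm/h shrinks the 1000 µm zone radius, and the pipeline recovers the
calibrated area of the remaining cell-free disc frame by frame.

A command-line front end (`inst/cli/zonequant.R`) exposes `simulate`,
`quantify`, `kinetics`, `track` and `compare` (an end-to-end demo plate):

```sh
Rscript inst/cli/zonequant.R simulate --treatment-preset egf --seed 1 --out sim/
Rscript inst/cli/zonequant.R quantify --in sim/ --scale 0.3525 --out results.csv
Rscript inst/cli/zonequant.R kinetics --results results.csv --layout plate.yaml --out kin/
```

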