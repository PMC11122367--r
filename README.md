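# octaquant

Quantification of the retinal microvasculature in 2D en-face OCTA
(optical coherence tomography angiography) images, for studies that track
capillary perfusion through disease and surgery — for example eyes operated
for macula-off rhegmatogenous retinal detachment, where the fellow eye
serves as the preoperative reference.

## What it computes

A 3 × 3 mm fovea-centered en-face angiogram (nominally 586 × 585 px,
1 px ≈ 5.13 µm) is segmented by a **three-way binarization**:

* a **global threshold** (Otsu on the 8-bit histogram),
* a multiscale **Hessian vesselness filter** (Frangi): with eigenvalues
  `|λ1| ≤ |λ2|` of the scale-normalized Hessian, the tubularity response is
  `exp(−R_B²/2β²) · (1 − exp(−S²/2c²))`, `R_B = λ1/λ2`, `S = √(λ1²+λ2²)`,
  zero where `λ2 ≥ 0` (bright-on-dark sign test), maximized over scales,
* an **adaptive local-mean threshold** (pixel > mean over a 51 px window),

fused (default) as `vesselness ∧ (global ∨ adaptive)`. The binary vessel map
is thinned to a unit-width, connectivity-preserving skeleton by iterative
boundary removal. Per region of interest (ETDRS-style foveal 1 mm disc,
parafoveal 1–3 mm annulus, whole scan):

* **VAD** — vessel area density: vessel pixels / ROI pixels,
* **VSD** — vessel skeleton density: skeleton pixels / ROI pixels
  (caliber-independent length of the network),
* **VDI** — vessel diameter index: vessel pixels / skeleton pixels
  (mean caliber), reported in px and µm,
* **FAZ** — foveal avascular zone area (mm²) by the shoelace formula from a
  manually traced contour.

A synthetic-vasculature generator grows branching, anastomosing vessel
trees with exact centerline/caliber ground truth, and a cohort layer
implements the longitudinal endpoint statistics (Mann–Whitney U with exact
small-sample p, repeated-measures ANOVA, Fisher/chi-square, logistic
regression with backward selection at entry p < 0.1 / stay p < 0.05,
Spearman inter-eye correlation, BCVA functional-success classification at
≥ 0.3 logMAR improvement).

## Worked example

```r
library(octaquant)

# a full-scale synthetic SCP angiogram with known ground truth
sc <- generate_scene(scene_params(), seed = 42)
sc$image
#> <enface_image> 586 x 585 px, 3.00 x 3.00 mm, plexus SCP
#>   pitch: 5.12 x 5.13 um/px; quality: 90; eye: synthetic-seed42; visit: synthetic

quantify(sc$image)[, c("region", "vad", "vsd", "vdi_px", "vdi_um")]
#>       region   vad    vsd vdi_px vdi_um
#> 1     foveal 0.315 0.0798   3.95   20.2
#> 2 parafoveal 0.445 0.1238   3.59   18.4
#> 3      whole 0.430 0.1180   3.65   18.7
```

The measured whole-image VAD (0.430) matches the generator's ground truth
(0.43); the VDI of ~18.7 µm is the mean capillary caliber at the 5.13 µm
pixel pitch. The vessel-free central disc of radius 0.276 mm corresponds to
a FAZ area of `faz_area(...)` = 0.239 mm² from a traced 64-gon.

Cohort side — 44 simulated eyes with a true preoperative-BCVA effect and
null vascular effects:

```r
rec <- simulate_rrd_cohort(44, seed = 42)
fs  <- functional_success_frame(rec)   # success = BCVA gain >= 0.3 logMAR
backward_selection(fs, "success",
                   c("preop_bcva", "vad_scp", "vsd_scp", "vdi_scp"))
#> Backward-selected logistic model:
#>    variable       or    ci_lo    ci_hi          p
#>  preop_bcva 235.7419 7.663454 7251.854 0.00177865
```

Only preoperative BCVA survives the backward screen; the (null) vascular
metrics are rejected.

## Command line

```sh
inst/cli/octaquant quantify --image scan.png --meta scan.json --out metrics.csv
inst/cli/octaquant simulate --seed 7 --out scene.png --truth truth.json
inst/cli/octaquant cohort   --records records.csv --out report/
```

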