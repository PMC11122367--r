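---
title: "Quantifying retinal capillary networks in en-face OCTA: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying retinal capillary networks in en-face OCTA: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octaquant)
```

## The measurement problem

OCTA renders blood flow as bright curvilinear structures on a dark
background. Clinical studies of the macular microvasculature — e.g., eyes
recovering from macula-off retinal detachment surgery — need *quantitative*
summaries of these en-face angiograms that are reproducible across visits
and eyes. `octaquant` implements the standard trio:

* **VAD** (vessel area density): the perfused fraction of the region of
  interest, from the binarized angiogram.
* **VSD** (vessel skeleton density): skeleton pixels per ROI pixel. Because
  every vessel is collapsed to a one-pixel centerline first, VSD measures
  total network *length* irrespective of caliber.
* **VDI** (vessel diameter index): vessel pixels divided by skeleton
  pixels — the mean vascular caliber. Its pixel value times the pixel pitch
  gives µm; at the study geometry (3 mm / 585 px = 5.13 µm per pixel)
  cohort-scale values around 18–19 are consistent with the µm reading, so
  µm is the default reporting unit (the px value is always reported
  alongside, since the unit convention is not universal in the literature).
* **FAZ area** (mm²): shoelace polygon area of a manually traced foveal
  avascular zone contour. Tracing itself stays manual; only the area
  computation is implemented, and self-intersecting contours are rejected.

Working representation: an 8-bit image. Raw data at other bit depths is
converted by linear min–max rescaling (`to_8bit()`); a constant image maps
to zero everywhere — it carries no contrast, and the degenerate rule is
explicit rather than an arbitrary division by zero. The nominal
586 × 585 px / 3 × 3 mm scan is slightly anisotropic (5.12 × 5.13 µm);
all geometry is computed with per-axis pitches, and the scalar pitch used
for VDI-µm is their mean.

Regions of interest follow the ETDRS convention — foveal disc of 1 mm
diameter, parafoveal annulus 1–3 mm, whole scan — because the source
protocol names the regions without stating diameters and ETDRS is the field
standard. The fovea center defaults to the image center (scans are
fovea-centered); an explicit override is accepted for decentered scans.
Eyes with a device quality index below 45 are excluded (`quality_filter()`),
and records without a score are excluded with a logged reason rather than
silently kept.

## Three-way binarization

`binarize_enface()` fuses three complementary masks:

1. **Global threshold** — Otsu's maximization of between-class variance on
   the full 8-bit histogram (ties broken toward the lowest threshold;
   pixels strictly above the threshold are foreground). Good when
   illumination is uniform; brittle under drift.
2. **Multiscale Hessian vesselness** — the 2D Frangi filter. At each scale
   σ the image is convolved with scale-normalized (σ²) Gaussian second
   derivatives; eigenvalues λ1, λ2 (|λ1| ≤ |λ2|) give
   `V = exp(−R_B²/2β²)(1 − exp(−S²/2c²))` with `R_B = λ1/λ2` and
   `S = √(λ1² + λ2²)`, zeroed where λ2 ≥ 0 (bright-on-dark sign test).
   The per-pixel maximum over scales is rescaled to [0, 1]. Defaults:
   β = 0.5; c chosen per scale as half the maximal Hessian norm; scales
   {1, 1.5, 2, 2.5, 3, 4} px. The ladder tops at σ = 4 because the tube
   response peaks near σ ≈ caliber/2 and retinal capillary calibers reach
   ~40 µm ≈ 8 px at this pitch; with a 3 px ceiling the filter visibly
   hollows out the cores of the widest vessels.
3. **Adaptive local-mean threshold** — pixel > mean over a 51 px
   (~261 µm) window plus offset 0. This leg keeps vessels through the slow
   decorrelation/illumination gradients that defeat any single global cut.

Default fusion: `vesselness ∧ (global ∨ adaptive)` — the Hessian gates
*shape*, the thresholds gate *intensity*. Majority (2-of-3), intersection
and union are selectable, every fused mask is a subset of the union of its
components, and the rule id plus all parameters (and a short hash) are
recorded in the output for provenance.

The vesselness response is cut at a deliberately permissive fixed 0.05 (of
the [0, 1] rescaled response). An Otsu cut on the nonzero response
histogram is available as an option but is not the default: measured on
noise-free synthetic trees it lands mid-vessel and keeps barely half of the
true vessel area, which destroys the mask (Dice ≈ 0.72 versus ≥ 0.97 with
the permissive gate). As a *shape* gate the vesselness mask must cover
whole vessel bodies — including junctions and wide cores where the Frangi
response is weak by construction — while the intensity legs carry the
foreground/background decision.

Border handling everywhere (derivative kernels, box means) is reflective
(mirror) padding, which affects at most a one-window-wide frame and avoids
the dark-frame artifacts of zero padding.

## Skeletonization

`skeletonize()` iteratively removes pixels from the outer perimeter of the
vessel map until one pixel remains in the width direction (Zhang–Suen
two-subiteration parallel thinning), with two safeguards:

* a deletion is vetoed when the pixel would retain no surviving neighbour —
  parallel thinning can otherwise erase a small component wholesale, and
  component counts must be preserved;
* residual 2 × 2 staircase blocks (a known Zhang–Suen artifact) are removed
  afterwards in deterministic row-major order, deleting only *simple
  points* — pixels whose Guo–Hall connectivity number is 1, so deletion can
  change neither connectivity nor component count.

The result is unit-width (no fully-set 2 × 2 block), a subset of the vessel
map, and preserves the number of 8-connected components; the test suite
checks all three on hundreds of generated scenes. Skeleton length is
counted in pixels (VSD is the skeleton-pixel fraction), matching how the
quantification literature computes it; a Euclidean variant (diagonal steps
weighted √2) is available behind a flag. An empty skeleton within an ROI
makes VDI an *error*, never 0 — silently reporting 0 would bias cohort
means toward narrower vessels.

## Synthetic angiograms with exact ground truth

No public en-face angiograms accompany the cohort, so validation rests on
`generate_scene()`: random walks with momentum grow vessel trees from
uniformly seeded points; each step can fork a branch (probability 0.02/px,
child caliber decayed ×0.9 with a floor at the configured minimum); a
branch that meets an existing vessel terminates shortly after contact, so
the trees *anastomose* into a mesh like a capillary plexus instead of
criss-crossing; a central avascular disc (default radius 0.276 mm,
i.e. πr² = 0.239 mm², the cohort-typical FAZ) repels growth. Growth stops
when the target vessel area fraction (default 0.43, the cohort's SCP
operating point) is reached. Calibers default to 2–5 px (~10–26 µm).
Vessels are rendered at constant contrast over the (optionally ramped)
background, lightly blurred (σ = 0.6 px) for a smooth profile, with
optional additive Gaussian or multiplicative speckle noise. One seed
determines everything; the caller's RNG state is restored.

Ground truth bookkeeping mirrors what a mask-based pipeline can possibly
see: the centerline is digitized at 1 px spacing (successive pixels
8-adjacent — the same minimal-chain convention a thinned skeleton
produces), and centerline pixels buried inside pre-existing vessels (fork
exits, anastomosis joins) are not double-counted. `truth_mean_caliber_px`
is total vessel area over total centerline length — exactly the
construction VDI estimates (for two equal-length bars of widths 2 and 6 it
is 4, not the simple mean); the area-weighted mean
(`truth_mean_caliber_area_weighted_px`, 5 in that example) is reported as
a secondary summary.

What the generator does *not* emulate: OCT speckle statistics, flow-related
signal variation, projection artifacts, layered plexuses, pathology. A
passing recovery test therefore shows the pipeline is unbiased on clean
tubular meshes of known geometry — not that it is robust to every artifact
of device data.

## Cohort statistics

The longitudinal layer works on eye × visit records (RRD and fellow eyes;
preop, months 1/3/6). Conventions, fixed and logged:

* BCVA is logMAR (lower = better); improvement is `pre − post`, and
  *functional success* is improvement ≥ 0.3 at month 6 (boundary
  inclusive). Gain/loss ≥ 0.1 classifications use the same sign convention.
* Mann–Whitney U uses midranks; exact two-sided p (twice the smaller tail
  of the null U distribution) for tie-free samples with n₁ + n₂ ≤ 12,
  otherwise a normal approximation with tie and continuity corrections.
* Repeated-measures ANOVA is the one-way within-subject F with df (v−1),
  (v−1)(n−1), fitted via `aov` with an error stratum; missing cells are an
  error (no imputation). At two visits F equals the squared paired t.
* 2 × 2 tables: Fisher's exact (two-sided, summing tables no more probable
  than observed) when any expected cell < 5 *or* any observed cell is 0 —
  a zero cell invalidates the χ² approximation regardless of margins —
  else plain Pearson χ² (1 df). The odds ratio is the cross-ratio ad/bc
  with the Haldane–Anscombe 0.5 correction under zero cells.
* Logistic regression is the `glm` ML fit with Wald inference; complete or
  quasi-complete separation is detected and flagged instead of reporting a
  divergent OR. Backward selection seeds the multivariate model with
  candidates at univariate p < 0.1 and repeatedly drops the largest
  Wald p ≥ 0.05, refitting each time; ties drop the later-listed candidate,
  making the procedure deterministic.
* Spearman inter-eye correlation: midranks, exact p for n ≤ 8 without
  ties, t-approximation otherwise.
* Quartiles use linear interpolation (R type 7). No multiple-testing
  correction is applied anywhere, matching the source protocol; outputs
  say so implicitly by reporting raw p-values only.
* Because preoperative OCTA of a detached macula is not interpretable,
  the fellow eye's preoperative metrics serve as surrogates. Both analysis
  variants are first-class: `visit_matrix(..., use_surrogate_preop = TRUE)`
  (preop + months 1/3/6) and `FALSE` (months only).

### The simulated cohort

`simulate_rrd_cohort()` encodes one true functional effect and null
vascular effects. Month-6 BCVA follows a mechanistic recovery model,
`0.30 + 0.25·preop + N(0, 0.25)` logMAR with preop ~ N(0.83, 0.29) (the
cohort's distribution): worse preoperative vision leaves more headroom for
a ≥ 0.3 gain, so preop BCVA genuinely drives success. This reproduces the
cohort's mean BCVA change (≈ −0.32) and success rate (≈ 55%), and a design
power calculation on the mechanistic model (run before the defaults were
frozen) gives ≈ 95% probability that backward selection retains preop BCVA
alone at n = 44. The residual SD of 0.25 logMAR is the design choice that
sets this power; smaller values approach separation at n = 44, larger ones
drop retention below 90%. All OCTA metrics are drawn around the cohort
means independently of outcome, with a per-subject random effect shared by
both eyes (inducing the inter-eye correlation the surrogate design needs).

## Numerical choices and degenerate inputs

* Otsu ties → lowest threshold; constant image → empty mask plus warning.
* Vesselness on a (numerically) flat image → exactly zero: derivative
  kernels are DC-corrected and a negligible-structure cutoff ignores
  floating-point residue.
* Region circles that overrun the scan are clipped with a warning, with a
  one-pixel tolerance so the nominal 3 mm geometry itself stays silent.
* Polygon areas are orientation-free (absolute shoelace); < 3 vertices or
  self-intersection are errors.
* Every mask/skeleton operation is deterministic; `quantify()` rows are
  byte-identical across reruns.

Problem sizes in the test suite are chosen for breadth rather than scale:
recovery and invariant checks run on 64–192 px scenes (hundreds of seeds),
with one full-scale 586 × 585 scene exercised end-to-end in the acceptance
script. Tolerances there reflect what the design can honestly promise:
VAD within ±0.05 absolute, VSD within ±15% relative, VDI-recovery slope
within 1 ± 0.15 on noise-free trees with calibers 3–8 px.

## Known limitations

* The binarization defaults were validated on synthetic meshes; device
  images with strong projection or motion artifacts will need parameter
  review (everything is exposed in `vesselness_params()` /
  `threshold_params()` and recorded in provenance).
* VSD/VDI inherit the usual mask-based biases near junctions, where
  skeletons merge; at mesh densities around VAD 0.4 this costs roughly
  5–10% of skeleton length, which the stated tolerances absorb.
* FAZ measurement assumes a traced, simple polygon; no automatic FAZ
  segmentation is attempted.
* The cohort generator is a statistical phantom for validating the
  *analysis* code paths, not a disease model; its effect sizes are design
  choices documented above.
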