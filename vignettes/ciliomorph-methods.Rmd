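---
title: "ciliomorph: methods, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ciliomorph: methods, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciliomorph)
```

## The measurement problem

Primary cilia appear in ADCY3-stained fluorescence micrographs as thin,
bright, elongated structures 1–15 µm long with a brighter proximal spot
where the basal body sits. The quantities of interest per cilium are its
length, width, and base-to-tip orientation; per region, the density of
cilia relative to DAPI-stained cell counts; and per section, mean length
and circular-mean angle, which are the units of all downstream
time-of-day statistics.

The pipeline assumes (i) cilia are brighter than the local background,
(ii) the basal body is the brightest part of each cilium, (iii) the
tissue background level is well above the camera noise floor, and (iv)
cilia are mostly isolated — touching or crossing cilia are *not* split,
and will be measured as a single object or discarded by the shape
filters.

## Cilia detection

1. **Grayscale + Gaussian blur.** RGB input is converted by Rec. 601
   luminance; a 3×3 Gaussian blur (σ ≈ 0.8 px, the standard
   kernel-derived value) suppresses single-pixel noise.
2. **Canny edges with median-derived thresholds.** Hysteresis thresholds
   are tied to the image median: lower = `0.67 × median`, upper =
   `1.33 × median`. The 0.67 factor is part of the published pipeline;
   the upper threshold is described there only as "slightly increased",
   and the symmetric 1.33 is this package's default
   (`detection_params(canny_upper_factor=)` to change it). Gradient
   magnitude is the L1 norm of 3×3 Sobel responses, with standard
   non-maximum suppression and 8-connected hysteresis linking.
   This thresholding scheme presupposes that the median intensity
   (tissue background) is several times the noise SD; on images whose
   background is at the noise floor the thresholds land inside the noise
   gradient distribution and detection degrades — that is a property of
   the method, reproduced faithfully.
3. **Morphology.** Closing with a 2×2 rectangle bridges 1-px gaps in the
   edge ring; erosion with a 1×1 rectangle for one iteration follows.
   A 1×1 erosion is mathematically the identity; it is implemented as
   specified rather than silently upgraded to a useful kernel, and the
   kernel is configurable for users who want the (possibly larger)
   kernel of the original program.
4. **Filtering.** Each external contour is measured by its minimum-area
   rotated rectangle; contours with length strictly between 1 and 15 µm
   and length/width ≥ 1.5 are kept (strict length inequalities follow
   the published wording "greater than 1 µm and less than 15 µm"). A
   degenerate zero-width contour counts as infinitely elongated.
   Boundary-touching contours are kept by default (`drop_border`).
5. **Measurement.** Length and width are the rectangle sides multiplied
   by the pixel size, and the raw angle is the long-axis orientation
   modulo 180° in a y-up mathematical frame (0° = image right,
   counter-clockwise positive). An axis-aligned bounding-box mode
   (`length_mode = "bounding_box"`) is available because the narrative
   description of the original method mentions it, but the rotated
   rectangle of the pipeline description is the default.
6. **Base and direction.** The brightest pixel within the filled contour
   mask is taken as the base (ties broken by smallest row, then column;
   a bounding-box search mode exists behind `base_search = "bbox"`).
   The search runs on the *blurred* working image: on the raw image a
   single ~3σ noise pixel on a long shaft occasionally outshines the
   basal body and displaces the base by many pixels, which is exactly
   the failure mode the published blur step exists to prevent. If the
   long-axis direction disagrees with the base→centre vector (negative
   dot product), 180° is added. For left-hemisphere images the angle is
   mirrored, θ → (180° − θ) mod 360°, so that medial/lateral
   orientations are comparable across hemispheres.

Records with an undefined angle (base exactly at the centre) are skipped
and logged, never silently assigned.

### Parameter summary

| parameter | default | unit | origin |
|---|---|---|---|
| `canny_lower_factor` | 0.67 | ×median | published pipeline |
| `canny_upper_factor` | 1.33 | ×median | package default ("slightly increased") |
| `close_kernel` | 2×2 | px | published pipeline |
| `erode_kernel` | 1×1, 1 iter | px | published pipeline (identity) |
| `min_length_um`, `max_length_um` | 1, 15 | µm | published filter |
| `min_aspect` | 1.5 | – | published filter |
| `blur_kernel` | 3×3 | px | published preprocessing |
| pixel size | **required** | µm/px | never guessed; no safe default |

## Nuclei detection and density

CLAHE (clip 2.0, 8×8 tiles) → adaptive local-mean threshold (block 41,
offset C = −10, i.e. foreground iff value > local mean + 10) → exact
Euclidean distance transform → threshold at 0.2 → 3×3 dilation →
external contours → DBSCAN on centroids (eps = 30 px, min_samples = 1,
so clustering is single-linkage with no noise points) → convex hull per
cluster → keep hulls with 20 ≤ area ≤ 1000 px² and circularity
4πA/P² ≥ 0.01. Density is `100 · n_cilia / n_cells`.

Two published steps needed interpretation:

* the 0.2 threshold is applied to the distance map **normalised to
  [0, 1] by its global maximum** — a 0.2 threshold on raw pixel
  distances would be sub-pixel and meaningless;
* the sure-background/"unknown" regions of the classical marker
  construction are derivable but unused — no watershed step exists in
  the published method, and none is added. Overlapping nuclei are
  therefore counted as one; the synthetic benchmark places
  non-overlapping nuclei (≥ 40 px separation, beyond the 30 px
  clustering radius) so counts are well-defined.

## Circular statistics and aggregation

The circular mean is `atan2(mean sin, mean cos)`, converted to degrees
with 360 added to negative values; a resultant vector shorter than 1e−12
(antipodal sets) raises an error rather than returning an arbitrary
direction. Angular differences are wrapped: `min(|Δ|, 360 − |Δ|)`.

The **section** is the analysis unit: each section contributes one mean
length and one circular-mean angle. Two regional averaging schemes are
provided — `direct` (every cilium counts once) and `section_based`
(every section counts once, SEM over sections) — which agree exactly
when sections are balanced. Length histograms default to 0.6 µm bins
anchored at 0, so one bin spans 4.8–5.4 µm.

## Time-of-day statistics

One-way ANOVA compares section summaries across zeitgeber times;
angles enter as linear values of the section circular means, exactly as
in the original analysis — for angle data tightly clustered around a
regional mean direction this is a reasonable approximation, but it is a
caveat, not a corrected choice. Multiplicity is controlled by the
two-stage Benjamini–Krieger–Yekutieli procedure: stage 1 runs the linear
step-up at q′ = q/(1+q); if it rejects r₁ ∈ (0, m) hypotheses, stage 2
re-runs the step-up at q′·m/(m − r₁). Note the working level is q′, not
q, in both stages (the published definition); a consequence is that the
procedure is uniformly at least as powerful as the linear step-up at
level q′, and at least as powerful as BH at q whenever stage 1 rejects
anything — but *not* unconditionally dominant over BH at q: if stage 1
rejects nothing the procedure stops, even on inputs where BH(q) would
have rejected. The acceptance suite asserts exactly the statements that
are theorems.

Pearson correlation matrices are computed between per-ZT mean profiles
of pairs of regions (unit diagonal, symmetric; zero-variance profiles
yield NA with a warning), with unadjusted p < 0.05 as the significance
flag used downstream.

**Rhythm detection.** The original study used an external deep-learning
tool (a DNN classifier/regressor with a synthetic-null p-value
construction). That tool is *not* re-implemented; `cosinor_fit()` is a
clearly-labelled stand-in that fits `y = M + A·cos(2π(t − φ)/24)` by
harmonic regression and tests the two harmonic terms with an F-test. It
detects fixed-24 h sinusoidal rhythms only, and its p-values are not
comparable to the original tool's.

## Network analysis

Projection density is divided by injection volume per experiment,
averaged per (source, target) pair, and log₁₀-transformed after flooring
zeros to the smallest positive entry (the source data are silent on
zeros; the floor keeps the transform finite and monotone). Louvain
community detection (resolution 1, seeded) runs on the symmetrised
matrix; log-scale matrices are shifted to non-negative weights first.
Correlation networks use `w = −ln(1 − min(|r|, 0.999))` — the published
account says only "log-scaled R value"; this transform is zero at r = 0,
strictly increasing in |r|, spreads the high-correlation regime, and the
cap avoids infinities.

The community-pair test statistic is the fraction of significantly
correlated region pairs among all pairs between two communities; the
null permutes the significance flags over all region pairs (preserving
their total count), and the percentile counts ties as ≤. With discrete
fractions the percentile is uniform on (0, 100) only up to tie-induced
granularity; the acceptance suite verifies approximate uniformity by a
KS test on a null simulation with many pairs.

## The synthetic world

`synth_cilia_image()` renders what the detector assumes: anti-aliased
capsules (width 2–4 px) whose caps are inset so the rendered extent
equals the base-to-tip length, a basal blob (radius 2 px, 1.6× shaft
intensity) centred 1 px inside the base, Gaussian PSF blur (σ 0.8 px),
and additive Gaussian noise with SNR (shaft amplitude / noise SD) 5.
The background level defaults to 60 on an 8-bit scale with amplitude 40
(noise SD 8): tissue autofluorescence in real micrographs sits well
above the noise floor, and the median-derived Canny thresholds require
that regime (with background at the noise floor, `0.67 × median` falls
inside the noise gradient distribution and the method, as published,
breaks down). The default benchmark ("bench-v1") is 20 images of
1024×1024 px at 0.5 µm/px with ~25 cilia each at ≥ 20 px segment
separation, seed 42, image *i* seeded `seed + i`.

Benchmark scenes contain only cilia *within the detector's filter
bounds as rendered*: a structure must satisfy
`length ≥ 1.75 × max(width, blob diameter)`. A 2 µm cilium carrying a
2 px-radius basal blob is ~5 px wide and fails the published 1.5 aspect
filter — correctly, but then recall would measure filter-boundary
geometry rather than detection. In practice this truncates benchmark
lengths to ≈ 4.4–12 µm of the nominal 2–12 µm range; cilia shorter than
~4.4 µm are unmeasurable under the published filters at 0.5 µm/px.

What the generator does **not** emulate: tissue texture and
autofluorescence structure, out-of-focus light, touching or crossing
cilia, anisotropic PSFs, and real basal-body/axoneme staining
variability. A green benchmark therefore establishes that the
implementation measures well-separated, well-stained structures
correctly at realistic noise — not that it reproduces the original
study's biological numbers, which derive from ~10⁷ real cilia and are
out of desk-scale scope.

The noisy background does produce spurious small contours that pass the
published size filters (as it would on real images). Recall and the
matched MAEs — the quantities the original validation reports — are
insensitive to them; precision is deliberately not scored.

## Numerical choices and degeneracies

* Brightest-pixel ties: smallest row, then smallest column.
* Collinear contours: zero width, flagged, treated as infinitely
  elongated by the aspect filter.
* Circular mean of an antipodal set: error at resultant < 1e−12.
* Greedy base matching (sorted by distance, ties by index, 5 px radius)
  is deterministic and within one pair of the optimal assignment on
  small scenes (checked by enumeration); 5 px is far below the 20 px
  benchmark separation, so matching is effectively unambiguous.
* The orientation of an L-px discrete object is only defined to about
  atan(1/L); moreover the minimum-area rectangle's argmin can move by a
  few degrees when a single edge pixel changes (e.g. under the
  anchor-asymmetric 2×2 closing of a rotated image). Rotation
  equivariance is therefore asserted on the mean wrapped deviation
  rather than per object.
* Images round-trip bit-exactly: PNG via libpng (8-bit) and a built-in
  single-strip uncompressed TIFF codec (8/16-bit grayscale, 8-bit RGB
  read). 16-bit output uses TIFF.

## Known limitations

Touching cilia are measured as one object; lengths are 2D projections
of 3D structures (`projection_error()` quantifies the shortening,
√(L² − Δz²), which is uniform across regions for constant section
thickness and so does not affect comparative analyses); the cosinor
stand-in detects only 24 h sinusoids; ANOVA on circular means ignores
angular topology; and the nuclei pipeline does not split merged nuclei.
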