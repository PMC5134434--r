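---
title: "Two-view silhouette grading of mango fruit: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-view silhouette grading of mango fruit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mangovision)
```

mangovision grades a mango from one frame containing its top view and a
mirror-reflected side view. This vignette records the models the package
implements, the assumptions behind them, the parameters a user may want to
change, and the design decisions we made where the method left choices
open.

## Segmentation

The tray is white and the fruit is dark green, so segmentation happens in
the blue channel. Top view: fruit = B strictly between the stem band and
the background threshold, i.e. `(20, 90)` by default. Published
descriptions of this step label foreground and background inconsistently;
we fix the polarity by defining *fruit = the intermediate band*: the very
dark stem (B ≤ 20) and the bright tray (B ≥ 90) are both excluded. Both
cut-offs are arguments of `threshold_top()`.

Small-particle removal (`remove_small_particles()`) deletes connected
components below `min_area` (default 500 px for a 1600 × 850 frame, scaled
with frame area) but always keeps the largest component: a grading pipeline
must emit exactly one object per view, so a valid fruit is never deleted
even if a pathological threshold leaves it small. `fill_holes()` then
closes interior holes left by dark spots on the skin. Both operations are
idempotent.

The side view is a mirror reflection: lower contrast, and the fruit casts a
shadow band that survives a single blue threshold. `threshold_side()` runs
three passes (B < 120, G < 110, B < 100 by default), each restricted to the
region surviving the previous pass, with a 7 × 7 median filter between
passes to erase the shadow boundary. The pass values are configuration, not
established constants: a grey shadow is darker than the tray in B (it
passes the first threshold) but brighter than the fruit in G (the second
pass removes it). Users with different lighting should expect to retune
these three values; the ordering B → G → B and the median size are the
stable part of the design.

Boundary extraction is Moore-neighbour tracing of the outer 8-connected
border, started at the topmost-then-leftmost boundary pixel. We treat the
"thinning" step of the original workflow as boundary extraction, since its
output is the shape outline. Orientation is normalised so the shoelace
signed area is negative (the package's clockwise convention); coordinates
are 0-based with pixel centres at integers. Rasterising the trace and
filling reproduces the mask exactly for hole-free masks, which the test
suite exercises.

## Calibration

The scale model is the pinhole relation
`object size = image size × pixel pitch × distance / focal length`, with
the sensor pitch (4.5 µm default) used as the per-pixel size. The side view
sits at the fixed distance h3 + h4 (plane-mirror equal-distance assumption;
the 65° mirror tilt is not modelled, consistent with the method we
implement). The top-view distance h1 is recalibrated per image:
`h1 = h2 − plane_fraction × height`, with the height measured from the side
view. `plane_fraction` defaults to 0.5 because the widest silhouette
section of an ovoid fruit sits near mid-height; descriptions of this
workflow do not pin down where on the fruit the object plane sits, so the
fraction is exposed as configuration rather than fixed.

Because volume scales with the square of the top-view mm/px, the fruit
height enters the error budget quadratically. A binary mask quantises the
height to one pixel (≈ 0.28 mm at the default geometry), which would
dominate all other errors; `mask_extent_px()` therefore estimates the
height sub-pixel by fitting a quadratic to the side-view extent profile
over its plateau (within 6 px of the maximum) and taking the vertex. The
fit falls back to the integer maximum when degenerate (fewer than five
plateau columns, non-concave fit, or vertex off the plateau).

## Shape features

From the boundary we compute the Green's-theorem polygon centroid (the
printed closed-form centroid equations in the source material are garbled;
the polygon centroid is what they approximate), the centroid-distance
signature R(k) in boundary order, a periodic linear-interpolation resample
to 512 points rescaled so the maximum is 100, and DFT magnitudes
`|F(m)| = (1/N) sqrt[(Σ R cos)² + (Σ R sin)²]`. Three conventions needed
fixing:

* summation runs over the N distinct boundary points k = 0..N−1 (the N-th
  point duplicates the 0-th on a closed curve);
* the 1/N factor sits outside the square root (standard DFT magnitude
  normalisation);
* S-features are computed on the normalised 512-point signature, which
  makes them scale-invariant — a fixed feature scale is what makes fixed
  classifier coefficients meaningful.

`s_features()` returns S_p = Σ_{m=1..10} |F(m)| m^p, p = 1, 2, 3. The
size-shape parameters are aspect ratio (max/min Feret diameter; the
minimum diameter is the extent perpendicular to the maximum-Feret
direction, since "min diameter" is otherwise undefined), area ratio
(area/aspect), and roundness `4·area/(π·maxD²)` — we drop the spurious π
of the printed formula so a circle scores exactly 1.

One caveat we deliberately expose rather than hide: the published
classification-function coefficients presume area ratio on the original
acquisition scale, which cannot be reconstructed from the printed setup
(the printed cohort mean is far too small for raw pixel areas at the
stated resolution). `run_config(feature_units = "px" | "mm")` controls the
scale; the shipped coefficients are most meaningful on data whose area
ratio matches their original scale, and retraining
(`train_shape_model()`) is the right path for any new acquisition
geometry.

## Classification

`discriminant_scores()` evaluates per-class linear functions
(constant + coefficient · features); `classify_shape()` takes the argmax
with ties broken deterministically to the first listed class. Training
(`fit_classification_functions()`) uses the pooled within-class covariance
W: coefficients `W⁻¹μ_k`, constants `−½ μ_k' W⁻¹ μ_k + log prior`, equal
priors by default — the priors implied by the shipped constants are not
recoverable, so equal priors are the neutral choice. Stepwise selection
minimises Wilks' Λ = det(W)/det(T) with partial-F thresholds
F-to-enter = 3.84 and F-to-remove = 2.71 (the conventional defaults; the
mechanism is specified but thresholds are not). With those thresholds the
per-feature null entry rate is about 5%, so with three or four noise
candidates the familywise probability that *some* noise feature enters is
15–20%: an informative feature is essentially always selected (and enters
first), but "exactly the informative set" cannot be expected in more than
roughly 85% of replicates. The test suite asserts the rates that the
thresholds actually imply.

## Volume, mass and grade

The disk method revolves each 1-pixel slice into an elliptic cylinder:
`V = Σ π (Δy_i/2)(Δz_i/2) Δx_i`, Δx one top-view pixel in mm. Two
registration details matter more than they look:

* Each view is profiled along its own major axis (principal axis of the
  pixel distribution; rotation is skipped below 0.5° so axis-aligned
  silhouettes are measured exactly).
* The side profile is interpolated at the top profile's physical positions
  (mm relative to each silhouette's centroid), *not* at normalised slice
  indices. Index normalisation stretches one profile over the other's
  slightly different pixel span and systematically inflates the tip
  heights; physical registration removes that bias.

Mass = slope × volume + intercept with the default coefficients
0.9973 g/mL and 6.778 g, refittable by `fit_mass_model()` (ordinary least
squares, constant-density assumption). Grades use half-open intervals
C = [0, 350), B = [350, 400), A = [400, ∞) g — the market table leaves
(349, 351) and (399, 401) unassigned, and half-open intervals make grade
assignment a total function. Misshapen fruit are rejected before volume
estimation and carry no volume or mass in reports.

Agreement statistics use the normal quantile 1.96 for the limits of
agreement (the convention of the validation we mirror), two-sided p-values
throughout, and a degenerate-case error when the paired differences have
zero variance.

## The synthetic scene generator

`fruit_spec()` describes a solid with elliptical cross-sections along the
length axis; the axial radius profile is
`p(t) = sqrt(1 − t²)(1 + taper·t)` on t ∈ [−1, 1], normalised to maximum 1
— the simplest mango-like asymmetric ovoid. Deformations are Gaussian
lobes in angle *and* axial position (`angle`, `amplitude` in mm, `width`
in rad, `center`, `extent` in t), damped by the axial profile so the solid
stays closed. The axial localisation is essential: a deformation spanning
the whole length merely widens the fruit and leaves the boundary smooth,
whereas a localised dent produces the wavy, non-uniform edge that
high-harmonic Fourier features respond to. Misshapen fruit default to 1–3
dents (negative amplitude, 6–12 mm — the "abnormal concavities" that make
graders reject fruit), the first of which is angled near the top-view
silhouette plane: the classifier, like the in-line system it models, sees
only the top view, so the expert-labelled misshapen cohort is emulated as
fruit whose deformation is visible in that view.

`generate_fruit()` integrates the true volume over 10,000 axial slices
(trapezoid over a 720-point angular grid) and projects both silhouettes
through the same pinhole model the calibration inverts, at h1 implied by
the fruit's own height — so the calibration chain can be validated end to
end. `render_scene()` paints flat colours (fruit B ≈ 55, i.e. inside the
top-view band; stem B ≈ 15; shadow B ≈ 105/G ≈ 118, removed by the G
pass; tray B ≈ 236) plus per-pixel Gaussian intensity noise (σ = 2),
dirt specks on the tray and dark spots on the fruit. The default
population draws lengths ~ N(130, 9) mm truncated to [108, 150], width
0.60 × length and height 0.88 × width, chosen so the regular aspect ratio
is about 1.66 and true masses span roughly 280–470 g across all three
grades.

What the generator does *not* emulate: skin texture and colour gradients,
specular highlights, uneven illumination, lens distortion, mirror
foreshortening, fruit touching the tray edge, or multiple fruit per tray.
Passing tests therefore demonstrate that the algorithms are correct under
the stated imaging model — flat-coloured, centred, single fruit with ideal
optics — not that the fixed default thresholds survive arbitrary real
lighting. On real images the thresholds and the feature scale are the
parts to recalibrate.

## Numerical choices and problem sizes

* Boundary tracing is exact integer arithmetic; orientation is fixed by
  the shoelace sign.
* Signature resampling is periodic linear interpolation; 512 points; DFT
  via FFT, checked against a brute-force O(N²) oracle at 1e-9.
* Wilks' Λ and the classification functions use dense determinants and
  solves; singular scatter matrices raise errors rather than
  pseudo-inverses.
* Degenerate guards: zero-area boundaries, empty masks, constant
  regression predictors and zero-variance paired differences all raise
  informative errors.
* Test problem sizes: digital discs/ellipses at radii 50–200 px;
  end-to-end batches of 50 fruit at the full 1600 × 850 frame; training
  cohorts of 60–180 fruit; 100-replicate selection simulations. These
  sizes keep the full suite and the acceptance script each within a few
  minutes on one CPU while leaving the statistical assertions
  well-powered.

## Known limitations

* The shipped classifier coefficients are tied to their original,
  unrecoverable acquisition scale; treat them as a worked reference and
  retrain for any new geometry.
* The disk method assumes elliptical cross-sections; for dented fruit it
  is an approximation (dents are rejected before volume estimation in the
  grading path, so this does not affect reported masses).
* The plane-mirror model ignores the mirror tilt; heights inherit
  whatever bias that introduces on a real rig.
* Stepwise selection inherits the multiplicity behaviour of its F
  thresholds, as quantified above.
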