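---
title: "Methods: end-to-end QA analytics for online adaptive radiotherapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: end-to-end QA analytics for online adaptive radiotherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaptqa)
```

## The problem this package addresses

Online adaptive radiotherapy (ART) re-optimizes the treatment plan to the
patient's anatomy of the day, immediately before delivery. Two AI-driven
steps sit at the heart of the workflow — auto-segmentation of the daily
image and adaptive plan re-optimization — and both must be commissioned and
periodically re-verified. An end-to-end (E2E) phantom test does this by
planting a *known* synthetic deformation in the planning CT of a rigid
pelvis phantom, letting the adaptive system recover it session after
session, and measuring how reproducible the resulting contours and
dose-volume values are. The product of such a test is a set of
*organ-specific action levels*: 95% intervals of the contouring and
dosimetric metrics under repetition, beyond which a future E2E run should
be investigated.

`adaptqa` implements the complete analytic chain for this test — synthetic
deformation generation, contour reproducibility metrics, DVH constraint
evaluation, and the action-level statistics — plus a *surrogate* of the
adaptive system itself (digital phantom, noisy re-segmentation, conformal
dose stand-in) so that the whole pipeline is runnable and testable with no
proprietary system and no external data.

## Gaussian deformation model

A deformation instance is the three-parameter field

$$ d_a(r) = m_a \exp\!\left(-\frac{\lVert r - c\rVert^2}{2\sigma^2}\right),
\qquad a \in \{x, y, z\}, $$

with per-axis magnitude $m$ (mm, the displacement exactly at the center
$c$) and isotropic fall-off $\sigma$ (mm). Randomized instances draw $c$
uniformly inside a rectangular box inscribed in the PTV (default
$22.3 \times 10.6 \times 62$ mm, left-right / anterior-posterior /
superior-inferior), one shared magnitude $|m| \sim U(10, 20)$ mm with an
independent random sign per axis (matching the equal-magnitude pattern of
the five reference instances bundled as `reference_deformations()`), and
$\sigma \sim U(15, 25)$ mm.

Two modeling choices deserve emphasis:

* **Functional form.** The parameterization names only "magnitude, center,
  standard deviation"; we adopt the isotropic Gaussian above because it
  makes the at-center displacement equal the printed magnitude — which is
  also what the acceptance checks verify exactly.
* **Warp convention.** Fields are applied by *pull-back* resampling,
  `output(x) = input(x + d(x))`, the convention of common registration
  toolkits; masks use nearest-neighbor sampling, images trilinear.

### Local invertibility is not guaranteed

For $d(r) = m\,w(r)$ the spatial Jacobian of $\varphi(x) = x + d(x)$ is a
rank-one update of the identity, so
$\det J = 1 + m \cdot \nabla w$, minimized over space at
$1 - \lVert m\rVert e^{-1/2}/\sigma$. Four of the five reference instances
are fold-free, but instance 3 ($\lVert m \rVert = 18.8\sqrt{3} \approx
32.6$ mm, $\sigma = 15.6$ mm) has a minimum determinant of about $-0.27$: a
genuine local fold. The test suite asserts this closed-form bound (numeric
central-difference minima agree with it) rather than a blanket positivity
claim. For QA purposes a locally folding field is still a usable
perturbation — the phantom test needs a *known, repeatable* deformation,
not a diffeomorphism — but users composing fields or inverting them should
prefer $\lVert m \rVert < \sigma e^{1/2}$.

## The digital phantom and the adaptive-process surrogate

The proprietary adaptive system (and the physical phantom's interior) are
out of scope; `adaptqa` replaces them with parametric stand-ins whose only
job is to produce *plausible topology and controllable repeatability*:

* **Phantom** (`build_phantom()`): ellipsoid prostate, bladder and seminal
  vesicles, tubular rectum, bowel region, two spherical femoral heads and
  an elliptic-cylinder body on a $128 \times 128 \times 96$ grid at 2 mm
  isotropic spacing. The grid is placed so the prostate sits at the mean of
  the five reference deformation centers, keeping all of them inside the
  PTV. Derived targets follow the planning convention: CTV_7000 = prostate
  ∪ seminal vesicles, PTV_7000 = prostate expanded by a 5 mm Euclidean
  margin. Prostate, bladder and rectum are made pairwise disjoint by
  precedence; all soft tissue is clipped to the body.
* **Re-segmentation** (`simulate_autoseg()`): the truth surface is warped
  by a smooth random vector field — white Gaussian noise filtered at a
  correlation length (default 8 mm) and rescaled to a per-component
  standard deviation $\sigma_b$ — then resampled. $\sigma_b$ is the single
  dial for contour repeatability. The defaults (`default_seg_noise()`)
  encode the qualitative organ ranking expected of AI-assisted adaptive
  contouring: uncorrected "AI" contours are noisier for the prostate,
  target volumes and bladder (2.5–3 mm) and *tighter* than corrected ones
  for bowel, femora and rectum (0.5–0.9 mm); "corrected" contours tighten
  the targets/bladder to ~1.2 mm. On the 2 mm grid, displacement noise well
  below half a voxel rarely flips a surface voxel, so sub-millimeter
  $\sigma_b$ yields near-perfect repetitions — the reason the defaults stay
  at or above 0.5 mm.
* **Dose** (`simulate_dose()`): prescription dose (70 Gy) inside the PTV,
  multiplied outside by a Gaussian of the PTV distance map with a
  plan-style penumbra (VMAT-like 6 mm, narrower for conformity; IMRT-like
  8 mm), plus seeded additive noise capped at 1% of Rx. This is a distance
  map construction, not an optimizer: it provides per-fraction dose
  variability (through the segmentation-dependent per-fraction PTV) and a
  systematic plan-type difference, which is all the interval statistics
  need. It does not model beams, leaf sequencing, or hot spots, so PTV
  Dmax sits essentially at Rx rather than the 105–110% typical of real
  optimized plans.

**What passing tests do and do not show.** The surrogate validates the
*analytics*: that STAPLE, the metrics, the ANOVA pooling rule and the
interval machinery do the right thing on data with known structure. It
does not validate the adaptive system itself, and its noise model (smooth,
stationary, organ-independent direction) omits real failure modes such as
systematic boundary bias, slice-wise artifacts, or anatomy-dependent
errors. Action levels derived from the surrogate characterize the
surrogate, not a clinical system.

## The virtual study design

`run_virtual_study()` enumerates the fractionation layout: 5 deformation
instances × 26 adapted fractions = 130 records, each fraction split 13
IMRT / 13 VMAT, with the first 3 fractions of each plan type carrying
uncorrected AI contours and the remaining 10 corrected ones. The layout
itself is a light tibble; masks and doses are realized lazily
(`realize_fraction()`), per record, from seeds derived deterministically
from the master seed — the full study never holds 130 × 9 volumes in
memory. All per-ROI computation happens on fixed padded bounding boxes
(one crop per ROI, shared by all fractions) so repetitions stay on a
common geometry.

## Contour reproducibility metrics

For every repetition group — one (ROI, deformation, plan type, correction
mode) cell — a STAPLE consensus is estimated and each repetition is
compared to it:

* **STAPLE** (`staple()`): EM with per-rater sensitivity/specificity,
  initialized at $p_j = q_j = 0.99$, foreground prior `auto` = mean
  foreground fraction of the inputs, convergence when the mean absolute
  per-voxel weight change falls below $10^{-6}$ (max 100 E-steps;
  non-convergence is flagged, not thrown). Consensus is weight ≥ 0.5, ties
  counting as foreground — with shared $(p, q)$ and prior 0.5 the first
  E-step is exactly a majority vote, which the tests exploit as an oracle.
  For efficiency the EM runs on the padded bounding box of the mask union;
  the reported specificities are relative to that region.
* **Dice** is the usual overlap ratio; two empty masks are defined to
  agree (Dice 1) and warn.
* **mSSD** (`mean_symmetric_surface_distance()`): surface voxels are
  inside voxels with a face-adjacent outside voxel (6-neighborhood,
  beyond-grid counts as outside); distances are exact Euclidean world-space
  distances via an anisotropic distance transform; the default variant is
  the *pooled* symmetric mean (one mean over the union of both directed
  distance sets), with the averaged-directed-means variant available — the
  two differ only when the surfaces have unequal voxel counts. The metric
  is fully 3-D; no sub-voxel meshing and no slice-wise contour distances.

## DVH engine

Cumulative DVHs are tabulated at 0.05 Gy bin edges (fraction of structure
voxels at or above each edge; exact at edges, linear between). $D_{v\%}$
interpolates the curve ($D_{100\%}$ returns the minimum structure dose);
$V_{d\,\mathrm{Gy}}$ returns percent or absolute cm³. Dmax is the point
maximum voxel dose — the simplest reproducible convention, chosen because
the template does not specify a near-max volume statistic. "% of Rx"
limits are evaluated against the total-course prescription (70 Gy) by
default, with a per-fraction option. Pass/fail is stable under bin
refinement (tested at 0.05 vs 0.01 Gy).

## Action-level statistics

The pooling question — may the five deformation instances be lumped into
one interval per ROI? — is answered by a per-ROI one-way fixed-effects
ANOVA across deformation groups, computed from explicit sums of squares
(and cross-checked against the reference implementation to $10^{-8}$ in
tests). The operational rule: pool when $p \ge \alpha$ (default 0.05),
otherwise stratify per deformation and flag the ROI. P values are reported
raw, without multiplicity correction across the eight ROIs — the flagging
is a screening device with a known ~5% false-positive rate per metric, not
a confirmatory test (the type-I error of the rule is itself verified by
simulation). The same machinery runs on both Dice and mSSD.

Intervals (`interval_95()`) are estimated directly from the metric
distributions, by default as empirical 2.5th/97.5th percentiles with
linear interpolation (a normal-theory mean ± 1.96 sd option is provided);
Dice intervals are clipped to [0, 1], distances to [0, ∞). Contour
intervals pool fractions × deformations (when pooling is justified); dose
constraint intervals are *always* stratified by plan type, because plan
styles differ systematically, with deformations pooled within plan type.

## Numerical choices

* Grids are axis-aligned, 0-based, voxel-centered, with no direction
  matrix; geometries compare equal within $10^{-6}$ mm.
* The Euclidean distance transform is the exact separable
  parabola-envelope algorithm with per-axis spacing weights (compiled);
  margin expansion thresholds the distance at margin + $10^{-9}$ mm to
  absorb roundoff.
* MetaImage I/O is double-precision and bit-exact on roundtrip; NIfTI-1
  stores its affine in float32, so geometry roundtrips through `.nii` are
  exact only to ~$10^{-4}$ mm.
* A structure set is stored as a single uint8 labelmap plus a YAML name
  table; overlapping masks are resolved by listed priority (first wins),
  so derived targets (CTV/PTV/Body) are best excluded and recomputed after
  loading.
* All randomness flows through per-purpose seeds derived from one master
  seed; the pipeline's output tables are byte-identical across repeated
  runs with the same seed.

## Problem sizes used in the test suite

Unit tests run on small grids (≤ $16^3$ for brute-force oracles, a
4 mm-spacing phantom sharing the default world extent for surrogate
checks). The acceptance suite additionally runs the full default design —
5 deformations × 26 fractions × 8 ROIs on the 2 mm phantom grid — once,
end to end; on one CPU this takes on the order of two minutes.

## Known limitations

* The phantom is topological, not anatomical; no image texture, no CBCT
  physics, and HU values are nominal per tissue class.
* The dose surrogate has no optimizer, no hot spots and no
  scheduled-vs-adapted comparison; plan-type differences reduce to the
  penumbra parameter.
* Deformable registration (recovering the applied field) is deliberately
  out of scope — in the physical test that role belongs to the adaptive
  system under test.
* Sharp deformations can locally fold (see above); fields are not
  guaranteed diffeomorphic.
* mSSD is voxelized: distances are between surface voxel centers, so
  sub-voxel surface differences are quantized by the grid.
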