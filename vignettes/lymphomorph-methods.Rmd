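---
title: "Models, estimators and design choices in lymphomorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, estimators and design choices in lymphomorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`lymphomorph` quantifies lymph-node (LN) compartments in 3D label volumes,
registers 2D micrographs to 3D volumes by mutual information, and runs the
differential-abundance and enrichment statistics used for bulk LN
proteomes. Because whole-organ synchrotron volumes are not practically
redistributable, every quantitative claim the package makes is validated
against *synthetic phantoms with known ground truth*. This vignette
describes the phantom model, the estimator conventions, the parameters
that matter, and the choices made where the design was genuinely open.

## The synthetic LN phantom

### Geometry

The phantom is an ellipsoidal LN (semi-axes `ln_radii_um`, axis order
z,y,x) built from concentric shells in the normalized ellipsoid coordinate
`rho`:

* an **adjacent-tissue** rim outside the organ (`rho` in (1, 1.10]);
* a **capsule** (3.5% of the normalized radius, labelled parenchyma — the
  eleven-class map has no separate capsule class);
* a **subcapsular sinus** shell (3.5%);
* an interior split into a **deep cortical unit** (DCU) — an ellipsoidal
  core displaced towards the +z pole — a **medulla** (the interior cap
  with normalized z below −0.05, minus the DCU), and **cortex** (the
  rest).

The medulla is permeated by a **medullary sinus** network: a jittered
lattice of tubes (spacing 54 µm, radius 7 µm) along the two in-plane axes,
so that every medullary point lies within a few tens of micrometres of a
sinus — the structural property the medulla test of the nodule classifier
relies on. **Follicles** are spheres placed in the cortical rim away from
the medullary boundary; **nodules** are random-orientation ellipsoids with
minor/major axis ratios uniform on [0.7, 1.0] (the spherical-to-ovoid
range) placed in the medulla and wrapped in a one-voxel medullary-sinus
rind, mirroring the lymphatic-endothelial encapsulation of the real
aggregates; **adipocytes** are spheres near the cortico-medullary border.
Placement is rejection sampling (cap 10 000 attempts per object, error
naming the host compartment on failure) with a two-voxel exclusion margin,
which guarantees that distinct objects never merge under 26-connectivity —
the property that makes component counts exact ground truth.

**Capillaries** are laid down per compartment as ~3-voxel-thick random
tube segments (length 40–80 µm) until the compartment's capillary voxel
fraction reaches its target, with two refinements: the final tube is
truncated so the realized count lands exactly on target, and tube voxels
are kept strictly interior to the compartment (no face contact with other
classes). The second rule makes the nearest-compartment attribution used
by `capillary_density()` exact by construction; without it, chord ends
touching a nodule's sinus rind leak attribution and bias density ratios
low by ~15%.

Intensity is a fixed per-class base level plus Gaussian noise
(`noise_sd`, default 0.04), ordered as in the imaging contrast convention
(cell-dense follicles and nodules brightest; sinuses, vessels and fat
darkest). No published intensity statistics exist for the classes, so the
contrast is stipulated, not fitted — phantoms carry the *geometric and
statistical* structure of the data, not CT texture, beam hardening,
phase-retrieval artifacts, or vascular tree topology. Tests passing on
phantoms therefore validate the measurement machinery, not robustness to
scanner physics.

### Size laws and scales

Object size laws are stated at the *unshrunk* ("true") tissue scale and
truncated at ±2 SD (symmetric truncation keeps the mean; unbounded tails
would produce non-physical objects). The default nodule law is the
corrected-scale distribution 128.57 ± 38.57 µm (= 90/0.7 and 27/0.7).
`generate_phantom(..., scale = "embedded")` — the default — multiplies all
object sizes by (1 − `shrinkage_s`), rendering the resin-embedded specimen
the scanner sees directly; `scale = "true"` renders native tissue, to
which `simulate_shrinkage()` can then be applied. Shrinkage resamples onto
a grid of `round(dim * (1 - s))` voxels (trilinear for intensities,
nearest-neighbour for labels) with the voxel size unchanged: the tissue
shrinks, the instrument does not.

### The packaged study configurations

`fixture_table()` / `phantom_config()` pin the configurations used by the
acceptance script, rendered at 4.5 µm voxels — a desk-scale sampling of
the same geometry (the default spec keeps the native 1.8 µm; at that
resolution the fixture LNs would need ~10⁸ voxels). The LN semi-axes are
derived analytically from the printed target fractions: with the truncated
nodule law, E[D³] = µ³ + 3µσ²·c (c = 0.774, the ±2σ truncation's variance
factor) and mean axis-ratio product 0.85², the expected nodule volume is
≈333 000 µm³, so an "old" LN carrying 59.5 nodules at 4.7% of its volume
must measure ≈4.2·10⁸ µm³, and similarly 1.9% for the young pair and 0.26%
for the 15-adipocyte young popliteal node (adipocyte diameters uniform
40–90 µm native). Per-phantom nodule counts are 28/29 (young) and 59/60
(old), making the pair means 28.5 and 59.5 exactly when every placed
nodule is recovered.

Capillary fractions default to a 2% DCU baseline — a physiological
capillary volume fraction for lymphoid tissue — with follicles at 2.2× and
nodules at 2.18×, the published density ratios. The *counting* fixtures
omit intra-nodular capillaries: carving tunnels through small nodules
inflates their face-count surface area and can push sphericity below the
0.6 acceptance floor, which would make the generator's ground truth
inconsistent with its own criteria. The vasculature phantom (where
densities, not object identities, are measured) keeps the full map.

## Preprocessing conventions

* **Background subtraction** is subtraction-based (`img − blur(img) +
  mean(img)`); the source tooling's wording is ambiguous between
  subtraction and division, and subtraction preserves additive noise
  models. The global mean is added back to keep 8-bit convertibility.
  The Gaussian blur is a separable row-normalized band-matrix convolution
  (replicate-equivalent boundaries), well defined even when the kernel
  support (σ = 300–500 px) exceeds the image.
* **Unsharp mask** uses the renormalized subtractive form
  `(img − w·blur)/(1 − w)`, the common imaging-software meaning of
  "weight"; constants are invariant.
* **Flat-field correction** divides by the Gaussian-blurred feature-empty
  reference (σ_ff default 50 px, configurable) with an ε-guard and unit-mean
  rescaling.
* **Stitching** re-estimates per-tile offsets by phase correlation in the
  nominal overlap window (±8 px search, ties to the smallest
  displacement), then composites with feathered linear blending whose
  weights sum to one wherever coverage exists. The phase correlation uses
  a Hann window and regularized spectral whitening (denominator floored at
  1% of the peak magnitude): plain whitening fails on smooth micrographs
  because numerically dead high frequencies dominate.
* **8-bit export** is deliberately not part of the analysis path; all
  analysis runs in float.

## Registration

The virtual slice at pose (rx, ry, rz, tx, ty, tz) samples the volume by
trilinear interpolation on a plane through the volume centre voxel
(`floor(dim/2)+1`), rotations applied in z·y·x order, translations in
voxels; out-of-volume samples are filled with 0 and *masked out* of the
metric rather than penalized. The in-plane affine (shear `x' = x + k·y`,
anisotropic scale, rotation) composes with the pose into a single sampling
transform, so the model view that is compared against the micrograph is
interpolated exactly once.

The similarity metric is dense joint-histogram mutual information
(64 bins, per-image min–max binning, bits). The published description
says the pipeline *minimizes* the MI metric; MI is maximal at alignment
(that is what the contrast-inversion step is for), so the package
maximizes MI, equivalently minimizing its negative. An optional
`binarize` switch scores median-thresholded images with a 2-bin histogram
at every level, for data where threshold-based binarization is the
effective representation.

The optimizer is a deterministic coordinate-descent hill-climb over the
fixed parameter order (tz, rx, ry, tx, ty, theta2d, sx, sy, k): ± one step
per parameter per sweep, steps halved after a sweep without improvement,
per level of a block-mean image/volume pyramid (default factors 8, 4, 2,
1); candidate views overlapping the volume by less than 50% are rejected.
Determinism was preferred over stochastic optimizers so registrations are
bit-reproducible; the cost is occasional capture failure on poses near the
edge of the ±10°/±10-voxel capture range, which the result flags
(`converged = FALSE`) rather than hides. Note rz is not optimized: for an
identity-orientation plane it is nearly degenerate with the in-plane
rotation theta2d. Zoom refinement freezes the plane orientation (rx, ry,
tz) and re-optimizes only in-plane parameters from the overview prior.

On the packaged 128³ registration phantom, 20 random ground-truth poses
(|rotations| ≤ 10°, |translations| ≤ 10 voxels, shear ≤ 0.1) are recovered
with median absolute errors of ~0.05°, ~0.06 voxels and ~0.0006 in shear —
comfortably inside the 1° / 2-voxel / 0.02 targets the tests assert.

## Morphometry conventions

* **Components**: 26-connectivity, deterministic ordering by the (z, y, x)
  of each component's first voxel, `min_voxels` filtering.
* **Feret diameter**: maximum pairwise Euclidean distance between
  surface-voxel centres *plus one voxel* (a single voxel has Feret = voxel
  size). Large surface sets are first reduced to their support points —
  extrema along 256 Fibonacci-lattice directions, a subset of the convex
  hull vertices — before the exact pairwise maximum; unit tests confirm
  equality with brute force. On smooth digital objects the whole chain
  (voxel-centre rasterization, nearest-neighbour shrinkage, extreme-point
  caliper) carries a systematic *positive* bias of ~1–1.5 voxels, which is
  why the isolated-nodule size study measures at half the acquisition
  voxel (0.9 µm) — halving the bias — and why sub-voxel agreement with
  continuous diameters should not be expected at 4.5 µm.
* **Sphericity**: ψ = π^(1/3)(6V)^(2/3)/A with A from exposed-face
  counting times a 0.735 lattice correction (the reciprocal of the 1.5
  overcount of axis-aligned faces for randomly oriented smooth surfaces).
  The estimator's sphere asymptote is 1/(1.5·0.735) ≈ 0.907; digital balls
  reach ψ ≥ 0.9 above ~120 µm at 1.8 µm voxels, and a 1×1×20 voxel rod
  scores 0.59 — well below the 0.6 nodule floor, though above the 0.47 of
  the analytic continuous cylinder (whose volume is π/4 of the voxel
  rod's).
* **Nodule criteria**: medullary localization (any medullary-sinus voxel
  within 45 µm of the object surface — the medulla *is* the sinus-bearing
  region, and phantom nodules carry a sinus rind), sphericity ≥ 0.6,
  Feret within 30–180 µm at embedded scale, ≥ 50 voxels. All thresholds
  are configurable. The fourth published criterion — a LYVE-1⁺ lymphatic
  boundary — requires molecular imaging and is not computable from label
  geometry; it is documented as excluded.
* **Capillary density** is defined as the capillary voxel fraction
  attributed to a compartment: attributed / (compartment + attributed),
  with attribution by majority over each capillary voxel's non-capillary
  6-neighbours, propagated iteratively into tube interiors (nearest
  non-capillary label). Whether published density ratios are ratios of
  means or means of per-LN ratios is not stated; `density_ratio()`
  operates on whatever `compartment_stats` objects the user supplies, so
  both are one line.
* **Shrinkage correction** is the exact linear inverse d/(1 − s), default
  s = 0.30; volume corrections are its cube and are left to the caller.

## Proteomics statistics

Per-protein differential testing over the site × age design follows the
adaptive scheme: Shapiro–Wilk in *each* contrast group (pooled "mean"
contrasts test the two pooled site groups); only if all groups pass
(p > 0.05) is a two-sided **Welch** t-test used (the unequal-variance form
is the robust default where pooled vs Welch is unspecified), otherwise a
two-sided Wilcoxon rank-sum (exact when both n ≤ 8 without ties, normal
approximation with continuity correction otherwise). Zero-variance groups
cannot be normality-tested and route to Wilcoxon. Proteins quantified in
under 60% of either group's samples are dropped — the missingness rule is
the package's own, as the source pipeline is silent on it. q-values are
Benjamini–Hochberg. The age-independent filter removes proteins with
log₂FC > 0 and q ≤ 0.05 in *both* per-site old-vs-young comparisons
(thresholds exposed, not asserted as the source's). On simulated data
(400 proteins, n = 10/group, 1.5-log₂ site effects) the suite checks
empirical FDR ≤ 0.10 and power > 0.8 at q ≤ 0.05, and a 1000-protein null
keeps the p ≤ 0.05 rejection rate within 0.05 ± 0.015.

ssGSEA is the rank-weighted running sum (descending abundance ranks,
average ties, weight rank^0.25, score = summed difference between the
weighted in-set and uniform out-set ECDFs), invariant to monotone
per-sample transforms; row-z scores are provided for visualization.
Pre-ranked GSEA uses the classic weighted Kolmogorov–Smirnov ES
(weight |t|) — verified against `fgsea::calcGseaStat` — with a
deterministic permutation null of random same-size sets:
NES = ES / mean(|null ES| of the same sign),
p = (1 + #{|null| ≥ |ES|})/(1 + nperm). The adaptive multilevel p-value of
fgsea is deliberately replaced by this plain permutation p for
determinism at desk scale. Moderated-t models are out of scope; ordinary
Welch t statistics feed the ranking. Total-abundance normalization
(`normalize_total`) emulates normalization to total protein amount as
per-sample total-sum scaling before log₂.

## Problem sizes and numerical conventions

The shipped configurations are sized for a single CPU: fixture phantoms of
7–12 million voxels at 4.5 µm, a 256³ vasculature phantom, a 128³
registration phantom, 200 isolated nodules at 0.9 µm, and 400–1000-protein
simulations; the full acceptance recomputation takes about two minutes and
the test suite a few minutes. All stochastic paths take explicit seeds and
restore the caller's RNG state (`with_seed`); identical spec + seed is
bit-identical output, which the suite asserts. Degenerate inputs error
loudly: empty compartments, s ≥ 1, non-positive scale factors (degenerate
affines), disconnected mosaics, empty set intersections, p-values outside
[0, 1]. Ties in the optimizer keep the current value; ties in capillary
attribution break to the smaller class code; complete-tie Wilcoxon
comparisons report p = 1.

## Known limitations

* Phantoms stipulate class contrast and contain no reconstruction
  artifacts; registration performance on real, artifact-laden scans will
  be worse than the phantom medians reported here.
* The vascular model is geometric (random tubes), not topological: no
  branching hierarchy, no arterio-venous structure.
* The medulla test of the nodule classifier presumes segmented medullary
  sinuses; label maps without that class cannot apply criterion (i).
* The caliper convention's ~1-voxel positive bias means absolute Feret
  values at coarse voxels should be interpreted with that margin in mind.
* Deformable registration, GPU execution and multi-start global search
  are out of scope by design.
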