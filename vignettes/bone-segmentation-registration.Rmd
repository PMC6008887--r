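---
title: "Cortical bone segmentation in 3D ultrasound and surface-based CT registration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cortical bone segmentation in 3D ultrasound and surface-based CT registration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Computer-assisted orthopedic surgery needs the preoperative CT model of a
bone registered to the patient on the table. Tracked ("freehand") 3D
ultrasound is an attractive intraoperative modality for this — safe, cheap,
real time — but bone in ultrasound is indirect: the cortex appears as a
bright specular line a few millimetres wide with an acoustic shadow beneath
it, embedded in speckle. `bonecho` implements an automatic pipeline for this
setting:

1. **Sheet enhancement.** Second derivatives of the intensity volume are
   estimated by convolution with sampled Gaussian-derivative kernels; the
   eigenvalues $\lambda_1 \ge \lambda_2 \ge \lambda_3$ of the per-voxel
   Hessian are combined into a sheetness score
   $S = |\lambda_3|\,\omega(\lambda_2;\lambda_3)\,\omega(\lambda_1;\lambda_3)$
   (for $\lambda_3 < 0$, else 0), which is large exactly where the local
   structure is a bright sheet — the cortical echo — and small for tubes,
   blobs and speckle.
2. **Voxel classification.** Each voxel carries the feature vector
   $(I, E, \mu, \sigma^2, \gamma)$: raw intensity, enhanced value, and the
   mean, variance and skewness of the enhanced values in a $9^3$ window. A
   Gaussian Bayes (quadratic discriminant) classifier with classes *bone*,
   *soft tissue* and *acoustic shadow* is trained on a small annotated block
   ($150^3$ voxels); a voxel is bone only when the bone discriminant strictly
   beats both others.
3. **Surface extraction.** Seeds are the top 0.01 % of classified bone voxels
   by bone score; 26-connected region growing restricted to the classified
   mask turns them into one connected sheet, which is meshed by isosurface
   extraction at level 0.5.
4. **Registration.** The preoperative CT surface mesh is registered to the
   ultrasound mesh in two stages: orthogonal-Procrustes alignment of 3–4
   coarsely picked landmark pairs, then point-to-point ICP on random
   2000-vertex subsets of both meshes.

Everything runs on synthetic phantoms with known ground truth, so accuracy is
measured end to end without any external data: the segmentation error is the
mean distance from ultrasound-mesh vertices to the nearest vertex of the true
cortical center surface, and the target registration error (TRE) is the mean
distance between corresponding vertices of the ICP-registered CT mesh and the
exactly posed reference CT mesh.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `sigma_mm` | 0.5 mm | Gaussian scale of the Hessian; kernel truncated at $3\sigma$ |
| `alpha`, `gamma` | 0.5, 1 | sheetness weight asymmetry and sharpness |
| `window` | 9 | cubic window (voxels) for the moment features |
| `seed_fraction` | $10^{-4}$ | share of bone voxels used as growth seeds (floor 1) |
| `n` (ICP) | 2000 | random vertex subset per mesh |
| ICP stop | $10^{-6}$ mm / 200 it. | RMS-change tolerance and iteration cap |

The filter scale deserves a note. The sheetness response to a Gaussian
cross-section echo of scale $\sigma_e$ has width
$\sqrt{\sigma^2 + \sigma_e^2}$, so large $\sigma$ smears the very centerline
the method is after. With 2–4 mm echo widths ($\sigma_e \approx 0.5$–1 mm), a
0.5 mm filter — about the axial resolution of a 7.5 MHz probe — keeps the
response compact while still suppressing voxel noise; segmentation accuracy on
the synthetic phantom is flat across $\sigma \in [0.35, 0.75]$ mm, so the
choice is not delicate. Derivative kernels are moment-normalized (zeroth
kernel sums to 1; the second-derivative kernel annihilates constants and maps
$x^2$ to exactly 2), which makes the discrete operator exact on quadratics and
keeps eigenvalues in physical units (mm$^{-2}$) on anisotropic grids.
Convolutions use reflect padding: zero padding would fabricate a strong ridge
at the top of the volume.

Numerical details that affect reproducibility: eigenvalues come from the
closed-form trigonometric solution for symmetric $3\times 3$ matrices (exact
ordering $\lambda_1 \ge \lambda_2 \ge \lambda_3$ by signed value); skewness is
defined as 0 in zero-variance windows (otherwise constant shadow would be
undefined); classifier covariances get a ridge $10^{-6}\,\mathrm{tr}/5$ only
if Cholesky fails, and genuinely singular classes are an error; discriminant
ties go to background, matching the strict inequalities of the labeling rule;
seed ranking breaks score ties by voxel index; nearest-neighbour ties resolve
to the lowest vertex index; all subsampling runs under an explicit seed
without touching the caller's RNG stream.

## The isosurface

No marching-cubes implementation was available to build on, so the package
extracts isosurfaces with the tetrahedral member of that algorithm family:
every cell between eight voxel centers is split into six tetrahedra around a
fixed main diagonal, and each tetrahedron contributes 0–2 triangles with
vertices linearly interpolated along its edges. Because every cell is split
the same way, shared faces conform and the surface is watertight away from
the volume boundary (verified by Euler characteristic on closed test shapes).
The per-tetrahedron cases are derived in code rather than transcribed from
the classical 256-entry cube tables, trading some extra triangles for
correctness by construction. On a binary mask at level 0.5 the vertices fall
midway between inside and outside voxel centers, i.e. within half a voxel of
the true boundary.

## Registration design

ICP is the classic point-to-point variant: exact nearest-neighbour
correspondences through a kd-tree, closed-form rigid update (Kabsch with a
reflection guard), iterated until the RMS closest-point distance stalls. The
recorded RMS sequence is provably non-increasing, which the tests assert on
random inputs. One asymmetry matters: the ultrasound mesh covers only the
insonated patch of the bone while the CT mesh is the whole surface, so
correspondences are drawn *from* the ultrasound subset *into* the CT subset
and the fitted transform is inverted to map CT into the ultrasound frame.
Matching in the opposite direction would let the CT underside — which no
ultrasound beam ever saw — drag the fit toward the visible sheet. No
correspondence rejection or trimming is used; partial-overlap robustness
beyond the direction choice is out of scope.

## What the phantom emulates — and what it does not

The generator renders a long-bone phantom under a downward beam: per column,
speckled soft tissue above the surface, a bright echo sheet with a Gaussian
profile in surface-normal distance (full width 2–4 mm, default 3 mm,
$\sigma_e = w/4$) centered on the true surface, and an attenuated shadow
below. Choices worth knowing, with their reasoning:

* **Geometry.** A 6 mm-radius shaft with a rounded-triangular cross-section
  (3$\varphi$ harmonic, relative amplitude 0.15) and an azimuthally
  asymmetric plateau flare (2.5 mm amplitude) at one end. Tibial shafts are
  triangular and tibial plateaus asymmetric; beyond realism this matters
  because a surface of revolution leaves roll unobservable to any surface
  registration — with a plain cylinder, ICP residual rotations of 10–15°
  about the bone axis occur regardless of implementation. Sections are drawn
  so the plateau is always inside the scan, mirroring acquisition protocols
  that always include it: the shaft alone cannot pin down axial slide.
* **Speckle.** Multiplicative log-normal noise ($\sigma_{\ln} = 0.35$) on a
  correlated Gaussian field with 0.45 mm lateral / 0.25 mm axial cells — the
  speckle-cell scale of a 7.5 MHz probe. White voxel noise would be far too
  easy: an 0.5 mm filter averages it away almost completely.
* **Specularity.** The echo amplitude carries a $\cos^2$ directivity in the
  beam-to-normal angle (the bright line fades where the bone turns away from
  the probe) and a smooth 1 mm-correlation gain modulation at 40 % of the
  tissue speckle log-sd: a coherent specular reflection fluctuates less, and
  more smoothly, than diffuse scattering. Without directivity the phantom
  grows physically impossible bright smears along grazing columns.
* **Annotations.** The training truth marks the cortical line as a thin band
  (±0.15 mm about the centerline, only where the line is visibly bright),
  with tissue and shadow regions painted up to it save a 0.1 mm imprecision
  margin — the way a human annotator partitions a training volume. The
  adjacency is load-bearing: if tissue/shadow annotations stop millimetres
  short of the line, the classifier never learns that flank-like features are
  *not* bone and claims the entire echo band.
* **Intensity scale.** 8-bit-like: tissue mean 55, echo amplitude 110, shadow
  at 12 % of tissue.

Not emulated: reverberation and refraction artifacts, beam-width dependent
lateral blur, freehand sweep reconstruction gaps, tissue inhomogeneity, and
the bright clutter (fascia, reverb layers) that real tissue contributes to
the training classes. Passing the synthetic suite therefore demonstrates the
pipeline's correctness and its geometric accuracy under controlled,
realistic-contrast conditions — not performance on clinical images.

## Problem sizes and observed accuracy

The evaluation protocol uses a single-acquisition run at $200^3$ voxels
(0.115 mm isotropic, classifier trained once on a $150^3$ block) and a
12-experiment suite at $160^3$ with per-experiment random sections, attitudes
and rigid poses (rotations up to 30°, translations up to 20 mm, 2 mm-jittered
landmarks). These sizes keep a full evaluation within minutes on one CPU
while preserving the physical voxel size, so millimetre errors are directly
comparable with full-scale volumes.

On these phantoms the pipeline segments the cortical centerline with mean
errors around 0.36–0.43 mm and registers the CT mesh with per-experiment mean
TREs from under 0.2 mm to about 1.1 mm (overall mean ≈ 0.5 mm) — the numbers
printed by `scripts/acceptance.R`, which recomputes them from scratch.

A structural limitation is worth stating plainly. The segmented surface is a
*band* (the set of voxels the classifier calls bone), and its mesh has two
faces at roughly ± the classification half-thickness from the centerline, so
the mean vertex-to-truth distance is bounded below by that half-thickness.
With a 3 mm Gaussian echo, the enhanced profile varies by well under a
percent within a voxel of the crest; no quadratic discriminant on these
features can place the class boundary much closer than ~3 voxels (0.35 mm)
to the centerline at realistic class spreads. Mean errors below ~0.25 mm on
this phantom would require a materially sharper echo model or a thinning step
(e.g. per-beam response-maximum extraction) that the pipeline deliberately
does not include.

## Reproducing the evaluation

```r
library(bonecho)

# one synthetic acquisition, trained once, segmented, evaluated
spec  <- phantom_spec(shape = c(200, 200, 200), noise_seed = 1)
model <- train_phantom_model(spec)
ph    <- generate_phantom(spec)
seg   <- segment_bone(ph$volume, model)
surface_distance(seg$mesh, ph$truth$center_surface_mesh)$mean

# the full 12-experiment suite (segmentation + registration)
suite <- run_experiment_suite(n_experiments = 12, base_seed = 1)
print(suite)
```

`Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json` runs
both at full size and writes the four summary numbers as JSON.
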