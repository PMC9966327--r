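---
title: "Statistical fracture-line and fragment mapping: models and methods"
author: "fracmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical fracture-line and fragment mapping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Complex proximal humerus fractures break the bone into several cortical
fragments — typically head, shaft and the two tuberosities — often with
zones of comminution where cortical bone is lost. Understanding where
fracture lines run and where bone stock is reliably preserved across a
patient population requires three ingredients: per-case reconstruction
(which voxels belong to which fragment, and where each fragment's border
runs), normalization (putting every case's fragments back into a common
anatomical position), and population aggregation (transferring all cases
onto one average anatomy and counting).

`fracmap` implements this entire chain as testable, deterministic code:

1. **Segmentation** — cortical bone is pre-segmented by a locally adaptive
   threshold; connected components identify detached fragments; fragments
   still joined by partial-volume bridges are separated by marker-driven
   removal of high-gradient voxels.
2. **Fracture lines** — each fragment is meshed, high-curvature border
   candidates are detected on the surface, and the fragment border is
   traced as a least-cost path through guide markers.
3. **Virtual reduction** — fragments are registered (rigid ICP) onto the
   mirrored intact contralateral bone, and the traced lines are projected
   onto that template by exact closest-point matching.
4. **Statistical shape model** — the intact cohort (right bones mirrored to
   the left) is aligned by generalized Procrustes analysis of named
   landmarks densified along surface geodesics; a mean surface with dense
   per-case correspondence is built by thin-plate landmark warping plus
   closest-point refinement.
5. **Probability maps** — every case's projected fracture lines and reduced
   fragment areas are pulled through the correspondence onto the mean
   surface and accumulated into per-vertex case counts: the fracture-line
   map and the fragment (bone-presence) map, whose complement marks
   comminution-prone zones.

Because no clinical data ship with the package, a parametric voxel phantom
generator stands in for the patient cohort and provides exact ground truth
for every stage.

# The phantom generator

`makeIntactPhantom()` renders an analytic humerus-like bone: the smooth
union (log-sum-exp blend, blend scale 1.2 mm) of a spherical head and a
capsule-shaped shaft, with two Gaussian surface bumps for the greater and
lesser tuberosities. The cortical shell is the band of signed distance
$-t \le d \le 0$ below the outer surface; the interior is medullary.
Intensities are fixed at background 0, interior 200, cortex 700 (arbitrary
CT-like units giving bimodal cortical contrast); imaging is emulated by a
Gaussian point-spread function (FWHM in mm) and additive Gaussian noise.

Everything downstream of the signed-distance function is analytic, so
ground truth is exact: the shell mask, the outer-surface distance function,
primary landmarks (ray/surface intersections at 12 named anatomical
positions), the rim curve of every cut on the outer surface, and the true
displacement of every fragment.

Deliberate design choices:

* **Scale.** Default dimensions (head radius 8 mm, shaft radius 4 mm,
  cortex 2 mm) are roughly 40 % of adult size so that a complete proximal
  segment fits a 64^3 grid at 0.5 mm spacing — the problem size used
  throughout the tests — with margin. All algorithms are scale-free.
* **Open distal shaft.** The default shaft is long enough to exit the grid
  distally, as clinical fields of view do. Image-boundary geometry is
  treated as an artifact everywhere downstream (marker selection and ICP
  exclude a 1.5 mm field-of-view margin).
* **Smooth anatomy.** Tuberosity bumps are broad (sigma about 4 mm) and the
  head–shaft junction is blended: real anatomical surfaces vary over
  centimetre scales, whereas fracture edges are sharp at the voxel scale.
  This scale separation is what curvature-based border detection exploits,
  on phantoms and on real bones alike.
* **Fractures.** `applyFracture()` partitions the shell by the side of one
  or more cut surfaces (planes or gently curved sheets), deletes
  comminution spheres, displaces each fragment rigidly (nearest-neighbour
  labels, trilinear grayscale), and re-renders with blur and noise.
  Voxels exactly on a cut go to the lower fragment id, making the
  partition deterministic.

What the phantom does *not* emulate: trabecular architecture, osteoporotic
density variation, scanner-specific noise texture, metal or motion
artefacts, and the anatomical variability of real fracture-pattern
frequencies. Passing tests therefore demonstrate algorithmic correctness
and robustness to geometry, blur and noise — not clinical performance.

# Segmentation

`adaptiveThreshold()` marks a voxel as cortical when its intensity exceeds
the local window mean by `offsetFraction * minContrast` *and* the window's
intensity range reaches `minContrast` (windows without structure stay
background). This separates cortex from a drifting background where any
global threshold fails. Because windows fully inside thick cortical stacks
have no contrast, `fillMaskHoles()` restores enclosed cavities afterwards
(open spaces — the medullary canal via the image border, fracture gaps —
stay background).

`splitFragment()` separates fragments that remain connected through
partial-volume bridges: voxels are removed in order of decreasing gradient
magnitude (computed once from the grayscale; ties broken by the smallest
lexicographic index) until no two marker groups remain connected, then
every removed voxel whose re-addition does not reconnect two groups is
added back, scanning in removal order. The implementation finds the
minimal removal prefix by a reverse union-find sweep, which is provably
identical to the literal one-at-a-time loop because connectivity is
monotone in the removed prefix. Pockets sealed behind the removed barrier
connect to no marker group; they are attached to the nearest labelled
fragment, which cannot reconnect anything. Two properties are guaranteed
and tested: the output labels plus the removed set tile the input mask,
and every retained removed voxel is reconnection-critical.

Key parameters (defaults in `studyConfig()`): window radius 2 voxels,
minimum contrast 100 intensity units, offset fraction 0.25, connectivity
26, minimum fragment size 27 voxels (smaller islands are discarded as
noise).

**Known limitation.** Small wedge fragments whose surface is mostly
blurred cut face approach the detection ceiling of the threshold: on
three-part phantom fractures the smallest fragment reaches a Dice overlap
of only about 0.86, echoing the clinical observation that small fragments
can be missed. Displaced two-part fractures segment at Dice 0.97–0.99.

# Meshing and fracture-line tracing

Fragments are meshed by surface nets (dual contouring with averaged edge
crossings) on the grayscale masked to the fragment, at the iso-level
midway between background and cortex (350). On blurred data this yields
sub-voxel-accurate smooth surfaces; meshing the binary indicator instead
(`meshFragment()`) reproduces the blocky mask exactly, which the
topology/volume tests rely on.

Border detection uses the signed cotangent-Laplacian mean curvature
(positive = convex), smoothed over the 1-ring a few times to suppress
voxelization spikes. Candidates above both a cohort quantile (0.9) and an
absolute floor (0.55 /mm) are thinned by geodesic non-maximum suppression.
The floor sits well above anatomical curvature at clinical smoothing
scales (head about 0.13 /mm, tuberosity shoulders below 0.4 /mm) and well
below blurred fracture-edge curvature (0.6–1.6 /mm). Three automated
cleanups replace the interactive marker editing of a GUI workflow:
endosteal candidates are rejected by grayscale probes along the outward
normal (air behind a periosteal vertex; marrow or, across a dark fracture
gap, the opposite fragment behind an endosteal one — the latter checked by
a label-map ray), candidates within 1.5 mm of the image border are
rejected, and only the largest geodesic cluster survives (the border is
one long chain; isolated patches are artefacts).

`traceFractureLine()` orders the markers by a nearest-neighbour tour on
geodesic distances improved by 2-opt, then connects consecutive markers by
least-cost paths on the mesh edge graph with edge cost

$$ \ell \,\bigl(1 + w_b \cdot \bar d_{\text{ridge}} + w_a \cdot
   (1 - \beta/\pi)\bigr), $$

where $\ell$ is edge length, $\bar d_{\text{ridge}}$ the mean geodesic
distance of the edge's endpoints to the high-curvature ridge, and $\beta$
the dihedral angle between the adjacent faces (so flat edges are penalized
and creases are free). Both weights default to 1. The exact cost form is a
package choice: it preserves the two ingredients the workflow needs — pull
towards the border ridge and preference for crease-like edges — and is
exposed in the configuration. The loop closes by the gap rule
(`closeGapFactor` mean edge lengths) or by decree (`closed = TRUE`), which
the pipeline uses since the border of a fragment of a closed surface is
always a loop.

Numerical accuracy: on planar-cut phantoms at 0.5 mm voxels with a 1.0 mm
FWHM point-spread function, traced borders land within one voxel
(Hausdorff 0.7–0.9 mm) of the analytic rim. The curvature crest of a
blurred edge cannot be localized more tightly than about one PSF sigma;
this bound, not the voxel size, dominates the error budget.

# Virtual reduction

`mirrorMesh()` reflects the intact contralateral surface across a
configurable plane (default: the volume's first-axis mid-plane) and
reverses triangle winding so outward normals stay outward.
`reduceFragment()` registers each fragment onto the template with
point-to-plane ICP over exact closest points (computed by compiled
point-to-triangle queries); a step that would increase the RMS
closest-point residual falls back to the point-to-point (Kabsch) update,
so the residual is non-increasing by construction. Convergence is declared
when the residual changes by less than 1e-4 mm (at most 200 iterations,
500 sample points); non-convergence is a flag, not an error. Within its
capture range (up to about 20 degrees and 10 mm on proximal fragments) the
registration recovers true displacements within 1 degree and 0.2 mm; a
90-degree displacement is outside the capture range and is reported as
such. Externally supplied transforms (e.g. from a manual reduction) are
accepted in place of the ICP, as are externally corrected label maps.
`projectLineToSurface()` replaces each line point by its exact closest
point on the template over all triangles — not vertex snapping — and is
idempotent.

# Statistical shape model

Primary landmarks are densified with `nSecondary` (default 4) secondary
landmarks per connecting line at equal arc-length fractions of the surface
geodesic (graph shortest path straightened by iterated midpoint smoothing
and reprojection; within 2 % of great-circle arcs on spheres).

`generalizedProcrustes()` iteratively aligns each configuration to the
running mean by least-squares similarity (or rigid) superimposition and
re-estimates the mean until its RMS change falls below
`1e-6 x centroid size`. Scaling is enabled by default — probability maps
are about pattern location, not bone size — and the flag is exposed. The
mean is centred at the origin; since a Procrustes mean is defined only up
to rotation, the result is canonicalized to its principal axes with signs
fixed by the largest-magnitude coordinate, making the output independent
of case order. With scaling, the mean's centroid size is fixed to the
cohort average.

The mean surface is built by choosing the case closest to the mean
configuration as warp template (deterministic, and minimizing warp
distortion), mapping the template surface to every case by a thin-plate
interpolating deformation of the landmarks (kernel $U(r) = r$,
pseudo-inverse solve so coplanar configurations work) followed by
closest-point refinement onto the case surface, and averaging the
corresponded positions in the aligned frame. Matches beyond a configurable
cap (5 mm) are flagged; more than 5 % flagged vertices is an error. Each
correspondence is stored as a case triangle id plus barycentric
coordinates, which are exact on the case surface and frame-independent.

# Probability maps

`mapLineIncidence()` resamples each projected line at half the kernel
radius, pulls each sample back to the mean surface through the inverse
correspondence (nearest corresponded vertex; the warp itself has no closed
inverse, and the error is bounded by the edge length), and flags every
mean vertex within the geodesic kernel radius (default 1.5 mean edge
lengths) — a fixed kernel makes "a line passes through a vertex"
well-defined and resolution-robust. `mapFragmentIncidence()` flags a mean
vertex when its corresponded case point lies within `fragmentMaxDist`
(default 1 mm) of the reduced fragment surface. Both are binary per case;
`accumulateProbability()` sums them into per-vertex case counts bounded by
the cohort size. Maps are written as per-vertex `quality` on PLY, as CSV,
and as four-view (anterior/lateral/posterior/medial) PNG renders.

# Determinism, degenerate inputs and numerical choices

* One master seed drives phantom sampling; every stage is otherwise
  deterministic (fixed tie-breaks in splitting and component ordering,
  deterministic subsampling in ICP, deterministic marker ordering).
  Re-running a completed case directory is a byte-identical no-op.
* Degenerate cuts (not splitting the mask), markers outside the mask,
  adjacent different-group markers, meshes with zero-area triangles,
  label maps with gaps, non-orthonormal or improper rotations, mixed map
  channels and mismatched landmark sets all raise immediate errors.
* Tolerances: rotations orthonormal within 1e-9; ICP convergence 1e-4 mm;
  Procrustes convergence 1e-6 of centroid size; thin-plate systems solved
  by SVD pseudo-inverse with a 1e-12 relative cutoff.

# Problem sizes used by the test-suite

The packaged tests and the acceptance script run entirely on generated
phantoms: 64^3 grids at 0.5 mm spacing, cohorts of 3–10 cases, 20 random
fractures for the splitting contract, 10 random displacements for
registration recovery, and 100 Monte-Carlo replicates for the Procrustes
noise law. These sizes were chosen as the smallest that exercise every
code path at realistic voxel-to-anatomy ratios.

# Known limitations

* Small wedge fragments segment at Dice about 0.86 (detection ceiling of
  blurred thin cut faces).
* Border localization is PSF-limited (about one sigma of the imaging
  blur).
* The ICP capture range requires initial displacements well below 90
  degrees; clinically extreme displacements would need an initial guess
  (`principalAxisInit()` or a supplied transform).
* Trabecular bone is out of scope throughout.
* The inter-operator distance reported by the acceptance script compares
  two automated reduction routes of the same case (ICP vs ground-truth
  transforms); it emulates the structure, not the magnitude, of human
  operator variability.
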