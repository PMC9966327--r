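# fracmap

Statistical fracture-line and fragment probability mapping from 3D images.

`fracmap` is an R package for quantitative 3D fracture morphology of long
bones imaged by CT, aimed at researchers studying fracture patterns (for
surgical planning, classification or implant design) who need to turn a
cohort of fractured-bone scans into population-level maps. It implements
the full chain:

* **Fragment segmentation** — locally adaptive cortical thresholding,
  connected components, and marker-driven separation of not-fully-detached
  fragments by iterative removal of the highest-gradient voxels (with the
  non-reconnecting voxels added back).
* **Fracture-line detection** — fragments are meshed (surface nets on the
  masked grayscale), border candidates are found as high signed mean
  curvature (cotangent Laplacian), and the border is traced as the
  least-cost path through guide markers, with edge cost
  `length * (1 + w_b * distance-to-ridge + w_a * dihedral deviation)`.
* **Virtual reduction** — rigid point-to-plane ICP of each fragment onto
  the mirrored intact contralateral surface (or externally supplied
  transforms), then exact closest-point projection of the traced lines
  onto the template.
* **Statistical mean shape** — generalized Procrustes alignment of named
  landmarks densified along surface geodesics, a mean surface via
  thin-plate landmark warping plus closest-point refinement, and dense
  per-vertex barycentric correspondence to every case.
* **Probability maps** — per-vertex counts of cases whose fracture lines
  (or cortical fragment areas) touch each point of the mean surface; the
  complement of the fragment map localizes comminution-prone zones.
* **Phantom generator** — an analytic humerus-like voxel phantom with
  programmable cuts, displacements, comminution, blur and noise, exporting
  exact ground truth (masks, rim curves, landmarks, true transforms) for
  validation.

The central quantity is the probability map: for mean-surface vertex $v$
and cohort of $N$ cases,

$$ P(v) \;=\; \sum_{i=1}^{N} \mathbf{1}\!\left[\, d_g\!\big(v,\;
   \Gamma_i \big) \le r \,\right], $$

the number of cases whose (correspondence-mapped) fracture line $\Gamma_i$
passes within geodesic radius $r$ of $v$ (analogously for fragment areas
with a Euclidean distance threshold). Counts are binary per case, so
$0 \le P(v) \le N$.

## Worked example

A displaced surgical-neck fracture with a comminution zone is generated,
segmented, traced, reduced onto the mirrored contralateral, and mapped
over a 10-case cohort:

```r
library(fracmap)

ph <- makeIntactPhantom(shapeParams(), gridSpec(), seed = 7)
n  <- c(0.15, 0, 1) / sqrt(1.0225)                 # oblique neck plane
spec <- fractureSpec(
  cuts          = list(list(type = "plane", point = c(0, 0, -5), normal = n)),
  displacements = list("2" = rigidTransform(diag(3), -0.8 * n)),
  comminution   = list(list(center = c(0, 4, -5), radius = 2.5)),
  blurFwhm = 1.0, seed = 7)
fx <- applyFracture(ph, spec)
fx$labels
#> LabelMap 64 x 64 x 64 voxels, 2 fragment(s)
#>   fragment voxel counts: 11306, 2997

mask    <- fillMaskHoles(adaptiveThreshold(fx$volume, 2, 100))
markers <- truthMarkers(fx$truth, mask)   # stands in for interactive clicks
contra  <- makeIntactPhantom(shapeParams(side = "right"), gridSpec(), seed = 8)
cfg <- studyConfig(mapping = list(lineRadius = 2))
rec <- runCase(cfg, fx$volume, contra$volume, tempfile("case"),
               caseId = "demo", markers = markers)
rec$labels
#> LabelMap 64 x 64 x 64 voxels, 2 fragment(s)
#>   fragment voxel counts: 11038, 2871
rec$projected[[1]]
#> FractureLine: fragment 1 | 94 points, closed
```

The detected fragments match the ground truth within a few percent of
voxels (Dice ≈ 0.97–0.99 on such cases), and the traced border of
fragment 1 is a closed 94-point loop on the template surface. Building the
cohort study (here ten copies of the same case; in a real study, ten
patients):

```r
cases <- lapply(sprintf("case%02d", 1:10), function(id)
  list(caseId = id, side = "left", mesh = rec$template,
       landmarks = ph$truth@landmarks,
       lines     = Filter(Negate(is.null), rec$projected),
       fragments = lapply(seq_along(rec$meshes), function(f)
         applyTransform(rec$reductions[[as.character(f)]], rec$meshes[[f]]))))
res <- runStudy(cfg, cases, outDir = NULL)
res$fractureMap
#> ProbabilityMap [fracture_line]: N = 10, counts 0..10 over 11554 vertices
res$fragmentMap
#> ProbabilityMap [fragment_area]: N = 10, counts 0..10 over 11554 vertices
```

Every vertex in the band around the fracture line counts all 10 cases and
the rest count 0; the fragment map counts 10 everywhere except the
comminution footprint. `runStudy(..., outDir = "maps/")` additionally
writes the maps as PLY (per-vertex `quality`), CSV and four-view PNG
renders, and `inst/cli/fracmap.R` exposes the per-stage operations as a
small command-line tool.

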