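Package: fracmap
Title: Statistical Fracture-Line and Fragment Probability Mapping from 3D Images
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
        role = c("aut", "cre"))
Description: A workflow for quantitative 3D fracture morphology of long
        bones imaged by computed tomography. Cortical fracture fragments are
        segmented from grayscale volumes by adaptive thresholding and
        marker-driven gradient splitting, fragment borders are traced as
        fracture lines on triangulated surfaces using curvature-guided
        least-cost paths, fragments are virtually reduced onto the mirrored
        intact contralateral template by rigid registration, and a
        landmark-based generalized Procrustes mean shape built from a cohort
        of intact bones receives every case's fracture lines and fragment
        areas through dense surface correspondence, yielding per-vertex
        fracture-line and fragment probability maps. A parametric voxel
        phantom generator provides humerus-like synthetic cases with exact
        ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, grDevices, graphics, Rcpp, Matrix, igraph,
        RANN, RNifti, jsonlite, yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), vegan, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Software, Segmentation, Visualization, BiomedicalInformatics
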