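#' @import methods
NULL

#' 3D grayscale image with physical geometry
#'
#' Carrier of CT-like scalar data: a 3D array of intensities together with
#' the physical voxel spacing (mm) and the world coordinate of the centre of
#' voxel `[1,1,1]`.
#'
#' @slot values 3D numeric array of intensities.
#' @slot spacing numeric(3), voxel spacing in mm; strictly positive.
#' @slot origin numeric(3), world position (mm) of the first voxel centre.
#' @export
setClass("VolumeImage",
    representation(values = "array", spacing = "numeric", origin = "numeric"),
    prototype(values = array(0, c(1, 1, 1)), spacing = c(1, 1, 1),
              origin = c(0, 0, 0)))

setValidity("VolumeImage", function(object) {
    if (length(dim(object@values)) != 3L) return("values must be a 3D array")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
        return("spacing must be 3 positive numbers")
    if (length(object@origin) != 3L) return("origin must have length 3")
    if (any(!is.finite(object@values))) return("values must be finite")
    TRUE
})

#' Integer fragment label map
#'
#' Non-negative integer labels on the same voxel geometry as the source
#' volume; 0 is background. Labels form a contiguous set `{0..K}`.
#'
#' @slot labels 3D integer array.
#' @slot spacing,origin voxel geometry, as in [VolumeImage-class].
#' @export
setClass("LabelMap",
    representation(labels = "array", spacing = "numeric", origin = "numeric"),
    prototype(labels = array(0L, c(1, 1, 1)), spacing = c(1, 1, 1),
              origin = c(0, 0, 0)))

setValidity("LabelMap", function(object) {
    if (length(dim(object@labels)) != 3L) return("labels must be a 3D array")
    if (any(object@labels < 0)) return("labels must be non-negative")
    k <- max(object@labels)
    present <- sort(unique(as.integer(object@labels)))
    if (k > 0 && !all(seq_len(k) %in% present))
        return("labels must form a contiguous set {0..K}")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
        return("spacing must be 3 positive numbers")
    TRUE
})

#' Triangulated surface in world coordinates
#'
#' @slot vertices n x 3 numeric matrix, mm.
#' @slot triangles m x 3 integer matrix of 1-based vertex indices.
#' @slot vertexData data.frame of optional per-vertex scalars (e.g. the
#'   `quality` column written to PLY).
#' @export
setClass("TriangleMesh",
    representation(vertices = "matrix", triangles = "matrix",
                   vertexData = "data.frame"),
    prototype(vertices = matrix(0, 0, 3), triangles = matrix(0L, 0, 3),
              vertexData = data.frame()))

setValidity("TriangleMesh", function(object) {
    if (ncol(object@vertices) != 3L) return("vertices must be n x 3")
    if (ncol(object@triangles) != 3L) return("triangles must be m x 3")
    if (nrow(object@triangles) > 0) {
        idx <- range(object@triangles)
        if (idx[1] < 1 || idx[2] > nrow(object@vertices))
            return("triangle indices out of range")
    }
    if (nrow(object@vertexData) > 0 &&
        nrow(object@vertexData) != nrow(object@vertices))
        return("vertexData rows must match vertex count")
    TRUE
})

#' Fracture line: ordered polyline on a fragment border
#'
#' @slot points k x 3 numeric matrix of ordered points, mm.
#' @slot closed logical, whether the polyline is a closed loop.
#' @slot fragment integer id of the source fragment.
#' @export
setClass("FractureLine",
    representation(points = "matrix", closed = "logical",
                   fragment = "integer"),
    prototype(points = matrix(0, 0, 3), closed = FALSE, fragment = NA_integer_))

setValidity("FractureLine", function(object) {
    if (ncol(object@points) != 3L) return("points must be k x 3")
    if (nrow(object@points) >= 2) {
        d <- diff(object@points)
        if (any(rowSums(d^2) == 0))
            return("consecutive points must be distinct")
    }
    TRUE
})

#' Rigid (optionally similarity) spatial transform
#'
#' Maps a point `x` to `scale * rotation %*% x + translation`.
#'
#' @slot rotation 3 x 3 proper orthonormal matrix.
#' @slot translation numeric(3), mm.
#' @slot scale positive scalar, default 1 (rigid).
#' @export
setClass("RigidTransform",
    representation(rotation = "matrix", translation = "numeric",
                   scale = "numeric"),
    prototype(rotation = diag(3), translation = c(0, 0, 0), scale = 1))

setValidity("RigidTransform", function(object) {
    R <- object@rotation
    if (!all(dim(R) == c(3, 3))) return("rotation must be 3 x 3")
    if (max(abs(crossprod(R) - diag(3))) > 1e-9)
        return("rotation must be orthonormal (R'R = I within 1e-9)")
    if (det(R) < 0) return("rotation must be proper (det = +1)")
    if (length(object@translation) != 3L) return("translation must be length 3")
    if (length(object@scale) != 1L || object@scale <= 0)
        return("scale must be a positive scalar")
    TRUE
})

#' Named anatomical landmarks plus ordered secondary landmarks
#'
#' Primary landmarks are named surface points; secondary landmarks are
#' ordered points generated along named connecting lines between primaries.
#'
#' @slot primary p x 3 matrix with unique rownames.
#' @slot secondary s x 3 matrix (possibly 0-row).
#' @slot secondaryLine character(s), the connecting-line id of each
#'   secondary landmark, e.g. `"head_apex--gt_peak"`.
#' @slot caseId character scalar.
#' @slot side `"left"` or `"right"`.
#' @export
setClass("LandmarkSet",
    representation(primary = "matrix", secondary = "matrix",
                   secondaryLine = "character", caseId = "character",
                   side = "character"),
    prototype(primary = matrix(0, 0, 3), secondary = matrix(0, 0, 3),
              secondaryLine = character(), caseId = "case", side = "left"))

setValidity("LandmarkSet", function(object) {
    if (ncol(object@primary) != 3L) return("primary must be p x 3")
    nm <- rownames(object@primary)
    if (nrow(object@primary) > 0 && (is.null(nm) || anyDuplicated(nm)))
        return("primary landmarks need unique rownames")
    if (nrow(object@secondary) != length(object@secondaryLine))
        return("secondaryLine must label every secondary landmark")
    if (!object@side %in% c("left", "right"))
        return("side must be 'left' or 'right'")
    TRUE
})

#' Dense correspondence from mean-surface vertices to one case surface
#'
#' @slot triangle integer vector: matched case triangle per mean vertex.
#' @slot bary n x 3 matrix of barycentric coordinates (non-negative,
#'   summing to 1 per row).
#' @slot flagged logical vector: vertices whose match exceeded the distance
#'   cap.
#' @slot caseId character scalar.
#' @export
setClass("CorrespondenceMap",
    representation(triangle = "integer", bary = "matrix",
                   flagged = "logical", caseId = "character"),
    prototype(triangle = integer(), bary = matrix(0, 0, 3),
              flagged = logical(), caseId = "case"))

setValidity("CorrespondenceMap", function(object) {
    if (nrow(object@bary) != length(object@triangle))
        return("bary rows must match triangle length")
    if (nrow(object@bary) > 0) {
        if (min(object@bary) < -1e-9) return("barycentric coords must be >= 0")
        if (max(abs(rowSums(object@bary) - 1)) > 1e-6)
            return("barycentric coords must sum to 1")
    }
    if (length(object@flagged) != length(object@triangle))
        return("flagged must match triangle length")
    TRUE
})

#' Statistical mean shape of an intact-bone cohort
#'
#' @slot meanSurface [TriangleMesh-class] of the Procrustes mean, centred at
#'   the origin of the aligned frame.
#' @slot meanLandmarks [LandmarkSet-class] mean landmark configuration.
#' @slot correspondences list of [CorrespondenceMap-class], one per case.
#' @slot transforms list of [RigidTransform-class] mapping each case's
#'   original frame into the aligned frame.
#' @slot templateCase integer index of the cohort case used as warp template.
#' @slot caseIds character vector of cohort case ids.
#' @export
setClass("MeanShapeModel",
    representation(meanSurface = "TriangleMesh",
                   meanLandmarks = "LandmarkSet",
                   correspondences = "list", transforms = "list",
                   templateCase = "integer", caseIds = "character",
                   scaling = "logical"),
    prototype(scaling = TRUE))

setValidity("MeanShapeModel", function(object) {
    if (length(object@correspondences) != length(object@transforms))
        return("one transform per correspondence map required")
    if (length(object@caseIds) != length(object@correspondences))
        return("one case id per correspondence map required")
    TRUE
})

#' Per-case binary incidence on the mean surface
#'
#' @slot flags integer 0/1 vector, one per mean-surface vertex.
#' @slot caseId character scalar.
#' @slot channel `"fracture_line"` or `"fragment_area"`.
#' @export
setClass("IncidenceVector",
    representation(flags = "integer", caseId = "character",
                   channel = "character"),
    prototype(flags = integer(), caseId = "case", channel = "fracture_line"))

setValidity("IncidenceVector", function(object) {
    if (!all(object@flags %in% c(0L, 1L))) return("flags must be 0/1")
    if (!object@channel %in% c("fracture_line", "fragment_area"))
        return("channel must be fracture_line or fragment_area")
    TRUE
})

#' Cohort probability map on the mean surface
#'
#' Per-vertex count of cases whose fracture line (channel
#' `"fracture_line"`) or cortical fragment area (channel `"fragment_area"`)
#' touches that vertex.
#'
#' @slot counts integer vector, one per mean-surface vertex.
#' @slot n integer cohort size.
#' @slot channel channel name.
#' @export
setClass("ProbabilityMap",
    representation(counts = "integer", n = "integer", channel = "character"),
    prototype(counts = integer(), n = 0L, channel = "fracture_line"))

setValidity("ProbabilityMap", function(object) {
    if (any(object@counts < 0) || any(object@counts > object@n))
        return("counts must lie in [0, n]")
    TRUE
})

#' Parametric shape of a humerus-like phantom
#'
#' The phantom is a cortical shell around the union of a spherical head and
#' a capsule-shaped shaft, with Gaussian surface bumps emulating the greater
#' and lesser tuberosities.
#'
#' @slot headRadius mm, articular head radius.
#' @slot shaftRadius mm.
#' @slot shaftLength mm (head centre to distal cap centre).
#' @slot tuberosities list of `list(direction = unit vector, amplitude = mm,
#'   sigma = mm, height = fraction)` surface bumps.
#' @slot corticalThickness mm; must be smaller than `headRadius`.
#' @slot side `"left"` or `"right"`.
#' @export
setClass("ShapeParams",
    representation(headRadius = "numeric", shaftRadius = "numeric",
                   shaftLength = "numeric", tuberosities = "list",
                   corticalThickness = "numeric", side = "character"))

setValidity("ShapeParams", function(object) {
    len <- c(object@headRadius, object@shaftRadius, object@shaftLength,
             object@corticalThickness)
    if (any(len <= 0)) return("all lengths must be > 0")
    if (object@corticalThickness >= object@headRadius)
        return("corticalThickness must be < headRadius")
    if (!object@side %in% c("left", "right"))
        return("side must be 'left' or 'right'")
    for (tb in object@tuberosities) {
        if (abs(sqrt(sum(tb$direction^2)) - 1) > 1e-6)
            return("tuberosity directions must be unit vectors")
    }
    TRUE
})

#' Specification of a synthetic fracture
#'
#' @slot cuts list of cut surfaces; each is `list(type = "plane", point,
#'   normal)` or `list(type = "sheet", point, normal, coef)` where `coef`
#'   are quadratic in-plane coefficients bending the sheet.
#' @slot displacements named list of [RigidTransform-class], one per
#'   fragment id.
#' @slot comminution list of `list(center = mm triple, radius = mm)`.
#' @slot noiseSd intensity units of additive Gaussian noise.
#' @slot blurFwhm mm, Gaussian blur full width at half maximum.
#' @slot seed integer RNG seed.
#' @export
setClass("FractureSpec",
    representation(cuts = "list", displacements = "list",
                   comminution = "list", noiseSd = "numeric",
                   blurFwhm = "numeric", seed = "integer"),
    prototype(cuts = list(), displacements = list(), comminution = list(),
              noiseSd = 0, blurFwhm = 0, seed = 1L))

setValidity("FractureSpec", function(object) {
    if (length(object@cuts) < 1) return("at least one cut surface required")
    for (tr in object@displacements) {
        if (!is(tr, "RigidTransform")) return("displacements must be RigidTransform")
        if (det(tr@rotation) < 0) return("displacement rotations must be proper")
    }
    for (cz in object@comminution)
        if (cz$radius < 0) return("comminution radii must be >= 0")
    if (object@noiseSd < 0 || object@blurFwhm < 0)
        return("noiseSd and blurFwhm must be >= 0")
    TRUE
})

#' Ground truth exported with every phantom
#'
#' @slot intactMask binary array: cortical shell of the intact bone.
#' @slot fragmentLabels [LabelMap-class] of displaced fragments (fractured
#'   phantoms only).
#' @slot removedVoxels binary array of comminution-deleted voxels, in the
#'   intact frame.
#' @slot cutCurves list of k x 3 matrices: rim polylines of each cut on the
#'   intact outer surface.
#' @slot trueDisplacements named list of [RigidTransform-class].
#' @slot landmarks [LandmarkSet-class].
#' @slot outerSurface function(points) returning the signed distance of
#'   world points to the intact outer surface (analytic).
#' @slot interiorMask binary array: medullary interior of the intact bone.
#' @export
setClass("GroundTruth",
    representation(intactMask = "array", fragmentLabels = "ANY",
                   removedVoxels = "array", cutCurves = "list",
                   trueDisplacements = "list", landmarks = "ANY",
                   outerSurface = "ANY", interiorMask = "array"))

#' Summary of point-to-line-set distances
#'
#' @slot mean,sd mm.
#' @slot nPoints number of sampled points.
#' @slot distances per-point distances, mm.
#' @slot direction label of the comparison (e.g. `"a_to_b"`).
#' @export
setClass("DistanceSummary",
    representation(mean = "numeric", sd = "numeric", nPoints = "integer",
                   distances = "numeric", direction = "character"))

setValidity("DistanceSummary", function(object) {
    if (object@mean < 0 || (!is.na(object@sd) && object@sd < 0))
        return("mean and sd must be >= 0")
    if (object@nPoints != length(object@distances))
        return("nPoints must equal length(distances)")
    TRUE
})
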