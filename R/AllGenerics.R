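#' Accessors for fracmap classes
#'
#' Small accessor generics: `spacing()`/`origin()` return voxel geometry,
#' `voxelValues()`/`labelValues()` the raw arrays, `meshVertices()`/
#' `meshTriangles()` mesh components, `linePoints()` the polyline matrix,
#' `mapCounts()` probability-map counts.
#'
#' @param x object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))
#' @rdname accessors
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))
#' @rdname accessors
#' @export
setGeneric("voxelValues", function(x) standardGeneric("voxelValues"))
#' @rdname accessors
#' @export
setGeneric("labelValues", function(x) standardGeneric("labelValues"))
#' @rdname accessors
#' @export
setGeneric("meshVertices", function(x) standardGeneric("meshVertices"))
#' @rdname accessors
#' @export
setGeneric("meshTriangles", function(x) standardGeneric("meshTriangles"))
#' @rdname accessors
#' @export
setGeneric("linePoints", function(x) standardGeneric("linePoints"))
#' @rdname accessors
#' @export
setGeneric("isClosed", function(x) standardGeneric("isClosed"))
#' @rdname accessors
#' @export
setGeneric("mapCounts", function(x) standardGeneric("mapCounts"))
#' @rdname accessors
#' @export
setGeneric("primaryLandmarks", function(x) standardGeneric("primaryLandmarks"))
#' @rdname accessors
#' @export
setGeneric("secondaryLandmarks", function(x) standardGeneric("secondaryLandmarks"))
#' @rdname accessors
#' @export
setGeneric("allLandmarks", function(x) standardGeneric("allLandmarks"))
#' @rdname accessors
#' @export
setGeneric("meanSurface", function(x) standardGeneric("meanSurface"))

#' Apply a spatial transform to an object
#'
#' @param transform a [RigidTransform-class].
#' @param x points matrix, [TriangleMesh-class], [FractureLine-class] or
#'   [LandmarkSet-class].
#' @return the transformed object.
#' @export
setGeneric("applyTransform",
           function(transform, x) standardGeneric("applyTransform"))

spacing_ <- function(x) x@spacing
#' @rdname accessors
#' @export
setMethod("spacing", "VolumeImage", spacing_)
#' @rdname accessors
#' @export
setMethod("spacing", "LabelMap", spacing_)
#' @rdname accessors
#' @export
setMethod("origin", "VolumeImage", function(x) x@origin)
#' @rdname accessors
#' @export
setMethod("origin", "LabelMap", function(x) x@origin)
#' @rdname accessors
#' @export
setMethod("voxelValues", "VolumeImage", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("labelValues", "LabelMap", function(x) x@labels)
#' @rdname accessors
#' @export
setMethod("meshVertices", "TriangleMesh", function(x) x@vertices)
#' @rdname accessors
#' @export
setMethod("meshTriangles", "TriangleMesh", function(x) x@triangles)
#' @rdname accessors
#' @export
setMethod("linePoints", "FractureLine", function(x) x@points)
#' @rdname accessors
#' @export
setMethod("isClosed", "FractureLine", function(x) x@closed)
#' @rdname accessors
#' @export
setMethod("mapCounts", "ProbabilityMap", function(x) x@counts)
#' @rdname accessors
#' @export
setMethod("primaryLandmarks", "LandmarkSet", function(x) x@primary)
#' @rdname accessors
#' @export
setMethod("secondaryLandmarks", "LandmarkSet", function(x) x@secondary)
#' @rdname accessors
#' @export
setMethod("allLandmarks", "LandmarkSet", function(x) {
    rbind(x@primary, x@secondary)
})
#' @rdname accessors
#' @export
setMethod("meanSurface", "MeanShapeModel", function(x) x@meanSurface)

setMethod("show", "VolumeImage", function(object) {
    d <- dim(object@values)
    cat("VolumeImage", paste(d, collapse = " x "),
        sprintf("voxels, spacing %.3g x %.3g x %.3g mm\n",
                object@spacing[1], object@spacing[2], object@spacing[3]))
    cat("  intensity range:", paste(signif(range(object@values), 4),
                                    collapse = " .. "), "\n")
})

setMethod("show", "LabelMap", function(object) {
    d <- dim(object@labels)
    k <- max(object@labels)
    cat("LabelMap", paste(d, collapse = " x "), "voxels,", k, "fragment(s)\n")
    if (k > 0) {
        sz <- tabulate(object@labels[object@labels > 0], nbins = k)
        cat("  fragment voxel counts:", paste(sz, collapse = ", "), "\n")
    }
})

setMethod("show", "TriangleMesh", function(object) {
    cat("TriangleMesh:", nrow(object@vertices), "vertices,",
        nrow(object@triangles), "triangles")
    if (ncol(object@vertexData) > 0)
        cat(" | vertex data:", paste(names(object@vertexData), collapse = ", "))
    cat("\n")
})

setMethod("show", "FractureLine", function(object) {
    cat("FractureLine: fragment", object@fragment, "|",
        nrow(object@points), "points,",
        if (object@closed) "closed" else "open", "\n")
})

setMethod("show", "RigidTransform", function(object) {
    ang <- rotationAngle(object@rotation) * 180 / pi
    cat(sprintf("RigidTransform: rotation %.2f deg, translation (%.2f, %.2f, %.2f) mm, scale %.4g\n",
                ang, object@translation[1], object@translation[2],
                object@translation[3], object@scale))
})

setMethod("show", "LandmarkSet", function(object) {
    cat("LandmarkSet [", object@caseId, ", ", object@side, "]: ",
        nrow(object@primary), " primary + ", nrow(object@secondary),
        " secondary landmarks\n", sep = "")
})

setMethod("show", "MeanShapeModel", function(object) {
    cat("MeanShapeModel:", length(object@caseIds), "cases, mean surface with",
        nrow(object@meanSurface@vertices), "vertices\n")
})

setMethod("show", "ProbabilityMap", function(object) {
    cat("ProbabilityMap [", object@channel, "]: N = ", object@n,
        ", counts ", min(object@counts), "..", max(object@counts),
        " over ", length(object@counts), " vertices\n", sep = "")
})

setMethod("show", "DistanceSummary", function(object) {
    cat(sprintf("DistanceSummary (%s): %.3f +/- %.3f mm over %d points\n",
                object@direction, object@mean, object@sd, object@nPoints))
})
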