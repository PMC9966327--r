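## Discrete curvature and high-curvature border-candidate detection.

#' Per-vertex absolute mean curvature
#'
#' Cotangent-Laplacian estimate: the norm of the discrete mean-curvature
#' normal `sum_j (cot a_ij + cot b_ij)(x_i - x_j) / (4 A_i)` with
#' barycentric vertex areas `A_i`. Vertices on boundary edges receive the
#' value of the nearest interior vertex.
#'
#' @param mesh a [TriangleMesh-class] with at least 4 vertices.
#' @param signed return signed mean curvature (positive = convex with
#'   respect to the outward orientation); default FALSE (absolute value).
#' @return numeric vector of curvatures (1/mm), one per vertex.
#' @export
vertexCurvature <- function(mesh, signed = FALSE) {
    v <- mesh@vertices
    tr <- mesh@triangles
    if (nrow(v) < 4) stop("mesh must have >= 4 vertices")
    tn <- triangleNormals(mesh)
    if (any(tn$areas <= .Machine$double.eps))
        stop("degenerate (zero-area) triangles")
    n <- nrow(v)
    ii <- integer(0); jj <- integer(0); ww <- numeric(0)
    for (corner in 1:3) {
        o <- tr[, corner]
        p <- tr[, corner %% 3 + 1]
        q <- tr[, (corner + 1) %% 3 + 1]
        # cotangent of the angle at o, opposite edge (p, q)
        u <- v[p, , drop = FALSE] - v[o, , drop = FALSE]
        w <- v[q, , drop = FALSE] - v[o, , drop = FALSE]
        cosv <- rowSums(u * w)
        crossv <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
                        u[, 3] * w[, 1] - u[, 1] * w[, 3],
                        u[, 1] * w[, 2] - u[, 2] * w[, 1])
        sinv <- sqrt(rowSums(crossv^2))
        cotv <- cosv / pmax(sinv, .Machine$double.eps)
        ii <- c(ii, p, q)
        jj <- c(jj, q, p)
        ww <- c(ww, cotv, cotv)
    }
    W <- Matrix::sparseMatrix(i = ii, j = jj, x = ww, dims = c(n, n))
    deg <- Matrix::rowSums(W)
    Hn <- as.matrix(deg * v - W %*% v)  # sum w_ij (x_i - x_j)
    area <- numeric(n)
    for (corner in 1:3) {
        at <- tapply(tn$areas, tr[, corner], sum)
        area[as.integer(names(at))] <- area[as.integer(names(at))] + at
    }
    area <- area / 3
    H <- sqrt(rowSums(Hn^2)) / (4 * pmax(area, .Machine$double.eps))
    if (signed) {
        # orientation from area-weighted vertex normals: the mean-curvature
        # vector points opposite the outward normal on convex regions
        vn <- matrix(0, n, 3)
        fn <- tn$normals * tn$areas
        for (corner in 1:3) {
            idx <- tr[, corner]
            vn[, 1] <- vn[, 1] + tapply2(fn[, 1], idx, n)
            vn[, 2] <- vn[, 2] + tapply2(fn[, 2], idx, n)
            vn[, 3] <- vn[, 3] + tapply2(fn[, 3], idx, n)
        }
        H <- H * sign(rowSums(Hn * vn))
    }

    # boundary vertices: propagate the nearest interior value inwards
    e <- rbind(tr[, 1:2], tr[, 2:3], tr[, c(3, 1)])
    key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    cnt <- table(key)
    bkey <- names(cnt)[cnt == 1]
    if (length(bkey) > 0) {
        bv <- unique(as.integer(unlist(strsplit(bkey, " "))))
        assigned <- rep(TRUE, n)
        assigned[bv] <- FALSE
        adj <- adjacencyList(mesh)
        # multi-source BFS from the interior: each boundary vertex copies
        # the value of its nearest interior vertex (waves of equal depth;
        # the smallest-id neighbour breaks ties)
        repeat {
            frontier <- which(!assigned)
            if (length(frontier) == 0) break
            snapshot <- assigned
            newVals <- rep(NA_real_, length(frontier))
            for (q in seq_along(frontier)) {
                nb <- adj[[frontier[q]]]
                srcs <- nb[snapshot[nb]]
                if (length(srcs) > 0) newVals[q] <- H[min(srcs)]
            }
            hit <- !is.na(newVals)
            if (!any(hit)) break
            H[frontier[hit]] <- newVals[hit]
            assigned[frontier[hit]] <- TRUE
        }
    }
    H
}

# vertex adjacency list from triangles
adjacencyList <- function(mesh) {
    e <- meshEdges(mesh)
    n <- nrow(mesh@vertices)
    adj <- vector("list", n)
    sp <- split(c(e[, 2], e[, 1]), c(e[, 1], e[, 2]))
    adj[as.integer(names(sp))] <- sp
    adj
}

#' Propose guide markers on high-curvature border candidates
#'
#' Selects vertices whose curvature exceeds both the given cohort quantile
#' and an absolute floor, then thins them by non-maximum suppression within
#' a geodesic radius; survivors are returned sorted by descending
#' curvature. On fracture fragments the sharp cut borders carry the highest
#' curvature, so the surviving markers delineate the fracture rim.
#'
#' @param mesh a [TriangleMesh-class].
#' @param curvature per-vertex curvature from [vertexCurvature()].
#' @param quantile curvature quantile in (0, 1) above which vertices are
#'   candidates (default 0.9).
#' @param minCurvature absolute curvature floor, 1/mm (default 0.25):
#'   uniformly smooth surfaces yield no markers.
#' @param suppressRadius geodesic non-maximum-suppression radius, mm
#'   (default 2 x mean edge length).
#' @return integer vector of vertex ids, sorted by descending curvature.
#' @export
proposeGuideMarkers <- function(mesh, curvature, quantile = 0.9,
                                minCurvature = 0.25,
                                suppressRadius = NULL) {
    stopifnot(quantile > 0, quantile < 1)
    if (is.null(suppressRadius)) suppressRadius <- 2 * meanEdgeLength(mesh)
    thr <- max(stats::quantile(curvature, quantile), minCurvature)
    cand <- which(curvature > thr)
    if (length(cand) == 0) return(integer(0))
    cand <- cand[order(-curvature[cand])]
    g <- meshGraph(mesh)
    D <- igraph::distances(g, v = cand, to = cand)
    keep <- logical(length(cand))
    for (i in seq_along(cand)) {
        prior <- which(keep)
        if (length(prior) == 0 || all(D[i, prior] > suppressRadius))
            keep[i] <- TRUE
    }
    cand[keep]
}

# fast grouped sum into a length-n vector
tapply2 <- function(x, idx, n) {
    out <- numeric(n)
    s <- tapply(x, idx, sum)
    out[as.integer(names(s))] <- s
    out
}

#' Select fracture-border guide markers on a fragment
#'
#' Convenience wrapper composing [proposeGuideMarkers()] with three
#' automated cleanups that stand in for the interactive marker editing of a
#' GUI workflow: candidates on the endosteal (inner) surface are rejected
#' by the grayscale probe of [outerSurfaceVertices()], candidates within a
#' field-of-view margin of the volume boundary are rejected (image-border
#' artefacts), and only the largest geodesic cluster is kept (the fracture
#' rim forms one long chain; isolated patches are spurious).
#'
#' @param mesh fragment [TriangleMesh-class].
#' @param curvature signed per-vertex curvature (smoothed; see
#'   [smoothVertexField()]).
#' @param volume grayscale [VolumeImage-class] (NULL skips the
#'   outer-surface and field-of-view filters).
#' @param quantile,minCurvature,suppressRadius see
#'   [proposeGuideMarkers()]; the floor defaults to 0.55/mm here because
#'   anatomical surfaces stay well below it at clinical smoothing scales.
#' @param fovMargin minimum distance to the volume boundary, mm (default
#'   1.5).
#' @param clusterGap geodesic gap above which marker clusters are
#'   considered separate, mm (default 6).
#' @param labels optional [LabelMap-class] for the fracture-gap ray test of
#'   [outerSurfaceVertices()].
#' @return integer vertex ids sorted by descending curvature.
#' @export
selectBorderMarkers <- function(mesh, curvature, volume = NULL,
                                quantile = 0.9, minCurvature = 0.55,
                                suppressRadius = NULL, fovMargin = 1.5,
                                clusterGap = 6, labels = NULL) {
    mk <- proposeGuideMarkers(mesh, curvature, quantile, minCurvature,
                              suppressRadius)
    if (length(mk) == 0) return(mk)
    if (!is.null(volume)) {
        mk <- mk[outerSurfaceVertices(mesh, volume, labels = labels)[mk]]
        if (length(mk) == 0) return(mk)
        v <- mesh@vertices[mk, , drop = FALSE]
        lo <- volume@origin + fovMargin
        hi <- volume@origin + (dim(volume@values) - 1) * volume@spacing -
            fovMargin
        inside <- v[, 1] > lo[1] & v[, 2] > lo[2] & v[, 3] > lo[3] &
            v[, 1] < hi[1] & v[, 2] < hi[2] & v[, 3] < hi[3]
        mk <- mk[inside]
    }
    if (length(mk) > 2) {
        D <- igraph::distances(meshGraph(mesh), v = mk, to = mk)
        adj <- D < clusterGap
        cl <- igraph::components(igraph::graph_from_adjacency_matrix(
            adj, mode = "undirected"))$membership
        mk <- mk[cl == which.max(tabulate(cl))]
    }
    mk
}
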