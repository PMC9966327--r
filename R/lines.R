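## Fracture-line tracing: least-cost paths on the mesh edge graph guided by
## distance to the high-curvature ridge and by crease (dihedral) angles.

#' Construct a FractureLine
#'
#' @param points k x 3 matrix of ordered points, mm.
#' @param closed logical.
#' @param fragment source fragment id.
#' @return a [FractureLine-class].
#' @export
fractureLine <- function(points, closed = FALSE, fragment = NA_integer_) {
    if (!is.matrix(points)) points <- matrix(points, ncol = 3)
    keep <- c(TRUE, rowSums((points[-1, , drop = FALSE] -
                             points[-nrow(points), , drop = FALSE])^2) > 0)
    new("FractureLine", points = points[keep, , drop = FALSE],
        closed = closed, fragment = as.integer(fragment))
}

# per-edge cost field: length x (1 + wB * mean ridge distance of the
# endpoints + wA * dihedral deviation from a crease)
edgeCosts <- function(mesh, ridge, wBoundary, wAngle) {
    e <- meshEdges(mesh)
    v <- mesh@vertices
    len <- sqrt(rowSums((v[e[, 1], , drop = FALSE] -
                         v[e[, 2], , drop = FALSE])^2))
    g <- meshGraph(mesh)
    # geodesic distance of every vertex to the ridge set (multi-source
    # Dijkstra via a zero-cost super source)
    n <- nrow(v)
    gs <- igraph::add_vertices(g, 1)
    gs <- igraph::add_edges(gs, rbind(rep(n + 1L, length(ridge)), ridge),
                            weight = rep(0, length(ridge)))
    dRidge <- as.numeric(igraph::distances(gs, v = n + 1L,
                                           to = seq_len(n)))
    # dihedral deviation: 0 for a sharp crease (face normals antiparallel),
    # 1 for a flat edge
    tn <- triangleNormals(mesh)$normals
    tr <- mesh@triangles
    ekey <- function(a, b) paste(pmin(a, b), pmax(a, b))
    faceEdges <- ekey(c(tr[, 1], tr[, 2], tr[, 3]),
                      c(tr[, 2], tr[, 3], tr[, 1]))
    faceIds <- rep(seq_len(nrow(tr)), 3)
    byEdge <- split(faceIds, faceEdges)
    dev <- rep(1, nrow(e))
    keys <- ekey(e[, 1], e[, 2])
    two <- lengths(byEdge[keys]) == 2
    if (any(two)) {
        pairs <- do.call(rbind, byEdge[keys[two]])
        cosb <- rowSums(tn[pairs[, 1], , drop = FALSE] *
                        tn[pairs[, 2], , drop = FALSE])
        beta <- acos(pmin(pmax(cosb, -1), 1))
        dev[two] <- 1 - beta / pi
    }
    cost <- len * (1 + wBoundary * (dRidge[e[, 1]] + dRidge[e[, 2]]) / 2 +
                   wAngle * dev)
    list(edges = e, cost = cost, length = len, dRidge = dRidge, dev = dev)
}

# weighted graph with the trace cost on the edges
costGraph <- function(mesh, ec) {
    g <- igraph::graph_from_edgelist(ec$edges, directed = FALSE)
    if (igraph::vcount(g) < nrow(mesh@vertices))
        g <- igraph::add_vertices(g, nrow(mesh@vertices) - igraph::vcount(g))
    igraph::set_edge_attr(g, "weight", value = ec$cost)
}

#' Cost of a fixed vertex path under the trace cost function
#'
#' @param mesh a [TriangleMesh-class].
#' @param path integer vector of vertex ids.
#' @param ridge ridge vertex set (see [traceFractureLine()]).
#' @param weights `c(wBoundary, wAngle)`.
#' @return total path cost.
#' @export
tracePathCost <- function(mesh, path, ridge, weights = c(1, 1)) {
    ec <- edgeCosts(mesh, ridge, weights[1], weights[2])
    key <- paste(pmin(ec$edges[, 1], ec$edges[, 2]),
                 pmax(ec$edges[, 1], ec$edges[, 2]))
    lut <- stats::setNames(ec$cost, key)
    a <- path[-length(path)]
    b <- path[-1]
    sum(lut[paste(pmin(a, b), pmax(a, b))])
}

#' Trace a fracture line through guide markers
#'
#' Orders the markers along the border ridge (nearest-neighbour tour on
#' geodesic distances, improved by 2-opt) and connects consecutive markers
#' by least-cost paths on the mesh edge graph, where the cost of an edge is
#' its length times `1 + wBoundary * (mean geodesic distance of its
#' endpoints to the ridge) + wAngle * (dihedral deviation from a crease)`.
#' The loop is closed when the tour's endpoints are within `closeGapFactor`
#' mean edge lengths geodesically. Markers can be freely added or removed
#' before tracing.
#'
#' @param mesh a [TriangleMesh-class].
#' @param markers integer vertex ids (>= 2), e.g. from
#'   [proposeGuideMarkers()].
#' @param weights numeric(2): `c(wBoundary, wAngle)`, default `c(1, 1)`.
#' @param ridge vertex set defining the high-curvature ridge for the
#'   distance term; defaults to the markers.
#' @param closeGapFactor close the loop when the end gap is below this
#'   multiple of the mean edge length (default 3).
#' @param closed force the closed flag: TRUE always closes the loop (the
#'   border of a fragment of a closed surface is a loop), FALSE never
#'   does; NULL (default) applies the gap rule.
#' @param fragment fragment id recorded on the line.
#' @return a [FractureLine-class] whose points are mesh vertex positions.
#' @export
traceFractureLine <- function(mesh, markers, weights = c(1, 1),
                              ridge = markers, closeGapFactor = 3,
                              closed = NULL, fragment = NA_integer_) {
    stopifnot(length(markers) >= 2)
    comp <- meshComponents(mesh)
    if (length(unique(comp[markers])) > 1)
        stop("markers lie on different mesh components")
    ec <- edgeCosts(mesh, ridge, weights[1], weights[2])
    gc <- costGraph(mesh, ec)
    gl <- meshGraph(mesh)

    # order markers: nearest-neighbour tour on geodesic distances + 2-opt
    D <- igraph::distances(gl, v = markers, to = markers)
    m <- length(markers)
    tour <- 1L
    left <- setdiff(seq_len(m), tour)
    while (length(left) > 0) {
        nxt <- left[which.min(D[tour[length(tour)], left])]
        tour <- c(tour, nxt)
        left <- setdiff(left, nxt)
    }
    tour <- twoOpt(tour, D)

    ordered <- markers[tour]
    pathVerts <- ordered[1]
    for (s in seq_len(length(ordered) - 1)) {
        sp <- igraph::shortest_paths(gc, from = ordered[s],
                                     to = ordered[s + 1],
                                     output = "vpath")$vpath[[1]]
        pathVerts <- c(pathVerts, as.integer(sp)[-1])
    }
    gap <- D[tour[length(tour)], tour[1]]
    if (is.null(closed))
        closed <- is.finite(gap) &&
            gap <= closeGapFactor * meanEdgeLength(mesh)
    if (closed && length(ordered) > 2) {
        sp <- igraph::shortest_paths(gc, from = ordered[length(ordered)],
                                     to = ordered[1],
                                     output = "vpath")$vpath[[1]]
        extra <- as.integer(sp)[-1]
        pathVerts <- c(pathVerts, extra[-length(extra)])
    }
    fractureLine(mesh@vertices[pathVerts, , drop = FALSE], closed = closed,
                 fragment = fragment)
}

# 2-opt tour improvement on an open path (delta evaluation: reversing
# tour[(i+1)..j] only changes the two cut edges)
twoOpt <- function(tour, D, maxPass = 20) {
    n <- length(tour)
    if (n < 4) return(tour)
    for (pass in seq_len(maxPass)) {
        improved <- FALSE
        for (i in 1:(n - 2)) {
            js <- (i + 1):(n - 1)
            old <- D[cbind(tour[i], tour[i + 1])] +
                D[cbind(tour[js], tour[js + 1])]
            new <- D[cbind(tour[i], tour[js])] +
                D[cbind(tour[i + 1], tour[js + 1])]
            j <- js[which.min(new - old)]
            if (new[j - i] - old[j - i] < -1e-12) {
                tour[(i + 1):j] <- rev(tour[(i + 1):j])
                improved <- TRUE
            }
        }
        if (!improved) break
    }
    tour
}

#' Write fracture lines to JSON
#'
#' Schema: `{"fragment": id, "closed": bool, "points": [[x,y,z],...]}`,
#' one object per line, in mm.
#'
#' @param lines list of [FractureLine-class] (or a single line).
#' @param path output file.
#' @export
writeLinesJson <- function(lines, path) {
    if (is(lines, "FractureLine")) lines <- list(lines)
    recs <- lapply(lines, function(l) list(
        fragment = l@fragment, closed = l@closed,
        points = unname(apply(l@points, 1, function(r) r,
                              simplify = FALSE))))
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' Read fracture lines from JSON
#'
#' @param path file written by [writeLinesJson()].
#' @return list of [FractureLine-class].
#' @export
readLinesJson <- function(path) {
    recs <- jsonlite::read_json(path, simplifyVector = FALSE)
    lapply(recs, function(r) {
        pts <- do.call(rbind, lapply(r$points, function(p)
            as.numeric(unlist(p))))
        fractureLine(pts, closed = isTRUE(r$closed),
                     fragment = if (is.null(r$fragment)) NA_integer_
                                else r$fragment)
    })
}
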