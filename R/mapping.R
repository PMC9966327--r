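## Probability maps: transfer of per-case fracture lines and fragment areas
## onto the mean surface and cohort-level accumulation.

# geodesic ball flags: mean-surface vertices within `radius` of any seed
geodesicFlags <- function(mesh, seeds, radius, g = NULL) {
    n <- nrow(mesh@vertices)
    flags <- integer(n)
    if (length(seeds) == 0) return(flags)
    if (is.null(g)) g <- meshGraph(mesh)
    gs <- igraph::add_vertices(g, 1)
    gs <- igraph::add_edges(gs, rbind(rep(n + 1L, length(seeds)),
                                      as.integer(seeds)),
                            weight = rep(0, length(seeds)))
    d <- as.numeric(igraph::distances(gs, v = n + 1L, to = seq_len(n)))
    flags[d <= radius] <- 1L
    flags
}

#' Map a fracture line into per-vertex incidence on the mean surface
#'
#' The line (given in the same frame as `caseMesh`) is resampled at
#' `radius / 2` arc-length spacing; each sample is pulled back to the mean
#' surface through the inverse correspondence (the mean vertex whose
#' corresponded case point is nearest) and every mean vertex within the
#' geodesic `radius` of a pulled-back vertex is flagged. Incidence is
#' binary per case regardless of multiplicity.
#'
#' @param model a [MeanShapeModel-class].
#' @param corr the case's [CorrespondenceMap-class].
#' @param caseMesh the case surface the correspondence refers to, in the
#'   frame the line lives in.
#' @param line a [FractureLine-class] (or list of lines) on the case
#'   surface.
#' @param radius geodesic kernel radius, mm; default 1.5 x mean edge
#'   length of the mean surface.
#' @return an [IncidenceVector-class] with channel `"fracture_line"`.
#' @export
mapLineIncidence <- function(model, corr, caseMesh, line, radius = NULL) {
    mesh <- model@meanSurface
    if (is.null(radius)) radius <- 1.5 * meanEdgeLength(mesh)
    lines <- if (is(line, "FractureLine")) list(line) else line
    pts <- do.call(rbind, lapply(lines, function(l) {
        if (nrow(l@points) == 0) return(NULL)
        resamplePolyline(l@points, radius / 2, closed = l@closed)
    }))
    if (is.null(pts) || nrow(pts) == 0)
        return(new("IncidenceVector", flags = integer(nrow(mesh@vertices)),
                   caseId = corr@caseId, channel = "fracture_line"))
    cp <- correspondedPoints(corr, caseMesh)
    seeds <- unique(RANN::nn2(cp, pts, k = 1)$nn.idx[, 1])
    flags <- geodesicFlags(mesh, seeds, radius)
    new("IncidenceVector", flags = flags, caseId = corr@caseId,
        channel = "fracture_line")
}

#' Map a reduced fragment's area into per-vertex incidence
#'
#' A mean vertex is flagged iff its corresponded case point lies within
#' `maxDist` of the reduced fragment's surface.
#'
#' @param model a [MeanShapeModel-class].
#' @param corr the case's [CorrespondenceMap-class].
#' @param caseMesh case surface in the frame the fragment is reduced into.
#' @param fragmentMesh the fragment [TriangleMesh-class] (pre-reduction
#'   frame).
#' @param reducedTransform [RigidTransform-class] placing the fragment onto
#'   the case template (identity if already reduced).
#' @param maxDist distance threshold, mm.
#' @return an [IncidenceVector-class] with channel `"fragment_area"`.
#' @export
mapFragmentIncidence <- function(model, corr, caseMesh, fragmentMesh,
                                 reducedTransform = rigidTransform(),
                                 maxDist = 1) {
    cp <- correspondedPoints(corr, caseMesh)
    frag <- applyTransform(reducedTransform, fragmentMesh)
    d <- closestOnMesh(cp, frag)$distance
    new("IncidenceVector", flags = as.integer(d <= maxDist),
        caseId = corr@caseId, channel = "fragment_area")
}

#' Combine incidence vectors of one case (logical OR)
#'
#' @param incidences list of [IncidenceVector-class] of one case and
#'   channel.
#' @return an [IncidenceVector-class].
#' @export
combineIncidence <- function(incidences) {
    stopifnot(length(incidences) >= 1)
    ch <- unique(vapply(incidences, function(iv) iv@channel, ""))
    if (length(ch) != 1) stop("mixed channels")
    flags <- as.integer(Reduce(`|`, lapply(incidences,
                                           function(iv) iv@flags)))
    new("IncidenceVector", flags = flags, caseId = incidences[[1]]@caseId,
        channel = ch)
}

#' Accumulate per-case incidences into a probability map
#'
#' Vertex-wise sum of binary incidences: the per-vertex count of cases
#' whose fracture line (or fragment area) touches that vertex.
#'
#' @param incidences list of [IncidenceVector-class], one per case, all of
#'   one channel and length.
#' @return a [ProbabilityMap-class].
#' @export
accumulateProbability <- function(incidences) {
    stopifnot(length(incidences) >= 1)
    ch <- unique(vapply(incidences, function(iv) iv@channel, ""))
    if (length(ch) != 1) stop("mixed channels in accumulation")
    len <- unique(vapply(incidences, function(iv) length(iv@flags), 0L))
    if (length(len) != 1) stop("incidence vectors differ in length")
    ids <- vapply(incidences, function(iv) iv@caseId, "")
    if (anyDuplicated(ids))
        stop("one incidence vector per case required; duplicated: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    counts <- Reduce(`+`, lapply(incidences, function(iv) iv@flags))
    new("ProbabilityMap", counts = as.integer(counts),
        n = length(incidences), channel = ch)
}

#' Write a probability map as PLY and CSV
#'
#' The PLY carries the counts as the per-vertex `quality` property on the
#' mean surface; the CSV has columns `vertex_id,count` (0-based ids).
#'
#' @param map a [ProbabilityMap-class].
#' @param model the [MeanShapeModel-class] the map lives on.
#' @param plyPath,csvPath output paths (NULL to skip either).
#' @export
writeProbabilityMap <- function(map, model, plyPath = NULL, csvPath = NULL) {
    if (!is.null(plyPath)) {
        mesh <- model@meanSurface
        mesh@vertexData <- data.frame(quality = as.numeric(map@counts))
        writePly(mesh, plyPath)
    }
    if (!is.null(csvPath)) {
        utils::write.csv(data.frame(vertex_id = seq_along(map@counts) - 1L,
                                    count = map@counts),
                         csvPath, row.names = FALSE)
    }
    invisible(NULL)
}

#' Render a probability map in four standard views
#'
#' Flat-shaded orthographic renders (painter's algorithm) in the anterior,
#' lateral, posterior and medial view order, colored by case count, written
#' as one PNG.
#'
#' @param map a [ProbabilityMap-class].
#' @param model the [MeanShapeModel-class].
#' @param path output PNG.
#' @param width,height device size in pixels.
#' @export
renderProbabilityMap <- function(map, model, path, width = 1200,
                                 height = 400) {
    mesh <- model@meanSurface
    v <- mesh@vertices
    tr <- mesh@triangles
    counts <- map@counts
    pal <- grDevices::hcl.colors(max(map@n, 1) + 1, "YlOrRd", rev = TRUE)
    # view directions: anterior (+y), lateral (+x), posterior (-y),
    # medial (-x); z stays up
    views <- list(anterior = c(0, 1, 0), lateral = c(1, 0, 0),
                  posterior = c(0, -1, 0), medial = c(-1, 0, 0))
    grDevices::png(path, width = width, height = height)
    on.exit(grDevices::dev.off())
    graphics::par(mfrow = c(1, 4), mar = c(0.5, 0.5, 2, 0.5))
    for (vn in names(views)) {
        dirv <- views[[vn]]
        up <- c(0, 0, 1)
        right <- c(dirv[2] * up[3] - dirv[3] * up[2],
                   dirv[3] * up[1] - dirv[1] * up[3],
                   dirv[1] * up[2] - dirv[2] * up[1])
        px <- v %*% right
        py <- v %*% up
        depth <- v %*% dirv
        td <- (depth[tr[, 1]] + depth[tr[, 2]] + depth[tr[, 3]]) / 3
        ord <- order(td)
        tc <- pmax(counts[tr[, 1]], counts[tr[, 2]], counts[tr[, 3]])
        graphics::plot(range(px), range(py), type = "n", asp = 1,
                       axes = FALSE, xlab = "", ylab = "", main = vn)
        for (t in ord) {
            graphics::polygon(px[tr[t, ]], py[tr[t, ]],
                              col = pal[tc[t] + 1], border = NA)
        }
    }
    invisible(path)
}
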