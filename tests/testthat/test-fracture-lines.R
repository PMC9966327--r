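test_that("curvature matches analytic surfaces", {
    sph <- sphereMesh(5, nLat = 40, nLon = 80)
    H <- vertexCurvature(sph)
    expect_lt(abs(median(H) - 1 / 5) / (1 / 5), 0.1)
    # signed curvature is positive on a convex surface
    expect_gt(min(smoothVertexField(sph, vertexCurvature(sph, signed = TRUE),
                                    2)), 0)

    sheet <- gridSheetMesh(15, 15, 0.5)
    Hs <- vertexCurvature(sheet)
    inner <- which(apply(meshVertices(sheet)[, 1:2], 1, function(p)
        all(p > 1 & p < 6)))
    expect_lt(max(Hs[inner]), 1e-6)

    cyl <- cylinderMesh(r = 2, h = 8, nz = 30, nTheta = 60)
    Hc <- vertexCurvature(cyl)
    mid <- which(abs(meshVertices(cyl)[, 3]) < 2)
    expect_lt(abs(median(Hc[mid]) - 1 / 4) / (1 / 4), 0.1)

    bad <- triangleMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                              c(0, 1, 0)),
                        rbind(c(1, 2, 3), c(1, 2, 4)))
    expect_error(vertexCurvature(bad), "degenerate")
})

test_that("marker proposal ignores smooth surfaces and finds creases", {
    sph <- sphereMesh(5, nLat = 30, nLon = 60)
    H <- vertexCurvature(sph, signed = TRUE)
    expect_length(proposeGuideMarkers(sph, H, 0.99), 0)

    # tent sheet: two planes meeting at a 90-degree crease along y
    n <- 21
    verts <- as.matrix(expand.grid(x = seq(-5, 5, length.out = n),
                                   y = seq(0, 10, length.out = n)))
    verts <- cbind(verts, 5 - abs(verts[, 1]))
    idx <- function(i, j) (j - 1) * n + i
    tris <- list()
    for (i in seq_len(n - 1)) for (j in seq_len(n - 1)) {
        tris[[length(tris) + 1]] <- c(idx(i, j), idx(i + 1, j),
                                      idx(i + 1, j + 1))
        tris[[length(tris) + 1]] <- c(idx(i, j), idx(i + 1, j + 1),
                                      idx(i, j + 1))
    }
    tent <- triangleMesh(verts, do.call(rbind, tris))
    Ht <- vertexCurvature(tent)
    mk <- proposeGuideMarkers(tent, Ht, 0.8, minCurvature = 0.25)
    expect_gt(length(mk), 3)
    # all markers on the crease x = 0, none on the flats
    expect_lt(max(abs(meshVertices(tent)[mk, 1])), 0.51)

    # two parallel ridge creases at x = +/-2.5 rising from a flat base
    verts2 <- verts
    verts2[, 3] <- pmax(2 - abs(verts2[, 1] - 2.5),
                        2 - abs(verts2[, 1] + 2.5), 0)
    w <- triangleMesh(verts2, do.call(rbind, tris))
    # signed curvature: the two convex ridges are positive, the concave
    # valley between them is negative and must attract no markers
    Hw <- vertexCurvature(w, signed = TRUE)
    mkw <- proposeGuideMarkers(w, Hw, 0.8, minCurvature = 0.25)
    dcrease <- pmin(abs(meshVertices(w)[mkw, 1] - 2.5),
                    abs(meshVertices(w)[mkw, 1] + 2.5))
    expect_lt(max(dcrease), 0.51)
    expect_true(any(meshVertices(w)[mkw, 1] > 0) &&
                any(meshVertices(w)[mkw, 1] < 0))
})

test_that("markers on a planar-cut fragment delineate the cut rim", {
    tr <- neckCutTrace()
    pts <- meshVertices(tr$mesh)[tr$markers, , drop = FALSE]
    d <- RANN::nn2(tr$rim, pts, k = 1)$nn.dists[, 1]
    expect_gt(length(tr$markers), 8)
    # the crest of the blurred cut edge sits within two voxels of the rim
    expect_gte(mean(d <= 1), 0.9)
    expect_lt(max(d), 2)
})

test_that("least-cost tracing follows the rim and matches shortest paths", {
    tr <- neckCutTrace()
    expect_true(isClosed(tr$line))
    expect_lte(curveHausdorff(tr$line, tr$rim, closedB = TRUE), 1.0)
    # every line point is a mesh vertex position
    nn <- RANN::nn2(meshVertices(tr$mesh), linePoints(tr$line), k = 1)
    expect_lt(max(nn$nn.dists), 1e-12)

    # two adjacent markers connect by their single shared edge
    sph <- sphereMesh(3, nLat = 10, nLon = 14)
    e <- meshEdges(sph)[40, ]
    ln <- traceFractureLine(sph, e)
    expect_identical(nrow(linePoints(ln)), 2L)
})

test_that("zero-weight tracing approximates great-circle geodesics", {
    R <- 5
    sph <- sphereMesh(R, nLat = 40, nLon = 80)
    v <- meshVertices(sph)
    # markers near the equator at regular longitudes
    target <- cbind(R * cos(seq(0, 2 * pi, length.out = 13)[-13]),
                    R * sin(seq(0, 2 * pi, length.out = 13)[-13]), 0)
    mk <- unique(RANN::nn2(v, target, k = 1)$nn.idx[, 1])
    ln <- traceFractureLine(sph, mk, weights = c(0, 0), closeGapFactor = 8)
    expect_true(isClosed(ln))
    p <- linePoints(ln)
    len <- sum(sqrt(rowSums((rbind(p[-1, ], p[1, ]) - p)^2)))
    expect_lt(abs(len - 2 * pi * R) / (2 * pi * R), 0.05)
})

test_that("traced paths are optimal on small meshes (exhaustive oracle)", {
    set.seed(8)
    sph <- sphereMesh(2, nLat = 12, nLon = 18)  # 218 vertices
    cv <- vertexCurvature(sph, signed = TRUE)
    ridge <- order(-cv)[1:10]
    ec <- fracmap:::edgeCosts(sph, ridge, 1, 1)
    from <- 3L
    to <- 150L
    dj <- oracleDijkstra(nrow(meshVertices(sph)), ec$edges, ec$cost, from)
    ln <- traceFractureLine(sph, c(from, to), weights = c(1, 1),
                            ridge = ridge)
    # recover the traced vertex path and compare its cost to the oracle
    ids <- RANN::nn2(meshVertices(sph), linePoints(ln), k = 1)$nn.idx[, 1]
    cost <- tracePathCost(sph, ids, ridge, c(1, 1))
    expect_equal(cost, dj$dist[to], tolerance = 1e-12)
})

test_that("path cost is monotone in the weights", {
    sph <- sphereMesh(2, nLat = 10, nLon = 14)
    cv <- vertexCurvature(sph, signed = TRUE)
    ridge <- order(-cv)[1:8]
    path <- as.integer(c(1, meshEdges(sph)[1, 2], 30, 31))
    # hold the path fixed; raising either weight cannot lower the cost
    g <- meshGraph(sph)
    sp <- igraph::shortest_paths(g, 1, 100, output = "vpath")$vpath[[1]]
    path <- as.integer(sp)
    base <- tracePathCost(sph, path, ridge, c(1, 1))
    expect_gte(tracePathCost(sph, path, ridge, c(2, 1)), base)
    expect_gte(tracePathCost(sph, path, ridge, c(1, 2)), base)
    expect_gte(tracePathCost(sph, path, ridge, c(3, 3)), base)
})

test_that("fracture-line JSON round-trips", {
    ln <- fractureLine(matrix(rnorm(15), 5, 3), closed = TRUE, fragment = 2L)
    f <- tempfile(fileext = ".json")
    writeLinesJson(list(ln), f)
    back <- readLinesJson(f)[[1]]
    expect_equal(linePoints(back), linePoints(ln), tolerance = 1e-12)
    expect_true(isClosed(back))
    expect_identical(back@fragment, 2L)
})
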