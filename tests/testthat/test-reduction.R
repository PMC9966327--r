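test_that("mirroring is an involution that preserves orientation", {
    m <- sphereMesh(3, nLat = 12, nLon = 20, center = c(5, 1, -2))
    mm <- mirrorMesh(m, point = c(1, 0, 0), normal = c(1, 0, 0))
    back <- mirrorMesh(mm, point = c(1, 0, 0), normal = c(1, 0, 0))
    expect_lt(max(abs(meshVertices(back) - meshVertices(m))), 1e-12)
    # signed volume preserved, not negated
    expect_equal(meshVolume(mm), meshVolume(m), tolerance = 1e-9)
    expect_error(mirrorMesh(m, normal = c(0, 0, 0)), "non-zero")
    expect_error(mirrorMesh(m, normal = c(2, 0, 0)), "unit")
})

test_that("mirrored right phantom reproduces its left twin", {
    grid <- smallGrid()
    p <- shapeParams(shaftLength = 10)
    left <- makeIntactPhantom(p, grid, seed = 2L)
    p@side <- "right"
    right <- makeIntactPhantom(p, grid, seed = 2L)
    mL <- meshMask(left$truth@intactMask, grid$spacing, grid$origin)
    mR <- meshMask(right$truth@intactMask, grid$spacing, grid$origin)
    ctr <- grid$origin + (grid$dims - 1) * grid$spacing / 2
    mRm <- mirrorMesh(mR, point = ctr, normal = c(1, 0, 0))
    dAB <- max(closestOnMesh(meshVertices(mRm), mL)$distance)
    dBA <- max(closestOnMesh(meshVertices(mL), mRm)$distance)
    expect_lt(max(dAB, dBA), 0.25)  # half a voxel
})

test_that("ICP recovers known displacements of phantom fragments", {
    fr <- neckCutCase()
    tpl <- meshMask(intactCase()$truth@intactMask, spacing(fr$volume),
                    origin(fr$volume), smoothSigma = 1)
    frag <- meshFragmentGray(fr$labels, 1L, fr$volume)

    # already aligned: identity recovery
    r0 <- reduceFragment(frag, tpl)
    expect_lt(r0$residual, 0.3)
    expect_lt(rotationAngle(r0$transform@rotation) * 180 / pi, 1)
    expect_true(all(diff(r0$residuals) <= 1e-12))

    set.seed(31)
    for (rep in 1:3) {
        ax <- rnorm(3)
        ang <- runif(1, 5, 20) * pi / 180
        tr <- rigidTransform(axisAngleRotation(ax, ang),
                             runif(3, -10, 10) * c(1, 1, 0.3) / 2)
        moved <- applyTransform(tr, frag)
        r <- reduceFragment(moved, tpl)
        # recovered transform composed with the displacement ~ identity
        err <- composeTransforms(r$transform, tr)
        expect_lt(rotationAngle(err@rotation) * 180 / pi, 1)
        expect_lt(sqrt(sum(err@translation^2)), 0.2)
        expect_true(all(diff(r$residuals) <= 1e-12))
    }
})

test_that("a 90-degree displacement exceeds the ICP capture range", {
    fr <- neckCutCase()
    tpl <- meshMask(intactCase()$truth@intactMask, spacing(fr$volume),
                    origin(fr$volume), smoothSigma = 1)
    frag <- meshFragmentGray(fr$labels, 2L, fr$volume)
    tr <- rigidTransform(axisAngleRotation(c(0, 1, 0), pi / 2), c(3, 0, 0))
    r <- reduceFragment(applyTransform(tr, frag), tpl, maxIter = 60L)
    err <- composeTransforms(r$transform, tr)
    failed <- !r$converged || r$residual > 0.5 ||
        rotationAngle(err@rotation) * 180 / pi > 5
    expect_true(failed)
})

test_that("transform JSON round-trips and validates", {
    tr <- list("1" = rigidTransform(axisAngleRotation(c(1, 2, 3), 0.4),
                                    c(1.5, -2, 0.25)),
               "2" = rigidTransform())
    f <- tempfile(fileext = ".json")
    saveTransforms(tr, f)
    back <- loadTransforms(f)
    expect_equal(back[["1"]]@rotation, tr[["1"]]@rotation,
                 tolerance = 1e-15)
    expect_equal(back[["1"]]@translation, tr[["1"]]@translation,
                 tolerance = 1e-15)
    expect_equal(back[["2"]]@rotation, diag(3), tolerance = 1e-15)
    # improper rotation (reflection) is rejected
    bad <- list(list(fragment = 1L,
                     matrix = as.numeric(t(diag(c(-1, 1, 1, 1))))))
    fb <- tempfile(fileext = ".json")
    jsonlite::write_json(bad, fb, auto_unbox = TRUE, digits = NA)
    expect_error(loadTransforms(fb), "proper")
    # invalid rotation blocks construction too
    expect_error(rigidTransform(matrix(c(1, 0.1, 0, 0, 1, 0, 0, 0, 1), 3)),
                 "orthonormal")
})

test_that("closest-point line projection is exact and idempotent", {
    sph <- sphereMesh(4, nLat = 24, nLon = 40)
    # points slightly off the surface project back onto it
    set.seed(5)
    raw <- matrix(rnorm(30), 10, 3)
    raw <- 4.8 * raw / sqrt(rowSums(raw^2))
    ln <- fractureLine(raw)
    pj <- projectLineToSurface(ln, sph)
    expect_lt(max(closestOnMesh(linePoints(pj), sph)$distance), 1e-9)
    pj2 <- projectLineToSurface(pj, sph)
    expect_lt(max(abs(linePoints(pj2) - linePoints(pj))), 1e-9)
    # flat sheet: offsetting along the normal is exactly undone
    sheet <- gridSheetMesh(12, 12, 1)
    pts <- cbind(runif(6, 2, 8), runif(6, 2, 8), 0)
    off <- pts
    off[, 3] <- 1
    pjs <- projectLineToSurface(fractureLine(off), sheet)
    expect_lt(max(abs(linePoints(pjs) - pts)), 1e-6)
    # projected distances match the exhaustive per-triangle oracle
    q <- matrix(rnorm(9, sd = 5), 3, 3)
    cp <- closestOnMesh(q, sph)
    for (i in 1:3)
        expect_equal(cp$distance[i], oracleMeshDistance(q[i, ], sph),
                     tolerance = 2e-3)
})
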