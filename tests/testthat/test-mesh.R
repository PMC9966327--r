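test_that("iso-surfaces have the expected topology and volume", {
    d <- c(16, 16, 16)
    one <- array(0L, d)
    one[8, 8, 8] <- 1L
    m1 <- meshFragment(labelMap(one), 1L)
    expect_identical(eulerCharacteristic(m1), 2L)  # topological sphere
    expect_identical(max(meshComponents(m1)), 1L)

    cube <- array(0L, d)
    cube[4:13, 4:13, 4:13] <- 1L
    m2 <- meshFragment(labelMap(cube), 1L)
    expect_identical(eulerCharacteristic(m2), 2L)
    expect_lt(abs(meshVolume(m2) - 1000) / 1000, 0.10)
    expect_gt(meshVolume(m2), 0)  # outward orientation

    # hollow shell: two boundary components
    ph <- intactCase()
    shell <- labelMap(array(as.integer(ph$truth@intactMask),
                            dim(ph$truth@intactMask)),
                      spacing(ph$volume), origin(ph$volume))
    m3 <- meshFragment(shell, 1L, smoothSigma = 1)
    expect_identical(max(meshComponents(m3)), 2L)

    expect_error(meshFragment(shell, 7L), "absent")
})

test_that("grayscale iso-surfacing is sub-voxel accurate on a blurred ball", {
    d <- c(40, 40, 40)
    org <- -(d - 1) / 4
    ax <- lapply(1:3, function(a) org[a] + (seq_len(d[a]) - 1) * 0.5)
    P <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
    r <- sqrt(rowSums(P^2))
    vol <- gaussianBlur(volumeImage(array(700 * (r <= 6), d),
                                    rep(0.5, 3), org), 0.6)
    lm <- labelMap(array(as.integer(vol@values > 350), d), rep(0.5, 3), org)
    m <- meshFragmentGray(lm, 1L, vol)
    rad <- sqrt(rowSums(meshVertices(m)^2))
    expect_lt(abs(mean(rad) - 6), 0.2)
    expect_lt(sd(rad), 0.1)
    expect_lt(abs(meshVolume(m) - 4 / 3 * pi * 6^3) / (4 / 3 * pi * 6^3),
              0.10)
})

test_that("PLY and STL round-trips preserve geometry", {
    m <- sphereMesh(2, nLat = 6, nLon = 8)
    m@vertexData <- data.frame(quality = seq_len(nrow(meshVertices(m))) / 10)
    f <- tempfile(fileext = ".ply")
    writePly(m, f)
    m2 <- readPly(f)
    expect_equal(meshVertices(m2), meshVertices(m), tolerance = 1e-6,
                 ignore_attr = TRUE)
    expect_equal(meshTriangles(m2), meshTriangles(m), ignore_attr = TRUE)
    expect_equal(m2@vertexData$quality, m@vertexData$quality,
                 tolerance = 1e-6)
    fs <- tempfile(fileext = ".stl")
    writeStl(m, fs)
    expect_true(file.size(fs) > 0)
    expect_identical(readLines(fs, n = 1), "solid fracmap")
})

test_that("volume containers read and write NIfTI and MetaImage", {
    arr <- array(rnorm(6 * 5 * 4), c(6, 5, 4))
    v <- volumeImage(arr, c(0.5, 0.6, 0.7), c(-1, 2, 3))
    for (ext in c(".nii.gz", ".mha")) {
        f <- tempfile(fileext = ext)
        writeVolume(v, f)
        v2 <- readVolume(f)
        expect_equal(voxelValues(v2), arr, tolerance = 1e-6,
                     ignore_attr = TRUE)
        expect_equal(spacing(v2), c(0.5, 0.6, 0.7), tolerance = 1e-6)
        expect_equal(origin(v2), c(-1, 2, 3), tolerance = 1e-5)
    }
    lab <- labelMap(array(sample(0:3, 60, TRUE), c(5, 4, 3)))
    f <- tempfile(fileext = ".nii.gz")
    writeVolume(lab, f)
    expect_identical(labelValues(readVolume(f, labels = TRUE)),
                     labelValues(lab))
})

test_that("closest-point queries match the exhaustive oracle", {
    set.seed(4)
    m <- sphereMesh(3, nLat = 8, nLon = 10)
    pts <- matrix(rnorm(3 * 3, sd = 4), 3, 3)
    cp <- closestOnMesh(pts, m)
    for (i in 1:3) {
        expect_equal(cp$distance[i], oracleMeshDistance(pts[i, ], m),
                     tolerance = 2e-3)
        # barycentric reconstruction reproduces the returned point
        tr <- meshTriangles(m)[cp$triangle[i], ]
        rec <- cp$bary[i, 1] * meshVertices(m)[tr[1], ] +
            cp$bary[i, 2] * meshVertices(m)[tr[2], ] +
            cp$bary[i, 3] * meshVertices(m)[tr[3], ]
        expect_equal(unname(rec), unname(cp$points[i, ]), tolerance = 1e-12)
    }
})
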