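test_that("noise-free phantom voxelization matches its own ground truth", {
    ph <- intactCase()
    # in the noise- and blur-free limit the rendered cortex at 700 is the
    # shell mask exactly
    expect_identical(voxelValues(ph$volume) == 700, ph$truth@intactMask)
    # interior and background intensities are as declared
    expect_identical(voxelValues(ph$volume) == 200, ph$truth@interiorMask)
    # landmarks sit on the analytic outer surface
    lm <- primaryLandmarks(ph$truth@landmarks)
    expect_lt(max(abs(ph$truth@outerSurface(lm))), 1e-8)
})

test_that("left and right phantoms are exact mirror images", {
    grid <- smallGrid()
    p <- shapeParams(shaftLength = 10)
    left <- makeIntactPhantom(p, grid, seed = 5L)
    p@side <- "right"
    right <- makeIntactPhantom(p, grid, seed = 5L)
    flipped <- voxelValues(right$volume)[dim(voxelValues(right$volume))[1]:1, , ]
    expect_equal(voxelValues(left$volume), flipped)
    # landmark names are shared and the sets are reflections
    lmL <- primaryLandmarks(left$truth@landmarks)
    lmR <- primaryLandmarks(right$truth@landmarks)
    expect_identical(rownames(lmL), rownames(lmR))
    expect_equal(lmL[, 2:3], lmR[, 2:3], tolerance = 1e-12)
    expect_equal(lmL[, 1], -lmR[, 1], tolerance = 1e-10)
})

test_that("cortical shell thickness measures 4 voxels +/- 1 along normals", {
    ph <- intactCase()
    mask <- ph$truth@intactMask
    sp <- spacing(ph$volume)[1]
    org <- origin(ph$volume)
    set.seed(11)
    # sample rays through the shaft wall and count mask voxels crossed
    thick <- replicate(20, {
        theta <- runif(1, 0, 2 * pi)
        z0 <- runif(1, -8, -4)
        dirv <- c(cos(theta), sin(theta), 0)
        ts <- seq(0, 12, by = sp / 4)
        pts <- cbind(ts * dirv[1], ts * dirv[2], z0)
        idx <- round(sweep(pts, 2, org) / sp) + 1
        lin <- idx[, 1] + (idx[, 2] - 1) * dim(mask)[1] +
            (idx[, 3] - 1) * dim(mask)[1] * dim(mask)[2]
        inshell <- mask[lin]
        if (!any(inshell)) return(NA_real_)
        diff(range(ts[inshell])) / sp + 1
    })
    thick <- thick[!is.na(thick)]
    expect_true(all(abs(thick - 4) <= 1.5))
    expect_lt(abs(median(thick) - 4), 1)
})

test_that("cohort sampling is reproducible and respects its RNG recipe", {
    base <- shapeParams()
    vr <- list(headRadius = 0.04, shaftRadius = 0.05, shaftLength = 0.03,
               corticalThickness = 0.05, tuberosityAmplitude = 0.1)
    a <- sampleCohort(4, base, vr, rightFraction = 0.5, seed = 42L,
                      grid = smallGrid())
    b <- sampleCohort(4, base, vr, rightFraction = 0.5, seed = 42L,
                      grid = smallGrid())
    for (i in seq_along(a)) {
        expect_identical(voxelValues(a[[i]]$volume),
                         voxelValues(b[[i]]$volume))
        expect_identical(a[[i]]$params@side, b[[i]]$params@side)
    }
    # zero variation, rightFraction 0: identical cases
    z <- sampleCohort(3, base, list(), rightFraction = 0, seed = 7L,
                      grid = smallGrid())
    expect_identical(voxelValues(z[[1]]$volume), voxelValues(z[[2]]$volume))
    expect_identical(voxelValues(z[[2]]$volume), voxelValues(z[[3]]$volume))
    # side counts equal an independent replay of the documented RNG order
    n <- 50
    cs <- sampleCohort(n, base, vr, rightFraction = 0.5, seed = 9L,
                      grid = smallGrid())
    got <- sum(vapply(cs, function(x) x$params@side == "right", TRUE))
    set.seed(9L)
    expected <- 0
    for (i in seq_len(n)) {
        rnorm(4 + length(base@tuberosities))
        expected <- expected + (runif(1) < 0.5)
    }
    expect_identical(got, as.integer(expected))
    # landmark names identical across the cohort
    nms <- lapply(cs, function(x) rownames(primaryLandmarks(x$truth@landmarks)))
    expect_true(all(vapply(nms, identical, TRUE, nms[[1]])))
})

test_that("fracture labels conserve the intact mask", {
    fr <- threePartCase()
    ph <- intactCase()
    il <- attr(fr$labels, "intactLabels")
    expect_identical((il > 0) | fr$truth@removedVoxels, ph$truth@intactMask)
    expect_identical(max(labelValues(fr$labels)), 3L)
    # identity displacements, no comminution: displaced labels equal the
    # intact-frame partition
    spec0 <- fractureSpec(cuts = list(list(type = "plane",
                                           point = c(0, 0, -5),
                                           normal = neckCutNormal)))
    fr0 <- applyFracture(ph, spec0)
    expect_identical(labelValues(fr0$labels) > 0, ph$truth@intactMask)
    # determinism: identical spec gives identical output
    fr0b <- applyFracture(ph, spec0)
    expect_identical(voxelValues(fr0$volume), voxelValues(fr0b$volume))
})

test_that("planar cut of a solid cube yields 2 fragments and its rim", {
    d <- c(32, 32, 32)
    sp <- c(1, 1, 1)
    org <- -(d - 1) / 2
    ax <- lapply(1:3, function(a) org[a] + (seq_len(d[a]) - 1))
    P <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
    half <- 8
    boxSdf <- function(pts) apply(abs(pts) - half, 1, max)
    mask <- array(boxSdf(P) <= 0, d)
    vol <- volumeImage(array(700 * mask, d), sp, org)
    truth <- new("GroundTruth", intactMask = mask,
                 removedVoxels = array(FALSE, d), cutCurves = list(),
                 trueDisplacements = list(),
                 landmarks = landmarkSet(matrix(0, 0, 3)),
                 outerSurface = boxSdf, interiorMask = array(FALSE, d))
    spec <- fractureSpec(cuts = list(list(type = "plane", point = c(1, 0, 0),
                                          normal = c(1, 0, 0))))
    fr <- applyFracture(list(volume = vol, truth = truth), spec)
    expect_identical(max(labelValues(fr$labels)), 2L)
    rim <- fr$truth@cutCurves[[1]]
    expect_gt(nrow(rim), 50)
    # the rim lies on the cut plane and on the cube surface
    expect_lt(max(abs(rim[, 1] - 1)), 1e-6)
    expect_lt(max(abs(boxSdf(rim))), 1e-6)
})

test_that("degenerate cuts are rejected", {
    ph <- intactCase()
    spec <- fractureSpec(cuts = list(list(type = "plane",
                                          point = c(0, 0, 100),
                                          normal = c(0, 0, 1))))
    expect_error(applyFracture(ph, spec), "degenerate cut")
})

test_that("comminution removal matches an independent voxel scan", {
    ph <- intactCase()
    ctr <- c(0, 4, -5)
    r <- 2
    spec <- fractureSpec(
        cuts = list(list(type = "plane", point = c(0, 0, -5),
                         normal = neckCutNormal)),
        comminution = list(list(center = ctr, radius = r)))
    fr <- applyFracture(ph, spec)
    d <- dim(ph$truth@intactMask)
    org <- origin(ph$volume)
    sp <- spacing(ph$volume)
    cnt <- 0L
    for (lin in which(ph$truth@intactMask)) {
        ijk <- arrayInd(lin, d)
        w <- org + (ijk - 1) * sp
        if (sum((w - ctr)^2) <= r^2) cnt <- cnt + 1L
    }
    expect_identical(sum(fr$truth@removedVoxels), cnt)
})

test_that("phantom exceeding the grid raises a sizing error", {
    expect_error(makeIntactPhantom(shapeParams(headRadius = 20),
                                   smallGrid()), "exceeds grid")
})
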