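test_that("landmark densification places equally spaced surface points", {
    sheet <- gridSheetMesh(21, 21, 0.5)
    lm <- landmarkSet(rbind(a = c(1, 5, 0), b = c(9, 5, 0)))
    # no secondary landmarks requested: unchanged
    expect_identical(densifyLandmarks(lm, sheet, list(), 5L), lm)
    out <- densifyLandmarks(lm, sheet, list(c("a", "b")), 3L)
    sec <- secondaryLandmarks(out)
    expect_identical(nrow(sec), 3L)
    expected <- cbind(1 + (9 - 1) * (1:3) / 4, 5, 0)
    expect_lt(max(abs(sec - expected)), 0.3)
    # collinear and ordered
    expect_true(all(diff(sec[, 1]) > 0))
    expect_lt(max(abs(sec[, 2] - 5)), 0.3)
})

test_that("geodesic densification on a sphere matches great-circle arcs", {
    R <- 5
    sph <- sphereMesh(R, nLat = 36, nLon = 72)
    a <- c(R, 0, 0)
    b <- c(0, R, 0)
    lm <- landmarkSet(rbind(a = a, b = b))
    out <- densifyLandmarks(lm, sph, list(c("a", "b")), 5L)
    sec <- secondaryLandmarks(out)
    # analytic great-circle subdivision at fractions 1/6..5/6
    fr <- (1:5) / 6
    arc <- pi / 2
    exact <- t(vapply(fr, function(f)
        R * c(cos(f * arc), sin(f * arc), 0), numeric(3)))
    err <- sqrt(rowSums((sec - exact)^2))
    # within 2% of the total arc length
    expect_lt(max(err), 0.02 * R * arc)
    expect_error(densifyLandmarks(landmarkSet(rbind(a = a, z = c(0, 0, 20))),
                                  sph, list(c("a", "q")), 2L), "unknown")
})

test_that("generalized Procrustes recovers transformed copies exactly", {
    set.seed(13)
    base <- matrix(rnorm(30), 10, 3)
    rownames(base) <- paste0("lm", 1:10)
    configs <- lapply(1:6, function(i) {
        R <- axisAngleRotation(rnorm(3), runif(1, 0, pi))
        s <- runif(1, 0.5, 2)
        applyTransform(rigidTransform(R, rnorm(3, sd = 20), s), base)
    })
    gpa <- generalizedProcrustes(configs, withScaling = TRUE)
    resid <- max(vapply(gpa$aligned, function(a) max(abs(a - gpa$mean)), 0))
    expect_lt(resid, 1e-9)
    # mean equals the base configuration up to similarity
    fit <- fitRigid(base, gpa$mean, scale = TRUE)
    expect_lt(max(abs(applyTransform(fit, base) - gpa$mean)), 1e-9)
    # mean is centred
    expect_lt(max(abs(colMeans(gpa$mean))), 1e-9)
    # order invariance
    gpa2 <- generalizedProcrustes(rev(configs), withScaling = TRUE)
    expect_lt(max(abs(gpa2$mean - gpa$mean)), 1e-6)
    # objective never increases (rigid variant)
    gpaR <- generalizedProcrustes(configs, withScaling = FALSE)
    expect_true(all(diff(gpaR$objective) <= 1e-9))
    expect_error(generalizedProcrustes(list(base[1:2, ], base[1:2, ])),
                 "degenerate|landmark")
})

test_that("two-configuration alignment agrees with vegan's procrustes", {
    skip_if_not_installed("vegan")
    set.seed(17)
    X <- matrix(rnorm(24), 8, 3)
    Y <- applyTransform(rigidTransform(axisAngleRotation(c(1, 1, 0), 0.7),
                                       c(3, -1, 2), 1.4), X) +
        matrix(rnorm(24, sd = 0.05), 8, 3)
    ours <- fitRigid(X, Y, scale = TRUE)
    vg <- vegan::procrustes(Y, X)  # rotates X onto Y
    ourFit <- applyTransform(ours, X)
    veganFit <- vg$scale * X %*% vg$rotation +
        matrix(vg$translation, 8, 3, byrow = TRUE)
    expect_lt(max(abs(ourFit - veganFit)), 1e-8)
})

test_that("noisy-landmark Procrustes mean error scales as sigma/sqrt(N)", {
    set.seed(23)
    k <- 20
    N <- 10
    sigma <- 0.1
    truth <- matrix(rnorm(3 * k, sd = 5), k, 3)
    truth <- sweep(truth, 2, colMeans(truth))
    rmse <- replicate(100, {
        configs <- lapply(seq_len(N), function(i)
            truth + matrix(rnorm(3 * k, sd = sigma), k, 3))
        gpa <- generalizedProcrustes(configs, withScaling = FALSE)
        fit <- fitRigid(gpa$mean, truth, scale = FALSE)
        sqrt(mean((applyTransform(fit, gpa$mean) - truth)^2))
    })
    expect_lt(abs(mean(rmse) - sigma / sqrt(N)) / (sigma / sqrt(N)), 0.2)
})

sphereLandmarks <- function(R, caseId = "c") {
    # symmetric set with zero centroid, so the aligned frame keeps the
    # sphere centred at the origin
    d1 <- c(1, 1, 1) / sqrt(3)
    d2 <- c(1, -1, 1) / sqrt(3)
    pts <- rbind(xp = c(R, 0, 0), xm = c(-R, 0, 0), yp = c(0, R, 0),
                 ym = c(0, -R, 0), zp = c(0, 0, R), zm = c(0, 0, -R),
                 d1p = R * d1, d1m = -R * d1, d2p = R * d2, d2m = -R * d2)
    landmarkSet(pts, caseId = caseId)
}

test_that("identical cohorts yield the member as mean shape", {
    sph <- sphereMesh(5, nLat = 16, nLon = 28)
    cohort <- lapply(1:3, function(i)
        list(mesh = sph, landmarks = sphereLandmarks(5, paste0("c", i))))
    model <- buildMeanShape(cohort, withScaling = FALSE, lines = list(),
                            nSecondary = 0L)
    # the mean lives in the aligned frame: compare against the member
    # carried into that frame
    member <- applyTransform(model@transforms[[1]], sph)
    d1 <- max(closestOnMesh(meshVertices(meanSurface(model)),
                            member)$distance)
    expect_lt(d1, 1e-6)
    # correspondence maps are valid barycentric coordinates
    for (corr in model@correspondences) {
        expect_true(all(corr@bary >= 0))
        expect_lt(max(abs(rowSums(corr@bary) - 1)), 1e-6)
        expect_false(any(corr@flagged))
    }
})

test_that("concentric-sphere cohorts average to the middle radius", {
    R <- 5
    cohort <- lapply(c(0.9, 1, 1.1), function(s)
        list(mesh = sphereMesh(s * R, nLat = 24, nLon = 44),
             landmarks = sphereLandmarks(s * R, paste0("r", s))))
    model <- buildMeanShape(cohort, withScaling = FALSE, lines = list(),
                            nSecondary = 0L)
    rad <- sqrt(rowSums(meshVertices(meanSurface(model))^2))
    expect_lt(abs(mean(rad) - R) / R, 0.01)
})

test_that("new cases correspond to the model consistently", {
    sph <- sphereMesh(5, nLat = 16, nLon = 28)
    cohort <- lapply(1:2, function(i)
        list(mesh = sph, landmarks = sphereLandmarks(5, paste0("c", i))))
    model <- buildMeanShape(cohort, withScaling = FALSE, lines = list(),
                            nSecondary = 0L)
    # the mean surface itself corresponds with ~zero displacement
    cc <- correspondCase(model, sph, sphereLandmarks(5, "self"))
    d <- sqrt(rowSums((cc$points - meshVertices(meanSurface(model)))^2))
    expect_lt(max(d), 1e-6)

    # a rigidly moved copy aligns back exactly
    tr <- rigidTransform(axisAngleRotation(c(0, 0, 1), 0.6), c(8, -3, 2))
    moved <- applyTransform(tr, sph)
    lmMoved <- sphereLandmarks(5, "moved")
    lmMoved@primary <- applyTransform(tr, lmMoved@primary)
    cc2 <- correspondCase(model, moved, lmMoved)
    rec <- correspondedPoints(cc2$correspondence, applyTransform(cc2$transform, moved))
    d2 <- sqrt(rowSums((rec - meshVertices(meanSurface(model)))^2))
    expect_lt(max(d2), 1e-6)
    # primary landmarks land near their named counterparts
    mlm <- primaryLandmarks(model@meanLandmarks)
    alignedLm <- applyTransform(cc2$transform,
                                primaryLandmarks(lmMoved))
    expect_lt(max(sqrt(rowSums((alignedLm - mlm)^2))),
              2 * meanEdgeLength(meanSurface(model)))
    expect_error(correspondCase(model, sph, landmarkSet(rbind(a = c(5, 0, 0),
                                                              b = c(0, 5, 0),
                                                              c = c(0, 0, 5)))),
                 "landmark")
})

test_that("mean shape is invariant to rigid perturbation of the inputs", {
    set.seed(41)
    sphA <- sphereMesh(5, nLat = 14, nLon = 24)
    sphB <- sphereMesh(5.5, nLat = 14, nLon = 24)
    cohort <- list(list(mesh = sphA, landmarks = sphereLandmarks(5, "a")),
                   list(mesh = sphB, landmarks = sphereLandmarks(5.5, "b")))
    m0 <- buildMeanShape(cohort, withScaling = FALSE, lines = list(),
                         nSecondary = 0L)
    moved <- lapply(cohort, function(cs) {
        tr <- rigidTransform(axisAngleRotation(rnorm(3), runif(1, 0, 2)),
                             rnorm(3, sd = 10))
        cs$mesh <- applyTransform(tr, cs$mesh)
        cs$landmarks@primary <- applyTransform(tr, cs$landmarks@primary)
        cs
    })
    m1 <- buildMeanShape(moved, withScaling = FALSE, lines = list(),
                         nSecondary = 0L)
    d <- max(abs(meshVertices(meanSurface(m0)) -
                 meshVertices(meanSurface(m1))))
    expect_lt(d, 1e-4)
})
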