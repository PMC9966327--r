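# a trivial "cohort" of two identical flat sheets makes the mean surface
# the sheet itself with identity-like correspondences
sheetModel <- function() {
    sheet <- gridSheetMesh(12, 12, 1)
    lm <- landmarkSet(rbind(a = c(0, 0, 0), b = c(11, 0, 0),
                            c = c(11, 11, 0), d = c(0, 11, 0),
                            e = c(5, 6, 0)))
    cohort <- list(list(mesh = sheet, landmarks = lm),
                   list(mesh = sheet, landmarks = setCaseId(lm, "c2")))
    buildMeanShape(cohort, withScaling = FALSE, lines = list(),
                   nSecondary = 0L)
}

setCaseId <- function(lm, id) {
    lm@caseId <- id
    lm
}

test_that("line incidence flags exactly the traversed vertices", {
    model <- sheetModel()
    mesh <- meanSurface(model)
    corr <- model@correspondences[[1]]
    caseMesh <- mesh  # identical cohort: aligned case surface = mean
    v <- meshVertices(mesh)
    # a straight line through one grid row of vertices
    row <- which(abs(v[, 2] - v[which.min(abs(v[, 2] - 5)), 2]) < 1e-9 &
                 v[, 1] > 1.5 & v[, 1] < 9.5)
    row <- row[order(v[row, 1])]
    ln <- fractureLine(v[row, , drop = FALSE])
    inc <- mapLineIncidence(model, corr, caseMesh, ln, radius = 0.6)
    expect_identical(sort(which(inc@flags == 1)), sort(row))
    # duplicating the line changes nothing (binary per case)
    inc2 <- mapLineIncidence(model, corr, caseMesh, list(ln, ln),
                             radius = 0.6)
    expect_identical(inc2@flags, inc@flags)
    # empty line: all zeros
    inc0 <- mapLineIncidence(model, corr, caseMesh,
                             new("FractureLine"), radius = 0.6)
    expect_true(all(inc0@flags == 0L))
})

test_that("fragment incidence respects the distance threshold", {
    model <- sheetModel()
    corr <- model@correspondences[[1]]
    # the case surface and the fragment live in the case's original frame;
    # carry both into the model's aligned frame
    tr <- model@transforms[[1]]
    sheet <- gridSheetMesh(12, 12, 1)
    half <- gridSheetMesh(6, 12, 1)   # covers x <= 5
    half@vertices[, 3] <- 0.05        # hovers just above the sheet
    caseAligned <- applyTransform(tr, sheet)
    halfAligned <- applyTransform(tr, half)
    inc <- mapFragmentIncidence(model, corr, caseAligned, halfAligned,
                                maxDist = 0.1)
    # mean vertex i corresponds to sheet vertex i of the warp template
    expected <- meshVertices(sheet)[, 1] <= 5.01
    expect_identical(inc@flags == 1L, unname(expected))
    # brute-force distance check on a subsample
    cp <- correspondedPoints(corr, caseAligned)
    idx <- seq(1, nrow(cp), by = 11)
    d <- vapply(idx, function(i) oracleMeshDistance(cp[i, ], halfAligned), 0)
    expect_identical(inc@flags[idx] == 1L, unname(d <= 0.1 + 1e-9))
})

setCaseId2 <- function(iv, id) {
    iv@caseId <- id
    iv
}

test_that("accumulation counts cases and enforces its contract", {
    n <- 20
    mk <- function(flags, id, ch = "fracture_line")
        new("IncidenceVector", flags = as.integer(flags), caseId = id,
            channel = ch)
    a <- mk(rep(c(1L, 0L), c(5, 15)), "a")
    b <- mk(rep(c(0L, 1L, 0L), c(5, 5, 10)), "b")
    same <- accumulateProbability(list(a, setCaseId2(a, "a2"),
                                       setCaseId2(a, "a3")))
    expect_identical(max(mapCounts(same)), 3L)
    expect_identical(sum(mapCounts(same)), 15L)
    disjoint <- accumulateProbability(list(a, b))
    expect_identical(max(mapCounts(disjoint)), 1L)
    # conservation: total mass equals the summed per-case flags
    expect_identical(sum(mapCounts(disjoint)), sum(a@flags) + sum(b@flags))
    # monotonicity: adding a case never decreases any vertex count
    more <- accumulateProbability(list(a, b, setCaseId2(b, "b2")))
    expect_true(all(mapCounts(more) >= mapCounts(disjoint)))
    expect_error(accumulateProbability(list(a, mk(a@flags, "x",
                                                  "fragment_area"))),
                 "mixed")
    expect_error(accumulateProbability(list(a, a)), "duplicated")
    expect_error(new("ProbabilityMap", counts = c(3L, 0L), n = 2L,
                     channel = "fracture_line"), "counts")
})

test_that("probability maps export to PLY and CSV", {
    model <- sheetModel()
    counts <- rep_len(c(0L, 1L, 2L), nrow(meshVertices(meanSurface(model))))
    map <- new("ProbabilityMap", counts = counts, n = 2L,
               channel = "fracture_line")
    ply <- tempfile(fileext = ".ply")
    csv <- tempfile(fileext = ".csv")
    writeProbabilityMap(map, model, ply, csv)
    back <- readPly(ply)
    expect_equal(back@vertexData$quality, as.numeric(counts))
    df <- read.csv(csv)
    expect_identical(df$count, counts)
    expect_identical(df$vertex_id, seq_along(counts) - 1L)
})
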