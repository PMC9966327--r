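test_that("adaptive threshold recovers the shell and rejects flat volumes", {
    ph <- intactCase()
    mask <- adaptiveThreshold(ph$volume, 2L, 100)
    expect_identical(mask, ph$truth@intactMask)
    flat <- volumeImage(array(500, c(10, 10, 10)))
    expect_false(any(adaptiveThreshold(flat, 2L, 50)))
    expect_error(adaptiveThreshold(flat, 12L, 50), "window")
})

test_that("adaptive threshold beats every global threshold on drifting intensities", {
    # constant local contrast (+150) riding on a strong background drift:
    # the slab's intensity range overlaps the background's, so no single
    # global threshold can separate them
    d <- c(60, 20, 20)
    x <- (seq_len(d[1]) - 1) / (d[1] - 1)
    bg <- array(rep(500 * x, times = prod(d[2:3])), d)
    slab <- array(FALSE, d)
    slab[, , 9:12] <- TRUE
    vol <- bg + 150 * slab
    v <- volumeImage(vol)
    mask <- adaptiveThreshold(v, 3L, 80)
    dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
    expect_gte(dice(mask, slab), 0.95)
    # sweep all candidate global thresholds
    cand <- sort(unique(as.numeric(vol)))
    bestGlobal <- max(vapply(cand, function(th) dice(vol > th, slab), 0))
    expect_lt(bestGlobal, 0.95)
})

test_that("gradient magnitude matches analytic ramps", {
    expect_equal(max(gradientMagnitude(volumeImage(array(5, c(6, 6, 6))))), 0)
    d <- c(8, 6, 6)
    ramp <- array(rep(2 * (seq_len(d[1]) - 1), times = prod(d[2:3])), d)
    g1 <- gradientMagnitude(volumeImage(ramp))
    expect_equal(unname(g1[4, 3, 3]), 2)
    expect_true(all(abs(g1[2:7, , ] - 2) < 1e-12))
    g2 <- gradientMagnitude(volumeImage(ramp, spacing = c(0.5, 1, 1)))
    expect_equal(unname(g2[4, 3, 3]), 4)
})

test_that("component labelling follows connectivity and ordering rules", {
    d <- c(10, 10, 10)
    m <- array(FALSE, d)
    m[2:4, 2:4, 2:4] <- TRUE     # 27 voxels
    m[6:7, 6:7, 6:7] <- TRUE     # 8 voxels
    lm <- labelComponents(m, 26)
    expect_identical(max(labelValues(lm)), 2L)
    # larger component gets label 1
    expect_identical(unname(labelValues(lm)[2, 2, 2]), 1L)
    expect_identical(unname(labelValues(lm)[6, 6, 6]), 2L)
    # edge-sharing cubes: connected at 26, separate at 6 (checked against
    # a brute-force flood fill)
    e <- array(FALSE, c(8, 8, 4))
    e[2:3, 2:3, 2] <- TRUE
    e[4:5, 4:5, 2] <- TRUE  # shares only an edge at (3,3)/(4,4)
    expect_identical(max(labelValues(labelComponents(e, 26))), 1L)
    expect_identical(max(labelValues(labelComponents(e, 6))), 2L)
    expect_identical(max(oracleFloodFill(e, 26)), 1L)
    expect_identical(max(oracleFloodFill(e, 6)), 2L)
    # empty mask, and the minimum-size filter
    expect_identical(max(labelValues(labelComponents(array(FALSE, d), 6))), 0L)
    expect_identical(max(labelValues(labelComponents(m, 26, minVoxels = 10))), 1L)
})

test_that("bar splitting reproduces the hand-executed removal loop", {
    vals <- array(c(10, 10, 10, 2, 10, 10, 10), c(7, 1, 1))
    vol <- volumeImage(vals)
    mask <- array(TRUE, c(7, 1, 1))
    markers <- data.frame(group = c(1L, 2L), i = c(1L, 7L), j = 1L, k = 1L)
    sp <- splitFragment(vol, mask, markers, connectivity = 6)
    # gradients peak at indices 3,4,5 (1-based) with equal magnitude; the
    # lexicographic tie-break removes index 3 first, which disconnects
    expect_identical(which(sp$removed), 3L)
    labs <- as.integer(labelValues(sp$labels))
    expect_identical(labs, c(1L, 1L, 0L, 2L, 2L, 2L, 2L))
})

test_that("already-separated markers return components unchanged", {
    vol <- volumeImage(array(10, c(9, 3, 3)))
    mask <- array(FALSE, c(9, 3, 3))
    mask[1:3, , ] <- TRUE
    mask[7:9, , ] <- TRUE
    markers <- data.frame(group = c(1L, 2L), i = c(2L, 8L), j = 2L, k = 2L)
    sp <- splitFragment(vol, mask, markers, 26)
    expect_identical(sum(sp$removed), 0L)
    expect_identical(labelValues(sp$labels) > 0, mask)
    expect_error(splitFragment(vol, mask,
                               data.frame(group = c(1L, 2L), i = c(2L, 5L),
                                          j = 2L, k = 2L), 26),
                 "inside the mask")
})

test_that("splitting satisfies its partition/disconnection/criticality contract", {
    set.seed(21)
    for (rep in 1:4) {
        d <- c(12, 12, 6)
        mask <- array(runif(prod(d)) < 0.75, d)
        # ensure one connected component containing two marker voxels
        comp <- oracleFloodFill(mask, 26)
        big <- which.max(tabulate(comp))
        mask <- comp == big
        vox <- which(mask)
        mk <- sample(vox, 2)
        ijk <- arrayInd(mk, d)
        markers <- data.frame(group = 1:2, i = ijk[, 1], j = ijk[, 2],
                              k = ijk[, 3])
        vol <- volumeImage(array(runif(prod(d), 0, 100), d))
        sp <- splitFragment(vol, mask, markers, 26)
        labs <- labelValues(sp$labels)
        # partition
        expect_identical((labs > 0) | sp$removed |
                         (mask & labs == 0 & !sp$removed), mask)
        expect_false(any(sp$removed & labs > 0))
        # disconnection of the marker groups (flood-fill oracle)
        kept <- mask & !sp$removed
        expect_false(oracleConnected(kept, mk[1], mk[2], 26))
        # criticality: re-adding any removed voxel reconnects the groups
        for (v in which(sp$removed)) {
            trial <- kept
            trial[v] <- TRUE
            expect_true(oracleConnected(trial, mk[1], mk[2], 26))
        }
    }
})
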