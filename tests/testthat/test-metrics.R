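test_that("line-set distances reproduce analytic cases", {
    a <- fractureLine(cbind(seq(0, 10, by = 0.25), 0, 0))
    self <- lineSetDistance(list(a), list(a))
    expect_identical(self@mean, 0)
    expect_identical(self@sd, 0)
    expect_identical(self@nPoints, length(self@distances))

    # parallel straight lines offset by d: mean d, SD 0
    b <- fractureLine(cbind(seq(0, 10, by = 0.25), 1.5, 0))
    ds <- lineSetDistance(list(a), list(b), step = 0.5)
    expect_equal(ds@mean, 1.5, tolerance = 1e-12)
    expect_equal(ds@sd, 0, tolerance = 1e-12)

    # asymmetry: a subset of b scores 0, but not the reverse
    far <- fractureLine(cbind(seq(0, 10, by = 0.25), 40, 0))
    dab <- lineSetDistance(list(a), list(a, far))
    dba <- lineSetDistance(list(a, far), list(a))
    expect_identical(dab@mean, 0)
    expect_gt(dba@mean, 0)
    # brute-force nearest-point oracle for the directional variant
    A <- resamplePolyline(linePoints(a), 0.5)
    B <- resamplePolyline(linePoints(far), 0.5)
    manual <- mean(apply(rbind(A, B), 1, function(p)
        min(sqrt(colSums((t(A) - p)^2)))))
    expect_equal(dba@mean, manual, tolerance = 1e-9)
    expect_error(lineSetDistance(list(), list(a)), "empty")
})

test_that("Dice overlap handles identical, disjoint and partial labels", {
    d <- c(10, 10, 4)
    a <- array(0L, d)
    a[1:4, 1:4, ] <- 1L
    a[6:9, 6:9, ] <- 2L
    A <- labelMap(a)
    expect_equal(unname(labelOverlapDice(A, A)), c(1, 1))
    b <- array(0L, d)
    b[1:4, 1:4, ] <- 2L  # swapped labels: disjoint per pairing
    b[6:9, 6:9, ] <- 1L
    expect_equal(unname(labelOverlapDice(A, labelMap(b))), c(0, 0))
    cc <- array(0L, d)
    cc[3:6, 1:4, ] <- 1L  # half-overlapping equal-size block
    expect_equal(unname(labelOverlapDice(A, labelMap(cc))[1]), 0.5)
    expect_error(labelOverlapDice(A, labelMap(array(0L, c(5, 5, 5)))),
                 "geometry")
})

test_that("curve Hausdorff distance matches analytic and brute force", {
    sq <- rbind(c(0, 0, 0), c(4, 0, 0), c(4, 4, 0), c(0, 4, 0))
    expect_identical(curveHausdorff(sq, sq, closedA = TRUE, closedB = TRUE), 0)
    off <- sweep(sq, 2, c(1, 0, 0), "+")
    expect_equal(curveHausdorff(sq, off, closedA = TRUE, closedB = TRUE), 1,
                 tolerance = 1e-12)
    set.seed(3)
    for (rep in 1:3) {
        A <- matrix(rnorm(24), 8, 3)
        B <- matrix(rnorm(18), 6, 3)
        got <- curveHausdorff(A, B, step = 0.25)
        RA <- resamplePolyline(A, 0.25)
        RB <- resamplePolyline(B, 0.25)
        dd <- as.matrix(dist(rbind(RA, RB)))[seq_len(nrow(RA)),
                                             nrow(RA) + seq_len(nrow(RB))]
        oracle <- max(max(apply(dd, 1, min)), max(apply(dd, 2, min)))
        expect_equal(got, oracle, tolerance = 1e-12)
    }
})

test_that("Hausdorff distance is symmetric and satisfies the triangle inequality", {
    set.seed(9)
    A <- matrix(rnorm(15), 5, 3)
    B <- matrix(rnorm(15), 5, 3)
    C <- matrix(rnorm(15), 5, 3)
    ab <- curveHausdorff(A, B)
    ba <- curveHausdorff(B, A)
    expect_identical(ab, ba)
    expect_lte(curveHausdorff(A, C), ab + curveHausdorff(B, C) + 1e-12)
})

test_that("polyline resampling preserves endpoints and step", {
    p <- rbind(c(0, 0, 0), c(3, 0, 0), c(3, 4, 0))
    r <- resamplePolyline(p, 0.5)
    expect_equal(r[1, ], c(0, 0, 0))
    expect_equal(r[nrow(r), ], c(3, 4, 0))
    seg <- sqrt(rowSums(diff(r)^2))
    expect_lte(max(seg), 0.5 + 1e-9)
    # closed resampling includes the wrap-around segment
    rc <- resamplePolyline(p, 0.5, closed = TRUE)
    total <- sum(sqrt(rowSums(diff(rbind(rc, rc[1, ]))^2)))
    expect_equal(total, 12, tolerance = 0.01)
})
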