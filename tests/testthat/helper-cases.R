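# Shared phantom fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
    if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
    .fixtures[[name]]
}

smallGrid <- function() gridSpec(c(48, 48, 48), c(0.5, 0.5, 0.5))

# a clean intact phantom on the default 64^3 grid
intactCase <- function() {
    fixture("intact64", function()
        makeIntactPhantom(shapeParams(), gridSpec(), seed = 1L))
}

# the standard oblique surgical-neck cut used across tests, with CT-like
# blur (the study's imaging condition) and no displacement
neckCutNormal <- c(0.15, 0, 1) / sqrt(1.0225)

neckCutCase <- function() {
    fixture("neckCut", function() {
        spec <- fractureSpec(
            cuts = list(list(type = "plane", point = c(0, 0, -5),
                             normal = neckCutNormal)),
            blurFwhm = 1.0, seed = 3L)
        applyFracture(intactCase(), spec)
    })
}

# three-part fracture with separating displacements and a comminution zone
threePartSpec <- function(blurFwhm = 1.2, noiseSd = 0, seed = 3L) {
    n1 <- neckCutNormal
    n2 <- c(0.8, 0.2, 0.45) / sqrt(sum(c(0.8, 0.2, 0.45)^2))
    fractureSpec(
        cuts = list(list(type = "plane", point = c(0, 0, -5), normal = n1),
                    list(type = "plane", point = c(3, 0, -1), normal = n2)),
        displacements = list(
            "1" = rigidTransform(axisAngleRotation(c(0, 1, 0), 6 * pi / 180),
                                 2.5 * n1),
            "3" = rigidTransform(axisAngleRotation(c(1, 0, 0), -5 * pi / 180),
                                 2.5 * n2)),
        comminution = list(list(center = c(0, 4, -5), radius = 2)),
        blurFwhm = blurFwhm, noiseSd = noiseSd, seed = seed)
}

threePartCase <- function() {
    fixture("threePart", function() applyFracture(intactCase(),
                                                  threePartSpec()))
}

# neck cut with a true interfragmentary gap (distraction along the cut
# normal), as in displaced fractures; the blurred gap is the partial-volume
# bridge the splitter works on
displacedNeckCase <- function() {
    fixture("displacedNeck", function() {
        spec <- fractureSpec(
            cuts = list(list(type = "plane", point = c(0, 0, -5),
                             normal = neckCutNormal)),
            displacements = list(
                "2" = rigidTransform(diag(3), -0.8 * neckCutNormal)),
            blurFwhm = 1.0, seed = 3L)
        applyFracture(intactCase(), spec)
    })
}

# fragment-1 grayscale mesh of the neck-cut case plus its traced line
neckCutTrace <- function() {
    fixture("neckTrace", function() {
        fr <- neckCutCase()
        msh <- meshFragmentGray(fr$labels, 1L, fr$volume)
        cv <- smoothVertexField(msh, vertexCurvature(msh, signed = TRUE), 4)
        mk <- selectBorderMarkers(msh, cv, fr$volume)
        line <- traceFractureLine(msh, mk, fragment = 1L, closed = TRUE)
        list(case = fr, mesh = msh, curvature = cv, markers = mk,
             line = line, rim = fr$truth@cutCurves[[1]])
    })
}
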