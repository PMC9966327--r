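## Parametric humerus-like phantom: a cortical shell around the union of a
## spherical head and a capsule-shaped shaft, with Gaussian surface bumps
## for the greater and lesser tuberosities. All geometry is analytic
## (signed-distance based) so ground-truth surfaces and landmarks are exact.

INTENSITY_BACKGROUND <- 0
INTENSITY_INTERIOR <- 200
INTENSITY_CORTEX <- 700

#' Construct phantom shape parameters
#'
#' Defaults describe a roughly 40%-scale adult proximal humerus, sized so
#' that a complete phantom fits a 64^3 grid at 0.5 mm spacing with margin.
#'
#' @param headRadius articular head radius, mm.
#' @param shaftRadius shaft radius, mm.
#' @param shaftLength head centre to distal cap centre, mm.
#' @param tuberosities list of Gaussian surface bumps, each
#'   `list(direction, amplitude, sigma)`; directions are unit vectors in the
#'   bone frame (x lateral, y anterior, z proximal for a left bone).
#' @param corticalThickness cortical shell thickness, mm.
#' @param side `"left"` or `"right"`; right-sided phantoms are exact mirror
#'   images (first grid axis) of left-sided ones with the same parameters.
#' @return a [ShapeParams-class].
#' @export
shapeParams <- function(headRadius = 8, shaftRadius = 4, shaftLength = 18,
                        tuberosities = list(
                            list(direction = c(0.85, 0.25, 0.25) /
                                     sqrt(sum(c(0.85, 0.25, 0.25)^2)),
                                 amplitude = 2.0, sigma = 4.5),
                            list(direction = c(0.35, 0.85, 0.15) /
                                     sqrt(sum(c(0.35, 0.85, 0.15)^2)),
                                 amplitude = 1.5, sigma = 4.0)),
                        corticalThickness = 2, side = "left") {
    new("ShapeParams", headRadius = headRadius, shaftRadius = shaftRadius,
        shaftLength = shaftLength, tuberosities = tuberosities,
        corticalThickness = corticalThickness, side = side)
}

#' Construct a fracture specification
#'
#' @param cuts list of cut surfaces: `list(type = "plane", point, normal)`
#'   (world mm) or `list(type = "sheet", point, normal, coef)` with `coef =
#'   c(cuu, cvv, cuv)` quadratic coefficients bending the sheet along its
#'   in-plane axes.
#' @param displacements named list of [RigidTransform-class] keyed by
#'   fragment id.
#' @param comminution list of `list(center, radius)` spheres whose cortical
#'   voxels are deleted.
#' @param noiseSd additive Gaussian noise SD, intensity units.
#' @param blurFwhm Gaussian blur FWHM, mm.
#' @param seed integer RNG seed for the noise field.
#' @return a [FractureSpec-class].
#' @export
fractureSpec <- function(cuts, displacements = list(), comminution = list(),
                         noiseSd = 0, blurFwhm = 0, seed = 1L) {
    new("FractureSpec", cuts = cuts, displacements = displacements,
        comminution = comminution, noiseSd = noiseSd, blurFwhm = blurFwhm,
        seed = as.integer(seed))
}

#' Grid specification helper
#'
#' @param dims integer(3) voxel counts.
#' @param spacing numeric(3) mm.
#' @param origin numeric(3) mm; default centres the grid on the world origin.
#' @return list with `dims`, `spacing`, `origin`.
#' @export
gridSpec <- function(dims = c(64, 64, 64), spacing = c(0.5, 0.5, 0.5),
                     origin = NULL) {
    dims <- as.integer(dims)
    spacing <- as.numeric(spacing)
    if (any(spacing <= 0)) stop("grid spacing must be > 0")
    if (is.null(origin)) origin <- -(dims - 1) * spacing / 2
    list(dims = dims, spacing = spacing, origin = origin)
}

# signed distance (mm) of bone-frame points (n x 3) to the left-sided outer
# surface; negative inside
sdfBoneLeft <- function(P, params) {
    rh <- params@headRadius
    rs <- params@shaftRadius
    L <- params@shaftLength
    dHead <- sqrt(rowSums(P^2)) - rh
    # capsule along -z from the head centre
    z <- pmin(pmax(P[, 3], -L), 0)
    dShaft <- sqrt(P[, 1]^2 + P[, 2]^2 + (P[, 3] - z)^2) - rs
    # smooth union: the metaphyseal flare between head and shaft is a
    # smooth transition, not a reentrant crease
    k <- 1.2
    d <- -k * log(exp(-dHead / k) + exp(-dShaft / k))
    for (tb in params@tuberosities) {
        ctr <- tb$direction * rh
        r2 <- rowSums(sweep(P, 2, ctr)^2)
        d <- d - tb$amplitude * exp(-r2 / (2 * tb$sigma^2))
    }
    d
}

# world -> bone frame (handles chirality); boneOrigin is the head centre in
# world coordinates
worldToBone <- function(P, boneOrigin, side) {
    Q <- sweep(P, 2, boneOrigin)
    if (side == "right") Q[, 1] <- -Q[, 1]
    Q
}

boneToWorld <- function(P, boneOrigin, side) {
    if (side == "right") P[, 1] <- -P[, 1]
    sweep(P, 2, boneOrigin, "+")
}

# phantom bounding box in the left bone frame
phantomExtent <- function(params) {
    amp <- if (length(params@tuberosities))
        max(vapply(params@tuberosities, function(t) t$amplitude, 0)) else 0
    list(rxy = max(params@headRadius, params@shaftRadius) + amp,
         zmin = -(params@shaftLength + params@shaftRadius + amp),
         zmax = params@headRadius + amp)
}

# primary landmark definitions: ray base points and directions in the left
# bone frame; landmarks are the exact ray/surface intersections
landmarkRays <- function(params) {
    rh <- params@headRadius
    L <- params@shaftLength
    dgt <- params@tuberosities[[1]]$direction
    dlt <- if (length(params@tuberosities) > 1)
        params@tuberosities[[2]]$direction else c(0, 1, 0)
    mid <- dgt + dlt
    mid <- mid / sqrt(sum(mid^2))
    zn <- -1.1 * rh
    zs <- -0.7 * L
    list(
        head_apex = list(base = c(0, 0, 0), dir = c(0, 0, 1)),
        gt_peak = list(base = c(0, 0, 0), dir = dgt),
        lt_peak = list(base = c(0, 0, 0), dir = dlt),
        sulcus_mid = list(base = c(0, 0, 0), dir = mid),
        neck_ant = list(base = c(0, 0, zn), dir = c(0, 1, 0)),
        neck_post = list(base = c(0, 0, zn), dir = c(0, -1, 0)),
        neck_lat = list(base = c(0, 0, zn), dir = c(1, 0, 0)),
        neck_med = list(base = c(0, 0, zn), dir = c(-1, 0, 0)),
        shaft_ant = list(base = c(0, 0, zs), dir = c(0, 1, 0)),
        shaft_post = list(base = c(0, 0, zs), dir = c(0, -1, 0)),
        shaft_lat = list(base = c(0, 0, zs), dir = c(1, 0, 0)),
        shaft_med = list(base = c(0, 0, zs), dir = c(-1, 0, 0)))
}

#' Default landmark connecting lines
#'
#' Named primary-landmark pairs along which secondary landmarks are
#' densified for the shape model.
#'
#' @return list of character pairs.
#' @export
defaultLandmarkLines <- function() {
    list(c("head_apex", "gt_peak"), c("head_apex", "lt_peak"),
         c("gt_peak", "shaft_lat"), c("lt_peak", "shaft_ant"),
         c("neck_ant", "neck_lat"), c("neck_post", "neck_med"),
         c("shaft_ant", "shaft_lat"), c("shaft_post", "shaft_med"))
}

#' Generate an intact phantom
#'
#' Renders the cortical shell (intensity 700), medullary interior (200) and
#' background (0) of the parametric bone on the given grid, applies Gaussian
#' blur and additive noise, and returns exact ground truth: the intact shell
#' mask, the analytic signed-distance function of the outer surface, and
#' primary landmarks at parametrically defined surface points.
#'
#' @param params a [ShapeParams-class].
#' @param grid a [gridSpec()] list.
#' @param seed integer seed for the noise field.
#' @param noiseSd noise SD (intensity units).
#' @param blurFwhm blur FWHM, mm.
#' @return list with `volume` ([VolumeImage-class]) and `truth`
#'   ([GroundTruth-class]).
#' @export
makeIntactPhantom <- function(params, grid = gridSpec(), seed = 1L,
                              noiseSd = 0, blurFwhm = 0) {
    ext <- phantomExtent(params)
    worldMin <- grid$origin
    worldMax <- grid$origin + (grid$dims - 1) * grid$spacing
    margin <- 2 * grid$spacing
    # bone frame: head centre on the grid's central x/y axis, z chosen to
    # centre the phantom's z extent
    xc <- (worldMin[1] + worldMax[1]) / 2
    yc <- (worldMin[2] + worldMax[2]) / 2
    zc <- (worldMin[3] + worldMax[3]) / 2 - (ext$zmax + ext$zmin) / 2
    # a long shaft may exit the grid distally, as in clinical fields of
    # view; the proximal end is then pinned at the top margin
    if (zc + ext$zmin < worldMin[3] + margin[3])
        zc <- worldMax[3] - margin[3] - ext$zmax
    boneOrigin <- c(xc, yc, zc)
    if (xc - ext$rxy < worldMin[1] + margin[1] ||
        xc + ext$rxy > worldMax[1] - margin[1] ||
        yc - ext$rxy < worldMin[2] + margin[2] ||
        yc + ext$rxy > worldMax[2] - margin[2] ||
        zc + ext$zmax > worldMax[3] - margin[3])
        stop("phantom exceeds grid (needs >= 2-voxel margin)")

    side <- params@side
    sdfWorld <- function(P) sdfBoneLeft(worldToBone(P, boneOrigin, side),
                                        params)
    ax <- gridAxes(grid$dims, grid$spacing, grid$origin)
    P <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]],
                               KEEP.OUT.ATTRS = FALSE))
    d <- sdfWorld(P)
    t <- params@corticalThickness
    shell <- array(d <= 0 & d > -t, grid$dims)
    interior <- array(d <= -t, grid$dims)

    gray <- array(INTENSITY_BACKGROUND, grid$dims)
    gray[interior] <- INTENSITY_INTERIOR
    gray[shell] <- INTENSITY_CORTEX
    vol <- volumeImage(gray, grid$spacing, grid$origin)
    vol <- renderImaging(vol, blurFwhm, noiseSd, seed)

    lm <- phantomLandmarks(params, boneOrigin)
    truth <- new("GroundTruth",
                 intactMask = shell, fragmentLabels = NULL,
                 removedVoxels = array(FALSE, grid$dims), cutCurves = list(),
                 trueDisplacements = list(), landmarks = lm,
                 outerSurface = sdfWorld, interiorMask = interior)
    list(volume = vol, truth = truth)
}

renderImaging <- function(vol, blurFwhm, noiseSd, seed) {
    if (blurFwhm > 0)
        vol <- gaussianBlur(vol, blurFwhm / (2 * sqrt(2 * log(2))))
    if (noiseSd > 0) {
        set.seed(seed)
        vol@values <- vol@values +
            array(stats::rnorm(length(vol@values), sd = noiseSd),
                  dim(vol@values))
    }
    vol
}

phantomLandmarks <- function(params, boneOrigin) {
    rays <- landmarkRays(params)
    pts <- t(vapply(rays, function(r) {
        f <- function(s) sdfBoneLeft(matrix(r$base + s * r$dir, 1, 3), params)
        smax <- params@headRadius + params@shaftLength +
            params@shaftRadius + 10
        s <- stats::uniroot(f, c(0, smax), tol = 1e-10)$root
        r$base + s * r$dir
    }, numeric(3)))
    pts <- boneToWorld(pts, boneOrigin, params@side)
    rownames(pts) <- names(rays)
    new("LandmarkSet", primary = pts, secondary = matrix(0, 0, 3),
        secondaryLine = character(), caseId = "phantom", side = params@side)
}

#' Sample a cohort of intact phantoms
#'
#' Shape parameters are perturbed per case by independent Gaussian relative
#' deviations; sides are drawn as Bernoulli(`rightFraction`). The RNG
#' procedure, in order per case: one `rnorm` each for head radius, shaft
#' radius, shaft length and cortical thickness; one `rnorm` per tuberosity
#' amplitude; one `runif` for the side; finally one `sample.int` per case
#' for the per-case noise seed (drawn after all shape draws).
#'
#' @param n number of cases.
#' @param base base [ShapeParams-class].
#' @param variation named list of relative SDs with entries among
#'   `headRadius`, `shaftRadius`, `shaftLength`, `corticalThickness`,
#'   `tuberosityAmplitude` (missing entries = 0).
#' @param rightFraction probability that a case is right-sided.
#' @param seed integer master seed.
#' @param grid grid specification for all cases.
#' @param noiseSd,blurFwhm imaging parameters passed to
#'   [makeIntactPhantom()].
#' @return list of per-case lists `(volume, truth, params, caseId)`.
#' @export
sampleCohort <- function(n, base = shapeParams(), variation = list(),
                         rightFraction = 0, seed = 1L, grid = gridSpec(),
                         noiseSd = 0, blurFwhm = 0) {
    stopifnot(n >= 1)
    v <- function(field) if (is.null(variation[[field]])) 0
        else variation[[field]]
    if (any(unlist(variation) < 0)) stop("variation SDs must be >= 0")
    set.seed(seed)
    paramsList <- vector("list", n)
    for (i in seq_len(n)) {
        p <- base
        p@headRadius <- base@headRadius * max(0.1, 1 + stats::rnorm(1) * v("headRadius"))
        p@shaftRadius <- base@shaftRadius * max(0.1, 1 + stats::rnorm(1) * v("shaftRadius"))
        p@shaftLength <- base@shaftLength * max(0.1, 1 + stats::rnorm(1) * v("shaftLength"))
        p@corticalThickness <- base@corticalThickness *
            max(0.1, 1 + stats::rnorm(1) * v("corticalThickness"))
        p@tuberosities <- lapply(base@tuberosities, function(tb) {
            tb$amplitude <- tb$amplitude *
                max(0, 1 + stats::rnorm(1) * v("tuberosityAmplitude"))
            tb
        })
        p@side <- if (stats::runif(1) < rightFraction) "right" else "left"
        paramsList[[i]] <- p
    }
    caseSeeds <- sample.int(.Machine$integer.max - 1L, n)
    lapply(seq_len(n), function(i) {
        case <- makeIntactPhantom(paramsList[[i]], grid, seed = caseSeeds[i],
                                  noiseSd = noiseSd, blurFwhm = blurFwhm)
        case$params <- paramsList[[i]]
        case$caseId <- sprintf("case%03d", i)
        case$truth@landmarks@caseId <- case$caseId
        case
    })
}

# evaluate a cut surface's signed function at world points
cutFunction <- function(cut, P) {
    n <- cut$normal / sqrt(sum(cut$normal^2))
    g <- sweep(P, 2, cut$point) %*% n
    if (identical(cut$type, "sheet")) {
        # quadratic bending along two in-plane axes
        u <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
        u <- u - sum(u * n) * n
        u <- u / sqrt(sum(u^2))
        vv <- c(n[2] * u[3] - n[3] * u[2], n[3] * u[1] - n[1] * u[3],
                n[1] * u[2] - n[2] * u[1])
        pu <- sweep(P, 2, cut$point) %*% u
        pv <- sweep(P, 2, cut$point) %*% vv
        cf <- cut$coef
        g <- g + cf[1] * pu^2 + cf[2] * pv^2 + cf[3] * pu * pv
    }
    as.numeric(g)
}

#' Apply a synthetic fracture to an intact phantom
#'
#' Cortical voxels are partitioned by cut-surface side (exactly-on-surface
#' voxels break ties toward the lower fragment id), comminution-zone voxels
#' are deleted, each fragment is rigidly displaced, and the grayscale is
#' re-rendered (nearest-neighbour labels, trilinear grayscale) with blur and
#' noise per the spec. Ground truth gains fragment labels (displaced frame),
#' removed voxels (intact frame), cut rim curves on the intact outer
#' surface, and the true displacements.
#'
#' @param intact list `(volume, truth)` from [makeIntactPhantom()].
#' @param spec a [FractureSpec-class].
#' @return list `(volume, truth, labels)` where `labels` is the displaced
#'   fragment [LabelMap-class].
#' @export
applyFracture <- function(intact, spec) {
    vol <- intact$volume
    truth <- intact$truth
    dims <- dim(vol@values)
    sp <- vol@spacing
    org <- vol@origin
    ax <- gridAxes(dims, sp, org)
    P <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]],
                               KEEP.OUT.ATTRS = FALSE))

    shell <- truth@intactMask
    interior <- truth@interiorMask

    # region code per voxel from cut-surface sides; g >= 0 counts as the
    # positive side, which implements the lower-id tie-break (codes are
    # mapped to ids in a fixed order)
    nc <- length(spec@cuts)
    code <- integer(prod(dims))
    for (ci in seq_len(nc)) {
        g <- cutFunction(spec@cuts[[ci]], P)
        if (all(g[shell] >= 0) || all(g[shell] < 0))
            stop("degenerate cut: cut ", ci,
                 " does not split the cortical mask")
        code <- code + (g >= 0) * 2L^(ci - 1L)
    }
    codeArr <- array(code, dims)

    shellCodes <- sort(unique(code[shell]))
    sizes <- vapply(shellCodes, function(cd) sum(code[shell] == cd), 0)
    ord <- order(-sizes, shellCodes)
    fragOfCode <- integer(max(shellCodes) + 1L)
    fragOfCode[shellCodes[ord] + 1L] <- seq_along(shellCodes)
    K <- length(shellCodes)
    if (K < 2) stop("cuts must partition the cortical mask into >= 2 pieces")

    labelsIntact <- array(0L, dims)
    labelsIntact[shell] <- fragOfCode[codeArr[shell] + 1L]

    # comminution: delete cortical voxels inside the spheres
    removed <- array(FALSE, dims)
    for (cz in spec@comminution) {
        r2 <- rowSums(sweep(P, 2, cz$center)^2)
        inSphere <- array(r2 <= cz$radius^2, dims)
        removed <- removed | (inSphere & shell)
    }
    labelsIntact[removed] <- 0L

    # displacements: fill missing fragments with identity
    transforms <- vector("list", K)
    names(transforms) <- as.character(seq_len(K))
    for (f in seq_len(K)) {
        tr <- spec@displacements[[as.character(f)]]
        transforms[[f]] <- if (is.null(tr)) rigidTransform() else tr
    }

    # clean (pre-blur) intact grayscale for resampling
    grayClean <- array(INTENSITY_BACKGROUND, dims)
    grayClean[interior] <- INTENSITY_INTERIOR
    grayClean[shell & !removed] <- INTENSITY_CORTEX

    # interior voxels move with the fragment sharing their region code (if
    # that code has cortical voxels; otherwise they stay put)
    interiorFrag <- array(0L, dims)
    icodes <- codeArr[interior]
    known <- icodes %in% shellCodes
    tmp <- integer(sum(interior))
    tmp[known] <- fragOfCode[icodes[known] + 1L]
    interiorFrag[interior] <- tmp

    labelsOut <- array(0L, dims)
    grayOut <- array(INTENSITY_BACKGROUND, prod(dims))
    for (f in seq_len(K)) {
        tr <- transforms[[f]]
        Pb <- applyTransform(invertTransform(tr), P)
        # nearest-neighbour label pull-back
        idx <- worldToIndex(Pb, sp, org)
        ok <- idx[, 1] >= 1 & idx[, 1] <= dims[1] &
              idx[, 2] >= 1 & idx[, 2] <= dims[2] &
              idx[, 3] >= 1 & idx[, 3] <= dims[3]
        lin <- idx[ok, 1] + (idx[ok, 2] - 1) * dims[1] +
            (idx[ok, 3] - 1) * dims[1] * dims[2]
        hit <- logical(prod(dims))
        hit[which(ok)[labelsIntact[lin] == f]] <- TRUE
        newLab <- hit & labelsOut == 0L
        labelsOut[newLab] <- f
        hitInt <- logical(prod(dims))
        hitInt[which(ok)[interiorFrag[lin] == f]] <- TRUE
        fill <- (hit | hitInt) & grayOut == INTENSITY_BACKGROUND
        if (any(fill))
            grayOut[fill] <- trilinear(grayClean, Pb[fill, , drop = FALSE],
                                       sp, org)
    }

    volOut <- volumeImage(array(grayOut, dims), sp, org)
    volOut <- renderImaging(volOut, spec@blurFwhm, spec@noiseSd, spec@seed)

    cutCurves <- lapply(spec@cuts, function(cut)
        cutRimCurve(cut, truth@outerSurface, P, shell, sp, org))

    truth@fragmentLabels <- labelMap(labelsOut, sp, org, relabel = FALSE)
    truth@removedVoxels <- removed
    truth@cutCurves <- cutCurves
    truth@trueDisplacements <- transforms
    # intact-frame labels for conservation checks
    attr(truth@fragmentLabels, "intactLabels") <- labelsIntact
    list(volume = volOut, truth = truth, labels = truth@fragmentLabels)
}

# trilinear interpolation of arr at world points
trilinear <- function(arr, pts, spacing, origin) {
    dims <- dim(arr)
    g <- sweep(sweep(pts, 2, origin), 2, spacing, "/") + 1
    g0 <- pmin(pmax(floor(g), 1), rep(dims - 1, each = nrow(g)))
    fr <- g - g0
    fr <- pmin(pmax(fr, 0), 1)
    out <- numeric(nrow(pts))
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
        w <- (if (dx) fr[, 1] else 1 - fr[, 1]) *
             (if (dy) fr[, 2] else 1 - fr[, 2]) *
             (if (dz) fr[, 3] else 1 - fr[, 3])
        lin <- (g0[, 1] + dx) + (g0[, 2] + dy - 1) * dims[1] +
            (g0[, 3] + dz - 1) * dims[1] * dims[2]
        out <- out + w * arr[lin]
    }
    out
}

# rim of a cut on the intact outer surface: radial root-finding in the cut
# plane around the in-shell centroid of the cut
cutRimCurve <- function(cut, sdf, P, shell, spacing, origin, nTheta = 180L) {
    n <- cut$normal / sqrt(sum(cut$normal^2))
    g <- cutFunction(cut, P)
    near <- shell & array(abs(g) <= max(spacing), dim(shell))
    if (!any(near)) return(matrix(0, 0, 3))
    c0 <- colMeans(P[near, , drop = FALSE])
    c0 <- c0 - sum((c0 - cut$point) * n) * n  # project onto the cut plane
    u <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u <- u - sum(u * n) * n
    u <- u / sqrt(sum(u^2))
    vv <- c(n[2] * u[3] - n[3] * u[2], n[3] * u[1] - n[1] * u[3],
            n[1] * u[2] - n[2] * u[1])
    rmax <- max(sqrt(rowSums(sweep(P[near, , drop = FALSE], 2, c0)^2))) + 5
    theta <- seq(0, 2 * pi, length.out = nTheta + 1L)[-(nTheta + 1L)]
    pts <- matrix(NA_real_, nTheta, 3)
    for (i in seq_len(nTheta)) {
        dirv <- cos(theta[i]) * u + sin(theta[i]) * vv
        f <- function(s) sdf(matrix(c0 + s * dirv, 1, 3))
        if (f(0) >= 0) next
        root <- tryCatch(stats::uniroot(f, c(0, rmax), tol = 1e-9)$root,
                         error = function(e) NA_real_)
        if (!is.na(root)) pts[i, ] <- c0 + root * dirv
    }
    pts[!is.na(pts[, 1]), , drop = FALSE]
}

#' Write phantom ground truth to a directory
#'
#' Volumes as NIfTI, labels as integer NIfTI, landmarks and cut curves as
#' JSON, the shape parameters as YAML.
#'
#' @param case list from [makeIntactPhantom()] / [applyFracture()].
#' @param dir output directory (created).
#' @export
writePhantomCase <- function(case, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    writeVolume(case$volume, file.path(dir, "volume.nii.gz"))
    truth <- case$truth
    sp <- case$volume@spacing
    org <- case$volume@origin
    writeVolume(labelMap(array(as.integer(truth@intactMask),
                               dim(truth@intactMask)), sp, org),
                file.path(dir, "intact_mask.nii.gz"))
    if (!is.null(truth@fragmentLabels))
        writeVolume(truth@fragmentLabels, file.path(dir, "fragment_labels.nii.gz"))
    writeLandmarksJson(truth@landmarks, file.path(dir, "landmarks.json"))
    if (length(truth@cutCurves) > 0) {
        jsonlite::write_json(lapply(truth@cutCurves, function(m)
            unname(apply(m, 1, function(r) r, simplify = FALSE))),
            file.path(dir, "cut_curves.json"), digits = NA)
    }
    if (length(truth@trueDisplacements) > 0)
        saveTransforms(truth@trueDisplacements,
                       file.path(dir, "true_displacements.json"))
    if (!is.null(case$params)) {
        p <- case$params
        yaml::write_yaml(list(headRadius = p@headRadius,
                              shaftRadius = p@shaftRadius,
                              shaftLength = p@shaftLength,
                              corticalThickness = p@corticalThickness,
                              side = p@side),
                         file.path(dir, "params.yaml"))
    }
    invisible(dir)
}

#' Derive split markers from phantom ground truth
#'
#' Stands in for the interactive clicks that indicate the parts to be
#' separated: for each true fragment, the in-mask voxel deepest inside the
#' cortical mask (and away from the other fragments) is returned as that
#' fragment's seed marker.
#'
#' @param truth a fractured-phantom [GroundTruth-class] (with
#'   `fragmentLabels`).
#' @param mask the detected cortical mask the markers must lie in.
#' @return data.frame with columns `group`, `i`, `j`, `k` (1-based), one
#'   marker per true fragment present in `mask`.
#' @export
truthMarkers <- function(truth, mask) {
    labs <- truth@fragmentLabels@labels
    d <- dim(mask)
    bg <- arrayInd(which(!mask), d)
    out <- lapply(seq_len(max(labs)), function(f) {
        idx <- which(labs == f & mask)
        if (length(idx) == 0) return(NULL)
        ijk <- arrayInd(idx, d)
        depth <- RANN::nn2(bg, ijk, k = 1)$nn.dists[, 1]
        other <- arrayInd(which(labs > 0 & labs != f), d)
        away <- RANN::nn2(other, ijk, k = 1)$nn.dists[, 1]
        best <- ijk[which.max(depth + 0.2 * away), ]
        data.frame(group = f, i = best[1], j = best[2], k = best[3])
    })
    do.call(rbind, out)
}
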