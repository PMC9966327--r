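## Statistical shape model: landmark densification along surface geodesics,
## generalized Procrustes alignment, and a mean surface with dense
## per-case correspondence.

#' Construct a LandmarkSet
#'
#' @param primary p x 3 matrix with unique rownames.
#' @param secondary s x 3 matrix.
#' @param secondaryLine connecting-line id per secondary landmark.
#' @param caseId,side identifiers.
#' @return a [LandmarkSet-class].
#' @export
landmarkSet <- function(primary, secondary = matrix(0, 0, 3),
                        secondaryLine = character(), caseId = "case",
                        side = "left") {
    new("LandmarkSet", primary = primary, secondary = secondary,
        secondaryLine = secondaryLine, caseId = caseId, side = side)
}

#' Write landmarks to JSON
#'
#' @param lm a [LandmarkSet-class].
#' @param path output file.
#' @export
writeLandmarksJson <- function(lm, path) {
    out <- list(caseId = lm@caseId, side = lm@side,
                primary = lapply(seq_len(nrow(lm@primary)), function(i)
                    list(name = rownames(lm@primary)[i],
                         point = as.numeric(lm@primary[i, ]))),
                secondary = lapply(seq_len(nrow(lm@secondary)), function(i)
                    list(line = lm@secondaryLine[i],
                         point = as.numeric(lm@secondary[i, ]))))
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' Read landmarks from JSON or CSV
#'
#' CSV must have columns `name,x,y,z` (primary landmarks only); JSON is the
#' format written by [writeLandmarksJson()].
#'
#' @param path input file.
#' @return a [LandmarkSet-class].
#' @export
readLandmarks <- function(path) {
    if (grepl("\\.csv$", path)) {
        df <- utils::read.csv(path)
        m <- as.matrix(df[, c("x", "y", "z")])
        rownames(m) <- df$name
        return(landmarkSet(m))
    }
    r <- jsonlite::read_json(path, simplifyVector = FALSE)
    pm <- do.call(rbind, lapply(r$primary, function(p)
        as.numeric(unlist(p$point))))
    rownames(pm) <- vapply(r$primary, function(p) p$name, "")
    sm <- if (length(r$secondary) > 0)
        do.call(rbind, lapply(r$secondary, function(p)
            as.numeric(unlist(p$point)))) else matrix(0, 0, 3)
    sl <- vapply(r$secondary, function(p) p$line, "")
    landmarkSet(pm, sm, sl, caseId = r$caseId, side = r$side)
}

# near-geodesic path between two surface points: graph shortest path,
# then iterative straightening (midpoint smoothing + closest-point
# reprojection onto the surface)
surfaceGeodesic <- function(surface, from, to, g = NULL, nIter = 30L,
                            step = NULL) {
    if (is.null(g)) g <- meshGraph(surface)
    nn <- RANN::nn2(surface@vertices, rbind(from, to), k = 1)$nn.idx
    sp <- igraph::shortest_paths(g, from = nn[1], to = nn[2],
                                 output = "vpath")$vpath[[1]]
    if (length(sp) == 0)
        stop("landmarks lie on different mesh components")
    pts <- surface@vertices[as.integer(sp), , drop = FALSE]
    pts <- rbind(from, pts, to)
    if (is.null(step)) step <- meanEdgeLength(surface) / 2
    for (it in seq_len(nIter)) {
        pts <- resamplePolyline(pts, step)
        if (nrow(pts) < 3) break
        mid <- (pts[-c(1, 2), , drop = FALSE] +
                pts[-c(nrow(pts) - 1, nrow(pts)), , drop = FALSE]) / 2
        inner <- 0.5 * pts[-c(1, nrow(pts)), , drop = FALSE] + 0.5 * mid
        inner <- closestOnMesh(inner, surface)$points
        pts <- rbind(pts[1, ], inner, pts[nrow(pts), ])
        dup <- c(FALSE, rowSums(diff(pts)^2) == 0)
        pts <- pts[!dup, , drop = FALSE]
    }
    pts
}

#' Densify landmarks along connecting surface lines
#'
#' For each named pair of primary landmarks, computes the surface geodesic
#' between them and places `nSecondary` secondary landmarks at equal
#' arc-length fractions, appended in the (deterministic) order of `lines`.
#'
#' @param landmarks a [LandmarkSet-class] with primary landmarks on the
#'   surface.
#' @param surface the case's [TriangleMesh-class].
#' @param lines list of character pairs of primary landmark names, e.g.
#'   [defaultLandmarkLines()].
#' @param nSecondary secondary landmarks per line (>= 0).
#' @return [LandmarkSet-class] with the secondary landmarks filled in.
#' @export
densifyLandmarks <- function(landmarks, surface, lines, nSecondary) {
    stopifnot(nSecondary >= 0)
    if (nSecondary == 0 || length(lines) == 0) return(landmarks)
    g <- meshGraph(surface)
    sec <- list()
    ids <- character(0)
    for (pair in lines) {
        if (!all(pair %in% rownames(landmarks@primary)))
            stop("unknown landmark name in line: ",
                 paste(pair, collapse = "--"))
        path <- surfaceGeodesic(surface, landmarks@primary[pair[1], ],
                                landmarks@primary[pair[2], ], g = g)
        s <- c(0, cumsum(sqrt(rowSums(diff(path)^2))))
        total <- s[length(s)]
        fr <- seq_len(nSecondary) / (nSecondary + 1)
        pts <- t(vapply(fr * total, function(target) {
            i <- max(which(s <= target))
            if (i == length(s)) return(path[i, ])
            w <- (target - s[i]) / (s[i + 1] - s[i])
            (1 - w) * path[i, ] + w * path[i + 1, ]
        }, numeric(3)))
        sec[[length(sec) + 1]] <- pts
        ids <- c(ids, rep(paste(pair, collapse = "--"), nSecondary))
    }
    landmarks@secondary <- do.call(rbind, sec)
    landmarks@secondaryLine <- ids
    landmarks
}

#' Generalized Procrustes alignment of landmark configurations
#'
#' Iteratively aligns each configuration to the running mean by
#' least-squares similarity (or rigid) superimposition and re-estimates the
#' mean until it stabilizes. The mean is centred at the origin; with
#' scaling, its centroid size is fixed to the average centroid size of the
#' inputs.
#'
#' @param configs list of k x 3 matrices (or [LandmarkSet-class] objects,
#'   whose primary+secondary landmarks are used) with identical landmark
#'   counts and names.
#' @param withScaling allow per-case uniform scaling (default TRUE).
#' @param tol convergence tolerance on the mean's RMS change, mm; default
#'   `1e-6 x mean centroid size`.
#' @param maxIter maximum iterations (default 100).
#' @return list with `aligned` (list of matrices), `mean` (k x 3 matrix),
#'   `transforms` (list of [RigidTransform-class] mapping each original
#'   configuration into the aligned frame), `objective` (per-iteration sum
#'   of squared deviations from the mean) and `iterations`.
#' @export
generalizedProcrustes <- function(configs, withScaling = TRUE, tol = NULL,
                                  maxIter = 100L) {
    X <- lapply(configs, function(cf)
        if (is(cf, "LandmarkSet")) allLandmarks(cf) else cf)
    stopifnot(length(X) >= 2)
    k <- nrow(X[[1]])
    if (any(vapply(X, nrow, 0L) != k))
        stop("all configurations need identical landmark counts")
    nms <- rownames(X[[1]])
    if (!is.null(nms)) {
        for (m in X) if (!is.null(rownames(m)) &&
                         !identical(rownames(m), nms))
            stop("landmark names differ between configurations")
    }
    if (qr(sweep(X[[1]], 2, colMeans(X[[1]])))$rank < 2)
        stop("degenerate configuration: < 3 non-collinear landmarks")
    csize <- function(m) sqrt(sum(sweep(m, 2, colMeans(m))^2))
    s0 <- mean(vapply(X, csize, 0))
    if (is.null(tol)) tol <- 1e-6 * s0
    mu <- sweep(X[[1]], 2, colMeans(X[[1]]))
    if (withScaling) mu <- mu * (s0 / csize(mu))
    transforms <- NULL
    aligned <- X
    objective <- numeric(0)
    iters <- 0L
    repeat {
        iters <- iters + 1L
        transforms <- lapply(X, function(m) fitRigid(m, mu, scale = withScaling))
        aligned <- Map(applyTransform, transforms, X)
        muNew <- Reduce(`+`, aligned) / length(aligned)
        muNew <- sweep(muNew, 2, colMeans(muNew))
        objective <- c(objective,
                       sum(vapply(aligned, function(a) sum((a - muNew)^2), 0)))
        delta <- sqrt(mean((muNew - mu)^2))
        if (withScaling) muNew <- muNew * (s0 / csize(muNew))
        mu <- muNew
        if (delta < tol || iters >= maxIter) break
    }
    # the GPA mean is defined only up to rotation; canonicalize it to its
    # principal axes (signs fixed by the largest-magnitude coordinate) so
    # the result is independent of case order
    sv <- svd(mu)
    V <- sv$v
    for (jx in 1:3) {
        proj <- mu %*% V[, jx]
        if (proj[which.max(abs(proj))] < 0) V[, jx] <- -V[, jx]
    }
    if (det(V) < 0) V[, 3] <- -V[, 3]
    canon <- rigidTransform(t(V))
    mu <- mu %*% V
    aligned <- lapply(aligned, function(a) a %*% V)
    transforms <- lapply(transforms, function(tr) composeTransforms(canon, tr))
    rownames(mu) <- nms
    list(aligned = aligned, mean = mu, transforms = transforms,
         objective = objective, iterations = iters)
}

# 3D thin-plate-style interpolating deformation with kernel U(r) = r;
# returns a function mapping points
tpsFit <- function(X, Y, lambda = 1e-9) {
    k <- nrow(X)
    K <- as.matrix(stats::dist(X))
    diag(K) <- 0
    K <- K + diag(lambda, k)
    P <- cbind(1, X)
    L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4, 4)))
    rhs <- rbind(Y, matrix(0, 4, 3))
    # pseudo-inverse solve: coplanar landmark configurations make the
    # affine block rank-deficient
    sv <- svd(L)
    pos <- sv$d > max(sv$d) * 1e-12
    coef <- sv$v[, pos, drop = FALSE] %*%
        ((t(sv$u[, pos, drop = FALSE]) %*% rhs) / sv$d[pos])
    W <- coef[seq_len(k), , drop = FALSE]
    A <- coef[k + 1:4, , drop = FALSE]
    function(pts) {
        if (!is.matrix(pts)) pts <- matrix(pts, ncol = 3)
        U <- sqrt(pmax(outer(rowSums(pts^2), rep(1, k)) +
                       outer(rep(1, nrow(pts)), rowSums(X^2)) -
                       2 * pts %*% t(X), 0))
        cbind(1, pts) %*% A + U %*% W
    }
}

# correspondence of a target surface given aligned landmarks:
# template/mean vertices are TPS-warped (srcLm -> dstLm) then refined to
# their closest points on the target surface
warpCorrespond <- function(srcVerts, srcLm, dstLm, targetMesh, matchCap) {
    warp <- tpsFit(srcLm, dstLm)
    warped <- warp(srcVerts)
    cp <- closestOnMesh(warped, targetMesh)
    flagged <- cp$distance > matchCap
    list(points = cp$points, triangle = cp$triangle, bary = cp$bary,
         flagged = flagged, distance = cp$distance)
}

#' Build the statistical mean shape of an intact cohort
#'
#' Runs generalized Procrustes alignment on the cohort's (densified)
#' landmark configurations, selects the case closest to the mean
#' configuration as warp template, maps the template surface onto every
#' case by a landmark-interpolating thin-plate deformation followed by
#' closest-point refinement, and averages the corresponded positions in
#' the aligned frame into the mean surface.
#'
#' @param cohort list of per-case lists with elements `mesh`
#'   ([TriangleMesh-class]) and `landmarks` ([LandmarkSet-class]); all
#'   cases must be left-sided (mirror right-sided cases upstream).
#' @param withScaling similarity (TRUE, default) or rigid Procrustes.
#' @param lines,nSecondary densification parameters applied when landmark
#'   sets carry no secondary landmarks yet (see [densifyLandmarks()]).
#' @param matchCap correspondence distance cap, mm: matches beyond it are
#'   flagged; an error is raised if more than 5 percent of vertices flag.
#' @return a [MeanShapeModel-class].
#' @export
buildMeanShape <- function(cohort, withScaling = TRUE,
                           lines = defaultLandmarkLines(), nSecondary = 4L,
                           matchCap = 5) {
    stopifnot(length(cohort) >= 2)
    sides <- vapply(cohort, function(cs) cs$landmarks@side, "")
    if (any(sides != "left"))
        stop("all cohort cases must be left-sided; mirror right cases first")
    lms <- lapply(cohort, function(cs) {
        if (nrow(cs$landmarks@secondary) == 0 && nSecondary > 0)
            densifyLandmarks(cs$landmarks, cs$mesh, lines, nSecondary)
        else cs$landmarks
    })
    gpa <- generalizedProcrustes(lms, withScaling = withScaling)
    n <- length(cohort)
    d2mean <- vapply(seq_len(n), function(i)
        sum((gpa$aligned[[i]] - gpa$mean)^2), 0)
    tpl <- which.min(d2mean)

    tplMeshAligned <- applyTransform(gpa$transforms[[tpl]],
                                     cohort[[tpl]]$mesh)
    tplLmAligned <- gpa$aligned[[tpl]]
    corrs <- vector("list", n)
    sumPos <- matrix(0, nrow(tplMeshAligned@vertices), 3)
    for (i in seq_len(n)) {
        caseMeshAligned <- applyTransform(gpa$transforms[[i]],
                                          cohort[[i]]$mesh)
        wc <- warpCorrespond(tplMeshAligned@vertices, tplLmAligned,
                             gpa$aligned[[i]], caseMeshAligned, matchCap)
        if (mean(wc$flagged) > 0.05)
            stop("correspondence failure for case ", i, ": ",
                 round(100 * mean(wc$flagged)), "% of vertices beyond cap")
        corrs[[i]] <- new("CorrespondenceMap", triangle = wc$triangle,
                          bary = pmax(wc$bary, 0), flagged = wc$flagged,
                          caseId = lms[[i]]@caseId)
        sumPos <- sumPos + wc$points
    }
    meanVerts <- sumPos / n
    meanMesh <- triangleMesh(meanVerts, tplMeshAligned@triangles)

    tplLm <- lms[[tpl]]
    np <- nrow(tplLm@primary)
    meanLm <- landmarkSet(gpa$mean[seq_len(np), , drop = FALSE],
                          gpa$mean[np + seq_len(nrow(tplLm@secondary)), ,
                                   drop = FALSE],
                          tplLm@secondaryLine, caseId = "mean",
                          side = "left")
    rownames(meanLm@primary) <- rownames(tplLm@primary)
    new("MeanShapeModel", meanSurface = meanMesh, meanLandmarks = meanLm,
        correspondences = corrs, transforms = gpa$transforms,
        templateCase = as.integer(tpl),
        caseIds = vapply(lms, function(l) l@caseId, ""),
        scaling = withScaling)
}

#' Correspond a new case to the mean shape
#'
#' Aligns the case to the mean by Procrustes on its landmarks, then maps
#' each mean vertex onto the case surface by the landmark-driven
#' deformation plus closest-point refinement used in [buildMeanShape()].
#'
#' @param model a [MeanShapeModel-class].
#' @param surface the case [TriangleMesh-class].
#' @param landmarks the case [LandmarkSet-class] (same names/structure as
#'   the model's).
#' @param matchCap distance cap, mm (see [buildMeanShape()]).
#' @return list with `correspondence` ([CorrespondenceMap-class]),
#'   `transform` (case-to-aligned-frame [RigidTransform-class]) and
#'   `points` (corresponded case positions, aligned frame).
#' @export
correspondCase <- function(model, surface, landmarks, matchCap = 5) {
    mlm <- allLandmarks(model@meanLandmarks)
    clm <- allLandmarks(landmarks)
    if (nrow(clm) != nrow(mlm))
        stop("landmark count mismatch with the model")
    if (!identical(rownames(landmarks@primary),
                   rownames(model@meanLandmarks@primary)))
        stop("landmark names incompatible with the model")
    tr <- fitRigid(clm, mlm, scale = model@scaling)
    caseAligned <- applyTransform(tr, surface)
    wc <- warpCorrespond(model@meanSurface@vertices, mlm,
                         applyTransform(tr, clm), caseAligned, matchCap)
    if (mean(wc$flagged) > 0.05)
        stop("correspondence failure: ",
             round(100 * mean(wc$flagged)), "% of vertices beyond cap")
    list(correspondence = new("CorrespondenceMap", triangle = wc$triangle,
                              bary = pmax(wc$bary, 0), flagged = wc$flagged,
                              caseId = landmarks@caseId),
         transform = tr, points = wc$points)
}

#' Reconstruct corresponded case positions from a correspondence map
#'
#' @param corr a [CorrespondenceMap-class].
#' @param caseMesh the case surface the map refers to (any rigid frame).
#' @return n x 3 matrix of corresponded positions on `caseMesh`.
#' @export
correspondedPoints <- function(corr, caseMesh) {
    tr <- caseMesh@triangles[corr@triangle, , drop = FALSE]
    v <- caseMesh@vertices
    corr@bary[, 1] * v[tr[, 1], , drop = FALSE] +
        corr@bary[, 2] * v[tr[, 2], , drop = FALSE] +
        corr@bary[, 3] * v[tr[, 3], , drop = FALSE]
}

#' Write a mean-shape model bundle
#'
#' Writes a directory with a YAML manifest: the mean surface (PLY), the
#' mean landmarks (JSON), per-case correspondence maps (JSON: triangle id
#' plus barycentric coordinates per mean vertex) and per-case alignment
#' transforms (JSON).
#'
#' @param model a [MeanShapeModel-class].
#' @param dir output directory (created).
#' @export
writeMeanShapeModel <- function(model, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    writePly(model@meanSurface, file.path(dir, "mean_surface.ply"))
    writeLandmarksJson(model@meanLandmarks,
                       file.path(dir, "mean_landmarks.json"))
    for (i in seq_along(model@correspondences)) {
        corr <- model@correspondences[[i]]
        jsonlite::write_json(
            list(caseId = corr@caseId, triangle = corr@triangle,
                 bary = unname(apply(corr@bary, 1, function(r) r,
                                     simplify = FALSE)),
                 flagged = which(corr@flagged)),
            file.path(dir, sprintf("correspondence_%02d.json", i)),
            auto_unbox = TRUE, digits = NA)
    }
    tr <- model@transforms
    names(tr) <- as.character(seq_along(tr))
    saveTransforms(tr, file.path(dir, "transforms.json"))
    yaml::write_yaml(list(
        type = "fracmap-mean-shape-model",
        cases = model@caseIds,
        templateCase = model@templateCase,
        scaling = model@scaling,
        vertices = nrow(model@meanSurface@vertices),
        files = list(meanSurface = "mean_surface.ply",
                     meanLandmarks = "mean_landmarks.json",
                     transforms = "transforms.json")),
        file.path(dir, "manifest.yaml"))
    invisible(dir)
}

#' Read a mean-shape model bundle
#'
#' @param dir directory written by [writeMeanShapeModel()].
#' @return a [MeanShapeModel-class].
#' @export
readMeanShapeModel <- function(dir) {
    man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
    mesh <- readPly(file.path(dir, man$files$meanSurface))
    lm <- readLandmarks(file.path(dir, man$files$meanLandmarks))
    trs <- loadTransforms(file.path(dir, man$files$transforms))
    corrs <- lapply(seq_along(man$cases), function(i) {
        r <- jsonlite::read_json(
            file.path(dir, sprintf("correspondence_%02d.json", i)),
            simplifyVector = FALSE)
        n <- length(r$triangle)
        flagged <- logical(n)
        flagged[unlist(r$flagged)] <- TRUE
        new("CorrespondenceMap",
            triangle = as.integer(unlist(r$triangle)),
            bary = do.call(rbind, lapply(r$bary, function(b)
                as.numeric(unlist(b)))),
            flagged = flagged, caseId = r$caseId)
    })
    new("MeanShapeModel", meanSurface = mesh, meanLandmarks = lm,
        correspondences = corrs, transforms = unname(trs),
        templateCase = as.integer(man$templateCase),
        caseIds = unlist(man$cases), scaling = isTRUE(man$scaling))
}
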