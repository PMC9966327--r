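## Virtual fracture reduction: mirroring, rigid ICP registration of
## fragments onto the mirrored contralateral template, and closest-point
## projection of fracture lines onto the template surface.

#' Mirror a mesh across a plane
#'
#' Reflects vertices across the plane and reverses triangle winding so that
#' outward normals remain outward (the signed volume is preserved, not
#' negated).
#'
#' @param mesh a [TriangleMesh-class].
#' @param point a point on the mirror plane, mm.
#' @param normal unit plane normal.
#' @return mirrored [TriangleMesh-class].
#' @export
mirrorMesh <- function(mesh, point = c(0, 0, 0), normal = c(1, 0, 0)) {
    nl <- sqrt(sum(normal^2))
    if (nl < .Machine$double.eps) stop("mirror normal must be non-zero")
    if (abs(nl - 1) > 1e-9) stop("mirror normal must be unit length")
    mesh@vertices <- mirrorPoints(mesh@vertices, point, normal)
    mesh@triangles <- mesh@triangles[, c(1, 3, 2), drop = FALSE]
    mesh
}

#' Reflect points across a plane
#'
#' @param pts n x 3 matrix.
#' @param point,normal plane definition (unit normal).
#' @return reflected n x 3 matrix.
#' @export
mirrorPoints <- function(pts, point = c(0, 0, 0), normal = c(1, 0, 0)) {
    d <- sweep(pts, 2, point) %*% normal
    pts - 2 * d %*% t(normal)
}

#' Mirror a landmark set (flips the recorded side)
#'
#' @param lm a [LandmarkSet-class].
#' @param point,normal plane definition (unit normal).
#' @return mirrored [LandmarkSet-class].
#' @export
mirrorLandmarks <- function(lm, point = c(0, 0, 0), normal = c(1, 0, 0)) {
    if (nrow(lm@primary) > 0)
        lm@primary <- mirrorPoints(lm@primary, point, normal)
    if (nrow(lm@secondary) > 0)
        lm@secondary <- mirrorPoints(lm@secondary, point, normal)
    lm@side <- if (lm@side == "left") "right" else "left"
    lm
}

#' Rigid ICP registration of a fragment onto a template surface
#'
#' Iterative closest-point registration of (a deterministic subsample of)
#' the fragment vertices onto the template surface. Each iteration matches
#' points to their exact closest points on the template and applies a
#' point-to-plane least-squares rigid update; if that update would increase
#' the RMS closest-point residual, a point-to-point (Kabsch) update is
#' used instead, so the residual is non-increasing across iterations.
#'
#' @param fragment [TriangleMesh-class] to register.
#' @param template target [TriangleMesh-class].
#' @param init initial [RigidTransform-class] (default identity).
#' @param maxIter maximum iterations (default 200).
#' @param tol convergence threshold on the residual change, mm (default
#'   1e-4).
#' @param maxPoints fragment vertices are subsampled to at most this many
#'   (default 500).
#' @param fovLo,fovHi optional corners (mm) of the imaged field of view:
#'   fragment vertices within `fovMargin` of the box are excluded from the
#'   registration sample, since surfaces clipped at the image border are
#'   artifacts that bias the fit.
#' @param fovMargin margin for the field-of-view exclusion, mm (default
#'   1.5).
#' @return list with `transform` ([RigidTransform-class]), `residual` (RMS
#'   closest-point distance, mm), `converged` (flag), `residuals` (per-
#'   iteration trajectory), `iterations`.
#' @export
reduceFragment <- function(fragment, template, init = rigidTransform(),
                           maxIter = 200L, tol = 1e-4, maxPoints = 500L,
                           fovLo = NULL, fovHi = NULL, fovMargin = 1.5) {
    stopifnot(nrow(fragment@vertices) > 0, nrow(template@vertices) > 0)
    P <- fragment@vertices
    if (!is.null(fovLo) && !is.null(fovHi)) {
        lo <- fovLo + fovMargin
        hi <- fovHi - fovMargin
        inside <- P[, 1] > lo[1] & P[, 2] > lo[2] & P[, 3] > lo[3] &
            P[, 1] < hi[1] & P[, 2] < hi[2] & P[, 3] < hi[3]
        if (sum(inside) >= 50) P <- P[inside, , drop = FALSE]
    }
    if (nrow(P) > maxPoints)
        P <- P[unique(round(seq(1, nrow(P), length.out = maxPoints))), ,
               drop = FALSE]
    tn <- triangleNormals(template)$normals
    T <- init
    resid <- function(Tc) {
        Q <- applyTransform(Tc, P)
        cp <- closestOnMesh(Q, template)
        list(rms = sqrt(mean(cp$distance^2)), Q = Q, cp = cp)
    }
    cur <- resid(T)
    trace <- cur$rms
    converged <- FALSE
    iters <- 0L
    for (it in seq_len(maxIter)) {
        iters <- it
        Q <- cur$Q
        C <- cur$cp$points
        N <- tn[cur$cp$triangle, , drop = FALSE]
        # point-to-plane linearized update: rows (q x n, n) . (w, t) = -(q-c).n
        qxn <- cbind(Q[, 2] * N[, 3] - Q[, 3] * N[, 2],
                     Q[, 3] * N[, 1] - Q[, 1] * N[, 3],
                     Q[, 1] * N[, 2] - Q[, 2] * N[, 1])
        A <- cbind(qxn, N)
        b <- -rowSums((Q - C) * N)
        x <- tryCatch(solve(crossprod(A), crossprod(A, b)),
                      error = function(e) NULL)
        cand <- NULL
        if (!is.null(x)) {
            w <- x[1:3]
            ang <- sqrt(sum(w^2))
            Rstep <- if (ang > .Machine$double.eps)
                axisAngleRotation(w / ang, ang) else diag(3)
            Tstep <- rigidTransform(Rstep, x[4:6])
            cand <- composeTransforms(Tstep, T)
            candRes <- resid(cand)
        }
        if (is.null(cand) || candRes$rms > cur$rms) {
            # fall back to a point-to-point (Kabsch) step, which cannot
            # increase the residual
            Tstep <- fitRigid(Q, C)
            cand <- composeTransforms(Tstep, T)
            candRes <- resid(cand)
            if (candRes$rms > cur$rms) {  # at a local minimum
                converged <- TRUE
                break
            }
        }
        delta <- cur$rms - candRes$rms
        T <- cand
        cur <- candRes
        trace <- c(trace, cur$rms)
        if (delta < tol) {
            converged <- TRUE
            break
        }
    }
    list(transform = T, residual = cur$rms, converged = converged,
         residuals = trace, iterations = iters)
}

#' Principal-axis initialization for fragment registration
#'
#' Aligns the fragment's centroid and principal axes to the template's; the
#' four proper-rotation sign combinations are tried and the one with the
#' smallest closest-point residual is returned.
#'
#' @param fragment,template [TriangleMesh-class] objects.
#' @return a [RigidTransform-class] suitable as `init` for
#'   [reduceFragment()].
#' @export
principalAxisInit <- function(fragment, template) {
    P <- fragment@vertices
    Q <- template@vertices
    cp <- colMeans(P)
    cq <- colMeans(Q)
    Ep <- eigen(stats::cov(P))$vectors
    Eq <- eigen(stats::cov(Q))$vectors
    if (det(Ep) < 0) Ep[, 3] <- -Ep[, 3]
    if (det(Eq) < 0) Eq[, 3] <- -Eq[, 3]
    best <- NULL
    bestRms <- Inf
    sub <- P[unique(round(seq(1, nrow(P), length.out = 200))), ,
             drop = FALSE]
    for (s1 in c(1, -1)) for (s2 in c(1, -1)) {
        S <- diag(c(s1, s2, s1 * s2))
        R <- Eq %*% S %*% t(Ep)
        T <- rigidTransform(R, cq - as.numeric(R %*% cp))
        rms <- sqrt(mean(closestOnMesh(applyTransform(T, sub),
                                       template)$distance^2))
        if (rms < bestRms) {
            bestRms <- rms
            best <- T
        }
    }
    best
}

#' Project a fracture line onto a surface by closest-point matching
#'
#' Each point is replaced by its exact closest point on the surface (over
#' all triangles, not only vertices); ordering and the closed flag are
#' preserved. The operation is idempotent.
#'
#' @param line a [FractureLine-class].
#' @param surface a [TriangleMesh-class].
#' @return projected [FractureLine-class].
#' @export
projectLineToSurface <- function(line, surface) {
    stopifnot(nrow(line@points) > 0)
    cp <- closestOnMesh(line@points, surface)
    fractureLine(cp$points, closed = line@closed, fragment = line@fragment)
}
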