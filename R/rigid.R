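#' Construct a rigid (or similarity) transform
#'
#' @param rotation 3 x 3 proper orthonormal matrix.
#' @param translation numeric(3), mm.
#' @param scale positive scalar (default 1: rigid).
#' @return a [RigidTransform-class].
#' @export
rigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0),
                           scale = 1) {
    new("RigidTransform", rotation = rotation,
        translation = as.numeric(translation), scale = as.numeric(scale))
}

#' Rotation about an axis
#'
#' @param axis numeric(3); normalized internally.
#' @param angle radians.
#' @return 3 x 3 rotation matrix (Rodrigues formula).
#' @export
axisAngleRotation <- function(axis, angle) {
    a <- axis / sqrt(sum(axis^2))
    K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
    diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Rotation angle of a rotation matrix
#'
#' @param R 3 x 3 rotation matrix.
#' @return angle in radians, in `[0, pi]`.
#' @export
rotationAngle <- function(R) {
    acos(max(-1, min(1, (sum(diag(R)) - 1) / 2)))
}

#' @rdname applyTransform
#' @export
setMethod("applyTransform", signature("RigidTransform", "matrix"),
    function(transform, x) {
        t(transform@scale * transform@rotation %*% t(x)) +
            rep(transform@translation, each = nrow(x))
    })

#' @rdname applyTransform
#' @export
setMethod("applyTransform", signature("RigidTransform", "TriangleMesh"),
    function(transform, x) {
        x@vertices <- applyTransform(transform, x@vertices)
        x
    })

#' @rdname applyTransform
#' @export
setMethod("applyTransform", signature("RigidTransform", "FractureLine"),
    function(transform, x) {
        x@points <- applyTransform(transform, x@points)
        x
    })

#' @rdname applyTransform
#' @export
setMethod("applyTransform", signature("RigidTransform", "LandmarkSet"),
    function(transform, x) {
        if (nrow(x@primary) > 0)
            x@primary <- applyTransform(transform, x@primary)
        if (nrow(x@secondary) > 0)
            x@secondary <- applyTransform(transform, x@secondary)
        x
    })

#' Compose two transforms
#'
#' `composeTransforms(a, b)` returns the transform equivalent to applying
#' `b` first, then `a`.
#'
#' @param a,b [RigidTransform-class] objects.
#' @return a [RigidTransform-class].
#' @export
composeTransforms <- function(a, b) {
    rigidTransform(rotation = a@rotation %*% b@rotation,
                   translation = a@scale * as.numeric(a@rotation %*% b@translation) +
                       a@translation,
                   scale = a@scale * b@scale)
}

#' Invert a transform
#'
#' @param transform a [RigidTransform-class].
#' @return the inverse [RigidTransform-class].
#' @export
invertTransform <- function(transform) {
    Rt <- t(transform@rotation)
    rigidTransform(rotation = Rt,
                   translation = -as.numeric(Rt %*% transform@translation) /
                       transform@scale,
                   scale = 1 / transform@scale)
}

#' Least-squares rigid or similarity fit of paired points
#'
#' Kabsch/Umeyama superimposition: the [RigidTransform-class] minimizing
#' `sum_i w_i |s R x_i + t - y_i|^2` over rotations `R`, translations `t`
#' and (optionally) a uniform scale `s`.
#'
#' @param X,Y n x 3 matrices of paired points (moving, fixed).
#' @param scale estimate a uniform scale (default FALSE: rigid).
#' @param weights optional per-point weights.
#' @return a [RigidTransform-class].
#' @export
fitRigid <- function(X, Y, scale = FALSE, weights = NULL) {
    if (is.null(weights)) weights <- rep(1, nrow(X))
    w <- weights / sum(weights)
    cx <- colSums(X * w)
    cy <- colSums(Y * w)
    Xc <- sweep(X, 2, cx)
    Yc <- sweep(Y, 2, cy)
    H <- crossprod(Xc * w, Yc)
    sv <- svd(H)
    d <- sign(det(sv$v %*% t(sv$u)))
    D <- diag(c(1, 1, d))
    R <- sv$v %*% D %*% t(sv$u)
    s <- 1
    if (scale) {
        varx <- sum(w * rowSums(Xc^2))
        s <- sum(diag(D) * sv$d) / varx
    }
    rigidTransform(rotation = R, translation = cy - s * as.numeric(R %*% cx),
                   scale = s)
}

#' Save transforms to JSON
#'
#' Written as `[{"fragment": id, "matrix": [16 numbers, row-major 4x4]}]`.
#'
#' @param transforms named list of [RigidTransform-class] (names = fragment
#'   ids).
#' @param path output file.
#' @export
saveTransforms <- function(transforms, path) {
    recs <- lapply(names(transforms), function(id) {
        tr <- transforms[[id]]
        M <- diag(4)
        M[1:3, 1:3] <- tr@scale * tr@rotation
        M[1:3, 4] <- tr@translation
        list(fragment = as.integer(id), matrix = as.numeric(t(M)))
    })
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' Load fragment transforms from JSON
#'
#' Validates each matrix against the rigid-transform invariants: the upper
#' 3 x 3 block must be `scale * rotation` with an orthonormal, proper
#' rotation; the last row must be `(0, 0, 0, 1)`.
#'
#' @param path JSON file written by [saveTransforms()].
#' @return named list of [RigidTransform-class] keyed by fragment id.
#' @export
loadTransforms <- function(path) {
    if (!file.exists(path)) stop("transform file not found: ", path)
    recs <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.data.frame(recs)) {
        recs <- lapply(seq_len(nrow(recs)), function(i)
            list(fragment = recs$fragment[i], matrix = recs$matrix[[i]]))
    }
    out <- list()
    for (rec in recs) {
        M <- matrix(as.numeric(rec$matrix), 4, 4, byrow = TRUE)
        if (max(abs(M[4, ] - c(0, 0, 0, 1))) > 1e-9)
            stop("transform for fragment ", rec$fragment,
                 ": last row must be (0,0,0,1)")
        A <- M[1:3, 1:3]
        s <- det(A)
        if (s <= 0)
            stop("transform for fragment ", rec$fragment,
                 ": rotation must be proper (det > 0)")
        s <- s^(1 / 3)
        R <- A / s
        if (max(abs(crossprod(R) - diag(3))) > 1e-9)
            stop("transform for fragment ", rec$fragment,
                 ": rotation not orthonormal")
        out[[as.character(rec$fragment)]] <-
            rigidTransform(rotation = R, translation = M[1:3, 4], scale = s)
    }
    out
}
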