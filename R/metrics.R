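## Evaluation metrics: the inter-operator line-distance summary, label
## overlap (Dice) and curve Hausdorff distances.

#' Resample a polyline at a fixed arc-length step
#'
#' @param points k x 3 matrix.
#' @param step arc-length step, mm.
#' @param closed treat the polyline as a closed loop (the closing segment
#'   is included).
#' @return resampled matrix (keeps the first point; last point included
#'   for open lines).
#' @export
resamplePolyline <- function(points, step, closed = FALSE) {
    if (!is.matrix(points)) points <- matrix(points, ncol = 3)
    if (nrow(points) < 2) return(points)
    if (closed) points <- rbind(points, points[1, ])
    seg <- sqrt(rowSums(diff(points)^2))
    s <- c(0, cumsum(seg))
    total <- s[length(s)]
    if (total == 0) return(points[1, , drop = FALSE])
    targets <- seq(0, total, by = step)
    if (!closed && targets[length(targets)] < total)
        targets <- c(targets, total)
    if (closed) targets <- targets[targets < total]
    out <- t(vapply(targets, function(target) {
        i <- findInterval(target, s, rightmost.closed = TRUE)
        i <- min(max(i, 1), length(s) - 1)
        w <- (target - s[i]) / max(s[i + 1] - s[i], .Machine$double.eps)
        (1 - w) * points[i, ] + w * points[i + 1, ]
    }, numeric(3)))
    out
}

linePointMatrix <- function(x, step) {
    if (is(x, "FractureLine")) x <- list(x)
    if (is.matrix(x)) x <- list(x)
    do.call(rbind, lapply(x, function(l) {
        if (is(l, "FractureLine"))
            resamplePolyline(l@points, step, closed = l@closed)
        else resamplePolyline(l, step)
    }))
}

#' Closest-point distances between two fracture-line sets
#'
#' Both sets are resampled at a common arc-length step; for every sampled
#' point of `a` the closest Euclidean distance to any sampled point of `b`
#' is computed, and the mean and SD over all points of `a` are reported.
#' The measure is directional (`a` to `b`); `symmetric = TRUE` pools both
#' directions.
#'
#' @param a,b lists of [FractureLine-class] (or point matrices).
#' @param step resampling step, mm (default 0.5).
#' @param symmetric pool distances of both directions (default FALSE).
#' @return a [DistanceSummary-class].
#' @export
lineSetDistance <- function(a, b, step = 0.5, symmetric = FALSE) {
    A <- linePointMatrix(a, step)
    B <- linePointMatrix(b, step)
    if (is.null(A) || is.null(B) || nrow(A) == 0 || nrow(B) == 0)
        stop("empty line set")
    d <- RANN::nn2(B, A, k = 1)$nn.dists[, 1]
    direction <- "a_to_b"
    if (symmetric) {
        d <- c(d, RANN::nn2(A, B, k = 1)$nn.dists[, 1])
        direction <- "symmetric"
    }
    new("DistanceSummary", mean = mean(d),
        sd = if (length(d) > 1) stats::sd(d) else 0,
        nPoints = length(d), distances = d, direction = direction)
}

#' Per-fragment Dice overlap between two label maps
#'
#' @param a,b [LabelMap-class] objects on the same grid.
#' @param pairing two-column matrix of (label in `a`, label in `b`) pairs;
#'   default pairs identical labels present in either map.
#' @return named numeric vector of Dice fractions
#'   `2|A n B| / (|A| + |B|)`.
#' @export
labelOverlapDice <- function(a, b, pairing = NULL) {
    if (!all(dim(a@labels) == dim(b@labels)) ||
        max(abs(a@spacing - b@spacing)) > 1e-9)
        stop("label maps must share the same grid geometry")
    if (is.null(pairing)) {
        labs <- sort(union(setdiff(unique(as.integer(a@labels)), 0L),
                           setdiff(unique(as.integer(b@labels)), 0L)))
        pairing <- cbind(labs, labs)
    }
    out <- apply(pairing, 1, function(pr) {
        A <- a@labels == pr[1]
        B <- b@labels == pr[2]
        den <- sum(A) + sum(B)
        if (den == 0) return(NA_real_)
        2 * sum(A & B) / den
    })
    names(out) <- paste(pairing[, 1], pairing[, 2], sep = ":")
    out
}

#' Symmetric Hausdorff distance between two polylines
#'
#' Both curves are resampled at a common step; the symmetric Hausdorff
#' distance (max over both directions of the max-min point distance) is
#' returned.
#'
#' @param a,b polylines (k x 3 matrices or [FractureLine-class]).
#' @param step resampling step, mm (default 0.5).
#' @param closedA,closedB treat the inputs as closed loops (defaults taken
#'   from [FractureLine-class] inputs).
#' @return distance, mm.
#' @export
curveHausdorff <- function(a, b, step = 0.5, closedA = NULL,
                           closedB = NULL) {
    getp <- function(x, closed) {
        if (is(x, "FractureLine")) {
            if (is.null(closed)) closed <- x@closed
            x <- x@points
        }
        resamplePolyline(x, step, closed = isTRUE(closed))
    }
    A <- getp(a, closedA)
    B <- getp(b, closedB)
    if (nrow(A) == 0 || nrow(B) == 0) stop("empty polyline")
    dab <- max(RANN::nn2(B, A, k = 1)$nn.dists[, 1])
    dba <- max(RANN::nn2(A, B, k = 1)$nn.dists[, 1])
    max(dab, dba)
}
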