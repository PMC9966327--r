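## Cortical pre-segmentation and marker-driven fragment splitting.

# shift a 3D array along one axis by k voxels, filling with `fill`
shiftArray <- function(arr, axis, k, fill) {
    if (k == 0) return(arr)
    d <- dim(arr)
    if (abs(k) >= d[axis]) return(array(fill, d))
    out <- array(fill, d)
    src <- lapply(d, seq_len)
    dst <- src
    if (k > 0) {
        dst[[axis]] <- (k + 1):d[axis]
        src[[axis]] <- 1:(d[axis] - k)
    } else {
        dst[[axis]] <- 1:(d[axis] + k)
        src[[axis]] <- (1 - k):d[axis]
    }
    out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
    out
}

# separable local box mean with border truncation (per-axis renormalized)
localBoxMean <- function(arr, radius) {
    d <- dim(arr)
    for (a in 1:3) {
        n <- d[a]
        i <- rep(seq_len(n), each = 2 * radius + 1)
        j <- i + rep(seq(-radius, radius), times = n)
        keep <- j >= 1 & j <= n
        K <- Matrix::sparseMatrix(i = i[keep], j = j[keep],
                                  x = rep(1, sum(keep)), dims = c(n, n))
        K <- K / Matrix::rowSums(K)
        perm <- c(a, setdiff(1:3, a))
        vp <- aperm(arr, perm)
        dm <- dim(vp)
        vp <- as.matrix(K %*% matrix(vp, nrow = dm[1]))
        dim(vp) <- dm
        arr <- aperm(vp, order(perm))
    }
    arr
}

# local box min/max via iterated per-axis shift reductions
localBoxExtreme <- function(arr, radius, op = pmax) {
    fill <- if (identical(op, pmax)) -Inf else Inf
    for (a in 1:3) {
        acc <- arr
        for (k in seq_len(radius)) {
            acc <- op(acc, shiftArray(arr, a, k, fill),
                      shiftArray(arr, a, -k, fill))
        }
        arr <- acc
    }
    arr
}

#' Adaptive (locally referenced) threshold
#'
#' A voxel is foreground iff its intensity exceeds the mean of its local
#' cubic window by a contrast-dependent offset
#' (`offsetFraction * minContrast`), and the local intensity range within
#' the window reaches `minContrast`; low-contrast windows are background.
#' This realizes cortical pre-segmentation robust to intensity drift, where
#' a single global threshold fails.
#'
#' @param volume a [VolumeImage-class].
#' @param windowRadius window half-width in voxels (window = cube of side
#'   `2*windowRadius+1`).
#' @param minContrast minimum local range (intensity units) for a window to
#'   contain structure.
#' @param offsetFraction offset above the local mean, as a fraction of
#'   `minContrast` (default 0.25).
#' @return logical 3D array (the cortical mask).
#' @export
adaptiveThreshold <- function(volume, windowRadius = 2L, minContrast = 100,
                              offsetFraction = 0.25) {
    if (windowRadius < 1) stop("windowRadius must be >= 1")
    d <- dim(volume@values)
    if (any(2 * windowRadius + 1 > d))
        stop("window larger than volume")
    v <- volume@values
    mu <- localBoxMean(v, windowRadius)
    hi <- localBoxExtreme(v, windowRadius, pmax)
    lo <- localBoxExtreme(v, windowRadius, pmin)
    (v > mu + offsetFraction * minContrast) & (hi - lo >= minContrast)
}

#' Gradient magnitude of a volume
#'
#' Central differences per axis divided by the physical spacing (one-sided
#' at the grid boundaries), combined as the Euclidean norm; units are
#' intensity per mm.
#'
#' @param volume a [VolumeImage-class].
#' @return 3D numeric array.
#' @export
gradientMagnitude <- function(volume) {
    v <- volume@values
    d <- dim(v)
    g2 <- array(0, d)
    for (a in 1:3) {
        if (d[a] < 2) next  # no variation along a singleton axis
        h <- volume@spacing[a]
        fwd <- shiftArray(v, a, -1, NA)  # value at index+1
        bwd <- shiftArray(v, a, 1, NA)   # value at index-1
        gr <- (fwd - bwd) / (2 * h)
        # one-sided differences at the two boundary slices
        lo <- lapply(d, seq_len); lo[[a]] <- 1L
        hi <- lapply(d, seq_len); hi[[a]] <- d[a]
        gr[lo[[1]], lo[[2]], lo[[3]]] <-
            (fwd - v)[lo[[1]], lo[[2]], lo[[3]]] / h
        gr[hi[[1]], hi[[2]], hi[[3]]] <-
            (v - bwd)[hi[[1]], hi[[2]], hi[[3]]] / h
        g2 <- g2 + gr^2
    }
    sqrt(g2)
}

# neighbor offset table for 6/26 connectivity (positive half only)
halfOffsets <- function(connectivity) {
    offs <- expand.grid(a = -1:1, b = -1:1, c = -1:1)
    offs <- offs[offs$a != 0 | offs$b != 0 | offs$c != 0, ]
    if (connectivity == 6)
        offs <- offs[abs(offs$a) + abs(offs$b) + abs(offs$c) == 1, ]
    # keep one of each +/- pair
    key <- offs$a * 9 + offs$b * 3 + offs$c
    offs[key > 0, ]
}

#' Label connected components of a binary mask
#'
#' Components are labelled `1..K` ordered by descending voxel count, ties
#' broken by the smallest lexicographic `(i, j, k)` seed voxel. Components
#' smaller than `minVoxels` are discarded (treated as noise).
#'
#' @param mask logical 3D array.
#' @param connectivity 6 or 26.
#' @param spacing,origin voxel geometry for the returned map.
#' @param minVoxels discard components with fewer voxels (default 0: keep
#'   all).
#' @return a [LabelMap-class].
#' @export
labelComponents <- function(mask, connectivity = 26, spacing = c(1, 1, 1),
                            origin = c(0, 0, 0), minVoxels = 0L) {
    stopifnot(connectivity %in% c(6, 26))
    d <- dim(mask)
    fg <- which(mask)
    out <- array(0L, d)
    if (length(fg) == 0)
        return(labelMap(out, spacing, origin, relabel = FALSE))
    vid <- integer(prod(d))
    vid[fg] <- seq_along(fg)
    offs <- halfOffsets(connectivity)
    edges <- list()
    for (r in seq_len(nrow(offs))) {
        sh <- shiftArray(mask, 1, -offs$a[r], FALSE)
        sh <- shiftArray(sh, 2, -offs$b[r], FALSE)
        sh <- shiftArray(sh, 3, -offs$c[r], FALSE)
        both <- which(mask & sh)
        if (length(both) == 0) next
        nb <- both + offs$a[r] + offs$b[r] * d[1] + offs$c[r] * d[1] * d[2]
        edges[[length(edges) + 1]] <- cbind(vid[both], vid[nb])
    }
    g <- igraph::graph_from_edgelist(do.call(rbind, c(edges,
            list(cbind(seq_along(fg), seq_along(fg))))), directed = FALSE)
    comp <- igraph::components(g)$membership[seq_along(fg)]
    sizes <- tabulate(comp)
    ijk <- arrayInd(fg, d)
    lexkey <- (ijk[, 1] * d[2] + ijk[, 2]) * d[3] + ijk[, 3]
    seedKey <- vapply(seq_along(sizes), function(cc)
        min(lexkey[comp == cc]), numeric(1))
    keep <- which(sizes >= max(1, minVoxels))
    ordc <- keep[order(-sizes[keep], seedKey[keep])]
    lut <- integer(length(sizes))
    lut[ordc] <- seq_along(ordc)
    out[fg] <- lut[comp]
    labelMap(out, spacing, origin, relabel = FALSE)
}

#' Read seed markers from JSON
#'
#' Format: `[{"group": 1, "index": [i, j, k]}, ...]` with 0-based voxel
#' indices.
#'
#' @param path JSON file.
#' @return data.frame with columns `group`, `i`, `j`, `k` (1-based).
#' @export
readMarkersJson <- function(path) {
    recs <- jsonlite::read_json(path, simplifyVector = TRUE)
    idx <- do.call(rbind, recs$index)
    data.frame(group = as.integer(recs$group), i = idx[, 1] + 1L,
               j = idx[, 2] + 1L, k = idx[, 3] + 1L)
}

#' Split a connected fragment along its grayscale gradient
#'
#' Implements marker-driven separation of not-fully-detached fragments:
#' in-mask voxels are iteratively removed in order of decreasing gradient
#' magnitude (computed once from the input grayscale; ties broken by the
#' smallest lexicographic `(i, j, k)` index) until no two marker groups
#' remain connected. Scanning the removed voxels in removal order, each
#' voxel whose re-addition does not reconnect two marker groups is then
#' added back. Surviving voxels are labelled with the group id of the
#' marker group they connect to; pockets sealed off behind the removed
#' barrier (connected to no group) are attached to the group of their
#' nearest labelled voxel, which cannot reconnect any groups since they
#' touch none directly (disable with `attachOrphans = FALSE` to leave
#' them unlabelled).
#'
#' @param volume grayscale [VolumeImage-class] (gradients are computed from
#'   it).
#' @param mask logical 3D array to split.
#' @param markers data.frame with columns `group`, `i`, `j`, `k` (1-based
#'   voxel indices), at least 2 distinct groups.
#' @param connectivity 6 or 26.
#' @param attachOrphans attach sealed-off unlabelled pockets to their
#'   nearest fragment (default TRUE).
#' @return list with `labels` (a [LabelMap-class]), `groups` (group id per
#'   label) and `removed` (logical array of finally removed voxels).
#' @export
splitFragment <- function(volume, mask, markers, connectivity = 26,
                          attachOrphans = TRUE) {
    stopifnot(connectivity %in% c(6, 26))
    d <- dim(mask)
    if (!all(dim(volume@values) == d)) stop("mask/volume geometry mismatch")
    if (length(unique(markers$group)) < 2)
        stop("at least 2 marker groups required")
    lin <- markers$i + (markers$j - 1) * d[1] + (markers$k - 1) * d[1] * d[2]
    if (any(markers$i < 1 | markers$i > d[1] | markers$j < 1 |
            markers$j > d[2] | markers$k < 1 | markers$k > d[3]) ||
        !all(mask[lin]))
        stop("all markers must lie inside the mask")
    grad <- gradientMagnitude(volume)
    res <- .cppSplitFragment(as.integer(d), as.integer(mask),
                             as.numeric(grad), as.integer(lin),
                             as.integer(markers$group),
                             as.integer(connectivity))
    if (isTRUE(res$infeasible))
        stop("marker groups are directly adjacent and cannot be disconnected")
    labels <- array(res$labels, d)
    removedArr <- array(FALSE, d)
    removedArr[res$removed] <- TRUE
    orphan <- mask & !removedArr & labels == 0L
    if (attachOrphans && any(orphan) && any(labels > 0)) {
        lab <- which(labels > 0)
        nn <- RANN::nn2(arrayInd(lab, d), arrayInd(which(orphan), d),
                        k = 1)$nn.idx[, 1]
        labels[orphan] <- labels[lab[nn]]
    }
    # compact group ids into contiguous labels; `groups` maps label -> group
    gl <- sort(unique(markers$group))
    labels[labels > 0] <- match(labels[labels > 0], gl)
    list(labels = labelMap(labels, volume@spacing, volume@origin,
                           relabel = FALSE),
         groups = as.integer(gl),
         removed = removedArr, removedOrder = res$removed)
}

#' Fill enclosed cavities of a binary mask
#'
#' Background components with no path to the volume boundary are turned
#' into foreground. Locally adaptive thresholds drop the interior of thick
#' cortical stacks (no contrast inside the window); those interiors are
#' fully enclosed by detected voxels and are restored here, while open
#' spaces (the medullary canal, fracture gaps) stay background.
#'
#' @param mask logical 3D array.
#' @return logical 3D array with holes filled.
#' @export
fillMaskHoles <- function(mask) {
    d <- dim(mask)
    # flood the complement from the volume boundary (6-connectivity)
    outside <- array(FALSE, d)
    outside[1, , ] <- !mask[1, , ]
    outside[d[1], , ] <- !mask[d[1], , ]
    outside[, 1, ] <- outside[, 1, ] | !mask[, 1, ]
    outside[, d[2], ] <- outside[, d[2], ] | !mask[, d[2], ]
    outside[, , 1] <- outside[, , 1] | !mask[, , 1]
    outside[, , d[3]] <- outside[, , d[3]] | !mask[, , d[3]]
    repeat {
        grown <- outside
        for (a in 1:3)
            grown <- grown | shiftArray(outside, a, 1, FALSE) |
                shiftArray(outside, a, -1, FALSE)
        grown <- grown & !mask
        if (identical(grown, outside)) break
        outside <- grown
    }
    mask | (!mask & !outside)
}
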