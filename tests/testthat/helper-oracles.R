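# Independent oracles used across tests: these deliberately re-derive
# results by brute force (BFS flood fill, O(V^2) Dijkstra, exhaustive
# point-triangle scans) and never call the code paths they check.

# neighbor offsets for 6/26 connectivity
oracleOffsets <- function(connectivity) {
    o <- as.matrix(expand.grid(a = -1:1, b = -1:1, c = -1:1))
    o <- o[rowSums(abs(o)) > 0, , drop = FALSE]
    if (connectivity == 6) o <- o[rowSums(abs(o)) == 1, , drop = FALSE]
    o
}

# BFS flood fill: component id per voxel of a logical 3D mask
oracleFloodFill <- function(mask, connectivity) {
    d <- dim(mask)
    offs <- oracleOffsets(connectivity)
    comp <- array(0L, d)
    cur <- 0L
    for (start in which(mask & comp == 0)) {
        if (comp[start] != 0) next
        cur <- cur + 1L
        queue <- start
        comp[start] <- cur
        while (length(queue) > 0) {
            v <- queue[1]
            queue <- queue[-1]
            ijk <- arrayInd(v, d)
            for (r in seq_len(nrow(offs))) {
                p <- ijk + offs[r, ]
                if (any(p < 1) || any(p > d)) next
                lin <- p[1] + (p[2] - 1) * d[1] + (p[3] - 1) * d[1] * d[2]
                if (mask[lin] && comp[lin] == 0) {
                    comp[lin] <- cur
                    queue <- c(queue, lin)
                }
            }
        }
    }
    comp
}

# are two voxel sets connected to each other within a mask?
oracleConnected <- function(mask, fromLin, toLin, connectivity) {
    comp <- oracleFloodFill(mask, connectivity)
    any(comp[fromLin] %in% comp[toLin][comp[toLin] > 0] &
        comp[fromLin] > 0)
}

# plain O(V^2) Dijkstra over an edge list with weights; returns distance
# and predecessor vectors from `from`
oracleDijkstra <- function(nVerts, edges, weights, from) {
    adj <- vector("list", nVerts)
    for (r in seq_len(nrow(edges))) {
        a <- edges[r, 1]; b <- edges[r, 2]; w <- weights[r]
        adj[[a]] <- rbind(adj[[a]], c(b, w))
        adj[[b]] <- rbind(adj[[b]], c(a, w))
    }
    dist <- rep(Inf, nVerts)
    prev <- rep(NA_integer_, nVerts)
    done <- rep(FALSE, nVerts)
    dist[from] <- 0
    repeat {
        u <- which(!done & is.finite(dist))
        if (length(u) == 0) break
        u <- u[which.min(dist[u])]
        done[u] <- TRUE
        nb <- adj[[u]]
        if (is.null(nb)) next
        for (r in seq_len(nrow(nb))) {
            v <- nb[r, 1]
            alt <- dist[u] + nb[r, 2]
            if (alt < dist[v]) {
                dist[v] <- alt
                prev[v] <- u
            }
        }
    }
    list(dist = dist, prev = prev)
}

# exhaustive closest point on a single triangle (barycentric clamping via
# direct minimization over a fine parameter grid plus edge/vertex checks)
oraclePointTriangle <- function(p, a, b, c) {
    best <- Inf
    for (u in seq(0, 1, length.out = 61)) {
        for (v in seq(0, 1 - u, length.out = max(2, round(61 * (1 - u))))) {
            q <- (1 - u - v) * a + u * b + v * c
            d <- sqrt(sum((p - q)^2))
            if (d < best) best <- d
        }
    }
    best
}

# exhaustive closest distance of a point to a whole mesh
oracleMeshDistance <- function(p, mesh) {
    v <- meshVertices(mesh)
    tr <- meshTriangles(mesh)
    best <- Inf
    for (t in seq_len(nrow(tr))) {
        d <- oraclePointTriangle(p, v[tr[t, 1], ], v[tr[t, 2], ],
                                 v[tr[t, 3], ])
        if (d < best) best <- d
    }
    best
}

# parametric UV-sphere mesh (poles + latitude rings)
sphereMesh <- function(R = 1, nLat = 24, nLon = 48, center = c(0, 0, 0)) {
    lat <- seq(0, pi, length.out = nLat + 1)[-c(1, nLat + 1)]
    lon <- seq(0, 2 * pi, length.out = nLon + 1)[-(nLon + 1)]
    verts <- rbind(c(0, 0, R),
                   do.call(rbind, lapply(lat, function(th)
                       cbind(R * sin(th) * cos(lon), R * sin(th) * sin(lon),
                             R * cos(th)))),
                   c(0, 0, -R))
    verts <- sweep(verts, 2, center, "+")
    idx <- function(i, j) 1 + (i - 1) * nLon + ((j - 1) %% nLon) + 1
    tris <- list()
    for (j in seq_len(nLon))  # top cap
        tris[[length(tris) + 1]] <- c(1, idx(1, j), idx(1, j + 1))
    for (i in seq_len(nLat - 2)) for (j in seq_len(nLon)) {
        tris[[length(tris) + 1]] <- c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1))
        tris[[length(tris) + 1]] <- c(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1))
    }
    bot <- nrow(verts)
    for (j in seq_len(nLon))
        tris[[length(tris) + 1]] <- c(bot, idx(nLat - 1, j + 1), idx(nLat - 1, j))
    triangleMesh(verts, do.call(rbind, tris))
}

# open cylinder tube mesh along z
cylinderMesh <- function(r = 1, h = 4, nz = 20, nTheta = 40) {
    z <- seq(-h / 2, h / 2, length.out = nz)
    th <- seq(0, 2 * pi, length.out = nTheta + 1)[-(nTheta + 1)]
    verts <- do.call(rbind, lapply(z, function(zz)
        cbind(r * cos(th), r * sin(th), zz)))
    idx <- function(i, j) (i - 1) * nTheta + ((j - 1) %% nTheta) + 1
    tris <- list()
    for (i in seq_len(nz - 1)) for (j in seq_len(nTheta)) {
        tris[[length(tris) + 1]] <- c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1))
        tris[[length(tris) + 1]] <- c(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1))
    }
    triangleMesh(verts, do.call(rbind, tris))
}

# flat triangulated grid sheet in the z = 0 plane
gridSheetMesh <- function(nx = 10, ny = 10, spacing = 1) {
    verts <- as.matrix(expand.grid(x = (0:(nx - 1)) * spacing,
                                   y = (0:(ny - 1)) * spacing))
    verts <- cbind(verts, 0)
    idx <- function(i, j) (j - 1) * nx + i
    tris <- list()
    for (i in seq_len(nx - 1)) for (j in seq_len(ny - 1)) {
        tris[[length(tris) + 1]] <- c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1))
        tris[[length(tris) + 1]] <- c(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1))
    }
    triangleMesh(verts, do.call(rbind, tris))
}
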