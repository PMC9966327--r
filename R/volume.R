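#' Construct a VolumeImage
#'
#' @param values 3D numeric array.
#' @param spacing numeric(3) voxel spacing, mm.
#' @param origin numeric(3) world position of voxel `[1,1,1]`, mm.
#' @return a [VolumeImage-class].
#' @export
volumeImage <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
    new("VolumeImage", values = values, spacing = as.numeric(spacing),
        origin = as.numeric(origin))
}

#' Construct a LabelMap
#'
#' @param labels 3D integer array (0 = background); relabelled to a
#'   contiguous `{0..K}` set if necessary, preserving order of first label.
#' @param spacing,origin voxel geometry.
#' @param relabel compact the label set if TRUE (default).
#' @return a [LabelMap-class].
#' @export
labelMap <- function(labels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                     relabel = TRUE) {
    storage.mode(labels) <- "integer"
    if (relabel) {
        u <- sort(setdiff(unique(as.integer(labels)), 0L))
        if (length(u) > 0 && !identical(u, seq_along(u))) {
            lut <- integer(max(u) + 1L)
            lut[u + 1L] <- seq_along(u)
            labels[] <- ifelse(labels > 0L, lut[labels + 1L], 0L)
        }
    }
    new("LabelMap", labels = labels, spacing = as.numeric(spacing),
        origin = as.numeric(origin))
}

# world coordinates (n x 3) of voxel indices (n x 3 matrix, 1-based)
indexToWorld <- function(idx, spacing, origin) {
    sweep(sweep(idx - 1, 2, spacing, "*"), 2, origin, "+")
}

# nearest-voxel indices of world points; may fall outside the grid
worldToIndex <- function(pts, spacing, origin) {
    round(sweep(sweep(pts, 2, origin), 2, spacing, "/")) + 1
}

# world coordinate vectors per axis for a grid
gridAxes <- function(dims, spacing, origin) {
    lapply(1:3, function(a) origin[a] + (seq_len(dims[a]) - 1) * spacing[a])
}

#' Gaussian blur of a volume
#'
#' Separable Gaussian filtering along each axis; sigma is given in mm and
#' converted to voxels per axis. Borders are handled by renormalizing the
#' truncated kernel (equivalent to zero-padding with weight renormalization).
#'
#' @param volume a [VolumeImage-class].
#' @param sigmaMm Gaussian standard deviation in mm (scalar).
#' @return blurred [VolumeImage-class].
#' @export
gaussianBlur <- function(volume, sigmaMm) {
    if (sigmaMm <= 0) return(volume)
    v <- volume@values
    d <- dim(v)
    for (a in 1:3) {
        sg <- sigmaMm / volume@spacing[a]
        if (sg < 1e-3) next
        r <- max(1L, ceiling(3 * sg))
        k <- exp(-(seq(-r, r))^2 / (2 * sg^2))
        n <- d[a]
        # banded convolution matrix with renormalized truncated rows
        i <- rep(seq_len(n), each = 2 * r + 1)
        j <- i + rep(seq(-r, r), times = n)
        w <- rep(k, times = n)
        keep <- j >= 1 & j <= n
        K <- Matrix::sparseMatrix(i = i[keep], j = j[keep], x = w[keep],
                                  dims = c(n, n))
        K <- K / Matrix::rowSums(K)
        perm <- c(a, setdiff(1:3, a))
        vp <- aperm(v, perm)
        dm <- dim(vp)
        vp <- matrix(vp, nrow = dm[1])
        vp <- as.matrix(K %*% vp)
        dim(vp) <- dm
        v <- aperm(vp, order(perm))
    }
    volumeImage(v, volume@spacing, volume@origin)
}

#' Write a volume or label map to disk
#'
#' Format chosen from the file extension: `.nii` / `.nii.gz` (NIfTI, via
#' RNifti) or `.mha` (uncompressed MetaImage, written natively). Voxel
#' spacing and origin are stored in the header.
#'
#' @param x a [VolumeImage-class] or [LabelMap-class].
#' @param path output file.
#' @export
writeVolume <- function(x, path) {
    arr <- if (is(x, "LabelMap")) x@labels else x@values
    if (grepl("\\.mha$", path)) {
        writeMha(arr, x@spacing, x@origin, path)
    } else {
        img <- RNifti::asNifti(arr, internal = FALSE)
        img <- RNifti::`pixdim<-`(img, x@spacing)
        # NIfTI sform: direct world mapping of our axis-aligned grid
        xf <- structure(diag(c(x@spacing, 1)), code = 2L)
        xf[1:3, 4] <- x@origin
        img <- RNifti::`sform<-`(img, xf)
        RNifti::writeNifti(img, path)
    }
    invisible(path)
}

#' Read a volume from disk
#'
#' @param path `.nii`, `.nii.gz` or `.mha` file.
#' @param labels read as [LabelMap-class] if TRUE.
#' @return [VolumeImage-class] or [LabelMap-class].
#' @export
readVolume <- function(path, labels = FALSE) {
    if (grepl("\\.mha$", path)) {
        m <- readMha(path)
        arr <- m$values; sp <- m$spacing; org <- m$origin
    } else {
        img <- RNifti::readNifti(path)
        arr <- array(as.vector(as.array(img)), dim = dim(img))
        sp <- RNifti::pixdim(img)[1:3]
        xf <- RNifti::xform(img)
        org <- xf[1:3, 4]
    }
    if (labels) labelMap(arr, sp, org) else volumeImage(arr, sp, org)
}

# Minimal uncompressed MetaImage (.mha) writer: ASCII header + raw data.
writeMha <- function(arr, spacing, origin, path) {
    type <- if (is.integer(arr)) "MET_INT" else "MET_DOUBLE"
    hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
             "BinaryDataByteOrderMSB = False", "CompressedData = False",
             "TransformMatrix = 1 0 0 0 1 0 0 0 1",
             paste("Offset =", paste(origin, collapse = " ")),
             paste("ElementSpacing =", paste(spacing, collapse = " ")),
             paste("DimSize =", paste(dim(arr), collapse = " ")),
             paste("ElementType =", type),
             "ElementDataFile = LOCAL")
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con)
    if (is.integer(arr)) writeBin(as.integer(arr), con, size = 4L,
                                  endian = "little")
    else writeBin(as.numeric(arr), con, size = 8L, endian = "little")
    invisible(path)
}

readMha <- function(path) {
    con <- file(path, "rb")
    on.exit(close(con))
    hdr <- list()
    repeat {
        line <- readHeaderLine(con)
        kv <- strsplit(line, " = ", fixed = TRUE)[[1]]
        hdr[[kv[1]]] <- kv[2]
        if (kv[1] == "ElementDataFile") break
    }
    dims <- as.integer(strsplit(hdr$DimSize, " ")[[1]])
    n <- prod(dims)
    type <- hdr$ElementType
    vals <- switch(type,
        MET_INT = readBin(con, "integer", n, size = 4L, endian = "little"),
        MET_DOUBLE = readBin(con, "numeric", n, size = 8L, endian = "little"),
        MET_FLOAT = readBin(con, "numeric", n, size = 4L, endian = "little"),
        MET_UCHAR = readBin(con, "integer", n, size = 1L, signed = FALSE),
        MET_SHORT = readBin(con, "integer", n, size = 2L, endian = "little"),
        stop("unsupported MetaImage element type: ", type))
    list(values = array(vals, dims),
         spacing = as.numeric(strsplit(hdr$ElementSpacing, " ")[[1]]),
         origin = as.numeric(strsplit(hdr$Offset, " ")[[1]]))
}

readHeaderLine <- function(con) {
    chars <- character()
    repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (length(ch) == 0 || ch == "\n") break
        chars <- c(chars, ch)
    }
    paste(chars, collapse = "")
}
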