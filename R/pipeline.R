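## End-to-end orchestration: per-case processing (segment -> mesh -> trace
## -> reduce -> project) and cohort-level analysis (mean shape -> incidence
## maps), with file-based intermediate artifacts.

#' Default study configuration
#'
#' Nested list of every tunable parameter of the pipeline; unknown keys are
#' rejected by validation.
#'
#' @param ... named overrides, e.g.
#'   `studyConfig(segmentation = list(minContrast = 150))`; unnamed top
#'   levels are not allowed.
#' @return validated configuration list.
#' @export
studyConfig <- function(...) {
    defaults <- list(
        seed = 1L,
        segmentation = list(windowRadius = 2L, minContrast = 100,
                            offsetFraction = 0.25, fillHoles = TRUE,
                            connectivity = 26, minVoxels = 27L),
        meshing = list(mode = "grayscale", grayIso = 350, iso = 0.5,
                       smoothSigma = 1, taubinIter = 10L),
        lines = list(quantile = 0.9, minCurvature = 0.55, curvSmooth = 4L,
                     wBoundary = 1, wAngle = 1, closeGapFactor = 6,
                     closed = TRUE, fovMargin = 1.5, clusterGap = 6),
        reduction = list(maxIter = 200L, tol = 1e-4, maxPoints = 500L,
                         init = "identity"),
        ssm = list(withScaling = TRUE, nSecondary = 4L, matchCap = 5),
        mapping = list(lineRadius = NULL, fragmentMaxDist = 1),
        metrics = list(step = 0.5))
    overrides <- list(...)
    cfg <- mergeConfig(defaults, overrides, path = "")
    cfg
}

mergeConfig <- function(defaults, overrides, path) {
    if (length(overrides) == 0) return(defaults)
    nms <- names(overrides)
    if (is.null(nms) || any(nms == ""))
        stop("config entries must be named (at ", path, ")")
    unknown <- setdiff(nms, names(defaults))
    if (length(unknown) > 0)
        stop("unknown config key(s): ",
             paste0(path, unknown, collapse = ", "))
    for (nm in nms) {
        if (is.list(defaults[[nm]]) && is.list(overrides[[nm]]))
            defaults[[nm]] <- mergeConfig(defaults[[nm]], overrides[[nm]],
                                          paste0(path, nm, "$"))
        else defaults[nm] <- overrides[nm]
    }
    defaults
}

#' Read a study configuration from YAML
#'
#' @param path YAML file with (a subset of) the [studyConfig()] keys.
#' @return validated configuration list.
#' @export
readStudyConfig <- function(path) {
    do.call(studyConfig, yaml::read_yaml(path))
}

stageDone <- function(outDir, stage) {
    file.exists(file.path(outDir, paste0(".stage_", stage)))
}

markStage <- function(outDir, stage, info, log) {
    writeLines(jsonlite::toJSON(info, auto_unbox = TRUE, null = "null"),
               file.path(outDir, paste0(".stage_", stage)))
    log[[stage]] <- info
    log
}

#' Run the per-case pipeline
#'
#' Segments the fractured volume, splits marker-indicated fragments,
#' meshes every fragment, traces its fracture line, mirrors the
#' contralateral template, reduces each fragment onto it (ICP, or
#' user-supplied transforms), and projects the fracture lines onto the
#' template surface. Every intermediate artifact is written below
#' `outDir`; completed stages are skipped on re-runs unless `force`.
#'
#' @param config [studyConfig()] list.
#' @param volume fractured [VolumeImage-class].
#' @param contralateral intact contralateral [VolumeImage-class] (it is
#'   thresholded, meshed and mirrored) or an already mirrored template
#'   [TriangleMesh-class].
#' @param outDir case output directory.
#' @param caseId case identifier.
#' @param markers optional seed-marker data.frame (see [splitFragment()])
#'   for not-fully-detached fragments.
#' @param labels optional externally supplied (e.g. manually corrected)
#'   fragment [LabelMap-class]; skips the automatic segmentation.
#' @param transforms optional named list of [RigidTransform-class] (or a
#'   JSON path for [loadTransforms()]): externally supplied reductions that
#'   replace the ICP.
#' @param mirrorPoint,mirrorNormal mirror plane for a volume
#'   `contralateral`; default: the volume grid's first-axis mid-plane.
#' @param force re-run completed stages.
#' @return case record list: `labels`, `meshes`, `lines`, `template`,
#'   `reductions`, `projected`, `log`.
#' @export
runCase <- function(config, volume, contralateral, outDir,
                    caseId = "case", markers = NULL, transforms = NULL,
                    labels = NULL, mirrorPoint = NULL,
                    mirrorNormal = c(1, 0, 0), force = FALSE) {
    if (missing(contralateral) || is.null(contralateral))
        stop("case ", caseId,
             ": stage reduction requires a contralateral template")
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    log <- list()
    runStage <- function(stage, fn) {
        tryCatch(fn(), error = function(e)
            stop("case ", caseId, ": stage ", stage, ": ",
                 conditionMessage(e), call. = FALSE))
    }

    # -- segmentation ------------------------------------------------------
    labPath <- file.path(outDir, "labels.nii.gz")
    if (force || !stageDone(outDir, "segmentation")) {
        runStage("segmentation", function() {
            if (!is.null(labels)) {
                writeVolume(labels, labPath)
                log <<- markStage(outDir, "segmentation",
                                  list(fragments = max(labels@labels),
                                       supplied = TRUE), log)
                return(invisible(NULL))
            }
            sc <- config$segmentation
            mask <- adaptiveThreshold(volume, sc$windowRadius,
                                      sc$minContrast, sc$offsetFraction)
            if (isTRUE(sc$fillHoles)) mask <- fillMaskHoles(mask)
            labels <- labelComponents(mask, sc$connectivity,
                                      volume@spacing, volume@origin,
                                      minVoxels = sc$minVoxels)
            if (!is.null(markers)) {
                d <- dim(mask)
                lin <- markers$i + (markers$j - 1) * d[1] +
                    (markers$k - 1) * d[1] * d[2]
                host <- labels@labels[lin]
                if (any(host == 0))
                    stop("markers must lie in labelled components")
                # components holding one marker group take that group's id;
                # components holding several are split along the gradient
                out <- array(0L, d)
                for (h in unique(host)) {
                    mh <- markers[host == h, , drop = FALSE]
                    sub <- labels@labels == h
                    if (length(unique(mh$group)) == 1) {
                        out[sub] <- mh$group[1]
                    } else {
                        sp <- splitFragment(volume, sub, mh,
                                            sc$connectivity)
                        keep <- sp$labels@labels > 0
                        out[keep] <- sp$groups[sp$labels@labels[keep]]
                    }
                }
                # unmarked components follow after the marker groups
                rest <- labels@labels > 0 & out == 0L &
                    !(labels@labels %in% unique(host))
                if (any(rest))
                    out[rest] <- max(markers$group) + labels@labels[rest]
                labels <- labelMap(out, volume@spacing, volume@origin)
            }
            writeVolume(labels, labPath)
            log <<- markStage(outDir, "segmentation",
                              list(fragments = max(labels@labels),
                                   voxels = sum(labels@labels > 0)), log)
        })
    }
    labels <- readVolume(labPath, labels = TRUE)

    # -- fragment meshes ---------------------------------------------------
    meshDir <- file.path(outDir, "meshes")
    K <- max(labels@labels)
    if (force || !stageDone(outDir, "meshes")) {
        runStage("meshes", function() {
            dir.create(meshDir, showWarnings = FALSE)
            mc <- config$meshing
            for (f in seq_len(K)) {
                m <- if (identical(mc$mode, "grayscale"))
                    meshFragmentGray(labels, f, volume, mc$grayIso)
                else meshSmooth(meshFragment(labels, f, mc$iso,
                                             mc$smoothSigma), mc$taubinIter)
                writePly(m, file.path(meshDir, sprintf("frag_%02d.ply", f)))
            }
            log <<- markStage(outDir, "meshes", list(meshes = K), log)
        })
    }
    meshes <- lapply(seq_len(K), function(f)
        readPly(file.path(meshDir, sprintf("frag_%02d.ply", f))))

    # -- fracture lines ----------------------------------------------------
    lineDir <- file.path(outDir, "lines")
    if (force || !stageDone(outDir, "lines")) {
        runStage("lines", function() {
            dir.create(lineDir, showWarnings = FALSE)
            lc <- config$lines
            nTraced <- 0L
            for (f in seq_len(K)) {
                m <- meshes[[f]]
                curv <- smoothVertexField(m, vertexCurvature(m, signed = TRUE),
                                          lc$curvSmooth)
                mk <- selectBorderMarkers(m, curv, volume, lc$quantile,
                                          lc$minCurvature,
                                          fovMargin = lc$fovMargin,
                                          clusterGap = lc$clusterGap,
                                          labels = labels)
                if (length(mk) >= 2) {
                    ln <- traceFractureLine(m, mk,
                                            c(lc$wBoundary, lc$wAngle),
                                            closeGapFactor = lc$closeGapFactor,
                                            closed = lc$closed,
                                            fragment = f)
                    writeLinesJson(ln, file.path(
                        lineDir, sprintf("frag_%02d.json", f)))
                    nTraced <- nTraced + 1L
                }
            }
            log <<- markStage(outDir, "lines", list(traced = nTraced), log)
        })
    }
    lines <- lapply(seq_len(K), function(f) {
        p <- file.path(lineDir, sprintf("frag_%02d.json", f))
        if (file.exists(p)) readLinesJson(p)[[1]] else NULL
    })

    # -- contralateral template -------------------------------------------
    tplPath <- file.path(outDir, "template.ply")
    if (force || !stageDone(outDir, "template")) {
        runStage("template", function() {
            if (is(contralateral, "VolumeImage")) {
                sc <- config$segmentation
                mask <- adaptiveThreshold(contralateral, sc$windowRadius,
                                          sc$minContrast, sc$offsetFraction)
                cl <- labelComponents(mask, sc$connectivity,
                                      contralateral@spacing,
                                      contralateral@origin,
                                      minVoxels = sc$minVoxels)
                mc <- config$meshing
                tpl <- if (identical(mc$mode, "grayscale"))
                    meshFragmentGray(cl, 1L, contralateral, mc$grayIso)
                else meshSmooth(meshFragment(cl, 1L, mc$iso, mc$smoothSigma),
                                mc$taubinIter)
                if (is.null(mirrorPoint)) {
                    d <- dim(contralateral@values)
                    mirrorPoint <- contralateral@origin +
                        (d - 1) * contralateral@spacing / 2
                }
                tpl <- mirrorMesh(tpl, mirrorPoint, mirrorNormal)
            } else tpl <- contralateral
            writePly(tpl, tplPath)
            log <<- markStage(outDir, "template",
                              list(vertices = nrow(tpl@vertices)), log)
        })
    }
    template <- readPly(tplPath)

    # -- reduction ---------------------------------------------------------
    redPath <- file.path(outDir, "reductions.json")
    if (force || !stageDone(outDir, "reduction")) {
        runStage("reduction", function() {
            rc <- config$reduction
            if (!is.null(transforms)) {
                red <- if (is.character(transforms))
                    loadTransforms(transforms) else transforms
                info <- list(mode = "supplied", fragments = length(red))
            } else {
                red <- list()
                iters <- integer(0)
                fovLo <- volume@origin
                fovHi <- volume@origin +
                    (dim(volume@values) - 1) * volume@spacing
                for (f in seq_len(K)) {
                    init <- if (identical(rc$init, "pca"))
                        principalAxisInit(meshes[[f]], template)
                    else rigidTransform()
                    r <- reduceFragment(meshes[[f]], template, init,
                                        rc$maxIter, rc$tol, rc$maxPoints,
                                        fovLo = fovLo, fovHi = fovHi)
                    red[[as.character(f)]] <- r$transform
                    iters <- c(iters, r$iterations)
                }
                info <- list(mode = "icp", fragments = K,
                             iterations = iters)
            }
            saveTransforms(red, redPath)
            log <<- markStage(outDir, "reduction", info, log)
        })
    }
    reductions <- loadTransforms(redPath)

    # -- projection --------------------------------------------------------
    projDir <- file.path(outDir, "projected")
    if (force || !stageDone(outDir, "projection")) {
        runStage("projection", function() {
            dir.create(projDir, showWarnings = FALSE)
            for (f in seq_len(K)) {
                if (is.null(lines[[f]])) next
                tr <- reductions[[as.character(f)]]
                if (is.null(tr)) tr <- rigidTransform()
                ln <- applyTransform(tr, lines[[f]])
                pj <- projectLineToSurface(ln, template)
                writeLinesJson(pj, file.path(
                    projDir, sprintf("frag_%02d.json", f)))
            }
            log <<- markStage(outDir, "projection", list(), log)
        })
    }
    projected <- lapply(seq_len(K), function(f) {
        p <- file.path(projDir, sprintf("frag_%02d.json", f))
        if (file.exists(p)) readLinesJson(p)[[1]] else NULL
    })

    list(caseId = caseId, labels = labels, meshes = meshes, lines = lines,
         template = template, reductions = reductions,
         projected = projected, log = log)
}

# mirror one study case (mesh, landmarks, lines, reduced fragments) into a
# left-oriented frame
mirrorStudyCase <- function(cs, point = NULL, normal = c(1, 0, 0)) {
    if (is.null(point))
        point <- (apply(cs$mesh@vertices, 2, min) +
                  apply(cs$mesh@vertices, 2, max)) / 2
    cs$mesh <- mirrorMesh(cs$mesh, point, normal)
    cs$landmarks <- mirrorLandmarks(cs$landmarks, point, normal)
    cs$lines <- lapply(cs$lines, function(l) {
        if (is.null(l)) return(NULL)
        l@points <- mirrorPoints(l@points, point, normal)
        l
    })
    cs$fragments <- lapply(cs$fragments, function(m)
        mirrorMesh(m, point, normal))
    cs
}

#' Run the cohort-level study
#'
#' Mirrors right-sided cases to the left, builds the Procrustes mean shape
#' from the intact surfaces and landmarks, maps every case's projected
#' fracture lines and reduced fragment areas through the dense
#' correspondence, and accumulates the fracture-line and fragment-area
#' probability maps.
#'
#' @param config [studyConfig()] list.
#' @param cases list of per-case lists with elements `caseId`, `side`,
#'   `mesh` (intact template surface), `landmarks` ([LandmarkSet-class] on
#'   that surface), `lines` (list of projected [FractureLine-class] on
#'   that surface) and `fragments` (list of reduced fragment
#'   [TriangleMesh-class], same frame).
#' @param outDir output directory (PLY/CSV maps and PNG renders); NULL to
#'   skip writing.
#' @param render write four-view PNG renders (default TRUE when `outDir`
#'   given).
#' @return list with `model` ([MeanShapeModel-class]), `fractureMap` and
#'   `fragmentMap` ([ProbabilityMap-class]).
#' @export
runStudy <- function(config, cases, outDir = NULL, render = !is.null(outDir)) {
    stopifnot(length(cases) >= 2)
    cases <- lapply(cases, function(cs) {
        if (identical(cs$side, "right")) {
            cs <- mirrorStudyCase(cs)
            cs$side <- "left"
            cs$landmarks@side <- "left"
        }
        cs
    })
    bad <- vapply(cases, function(cs)
        !identical(rownames(cs$landmarks@primary),
                   rownames(cases[[1]]$landmarks@primary)), TRUE)
    if (any(bad))
        stop("incompatible landmark sets for case(s): ",
             paste(vapply(cases[bad], function(cs) cs$caseId, ""),
                   collapse = ", "))
    cohort <- lapply(cases, function(cs) {
        cs$landmarks@caseId <- cs$caseId
        list(mesh = cs$mesh, landmarks = cs$landmarks)
    })
    model <- buildMeanShape(cohort, withScaling = config$ssm$withScaling,
                            nSecondary = config$ssm$nSecondary,
                            matchCap = config$ssm$matchCap)
    radius <- config$mapping$lineRadius
    if (is.null(radius)) radius <- 1.5 * meanEdgeLength(model@meanSurface)

    lineInc <- list()
    fragInc <- list()
    for (i in seq_along(cases)) {
        cs <- cases[[i]]
        corr <- model@correspondences[[i]]
        tr <- model@transforms[[i]]
        caseMeshAligned <- applyTransform(tr, cs$mesh)
        lns <- Filter(Negate(is.null), cs$lines)
        lnsAligned <- lapply(lns, function(l) applyTransform(tr, l))
        lineInc[[i]] <- mapLineIncidence(model, corr, caseMeshAligned,
                                         lnsAligned, radius)
        fvs <- lapply(cs$fragments, function(fm)
            mapFragmentIncidence(model, corr, caseMeshAligned,
                                 applyTransform(tr, fm),
                                 maxDist = config$mapping$fragmentMaxDist))
        fragInc[[i]] <- if (length(fvs) > 0) combineIncidence(fvs)
        else new("IncidenceVector",
                 flags = integer(nrow(model@meanSurface@vertices)),
                 caseId = corr@caseId, channel = "fragment_area")
    }
    fractureMap <- accumulateProbability(lineInc)
    fragmentMap <- accumulateProbability(fragInc)

    if (!is.null(outDir)) {
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        writeProbabilityMap(fractureMap, model,
                            file.path(outDir, "fracture_map.ply"),
                            file.path(outDir, "fracture_map.csv"))
        writeProbabilityMap(fragmentMap, model,
                            file.path(outDir, "fragment_map.ply"),
                            file.path(outDir, "fragment_map.csv"))
        writeMeanShapeModel(model, file.path(outDir, "model"))
        if (render) {
            renderProbabilityMap(fractureMap, model,
                                 file.path(outDir, "fracture_map.png"))
            renderProbabilityMap(fragmentMap, model,
                                 file.path(outDir, "fragment_map.png"))
        }
    }
    list(model = model, fractureMap = fractureMap, fragmentMap = fragmentMap)
}
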