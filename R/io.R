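#' Write a phantom volume to disk
#'
#' The 4-D data go to a NIfTI-1 file; tile geometry, ground truth, the
#' configuration (including the seed) and the AIF/VOF samples go to a JSON
#' sidecar next to it; the AIF and VOF are additionally written as a CSV of
#' (time, aif, vof).
#'
#' @param phantom A [PhantomVolume-class].
#' @param path Output path; \code{.nii.gz} is appended if no NIfTI
#'   extension is present.
#' @return Invisibly, the paths written (nifti, sidecar, curves).
#' @export
writePhantom <- function(phantom, path) {
    stopifnot(is(phantom, "PhantomVolume"))
    if (!grepl("\\.nii(\\.gz)?$", path)) path <- paste0(path, ".nii.gz")
    # NIfTI stores (x, y, z, t); phantom data are (slice, row, col, t)
    d <- aperm(phantom@data, c(2, 3, 1, 4))
    RNifti::writeNifti(RNifti::asNifti(d, pixdim = c(1, 1, 1,
                                                     phantom@grid@dt)),
                       path)
    sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
    jsonlite::write_json(list(
        format = "BayesTmax phantom sidecar v1",
        config = phantom@config,
        tileGeometry = phantom@tileGeometry,
        groundTruth = phantom@groundTruth,
        time = phantom@grid@times,
        aif = phantom@aif@values,
        vof = phantom@vof@values), sidecar,
        auto_unbox = TRUE, digits = NA)
    curves <- sub("\\.nii(\\.gz)?$", "_curves.csv", path)
    utils::write.csv(data.frame(time = phantom@grid@times,
                                aif = phantom@aif@values,
                                vof = phantom@vof@values),
                     curves, row.names = FALSE)
    invisible(c(nifti = path, sidecar = sidecar, curves = curves))
}

#' Read a phantom volume written by [writePhantom()]
#'
#' @param path Path to the NIfTI file.
#' @return A [PhantomVolume-class] equal to the one written.
#' @export
readPhantom <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
    if (!file.exists(sidecar))
        stop("sidecar missing: expected ", sidecar)
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    img <- RNifti::readNifti(path)
    data <- aperm(array(as.numeric(img), dim = dim(img)), c(3, 1, 2, 4))
    grid <- new("TimeGrid", dt = side$config$dt, times = side$time)
    cfg <- side$config
    cfg$aifParams <- as.list(cfg$aifParams)
    new("PhantomVolume", data = data, grid = grid,
        tileGeometry = as.data.frame(side$tileGeometry),
        groundTruth = as.data.frame(side$groundTruth),
        aif = new("Curve", grid = grid, values = side$aif, label = "aif"),
        vof = new("Curve", grid = grid, values = side$vof, label = "vof"),
        config = cfg)
}

#' Write / read tile-level perfusion maps
#'
#' Maps are tabular (one row per tile ROI); they are written as CSV with a
#' JSON sidecar recording the method and its parameters, and read back
#' losslessly.
#'
#' @param maps A [PerfusionMaps-class].
#' @param path CSV output path (\code{.csv} appended if absent).
#' @return \code{writeMaps}: invisibly, the paths written. \code{readMaps}:
#'   the reconstructed [PerfusionMaps-class].
#' @export
writeMaps <- function(maps, path) {
    stopifnot(is(maps, "PerfusionMaps"))
    if (!grepl("\\.csv$", path)) path <- paste0(path, ".csv")
    utils::write.csv(mapTable(maps), path, row.names = FALSE)
    sidecar <- sub("\\.csv$", ".json", path)
    jsonlite::write_json(list(format = "BayesTmax maps sidecar v1",
                              method = maps@method, params = maps@params),
                         sidecar, auto_unbox = TRUE, digits = NA)
    invisible(c(csv = path, sidecar = sidecar))
}

#' @rdname writeMaps
#' @export
readMaps <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    sidecar <- sub("\\.csv$", ".json", path)
    if (!file.exists(sidecar))
        stop("sidecar missing: expected ", sidecar)
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    tab <- utils::read.csv(path)
    new("PerfusionMaps", table = tab, method = side$method,
        params = as.list(side$params))
}

#' Paint tile-level map values into a per-voxel volume
#'
#' Inverse of [tileMeans()] for constant tiles: fills each tile's voxel
#' block with its scalar value, NA elsewhere. Useful to export tile maps as
#' NIfTI images.
#'
#' @param values Numeric vector, one value per geometry row.
#' @param geometry Tile geometry \code{data.frame}.
#' @param dims Length-3 volume dimensions (slice, row, col).
#' @return 3-D array.
#' @export
mapsToVolume <- function(values, geometry, dims) {
    stopifnot(length(values) == nrow(geometry), length(dims) == 3L)
    vol <- array(NA_real_, dim = dims)
    for (r in seq_len(nrow(geometry))) {
        rows <- geometry$row0[r] + seq_len(geometry$size[r])
        cols <- geometry$col0[r] + seq_len(geometry$size[r])
        vol[geometry$slice[r], rows, cols] <- values[r]
    }
    vol
}

#' Run configuration for the end-to-end experiment
#'
#' @param phantom A [phantomConfig()] list (or arguments for one).
#' @param methods Deconvolution methods to run; subset of
#'   \code{c("ssvd", "bsvd", "osvd", "bayes")}. Must include \code{"bayes"}
#'   and at least one SVD reference for the calibration stage.
#' @param reference Which SVD method's Tmax calibrates the Bayesian maps.
#' @param threshold,oiLimit SVD settings (see [svdDeconvolve()]).
#' @param bayesSpec A [bayesSearchSpec()].
#' @param outDir Output directory (created if needed), or \code{NULL} to
#'   skip writing files.
#' @param seed Overrides the phantom config seed when non-NULL.
#' @return A list of class \code{"RunConfig"}.
#' @export
runConfig <- function(phantom = phantomConfig(),
                      methods = c("bsvd", "bayes"), reference = "bsvd",
                      threshold = 0.15, oiLimit = 0.035,
                      bayesSpec = bayesSearchSpec(), outDir = NULL,
                      seed = NULL) {
    known <- c("ssvd", "bsvd", "osvd", "bayes")
    bad <- setdiff(methods, known)
    if (length(bad))
        stop("unknown method(s): ", paste(bad, collapse = ", "))
    if (!"bayes" %in% methods)
        stop("'methods' must include \"bayes\"")
    if (!reference %in% setdiff(methods, "bayes"))
        stop("'reference' must be one of the requested SVD methods")
    if (!inherits(phantom, "PhantomConfig"))
        phantom <- do.call(phantomConfig, phantom)
    if (!is.null(seed)) phantom$seed <- as.integer(seed)
    structure(list(phantom = phantom, methods = methods,
                   reference = reference, threshold = threshold,
                   oiLimit = oiLimit, bayesSpec = bayesSpec,
                   outDir = outDir), class = "RunConfig")
}

#' Run the full phantom-to-agreement experiment
#'
#' Pipeline: build the phantom, deconvolve with the requested methods
#' (tile-mean ROIs), fit the (p, q) calibration of the Bayesian TD/MTT
#' against the reference Tmax, apply it, and compute the agreement reports:
#' calibrated Bayesian Tmax vs reference Tmax, plus Bayesian TD and MTT vs
#' ground truth. When \code{outDir} is set, all artifacts (phantom, map
#' CSVs, fit.json, report.json, manifest.json) are written there.
#'
#' @param config A [runConfig()].
#' @param verbose Print stage progress.
#' @return A list bundle: \code{phantom}, \code{maps} (named list of
#'   [PerfusionMaps-class]), \code{fit} ([CalibrationFit-class]),
#'   \code{reports} (named list of [AgreementReport-class]).
#' @export
runExperiment <- function(config = runConfig(), verbose = FALSE) {
    stopifnot(inherits(config, "RunConfig"))
    say <- function(...) if (verbose)
        message(format(Sys.time(), "%H:%M:%S"), " [", ..1, "] ",
                paste(c(...)[-1], collapse = " "))
    say("phantom", "building, seed", config$phantom$seed)
    phantom <- buildPhantom(config$phantom)

    maps <- list()
    for (m in setdiff(config$methods, "bayes")) {
        say("deconvolve", m)
        maps[[m]] <- deconvolveVolume(phantom, method = m,
                                      threshold = config$threshold,
                                      oiLimit = config$oiLimit)
    }
    say("deconvolve", "bayes")
    maps$bayes <- bayesFitVolume(phantom, config$bayesSpec)

    say("calibrate", "vs", config$reference)
    cal <- calibrateTmax(maps$bayes, maps[[config$reference]])
    maps$bayes <- cal$maps

    gt <- groundTruth(phantom)
    bt <- mapTable(maps$bayes)
    refTmax <- mapTable(maps[[config$reference]])$tmax
    reports <- list(
        tmax = agreementReport(refTmax, bt$tmax,
                               labels = c(paste0("tmax_", config$reference),
                                          "tmax_bayesian")),
        td = agreementReport(gt$td, bt$td, labels = c("td_true", "td_bayesian")),
        mtt = agreementReport(gt$mtt, bt$mtt,
                              labels = c("mtt_true", "mtt_bayesian")))

    if (!is.null(config$outDir)) {
        dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
        say("write", config$outDir)
        writePhantom(phantom, file.path(config$outDir, "phantom"))
        for (m in names(maps))
            writeMaps(maps[[m]], file.path(config$outDir,
                                           paste0("maps_", m, ".csv")))
        jsonlite::write_json(list(p = cal$fit@p, q = cal$fit@q,
                                  reference = cal$fit@reference,
                                  n = cal$fit@nPoints,
                                  rms = cal$fit@rmsResidual),
                             file.path(config$outDir, "fit.json"),
                             auto_unbox = TRUE, digits = NA)
        jsonlite::write_json(lapply(reports, as.list),
                             file.path(config$outDir, "report.json"),
                             auto_unbox = TRUE, digits = NA)
        manifest <- list(package = "BayesTmax",
                         version = as.character(utils::packageVersion("BayesTmax")),
                         seed = config$phantom$seed,
                         methods = config$methods,
                         reference = config$reference,
                         threshold = config$threshold,
                         config = unclass(config$phantom))
        jsonlite::write_json(manifest,
                             file.path(config$outDir, "manifest.json"),
                             auto_unbox = TRUE, digits = NA)
    }
    invisible(list(phantom = phantom, maps = maps, fit = cal$fit,
                   reports = reports))
}

#' Read a run configuration from YAML or JSON
#'
#' The file may contain any [runConfig()] fields; \code{phantom} is a
#' mapping of [phantomConfig()] fields.
#'
#' @param path YAML (.yml/.yaml) or JSON file.
#' @return A [runConfig()].
#' @export
readRunConfig <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
           else jsonlite::read_json(path, simplifyVector = TRUE)
    args <- raw[intersect(names(raw),
                          c("methods", "reference", "threshold", "oiLimit",
                            "outDir", "seed"))]
    if (!is.null(raw$phantom))
        args$phantom <- do.call(phantomConfig, as.list(raw$phantom))
    if (!is.null(raw$bayes))
        args$bayesSpec <- do.call(bayesSearchSpec, as.list(raw$bayes))
    do.call(runConfig, args)
}
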