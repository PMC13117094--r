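#' Accessors for FibroSeg objects
#'
#' @param object a FibroSeg S4 object.
#' @return \code{pixelData} returns the underlying \code{H x W x 3} array;
#'   \code{mask} the logical fibrosis mask; \code{percentage} the fibrosis
#'   percentage; \code{imageWidth}/\code{imageHeight} raster dimensions;
#'   \code{meanLab}/\code{stdLab}/\code{suggestedTolerance} seed statistics;
#'   \code{clusterLabels} the raw k-means label matrix.
#' @name accessors
#' @aliases pixelData mask percentage imageWidth imageHeight meanLab stdLab
#'   suggestedTolerance clusterLabels seedStats
NULL

#' @rdname accessors
#' @export
setGeneric("pixelData", function(object) standardGeneric("pixelData"))

#' @rdname accessors
#' @export
setGeneric("mask", function(object) standardGeneric("mask"))

#' @rdname accessors
#' @export
setGeneric("percentage", function(object) standardGeneric("percentage"))

#' @rdname accessors
#' @export
setGeneric("imageWidth", function(object) standardGeneric("imageWidth"))

#' @rdname accessors
#' @export
setGeneric("imageHeight", function(object) standardGeneric("imageHeight"))

#' @rdname accessors
#' @export
setGeneric("meanLab", function(object) standardGeneric("meanLab"))

#' @rdname accessors
#' @export
setGeneric("stdLab", function(object) standardGeneric("stdLab"))

#' @rdname accessors
#' @export
setGeneric("suggestedTolerance",
    function(object) standardGeneric("suggestedTolerance"))

#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(object) standardGeneric("clusterLabels"))

#' @rdname accessors
#' @export
setGeneric("seedStats", function(object) standardGeneric("seedStats"))

#' @rdname generateTile
#' @export
setGeneric("generateTile", function(spec) standardGeneric("generateTile"))

setMethod("pixelData", "RGBImage", function(object) object@pixels)
setMethod("pixelData", "LABImage", function(object) object@pixels)

setMethod("imageWidth", "RGBImage", function(object) dim(object@pixels)[2])
setMethod("imageWidth", "LABImage", function(object) dim(object@pixels)[2])
setMethod("imageHeight", "RGBImage", function(object) dim(object@pixels)[1])
setMethod("imageHeight", "LABImage", function(object) dim(object@pixels)[1])

setMethod("mask", "Segmentation", function(object) object@mask)
setMethod("percentage", "Segmentation", function(object) object@percentage)
setMethod("clusterLabels", "TextureSegmentation",
    function(object) object@labels)
setMethod("seedStats", "ColorSegmentation", function(object) object@seedStats)

setMethod("meanLab", "SeedStats", function(object) object@meanLab)
setMethod("stdLab", "SeedStats", function(object) object@stdLab)
setMethod("suggestedTolerance", "SeedStats",
    function(object) object@suggestedTolerance)

setMethod("show", "RGBImage", function(object) {
    cat(sprintf("RGBImage: %d x %d px, 8-bit sRGB\n",
        imageWidth(object), imageHeight(object)))
})

setMethod("show", "LABImage", function(object) {
    rng <- range(object@pixels[, , 1])
    cat(sprintf("LABImage: %d x %d px, L* in [%.2f, %.2f]\n",
        imageWidth(object), imageHeight(object), rng[1], rng[2]))
})

setMethod("show", "SeedRegion", function(object) {
    cat(sprintf("SeedRegion: %s, %d vertices\n", object@kind,
        nrow(object@vertices)))
})

setMethod("show", "SeedStats", function(object) {
    cat(sprintf(paste0("SeedStats: %d px, mean LAB (%.2f, %.2f, %.2f), ",
        "sd (%.2f, %.2f, %.2f), suggested tolerance %.3f\n"),
        object@pixelCount, object@meanLab[1], object@meanLab[2],
        object@meanLab[3], object@stdLab[1], object@stdLab[2],
        object@stdLab[3], object@suggestedTolerance))
})

setMethod("show", "ColorSegmentation", function(object) {
    cat(sprintf("ColorSegmentation: %.2f%% fibrosis at Delta-E tolerance %g\n",
        object@percentage, object@tolerance))
})

setMethod("show", "TextureSegmentation", function(object) {
    cat(sprintf("TextureSegmentation: %.2f%% fibrosis (%s policy)\n",
        object@percentage, object@policy))
})

setMethod("show", "GaborBankConfig", function(object) {
    cat(sprintf(paste0("GaborBankConfig: %d filters (orientations %s deg; ",
        "wavelengths %s px), bandwidth %g, smoothing %g*lambda, spatial %s, ",
        "seed %d, restarts %d, k = %d\n"),
        length(object@orientations) * length(object@wavelengths),
        paste(object@orientations, collapse = "/"),
        paste(object@wavelengths, collapse = "/"),
        object@bandwidth, object@smoothingFactor,
        if (object@includeSpatial) "on" else "off",
        object@rngSeed, object@restarts, object@k))
})

setMethod("show", "FeatureStack", function(object) {
    cat(sprintf("FeatureStack: %d x %d px, %d channels (%s)\n",
        object@width, object@height, ncol(object@features),
        paste(object@channelNames, collapse = ", ")))
})

setMethod("show", "MethodSummary", function(object) {
    cat(sprintf(paste0("MethodSummary [%s, %s]: mean %.4f%%, mean-based ",
        "accuracy %.4f%%, count-based accuracy %.2f%% (%d/%d correct)\n"),
        object@method, object@subset, object@meanPct, object@meanAccuracy,
        object@countAccuracy, object@correctCount, object@n))
})

setMethod("show", "SyntheticSpec", function(object) {
    cat(sprintf(paste0("SyntheticSpec: %d x %d px, %s geometry, Delta-E ",
        "offset %g, noise sd %g, seed %d\n"), object@width, object@height,
        object@geometry, object@deltaEOffset, object@noiseSigma,
        object@rngSeed))
})
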