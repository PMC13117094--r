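#' @import methods
NULL

#' 8-bit sRGB raster
#'
#' Container for an 8-bit sRGB histology image. Pixels are stored as a
#' \code{height x width x 3} numeric array with integer channel values in
#' \code{[0, 255]}; row index is the image row (y), column index the image
#' column (x), third index the R, G, B channel.
#'
#' @slot pixels numeric array, \code{H x W x 3}, values in \code{[0, 255]}.
#' @seealso [RGBImage()], [readRGBImage()], [srgbToLab()]
#' @exportClass RGBImage
setClass("RGBImage", representation(pixels = "array"))

setValidity("RGBImage", function(object) {
    p <- object@pixels
    if (length(dim(p)) != 3L || dim(p)[3] != 3L)
        return("pixels must be a H x W x 3 array")
    if (dim(p)[1] < 1L || dim(p)[2] < 1L)
        return("empty image")
    if (anyNA(p) || any(!is.finite(p)))
        return("pixel values must be finite")
    if (min(p) < 0 || max(p) > 255)
        return("channel values must lie in [0, 255]")
    if (any(p != round(p)))
        return("channel values must be 8-bit integers")
    TRUE
})

#' CIELAB raster
#'
#' Per-pixel (L*, a*, b*) triplets produced by [srgbToLab()]. For any valid
#' 8-bit sRGB input, L* lies in \code{[0, 100]}; a* and b* are unbounded in
#' principle but stay within roughly \code{[-128, 127]} in practice.
#'
#' @slot pixels numeric array, \code{H x W x 3}, channels L*, a*, b*.
#' @exportClass LABImage
setClass("LABImage", representation(pixels = "array"))

setValidity("LABImage", function(object) {
    p <- object@pixels
    if (length(dim(p)) != 3L || dim(p)[3] != 3L)
        return("pixels must be a H x W x 3 array")
    if (dim(p)[1] < 1L || dim(p)[2] < 1L)
        return("empty image")
    if (anyNA(p) || any(!is.finite(p)))
        return("pixel values must be finite")
    TRUE
})

#' Pathologist seed region
#'
#' The user-drawn region of interest marking a patch of presumed fibrosis.
#' Either a free polygon (at least three vertices) or an axis-aligned
#' rectangle stored as two opposite corners. Coordinates are continuous,
#' 0-based, x = column and y = row; a pixel \code{(x, y)} has its center at
#' \code{(x + 0.5, y + 0.5)}.
#'
#' @slot kind \code{"polygon"} or \code{"rectangle"}.
#' @slot vertices numeric matrix with columns x, y.
#' @seealso [seedRegion()], [rasterizeROI()]
#' @exportClass SeedRegion
setClass("SeedRegion", representation(kind = "character", vertices = "matrix"))

setValidity("SeedRegion", function(object) {
    v <- object@vertices
    if (!object@kind %in% c("polygon", "rectangle"))
        return("kind must be 'polygon' or 'rectangle'")
    if (ncol(v) != 2L || anyNA(v) || any(!is.finite(v)))
        return("vertices must be a finite n x 2 matrix")
    if (object@kind == "polygon" && nrow(v) < 3L)
        return("polygon needs at least 3 vertices")
    if (object@kind == "rectangle") {
        if (nrow(v) != 2L)
            return("rectangle is stored as two opposite corners")
        if (v[1, 1] == v[2, 1] || v[1, 2] == v[2, 2])
            return("rectangle must have positive area")
    }
    TRUE
})

#' CIELAB statistics of a seed region
#'
#' Mean color, per-channel standard deviation (sample, n - 1 convention) and
#' the suggested Delta-E tolerance — the mean of the three channel standard
#' deviations — of the pixels under a seed-region mask.
#'
#' @slot meanLab numeric(3), mean (L*, a*, b*).
#' @slot stdLab numeric(3), per-channel sample standard deviation.
#' @slot suggestedTolerance numeric(1), \code{mean(stdLab)}, Delta-E units.
#' @slot pixelCount integer(1), pixels in the region.
#' @seealso [roiColorStats()]
#' @exportClass SeedStats
setClass("SeedStats", representation(meanLab = "numeric", stdLab = "numeric",
    suggestedTolerance = "numeric", pixelCount = "integer"))

setValidity("SeedStats", function(object) {
    if (length(object@meanLab) != 3L || length(object@stdLab) != 3L)
        return("meanLab and stdLab must have length 3")
    if (any(object@stdLab < 0))
        return("standard deviations must be non-negative")
    if (object@pixelCount < 1L)
        return("pixelCount must be >= 1")
    if (abs(object@suggestedTolerance - mean(object@stdLab)) > 1e-8)
        return("suggestedTolerance must equal mean(stdLab)")
    TRUE
})

#' Binary fibrosis segmentation
#'
#' Virtual parent of [ColorSegmentation-class] and
#' [TextureSegmentation-class]: a logical fibrosis mask plus the fibrosis
#' percentage computed over the full raster.
#'
#' @slot mask logical matrix, \code{H x W}, \code{TRUE} = fibrosis.
#' @slot percentage numeric(1) in \code{[0, 100]}.
#' @exportClass Segmentation
setClass("Segmentation",
    representation(mask = "matrix", percentage = "numeric", "VIRTUAL"))

setValidity("Segmentation", function(object) {
    if (!is.logical(object@mask))
        return("mask must be logical")
    pct <- 100 * sum(object@mask) / length(object@mask)
    if (abs(object@percentage - pct) > 1e-8)
        return("percentage must equal 100 * sum(mask) / (W * H)")
    TRUE
})

#' Delta-E color segmentation result
#'
#' Fibrosis mask from the CIELAB seeded segmenter: the set of pixels whose
#' CIE76 Delta-E distance to the seed region's mean color is at most the
#' tolerance.
#'
#' @slot tolerance numeric(1), Delta-E threshold used.
#' @slot seedStats the [SeedStats-class] the segmentation was seeded with.
#' @seealso [segmentByColor()]
#' @exportClass ColorSegmentation
setClass("ColorSegmentation", contains = "Segmentation",
    representation(tolerance = "numeric", seedStats = "SeedStats"))

#' Gabor texture segmentation result
#'
#' Fibrosis mask from the Gabor-bank/k-means texture segmenter, together with
#' the raw two-cluster label matrix and the policy used to decide which
#' cluster is fibrosis.
#'
#' @slot labels integer matrix, \code{H x W}, raw k-means cluster ids.
#' @slot policy \code{"lightness"} or \code{"seeded"}.
#' @seealso [segmentByTexture()], [assignFibrosisCluster()]
#' @exportClass TextureSegmentation
setClass("TextureSegmentation", contains = "Segmentation",
    representation(labels = "matrix", policy = "character"))

#' Gabor filter-bank configuration
#'
#' Orientations and wavelengths of the texture filter bank plus the smoothing,
#' feature and clustering knobs of the texture segmenter. [defaultBank()]
#' builds the standard bank for a given raster size.
#'
#' @slot orientations numeric, angles in degrees, each in \code{[0, 180)}.
#' @slot wavelengths numeric, pixels per cycle, each \code{>= 2}.
#' @slot bandwidth numeric(1), spatial-frequency bandwidth in octaves.
#' @slot smoothingFactor numeric(1), post-filter Gaussian sigma as a multiple
#'   of the wavelength.
#' @slot includeSpatial logical(1), append pixel coordinates to the features.
#' @slot rngSeed integer(1), seed for the k-means initialization.
#' @slot restarts integer(1), k-means restarts (best by within-cluster SS).
#' @slot k integer(1), number of clusters (2 = fibrosis vs healthy).
#' @exportClass GaborBankConfig
setClass("GaborBankConfig", representation(orientations = "numeric",
    wavelengths = "numeric", bandwidth = "numeric", smoothingFactor = "numeric",
    includeSpatial = "logical", rngSeed = "integer", restarts = "integer",
    k = "integer"))

setValidity("GaborBankConfig", function(object) {
    if (length(object@orientations) < 1L || length(object@wavelengths) < 1L)
        return("need at least one orientation and one wavelength")
    if (any(object@wavelengths < 2))
        return("wavelengths must be >= 2 pixels/cycle")
    if (any(object@orientations < 0 | object@orientations >= 180))
        return("orientations must lie in [0, 180) degrees")
    if (object@bandwidth <= 0)
        return("bandwidth must be positive")
    if (object@smoothingFactor < 0)
        return("smoothingFactor must be non-negative")
    if (object@restarts < 1L)
        return("restarts must be >= 1")
    if (object@k < 2L)
        return("k must be >= 2")
    TRUE
})

#' Per-pixel joint color-texture features
#'
#' Feature matrix of the texture segmenter: one row per pixel (column-major
#' over the \code{H x W} raster), columns L*, a*, b*, the smoothed Gabor
#' magnitudes E1..Es and, optionally, the pixel coordinates. Channels are
#' standardized to mean 0, sd 1 over the image.
#'
#' @slot features numeric matrix, \code{N x C}.
#' @slot width,height integer(1), raster dimensions (\code{N = W * H}).
#' @slot channelNames character, one name per feature column.
#' @seealso [gaborFeatures()]
#' @exportClass FeatureStack
setClass("FeatureStack", representation(features = "matrix",
    width = "integer", height = "integer", channelNames = "character"))

setValidity("FeatureStack", function(object) {
    if (nrow(object@features) != object@width * object@height)
        return("feature rows must equal width * height")
    if (ncol(object@features) != length(object@channelNames))
        return("one channel name per feature column")
    TRUE
})

#' Per-method evaluation summary
#'
#' One row of the aggregate accuracy tables: a method's mean fibrosis
#' percentage over an image subset, its accuracy under the named formula, and
#' its correct/error counts under the ten-point rule.
#'
#' @slot method method name.
#' @slot subset \code{"fibrosis"}, \code{"special"} or \code{"all"}.
#' @slot meanPct mean fibrosis percentage over the subset.
#' @slot meanAccuracy accuracy from the mean-based relative formula.
#' @slot countAccuracy accuracy as \code{100 * correctCount / n}.
#' @slot correctCount,errorCount integer, images passing/failing the
#'   ten-point rule (union rule for the combined system).
#' @slot n integer, images in the subset.
#' @seealso [summarizeMethod()], [evaluationTables()]
#' @exportClass MethodSummary
setClass("MethodSummary", representation(method = "character",
    subset = "character", meanPct = "numeric", meanAccuracy = "numeric",
    countAccuracy = "numeric", correctCount = "integer",
    errorCount = "integer", n = "integer"))

setValidity("MethodSummary", function(object) {
    if (object@correctCount + object@errorCount != object@n)
        return("correctCount + errorCount must equal n")
    TRUE
})

#' Synthetic histology tile specification
#'
#' Recipe for a ground-truthed two-region H&E-like tile: a healthy base color
#' in CIELAB, a fibrosis region (half-split, centered disc, or polygon) whose
#' mean color is offset by a controlled Delta-E along a stated LAB direction,
#' optional oriented sinusoidal gratings per region, and Gaussian pixel noise.
#'
#' @slot width,height integer(1), raster size in pixels.
#' @slot geometry \code{"half-split"}, \code{"disc"} or \code{"polygon"}.
#' @slot vertices polygon vertices (only for \code{geometry = "polygon"}).
#' @slot baseLab numeric(3), healthy-region CIELAB color.
#' @slot deltaEOffset numeric(1), CIE76 distance between region colors.
#' @slot offsetDirection numeric(3), LAB direction of the offset (normalized
#'   internally).
#' @slot textureHealthy,textureFibrosis numeric(3)
#'   \code{c(wavelength, orientation, amplitude)} grating per region, or
#'   length 0 for none. Wavelength in px/cycle, orientation in degrees,
#'   amplitude in 8-bit units.
#' @slot noiseSigma numeric(1), Gaussian pixel noise sd, 8-bit units.
#' @slot rngSeed integer(1), seed making generation deterministic.
#' @seealso [syntheticSpec()], [generateTile()]
#' @exportClass SyntheticSpec
setClass("SyntheticSpec", representation(width = "integer", height = "integer",
    geometry = "character", vertices = "matrix", baseLab = "numeric",
    deltaEOffset = "numeric", offsetDirection = "numeric",
    textureHealthy = "numeric", textureFibrosis = "numeric",
    noiseSigma = "numeric", rngSeed = "integer"))

setValidity("SyntheticSpec", function(object) {
    if (object@width < 1L || object@height < 1L)
        return("width and height must be positive")
    if (!object@geometry %in% c("half-split", "disc", "polygon"))
        return("geometry must be 'half-split', 'disc' or 'polygon'")
    if (object@geometry == "polygon" && nrow(object@vertices) < 3L)
        return("polygon geometry needs at least 3 vertices")
    if (object@deltaEOffset < 0)
        return("deltaEOffset must be >= 0")
    if (object@noiseSigma < 0)
        return("noiseSigma must be >= 0")
    if (sum(object@offsetDirection^2) == 0)
        return("offsetDirection must be non-zero")
    for (tx in list(object@textureHealthy, object@textureFibrosis))
        if (length(tx) && (length(tx) != 3L || tx[1] < 2))
            return("textures are c(wavelength >= 2, orientation, amplitude)")
    TRUE
})
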