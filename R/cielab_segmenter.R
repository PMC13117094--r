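# Seeded CIELAB segmentation: the fibrosis mask is the Delta-E tolerance set
# {pixels : deltaE(pixel, seed mean) <= tolerance}.

#' Segment fibrosis by seeded CIELAB color distance
#'
#' Flags every pixel whose CIE76 Delta-E distance to the seed region's mean
#' color is at most \code{tolerance} (inclusive threshold). The default
#' tolerance of 10 Delta-E units is the value used throughout the reference
#' study; [suggestedTolerance()] of the seed statistics offers a data-driven
#' alternative. The fibrosis percentage is computed over the full raster with
#' no background exclusion.
#'
#' @param lab a [LABImage-class].
#' @param seed a [SeedStats-class] from [roiColorStats()].
#' @param tolerance Delta-E threshold, \code{>= 0}.
#' @return a [ColorSegmentation-class].
#' @examples
#' tile <- generateTile(syntheticSpec(width = 48, height = 48))
#' lab <- srgbToLab(tile$image)
#' roi <- rasterizeROI(seedRegion("rectangle", rbind(c(36, 20), c(44, 28))),
#'     48, 48)
#' segmentByColor(lab, roiColorStats(lab, roi))
#' @seealso [deltaEMap()], [fibrosisPercentage()]
#' @export
segmentByColor <- function(lab, seed, tolerance = 10) {
    stopifnot(is(lab, "LABImage"), is(seed, "SeedStats"))
    if (length(tolerance) != 1L || is.na(tolerance) || tolerance < 0)
        stop("tolerance must be a non-negative Delta-E value")
    de <- deltaEMap(lab, seed@meanLab)
    msk <- de <= tolerance
    new("ColorSegmentation", mask = msk,
        percentage = fibrosisPercentage(sum(msk), ncol(msk), nrow(msk)),
        tolerance = as.numeric(tolerance), seedStats = seed)
}

#' Fibrosis percentage from a pixel count
#'
#' Relates a fibrosis pixel count to the raster size:
#' \code{100 * count / (width * height)}.
#'
#' @param count fibrosis pixels, in \code{[0, width * height]}.
#' @param width,height raster dimensions in pixels.
#' @return percentage in \code{[0, 100]}.
#' @examples
#' fibrosisPercentage(148047, 1155, 774)  # 16.56
#' @export
fibrosisPercentage <- function(count, width, height) {
    if (width < 1 || height < 1)
        stop("raster dimensions must be positive")
    if (count < 0 || count > width * height)
        stop("count must lie in [0, width * height]")
    100 * count / (width * height)
}

#' Write a segmentation mask as a binary PNG
#'
#' Fibrosis pixels are written as 255, background as 0.
#'
#' @param segmentation a [Segmentation-class] (or a logical matrix).
#' @param path output PNG path.
#' @return invisibly, \code{path}.
#' @export
writeMaskImage <- function(segmentation, path) {
    m <- if (is(segmentation, "Segmentation")) mask(segmentation)
         else segmentation
    EBImage::writeImage(EBImage::Image(t(m * 1)), path)
    invisible(path)
}

#' Write a fibrosis overlay
#'
#' Original color where the mask is set, black elsewhere — the convention
#' under which automatic outputs are re-counted by
#' [countAnnotationPixels()] with the \code{"auto_black"} rule.
#'
#' @param image the source [RGBImage-class].
#' @param segmentation a [Segmentation-class] (or a logical matrix).
#' @param path output PNG path.
#' @return invisibly, \code{path}.
#' @export
writeOverlayImage <- function(image, segmentation, path) {
    stopifnot(is(image, "RGBImage"))
    m <- if (is(segmentation, "Segmentation")) mask(segmentation)
         else segmentation
    px <- image@pixels * array(rep(m, 3), dim = dim(image@pixels))
    writeRGBImage(RGBImage(px), path)
    invisible(path)
}

#' Tabular report for a segmentation run
#'
#' @param imageName image identifier (file name or label).
#' @param segmentation a [Segmentation-class].
#' @return one-row \code{data.frame} with image, method, tolerance (NA for
#'   texture runs), pixel count, raster dimensions and percentage.
#' @export
segmentationReport <- function(imageName, segmentation) {
    stopifnot(is(segmentation, "Segmentation"))
    m <- mask(segmentation)
    data.frame(image = imageName,
        method = if (is(segmentation, "ColorSegmentation")) "cielab"
                 else "gabor",
        tolerance = if (is(segmentation, "ColorSegmentation"))
                segmentation@tolerance else NA_real_,
        count = sum(m), width = ncol(m), height = nrow(m),
        percentage = percentage(segmentation))
}
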