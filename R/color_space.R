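# sRGB <-> CIELAB conversion (D65), color variance and CIE76 Delta-E.
# All arithmetic in double precision; 8-bit inputs are scaled to [0,1]
# before companding.

# sRGB -> XYZ (D65) linear-RGB matrix and white point
.M_RGB2XYZ <- matrix(c(
    0.4124564, 0.3575761, 0.1804375,
    0.2126729, 0.7151522, 0.0721750,
    0.0193339, 0.1191920, 0.9503041), nrow = 3, byrow = TRUE)
.M_XYZ2RGB <- solve(.M_RGB2XYZ)
.WHITE_D65 <- c(0.95047, 1.00000, 1.08883)

.srgb_linearize <- function(c01)
    ifelse(c01 <= 0.04045, c01 / 12.92, ((c01 + 0.055) / 1.055)^2.4)

.srgb_compand <- function(lin)
    ifelse(lin <= 0.0031308, 12.92 * lin, 1.055 * lin^(1 / 2.4) - 0.055)

# CIE f(t) with the linear segment below (6/29)^3
.lab_f <- function(t) {
    d <- 6 / 29
    ifelse(t > d^3, t^(1 / 3), t / (3 * d^2) + 4 / 29)
}

.lab_finv <- function(ft) {
    d <- 6 / 29
    ifelse(ft > d, ft^3, 3 * d^2 * (ft - 4 / 29))
}

# N x 3 matrix of 8-bit sRGB rows -> N x 3 CIELAB rows
.srgb2lab_mat <- function(rgb) {
    lin <- .srgb_linearize(rgb / 255)
    xyz <- lin %*% t(.M_RGB2XYZ)
    f <- .lab_f(sweep(xyz, 2, .WHITE_D65, "/"))
    cbind(L = 116 * f[, 2] - 16,
          a = 500 * (f[, 1] - f[, 2]),
          b = 200 * (f[, 2] - f[, 3]))
}

# N x 3 CIELAB rows -> N x 3 sRGB rows on the continuous 0..255 scale,
# unclipped (used for gamut checks in the synthetic generator)
.lab2srgb_mat <- function(lab) {
    fy <- (lab[, 1] + 16) / 116
    f <- cbind(fy + lab[, 2] / 500, fy, fy - lab[, 3] / 200)
    xyz <- sweep(.lab_finv(f), 2, .WHITE_D65, "*")
    255 * .srgb_compand(xyz %*% t(.M_XYZ2RGB))
}

#' Construct an RGBImage
#'
#' @param pixels a \code{H x W x 3} numeric array with 8-bit integer channel
#'   values in \code{[0, 255]}.
#' @return an [RGBImage-class].
#' @examples
#' img <- RGBImage(array(128, dim = c(4, 4, 3)))
#' imageWidth(img)
#' @export
RGBImage <- function(pixels) {
    if (is.null(dim(pixels)) || length(dim(pixels)) != 3L)
        stop("empty image: pixels must be a H x W x 3 array")
    storage.mode(pixels) <- "double"
    new("RGBImage", pixels = pixels)
}

#' @rdname RGBImage
#' @param lab for \code{LABImage()}, a \code{H x W x 3} array of (L*, a*, b*)
#'   triplets.
#' @export
LABImage <- function(lab) {
    if (is.null(dim(lab)) || length(dim(lab)) != 3L)
        stop("empty image: pixels must be a H x W x 3 array")
    storage.mode(lab) <- "double"
    new("LABImage", pixels = lab)
}

#' Convert an sRGB image to CIELAB
#'
#' Standard sRGB (D65) conversion: inverse companding of the 8-bit channels,
#' the linear RGB-to-XYZ matrix, then the CIE cube-root transform with its
#' linear segment for small values. Deterministic and dimension-preserving;
#' L* of any valid 8-bit pixel lies in \code{[0, 100]}.
#'
#' @param image an [RGBImage-class].
#' @return a [LABImage-class] of the same dimensions.
#' @examples
#' lab <- srgbToLab(RGBImage(array(255, dim = c(2, 2, 3))))
#' pixelData(lab)[1, 1, ]  # white -> (100, 0, 0)
#' @seealso [labToSrgb()], [deltaEMap()]
#' @export
srgbToLab <- function(image) {
    stopifnot(is(image, "RGBImage"))
    d <- dim(image@pixels)
    lab <- .srgb2lab_mat(matrix(image@pixels, ncol = 3))
    LABImage(array(lab, dim = d))
}

#' Convert a CIELAB image back to 8-bit sRGB
#'
#' Inverse of [srgbToLab()]; out-of-gamut values are clipped to \code{[0, 255]}
#' and channels rounded to 8-bit integers.
#'
#' @param lab a [LABImage-class].
#' @return an [RGBImage-class].
#' @export
labToSrgb <- function(lab) {
    stopifnot(is(lab, "LABImage"))
    d <- dim(lab@pixels)
    rgb <- .lab2srgb_mat(matrix(lab@pixels, ncol = 3))
    RGBImage(array(round(pmin(255, pmax(0, rgb))), dim = d))
}

#' Color variance of an image
#'
#' Mean squared Euclidean distance of the 8-bit RGB pixels from their mean
#' triplet: \code{V = (1/N) * sum(||pixel - mu||^2)}. Equals the sum of the
#' three per-channel population variances.
#'
#' @param image an [RGBImage-class].
#' @return non-negative scalar, squared 8-bit-channel units.
#' @examples
#' colorVariance(RGBImage(array(7, dim = c(3, 3, 3))))  # constant image -> 0
#' @export
colorVariance <- function(image) {
    stopifnot(is(image, "RGBImage"))
    m <- matrix(image@pixels, ncol = 3)
    mu <- colMeans(m)
    mean(rowSums(sweep(m, 2, mu)^2))
}

#' Per-pixel Delta-E distance map
#'
#' CIE76 Delta-E: the Euclidean distance in CIELAB between each pixel and a
#' reference color.
#'
#' @param lab a [LABImage-class].
#' @param reference numeric(3), the reference (L*, a*, b*) triplet.
#' @return a \code{H x W} numeric matrix of non-negative distances.
#' @seealso [segmentByColor()]
#' @export
deltaEMap <- function(lab, reference) {
    stopifnot(is(lab, "LABImage"))
    if (length(reference) != 3L || anyNA(reference) ||
        any(!is.finite(reference)))
        stop("reference must be a finite LAB triplet")
    d <- dim(lab@pixels)
    m <- matrix(lab@pixels, ncol = 3)
    matrix(sqrt(rowSums(sweep(m, 2, reference)^2)), d[1], d[2])
}

#' Read an 8-bit RGB image
#'
#' Reads PNG, TIFF or JPEG into an [RGBImage-class]. Images with an alpha
#' channel are rejected, as are grayscale images.
#'
#' @param path file path.
#' @return an [RGBImage-class].
#' @seealso [writeRGBImage()]
#' @export
readRGBImage <- function(path) {
    if (!file.exists(path))
        stop("cannot read image: ", path)
    img <- EBImage::readImage(path)
    d <- dim(img)
    if (length(d) == 3L && d[3] == 4L)
        stop("alpha channels are not supported; expected 8-bit RGB")
    if (length(d) != 3L || d[3] != 3L)
        stop("expected an 8-bit RGB image (3 channels)")
    px <- aperm(EBImage::imageData(img), c(2, 1, 3))
    RGBImage(array(round(pmin(255, pmax(0, px * 255))), dim = dim(px)))
}

#' Write an RGBImage to disk
#'
#' Format follows the file extension (png, tiff, jpeg).
#'
#' @param image an [RGBImage-class].
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeRGBImage <- function(image, path) {
    stopifnot(is(image, "RGBImage"))
    eb <- EBImage::Image(aperm(image@pixels / 255, c(2, 1, 3)),
        colormode = "Color")
    EBImage::writeImage(eb, path)
    invisible(path)
}
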