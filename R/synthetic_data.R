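# Ground-truthed synthetic H&E-like tiles and the packaged per-image study
# dataset.

.FIXTURE_MD5 <- "50a97d5265b8b84d922af62dabb383b1"

#' Construct a synthetic tile specification
#'
#' Defaults describe the strong-color-contrast regime: an eosin-pink healthy
#' base, CIELAB roughly (70, 25, 5), with the fibrosis region offset by 40
#' Delta-E units along the paler-and-less-pink direction (+L*, -a*) that
#' collagen takes against myocardium on H&E, no gratings and no noise. The
#' weak-contrast regime that defeats color segmentation is obtained with
#' \code{deltaEOffset = 0} plus orthogonal gratings.
#'
#' @param width,height tile size in pixels.
#' @param geometry \code{"half-split"} (right half is fibrosis),
#'   \code{"disc"} (centered disc of radius \code{min(width, height) / 3}),
#'   or \code{"polygon"}.
#' @param vertices polygon vertices, for \code{geometry = "polygon"}.
#' @param baseLab healthy-region CIELAB triplet.
#' @param deltaEOffset CIE76 distance between the two region colors.
#' @param offsetDirection LAB direction of the offset (normalized).
#' @param textureHealthy,textureFibrosis \code{c(wavelength, orientation,
#'   amplitude)} sinusoidal grating per region, or \code{NULL}.
#' @param noiseSigma Gaussian pixel noise sd, 8-bit units.
#' @param rngSeed integer seed; generation is bitwise deterministic.
#' @return a [SyntheticSpec-class].
#' @seealso [generateTile()]
#' @export
syntheticSpec <- function(width = 128, height = 128,
        geometry = c("half-split", "disc", "polygon"), vertices = NULL,
        baseLab = c(70, 25, 5), deltaEOffset = 40,
        offsetDirection = c(1, -1, 0), textureHealthy = NULL,
        textureFibrosis = NULL, noiseSigma = 0, rngSeed = 1L) {
    geometry <- match.arg(geometry)
    new("SyntheticSpec", width = as.integer(width),
        height = as.integer(height), geometry = geometry,
        vertices = if (is.null(vertices)) matrix(0, 0, 2)
                   else as.matrix(vertices),
        baseLab = as.numeric(baseLab),
        deltaEOffset = as.numeric(deltaEOffset),
        offsetDirection = as.numeric(offsetDirection),
        textureHealthy = as.numeric(textureHealthy %||% numeric(0)),
        textureFibrosis = as.numeric(textureFibrosis %||% numeric(0)),
        noiseSigma = as.numeric(noiseSigma), rngSeed = as.integer(rngSeed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.truthMask <- function(spec) {
    w <- spec@width; h <- spec@height
    cx <- rep(seq_len(w) - 0.5, each = h)
    cy <- rep(seq_len(h) - 0.5, times = w)
    inside <- switch(spec@geometry,
        "half-split" = cx >= w / 2,
        "disc" = (cx - w / 2)^2 + (cy - h / 2)^2 <= (min(w, h) / 3)^2,
        "polygon" = .pointsInPolygonEvenOdd(cx, cy, spec@vertices))
    m <- matrix(inside, h, w)
    if (!any(m) || all(m))
        stop("truth mask must be non-empty and non-full")
    m
}

#' Generate a ground-truthed synthetic tile
#'
#' Builds the two-region image in continuous RGB: each region is filled with
#' the sRGB rendering of its CIELAB color (the fibrosis color sits exactly
#' \code{deltaEOffset} Delta-E units from the healthy one along
#' \code{offsetDirection}), per-region gratings
#' \code{amplitude * sin(2*pi*(x*cos(theta) + y*sin(theta)) / wavelength)}
#' are added to all three channels, then Gaussian noise; the result is
#' clipped to \code{[0, 255]} and rounded to 8 bits. An error is raised when
#' either region color leaves the sRGB gamut before texture/noise.
#'
#' @param spec a [SyntheticSpec-class].
#' @return list with \code{image} (an [RGBImage-class]) and \code{truth}
#'   (logical \code{H x W} fibrosis mask).
#' @examples
#' tile <- generateTile(syntheticSpec(width = 48, height = 48))
#' mean(tile$truth)  # about a half
#' @export
setMethod("generateTile", "SyntheticSpec", function(spec) {
    truth <- .truthMask(spec)
    w <- spec@width; h <- spec@height
    dir <- spec@offsetDirection / sqrt(sum(spec@offsetDirection^2))
    fibLab <- spec@baseLab + spec@deltaEOffset * dir
    cols <- .lab2srgb_mat(rbind(spec@baseLab, fibLab))
    if (any(cols < -1e-6) || any(cols > 255 + 1e-6))
        stop("offset out of gamut")
    cols <- matrix(pmin(255, pmax(0, cols)), nrow = 2)
    px <- array(0, dim = c(h, w, 3))
    for (ch in 1:3)
        px[, , ch] <- ifelse(truth, cols[2, ch], cols[1, ch])
    X <- matrix(rep(seq_len(w) - 1, each = h), h, w)
    Y <- matrix(rep(seq_len(h) - 1, times = w), h, w)
    addGrating <- function(px, tx, region) {
        if (!length(tx)) return(px)
        theta <- tx[2] * pi / 180
        g <- tx[3] * sin(2 * pi * (X * cos(theta) + Y * sin(theta)) / tx[1])
        for (ch in 1:3)
            px[, , ch] <- px[, , ch] + ifelse(region, g, 0)
        px
    }
    px <- addGrating(px, spec@textureHealthy, !truth)
    px <- addGrating(px, spec@textureFibrosis, truth)
    if (spec@noiseSigma > 0) {
        set.seed(spec@rngSeed)
        px <- px + array(stats::rnorm(length(px), 0, spec@noiseSigma),
            dim = dim(px))
    }
    list(image = RGBImage(array(round(pmin(255, pmax(0, px))), dim = dim(px))),
         truth = truth)
})

#' Load the packaged per-image study dataset
#'
#' Reads the packaged CSV of per-image records from the 45-image study (40
#' fibrosis images, 5 special-tissue images): raster dimensions, fibrosis
#' pixel counts and fibrosis percentages for the manual annotation and the
#' three automatic methods. The packaged file is checksum-verified, and
#' every row's percentages are checked for consistency with its pixel count
#' and raster dimensions within 0.005 (manual and python counts are relative
#' to the original raster, matlab and gabor counts to the processed raster).
#'
#' @param path optional path to an alternative CSV with the same columns;
#'   the checksum check applies only to the packaged file.
#' @return \code{data.frame} with 45 rows and columns \code{image_id},
#'   \code{group}, \code{width_orig}, \code{height_orig},
#'   \code{width_matlab}, \code{height_matlab}, \code{manual_px},
#'   \code{matlab_px}, \code{python_px}, \code{gabor_px}, \code{manual_pct},
#'   \code{matlab_pct}, \code{python_pct}, \code{gabor_pct}.
#' @examples
#' rec <- loadFixtures()
#' rec[1, c("manual_pct", "matlab_pct", "python_pct", "gabor_pct")]
#' @seealso [evaluationTables()]
#' @export
loadFixtures <- function(path = NULL) {
    packaged <- is.null(path)
    if (packaged)
        path <- system.file("extdata", "fibrosis_percentages.csv",
            package = "FibroSeg", mustWork = TRUE)
    if (packaged && unname(tools::md5sum(path)) != .FIXTURE_MD5)
        stop("checksum mismatch: packaged dataset is corrupted")
    rec <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("image_id", "group", "width_orig", "height_orig",
        "width_matlab", "height_matlab", "manual_px", "matlab_px",
        "python_px", "gabor_px", "manual_pct", "matlab_pct", "python_pct",
        "gabor_pct")
    if (!identical(names(rec), need))
        stop("unexpected dataset columns")
    if (nrow(rec) != 45L || sum(rec$group == "fibrosis") != 40L ||
        sum(rec$group == "special") != 5L)
        stop("expected 45 records: 40 fibrosis + 5 special")
    if (!all((rec$group == "special") == (rec$manual_pct == 0)))
        stop("special records must have zero manual percentage")
    checks <- rbind(
        cbind(rec$manual_px, rec$width_orig * rec$height_orig,
            rec$manual_pct),
        cbind(rec$python_px, rec$width_orig * rec$height_orig,
            rec$python_pct),
        cbind(rec$matlab_px, rec$width_matlab * rec$height_matlab,
            rec$matlab_pct),
        cbind(rec$gabor_px, rec$width_matlab * rec$height_matlab,
            rec$gabor_pct))
    if (any(abs(100 * checks[, 1] / checks[, 2] - checks[, 3]) >= 0.005))
        stop("percentage inconsistent with pixel count and raster size")
    rec
}
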