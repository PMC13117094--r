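# Seed-region representation, rasterization and CIELAB statistics.
#
# Coordinates are continuous and 0-based: x = column, y = row, so the valid
# domain of a W x H raster is [0, W] x [0, H] and pixel (x, y) has its center
# at (x + 0.5, y + 0.5). Polygons are filled by the even-odd rule applied to
# pixel centers; a rectangle is the half-open box [x0, x1) x [y0, y1).

#' Construct a seed region
#'
#' @param kind \code{"polygon"} or \code{"rectangle"}.
#' @param vertices numeric \code{n x 2} matrix of (x, y) coordinates; a
#'   rectangle is given as two opposite corners.
#' @return a [SeedRegion-class].
#' @examples
#' seedRegion("rectangle", rbind(c(2, 3), c(10, 8)))
#' seedRegion("polygon", rbind(c(0, 0), c(10, 0), c(0, 10)))
#' @export
seedRegion <- function(kind = c("polygon", "rectangle"), vertices) {
    kind <- match.arg(kind)
    vertices <- as.matrix(vertices)
    colnames(vertices) <- c("x", "y")
    new("SeedRegion", kind = kind, vertices = vertices)
}

#' Read a seed region from JSON
#'
#' Expects \code{{"kind": "polygon"|"rectangle", "vertices": [[x,y], ...]}}.
#'
#' @param path JSON file path.
#' @return a [SeedRegion-class].
#' @export
readSeedRegion <- function(path) {
    obj <- jsonlite::fromJSON(path)
    if (is.null(obj$kind) || is.null(obj$vertices))
        stop("ROI file must contain 'kind' and 'vertices'")
    seedRegion(obj$kind, matrix(unlist(obj$vertices), ncol = 2, byrow = TRUE))
}

#' Rasterize a seed region to a binary mask
#'
#' A pixel belongs to the mask iff its center (x + 0.5, y + 0.5) lies inside
#' the region: inside the half-open box for a rectangle, or inside by the
#' even-odd (crossing-number) rule for a polygon. Points exactly on a polygon
#' edge are resolved by the crossing rule's half-open edge convention.
#'
#' @param region a [SeedRegion-class].
#' @param width,height raster dimensions in pixels.
#' @return logical \code{height x width} matrix.
#' @examples
#' m <- rasterizeROI(seedRegion("rectangle", rbind(c(0, 0), c(5, 5))), 10, 10)
#' sum(m)  # 25
#' @export
rasterizeROI <- function(region, width, height) {
    stopifnot(is(region, "SeedRegion"))
    v <- region@vertices
    if (any(v[, 1] < 0) || any(v[, 1] > width) ||
        any(v[, 2] < 0) || any(v[, 2] > height))
        stop("seed region lies outside the image bounds")
    cx <- rep(seq_len(width) - 0.5, each = height)
    cy <- rep(seq_len(height) - 0.5, times = width)
    if (region@kind == "rectangle") {
        x0 <- min(v[, 1]); x1 <- max(v[, 1])
        y0 <- min(v[, 2]); y1 <- max(v[, 2])
        inside <- cx >= x0 & cx < x1 & cy >= y0 & cy < y1
    } else {
        inside <- .pointsInPolygonEvenOdd(cx, cy, v)
    }
    m <- matrix(inside, height, width)
    if (!any(m))
        stop("empty seed region")
    m
}

# Vectorized even-odd (crossing number) test: count edges whose half-open
# y-span contains the point and whose x-intersection is right of the point.
.pointsInPolygonEvenOdd <- function(px, py, v) {
    n <- nrow(v)
    crossings <- integer(length(px))
    for (i in seq_len(n)) {
        j <- if (i == n) 1L else i + 1L
        x1 <- v[i, 1]; y1 <- v[i, 2]
        x2 <- v[j, 1]; y2 <- v[j, 2]
        if (y1 == y2) next
        spans <- (py >= pmin(y1, y2)) & (py < pmax(y1, y2))
        xint <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
        crossings <- crossings + as.integer(spans & xint > px)
    }
    crossings %% 2L == 1L
}

#' CIELAB statistics of a masked region
#'
#' Mean and per-channel sample (n - 1) standard deviation of the CIELAB
#' values under a mask, and the suggested Delta-E tolerance: the mean of the
#' three channel standard deviations. A one-pixel region is allowed; its
#' standard deviations (and hence the suggested tolerance) are zero, with a
#' warning.
#'
#' @param lab a [LABImage-class].
#' @param roiMask logical \code{H x W} matrix selecting at least one pixel.
#' @return a [SeedStats-class].
#' @seealso [rasterizeROI()], [segmentByColor()]
#' @export
roiColorStats <- function(lab, roiMask) {
    stopifnot(is(lab, "LABImage"))
    d <- dim(lab@pixels)
    if (!identical(dim(roiMask), d[1:2]))
        stop("mask dimensions must match the image")
    n <- sum(roiMask)
    if (n < 1L)
        stop("empty mask: the seed region selects no pixels")
    m <- matrix(lab@pixels, ncol = 3)[as.vector(roiMask), , drop = FALSE]
    mu <- colMeans(m)
    if (n == 1L) {
        warning("one-pixel seed region: standard deviation and suggested ",
            "tolerance are 0")
        sdv <- c(0, 0, 0)
    } else {
        sdv <- apply(m, 2, stats::sd)
    }
    new("SeedStats", meanLab = unname(mu), stdLab = unname(sdv),
        suggestedTolerance = mean(sdv), pixelCount = as.integer(n))
}
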