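# Gabor filter-bank texture segmentation: multi-orientation, multi-scale
# filter magnitudes, Gaussian smoothing, joint color-texture features,
# k-means with k = 2, and an explicit fibrosis-cluster selection policy.

#' Construct a Gabor bank configuration
#'
#' @param orientations angles in degrees, each in \code{[0, 180)}.
#' @param wavelengths pixels per cycle, each \code{>= 2}.
#' @param bandwidth spatial-frequency bandwidth, octaves.
#' @param smoothingFactor Gaussian smoothing sigma as a multiple of each
#'   filter's wavelength.
#' @param includeSpatial append pixel coordinates to the feature vector.
#' @param rngSeed seed for the k-means initialization.
#' @param restarts k-means restarts; the run with the lowest within-cluster
#'   sum of squares wins.
#' @param k number of clusters.
#' @return a [GaborBankConfig-class].
#' @seealso [defaultBank()]
#' @export
gaborBankConfig <- function(orientations = c(0, 45, 90, 135),
        wavelengths = 4, bandwidth = 1, smoothingFactor = 0.5,
        includeSpatial = TRUE, rngSeed = 1L, restarts = 10L, k = 2L) {
    new("GaborBankConfig", orientations = as.numeric(orientations),
        wavelengths = as.numeric(wavelengths),
        bandwidth = as.numeric(bandwidth),
        smoothingFactor = as.numeric(smoothingFactor),
        includeSpatial = isTRUE(includeSpatial),
        rngSeed = as.integer(rngSeed), restarts = as.integer(restarts),
        k = as.integer(k))
}

#' Default Gabor bank for a raster size
#'
#' Four orientations at 45-degree steps and octave-spaced wavelengths
#' \code{4 * 2^k} for \code{k = 0..K} with
#' \code{K = max(0, floor(log2(hypot(width, height) / 8)) - 2)}, so that
#' every wavelength stays at or below an eighth of the image diagonal;
#' bandwidth 1 octave, smoothing sigma \code{0.5 * lambda}, spatial features
#' on.
#'
#' @param width,height raster dimensions, both \code{>= 16}.
#' @param ... overrides passed on to [gaborBankConfig()].
#' @return a [GaborBankConfig-class].
#' @examples
#' defaultBank(16, 16)      # single wavelength, 4 filters
#' defaultBank(774, 1155)
#' @export
defaultBank <- function(width, height, ...) {
    if (width < 16 || height < 16)
        stop("image too small for texture analysis (minimum 16 x 16)")
    K <- max(0, floor(log2(sqrt(width^2 + height^2) / 8)) - 2)
    gaborBankConfig(orientations = c(0, 45, 90, 135),
        wavelengths = 4 * 2^(0:K), ...)
}

#' Complex Gabor kernel
#'
#' Oriented sinusoid under a Gaussian envelope. The envelope sigma follows
#' the standard bandwidth relation
#' \code{sigma = lambda / pi * sqrt(log(2) / 2) * (2^b + 1) / (2^b - 1)};
#' the kernel is truncated at 3 sigma. The even (cosine) part is DC-corrected
#' against the envelope so that a constant image yields zero response.
#'
#' @param wavelength pixels per cycle, \code{>= 2}.
#' @param orientation angle in degrees (0 = horizontal wave vector).
#' @param bandwidth octaves.
#' @return list with \code{re} and \code{im} square matrices (odd side).
#' @export
gaborKernel <- function(wavelength, orientation, bandwidth = 1) {
    stopifnot(wavelength >= 2)
    theta <- orientation * pi / 180
    sigma <- wavelength / pi * sqrt(log(2) / 2) *
        (2^bandwidth + 1) / (2^bandwidth - 1)
    r <- ceiling(3 * sigma)
    xs <- -r:r
    X <- matrix(xs, 2 * r + 1, 2 * r + 1, byrow = TRUE)  # columns = x
    Y <- matrix(xs, 2 * r + 1, 2 * r + 1)                # rows = y
    xp <- X * cos(theta) + Y * sin(theta)
    yp <- -X * sin(theta) + Y * cos(theta)
    env <- exp(-(xp^2 + yp^2) / (2 * sigma^2))
    re <- env * cos(2 * pi * xp / wavelength)
    im <- env * sin(2 * pi * xp / wavelength)
    re <- re - env * sum(re) / sum(env)   # remove DC of the even part
    list(re = re, im = im)
}

.grayscale <- function(image) {
    px <- image@pixels / 255
    0.2989 * px[, , 1] + 0.5870 * px[, , 2] + 0.1140 * px[, , 3]
}

.gaussianSmooth <- function(m, sigma) {
    if (sigma <= 0) return(m)
    EBImage::imageData(EBImage::gblur(EBImage::Image(m), sigma = sigma))
}

.standardizeColumns <- function(x) {
    mu <- colMeans(x)
    sdv <- apply(x, 2, stats::sd)
    x <- sweep(x, 2, mu)
    # channels with no real spread (incl. FFT ripple on flat input) stay at 0
    const <- sdv < 1e-8
    x[, const] <- 0
    if (any(!const))
        x[, !const] <- sweep(x[, !const, drop = FALSE], 2, sdv[!const], "/")
    x
}

#' Joint color-texture feature stack
#'
#' Filters the grayscale image with every (orientation, wavelength) pair of
#' the bank, takes the response magnitude, smooths each magnitude map with a
#' Gaussian of sigma \code{smoothingFactor * wavelength}, and concatenates
#' the CIELAB channels (plus pixel coordinates when \code{includeSpatial} is
#' on). All channels are standardized to mean 0, sd 1 unless
#' \code{standardize = FALSE}.
#'
#' @param image an [RGBImage-class].
#' @param bank a [GaborBankConfig-class].
#' @param standardize standardize the channels (default, required for
#'   clustering); turn off only for inspecting raw responses.
#' @return a [FeatureStack-class] with \code{3 + s} (+2 spatial) channels for
#'   a bank of \code{s} filters.
#' @seealso [segmentByTexture()]
#' @export
gaborFeatures <- function(image, bank, standardize = TRUE) {
    stopifnot(is(image, "RGBImage"), is(bank, "GaborBankConfig"))
    h <- imageHeight(image); w <- imageWidth(image)
    gray <- .grayscale(image)
    labpx <- matrix(srgbToLab(image)@pixels, ncol = 3)
    feats <- list(L = labpx[, 1], a = labpx[, 2], b = labpx[, 3])
    for (lam in bank@wavelengths) {
        for (th in bank@orientations) {
            k <- gaborKernel(lam, th, bank@bandwidth)
            if (nrow(k$re) > h || ncol(k$re) > w)
                stop("wavelength ", lam, " too large for a ", w, " x ", h,
                     " image")
            mag <- sqrt(
                EBImage::filter2(gray, k$re, boundary = "replicate")^2 +
                EBImage::filter2(gray, k$im, boundary = "replicate")^2)
            mag <- .gaussianSmooth(mag, bank@smoothingFactor * lam)
            feats[[sprintf("E_t%g_l%g", th, lam)]] <- as.vector(mag)
        }
    }
    if (bank@includeSpatial) {
        feats$x <- rep(seq_len(w) - 1, each = h)
        feats$y <- rep(seq_len(h) - 1, times = w)
    }
    X <- do.call(cbind, feats)
    if (standardize)
        X <- .standardizeColumns(X)
    new("FeatureStack", features = X, width = as.integer(w),
        height = as.integer(h), channelNames = names(feats))
}

#' Segment fibrosis by texture clustering
#'
#' Clusters the per-pixel feature vectors with k-means (k = 2, squared
#' Euclidean distance, seeded initialization, best of \code{restarts} runs by
#' within-cluster sum of squares, 300-iteration cap) and maps the two
#' clusters to healthy/fibrosis via [assignFibrosisCluster()]. Identical
#' inputs and seed give bitwise-identical labels.
#'
#' @param features a [FeatureStack-class] from [gaborFeatures()].
#' @param bank the [GaborBankConfig-class] used (supplies seed, restarts, k).
#' @param lab the image's [LABImage-class], used by the cluster-selection
#'   policy.
#' @param policy \code{"lightness"} (default) or \code{"seeded"}; see
#'   [assignFibrosisCluster()].
#' @param seedMask logical mask for the \code{"seeded"} policy.
#' @return a [TextureSegmentation-class].
#' @export
segmentByTexture <- function(features, bank, lab,
        policy = c("lightness", "seeded"), seedMask = NULL) {
    stopifnot(is(features, "FeatureStack"), is(bank, "GaborBankConfig"))
    policy <- match.arg(policy)
    X <- features@features
    if (nrow(unique(X)) < 2L)
        stop("degenerate texture: single cluster")
    set.seed(bank@rngSeed)
    km <- stats::kmeans(X, centers = bank@k, nstart = bank@restarts,
        iter.max = 300L)
    labels <- matrix(as.integer(km$cluster), features@height, features@width)
    assignFibrosisCluster(labels, lab, policy, seedMask)
}

#' Decide which cluster is fibrosis
#'
#' \code{"seeded"}: the cluster with the majority overlap with the provided
#' seed mask is fibrosis. \code{"lightness"}: the cluster with the higher
#' mean L* is fibrosis (collagen is pale eosinophilic, so fibrotic regions
#' tend to be lighter); mean-L* ties within 1e-9 are broken deterministically
#' toward the cluster containing pixel (0, 0).
#'
#' @param labels integer \code{H x W} matrix with exactly two cluster ids.
#' @param lab the image's [LABImage-class].
#' @param policy \code{"lightness"} or \code{"seeded"}.
#' @param seedMask logical mask, required for the \code{"seeded"} policy.
#' @return a [TextureSegmentation-class].
#' @export
assignFibrosisCluster <- function(labels, lab,
        policy = c("lightness", "seeded"), seedMask = NULL) {
    stopifnot(is(lab, "LABImage"))
    policy <- match.arg(policy)
    ids <- sort(unique(as.vector(labels)))
    if (length(ids) != 2L)
        stop("exactly 2 clusters are required, got ", length(ids))
    if (policy == "seeded") {
        if (is.null(seedMask))
            stop("seeded policy requires a seed region mask")
        ov <- vapply(ids, function(i) sum(labels == i & seedMask), 0)
        fib <- ids[which.max(ov)]
    } else {
        Lstar <- lab@pixels[, , 1]
        mL <- vapply(ids, function(i) mean(Lstar[labels == i]), 0)
        fib <- if (abs(mL[1] - mL[2]) < 1e-9) labels[1, 1]
               else ids[which.max(mL)]
    }
    msk <- labels == fib
    new("TextureSegmentation", mask = msk,
        percentage = fibrosisPercentage(sum(msk), ncol(msk), nrow(msk)),
        labels = labels, policy = policy)
}
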