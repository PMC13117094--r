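test_that("the default bank follows the size-adaptive recipe", {
    b <- defaultBank(16, 16)
    expect_equal(b@orientations, c(0, 45, 90, 135))
    expect_equal(b@wavelengths, 4)     # K = 0 at 16 x 16
    b2 <- defaultBank(774, 1155)
    expect_equal(length(b2@orientations), 4)
    expect_true(all(b2@wavelengths <= sqrt(774^2 + 1155^2) / 8))
    expect_true(all(diff(log2(b2@wavelengths)) == 1))  # octave spacing
    expect_true(validObject(b2))
    expect_error(defaultBank(15, 200), "too small")
})

test_that("Gabor kernels are zero-mean and respond to matched gratings", {
    k <- gaborKernel(6, 30)
    expect_equal(sum(k$re), 0, tolerance = 1e-9)
    expect_equal(sum(k$im), 0, tolerance = 1e-9)
    expect_equal(nrow(k$re) %% 2, 1)
    # constant image: every raw magnitude channel is ~0
    bank <- gaborBankConfig(wavelengths = c(4, 8), includeSpatial = FALSE)
    fs <- gaborFeatures(constImage(48, 48, c(120, 120, 120)), bank,
        standardize = FALSE)
    gcols <- grepl("^E_", fs@channelNames)
    expect_lt(max(abs(fs@features[, gcols])), 1e-6)
    # a pure grating: the matched (orientation, wavelength) channel wins
    h <- 64; w <- 64
    X <- matrix(rep(0:(w - 1), each = h), h, w)
    Y <- matrix(rep(0:(h - 1), times = w), h, w)
    th <- 45 * pi / 180
    g <- 128 + 60 * sin(2 * pi * (X * cos(th) + Y * sin(th)) / 8)
    img <- RGBImage(array(round(rep(g, 3)), dim = c(h, w, 3)))
    bank2 <- gaborBankConfig(wavelengths = c(4, 8, 16),
        includeSpatial = FALSE)
    fs2 <- gaborFeatures(img, bank2, standardize = FALSE)
    e <- colMeans(fs2@features[, grepl("^E_", fs2@channelNames)])
    expect_equal(names(which.max(e)), "E_t45_l8")
})

test_that("feature stacks have the documented shape and standardization", {
    img <- randImage(32, 32, 3L)
    bank <- gaborBankConfig(wavelengths = c(4, 8))  # s = 8 filters
    fs <- gaborFeatures(img, bank)
    expect_equal(ncol(fs@features), 3 + 8 + 2)
    expect_equal(nrow(fs@features), 32 * 32)
    expect_true(all(abs(colMeans(fs@features)) < 1e-6))
    expect_true(all(abs(apply(fs@features, 2, sd) - 1) < 1e-6))
    # oversized wavelengths are refused rather than wrapped
    expect_error(gaborFeatures(randImage(20, 20, 1L),
        gaborBankConfig(wavelengths = 32)), "too large")
})

test_that("orthogonal gratings of identical color are separated by texture", {
    tile <- generateTile(gratingTileSpec())
    bank <- defaultBank(128, 128, rngSeed = 11L)
    fs <- gaborFeatures(tile$image, bank)
    lab <- srgbToLab(tile$image)
    seg <- segmentByTexture(fs, bank, lab, policy = "seeded",
        seedMask = fibrosisSeedMask())
    expect_gte(dice(mask(seg), tile$truth), 0.95)
    # determinism: identical seed and inputs give bitwise-identical labels
    seg2 <- segmentByTexture(fs, bank, lab, policy = "seeded",
        seedMask = fibrosisSeedMask())
    expect_identical(clusterLabels(seg2), clusterLabels(seg))
    expect_identical(mask(seg2), mask(seg))
    # label permutation leaves the matched Dice unchanged
    flipped <- 3L - clusterLabels(seg)
    bestDice <- function(lbl) max(dice(lbl == 1, tile$truth),
        dice(lbl == 2, tile$truth))
    expect_equal(bestDice(flipped), bestDice(clusterLabels(seg)))
})

test_that("texture separation survives moderate pixel noise", {
    tile <- generateTile(gratingTileSpec(noiseSigma = 5))
    bank <- defaultBank(128, 128, rngSeed = 11L)
    seg <- segmentByTexture(gaborFeatures(tile$image, bank), bank,
        srgbToLab(tile$image), policy = "seeded",
        seedMask = fibrosisSeedMask())
    expect_gte(dice(mask(seg), tile$truth), 0.90)
    expect_gte(percentage(seg), 0)
    expect_lte(percentage(seg), 100)
})

test_that("degenerate single-texture input is refused", {
    bank <- gaborBankConfig(includeSpatial = FALSE)
    img <- constImage(32, 32, c(100, 100, 100))
    fs <- gaborFeatures(img, bank)
    expect_error(segmentByTexture(fs, bank, srgbToLab(img)),
        "degenerate texture")
})

test_that("fibrosis-cluster policies behave as documented", {
    labels <- matrix(1L, 8, 8); labels[, 5:8] <- 2L
    # lightness: right half is much lighter
    lp <- array(0, dim = c(8, 8, 3))
    lp[, 1:4, 1] <- 40; lp[, 5:8, 1] <- 80
    lab <- LABImage(lp)
    seg <- assignFibrosisCluster(labels, lab, "lightness")
    expect_identical(mask(seg), labels == 2L)
    # seeded: the seed sits mostly in cluster 1
    sm <- matrix(FALSE, 8, 8); sm[3:6, 1:3] <- TRUE
    seg2 <- assignFibrosisCluster(labels, lab, "seeded", seedMask = sm)
    expect_identical(mask(seg2), labels == 1L)
    expect_error(assignFibrosisCluster(labels, lab, "seeded"),
        "requires a seed")
    # exact mean-L* tie: deterministic tie-break to the pixel (0,0) cluster
    tie <- array(0, dim = c(8, 8, 3)); tie[, , 1] <- 50
    seg3 <- assignFibrosisCluster(labels, LABImage(tie), "lightness")
    expect_identical(mask(seg3), labels == labels[1, 1])
    expect_error(assignFibrosisCluster(matrix(1L, 4, 4), lab),
        "exactly 2 clusters")
})
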