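# Shared fixtures: all images are generated in code at test time.

constImage <- function(w, h, rgb)
    RGBImage(array(rep(rgb, each = h * w), dim = c(h, w, 3)))

randImage <- function(w, h, seed = 1L) {
    set.seed(seed)
    RGBImage(array(sample(0:255, h * w * 3, replace = TRUE),
        dim = c(h, w, 3)))
}

# 1x1 image -> LAB triplet
labOf <- function(rgb) as.numeric(pixelData(srgbToLab(constImage(1, 1, rgb))))

# study-condition synthetic tiles (128 px; seeds fixed)
colorTileSpec <- function()
    syntheticSpec(width = 128, height = 128, rngSeed = 3L)

gratingTileSpec <- function(noiseSigma = 0)
    syntheticSpec(width = 128, height = 128, deltaEOffset = 0,
        textureHealthy = c(8, 0, 30), textureFibrosis = c(8, 90, 30),
        noiseSigma = noiseSigma, rngSeed = 7L)

# a small seed rectangle inside the fibrosis (right) half of a 128-px tile
fibrosisSeedMask <- function()
    rasterizeROI(seedRegion("rectangle", rbind(c(96, 56), c(108, 68))),
        128, 128)

# independent per-point crossing-number oracle (loop, not vectorized)
pointInPolygonOracle <- function(px, py, v) {
    n <- nrow(v)
    cn <- 0L
    for (i in seq_len(n)) {
        j <- i %% n + 1L
        if ((v[i, 2] <= py) != (v[j, 2] <= py)) {
            xi <- v[i, 1] + (py - v[i, 2]) * (v[j, 1] - v[i, 1]) /
                (v[j, 2] - v[i, 2])
            if (xi > px) cn <- cn + 1L
        }
    }
    cn %% 2L == 1L
}

# reference CIELAB values for 8-bit sRGB colors, frozen from an independent
# implementation of the CIE sRGB(D65) formulas
REFERENCE_LAB <- rbind(
    c(255,   0,   0,  53.2406,  80.0923,   67.2028),
    c(  0, 255,   0,  87.7351, -86.1830,   83.1797),
    c(  0,   0, 255,  32.2957,  79.1856, -107.8573),
    c(255, 255,   0,  97.1395, -21.5547,   94.4781),
    c(128,  64, 200,  41.8848,  53.5213,  -60.3550),
    c(200, 150, 160,  67.0000,  20.2497,    2.1001),
    c( 37, 211, 102,  74.7860, -64.8687,   42.0374),
    c( 10,  10,  10,   2.7417,  -0.0002,    0.0003))
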