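test_that("the ten-point rule is strict, symmetric and validated", {
    expect_true(isCorrect(24.72, 24.80))
    expect_false(isCorrect(38.02, 16.56))
    expect_true(isCorrect(0, 1.84))      # zero-manual specials, same rule
    expect_false(isCorrect(20, 30))      # boundary: strict inequality
    expect_true(isCorrect(20, 29.999))
    set.seed(5)
    a <- runif(20, 0, 100); b <- runif(20, 0, 100)
    expect_identical(isCorrect(a, b), isCorrect(b, a))
    expect_error(isCorrect(10, 10, threshold = 0), "positive")
    expect_error(isCorrect(10, 101), "\\[0, 100\\]")
})

test_that("the union combiner follows the any-method rule", {
    rec <- loadFixtures()
    ok <- combineMethods(rec)
    expect_true(ok[rec$image_id == 11])    # Gabor passes: |31.37-36.80| < 10
    expect_false(ok[rec$image_id == 1])    # diffs 21.46, 13.57, 22.54
    # any record with an exact match is correct
    r <- data.frame(manual_pct = 33, matlab_pct = 90, python_pct = 33,
        gabor_pct = 80)
    expect_true(combineMethods(r))
    # monotone: adding a passing method never flips correct -> incorrect
    base <- data.frame(manual_pct = 50, matlab_pct = 48, python_pct = 90,
        gabor_pct = 90)
    better <- transform(base, gabor_pct = 51)
    expect_true(combineMethods(base))
    expect_true(combineMethods(better))
    expect_error(combineMethods(data.frame(manual_pct = 1)), "columns")
    expect_error(combineMethods(transform(base, gabor_pct = NA)), "missing")
})

test_that("annotation pixel counting honors both color conventions", {
    expect_equal(countAnnotationPixels(constImage(7, 7, c(0, 0, 0)),
        "auto_black"), 0)
    p <- array(0, dim = c(10, 10, 3))
    p[1, 1:37 %% 10 + 1, ] <- 0  # keep black
    ys <- ((0:36) %% 10) + 1; xs <- ((0:36) %/% 10) + 1
    for (i in 1:37) { p[ys[i], xs[i], 1] <- 255; p[ys[i], xs[i], 2] <- 255 }
    img <- RGBImage(p)
    expect_equal(countAnnotationPixels(img, "manual_yellow"), 37)
    expect_equal(countAnnotationPixels(img, "auto_black"), 37)
    # near-yellow within the channel tolerance still counts
    p[10, 10, ] <- c(250, 246, 9)
    expect_equal(countAnnotationPixels(RGBImage(p), "manual_yellow"), 38)
})

test_that("method summaries reproduce the printed aggregates", {
    rec <- loadFixtures()
    gs <- summarizeMethod(rec, "gabor", "special")
    expect_equal(gs@meanPct, 54.93, tolerance = 0.001)
    expect_equal(gs@meanAccuracy, 45.07, tolerance = 0.001)
    pf <- summarizeMethod(rec, "python", "fibrosis")
    expect_equal(pf@meanAccuracy, 74.4602, tolerance = 0.05)
    # a method identical to manual scores perfectly under both formulas
    ideal <- data.frame(image_id = 1:4, group = "fibrosis",
        manual_pct = c(10, 20, 30, 40), matlab_pct = c(10, 20, 30, 40),
        python_pct = 0, gabor_pct = 0)
    ms <- summarizeMethod(ideal, "matlab", "fibrosis")
    expect_equal(ms@meanAccuracy, 100)
    expect_equal(ms@errorCount, 0L)
    expect_equal(ms@countAccuracy, 100)
    expect_error(summarizeMethod(rec[rec$group == "fibrosis", ], "gabor",
        "special"), "empty subset")
})

test_that("the full tables are reproduced from the packaged records", {
    tabs <- evaluationTables(loadFixtures())
    ef <- tabs$errors_fibrosis
    expect_identical(ef$errors[match(c("matlab", "python", "gabor", "system"),
        ef$method)], c(14L, 33L, 29L, 5L))
    expect_equal(ef$accuracy_pct[ef$method == "system"], 87.5)
    es <- tabs$errors_special
    expect_identical(es$errors[match(c("matlab", "python", "gabor", "system"),
        es$method)], c(4L, 4L, 5L, 4L))
    ea <- tabs$errors_all
    expect_identical(ea$errors[match(c("matlab", "python", "gabor", "system"),
        ea$method)], c(18L, 37L, 34L, 9L))
    expect_equal(ea$accuracy_pct[ea$method == "system"], 80)
    # image 43 is the only correctly handled special image
    rec <- loadFixtures()
    sp <- rec[rec$group == "special", ]
    expect_identical(sp$image_id[combineMethods(sp)], 43L)
    # mean-based tables against the printed values, within 0.05
    mf <- tabs$mean_fibrosis
    printedMean <- c(manual = 30.3786, python = 38.1372, matlab = 22.3701,
        gabor = 54.9730, system = 38.4934)
    printedAcc <- c(manual = 100, python = 74.4602, matlab = 73.6376,
        gabor = 19.04, system = 73.2875)
    for (m in names(printedMean)) {
        expect_equal(mf$mean_pct[mf$method == m], unname(printedMean[m]),
            tolerance = 0.05 / max(1, printedMean[m]))
        expect_equal(mf$accuracy_pct[mf$method == m], unname(printedAcc[m]),
            tolerance = 0.05 / max(1, printedAcc[m]))
    }
    ms <- tabs$mean_special
    printedMeanS <- c(manual = 0, python = 36.7962, matlab = 19.5464,
        gabor = 54.9322, system = 37.0916)
    printedAccS <- c(manual = 100, python = 63.2038, matlab = 80.4534,
        gabor = 45.0678, system = 62.9084)
    for (m in names(printedMeanS)) {
        expect_lt(abs(ms$mean_pct[ms$method == m] - printedMeanS[m]), 0.05)
        expect_lt(abs(ms$accuracy_pct[ms$method == m] - printedAccS[m]), 0.05)
    }
})

test_that("evaluation reports are written to disk", {
    d <- withr::local_tempdir()
    paths <- writeEvaluationReport(evaluationTables(loadFixtures()), d)
    expect_true(file.exists(file.path(d, "errors_all.csv")))
    expect_true(file.exists(file.path(d, "evaluation.json")))
    back <- read.csv(file.path(d, "errors_all.csv"))
    expect_equal(back$errors[back$method == "system"], 9)
})

test_that("the Dice coefficient behaves as an overlap score", {
    a <- matrix(FALSE, 10, 10); a[1:10] <- TRUE
    expect_equal(dice(a, a), 1)
    b <- matrix(FALSE, 10, 10); b[51:55] <- TRUE
    expect_equal(dice(a, b), 0)
    ov <- matrix(FALSE, 10, 10); ov[1:50] <- TRUE  # A 50 px inside B 100 px?
    A <- matrix(FALSE, 10, 10); A[1:100] <- TRUE
    expect_equal(dice(A, ov), 2 * 50 / 150)
    expect_equal(dice(matrix(FALSE, 3, 3), matrix(FALSE, 3, 3)), 1)
    expect_equal(dice(a, b), dice(b, a))
    expect_error(dice(a, matrix(FALSE, 9, 10)), "dimensions")
})
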