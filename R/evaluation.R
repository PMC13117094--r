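# The quantitative evaluation layer: annotation pixel counting, the
# ten-percentage-point correctness rule, the union combiner across methods,
# and the per-method aggregate tables.

#' Count annotated fibrosis pixels
#'
#' Two counting conventions are supported: \code{"auto_black"} — automatic
#' overlays keep the original color on fibrosis and set everything else to
#' black, so any pixel with a nonzero channel counts; \code{"manual_yellow"}
#' — manual annotation paints fibrosis pure yellow, so pixels within a
#' per-channel tolerance of 10 around (255, 255, 0) count.
#'
#' @param image an [RGBImage-class].
#' @param convention \code{"auto_black"} or \code{"manual_yellow"}.
#' @return integer pixel count.
#' @seealso [writeOverlayImage()]
#' @export
countAnnotationPixels <- function(image,
        convention = c("auto_black", "manual_yellow")) {
    stopifnot(is(image, "RGBImage"))
    convention <- match.arg(convention)
    px <- image@pixels
    if (convention == "auto_black") {
        sum(px[, , 1] > 0 | px[, , 2] > 0 | px[, , 3] > 0)
    } else {
        sum(abs(px[, , 1] - 255) <= 10 & abs(px[, , 2] - 255) <= 10 &
            px[, , 3] <= 10)
    }
}

#' Ten-point correctness rule
#'
#' An automatic identification is correct when the absolute difference
#' between the manual and automatic fibrosis percentages is strictly below
#' the threshold (10 percentage points by default). Vectorized and symmetric
#' in its two percentage arguments.
#'
#' @param manualPct,autoPct fibrosis percentages in \code{[0, 100]}.
#' @param threshold positive difference threshold, percentage points.
#' @return logical.
#' @examples
#' isCorrect(24.72, 24.80)  # TRUE
#' isCorrect(38.02, 16.56)  # FALSE
#' @export
isCorrect <- function(manualPct, autoPct, threshold = 10) {
    if (length(threshold) != 1L || is.na(threshold) || threshold <= 0)
        stop("threshold must be a positive number of percentage points")
    if (any(manualPct < 0 | manualPct > 100 | autoPct < 0 | autoPct > 100))
        stop("percentages must lie in [0, 100]")
    abs(manualPct - autoPct) < threshold
}

#' Union correctness across the three methods
#'
#' The combined system scores an image as correct when at least one of the
#' three per-method percentages passes [isCorrect()] against the manual one.
#' Adding a passing method can never flip a correct image to incorrect.
#'
#' @param records data.frame with columns \code{manual_pct},
#'   \code{matlab_pct}, \code{python_pct} and \code{gabor_pct} (one row per
#'   image; a single row works too).
#' @param threshold passed to [isCorrect()].
#' @return logical, one value per row.
#' @export
combineMethods <- function(records, threshold = 10) {
    need <- c("manual_pct", "matlab_pct", "python_pct", "gabor_pct")
    if (!all(need %in% names(records)))
        stop("records must carry columns ", paste(need, collapse = ", "))
    if (anyNA(records[, need]))
        stop("missing method percentage")
    isCorrect(records$manual_pct, records$matlab_pct, threshold) |
        isCorrect(records$manual_pct, records$python_pct, threshold) |
        isCorrect(records$manual_pct, records$gabor_pct, threshold)
}

.subsetRecords <- function(records, subset) {
    subset <- match.arg(subset, c("fibrosis", "special", "all"))
    out <- if (subset == "all") records
           else records[records$group == subset, , drop = FALSE]
    if (nrow(out) == 0L)
        stop("empty subset")
    out
}

.methodColumn <- function(method)
    c(manual = "manual_pct", matlab = "matlab_pct", python = "python_pct",
      gabor = "gabor_pct")[[method]]

#' Summarize one method over an image subset
#'
#' Computes, for a method over the chosen subset: the arithmetic mean
#' fibrosis percentage (for the combined \code{"system"}, the unweighted
#' mean of the three per-method means); the mean-based accuracy
#' \code{100 * (1 - |mean - mu_manual| / mu_manual)} when the manual mean is
#' positive, degenerating to \code{100 - mean} when the manual mean is zero
#' (the no-fibrosis subsets); and the count-based accuracy
#' \code{100 * correct / n} under the ten-point rule ([isCorrect()], or the
#' union rule [combineMethods()] for the system).
#'
#' @param records evaluation records, e.g. from [loadFixtures()].
#' @param method \code{"manual"}, \code{"matlab"}, \code{"python"},
#'   \code{"gabor"} or \code{"system"}.
#' @param subset \code{"fibrosis"}, \code{"special"} or \code{"all"}.
#' @param threshold correctness threshold in percentage points.
#' @return a [MethodSummary-class].
#' @examples
#' rec <- loadFixtures()
#' summarizeMethod(rec, "gabor", "special")
#' summarizeMethod(rec, "system", "fibrosis")
#' @export
summarizeMethod <- function(records,
        method = c("manual", "matlab", "python", "gabor", "system"),
        subset = c("fibrosis", "special", "all"), threshold = 10) {
    method <- match.arg(method)
    subset <- match.arg(subset)
    rec <- .subsetRecords(records, subset)
    n <- nrow(rec)
    muManual <- mean(rec$manual_pct)
    if (method == "system") {
        meanPct <- mean(c(mean(rec$matlab_pct), mean(rec$python_pct),
            mean(rec$gabor_pct)))
        ok <- combineMethods(rec, threshold)
    } else {
        meanPct <- mean(rec[[.methodColumn(method)]])
        ok <- if (method == "manual") rep(TRUE, n)
              else isCorrect(rec$manual_pct, rec[[.methodColumn(method)]],
                  threshold)
    }
    meanAcc <- if (method == "manual") 100
        else if (muManual > 0) 100 * (1 - abs(meanPct - muManual) / muManual)
        else 100 - meanPct
    new("MethodSummary", method = method, subset = subset,
        meanPct = meanPct, meanAccuracy = meanAcc,
        countAccuracy = 100 * sum(ok) / n, correctCount = sum(ok),
        errorCount = n - sum(ok), n = n)
}

#' Aggregate accuracy tables
#'
#' Builds the full evaluation-layer output from per-image records: mean-based
#' summaries (mean fibrosis percentage and relative accuracy) for the
#' fibrosis and special subsets, and count-based summaries (errors and
#' percentage of images passing the ten-point rule) for the fibrosis,
#' special, and combined subsets. Each table carries a \code{formula} column
#' naming the accuracy variant.
#'
#' @param records evaluation records, e.g. from [loadFixtures()].
#' @param threshold correctness threshold in percentage points.
#' @return named list of five \code{data.frame}s: \code{mean_fibrosis},
#'   \code{mean_special}, \code{errors_fibrosis}, \code{errors_special},
#'   \code{errors_all}.
#' @examples
#' tabs <- evaluationTables(loadFixtures())
#' tabs$errors_fibrosis
#' @export
evaluationTables <- function(records, threshold = 10) {
    methods <- c("manual", "python", "matlab", "gabor", "system")
    meanTab <- function(subset) {
        rows <- lapply(methods, summarizeMethod, records = records,
            subset = subset, threshold = threshold)
        data.frame(method = methods,
            mean_pct = vapply(rows, function(s) s@meanPct, 0),
            accuracy_pct = vapply(rows, function(s) s@meanAccuracy, 0),
            formula = "mean-based: 100*(1-|mean-mu_manual|/mu_manual), or 100-mean when mu_manual=0")
    }
    errTab <- function(subset) {
        rows <- lapply(methods, summarizeMethod, records = records,
            subset = subset, threshold = threshold)
        data.frame(method = methods,
            errors = vapply(rows, function(s) s@errorCount, 0L),
            accuracy_pct = vapply(rows, function(s) s@countAccuracy, 0),
            formula = "count-based: 100*correct/n under the ten-point rule")
    }
    list(mean_fibrosis = meanTab("fibrosis"),
         mean_special = meanTab("special"),
         errors_fibrosis = errTab("fibrosis"),
         errors_special = errTab("special"),
         errors_all = errTab("all"))
}

#' Write the evaluation tables to disk
#'
#' One CSV per table plus a single JSON mirror.
#'
#' @param tables list from [evaluationTables()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeEvaluationReport <- function(tables, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- character(0)
    for (nm in names(tables)) {
        p <- file.path(dir, paste0(nm, ".csv"))
        utils::write.csv(tables[[nm]], p, row.names = FALSE)
        paths <- c(paths, p)
    }
    jp <- file.path(dir, "evaluation.json")
    jsonlite::write_json(tables, jp, dataframe = "rows", auto_unbox = TRUE,
        digits = NA)
    invisible(c(paths, jp))
}

#' Dice overlap coefficient
#'
#' \code{2|A n B| / (|A| + |B|)} between two binary masks of equal
#' dimensions; defined as 1 when both masks are empty.
#'
#' @param maskA,maskB logical (or 0/1) matrices.
#' @return scalar in \code{[0, 1]}.
#' @examples
#' a <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2)
#' dice(a, a)  # 1
#' @export
dice <- function(maskA, maskB) {
    if (!identical(dim(maskA), dim(maskB)))
        stop("mask dimensions differ")
    a <- as.logical(maskA); b <- as.logical(maskB)
    denom <- sum(a) + sum(b)
    if (denom == 0) return(1)
    2 * sum(a & b) / denom
}
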