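#' @include AllClasses.R utils.R
NULL

#' Arcsinh transformation for raw cytometry intensities
#'
#' Elementwise `asinh(x / cofactor)`; cofactor 5 is the mass-cytometry
#' convention.
#'
#' @param raw numeric matrix (or vector) of nonnegative raw intensities.
#' @param cofactor positive scale divisor.
#' @return transformed object of the same shape.
#' @examples
#' arcsinhTransform(5)          # log(1 + sqrt(2)) = 0.8814
#' @export
arcsinhTransform <- function(raw, cofactor = 5) {
    stopIfNot(is.numeric(cofactor) && length(cofactor) == 1L && cofactor > 0,
              "cofactor must be a positive scalar")
    asinh(raw / cofactor)
}

#' Automated CD45+ gate
#'
#' Stand-in for manual live/singlet/CD45+ gating: retains cells whose
#' arcsinh CD45 intensity is at least `threshold`.
#'
#' @param study a [CytoStudy-class] with per-cell data.
#' @param threshold arcsinh CD45 cutoff (default 1).
#' @return the gated [CytoStudy-class]; per-sample retained counts are
#'   reported in `sampleData(x)$n_cells_gated`.
#' @export
gateCD45 <- function(study, threshold = 1.0) {
    stopIfNot(!is.null(study@exprs), "study has no per-cell data")
    stopIfNot("CD45" %in% colnames(study@exprs), "CD45 is not in the panel")
    keep <- study@exprs[, "CD45"] >= threshold
    out <- study
    out@exprs <- study@exprs[keep, , drop = FALSE]
    out@cellData <- study@cellData[keep, , drop = FALSE]
    kept <- table(factor(out@cellData$sample_id,
                         levels = study@samples$sample_id))
    out@samples$n_cells_gated <- as.integer(kept)
    out
}

#' Build a per-sample subset frequency matrix from cell labels
#'
#' Counts labelled cells per sample and subset and converts to percentages.
#' Under `total_CD45` the denominator is all labelled cells of the sample;
#' under `lineage` it is the labelled cells of each subset's lineage.
#' Rejected/unlabelled cells (`NA` label) are excluded from numerator and
#' denominator. Samples with an empty denominator are dropped with a
#' warning.
#'
#' @param labels per-cell subset labels (character; `NA` = rejected), or a
#'   [SubsetLabeling-class].
#' @param sampleIds per-cell sample assignment (same length as the labels).
#' @param sampleData optional per-sample metadata `DFrame`/`data.frame` with
#'   a `sample_id` column; carried into the result's `colData`.
#' @param mode denominator mode.
#' @param hierarchy named character mapping subset id to lineage; required
#'   for `mode = "lineage"` unless `labels` is a [SubsetLabeling-class].
#' @param subsetLevels optional subset id universe fixing the column set and
#'   order (absent subsets get 0).
#' @return a [FrequencyMatrix-class].
#' @examples
#' computeFrequencies(c("a", "a", "b"), rep("s1", 3))
#' @export
computeFrequencies <- function(labels, sampleIds, sampleData = NULL,
                               mode = c("total_CD45", "lineage"),
                               hierarchy = NULL, subsetLevels = NULL) {
    mode <- match.arg(mode)
    if (is(labels, "SubsetLabeling")) {
        if (is.null(hierarchy)) hierarchy <- labels@hierarchy
        labels <- labels@subset
    }
    stopIfNot(length(labels) == length(sampleIds),
              "labels and sampleIds must have the same length")
    if (mode == "lineage")
        stopIfNot(!is.null(hierarchy),
                  "lineage mode needs a subset -> lineage hierarchy")
    keep <- !is.na(labels)
    labels <- labels[keep]
    sampleIds <- sampleIds[keep]
    if (is.null(subsetLevels)) subsetLevels <- sort(unique(labels))
    sLev <- unique(sampleIds)
    counts <- table(factor(sampleIds, levels = sLev),
                    factor(labels, levels = subsetLevels))
    counts <- matrix(as.integer(counts), nrow(counts), ncol(counts),
                     dimnames = dimnames(counts))
    if (mode == "total_CD45") {
        den <- rowSums(counts)
        empty <- den == 0
        if (any(empty)) {
            warning("dropping ", sum(empty), " sample(s) with empty denominator")
            counts <- counts[!empty, , drop = FALSE]
            den <- den[!empty]
        }
        f <- 100 * counts / den
    } else {
        lin <- hierarchy[subsetLevels]
        f <- matrix(0, nrow(counts), ncol(counts), dimnames = dimnames(counts))
        for (lv in unique(lin)) {
            cols <- which(lin == lv)
            den <- rowSums(counts[, cols, drop = FALSE])
            ratio <- 100 * counts[, cols, drop = FALSE] / den
            ratio[den == 0, ] <- 0
            f[, cols] <- ratio
        }
        empty <- rowSums(counts) == 0
        if (any(empty)) {
            warning("dropping ", sum(empty), " sample(s) with empty denominator")
            f <- f[!empty, , drop = FALSE]
        }
    }
    sdf <- if (is.null(sampleData))
        S4Vectors::DataFrame(sample_id = rownames(f))
    else S4Vectors::DataFrame(sampleData)
    .FrequencyMatrix(f, sdf, mode)
}

#' Standard pre-processing of frequency matrices
#'
#' Applies, in order, the requested steps: `arcsine_sqrt` maps a percentage
#' p to `asin(sqrt(p / 100))` (variance stabilisation for proportions);
#' `zscore_columns` standardises each subset column to mean 0, sd 1
#' (constant columns become all zeros). Used before sample-level t-SNE/PCA;
#' Spearman correlations are rank-invariant to the arcsine-sqrt map, so the
#' network stage may equally use raw percentages.
#'
#' @param freq a [FrequencyMatrix-class] or a samples-x-subsets percentage
#'   matrix.
#' @param steps character subset of `c("arcsine_sqrt", "zscore_columns")`.
#' @return a numeric samples-x-subsets matrix.
#' @examples
#' preprocessFrequencies(matrix(c(0, 25, 100), 3, 1), steps = "arcsine_sqrt")
#' @export
preprocessFrequencies <- function(freq,
                                  steps = c("arcsine_sqrt", "zscore_columns")) {
    steps <- match.arg(steps, several.ok = TRUE)
    x <- if (is(freq, "FrequencyMatrix")) freqValues(freq) else as.matrix(freq)
    stopIfNot(all(x >= -1e-9 & x <= 100 + 1e-6),
              "frequencies must be percentages in [0, 100]")
    if ("arcsine_sqrt" %in% steps)
        x <- asin(sqrt(pmin(pmax(x / 100, 0), 1)))
    if ("zscore_columns" %in% steps) {
        mu <- colMeans(x)
        s <- apply(x, 2L, sd)
        x <- sweep(x, 2L, mu)
        x <- sweep(x, 2L, ifelse(s > 0, s, 1), "/")
    }
    x
}
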