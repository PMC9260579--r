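#' @include AllClasses.R ingest.R
NULL

#' Fit a linear discriminant model over cell marker vectors
#'
#' Homoscedastic Gaussian classifier: per-class mean vectors, one pooled
#' within-class covariance (class scatter summed and divided by `N - K`)
#' ridge-regularised by `epsReg` on the diagonal, and class priors equal to
#' the class proportions.
#'
#' @param cells a [CytoStudy-class] or cells-x-markers matrix.
#' @param labels per-cell class (subset) labels or a
#'   [SubsetLabeling-class].
#' @param epsReg diagonal ridge; default `1e-6 * mean(diag(Sigma))`.
#' @return an [LDAModel-class].
#' @export
fitLDA <- function(cells, labels, epsReg = NULL) {
    if (is(cells, "CytoStudy")) cells <- cells@exprs
    if (is(labels, "SubsetLabeling")) labels <- labels@subset
    keep <- !is.na(labels)
    x <- cells[keep, , drop = FALSE]
    labels <- labels[keep]
    classes <- sort(unique(labels))
    K <- length(classes)
    d <- ncol(x)
    stopIfNot(K >= 2L, "need at least 2 classes")
    ns <- table(factor(labels, levels = classes))
    stopIfNot(all(ns >= d + 1L),
              "every class needs at least n_markers + 1 cells")
    means <- matrix(NA_real_, K, d, dimnames = list(classes, colnames(x)))
    scatter <- matrix(0, d, d)
    for (k in seq_len(K)) {
        xi <- x[labels == classes[k], , drop = FALSE]
        means[k, ] <- colMeans(xi)
        xc <- sweep(xi, 2L, means[k, ])
        scatter <- scatter + crossprod(xc)
    }
    sigma <- scatter / (nrow(x) - K)
    if (is.null(epsReg)) epsReg <- 1e-6 * mean(diag(sigma))
    sigma <- sigma + diag(epsReg, d)
    ev <- min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values)
    stopIfNot(ev > 0, "pooled covariance singular even after regularisation")
    new("LDAModel", classes = classes, means = means, sigma = sigma,
        priors = as.numeric(ns) / nrow(x), epsReg = epsReg,
        markers = colnames(x))
}

## log posterior matrix (cells x classes), normalised by log-sum-exp
.ldaLogPosterior <- function(model, x) {
    ch <- chol(model@sigma)
    W <- backsolve(ch, forwardsolve(t(ch), t(model@means)))  # Sigma^-1 M'
    lin <- x %*% W  # x' Sigma^-1 mu_k
    quad <- colSums(t(model@means) * W) / 2  # mu_k' Sigma^-1 mu_k / 2
    disc <- sweep(lin, 2L, quad) +
        matrix(log(model@priors), nrow(x), length(model@priors), byrow = TRUE)
    disc - logSumExp(disc)
}

#' Predict classes with a posterior-probability rejection option
#'
#' Posteriors `p(k | x)` are proportional to
#' `pi_k exp(-(x - mu_k)' Sigma^-1 (x - mu_k) / 2)` and computed in log
#' space with log-sum-exp. A cell is assigned to its maximum-posterior
#' class when that posterior is at least `tau - 1e-6` and rejected
#' otherwise (so `tau = 1` means posterior `>= 0.999999`). Optionally,
#' cells whose Mahalanobis distance to the assigned class exceeds the
#' `outlierCut` chi-squared quantile are flagged as phenotype outliers.
#'
#' @param model an [LDAModel-class].
#' @param cells a [CytoStudy-class] or cells-x-markers matrix (columns must
#'   cover the model's markers).
#' @param tau rejection threshold in (0, 1].
#' @param outlierCut optional chi-squared probability (e.g. 0.999) for the
#'   Mahalanobis novelty flag; `NULL` disables it.
#' @return a [TransferResult-class]; when `cells` is a study, the result
#'   also carries the predicted per-sample [FrequencyMatrix-class] with all
#'   cells (accepted + rejected) as denominator.
#' @export
predictWithRejection <- function(model, cells, tau = 0.95,
                                 outlierCut = NULL) {
    stopIfNot(tau > 0 && tau <= 1, "tau must be in (0, 1]")
    study <- NULL
    if (is(cells, "CytoStudy")) { study <- cells; cells <- cells@exprs }
    stopIfNot(all(model@markers %in% colnames(cells)),
              "cells lack markers the model was trained on")
    x <- cells[, model@markers, drop = FALSE]
    lp <- .ldaLogPosterior(model, x)
    best <- max.col(lp, ties.method = "first")
    post <- exp(lp[cbind(seq_len(nrow(lp)), best)])
    rejected <- post < tau - 1e-6
    predicted <- ifelse(rejected, NA_character_, model@classes[best])
    outlier <- NULL
    if (!is.null(outlierCut)) {
        ch <- chol(model@sigma)
        dev <- x - model@means[best, , drop = FALSE]
        md2 <- colSums(forwardsolve(t(ch), t(dev))^2)
        outlier <- md2 > stats::qchisq(outlierCut, df = ncol(x))
    }
    freq <- NULL
    if (!is.null(study)) {
        den <- table(factor(study@cellData$sample_id,
                            levels = study@samples$sample_id))
        keepS <- as.numeric(den) > 0  # samples without cells carry no info
        lev <- study@samples$sample_id[keepS]
        tab <- table(factor(study@cellData$sample_id, levels = lev),
                     factor(predicted, levels = model@classes))
        f <- 100 * matrix(as.numeric(tab), nrow(tab), ncol(tab),
                          dimnames = dimnames(tab)) /
            as.numeric(den[keepS])
        se <- SummarizedExperiment::SummarizedExperiment(
            assays = list(freq = t(f)),
            colData = study@samples[keepS, , drop = FALSE],
            metadata = list(
                mode = "total_CD45", denominator = "all_cells",
                note = paste("columns need not sum to 100: rejected cells",
                             "stay in the denominator")))
        freq <- new("FrequencyMatrix", se)
    }
    new("TransferResult", predicted = predicted, posterior = post,
        tau = tau, rejected = rejected, outlier = outlier, freq = freq,
        matchedFraction = 100 * mean(!rejected))
}

#' Concordance of true and predicted frequency matrices
#'
#' Pearson correlation of the paired (sample, subset) percentage entries,
#' pooled over the whole matrix (`by = "all"`) or per subset.
#'
#' @param trueFreq,predFreq [FrequencyMatrix-class] objects (or matrices)
#'   sharing samples and subsets.
#' @param by `"all"` (flattened, default) or `"subset"`.
#' @return a single Pearson R, or a named vector per subset.
#' @export
frequencyConcordance <- function(trueFreq, predFreq, by = c("all", "subset")) {
    by <- match.arg(by)
    a <- if (is(trueFreq, "FrequencyMatrix")) freqValues(trueFreq)
         else as.matrix(trueFreq)
    b <- if (is(predFreq, "FrequencyMatrix")) freqValues(predFreq)
         else as.matrix(predFreq)
    sh <- intersect(rownames(a), rownames(b))
    cols <- intersect(colnames(a), colnames(b))
    stopIfNot(length(sh) >= 2L && length(cols) >= 1L,
              "matrices must share samples and subsets")
    a <- a[sh, cols, drop = FALSE]
    b <- b[sh, cols, drop = FALSE]
    if (by == "all") {
        stopIfNot(sd(a) > 0 && sd(b) > 0, "zero variance input")
        return(cor(as.vector(a), as.vector(b)))
    }
    vapply(cols, function(k) cor(a[, k], b[, k]), 0)
}

#' Match blood cells to intestinal subset phenotypes
#'
#' Applies an intestinally trained LDA model to blood cells under the
#' rejection option and summarises the matched fraction overall, per
#' intestinal subset, and per blood sample (as % of all blood CD45+ cells).
#'
#' @param model an [LDAModel-class] trained on intestinal cells.
#' @param blood a [CytoStudy-class] of blood samples (or one restricted to
#'   blood via its metadata).
#' @param tau rejection threshold (the study design uses 1 and 0.95).
#' @param outlierCut optional Mahalanobis novelty cut, see
#'   [predictWithRejection()].
#' @return list with `result` (the [TransferResult-class]),
#'   `matched_fraction` (%), `per_subset` (% of blood cells matched to each
#'   intestinal subset) and `per_sample` (the predicted
#'   [FrequencyMatrix-class]).
#' @export
matchBloodToTissue <- function(model, blood, tau = 0.95, outlierCut = NULL) {
    if (is(blood, "CytoStudy") && "tissue" %in% colnames(blood@samples) &&
        any(blood@samples$tissue != "blood")) {
        keepS <- blood@samples$tissue == "blood"
        keepC <- blood@cellData$sample_id %in%
            blood@samples$sample_id[keepS]
        blood <- new("CytoStudy", exprs = blood@exprs[keepC, , drop = FALSE],
                     cellData = blood@cellData[keepC, , drop = FALSE],
                     samples = blood@samples[keepS, , drop = FALSE],
                     panel = blood@panel, truth = list())
    }
    res <- predictWithRejection(model, blood, tau = tau,
                                outlierCut = outlierCut)
    perSubset <- 100 * table(factor(res@predicted, levels = model@classes)) /
        length(res@predicted)
    list(result = res, matched_fraction = res@matchedFraction,
         per_subset = perSubset, per_sample = res@freq)
}
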