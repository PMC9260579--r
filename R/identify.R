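#' @include AllClasses.R panel.R utils.R
#' @import mclust
#' @importFrom stats kmeans
NULL

#' Assign cells to major immune lineages by signature scoring
#'
#' Each cell is scored against every lineage signature (mean of the
#' signature's `high` markers minus mean of its `low` markers) and assigned
#' to the lineage with the maximal score; exact ties go to the earlier
#' lineage in the panel's signature order.
#'
#' @param cells a [CytoStudy-class] or a cells-x-markers arcsinh matrix.
#' @param panel a [MarkerPanel-class] providing the signatures (defaults to
#'   the study's own panel).
#' @return character vector of per-cell lineage assignments.
#' @export
assignLineages <- function(cells, panel = NULL) {
    if (is(cells, "CytoStudy")) {
        if (is.null(panel)) panel <- cells@panel
        cells <- cells@exprs
    }
    stopIfNot(!is.null(panel) && length(panel@signatures) > 0,
              "panel must provide lineage signatures")
    miss <- setdiff(unlist(lapply(panel@signatures, unlist)), colnames(cells))
    stopIfNot(length(miss) == 0L,
              paste("missing signature markers:", paste(miss, collapse = ", ")))
    scores <- lineageScores(cells, panel)
    names(panel@signatures)[max.col(scores, ties.method = "first")]
}

#' Per-cell lineage signature scores
#'
#' The score matrix behind [assignLineages()]: one column per lineage, each
#' the mean of that signature's `high` markers minus the mean of its `low`
#' markers. The margin between the best and second-best score measures how
#' unambiguous a cell's lineage call is.
#'
#' @inheritParams assignLineages
#' @return numeric matrix (cells x lineages).
#' @export
lineageScores <- function(cells, panel = NULL) {
    if (is(cells, "CytoStudy")) {
        if (is.null(panel)) panel <- cells@panel
        cells <- cells@exprs
    }
    vapply(panel@signatures, function(sig) {
        hi <- rowMeans(cells[, sig$high, drop = FALSE])
        lo <- if (length(sig$low))
            rowMeans(cells[, sig$low, drop = FALSE]) else 0
        hi - lo
    }, numeric(nrow(cells)))
}

## EM prediction for all cells from a fitted mixture
.gmmPredict <- function(fit, x) {
    if (fit$G == 1L) return(rep(1L, nrow(x)))
    es <- mclust::estep(modelName = fit$modelName, data = x,
                        parameters = fit$parameters)
    max.col(es$z, ties.method = "first")
}

## single-component model name for the G = 1 case
.mvnModel <- function(modelNames) {
    switch(substr(modelNames, 3L, 3L), I = if (substr(modelNames, 2L, 2L)
           == "I") "XII" else "XXI", "XXX")
}

## Fit one Gaussian mixture at fixed g: EM started from a multi-restart
## kmeans partition and, when supplied, from a warm-start partition; the
## better log-likelihood wins.
.gmmFit <- function(xf, g, modelNames, zInit = NULL) {
    n <- nrow(xf)
    d <- ncol(xf)
    if (g == 1L) {
        fit <- mclust::mvn(modelName = .mvnModel(modelNames), data = xf)
        ll <- fit$loglik
        params <- fit$parameters
    } else {
        km <- stats::kmeans(xf, centers = g, nstart = 25L, iter.max = 200L)
        fit <- mclust::me(modelName = modelNames, data = xf,
                          z = mclust::unmap(km$cluster,
                                            groups = seq_len(g)))
        ll <- fit$loglik
        if (!is.null(zInit)) {
            alt <- tryCatch(mclust::me(modelName = modelNames, data = xf,
                                       z = zInit),
                            error = function(e) NULL)
            if (!is.null(alt) && is.finite(alt$loglik) &&
                (!is.finite(ll) || alt$loglik > ll)) {
                fit <- alt
                ll <- alt$loglik
            }
        }
        params <- fit$parameters
    }
    if (is.null(ll) || !is.finite(ll)) return(NULL)
    m <- mclust::nMclustParams(modelNames, d = d, G = g)
    list(G = g, modelName = modelNames, parameters = params, loglik = ll,
         bic = 2 * ll - m * log(n), n = n, d = d)
}

## restrict a fitted mixture to a subset of its components
.dropComponents <- function(fit, keep) {
    p <- fit$parameters
    p$pro <- p$pro[keep] / sum(p$pro[keep])
    p$mean <- p$mean[, keep, drop = FALSE]
    if (!is.null(p$variance$sigma))
        p$variance$sigma <- p$variance$sigma[, , keep, drop = FALSE]
    if (!is.null(p$variance$sigmasq) && length(p$variance$sigmasq) > 1L)
        p$variance$sigmasq <- p$variance$sigmasq[keep]
    if (!is.null(p$variance$scale) && length(p$variance$scale) > 1L)
        p$variance$scale <- p$variance$scale[keep]
    if (!is.null(p$variance$shape) && is.matrix(p$variance$shape))
        p$variance$shape <- p$variance$shape[, keep, drop = FALSE]
    p$variance$G <- length(keep)
    fit$parameters <- p
    fit$G <- length(keep)
    fit
}

## warm start for g + 1 components: split the widest component of the
## previous fit in two (2-means on its cells)
.splitInit <- function(xf, prev) {
    cls <- .gmmPredict(prev, xf)
    wss <- vapply(seq_len(prev$G), function(j) {
        xi <- xf[cls == j, , drop = FALSE]
        if (nrow(xi) < 20L) return(-Inf)
        sum(apply(xi, 2L, stats::var)) * nrow(xi)
    }, 0)
    j <- which.max(wss)
    if (!is.finite(wss[j])) return(NULL)
    idx <- which(cls == j)
    km <- stats::kmeans(xf[idx, , drop = FALSE], centers = 2L,
                        nstart = 10L, iter.max = 100L)
    out <- cls
    out[idx[km$cluster == 2L]] <- prev$G + 1L
    mclust::unmap(out, groups = seq_len(prev$G + 1L))
}

## BIC scan over candidate component numbers: warm-start chain plus fresh
## kmeans initialisations, early stopping on consecutive BIC declines
.gmmScan <- function(xf, kr, modelNames, earlyStop) {
    best <- NULL
    prev <- NULL
    declines <- 0L
    for (g in kr) {
        zInit <- if (!is.null(prev) && prev$G == g - 1L)
            tryCatch(.splitInit(xf, prev), error = function(e) NULL)
        fg <- tryCatch(.gmmFit(xf, g, modelNames, zInit),
                       error = function(e) NULL)
        if (is.null(fg)) next
        prev <- fg
        if (is.null(best) || fg$bic > best$bic) {
            best <- fg
            declines <- 0L
        } else declines <- declines + 1L
        if (declines >= earlyStop) break
    }
    best
}

#' Cluster cells into subsets within each lineage
#'
#' The second level of the two-level subset identification stage: within
#' each lineage, Gaussian mixture models are fitted over a range of
#' component numbers and the number of subsets is selected by maximum BIC
#' (`2 loglik - m log n`, larger is better). Each candidate fit is
#' initialised from a multi-restart kmeans partition and refined by EM
#' under the requested mclust covariance family. To keep the fit
#' tractable, mixtures are estimated on a random subsample of at most
#' `maxFitCells` cells per lineage (deterministic given `seed`), the scan
#' stops early once BIC has declined for `earlyStop` consecutive k, and
#' all cells are then assigned to their maximum-responsibility component.
#' Subset ids are `<lineage>_<k>` with components numbered by decreasing
#' size. Lineages with fewer than `10 * max(kRange)` cells are clustered
#' over a reduced range with a warning.
#'
#' @param cells a [CytoStudy-class] or cells-x-markers matrix.
#' @param lineages per-cell lineage labels from [assignLineages()].
#' @param kRange integer candidate numbers of components (within 1..40).
#' @param modelNames mclust covariance family; `"VVI"` (diagonal, varying
#'   volume and shape) by default.
#' @param maxFitCells per-lineage subsample size for mixture fitting.
#' @param seed RNG seed for subsampling and initialisation.
#' @param nInit number of additional random-subsample restarts per lineage
#'   (extra starts refit on fresh subsamples and keep the best
#'   per-observation log-likelihood; each fit already uses 10 kmeans
#'   restarts internally).
#' @param earlyStop stop the BIC scan after this many consecutive declines
#'   (`Inf` scans the whole range).
#' @param fitEligible optional logical per cell: only eligible cells enter
#'   the fitting subsample (all cells are still assigned). Used to keep
#'   lineage-ambiguous stragglers from seeding spurious components.
#' @param minClusterCells components attracting fewer cells than this on
#'   the full data (capped at 5 percent of the lineage) are dropped and
#'   their cells reassigned.
#' @return a [SubsetLabeling-class].
#' @export
clusterWithinLineage <- function(cells, lineages, kRange = 1:12,
                                 modelNames = "VVI", maxFitCells = 2000L,
                                 seed = 42L, nInit = 1L, earlyStop = 3L,
                                 fitEligible = NULL,
                                 minClusterCells = 30L) {
    if (is(cells, "CytoStudy")) cells <- cells@exprs
    stopIfNot(nrow(cells) == length(lineages),
              "one lineage label per cell required")
    kRange <- sort(unique(as.integer(kRange)))
    stopIfNot(all(kRange >= 1L & kRange <= 40L), "kRange must lie in [1, 40]")

    subset <- character(nrow(cells))
    fits <- list()
    withPrivateSeed(seed, {
        for (lv in unique(lineages)) {
            idx <- which(lineages == lv)
            x <- cells[idx, , drop = FALSE]
            elig <- if (is.null(fitEligible)) seq_len(nrow(x))
                    else which(fitEligible[idx])
            if (!length(elig)) elig <- seq_len(nrow(x))
            kr <- kRange
            if (length(idx) < 10L * max(kRange)) {
                kr <- kr[kr <= max(1L, length(idx) %/% 10L)]
                if (!length(kr)) kr <- 1L
                warning("lineage ", lv, " has few cells (", length(idx),
                        "); reduced k range to ", max(kr))
            }
            fitIdx <- if (length(elig) > maxFitCells)
                sample(elig, maxFitCells) else elig
            xf <- x[fitIdx, , drop = FALSE]
            fit <- .gmmScan(xf, kr, modelNames, earlyStop)
            if (nInit > 1L && length(elig) > maxFitCells) {
                for (r in seq_len(nInit - 1L)) {
                    xr <- x[sample(elig, maxFitCells), , drop = FALSE]
                    alt <- .gmmScan(xr, kr, modelNames, earlyStop)
                    if (!is.null(alt) && !is.null(fit) &&
                        alt$loglik / nrow(xr) > fit$loglik / nrow(xf)) {
                        fit <- alt; xf <- xr
                    }
                }
            }
            stopIfNot(!is.null(fit), paste("mixture fit failed for", lv))
            cl <- .gmmPredict(fit, x)
            ## drop components that attract almost no cells on the full
            ## data (subsample artifacts) and reassign their members
            floorCells <- min(minClusterCells,
                              max(1L, length(idx) %/% 20L))
            repeat {
                sizes <- tabulate(cl, nbins = fit$G)
                small <- which(sizes > 0L & sizes < floorCells)
                if (!length(small) || fit$G - length(small) < 1L) break
                keep <- setdiff(seq_len(fit$G), small)
                fit <- .dropComponents(fit, keep)
                cl <- .gmmPredict(fit, x)
            }
            ## renumber components by decreasing size
            sizes <- tabulate(cl, nbins = fit$G)
            ord <- order(sizes, decreasing = TRUE)
            remap <- integer(fit$G)
            remap[ord] <- seq_len(fit$G)
            subset[idx] <- paste0(lv, "_", remap[cl])
            fits[[lv]] <- list(G = fit$G, bic = fit$bic,
                               model = fit$modelName)
        }
    })
    hier <- unlist(lapply(names(fits), function(lv)
        setNames(rep(lv, fits[[lv]]$G), paste0(lv, "_", seq_len(fits[[lv]]$G)))))
    new("SubsetLabeling", lineage = lineages, subset = subset,
        hierarchy = hier, fits = fits)
}

#' Two-level subset identification
#'
#' Convenience wrapper running [assignLineages()] then
#' [clusterWithinLineage()] on a study's cells. Cells whose lineage call is
#' ambiguous (best-vs-second signature score margin below `fitMargin`
#' arcsinh units) are kept out of the mixture-fitting subsamples so that
#' cross-lineage stragglers cannot seed spurious components; every cell is
#' still assigned to a subset.
#'
#' @inheritParams clusterWithinLineage
#' @param study a [CytoStudy-class] with per-cell data.
#' @param fitMargin minimum lineage score margin for a cell to enter the
#'   fitting subsample.
#' @param ... passed to [clusterWithinLineage()].
#' @return a [SubsetLabeling-class].
#' @export
identifySubsets <- function(study, kRange = 1:12, fitMargin = 0.5, ...) {
    sc <- lineageScores(study)
    lin <- colnames(sc)[max.col(sc, ties.method = "first")]
    top2 <- apply(sc, 1L, function(v) -diff(sort(v, decreasing = TRUE)[1:2]))
    clusterWithinLineage(study, lin, kRange = kRange,
                         fitEligible = top2 >= fitMargin, ...)
}

#' Median marker phenotype of each subset
#'
#' @param cells a [CytoStudy-class] or cells-x-markers matrix.
#' @param labeling a [SubsetLabeling-class] or per-cell subset labels.
#' @return list with `medians` (subsets x markers matrix of per-subset
#'   median arcsinh expression) and `counts` (per-subset cell counts).
#'   Empty subsets give a row of `NaN` (with a warning).
#' @export
profileSubsets <- function(cells, labeling) {
    if (is(cells, "CytoStudy")) cells <- cells@exprs
    labels <- if (is(labeling, "SubsetLabeling")) labeling@subset else labeling
    stopIfNot(nrow(cells) == length(labels), "labeling must cover the cells")
    lev <- if (is(labeling, "SubsetLabeling")) names(labeling@hierarchy)
           else if (is.factor(labels)) levels(labels)
           else sort(unique(labels[!is.na(labels)]))
    med <- matrix(NaN, length(lev), ncol(cells),
                  dimnames = list(lev, colnames(cells)))
    counts <- setNames(integer(length(lev)), lev)
    for (i in seq_along(lev)) {
        idx <- which(labels == lev[i])
        counts[i] <- length(idx)
        if (length(idx))
            med[i, ] <- apply(cells[idx, , drop = FALSE], 2L, median)
    }
    if (any(counts == 0L))
        warning("empty subset(s): ",
                paste(lev[counts == 0L], collapse = ", "))
    list(medians = med, counts = counts)
}

#' Match recovered subsets to ground truth
#'
#' Solves the maximal-overlap assignment between recovered and true subset
#' labels (Hungarian algorithm on the contingency table) and reports the
#' adjusted Rand index of the two partitions.
#'
#' @param labeling a [SubsetLabeling-class] or per-cell recovered labels.
#' @param truthLabels per-cell true subset labels (same cells, same order).
#' @return list with `mapping` (named character: recovered id -> matched
#'   true id under the one-to-one assignment; only mutually matched pairs),
#'   `majority` (named character: recovered id -> its maximum-overlap true
#'   id, many-to-one, defined for every recovered id), `overlap` (the
#'   contingency table) and `ari`.
#' @export
matchToTruth <- function(labeling, truthLabels) {
    rec <- if (is(labeling, "SubsetLabeling")) labeling@subset else labeling
    stopIfNot(length(rec) == length(truthLabels),
              "labelings must cover the same cells")
    tab <- table(rec, truthLabels)
    n <- max(dim(tab))
    ## pad to square for the assignment solver
    m <- matrix(0L, n, n)
    m[seq_len(nrow(tab)), seq_len(ncol(tab))] <- tab
    sol <- clue::solve_LSAP(max(m) - m)  # minimise cost = maximise overlap
    mapping <- character(0)
    for (i in seq_len(nrow(tab))) {
        j <- sol[i]
        if (j <= ncol(tab) && tab[i, j] > 0)
            mapping[rownames(tab)[i]] <- colnames(tab)[j]
    }
    majority <- setNames(colnames(tab)[max.col(tab, ties.method = "first")],
                         rownames(tab))
    list(mapping = mapping, majority = majority, overlap = tab,
         ari = mclust::adjustedRandIndex(rec, truthLabels))
}
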