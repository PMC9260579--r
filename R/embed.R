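#' @include AllClasses.R utils.R
NULL

#' Sample-level t-SNE embedding
#'
#' 2-D t-SNE of preprocessed per-sample frequency profiles (every dot a
#' sample). Exact (theta = 0) t-SNE is used: sample-level inputs are small.
#' Coordinates are centred; a fixed seed makes the embedding reproducible.
#'
#' @param x numeric samples-x-features matrix (typically
#'   [preprocessFrequencies()] output).
#' @param seed RNG seed.
#' @param perplexity t-SNE perplexity; must be below `(n - 1) / 3`.
#' @param ... further arguments to [Rtsne::Rtsne()].
#' @return an [EmbeddingResult-class].
#' @details The embedding is initialised from the first two principal
#'   components (scaled to sd 1e-4, the usual convention), which makes runs
#'   reproducible and maps identical samples to identical coordinates.
#' @export
embedSamplesTSNE <- function(x, seed = 42L, perplexity = 15, ...) {
    x <- as.matrix(x)
    stopIfNot(nrow(x) >= 5L, "too few samples")
    stopIfNot(perplexity < (nrow(x) - 1) / 3,
              "perplexity must be < (n_samples - 1) / 3")
    pc <- prcomp(x, center = TRUE, scale. = FALSE)$x
    init <- cbind(pc[, 1L], if (ncol(pc) > 1L) pc[, 2L] else 0)
    init <- 1e-4 * scale(init, center = TRUE,
                         scale = apply(init, 2L, function(v)
                             max(sd(v), 1e-12)))
    coords <- withPrivateSeed(seed, {
        Rtsne::Rtsne(x, perplexity = perplexity, theta = 0,
                     check_duplicates = FALSE, pca = FALSE,
                     Y_init = init, max_iter = 1000, ...)$Y
    })
    coords <- scale(coords, center = TRUE, scale = FALSE)
    rownames(coords) <- rownames(x)
    colnames(coords) <- c("tsne1", "tsne2")
    new("EmbeddingResult", coords = coords, method = "tsne",
        seed = as.numeric(seed), params = list(perplexity = perplexity),
        centroids = NULL)
}

#' Replicate quality control by silhouette
#'
#' Mean silhouette width of the replicate (internal-control) samples in an
#' embedding, treating the replicates as one cluster against all other
#' samples. Near 1 when replicates are mutually tight and well separated;
#' near 0 when they scatter among the rest.
#'
#' @param coords samples x 2 embedding coordinates (or an
#'   [EmbeddingResult-class]).
#' @param isReplicate logical per sample.
#' @return mean silhouette width of the replicate samples.
#' @export
replicateQC <- function(coords, isReplicate) {
    if (is(coords, "EmbeddingResult")) coords <- coords@coords
    stopIfNot(sum(isReplicate) >= 2L, "need at least 2 replicates")
    stopIfNot(any(!isReplicate), "all samples are replicates")
    sil <- cluster::silhouette(ifelse(isReplicate, 1L, 2L), dist(coords))
    mean(sil[isReplicate, "sil_width"])
}

#' Sample-level PCA with group centroids
#'
#' Principal components of the column-centred sample profile matrix, with
#' per-group centroids in PC space and the explained-variance profile.
#'
#' @param x numeric samples-x-features matrix.
#' @param groups optional per-sample group labels for centroids.
#' @param d number of leading components kept as `coords` (default 2).
#' @return an [EmbeddingResult-class]; `params` carries `explainedVar`
#'   (fractions, non-increasing) and the full score matrix `scores`.
#' @export
pcaSamples <- function(x, groups = NULL, d = 2L) {
    x <- as.matrix(x)
    stopIfNot(nrow(x) >= 3L, "need at least 3 samples")
    pc <- prcomp(x, center = TRUE, scale. = FALSE)
    ev <- pc$sdev^2 / sum(pc$sdev^2)
    stopIfNot(is.finite(ev[1L]) && ev[1L] > 0, "degenerate (rank 0) input")
    d <- min(d, ncol(pc$x))
    coords <- pc$x[, seq_len(d), drop = FALSE]
    centroids <- NULL
    if (!is.null(groups)) {
        centroids <- do.call(rbind, lapply(split(seq_len(nrow(coords)),
                                                 groups), function(i)
            colMeans(coords[i, , drop = FALSE])))
    }
    new("EmbeddingResult", coords = coords, method = "pca", seed = NA_real_,
        params = list(explainedVar = ev, scores = pc$x,
                      rotation = pc$rotation, center = pc$center),
        centroids = centroids)
}

#' Hotelling's two-sample T-squared test
#'
#' Multivariate comparison of two group mean vectors:
#' `T2 = (nA nB / (nA + nB)) (xbarA - xbarB)' S_pooled^-1 (xbarA - xbarB)`,
#' referred to an F distribution with `(d, nA + nB - d - 1)` degrees of
#' freedom via `F = ((nA + nB - d - 1) / (d (nA + nB - 2))) T2`. Typically
#' applied to PCA-reduced sample scores ([pcaSamples()]).
#'
#' @param groupA,groupB numeric matrices (samples x d) or vectors (d = 1).
#' @return an object of class `"htest"` with `statistic` (`T2`, `F`),
#'   `parameter` (`df1`, `df2`), and `p.value`.
#' @examples
#' hotellingT2(c(0, 2), c(3, 5))  # T2 = 4.5 on df (1, 2)
#' @export
hotellingT2 <- function(groupA, groupB) {
    a <- as.matrix(groupA)
    b <- as.matrix(groupB)
    stopIfNot(ncol(a) == ncol(b), "groups must share dimensions")
    nA <- nrow(a); nB <- nrow(b); d <- ncol(a)
    stopIfNot(nA + nB - 2 > d,
              "need nA + nB - 2 > d; reduce dimensions first")
    xbar <- colMeans(a) - colMeans(b)
    S <- (crossprod(sweep(a, 2L, colMeans(a))) +
          crossprod(sweep(b, 2L, colMeans(b)))) / (nA + nB - 2)
    Sinv <- tryCatch(solve(S), error = function(e)
        stop("pooled covariance is singular; reduce dimensions first",
             call. = FALSE))
    T2 <- as.numeric(nA * nB / (nA + nB) * t(xbar) %*% Sinv %*% xbar)
    Fstat <- (nA + nB - d - 1) / (d * (nA + nB - 2)) * T2
    p <- pf(Fstat, d, nA + nB - d - 1, lower.tail = FALSE)
    structure(list(
        statistic = c(T2 = T2, F = Fstat),
        parameter = c(df1 = d, df2 = nA + nB - d - 1),
        p.value = p,
        method = "Hotelling's two-sample T-squared test",
        data.name = paste(nA, "vs", nB, "samples in", d, "dimensions")),
        class = "htest")
}
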