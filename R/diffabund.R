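#' @include AllClasses.R ingest.R
NULL

#' Benjamini-Hochberg FDR control
#'
#' Step-up adjustment: with p-values sorted ascending,
#' `q_(i) = min_{j >= i} m p_(j) / j`, capped at 1. `NA` entries
#' (untestable hypotheses) are excluded from `m` and stay `NA`.
#'
#' @param pvals numeric p-values in `[0, 1]` (NA allowed).
#' @param alpha FDR level for the significance flags (default 0.05).
#' @return list with `q` and logical `significant` (`q <= alpha`).
#' @examples
#' bhFDR(c(0.001, 0.02, 0.03, 0.5))$q  # 0.004 0.04 0.04 0.50
#' @export
bhFDR <- function(pvals, alpha = 0.05) {
    stopIfNot(alpha > 0 && alpha < 1, "alpha must be in (0, 1)")
    ok <- !is.na(pvals)
    stopIfNot(all(pvals[ok] >= 0 & pvals[ok] <= 1),
              "p-values must lie in [0, 1]")
    q <- rep(NA_real_, length(pvals))
    q[ok] <- p.adjust(pvals[ok], method = "BH")
    list(q = q, significant = !is.na(q) & q <= alpha)
}

#' Per-subset Welch t-tests: inflamed vs noninflamed/control
#'
#' Two-sample t-tests of each subset's frequencies between inflamed samples
#' and the pooled noninflamed-IBD/control samples, with optional
#' arcsine-square-root variance stabilisation, two-sided p-values, and
#' Benjamini-Hochberg adjustment across subsets.
#'
#' @param freq a [FrequencyMatrix-class] or samples-x-subsets percentage
#'   matrix.
#' @param groups per-sample group labels (`"inflamed"` vs anything else);
#'   defaults to `sampleData(freq)$status == "inflamed"`.
#' @param transform apply arcsine-sqrt before testing (default `TRUE`).
#' @param varEqual use the pooled-variance Student variant instead of Welch.
#' @param alpha FDR level.
#' @return a [DAResult-class] `DFrame` with columns `subset_id`,
#'   `direction`, `t`, `p`, `q`, `significant`. Subsets untestable because
#'   a group is degenerate get `NA` statistics.
#' @export
ttestInflamedVsRest <- function(freq, groups = NULL, transform = TRUE,
                                varEqual = FALSE, alpha = 0.05) {
    if (is.null(groups)) {
        stopIfNot(is(freq, "FrequencyMatrix"),
                  "groups required unless freq carries sample metadata")
        sd0 <- sampleData(freq)
        ## the comparison is defined over intestinal biopsies
        if ("tissue" %in% colnames(sd0) && any(sd0$tissue == "blood"))
            freq <- freq[, sd0$tissue != "blood"]
        groups <- ifelse(sampleData(freq)$status == "inflamed",
                         "inflamed", "rest")
    }
    x <- if (is(freq, "FrequencyMatrix")) freqValues(freq) else as.matrix(freq)
    stopIfNot(length(groups) == nrow(x), "one group label per sample required")
    inf <- groups == "inflamed"
    stopIfNot(sum(inf) >= 2 && sum(!inf) >= 2,
              "need >= 2 samples per group")
    y <- if (transform) preprocessFrequencies(x, "arcsine_sqrt") else x
    K <- ncol(x)
    tstat <- p <- rep(NA_real_, K)
    direction <- character(K)
    for (k in seq_len(K)) {
        a <- y[inf, k]
        b <- y[!inf, k]
        direction[k] <- if (mean(a) >= mean(b)) "up_in_inflamed"
                        else "down_in_inflamed"
        if (sd(a) == 0 && sd(b) == 0) next  # untestable: both degenerate
        tt <- tryCatch(t.test(a, b, var.equal = varEqual),
                       error = function(e) NULL)
        if (is.null(tt)) next
        tstat[k] <- unname(tt$statistic)
        p[k] <- tt$p.value
    }
    adj <- bhFDR(p, alpha)
    res <- S4Vectors::DataFrame(
        subset_id = colnames(x), direction = direction, t = tstat, p = p,
        q = adj$q, significant = adj$significant)
    out <- new("DAResult", res)
    S4Vectors::metadata(out) <- list(alpha = alpha, transform = transform,
                                     welch = !varEqual,
                                     n_inflamed = sum(inf),
                                     n_rest = sum(!inf))
    out
}

## Kruskal-Wallis + Dunn's post hoc on one response vector
.kruskalDunnOne <- function(values, groups) {
    groups <- factor(groups)
    stopIfNot(nlevels(groups) >= 2L, "need >= 2 groups")
    stopIfNot(all(table(groups) >= 2L), "each group needs >= 2 samples")
    if (length(unique(values)) == 1L) {
        ## all values tied across groups: no evidence against the null
        pairs <- utils::combn(levels(groups), 2L)
        dunn <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                           z = 0, p = 1, p.adj = 1)
        return(list(H = 0, p = 1, dunn = dunn))
    }
    kw <- kruskal.test(values, groups)
    N <- length(values)
    r <- rank(values)
    ties <- table(values)
    tieCorr <- sum(ties^3 - ties) / (12 * (N - 1))
    rbar <- tapply(r, groups, mean)
    ns <- tapply(r, groups, length)
    lev <- levels(groups)
    pairs <- utils::combn(lev, 2L)
    z <- p <- numeric(ncol(pairs))
    for (j in seq_len(ncol(pairs))) {
        a <- pairs[1L, j]; b <- pairs[2L, j]
        se <- sqrt((N * (N + 1) / 12 - tieCorr) * (1 / ns[[a]] + 1 / ns[[b]]))
        z[j] <- if (se > 0) (rbar[[a]] - rbar[[b]]) / se else 0
        p[j] <- 2 * pnorm(-abs(z[j]))
    }
    dunn <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                       z = z, p = p,
                       p.adj = pmin(1, p * ncol(pairs)))  # Bonferroni
    list(H = unname(kw$statistic), p = kw$p.value, dunn = dunn)
}

#' Kruskal-Wallis test with Dunn's post-hoc comparisons
#'
#' Rank-based multi-group comparison per subset: the Kruskal-Wallis H
#' statistic with tie correction, then Dunn's pairwise z tests on the
#' pooled ranks with Bonferroni adjustment over the pairs.
#'
#' @param freq a [FrequencyMatrix-class], samples-x-subsets matrix, or a
#'   single numeric vector.
#' @param groups per-sample group labels (>= 2 groups, each with >= 2
#'   samples).
#' @return for a vector input, a list with `H`, `p` and a `dunn` data frame
#'   (`group1`, `group2`, `z`, `p`, `p.adj`); for matrix input, a named
#'   list of such results per subset.
#' @export
kruskalDunn <- function(freq, groups = NULL) {
    if (is.numeric(freq) && is.null(dim(freq)))
        return(.kruskalDunnOne(freq, groups))
    if (is(freq, "FrequencyMatrix")) {
        if (is.null(groups)) groups <- sampleData(freq)$status
        freq <- freqValues(freq)
    }
    lapply(setNames(seq_len(ncol(freq)), colnames(freq)),
           function(k) .kruskalDunnOne(freq[, k], groups))
}

#' Compare per-sample CD45+ cell yields between groups
#'
#' Kruskal-Wallis/Dunn comparison of acquired CD45+ cell counts (e.g.
#' inflamed vs noninflamed vs control biopsies).
#'
#' @param samples per-sample metadata (`DFrame`/`data.frame`) with an
#'   `n_cells` column, or a numeric count vector.
#' @param groups per-sample group labels; defaults to `samples$status`.
#' @return as [kruskalDunn()] for a single response.
#' @export
compareCellCounts <- function(samples, groups = NULL) {
    counts <- if (is.numeric(samples)) samples else samples$n_cells
    if (is.null(groups) && !is.numeric(samples)) groups <- samples$status
    stopIfNot(all(counts >= 0), "counts must be nonnegative")
    .kruskalDunnOne(as.numeric(counts), groups)
}
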