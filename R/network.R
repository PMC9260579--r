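#' @include AllClasses.R ingest.R
NULL

#' Spearman correlation matrix over subset frequencies
#'
#' Pairwise Spearman rank correlations (average ranks for ties) between
#' subset frequency profiles across intestinal samples. When the input
#' carries sample metadata, blood samples are excluded (the co-abundance
#' network is defined over intestinal biopsies). Pairs involving a constant
#' column are set to 0 with a warning.
#'
#' @param freq a [FrequencyMatrix-class] or samples-x-subsets matrix
#'   (>= 5 samples).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
spearmanMatrix <- function(freq) {
    if (is(freq, "FrequencyMatrix")) {
        sd0 <- sampleData(freq)
        x <- freqValues(freq)
        if ("tissue" %in% colnames(sd0) && any(sd0$tissue == "blood"))
            x <- x[sd0$tissue != "blood", , drop = FALSE]
    } else x <- as.matrix(freq)
    stopIfNot(nrow(x) >= 5L, "need >= 5 samples")
    const <- apply(x, 2L, function(v) sd(v) == 0)
    rho <- suppressWarnings(cor(x, method = "spearman"))
    if (any(const)) {
        warning("constant column(s): ",
                paste(colnames(x)[const], collapse = ", "),
                "; correlations set to 0")
        rho[const, ] <- 0
        rho[, const] <- 0
    }
    rho[is.na(rho)] <- 0
    diag(rho) <- 1
    rho
}

.meanWithinRho <- function(rho, members) {
    if (length(members) < 2L) return(NA_real_)
    sub <- rho[members, members]
    mean(sub[upper.tri(sub)])
}

#' Extract and qualify co-abundance modules
#'
#' Average-linkage agglomerative clustering on distance `1 - rho`; the
#' number of clusters is chosen by maximum mean silhouette width over
#' `kRange`. A cluster qualifies as a network when it has at least `mMin`
#' members and mean within-module pairwise correlation at least `rhoMin`.
#' When a [DAResult-class] is supplied, qualified modules receive semantic
#' labels: the module whose effect-significant members are predominantly
#' depleted in inflamed samples is `network1`, the predominantly enriched
#' one `network2`, and the remaining qualified modules `network3`,
#' `network4`, ... by decreasing size (label metadata only).
#'
#' @param rho symmetric correlation matrix (from [spearmanMatrix()]).
#' @param mMin minimum module membership (default 4).
#' @param rhoMin minimum mean within-module pairwise correlation
#'   (default 0.3).
#' @param kRange candidate cluster numbers for the silhouette scan.
#' @param da optional [DAResult-class] used for semantic network labels.
#' @return a [CorrelationModules-class].
#' @export
extractModules <- function(rho, mMin = 4L, rhoMin = 0.3, kRange = 2:8,
                           da = NULL) {
    stopIfNot(nrow(rho) >= 3L, "need at least 3 subsets")
    stopIfNot(mMin >= 2L, "mMin must be >= 2")
    stopIfNot(rhoMin > 0 && rhoMin < 1, "rhoMin must be in (0, 1)")
    d <- stats::as.dist(1 - rho)
    tree <- stats::hclust(d, method = "average")
    kRange <- kRange[kRange < nrow(rho)]
    sil <- vapply(kRange, function(k) {
        ct <- stats::cutree(tree, k)
        mean(cluster::silhouette(ct, d)[, "sil_width"])
    }, 0)
    k <- kRange[which.max(sil)]
    modules <- stats::cutree(tree, k)
    sizes <- tabulate(modules, nbins = k)
    meanRho <- vapply(seq_len(k), function(m)
        .meanWithinRho(rho, which(modules == m)), 0)
    isNet <- sizes >= mMin & !is.na(meanRho) & meanRho >= rhoMin
    st <- S4Vectors::DataFrame(module = seq_len(k), size = sizes,
                               meanRho = meanRho, isNetwork = isNet)
    if (!is.null(da)) st$label <- .labelNetworks(st, modules, da)
    new("CorrelationModules", rho = rho, tree = tree, modules = modules,
        moduleStats = st, mMin = as.integer(mMin), rhoMin = rhoMin)
}

.labelNetworks <- function(st, modules, da) {
    lab <- rep(NA_character_, nrow(st))
    qual <- which(st$isNetwork)
    if (!length(qual)) return(lab)
    dirSig <- function(m) {
        mem <- names(modules)[modules == m]
        i <- match(mem, da$subset_id)
        sig <- da$significant[i] & !is.na(da$significant[i])
        c(down = sum(sig & da$direction[i] == "down_in_inflamed"),
          up = sum(sig & da$direction[i] == "up_in_inflamed"))
    }
    cnt <- vapply(qual, dirSig, c(down = 0, up = 0))
    left <- qual
    iDown <- qual[cnt["down", ] > cnt["up", ]]
    if (length(iDown)) {
        m1 <- iDown[which.max(cnt["down", match(iDown, qual)])]
        lab[m1] <- "network1"; left <- setdiff(left, m1)
    }
    iUp <- intersect(left, qual[cnt["up", ] > cnt["down", ]])
    if (length(iUp)) {
        m2 <- iUp[which.max(cnt["up", match(iUp, qual)])]
        lab[m2] <- "network2"; left <- setdiff(left, m2)
    }
    if (length(left)) {
        left <- left[order(st$size[left], decreasing = TRUE)]
        lab[left] <- paste0("network", seq_along(left) + 2L)
    }
    lab
}

#' Collective network frequencies per sample
#'
#' For each qualified module, the sum of its member subsets' frequencies
#' (% of total CD45+ cells) per sample.
#'
#' @param freq a [FrequencyMatrix-class] in `total_CD45` mode.
#' @param modules a [CorrelationModules-class].
#' @return `DFrame` with the sample metadata plus one `module<i>` (or
#'   semantic label) column per qualified module.
#' @export
collectiveFrequencies <- function(freq, modules) {
    stopIfNot(is(freq, "FrequencyMatrix") &&
              identical(freqMode(freq), "total_CD45"),
              "freq must be a total_CD45 FrequencyMatrix")
    x <- freqValues(freq)
    miss <- setdiff(names(modules@modules), colnames(x))
    stopIfNot(length(miss) == 0L,
              paste("module references unknown subsets:",
                    paste(miss, collapse = ", ")))
    st <- modules@moduleStats
    out <- sampleData(freq)
    for (i in which(st$isNetwork)) {
        mem <- names(modules@modules)[modules@modules == st$module[i]]
        nm <- if ("label" %in% colnames(st) && !is.na(st$label[i]))
            st$label[i] else paste0("module", st$module[i])
        out[[nm]] <- rowSums(x[, mem, drop = FALSE])
    }
    out
}

#' Stratify patients by collective network abundance
#'
#' A patient is flagged when any of their inflamed samples has a collective
#' module frequency above `cutoff` percent of CD45+ cells. Patients with no
#' inflamed sample are recorded but never flagged.
#'
#' @param collective output of [collectiveFrequencies()] (needs
#'   `subject_id` and `status` columns).
#' @param module name of the collective column to threshold
#'   (e.g. `"network2"`).
#' @param cutoff percentage cutoff in (0, 100); default 50.
#' @return list with `flagged` (named logical per patient), `summary` a
#'   string `"<flagged>/<total>"` over patients having inflamed samples,
#'   and `no_inflamed` (patients without inflamed samples).
#' @export
stratifyPatients <- function(collective, module, cutoff = 50) {
    stopIfNot(cutoff > 0 && cutoff < 100, "cutoff must be in (0, 100)")
    stopIfNot(module %in% colnames(collective),
              paste("no collective column", module))
    subj <- unique(collective$subject_id[!collective$is_internal_control])
    flagged <- setNames(logical(length(subj)), subj)
    hasInf <- setNames(logical(length(subj)), subj)
    for (s in subj) {
        rows <- collective$subject_id == s & collective$status == "inflamed"
        hasInf[s] <- any(rows)
        if (hasInf[s])
            flagged[s] <- max(collective[[module]][rows]) > cutoff
    }
    list(flagged = flagged,
         summary = paste0(sum(flagged), "/", sum(hasInf)),
         no_inflamed = names(hasInf)[!hasInf])
}

#' Export a correlation network as an edge list
#'
#' @param modules a [CorrelationModules-class].
#' @param threshold minimum `|rho|` for an edge (default 0.4).
#' @return data.frame (`subset_i`, `subset_j`, `rho`).
#' @export
edgeList <- function(modules, threshold = 0.4) {
    rho <- modules@rho
    idx <- which(upper.tri(rho) & abs(rho) >= threshold, arr.ind = TRUE)
    data.frame(subset_i = rownames(rho)[idx[, 1L]],
               subset_j = colnames(rho)[idx[, 2L]],
               rho = rho[idx])
}
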