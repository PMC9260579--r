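#' @include catalog.R utils.R
NULL

## latent composition factors: the three designed networks plus one weak
## residual factor shared by the module-free subsets
.MODULES <- c("network1", "network2", "network3", "residual")

## deterministic subject/sample layout for one cohort
.studyLayout <- function(config) {
    tag <- if (config@cohort == "primary") "P" else "V"
    groups <- rep(names(config@nSubjects), config@nSubjects)
    subj <- sprintf("%s_%s%02d", tag, groups,
                    unlist(lapply(config@nSubjects, seq_len)))
    diagnosis <- groups
    rows <- list()
    for (i in seq_along(subj)) {
        g <- groups[i]
        ## three intestinal samples (ileum + two colon) + one blood sample;
        ## CD: inflamed ileum + one inflamed colon; UC: one inflamed colon
        status <- switch(g,
            control = c("control", "control", "control"),
            CD = c("inflamed", "inflamed", "noninflamed"),
            UC = c("noninflamed", "inflamed", "noninflamed"))
        tissue <- c("ileum", "colon", "colon")
        sid <- paste0(subj[i], c("_ileum", "_colon1", "_colon2", "_blood"))
        rows[[i]] <- data.frame(
            sample_id = sid,
            subject_id = subj[i],
            tissue = c(tissue, "blood"),
            status = c(status, if (g == "control") "control" else "noninflamed"),
            diagnosis = diagnosis[i],
            is_internal_control = FALSE)
    }
    nIC <- config@nInternalControls
    if (nIC > 0L)
        rows[[length(rows) + 1L]] <- data.frame(
            sample_id = sprintf("%s_IC%02d", tag, seq_len(nIC)),
            subject_id = "IC",
            tissue = "blood", status = "control", diagnosis = "control",
            is_internal_control = TRUE)
    do.call(rbind, rows)
}

#' Simulate a synthetic mass-cytometry study with full ground truth
#'
#' Draws per-sample subset compositions from a logistic-normal model --
#' tissue baseline log-abundance, a per-subject random effect shared across
#' that subject's samples, per-sample latent module factors shared across
#' module members, independent noise, and inflammation effect shifts for the
#' designed effect subsets -- then samples cell counts multinomially and,
#' when `markers = TRUE`, per-cell arcsinh marker intensities from truncated
#' normals around each subset's mean profile. Internal-control replicates
#' share one fixed composition and differ only by multinomial and expression
#' noise.
#'
#' @param config a [GeneratorConfig-class], e.g. from [defaultConfig()].
#' @param seed integer RNG seed; the caller's RNG state is left untouched.
#' @param markers `TRUE` (all samples), `FALSE` (composition-only study:
#'   counts and ground truth but no per-cell data -- much faster for
#'   frequency-level analyses), or `"intestinal"` (per-cell data for
#'   intestinal samples only).
#' @return a [CytoStudy-class] with ground truth (`groundTruth(x)`), holding
#'   `probs` (the pre-sampling per-sample subset proportions, each row
#'   summing to 1), `counts`, the subset catalogue, and the designated
#'   high-network2 subject set.
#' @examples
#' cfg <- defaultConfig("primary")
#' st <- simulateStudy(cfg, seed = 1, markers = FALSE)
#' dim(groundTruth(st)$counts)
#' @export
simulateStudy <- function(config, seed = 1L, markers = TRUE) {
    stopIfNot(is(config, "GeneratorConfig"), "config must be a GeneratorConfig")
    validObject(config)
    withPrivateSeed(seed, .simulateStudyImpl(config, markers))
}

.simulateStudyImpl <- function(config, markers) {
    layout <- .studyLayout(config)
    subs <- config@subsets
    K <- nrow(subs)
    ids <- subs$subset_id
    subjects <- unique(layout$subject_id[layout$subject_id != "IC"])
    ibd <- unique(layout$subject_id[layout$diagnosis %in% c("CD", "UC")])
    nHigh <- round(config@highNetwork2Fraction * length(ibd))
    highSubj <- if (nHigh > 0L) sort(sample(ibd, nHigh)) else character()

    up <- subs$effect == "up_in_inflamed"
    down <- subs$effect == "down_in_inflamed"
    net2up <- up & subs$module == "network2"
    spikeIdx <- match("CD4_T_EM_HLADR_CD38", ids)
    loading <- subs$loading
    noiseMult <- if ("noise_mult" %in% colnames(subs)) subs$noise_mult else 1
    modIdx <- match(subs$module, .MODULES)
    modIdx[subs$module == "none"] <- match("residual", .MODULES)

    u <- matrix(rnorm(length(subjects) * K, sd = config@sigmaSubj),
                length(subjects), K, dimnames = list(subjects, ids))

    nS <- nrow(layout)
    probs <- matrix(NA_real_, nS, K, dimnames = list(layout$sample_id, ids))
    counts <- matrix(NA_integer_, nS, K, dimnames = list(layout$sample_id, ids))
    icProbs <- softmax(config@baselines[, "blood"])

    for (s in seq_len(nS)) {
        tis <- layout$tissue[s]
        if (layout$is_internal_control[s]) {
            p <- icProbs
        } else {
            f <- rnorm(length(.MODULES), sd = config@sigmaMod)
            inflamed <- layout$status[s] == "inflamed"
            if (inflamed) {
                f[2L] <- f[2L] + config@deltaFactor
                f[1L] <- f[1L] - config@deltaFactor
            }
            la <- config@baselines[, tis] + u[layout$subject_id[s], ] +
                ifelse(is.na(modIdx), 0, loading * f[modIdx]) +
                rnorm(K, sd = config@sigmaNoise * noiseMult)
            if (inflamed) {
                la[up] <- la[up] + config@deltaEffect
                la[down] <- la[down] - config@deltaEffect
                if (layout$subject_id[s] %in% highSubj)
                    la[net2up] <- la[net2up] + config@deltaHigh
            }
            if (tis == "blood" && layout$diagnosis[s] %in% c("CD", "UC"))
                la[spikeIdx] <- la[spikeIdx] + config@deltaBloodSpike
            p <- softmax(la)
        }
        n <- max(100L, rpois(1L, config@cellsPerSample[[tis]]))
        probs[s, ] <- p
        counts[s, ] <- rmultinom(1L, n, p)[, 1L]
    }

    layout$high_network2 <- layout$subject_id %in% highSubj
    layout$n_cells <- rowSums(counts)
    samples <- S4Vectors::DataFrame(layout)

    truth <- list(probs = probs, counts = counts, subsets = subs,
                  high_network2_subjects = highSubj)

    exprs <- NULL
    cellDat <- NULL
    if (!isFALSE(markers)) {
        cc <- counts
        if (identical(markers, "intestinal"))
            cc[layout$tissue == "blood", ] <- 0L
        M <- length(config@panel@markers)
        total <- sum(cc)
        perCell <- as.vector(t(cc))  # sample-major, catalogue order
        cellSample <- rep(rep(layout$sample_id, each = K), perCell)
        cellSubset <- rep(rep(ids, nS), perCell)
        exprs <- matrix(NA_real_, total, M,
                        dimnames = list(NULL, config@panel@markers))
        mu <- config@means + config@batchShift
        for (k in seq_len(K)) {
            idx <- which(cellSubset == ids[k])
            nk <- length(idx)
            if (!nk) next
            exprs[idx, ] <- rtruncNorm(
                nk * M,
                mean = rep(mu[k, ], each = nk),
                sd = rep(config@sds[k, ], each = nk))
        }
        cellDat <- S4Vectors::DataFrame(
            sample_id = cellSample,
            subset = cellSubset,
            lineage = subs$lineage[match(cellSubset, ids)])
    }

    new("CytoStudy", exprs = exprs, cellData = cellDat, samples = samples,
        panel = config@panel, truth = truth)
}

#' Ground-truth frequency matrix of a synthetic study
#'
#' Per-sample subset frequencies computed by counting the generator's
#' realised multinomial cell counts, as percentages of all CD45+ cells
#' (`mode = "total_CD45"`) or of each subset's lineage (`mode = "lineage"`).
#'
#' @param study a synthetic [CytoStudy-class].
#' @param mode denominator mode.
#' @return a [FrequencyMatrix-class].
#' @export
trueFrequencies <- function(study, mode = c("total_CD45", "lineage")) {
    mode <- match.arg(mode)
    truth <- study@truth
    stopIfNot(!is.null(truth$counts), "study carries no ground-truth counts")
    counts <- truth$counts
    if (mode == "total_CD45") {
        f <- 100 * counts / rowSums(counts)
    } else {
        lin <- truth$subsets$lineage
        f <- counts
        for (lv in unique(lin)) {
            cols <- lin == lv
            den <- rowSums(counts[, cols, drop = FALSE])
            ratio <- 100 * counts[, cols, drop = FALSE] / den
            ratio[den == 0, ] <- 0
            f[, cols] <- ratio
        }
    }
    .FrequencyMatrix(f, study@samples, mode)
}

.FrequencyMatrix <- function(freqSamplesBySubsets, sampleDF, mode) {
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(freq = t(freqSamplesBySubsets)),
        colData = sampleDF[match(rownames(freqSamplesBySubsets),
                                 sampleDF$sample_id), , drop = FALSE],
        metadata = list(mode = mode))
    new("FrequencyMatrix", se)
}

#' Write a study to disk / read it back
#'
#' `writeStudy()` writes one CSV file of per-cell marker intensities per
#' sample plus tab-separated tables for the sample metadata, per-cell
#' ground-truth labels, the subset catalogue and the true composition
#' (counts and proportions). `readStudy()` reconstructs the
#' [CytoStudy-class] from such a directory; the round trip preserves marker
#' values beyond float32 precision.
#'
#' @param study a [CytoStudy-class] with per-cell data.
#' @param dir output directory (created if needed).
#' @param format only `"csv"` is supported; `"fcs"` raises an informative
#'   error (no FCS writer is available to this package).
#' @return `writeStudy()`: invisibly, a manifest `data.frame` with one row
#'   per sample (`sample_id`, `file`, `n_cells`); `readStudy()`: a
#'   [CytoStudy-class].
#' @export
writeStudy <- function(study, dir, format = c("csv", "fcs")) {
    format <- match.arg(format)
    if (format == "fcs")
        stop("FCS output is not supported (no FCS writer available); ",
             "use format = 'csv'")
    stopIfNot(!is.null(study@exprs), "study has no per-cell data to write")
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    sids <- study@samples$sample_id
    files <- file.path(dir, paste0(sids, ".csv"))
    ncells <- integer(length(sids))
    for (i in seq_along(sids)) {
        idx <- study@cellData$sample_id == sids[i]
        ncells[i] <- sum(idx)
        utils::write.csv(
            as.data.frame(study@exprs[idx, , drop = FALSE]),
            files[i], row.names = FALSE)
    }
    write.table(as.data.frame(study@samples),
                file.path(dir, "metadata.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(as.data.frame(study@cellData),
                file.path(dir, "cell_labels.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (length(study@truth)) {
        write.table(as.data.frame(study@truth$subsets),
                    file.path(dir, "subsets.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        write.table(study@truth$counts, file.path(dir, "truth_counts.tsv"),
                    sep = "\t", quote = FALSE)
        write.table(study@truth$probs, file.path(dir, "truth_probs.tsv"),
                    sep = "\t", quote = FALSE)
    }
    manifest <- data.frame(sample_id = sids, file = basename(files),
                           n_cells = ncells)
    write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    invisible(manifest)
}

#' @rdname writeStudy
#' @param panel the [MarkerPanel-class] to attach on read (defaults to the
#'   markers found in the files, with the default lineage signatures when
#'   they apply).
#' @export
readStudy <- function(dir, panel = NULL) {
    manifest <- read.table(file.path(dir, "manifest.tsv"), header = TRUE,
                           sep = "\t")
    samples <- S4Vectors::DataFrame(
        read.table(file.path(dir, "metadata.tsv"), header = TRUE, sep = "\t"))
    cellDat <- S4Vectors::DataFrame(
        read.table(file.path(dir, "cell_labels.tsv"), header = TRUE,
                   sep = "\t"))
    mats <- lapply(file.path(dir, manifest$file), function(f)
        as.matrix(utils::read.csv(f, check.names = FALSE)))
    exprs <- do.call(rbind, mats)
    ## cell_labels rows are written in the same per-sample order
    ord <- order(match(cellDat$sample_id, manifest$sample_id))
    cellDat <- cellDat[ord, , drop = FALSE]
    if (is.null(panel)) {
        def <- defaultPanel("validation")
        sig <- if (all(unlist(lapply(def@signatures, unlist)) %in%
                       colnames(exprs))) def@signatures else list()
        panel <- markerPanel(colnames(exprs), sig)
    }
    truth <- list()
    sf <- file.path(dir, "subsets.tsv")
    if (file.exists(sf)) {
        truth$subsets <- S4Vectors::DataFrame(
            read.table(sf, header = TRUE, sep = "\t"))
        truth$counts <- as.matrix(read.table(
            file.path(dir, "truth_counts.tsv"), header = TRUE, sep = "\t",
            check.names = FALSE))
        truth$probs <- as.matrix(read.table(
            file.path(dir, "truth_probs.tsv"), header = TRUE, sep = "\t",
            check.names = FALSE))
    }
    new("CytoStudy", exprs = exprs, cellData = cellDat, samples = samples,
        panel = panel, truth = truth)
}
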