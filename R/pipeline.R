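#' @include simulate.R ingest.R identify.R diffabund.R network.R lda.R embed.R
NULL

#' Combine frequency matrices over shared subsets
#'
#' Row-binds the samples of two frequency matrices restricted to their
#' shared subset columns (e.g. to pool the primary and validation cohorts).
#'
#' @param a,b [FrequencyMatrix-class] objects with the same mode.
#' @return a [FrequencyMatrix-class].
#' @export
combineFrequencies <- function(a, b) {
    stopIfNot(identical(freqMode(a), freqMode(b)),
              "frequency matrices must share the denominator mode")
    cols <- intersect(rownames(SummarizedExperiment::assay(a, "freq")),
                      rownames(SummarizedExperiment::assay(b, "freq")))
    stopIfNot(length(cols) >= 1L, "no shared subsets")
    fa <- freqValues(a)[, cols, drop = FALSE]
    fb <- freqValues(b)[, cols, drop = FALSE]
    sa <- as.data.frame(sampleData(a))
    sb <- as.data.frame(sampleData(b))
    shared <- intersect(colnames(sa), colnames(sb))
    sdf <- S4Vectors::DataFrame(rbind(sa[, shared, drop = FALSE],
                                      sb[, shared, drop = FALSE]))
    out <- rbind(fa, fb)
    rownames(out) <- sdf$sample_id
    ## renormalise is not needed: shared subsets form the full universe when
    ## both cohorts use the same catalogue; otherwise keep raw percentages
    .FrequencyMatrix(out, sdf, freqMode(a))
}

#' Pipeline configuration
#'
#' Collects every stage parameter of [runPipeline()] with the study
#' defaults. Any entry can be overridden via `...` or by editing the
#' returned list; `yaml` gives a path to a YAML file whose entries override
#' the defaults.
#'
#' @param ... named overrides.
#' @param yaml optional path to a YAML config file.
#' @return a named list with class `"cytoPipelineConfig"`.
#' @export
pipelineConfig <- function(..., yaml = NULL) {
    cfg <- list(
        seed = 1L,
        labels = "cluster",        # "cluster" or "truth"
        gateThreshold = 1.0,
        kRange = 1:12,
        alpha = 0.05,
        mMin = 4L,
        rhoMin = 0.3,
        tau = c(1.0, 0.95),
        cutoffPercent = 50,
        perplexity = 15,
        embedDims = 2L,
        stages = c(abundance = TRUE, network = TRUE, transfer = TRUE,
                   embed = TRUE),
        figures = FALSE)
    if (!is.null(yaml)) {
        ov <- yaml::read_yaml(yaml)
        cfg[names(ov)] <- ov
    }
    dots <- list(...)
    if ("stages" %in% names(dots)) {
        st <- cfg$stages
        st[names(dots$stages)] <- dots$stages
        dots$stages <- st
    }
    cfg[names(dots)] <- dots
    structure(cfg, class = "cytoPipelineConfig")
}

.writeTable <- function(x, path)
    write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                row.names = FALSE)

#' Run the full analysis pipeline on a synthetic study
#'
#' End-to-end orchestration: simulate both cohorts, gate CD45+, identify
#' subsets (two-level clustering, or ground-truth labels), build the pooled
#' intestinal frequency matrix, run differential abundance, extract and
#' qualify correlation networks, compute collective network frequencies and
#' patient stratification, transfer labels to the validation cohort and
#' match blood cells (LDA with rejection), embed samples (t-SNE with
#' replicate QC; PCA with Hotelling T-squared group tests), and write a
#' report directory with tab-separated tables, a JSON summary and a log.
#' Deterministic for a fixed config.
#'
#' @param config a [pipelineConfig()] list.
#' @param outDir report directory (created).
#' @param generatorConfigs optional list with elements `primary` and
#'   `validation` overriding [defaultConfig()] (e.g. scaled-down studies).
#' @return invisibly, the summary list (also written as `summary.json`).
#' @export
runPipeline <- function(config = pipelineConfig(), outDir,
                        generatorConfigs = NULL) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    logFile <- file.path(outDir, "pipeline.log")
    logln <- function(...) cat(..., "\n", sep = "", file = logFile,
                               append = TRUE)
    cat("", file = logFile)
    logln("cytomodules ", as.character(packageVersion("cytomodules")),
          " pipeline run")
    cfgYaml <- file.path(outDir, "config.yaml")
    yaml::write_yaml(unclass(config), cfgYaml)
    logln("config hash: ", unname(tools::md5sum(cfgYaml)))
    logln("seed: ", config$seed)

    summary <- list(seed = config$seed)
    stage <- function(name, expr) {
        logln("stage ", name, " ...")
        tryCatch(expr, error = function(e)
            stop("stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE))
    }

    gp <- if (is.null(generatorConfigs)) defaultConfig("primary")
          else generatorConfigs$primary
    gv <- if (is.null(generatorConfigs)) defaultConfig("validation")
          else generatorConfigs$validation

    needCells <- config$labels == "cluster" || config$stages[["transfer"]]
    prim <- stage("simulate", simulateStudy(gp, seed = config$seed,
                                            markers = needCells))
    vali <- stage("simulate", simulateStudy(gv, seed = config$seed + 1L,
                                            markers = needCells))

    intestinal <- function(study) {
        keepS <- study@samples$tissue != "blood"
        ids <- study@samples$sample_id[keepS]
        if (is.null(study@exprs))
            return(new("CytoStudy", exprs = NULL, cellData = NULL,
                       samples = study@samples[keepS, ], panel = study@panel,
                       truth = list(
                           probs = study@truth$probs[ids, , drop = FALSE],
                           counts = study@truth$counts[ids, , drop = FALSE],
                           subsets = study@truth$subsets)))
        keepC <- study@cellData$sample_id %in% ids
        new("CytoStudy", exprs = study@exprs[keepC, , drop = FALSE],
            cellData = study@cellData[keepC, , drop = FALSE],
            samples = study@samples[keepS, ], panel = study@panel,
            truth = list(probs = study@truth$probs[ids, , drop = FALSE],
                         counts = study@truth$counts[ids, , drop = FALSE],
                         subsets = study@truth$subsets))
    }
    primInt <- intestinal(prim)
    valiInt <- intestinal(vali)

    model <- NULL
    if (config$labels == "cluster") {
        gated <- stage("gate", gateCD45(primInt, config$gateThreshold))
        labeling <- stage("cluster",
                          identifySubsets(gated, kRange = config$kRange))
        summary$n_subsets <- length(labeling@hierarchy)
        freqPrim <- computeFrequencies(
            labeling, gated@cellData$sample_id,
            sampleData = gated@samples, mode = "total_CD45",
            subsetLevels = names(labeling@hierarchy))
        model <- fitLDA(gated, labeling)
        if (config$stages[["transfer"]]) {
            gatedV <- gateCD45(valiInt, config$gateThreshold)
            predV <- predictWithRejection(model, gatedV,
                                          tau = min(config$tau))
            freqVali <- predV@freq
            ## put predicted frequencies on the all-cells denominator into
            ## the shared percentage space
            freqPool <- combineFrequencies(freqPrim, .renorm(freqVali))
        } else freqPool <- freqPrim
        .writeTable(data.frame(cell = seq_along(labeling@subset),
                               sample_id = gated@cellData$sample_id,
                               lineage = labeling@lineage,
                               subset_id = labeling@subset),
                    file.path(outDir, "cell_labels.tsv"))
    } else {
        summary$n_subsets <- nrow(gp@subsets)
        freqPool <- combineFrequencies(trueFrequencies(primInt),
                                       trueFrequencies(valiInt))
    }

    da <- NULL
    if (config$stages[["abundance"]]) {
        da <- stage("abundance",
                    ttestInflamedVsRest(freqPool, alpha = config$alpha))
        .writeTable(da, file.path(outDir, "differential_abundance.tsv"))
        summary$n_significant <- sum(da$significant, na.rm = TRUE)
        summary$n_up <- sum(da$significant &
                            da$direction == "up_in_inflamed", na.rm = TRUE)
        summary$n_down <- sum(da$significant &
                              da$direction == "down_in_inflamed",
                              na.rm = TRUE)
    }

    if (config$stages[["network"]]) {
        rho <- stage("network", spearmanMatrix(freqPool))
        mods <- extractModules(rho, mMin = config$mMin,
                               rhoMin = config$rhoMin, da = da)
        coll <- collectiveFrequencies(freqPool, mods)
        .writeTable(data.frame(subset_id = names(mods@modules),
                               module = mods@modules),
                    file.path(outDir, "modules.tsv"))
        .writeTable(moduleStats(mods), file.path(outDir, "module_stats.tsv"))
        .writeTable(coll, file.path(outDir, "collective_frequencies.tsv"))
        .writeTable(edgeList(mods), file.path(outDir, "edges.tsv"))
        st <- moduleStats(mods)
        summary$n_networks <- sum(st$isNetwork)
        summary$module_sizes <- sort(st$size[st$isNetwork],
                                     decreasing = TRUE)
        lab2 <- if ("label" %in% colnames(st) &&
                    "network2" %in% st$label) "network2"
                else paste0("module", st$module[st$isNetwork][
                    which.max(st$size[st$isNetwork])])
        if (lab2 %in% colnames(coll)) {
            strat <- stratifyPatients(coll, lab2, config$cutoffPercent)
            summary$patients_high_network2 <- strat$summary
        }
        if (isTRUE(config$figures) &&
            requireNamespace("pheatmap", quietly = TRUE)) {
            grDevices::png(file.path(outDir, "correlation_heatmap.png"),
                           900, 900)
            pheatmap::pheatmap(rho, cluster_rows = mods@tree,
                               cluster_cols = mods@tree)
            grDevices::dev.off()
        }
    }

    if (config$stages[["transfer"]] && config$labels == "cluster") {
        tr <- stage("transfer", {
            gatedV <- gateCD45(valiInt, config$gateThreshold)
            mt <- matchToTruth(labeling, gated@cellData$subset)
            predV <- predictWithRejection(model, gatedV, tau = 0.95)
            trueV <- trueFrequencies(valiInt)
            ## map validation truth columns into recovered-label space
            predF <- freqValues(predV@freq)
            inv <- setNames(names(mt$mapping), mt$mapping)
            tv <- freqValues(trueV)
            shared <- intersect(colnames(tv), names(inv))
            tvm <- tv[, shared, drop = FALSE]
            colnames(tvm) <- inv[shared]
            list(R = frequencyConcordance(tvm, predF),
                 matched = predV@matchedFraction, ari = mt$ari)
        })
        summary$transfer_concordance_R <- tr$R
        summary$primary_clustering_ari <- tr$ari
        summary$validation_matched_percent <- tr$matched
        bloodRes <- lapply(config$tau, function(tau)
            matchBloodToTissue(model, prim, tau = tau)$matched_fraction)
        summary$blood_matched_percent <- setNames(
            unlist(bloodRes), paste0("tau_", config$tau))
    }

    if (config$stages[["embed"]]) {
        emb <- stage("embed", {
            fAll <- if (config$labels == "truth") trueFrequencies(prim)
                    else NULL
            out <- list()
            if (!is.null(fAll)) {
                xs <- preprocessFrequencies(fAll)
                ts <- embedSamplesTSNE(xs, seed = config$seed,
                                       perplexity = config$perplexity)
                out$ic_silhouette <- replicateQC(
                    ts, sampleData(fAll)$is_internal_control)
                .writeTable(data.frame(sample_id = rownames(ts@coords),
                                       ts@coords),
                            file.path(outDir, "tsne_coordinates.tsv"))
            }
            xp <- preprocessFrequencies(freqPool)
            groups <- ifelse(sampleData(freqPool)$status == "inflamed",
                             "inflamed", "noninflamed_control")
            pca <- pcaSamples(xp, groups, d = config$embedDims)
            sc <- pca@params$scores[, seq_len(config$embedDims),
                                    drop = FALSE]
            ht <- hotellingT2(sc[groups == "inflamed", , drop = FALSE],
                              sc[groups != "inflamed", , drop = FALSE])
            out$hotelling_T2 <- unname(ht$statistic["T2"])
            out$hotelling_p <- ht$p.value
            .writeTable(data.frame(sample_id = rownames(pca@coords),
                                   pca@coords, group = groups),
                        file.path(outDir, "pca_coordinates.tsv"))
            out
        })
        summary <- c(summary, emb)
    }

    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    logln("done")
    invisible(summary)
}

## rescale a predicted all-cells-denominator frequency matrix so columns of
## accepted subsets sum to 100 (drops the rejected mass)
.renorm <- function(freq) {
    f <- freqValues(freq)
    tot <- rowSums(f)
    tot[tot == 0] <- 1
    .FrequencyMatrix(100 * f / tot, sampleData(freq), "total_CD45")
}
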