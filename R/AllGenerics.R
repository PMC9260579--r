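#' @include AllClasses.R
NULL

#' Accessors for cytomodules classes
#'
#' Small accessor generics: `markerNames()` returns the panel marker vector,
#' `lineageSignatures()` the lineage gating rules, `cellExprs()` the
#' cells-x-markers matrix, `cellData()`/`sampleData()` the per-cell and
#' per-sample metadata, `groundTruth()` the generator-side truth record,
#' `subsetCatalog()` the subset catalogue of a config or study,
#' `freqValues()` a samples-x-subsets percentage matrix, `freqMode()` the
#' denominator mode, `rhoMatrix()`/`moduleAssignments()`/`moduleStats()` the
#' parts of a correlation-module object, and `networkMembers()` the member
#' subsets of a (qualified) module.
#'
#' @param x an object of the documented class.
#' @param ... unused.
#' @return See each accessor's description.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("markerNames", function(x) standardGeneric("markerNames"))
#' @rdname accessors
#' @export
setGeneric("lineageSignatures", function(x) standardGeneric("lineageSignatures"))
#' @rdname accessors
#' @export
setGeneric("cellExprs", function(x) standardGeneric("cellExprs"))
#' @rdname accessors
#' @export
setGeneric("cellData", function(x) standardGeneric("cellData"))
#' @rdname accessors
#' @export
setGeneric("sampleData", function(x) standardGeneric("sampleData"))
#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))
#' @rdname accessors
#' @export
setGeneric("subsetCatalog", function(x) standardGeneric("subsetCatalog"))
#' @rdname accessors
#' @export
setGeneric("freqValues", function(x) standardGeneric("freqValues"))
#' @rdname accessors
#' @export
setGeneric("freqMode", function(x) standardGeneric("freqMode"))
#' @rdname accessors
#' @export
setGeneric("rhoMatrix", function(x) standardGeneric("rhoMatrix"))
#' @rdname accessors
#' @export
setGeneric("moduleAssignments", function(x) standardGeneric("moduleAssignments"))
#' @rdname accessors
#' @export
setGeneric("moduleStats", function(x) standardGeneric("moduleStats"))
#' @rdname accessors
#' @param module module index or semantic label (e.g. `"network2"`).
#' @export
setGeneric("networkMembers", function(x, module) standardGeneric("networkMembers"))

#' @rdname accessors
setMethod("markerNames", "MarkerPanel", function(x) x@markers)
#' @rdname accessors
setMethod("markerNames", "CytoStudy", function(x) x@panel@markers)
#' @rdname accessors
setMethod("markerNames", "GeneratorConfig", function(x) x@panel@markers)
#' @rdname accessors
setMethod("lineageSignatures", "MarkerPanel", function(x) x@signatures)
#' @rdname accessors
setMethod("cellExprs", "CytoStudy", function(x) x@exprs)
#' @rdname accessors
setMethod("cellData", "CytoStudy", function(x) x@cellData)
#' @rdname accessors
setMethod("sampleData", "CytoStudy", function(x) x@samples)
#' @rdname accessors
setMethod("groundTruth", "CytoStudy", function(x) x@truth)
#' @rdname accessors
setMethod("subsetCatalog", "GeneratorConfig", function(x) x@subsets)
#' @rdname accessors
setMethod("subsetCatalog", "CytoStudy", function(x) x@truth$subsets)
#' @rdname accessors
setMethod("sampleData", "FrequencyMatrix",
          function(x) SummarizedExperiment::colData(x))
#' @rdname accessors
setMethod("freqValues", "FrequencyMatrix",
          function(x) t(SummarizedExperiment::assay(x, "freq")))
#' @rdname accessors
setMethod("freqMode", "FrequencyMatrix",
          function(x) S4Vectors::metadata(x)$mode)
#' @rdname accessors
setMethod("rhoMatrix", "CorrelationModules", function(x) x@rho)
#' @rdname accessors
setMethod("moduleAssignments", "CorrelationModules", function(x) x@modules)
#' @rdname accessors
setMethod("moduleStats", "CorrelationModules", function(x) x@moduleStats)
#' @rdname accessors
setMethod("networkMembers", "CorrelationModules", function(x, module) {
    st <- x@moduleStats
    if (is.character(module)) {
        if (!"label" %in% colnames(st) || !module %in% st$label)
            stop("no module labelled '", module, "'")
        module <- st$module[match(module, st$label)]
    }
    names(x@modules)[x@modules == module]
})

setMethod("show", "MarkerPanel", function(object) {
    cat("MarkerPanel with", length(object@markers), "markers and",
        length(object@signatures), "lineage signatures\n")
    cat("  markers:", paste(utils::head(object@markers, 8), collapse = ", "),
        "...\n")
})

setMethod("show", "GeneratorConfig", function(object) {
    cat("GeneratorConfig (", object@cohort, " cohort)\n", sep = "")
    cat("  ", nrow(object@subsets), " subsets, ",
        length(object@panel@markers), " markers\n", sep = "")
    cat("  subjects:", paste(names(object@nSubjects), object@nSubjects,
                             sep = "=", collapse = ", "), "\n")
    cat("  mean cells/sample:", paste(names(object@cellsPerSample),
                                      object@cellsPerSample, sep = "=",
                                      collapse = ", "), "\n")
})

setMethod("show", "CytoStudy", function(object) {
    n <- if (is.null(object@exprs)) 0L else nrow(object@exprs)
    cat("CytoStudy:", nrow(object@samples), "samples,",
        if (n) paste(n, "cells x", ncol(object@exprs), "markers")
        else "composition-only (no per-cell data)", "\n")
    tab <- table(object@samples$tissue)
    cat("  tissues:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "FrequencyMatrix", function(object) {
    cat("FrequencyMatrix:", ncol(object), "samples x", nrow(object),
        "subsets (mode:", S4Vectors::metadata(object)$mode, ")\n")
})

setMethod("show", "CorrelationModules", function(object) {
    st <- object@moduleStats
    cat("CorrelationModules over", nrow(object@rho), "subsets:",
        nrow(st), "modules,", sum(st$isNetwork), "qualified networks\n")
    for (i in seq_len(nrow(st))) {
        cat(sprintf("  module %d: %d members, mean rho %.2f%s%s\n",
                    st$module[i], st$size[i], st$meanRho[i],
                    if (st$isNetwork[i]) " [network]" else "",
                    if ("label" %in% colnames(st) && !is.na(st$label[i]))
                        paste0(" <", st$label[i], ">") else ""))
    }
})

setMethod("show", "LDAModel", function(object) {
    cat("LDAModel:", length(object@classes), "classes,",
        length(object@markers), "markers, epsReg =",
        format(object@epsReg, digits = 3), "\n")
})

setMethod("show", "TransferResult", function(object) {
    cat(sprintf("TransferResult: %d cells, tau = %g, matched %.1f%%\n",
                length(object@predicted), object@tau, object@matchedFraction))
})

setMethod("show", "EmbeddingResult", function(object) {
    cat("EmbeddingResult (", object@method, "): ", nrow(object@coords),
        " samples\n", sep = "")
})
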