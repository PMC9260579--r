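#' @import methods
#' @importClassesFrom S4Vectors DFrame
NULL

#' MarkerPanel: an antibody panel with lineage gating signatures
#'
#' A panel is the ordered set of marker (antibody target) names measured per
#' cell, on the arcsinh scale, together with marker-based signatures for the
#' six major immune lineages (CD4 T, CD8 T, TCRgd T, ILC/NK, B,
#' myeloid/granulocyte). A signature is a list with `high` and `low` marker
#' sets; a cell's lineage score is the mean of its `high` markers minus the
#' mean of its `low` markers.
#'
#' @slot markers character vector of unique marker names.
#' @slot signatures named list (one entry per lineage, in tie-break order);
#'   each element is `list(high = <chr>, low = <chr>)`.
#' @export
setClass("MarkerPanel", representation(
    markers = "character",
    signatures = "list"
))

setValidity("MarkerPanel", function(object) {
    msg <- NULL
    if (anyDuplicated(object@markers))
        msg <- c(msg, "marker names must be unique")
    sig <- unlist(lapply(object@signatures, unlist), use.names = FALSE)
    if (!all(sig %in% object@markers))
        msg <- c(msg, "every signature marker must be in the panel")
    if (length(object@signatures) &&
        (is.null(names(object@signatures)) || anyDuplicated(names(object@signatures))))
        msg <- c(msg, "signatures must be uniquely named by lineage")
    if (is.null(msg)) TRUE else msg
})

#' GeneratorConfig: full specification of a synthetic study
#'
#' Holds the marker panel, the subset catalogue (identity, lineage, module
#' membership, inflammation effect flags), per-subset arcsinh mean/sd
#' expression profiles, per-tissue baseline log-abundances, cohort layout and
#' all composition-model parameters. Created by [defaultConfig()].
#'
#' @slot cohort `"primary"` or `"validation"`.
#' @slot panel a [MarkerPanel-class].
#' @slot subsets `DFrame` with columns `subset_id`, `lineage`, `module`
#'   (`network1`, `network2`, `network3` or `none`), `effect`
#'   (`up_in_inflamed`, `down_in_inflamed`, `null`) and `loading`.
#' @slot means,sds numeric matrices (subsets x markers), arcsinh scale.
#' @slot baselines numeric matrix (subsets x tissues `ileum`,`colon`,`blood`)
#'   of baseline log-abundances.
#' @slot nSubjects named integer, subjects per diagnosis group.
#' @slot cellsPerSample named numeric, mean acquired cells per tissue.
#' @slot sigmaSubj,sigmaMod,sigmaNoise positive sds of the subject random
#'   effect, module latent factor, and independent log-abundance noise.
#' @slot deltaEffect log-scale abundance shift applied to effect-flagged
#'   subsets in inflamed samples.
#' @slot deltaFactor mean shift of the module latent factors in inflamed
#'   samples (+ for network2, - for network1).
#' @slot deltaHigh extra network2 shift for the designated high-network2
#'   patient subgroup; @slot highNetwork2Fraction its fraction of IBD subjects.
#' @slot deltaBloodSpike blood log-abundance boost of the HLA-DR+CD38+ EM CD4
#'   subset in IBD subjects.
#' @slot nInternalControls replicate internal-control blood samples.
#' @slot batchShift additive arcsinh shift applied to all marker means
#'   (cohort batch effect; 0 by default).
#' @export
setClass("GeneratorConfig", representation(
    cohort = "character",
    panel = "MarkerPanel",
    subsets = "DFrame",
    means = "matrix",
    sds = "matrix",
    baselines = "matrix",
    nSubjects = "integer",
    cellsPerSample = "numeric",
    sigmaSubj = "numeric",
    sigmaMod = "numeric",
    sigmaNoise = "numeric",
    deltaEffect = "numeric",
    deltaFactor = "numeric",
    deltaHigh = "numeric",
    highNetwork2Fraction = "numeric",
    deltaBloodSpike = "numeric",
    nInternalControls = "integer",
    batchShift = "numeric"
))

setValidity("GeneratorConfig", function(object) {
    msg <- NULL
    ids <- object@subsets$subset_id
    if (anyDuplicated(ids)) msg <- c(msg, "subset ids must be unique")
    if (!all(rownames(object@means) == ids) || !all(rownames(object@sds) == ids) ||
        !all(rownames(object@baselines) == ids))
        msg <- c(msg, "means/sds/baselines rows must match subset ids")
    if (!all(colnames(object@means) %in% object@panel@markers))
        msg <- c(msg, "mean matrix columns must be panel markers")
    if (any(object@sds <= 0)) msg <- c(msg, "all expression sds must be positive")
    if (any(object@means < 0 | object@means > 6))
        msg <- c(msg, "arcsinh means must lie in [0, 6]")
    if (any(c(object@sigmaSubj, object@sigmaMod, object@sigmaNoise) < 0))
        msg <- c(msg, "composition sd parameters must be >= 0")
    if (any(object@cellsPerSample < 100))
        msg <- c(msg, "cells per sample must be >= 100")
    if (!all(object@subsets$module %in% c("network1", "network2", "network3", "none")))
        msg <- c(msg, "unknown module label")
    if (!all(object@subsets$effect %in% c("up_in_inflamed", "down_in_inflamed", "null")))
        msg <- c(msg, "unknown effect label")
    if (is.null(msg)) TRUE else msg
})

#' CytoStudy: per-cell marker data plus sample metadata and ground truth
#'
#' The central data container for a (synthetic or ingested) study. Cells are
#' rows of `exprs`; `cellData` carries per-cell sample assignment and, when
#' available, the true subset label. For composition-only simulations
#' (`markers = FALSE`) `exprs`/`cellData` are `NULL` and only per-sample
#' subset counts exist in the ground truth.
#'
#' @slot exprs numeric matrix (cells x markers, arcsinh scale) or `NULL`.
#' @slot cellData `DFrame` with columns `sample_id`, and for synthetic data
#'   `subset` and `lineage` (true labels); or `NULL`.
#' @slot samples `DFrame` of per-sample metadata (`sample_id`, `subject_id`,
#'   `cohort`, `tissue`, `status`, `diagnosis`, `is_internal_control`,
#'   `high_network2`, `n_cells`).
#' @slot panel the [MarkerPanel-class] used.
#' @slot truth list with `probs` (samples x subsets pre-sampling proportions),
#'   `counts` (realised multinomial counts) and `subsets` (catalogue), or an
#'   empty list for ingested data without ground truth.
#' @export
setClass("CytoStudy", representation(
    exprs = "ANY",
    cellData = "ANY",
    samples = "DFrame",
    panel = "MarkerPanel",
    truth = "list"
))

setValidity("CytoStudy", function(object) {
    msg <- NULL
    if (!is.null(object@exprs)) {
        if (is.null(object@cellData) || nrow(object@exprs) != nrow(object@cellData))
            msg <- c(msg, "exprs and cellData must describe the same cells")
        if (anyNA(object@exprs)) msg <- c(msg, "exprs must not contain NA")
        if (!all(colnames(object@exprs) %in% object@panel@markers))
            msg <- c(msg, "exprs columns must be panel markers")
        if (!all(object@cellData$sample_id %in% object@samples$sample_id))
            msg <- c(msg, "cellData sample ids must appear in sample metadata")
    }
    if (anyDuplicated(object@samples$sample_id))
        msg <- c(msg, "sample ids must be unique")
    if (length(object@truth)) {
        p <- object@truth$probs
        if (!is.null(p) && any(abs(rowSums(p) - 1) > 1e-9))
            msg <- c(msg, "true per-sample frequencies must sum to 1")
    }
    if (is.null(msg)) TRUE else msg
})

#' FrequencyMatrix: per-sample subset frequencies
#'
#' A [SummarizedExperiment::SummarizedExperiment-class] whose single `"freq"`
#' assay holds subset-by-sample percentages, with the sample metadata in
#' `colData` and the denominator mode (`"total_CD45"` or `"lineage"`) in
#' `metadata(x)$mode`. Under `total_CD45`, each sample's column sums to 100.
#'
#' @export
setClass("FrequencyMatrix", contains = "SummarizedExperiment")

setValidity("FrequencyMatrix", function(object) {
    msg <- NULL
    mode <- S4Vectors::metadata(object)$mode
    if (is.null(mode) || !mode %in% c("total_CD45", "lineage"))
        msg <- c(msg, "metadata(x)$mode must be 'total_CD45' or 'lineage'")
    f <- SummarizedExperiment::assay(object, "freq")
    if (any(f < -1e-9 | f > 100 + 1e-6)) msg <- c(msg, "frequencies must be in [0, 100]")
    ## predicted frequencies with a rejection option keep rejected cells in
    ## the denominator, so their columns may sum below 100
    partial <- identical(S4Vectors::metadata(object)$denominator, "all_cells")
    if (identical(mode, "total_CD45") && ncol(f) && !partial &&
        any(abs(colSums(f) - 100) > 1e-6))
        msg <- c(msg, "total_CD45 frequencies must sum to 100 per sample")
    if (is.null(msg)) TRUE else msg
})

#' SubsetLabeling: two-level cell annotation
#'
#' @slot lineage per-cell lineage assignment.
#' @slot subset per-cell subset id (`<lineage>_<k>` by decreasing size).
#' @slot hierarchy named character mapping subset id to lineage.
#' @slot fits list of per-lineage mixture fit summaries (selected k, BIC).
#' @export
setClass("SubsetLabeling", representation(
    lineage = "character",
    subset = "character",
    hierarchy = "character",
    fits = "list"
))

setValidity("SubsetLabeling", function(object) {
    msg <- NULL
    if (length(object@lineage) != length(object@subset))
        msg <- c(msg, "lineage and subset must have one entry per cell")
    lab <- !is.na(object@subset)
    if (!all(object@subset[lab] %in% names(object@hierarchy)))
        msg <- c(msg, "every subset id must appear in the hierarchy map")
    if (any(object@hierarchy[object@subset[lab]] != object@lineage[lab]))
        msg <- c(msg, "subset ids must map to their cells' lineage")
    if (is.null(msg)) TRUE else msg
})

#' CorrelationModules: a Spearman co-abundance network with modules
#'
#' @slot rho symmetric Spearman correlation matrix over subsets (diagonal 1).
#' @slot tree the average-linkage `hclust` tree on distance `1 - rho`.
#' @slot modules named integer: module index per subset.
#' @slot moduleStats `DFrame` with per-module `module`, `size`, `meanRho`,
#'   `isNetwork` and (when differential-abundance results are supplied)
#'   a semantic `label` (`network1` depleted / `network2` enriched /
#'   `network3`...).
#' @slot mMin,rhoMin qualification parameters (minimum membership, minimum
#'   mean within-module pairwise correlation).
#' @export
setClass("CorrelationModules", representation(
    rho = "matrix",
    tree = "ANY",
    modules = "integer",
    moduleStats = "DFrame",
    mMin = "integer",
    rhoMin = "numeric"
))

setValidity("CorrelationModules", function(object) {
    msg <- NULL
    if (!isSymmetric(unname(object@rho), tol = 1e-8))
        msg <- c(msg, "rho must be symmetric")
    if (any(abs(object@rho) > 1 + 1e-8)) msg <- c(msg, "rho entries must be in [-1, 1]")
    if (length(object@modules) != nrow(object@rho))
        msg <- c(msg, "one module assignment per subset required")
    ok <- object@moduleStats$size >= object@mMin &
        object@moduleStats$meanRho >= object@rhoMin
    if (!identical(as.logical(ok), as.logical(object@moduleStats$isNetwork)))
        msg <- c(msg, "isNetwork flags must follow the mMin/rhoMin rule")
    if (is.null(msg)) TRUE else msg
})

#' DAResult: per-subset differential-abundance results
#'
#' A `DFrame` with columns `subset_id`, `direction`, `t`, `p`, `q` and
#' `significant`, plus the testing parameters in `metadata()`.
#' @export
setClass("DAResult", contains = "DFrame")

#' LDAModel: linear discriminant classifier with shared covariance
#'
#' Gaussian classes with per-class means, one pooled within-class covariance
#' (ridge-regularised), and prior probabilities estimated from class sizes.
#'
#' @slot classes class (subset) names.
#' @slot means numeric matrix (classes x markers).
#' @slot sigma pooled within-class covariance plus `epsReg` on the diagonal.
#' @slot priors class priors (sum to 1).
#' @slot epsReg ridge added to the covariance diagonal.
#' @slot markers marker names the model was trained on.
#' @export
setClass("LDAModel", representation(
    classes = "character",
    means = "matrix",
    sigma = "matrix",
    priors = "numeric",
    epsReg = "numeric",
    markers = "character"
))

setValidity("LDAModel", function(object) {
    msg <- NULL
    if (abs(sum(object@priors) - 1) > 1e-8) msg <- c(msg, "priors must sum to 1")
    ev <- tryCatch(min(eigen(object@sigma, symmetric = TRUE,
                             only.values = TRUE)$values),
                   error = function(e) NA_real_)
    if (is.na(ev) || ev <= 0)
        msg <- c(msg, "regularised covariance must be positive definite")
    if (is.null(msg)) TRUE else msg
})

#' TransferResult: label-transfer predictions under a rejection option
#'
#' @slot predicted per-cell predicted class, `NA` where rejected.
#' @slot posterior per-cell maximum posterior probability.
#' @slot tau the rejection threshold used (posterior >= tau - 1e-6 accepts).
#' @slot rejected logical per cell.
#' @slot outlier logical per cell (Mahalanobis chi-squared cut) or `NULL`.
#' @slot freq predicted per-sample [FrequencyMatrix-class] (denominator: all
#'   classified-or-rejected cells) or `NULL`.
#' @slot matchedFraction percent of cells not rejected.
#' @export
setClass("TransferResult", representation(
    predicted = "character",
    posterior = "numeric",
    tau = "numeric",
    rejected = "logical",
    outlier = "ANY",
    freq = "ANY",
    matchedFraction = "numeric"
))

#' EmbeddingResult: a 2-D sample embedding
#'
#' @slot coords samples x 2 coordinates (centred).
#' @slot method `"tsne"` or `"pca"`.
#' @slot seed RNG seed used (t-SNE).
#' @slot params method parameters; for PCA includes `explainedVar` and the
#'   full score matrix, for t-SNE the perplexity.
#' @slot centroids per-group centroid coordinates or `NULL`.
#' @export
setClass("EmbeddingResult", representation(
    coords = "matrix",
    method = "character",
    seed = "numeric",
    params = "list",
    centroids = "ANY"
))
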