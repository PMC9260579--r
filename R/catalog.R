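#' @include panel.R
NULL

## ---- designed subset catalogue -------------------------------------------
##
## 44 subsets across the six lineages. Each entry: lineage, correlation-module
## membership, inflammation effect flag, marker tweaks on top of the lineage
## base profile, and per-tissue baseline abundance shares (arbitrary mass on
## the natural scale; the composition model works with their logs and a
## softmax renormalisation, so only ratios matter).
##
## module sizes: network1 = 11 (10 down_in_inflamed), network2 = 21
## (11 up_in_inflamed), network3 = 9 blood-like subsets, none = 3.

.lineageBase <- list(
    CD4T = c(CD3 = 4, CD4 = 4, CD5 = 3.8, CD7 = 3.5, CD28 = 3, CD127 = 3),
    CD8T = c(CD3 = 4, CD8 = 4, CD5 = 3.5, CD7 = 4, CD28 = 2.5, CD127 = 2.5),
    TCRgd = c(CD3 = 4, TCRgd = 4, CD7 = 4, CD5 = 3, CD28 = 2),
    ILC = c(CD7 = 4, CD122 = 2),
    B = c(CD19 = 4, CD20 = 4, "HLA-DR" = 4, CD45RA = 3),
    Myeloid = c(CD11b = 2))

.subsetSpecs <- list(
 ## CD4 T (9)
 list("CD4_T_naive", "CD4T", "network3", "null",
      c(CD45RA = 4, CD27 = 4, CCR7 = 4), blood = 14),
 list("CD4_T_CM", "CD4T", "network3", "null",
      c(CD45RO = 4, CD27 = 4, CCR7 = 3.8), blood = 8),
 list("CD4_T_EM", "CD4T", "network2", "null",
      c(CD45RO = 4, CD27 = 0.5), blood = 6),
 list("CD4_T_EM_HLADR_CD38", "CD4T", "network2", "up_in_inflamed",
      c(CD45RO = 4, CD27 = 0.5, "HLA-DR" = 4, CD38 = 4, "PD-1" = 2,
        CD25 = 1.5), blood = 0.15),
 list("CD4_T_Treg", "CD4T", "network2", "up_in_inflamed",
      c(CD45RO = 4, CD25 = 4.2, CD127 = 0.3, CD38 = 1.5), blood = 1.5),
 list("CD4_T_EM_CD56", "CD4T", "network1", "down_in_inflamed",
      c(CD45RO = 4, CD27 = 0.5, CD56 = 3.5, KLRG1 = 3), blood = 0.5),
 list("CD4_T_EM_CCR6_CD161", "CD4T", "network2", "null",
      c(CD45RO = 4, CD27 = 0.5, CCR6 = 4, CD161 = 4), blood = 3),
 list("CD4_T_EM_PD1", "CD4T", "network2", "up_in_inflamed",
      c(CD45RO = 4, CD27 = 0.5, "PD-1" = 4, CD38 = 2), blood = 0.3),
 list("CD4_T_EM_CCR6_CD27", "CD4T", "none", "null",
      c(CD45RO = 4, CCR6 = 4, CD27 = 4), blood = 2),
 ## CD8 T (8)
 list("CD8_T_naive", "CD8T", "network3", "null",
      c(CD45RA = 4, CD27 = 4, CCR7 = 4), blood = 10),
 list("CD8_T_CM", "CD8T", "network3", "null",
      c(CD45RO = 4, CD27 = 4, CCR7 = 3.8), blood = 4),
 list("CD8_T_EM_CD103", "CD8T", "network2", "null",
      c(CD45RO = 4, CD103 = 3.5), blood = 0.3),
 list("CD8_T_EM_PD1", "CD8T", "network2", "up_in_inflamed",
      c(CD45RO = 4, "PD-1" = 4, CD38 = 2.5), blood = 0.5),
 list("CD8_T_EM_CD56", "CD8T", "network1", "down_in_inflamed",
      c(CD45RO = 4, CD56 = 3.5, KLRG1 = 3), blood = 1.5),
 list("CD8_T_TEMRA", "CD8T", "network3", "null",
      c(CD45RA = 4, KLRG1 = 3.2, CD28 = 0.3), blood = 4),
 list("CD8_T_EM_CD161", "CD8T", "network1", "null",
      c(CD45RO = 4, CD161 = 4, CCR6 = 3), blood = 1.5),
 list("CD8_T_EM_HLADR_CD38", "CD8T", "network2", "up_in_inflamed",
      c(CD45RO = 4, "HLA-DR" = 4, CD38 = 4), blood = 0.15),
 ## TCRgd T (7)
 list("gd_T_naive", "TCRgd", "network3", "null",
      c(CD45RA = 4, CD27 = 4, CCR7 = 3.5), blood = 1.5),
 list("gd_T_CD27_mem", "TCRgd", "network2", "up_in_inflamed",
      c(CD45RO = 3.8, CD27 = 4), blood = 1),
 list("gd_T_CD56", "TCRgd", "network1", "down_in_inflamed",
      c(CD45RO = 3.8, CD56 = 3.5, KLRG1 = 2.5), blood = 0.5),
 list("gd_T_CD161", "TCRgd", "network1", "down_in_inflamed",
      c(CD45RO = 3.8, CD161 = 4, CCR6 = 3), blood = 0.5),
 list("gd_T_CD8", "TCRgd", "network2", "null",
      c(CD45RO = 3.8, CD8 = 2.8), blood = 0.5),
 list("gd_T_PD1", "TCRgd", "network2", "up_in_inflamed",
      c(CD45RO = 3.8, "PD-1" = 4, CD38 = 2.5), blood = 0.2),
 list("gd_T_TEMRA", "TCRgd", "network1", "down_in_inflamed",
      c(CD45RA = 4, KLRG1 = 3), blood = 0.5),
 ## ILC / NK (8)
 list("NK_CD16", "ILC", "network2", "up_in_inflamed",
      c(CD56 = 3, CD16 = 4, NKp46 = 4, CD122 = 3), blood = 8),
 list("NK_CD56bright", "ILC", "network2", "null",
      c(CD56 = 5, NKp46 = 4, CD122 = 3, CD127 = 1.5), blood = 1),
 list("NK_CD27", "ILC", "network2", "null",
      c(CD56 = 3.5, CD27 = 3.5, NKp46 = 4, CD122 = 3), blood = 0.8),
 list("NK_CD38", "ILC", "network2", "up_in_inflamed",
      c(CD56 = 3, NKp46 = 4, CD38 = 4, "HLA-DR" = 2, CD122 = 3),
      blood = 0.5),
 list("ILC_Lin_neg", "ILC", "network1", "down_in_inflamed",
      c(CD127 = 3.5, CD161 = 3.5, CD117 = 3), blood = 0.1),
 list("int_ILC", "ILC", "network1", "down_in_inflamed",
      c(CD127 = 2, CD161 = 3.5, CD56 = 2, CD117 = 1.2), blood = 0.1),
 list("ILC2", "ILC", "network1", "down_in_inflamed",
      c(CRTH2 = 4, CD127 = 4, CD161 = 2.5), blood = 0.2),
 list("ILC3", "ILC", "network1", "down_in_inflamed",
      c(CD117 = 4, CD127 = 4, CCR6 = 3, NKp46 = 2, CD161 = 2), blood = 0.1),
 ## B (5)
 list("B_naive", "B", "network3", "null",
      c(IgM = 4, CD38 = 1), blood = 6),
 list("B_memory", "B", "network3", "null",
      c(CD27 = 4, IgM = 1, CD45RO = 1), blood = 3),
 list("B_transitional", "B", "network3", "null",
      c(IgM = 4, CD38 = 3.5, CD5 = 2), blood = 1),
 list("B_plasma", "B", "none", "null",
      c(CD38 = 5, CD27 = 4, CD20 = 0.3, CD19 = 2.5, "HLA-DR" = 2,
        IgM = 0.5), blood = 0.5),
 list("B_CD11c", "B", "none", "null",
      c(CD11c = 3, CD27 = 1, CD45RA = 3.5, IgM = 1, CD38 = 0.5),
      blood = 0.5),
 ## Myeloid / granulocyte (7)
 list("My_neutrophil", "Myeloid", "network2", "up_in_inflamed",
      c(CD16 = 4, CD15 = 4, CD11b = 4, CD45 = 3.2, "HLA-DR" = 0.2),
      blood = 0.3),
 list("My_eosinophil", "Myeloid", "network1", "down_in_inflamed",
      c(CD15 = 4, CD11b = 3.5, CRTH2 = 3, CD11c = 1), blood = 0.3),
 list("My_mono_classical", "Myeloid", "network2", "up_in_inflamed",
      c(CD14 = 4, CD11b = 4, CD11c = 3.5, "HLA-DR" = 3.5, CD38 = 2.5),
      blood = 10),
 list("My_mono_nonclassical", "Myeloid", "network2", "null",
      c(CD16 = 4, CD14 = 1, CD11c = 3.5, "HLA-DR" = 3.5, CD11b = 1.5,
        CD38 = 1), blood = 2),
 list("My_cDC", "Myeloid", "network2", "null",
      c(CD11c = 4, "HLA-DR" = 5, CD11b = 0.5), blood = 1),
 list("My_pDC", "Myeloid", "network2", "null",
      c(CD123 = 4, "HLA-DR" = 4, CD11c = 1.5, CD4 = 0.8, CD11b = 0.3),
      blood = 1.5),
 list("My_macrophage", "Myeloid", "network2", "null",
      c(CD14 = 3.5, CD11c = 3, "HLA-DR" = 4, CD103 = 2.5, CD11b = 1.5),
      blood = 0.1))

## validation-panel-only markers: subset-specific means for the 3 extras
.extraMarkerMeans <- list(
    CD66b = c(My_neutrophil = 4, My_eosinophil = 3.5),
    CD1c = c(My_cDC = 3.5),
    CD163 = c(My_macrophage = 3.5))

## healthy-intestine baseline share by module role (percent-like mass)
.intestShareByRole <- function(module, effect) {
    if (module == "network1") 2.2
    else if (module == "network2" && effect == "up_in_inflamed") 0.5
    else if (module == "network2") 1.3
    else if (module == "network3") 1.2
    else 4.0
}

## small deterministic tissue offsets (log scale) so that noninflamed ileum
## and colon have distinguishable compositions
.ileumOffsets <- c(CD8_T_EM_CD103 = 0.5, CD8_T_EM_CD56 = 0.3,
                   My_eosinophil = 0.4, gd_T_CD161 = 0.3,
                   CD8_T_EM_CD161 = 0.4)
.colonOffsets <- c(CD4_T_Treg = 0.3, B_naive = 0.3, B_memory = 0.3,
                   CD4_T_EM_CCR6_CD161 = 0.3, My_mono_classical = 0.2)

## Verify the separability guarantee: every pair of subset mean vectors must
## differ by >= minDiff arcsinh units in >= minMarkers markers.
checkSeparability <- function(means, minMarkers = 2L, minDiff = 1.5) {
    ids <- rownames(means)
    bad <- character()
    for (i in seq_len(nrow(means) - 1L)) {
        d <- abs(sweep(means[-seq_len(i), , drop = FALSE], 2L, means[i, ]))
        n <- rowSums(d >= minDiff)
        if (any(n < minMarkers))
            bad <- c(bad, paste(ids[i], ids[-seq_len(i)][n < minMarkers],
                                sep = " ~ "))
    }
    bad
}

#' Default synthetic-study configuration
#'
#' Returns the fully specified study design emulated by the generator: a
#' 36-marker panel (39 for the validation cohort), 44 designed immune subsets
#' across six lineages with arcsinh mean/sd expression profiles separated by
#' at least 1.5 arcsinh units in at least two markers for every pair, three
#' latent co-abundance modules (network1: 11 members of which 10 are depleted
#' in inflamed samples; network2: 21 members of which 11 are enriched;
#' network3: 9 blood-like subsets) plus 3 unassigned subsets, cohort sizes
#' (primary: 11 control / 13 CD / 10 UC subjects; validation: 15 control /
#' 10 CD / 9 UC), three intestinal samples plus one blood sample per subject,
#' internal-control blood replicates, and the logistic-normal composition
#' model parameters.
#'
#' @param cohort `"primary"` or `"validation"`.
#' @return a [GeneratorConfig-class]; deterministic for a given cohort.
#' @examples
#' cfg <- defaultConfig("primary")
#' nrow(subsetCatalog(cfg))  # 44
#' @export
defaultConfig <- function(cohort = c("primary", "validation")) {
    cohort <- match.arg(cohort)
    panel <- defaultPanel(cohort)
    markers <- panel@markers
    ids <- vapply(.subsetSpecs, `[[`, "", 1L)
    K <- length(ids)

    ## background (unstained) channels sit at 0.45 arcsinh units with a
    ## tight spread, three sd above the zero truncation bound, so the
    ## truncated draws stay near-Gaussian
    means <- matrix(0.45, K, length(markers), dimnames = list(ids, markers))
    means[, "CD45"] <- 4
    baselines <- matrix(NA_real_, K, 3L,
                        dimnames = list(ids, c("ileum", "colon", "blood")))
    subs <- S4Vectors::DataFrame(
        subset_id = ids,
        lineage = vapply(.subsetSpecs, `[[`, "", 2L),
        module = vapply(.subsetSpecs, `[[`, "", 3L),
        effect = vapply(.subsetSpecs, `[[`, "", 4L),
        loading = 1.0,
        noise_mult = 1.0)
    ## the large heterogeneous module and the blood-like module get stronger
    ## factor loadings: their members are rarer (more counting noise), so a
    ## stronger latent factor is needed for comparable co-abundance signal
    subs$loading[subs$module == "network2"] <- 1.25
    subs$loading[subs$module == "network3"] <- 1.2
    ## module-free subsets share only a weak residual factor (within-module
    ## correlation ~0.15, below qualification) and fluctuate with larger
    ## idiosyncratic variance, so they form a detected-but-unqualified
    ## residual cluster
    subs$loading[subs$module == "none"] <- 0.7
    subs$noise_mult[subs$module == "none"] <- 2.2

    for (i in seq_len(K)) {
        sp <- .subsetSpecs[[i]]
        base <- .lineageBase[[sp[[2L]]]]
        means[i, names(base)] <- base
        means[i, names(sp[[5L]])] <- sp[[5L]]
        share <- .intestShareByRole(sp[[3L]], sp[[4L]])
        baselines[i, "ileum"] <- log(share)
        baselines[i, "colon"] <- log(share)
        baselines[i, "blood"] <- log(sp$blood)
    }
    baselines[names(.ileumOffsets), "ileum"] <-
        baselines[names(.ileumOffsets), "ileum"] + .ileumOffsets
    baselines[names(.colonOffsets), "colon"] <-
        baselines[names(.colonOffsets), "colon"] + .colonOffsets
    for (m in intersect(names(.extraMarkerMeans), markers)) {
        v <- .extraMarkerMeans[[m]]
        means[names(v), m] <- v
    }
    ## no designed mean below the background floor
    means <- pmax(means, 0.45)

    bad <- checkSeparability(means[, intersect(colnames(means),
                                               defaultPanel()@markers)])
    stopIfNot(length(bad) == 0L,
              paste("subset separability violated:", paste(bad, collapse = "; ")))

    sds <- matrix(0.35, K, length(markers), dimnames = dimnames(means))
    sds[means < 1] <- 0.15
    nSubjects <- if (cohort == "primary")
        c(control = 11L, CD = 13L, UC = 10L)
    else c(control = 15L, CD = 10L, UC = 9L)

    new("GeneratorConfig",
        cohort = cohort, panel = panel, subsets = subs, means = means,
        sds = sds, baselines = baselines, nSubjects = nSubjects,
        cellsPerSample = c(ileum = 2000, colon = 1000, blood = 5000),
        sigmaSubj = 0.4, sigmaMod = 0.7, sigmaNoise = 0.4,
        deltaEffect = 1.0, deltaFactor = 0.0, deltaHigh = 0.5,
        highNetwork2Fraction = 0.45, deltaBloodSpike = 1.2,
        nInternalControls = 7L, batchShift = 0.0)
}
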