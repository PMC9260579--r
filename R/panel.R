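#' @include AllClasses.R
NULL

## The six major immune lineages in fixed tie-break order.
LINEAGES <- c("CD4T", "CD8T", "TCRgd", "ILC", "B", "Myeloid")

#' Construct a marker panel
#'
#' @param markers character vector of unique marker names.
#' @param signatures named list of lineage signatures, each
#'   `list(high = <chr>, low = <chr>)`; names give the tie-break order used by
#'   [assignLineages()].
#' @return a [MarkerPanel-class].
#' @examples
#' markerPanel(c("CD45", "CD3"), list(T = list(high = "CD3", low = character())))
#' @export
markerPanel <- function(markers, signatures = list()) {
    new("MarkerPanel", markers = as.character(markers), signatures = signatures)
}

#' The default 36-antibody CyTOF panel (39 for the validation cohort)
#'
#' Markers resolving the six major immune lineages plus activation,
#' maturation and trafficking markers, on the arcsinh scale. The validation
#' panel appends three extra antibodies (CD66b, CD1c, CD163) used to resolve
#' granulocytes and myeloid subtypes.
#'
#' @param cohort `"primary"` (36 markers) or `"validation"` (39).
#' @return a [MarkerPanel-class].
#' @examples
#' length(markerNames(defaultPanel()))            # 36
#' length(markerNames(defaultPanel("validation"))) # 39
#' @export
defaultPanel <- function(cohort = c("primary", "validation")) {
    cohort <- match.arg(cohort)
    markers <- c(
        "CD45", "CD3", "CD4", "CD8", "TCRgd", "CD7", "CD127", "CD161",
        "CD56", "CD27", "CD45RA", "CD45RO", "CCR7", "CCR6", "CD25", "CD28",
        "CD38", "HLA-DR", "PD-1", "CD19", "CD11c", "CD14", "CD16", "CD15",
        "CD5", "CD20", "CD11b", "CD123", "CD34", "CD103", "CRTH2", "CD117",
        "KLRG1", "IgM", "NKp46", "CD122")
    if (cohort == "validation")
        markers <- c(markers, "CD66b", "CD1c", "CD163")
    signatures <- list(
        CD4T = list(high = c("CD3", "CD4", "CD5"),
                    low = c("CD8", "TCRgd", "CD19")),
        CD8T = list(high = c("CD3", "CD8", "CD5"),
                    low = c("CD4", "TCRgd", "CD19")),
        TCRgd = list(high = c("CD3", "TCRgd", "CD5"),
                     low = c("CD4", "CD19")),
        ILC = list(high = "CD7",
                   low = c("CD3", "CD5", "CD8", "TCRgd", "CD19", "CD14",
                           "CD15")),
        B = list(high = c("CD19", "CD20"),
                 low = c("CD3", "CD7", "CD14")),
        Myeloid = list(high = c("CD11c", "CD11b", "CD14", "CD16", "CD15",
                                "CD123", "HLA-DR"),
                       low = c("CD3", "CD19", "CD7")))
    markerPanel(markers, signatures)
}
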