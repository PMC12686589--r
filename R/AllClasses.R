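#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

## Controlled vocabularies for the study design
.LAYERS <- c("rna", "ribo", "protein")
.COMPARTMENTS <- c("TH", "SYN")
.AGE_LEVELS <- c("3w", "5m", "18m")
.AGE_DAYS <- c(`3w` = 21, `5m` = 150, `18m` = 540)
.QUADRANTS <- c("Q1", "Q2", "Q3", "Q4", "boundary")

#' OmicsLayer: one measurement layer of a compartment/age study
#'
#' An \code{OmicsLayer} holds a gene-by-sample matrix for a single
#' measurement layer -- \code{"rna"} (transcript counts), \code{"ribo"}
#' (ribosome-associated transcript counts, i.e. the sucrose-cushion
#' translatome) or \code{"protein"} (absolute intensities) -- together with
#' the sample annotation needed for compartment and age contrasts. It extends
#' \linkS4class{SummarizedExperiment}; the single assay is named
#' \code{"values"}.
#'
#' Column data must provide \code{compartment} (\code{"TH"} total homogenate
#' or \code{"SYN"} synaptosome), \code{age_group} (ordered \code{"3w"},
#' \code{"5m"}, \code{"18m"}), \code{age_days} (numeric age, strictly
#' increasing with \code{age_group}), \code{layer} (identical across
#' samples) and \code{replicate} (positive integer). Row data carry
#' \code{gene_length} (bp) for count layers; protein layers have none.
#'
#' @aliases OmicsLayer-class
#' @seealso [OmicsLayer()] for the constructor, [rpkm()],
#'   [runDifferential()], [simulateStudy()]
#' @exportClass OmicsLayer
setClass("OmicsLayer", contains = "SummarizedExperiment")

.validOmicsLayer <- function(object) {
    msg <- NULL
    cd <- colData(object)
    needed <- c("compartment", "age_group", "age_days", "layer", "replicate")
    miss <- setdiff(needed, colnames(cd))
    if (length(miss))
        return(paste("colData lacks column(s):", paste(miss, collapse = ", ")))
    if (!"values" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'values' is required")
    v <- assay(object, "values")
    if (anyNA(v))
        msg <- c(msg, "values contain NA")
    else if (any(v < 0))
        msg <- c(msg, "values must be non-negative")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "gene IDs must be unique")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "sample IDs must be unique")
    lay <- unique(as.character(cd$layer))
    if (length(lay) != 1L || !lay %in% .LAYERS)
        msg <- c(msg, sprintf("all samples must share one layer in {%s}",
                              paste(.LAYERS, collapse = ", ")))
    if (!all(as.character(cd$compartment) %in% .COMPARTMENTS))
        msg <- c(msg, "compartment must be TH or SYN")
    if (!all(as.character(cd$age_group) %in% .AGE_LEVELS))
        msg <- c(msg, sprintf("age_group must be one of {%s}",
                              paste(.AGE_LEVELS, collapse = ", ")))
    if (any(cd$age_days <= 0))
        msg <- c(msg, "age_days must be positive")
    if (any(cd$replicate < 1) || any(cd$replicate != round(cd$replicate)))
        msg <- c(msg, "replicate must be a positive integer")
    ## numeric age must increase with the ordered age label
    ag <- factor(as.character(cd$age_group), levels = .AGE_LEVELS)
    med <- tapply(cd$age_days, ag, stats::median)
    med <- med[!is.na(med)]
    if (length(med) > 1L && any(diff(med) <= 0))
        msg <- c(msg, "age_days must increase strictly with age_group")
    if (is.null(msg)) TRUE else msg
}
setValidity("OmicsLayer", .validOmicsLayer)

#' GeneSetCollection: named gene sets with a minimum-size rule
#'
#' A light container for gene sets as read from a GMT file: a named list of
#' unique gene identifiers plus the minimum set size used when filtering
#' against an analysis universe (default 5 members present in the universe).
#'
#' @aliases GeneSetCollection-class
#' @seealso [readGeneSets()], [filterGeneSets()], [enrichCollection()]
#' @exportClass GeneSetCollection
setClass("GeneSetCollection",
         representation(sets = "list", minSize = "integer"))

.validGeneSetCollection <- function(object) {
    msg <- NULL
    s <- object@sets
    if (length(s)) {
        if (is.null(names(s)) || any(!nzchar(names(s))))
            msg <- c(msg, "every set must be named")
        if (anyDuplicated(names(s)))
            msg <- c(msg, paste("duplicate set name:",
                                names(s)[duplicated(names(s))][1L]))
        if (!all(vapply(s, is.character, logical(1))))
            msg <- c(msg, "set members must be character vectors")
        if (any(vapply(s, anyDuplicated, integer(1)) > 0))
            msg <- c(msg, "set members must be unique within a set")
    }
    if (length(object@minSize) != 1L || object@minSize < 1L)
        msg <- c(msg, "minSize must be a single positive integer")
    if (is.null(msg)) TRUE else msg
}
setValidity("GeneSetCollection", .validGeneSetCollection)

#' SimStudy: a simulated soma/synapse multi-omics study
#'
#' Container returned by [simulateStudy()]: the three measurement layers
#' (each an [OmicsLayer] spanning both compartments, three ages and all
#' replicates), the per-gene ground truth table, and the parameter list that
#' generated them.
#'
#' @aliases SimStudy-class
#' @seealso [simulateStudy()], [truthLabels()], [studyLayer()]
#' @exportClass SimStudy
setClass("SimStudy",
         representation(rna = "OmicsLayer", ribo = "OmicsLayer",
                        protein = "OmicsLayer", truth = "DataFrame",
                        params = "list"))
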