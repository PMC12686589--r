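#' Construct an OmicsLayer
#'
#' Bundles a gene-by-sample value matrix with its sample annotation into an
#' [OmicsLayer-class] object. Values are raw counts for the \code{"rna"} and
#' \code{"ribo"} layers and absolute intensities for \code{"protein"}.
#'
#' @param values numeric matrix, genes in rows (rownames = gene IDs), samples
#'   in columns (colnames = sample IDs). Must be non-negative.
#' @param sampleData data.frame or DataFrame with one row per column of
#'   \code{values} (matched by \code{sample_id} or by order) providing
#'   \code{compartment}, \code{age_group} and \code{replicate};
#'   \code{age_days} is filled from the default encoding
#'   (21, 150, 540 days) when absent.
#' @param layer one of \code{"rna"}, \code{"ribo"}, \code{"protein"}.
#' @param geneLengths optional named numeric vector of gene lengths in bp
#'   (required later for RPKM on count layers; ignored for protein).
#'
#' @return an [OmicsLayer-class] object.
#' @examples
#' m <- matrix(rpois(20, 10), nrow = 5,
#'             dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
#' sd <- data.frame(sample_id = paste0("s", 1:4),
#'                  compartment = c("TH", "TH", "SYN", "SYN"),
#'                  age_group = "5m", replicate = c(1, 2, 1, 2))
#' ol <- OmicsLayer(m, sd, layer = "rna",
#'                  geneLengths = setNames(rep(1000, 5), paste0("g", 1:5)))
#' layerType(ol)
#' @export
OmicsLayer <- function(values, sampleData, layer = c("rna", "ribo", "protein"),
                       geneLengths = NULL) {
    layer <- match.arg(layer)
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    sampleData <- as.data.frame(sampleData)
    if ("sample_id" %in% colnames(sampleData)) {
        rownames(sampleData) <- sampleData$sample_id
        if (!is.null(colnames(values))) {
            miss <- setdiff(colnames(values), rownames(sampleData))
            if (length(miss))
                stop("sample(s) absent from metadata: ",
                     paste(miss, collapse = ", "))
            sampleData <- sampleData[colnames(values), , drop = FALSE]
        }
    }
    if (nrow(sampleData) != ncol(values))
        stop("sampleData must have one row per sample column")
    cd <- DataFrame(
        compartment = factor(as.character(sampleData$compartment),
                             levels = .COMPARTMENTS),
        age_group = factor(as.character(sampleData$age_group),
                           levels = .AGE_LEVELS, ordered = TRUE),
        age_days = if ("age_days" %in% colnames(sampleData))
            as.numeric(sampleData$age_days)
        else unname(.AGE_DAYS[as.character(sampleData$age_group)]),
        layer = layer,
        replicate = as.integer(sampleData$replicate),
        row.names = colnames(values))
    rd <- DataFrame(row.names = rownames(values))
    if (layer != "protein") {
        gl <- rep(NA_real_, nrow(values))
        if (!is.null(geneLengths)) {
            if (is.null(names(geneLengths)))
                stop("geneLengths must be named by gene ID")
            gl <- unname(geneLengths[rownames(values)])
        }
        rd$gene_length <- gl
    }
    se <- SummarizedExperiment(assays = list(values = values),
                               colData = cd, rowData = rd)
    new("OmicsLayer", se)
}

#' @describeIn OmicsLayer the measurement layer of the object
#'   (\code{"rna"}, \code{"ribo"} or \code{"protein"}).
#' @param object an OmicsLayer
#' @export
setMethod("layerType", "OmicsLayer", function(object)
    as.character(colData(object)$layer[1L]))

#' @describeIn OmicsLayer named vector of gene lengths (bp); all-\code{NA}
#'   when lengths were never supplied, \code{NULL} for protein layers.
#' @export
setMethod("geneLengths", "OmicsLayer", function(object) {
    rd <- rowData(object)
    if (!"gene_length" %in% colnames(rd)) return(NULL)
    stats::setNames(rd$gene_length, rownames(object))
})

setMethod("show", "OmicsLayer", function(object) {
    cd <- colData(object)
    cat(sprintf("OmicsLayer (%s): %d genes x %d samples\n",
                layerType(object), nrow(object), ncol(object)))
    cat("  compartments:", paste(levels(droplevels(cd$compartment)),
                                 collapse = ", "), "\n")
    cat("  age groups:  ", paste(levels(droplevels(cd$age_group)),
                                 collapse = ", "), "\n")
})

## logical index of samples matching the given design cells
.sampleIndex <- function(object, compartment = NULL, ageGroup = NULL,
                         replicate = NULL) {
    cd <- colData(object)
    keep <- rep(TRUE, ncol(object))
    if (!is.null(compartment))
        keep <- keep & as.character(cd$compartment) %in% compartment
    if (!is.null(ageGroup))
        keep <- keep & as.character(cd$age_group) %in% ageGroup
    if (!is.null(replicate))
        keep <- keep & cd$replicate %in% replicate
    keep
}

#' Select sample IDs by design cell
#'
#' Convenience filter returning the sample identifiers that match a
#' compartment and/or age group, for use as the group arguments of
#' [runDifferential()].
#'
#' @param object an [OmicsLayer-class]
#' @param compartment optional, \code{"TH"} and/or \code{"SYN"}
#' @param ageGroup optional, subset of \code{"3w"}, \code{"5m"}, \code{"18m"}
#' @param replicate optional replicate numbers
#' @return character vector of sample IDs
#' @export
sampleFilter <- function(object, compartment = NULL, ageGroup = NULL,
                         replicate = NULL) {
    stopifnot(is(object, "OmicsLayer"))
    colnames(object)[.sampleIndex(object, compartment, ageGroup, replicate)]
}
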