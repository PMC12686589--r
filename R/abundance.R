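#' Median-of-ratios size factors
#'
#' Per-sample normalization factors for count layers: each sample's factor
#' is the median, over genes with strictly positive counts in every sample,
#' of the ratio between the sample's count and the gene's geometric mean
#' across samples. Factors are rescaled to geometric mean 1. When no gene is
#' positive in all samples the method degenerates; the fallback is the ratio
#' of total counts (again scaled to geometric mean 1), with a warning.
#'
#' @param object an [OmicsLayer-class] count layer
#' @return named positive numeric vector, one factor per sample
#' @export
setMethod("sizeFactors", "OmicsLayer", function(object) {
    v <- assay(object, "values")
    if (any(colSums(v) == 0))
        stop("every sample needs at least one nonzero count")
    allPos <- rowSums(v == 0) == 0
    if (!any(allPos)) {
        warning("no gene positive in all samples; ",
                "falling back to total-count ratios")
        sf <- colSums(v)
    } else {
        gm <- exp(rowMeans(log(v[allPos, , drop = FALSE])))
        sf <- apply(v[allPos, , drop = FALSE], 2L, function(x) median(x / gm))
    }
    sf <- sf / exp(mean(log(sf)))
    stats::setNames(sf, colnames(v))
})

#' Reads per kilobase per million mapped reads
#'
#' \deqn{RPKM_{gs} = \frac{c_{gs}}{(L_g/10^3)(N_s/10^6)}}
#' with \eqn{c_{gs}} the raw count, \eqn{L_g} the gene length in bp and
#' \eqn{N_s} the sample's total count. Requires gene lengths; protein layers
#' have no notion of RPKM.
#'
#' @param object an [OmicsLayer-class] count layer with gene lengths
#' @return matrix of RPKM values, same dimensions as the counts
#' @export
setMethod("rpkm", "OmicsLayer", function(object) {
    if (layerType(object) == "protein")
        stop("RPKM is undefined for the protein layer")
    gl <- geneLengths(object)
    if (is.null(gl) || anyNA(gl)) {
        bad <- if (is.null(gl)) rownames(object) else names(gl)[is.na(gl)]
        stop("missing gene length for: ",
             paste(utils::head(bad, 3L), collapse = ", "),
             if (length(bad) > 3L) ", ..." else "")
    }
    v <- assay(object, "values")
    totals <- colSums(v)
    if (any(totals == 0)) stop("sample with zero total count")
    sweep(v / (gl / 1e3), 2L, totals / 1e6, "/")
})

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a p-value vector (wrapper
#' around \code{p.adjust(method = "BH")} with input validation: p-values
#' must lie in (0, 1]).
#'
#' @param pvals numeric vector of p-values in (0, 1]
#' @return adjusted p-values, same length and order
#' @export
bhAdjust <- function(pvals) {
    if (!length(pvals)) stop("empty p-value vector")
    if (anyNA(pvals) || any(pvals <= 0) || any(pvals > 1))
        stop("p-values must lie in (0, 1]")
    stats::p.adjust(pvals, method = "BH")
}

## Welch two-sample t on rows of two matrices; returns stat (A - B), p.
## Degenerate rows (zero variance in both groups) follow the zero-statistic
## convention: equal means give t = 0, p = 1; unequal means give p = 0.
.welchRows <- function(a, b) {
    nA <- ncol(a); nB <- ncol(b)
    mA <- rowMeans(a); mB <- rowMeans(b)
    vA <- apply(a, 1L, stats::var); vB <- apply(b, 1L, stats::var)
    se2 <- vA / nA + vB / nB
    stat <- (mA - mB) / sqrt(se2)
    df <- se2^2 / ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1))
    p <- 2 * stats::pt(abs(stat), df, lower.tail = FALSE)
    zero <- se2 == 0
    if (any(zero)) {
        eq <- zero & (mA == mB)
        stat[eq] <- 0; p[eq] <- 1
        ne <- zero & (mA != mB)
        stat[ne] <- ifelse(mA[ne] > mB[ne], Inf, -Inf); p[ne] <- 0
    }
    list(stat = stat, p = p)
}

#' Two-group differential abundance
#'
#' The pipeline's differential stage: counts are normalized by
#' median-of-ratios size factors (protein intensities are used as-is),
#' transformed as \eqn{y = \log_2(x + \mathrm{pseudocount})}, and each gene
#' is tested by a Welch two-sample t-test between the groups. The reported
#' \code{log2fc} is \code{mean(y_B) - mean(y_A)} (contrast B vs A); the
#' reported \code{stat} follows the \code{t.test(A, B)} sign convention.
#' Genes with zero counts throughout both groups are not tested; p-values
#' are BH-adjusted across the tested genes.
#'
#' This is a deliberately simple stage: no dispersion shrinkage, no
#' NB likelihood. All downstream integration consumes only \code{log2fc}
#' and \code{padj}, so the choice is contained.
#'
#' @param object an [OmicsLayer-class]
#' @param groupA,groupB disjoint character vectors of sample IDs (or logical
#'   masks over samples), each of size >= 2; see [sampleFilter()]
#' @param pseudocount offset added before log2; default 1 for count layers
#'   and 0 for (already positive) protein intensities
#' @return a [S4Vectors::DataFrame] with one row per tested gene:
#'   \code{gene_id}, \code{base_mean} (mean normalized value over both
#'   groups), \code{log2fc}, \code{stat}, \code{p}, \code{padj},
#'   \code{n_A}, \code{n_B}
#' @examples
#' study <- simulateStudy(simParams(nGenes = 300, seed = 1))
#' rna <- studyLayer(study, "rna", ageGroup = "5m")
#' res <- runDifferential(rna, sampleFilter(rna, "TH"),
#'                        sampleFilter(rna, "SYN"))
#' head(res[order(res$padj), ])
#' @export
runDifferential <- function(object, groupA, groupB, pseudocount = NULL) {
    stopifnot(is(object, "OmicsLayer"))
    ids <- colnames(object)
    toIdx <- function(g) if (is.logical(g)) ids[g] else as.character(g)
    groupA <- toIdx(groupA); groupB <- toIdx(groupB)
    if (length(intersect(groupA, groupB)))
        stop("groups must be disjoint")
    if (length(groupA) < 2L || length(groupB) < 2L)
        stop("each group needs at least 2 replicates")
    miss <- setdiff(c(groupA, groupB), ids)
    if (length(miss)) stop("unknown sample(s): ", paste(miss, collapse = ", "))

    isCount <- layerType(object) != "protein"
    if (is.null(pseudocount)) pseudocount <- if (isCount) 1 else 0
    sub <- object[, c(groupA, groupB)]
    v <- assay(sub, "values")
    if (isCount) {
        sf <- sizeFactors(sub)
        v <- sweep(v, 2L, sf, "/")
    }
    tested <- rowMeans(v[, groupA, drop = FALSE]) > 0 |
        rowMeans(v[, groupB, drop = FALSE]) > 0
    v <- v[tested, , drop = FALSE]
    y <- log2(v + pseudocount)
    a <- y[, groupA, drop = FALSE]
    b <- y[, groupB, drop = FALSE]
    w <- .welchRows(a, b)
    DataFrame(gene_id = rownames(v),
              base_mean = unname(rowMeans(v)),
              log2fc = unname(rowMeans(b) - rowMeans(a)),
              stat = unname(w$stat),
              p = unname(w$p),
              padj = unname(bhAdjust(w$p)),
              n_A = length(groupA), n_B = length(groupB),
              row.names = rownames(v))
}

#' @rdname runDifferential
#' @param ageGroup age at which to contrast SYN vs TH
#' @param ... passed on to [runDifferential()]
#' @export
diffCompartments <- function(object, ageGroup = "5m", ...) {
    runDifferential(object,
                    sampleFilter(object, "TH", ageGroup),
                    sampleFilter(object, "SYN", ageGroup), ...)
}

#' @rdname runDifferential
#' @param compartment compartment within which to contrast two ages
#' @param from,to age groups; the contrast is \code{to} vs \code{from}
#' @export
diffAges <- function(object, compartment, from = "3w", to = "5m", ...) {
    runDifferential(object,
                    sampleFilter(object, compartment, from),
                    sampleFilter(object, compartment, to), ...)
}
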