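#' Translational efficiency from ribosome-associated RNA
#'
#' Computes per-gene translational efficiency (TE) as a ratio of
#' replicate-mean RPKMs at one age:
#' \describe{
#'   \item{\code{cross_compartment}}{TE = SC_SYN / SC_TH: the
#'     ribosome-associated (sucrose-cushion, SC) abundance in the
#'     synaptosome divided by that in the total homogenate. \code{sc} must
#'     be a ribo layer containing both compartments; \code{reference} is
#'     not used.}
#'   \item{\code{within_compartment}}{TE = SC / input within one
#'     compartment: \code{sc} is the ribo layer and \code{reference} the
#'     rna (input) layer, both restricted to \code{compartment}.}
#' }
#' Genes whose denominator mean RPKM is zero are dropped from the result;
#' their number is recorded in \code{metadata(result)$dropped}.
#'
#' A single TE per gene (ratio of replicate means) is the default; set
#' \code{perReplicate = TRUE} to additionally obtain the per-replicate-pair
#' ratio matrix in \code{metadata(result)$per_replicate} for uncertainty
#' estimation.
#'
#' @param sc ribo-layer [OmicsLayer-class] (the numerator source)
#' @param reference rna-layer [OmicsLayer-class] for
#'   \code{within_compartment}; ignored for \code{cross_compartment}
#' @param mode \code{"cross_compartment"} or \code{"within_compartment"}
#' @param ageGroup the age at which TE is evaluated (default adult,
#'   \code{"5m"})
#' @param compartment required for \code{within_compartment}
#' @param perReplicate also return per-replicate ratios
#' @return [S4Vectors::DataFrame] with \code{gene_id}, \code{te},
#'   \code{log2_te}; metadata fields \code{numerator}, \code{denominator},
#'   \code{age_group}, \code{dropped}
#' @export
translationalEfficiency <- function(sc, reference = NULL,
                                    mode = c("cross_compartment",
                                             "within_compartment"),
                                    ageGroup = "5m", compartment = NULL,
                                    perReplicate = FALSE) {
    mode <- match.arg(mode)
    stopifnot(is(sc, "OmicsLayer"))
    if (layerType(sc) == "protein")
        stop("translational efficiency needs count layers, not protein")
    if (mode == "cross_compartment") {
        num <- sc[, .sampleIndex(sc, "SYN", ageGroup)]
        den <- sc[, .sampleIndex(sc, "TH", ageGroup)]
        numLab <- "SC_SYN"; denLab <- "SC_TH"
    } else {
        if (is.null(reference))
            stop("within_compartment mode needs the input (rna) layer")
        stopifnot(is(reference, "OmicsLayer"))
        if (layerType(reference) == "protein")
            stop("reference must be a count layer")
        if (is.null(compartment))
            stop("within_compartment mode needs a compartment")
        num <- sc[, .sampleIndex(sc, compartment, ageGroup)]
        den <- reference[, .sampleIndex(reference, compartment, ageGroup)]
        numLab <- paste0("SC_", compartment)
        denLab <- paste0("input_", compartment)
    }
    if (ncol(num) == 0L || ncol(den) == 0L)
        stop("no samples for age group ", ageGroup)
    shared <- intersect(rownames(num), rownames(den))
    rNum <- rpkm(num[shared, ]); rDen <- rpkm(den[shared, ])
    mNum <- rowMeans(rNum); mDen <- rowMeans(rDen)
    keep <- mDen > 0
    te <- mNum[keep] / mDen[keep]
    out <- DataFrame(gene_id = shared[keep], te = unname(te),
                     log2_te = unname(log2(te)),
                     row.names = shared[keep])
    metadata(out) <- list(numerator = numLab, denominator = denLab,
                          age_group = ageGroup,
                          dropped = sum(!keep))
    if (perReplicate) {
        k <- min(ncol(rNum), ncol(rDen))
        metadata(out)$per_replicate <-
            rNum[keep, seq_len(k), drop = FALSE] /
            rDen[keep, seq_len(k), drop = FALSE]
    }
    out
}

#' Compare value distributions between groups
#'
#' Rank-based comparison of per-gene values (typically log2 TE) between
#' gene groups: two-sided Wilcoxon rank-sum for two groups (exact
#' enumeration when both groups have at most 20 untied values, normal
#' approximation with tie correction otherwise), or Kruskal-Wallis for two
#' or more groups.
#'
#' @param valuesByGroup named list of numeric vectors
#' @param test \code{"wilcoxon"} (exactly 2 groups) or \code{"kruskal"}
#' @return list with \code{statistic}, \code{p} and \code{method}
#' @examples
#' compareDistributions(list(a = 1:3, b = 4:6))  # exact p = 0.1
#' @export
compareDistributions <- function(valuesByGroup,
                                 test = c("wilcoxon", "kruskal")) {
    test <- match.arg(test)
    if (!is.list(valuesByGroup) || length(valuesByGroup) < 2L)
        stop("valuesByGroup must be a list of >= 2 groups")
    if (any(lengths(valuesByGroup) < 1L)) stop("empty group")
    if (test == "wilcoxon") {
        if (length(valuesByGroup) != 2L)
            stop("wilcoxon requires exactly 2 groups")
        x <- valuesByGroup[[1L]]; y <- valuesByGroup[[2L]]
        exact <- length(x) <= 20L && length(y) <= 20L &&
            !anyDuplicated(c(x, y))
        ht <- suppressWarnings(
            stats::wilcox.test(x, y, exact = exact, correct = TRUE))
    } else {
        ht <- stats::kruskal.test(valuesByGroup)
    }
    list(statistic = unname(ht$statistic), p = ht$p.value,
         method = ht$method)
}

#' Gaussian kernel density estimate
#'
#' Density of a value vector (optionally on the log2 scale) with Silverman's
#' rule-of-thumb bandwidth, renormalized so the curve integrates to 1 over
#' its grid by the trapezoid rule.
#'
#' @param values numeric vector, length >= 2, non-constant; all positive
#'   when \code{logTransform}
#' @param logTransform estimate the density of \code{log2(values)}
#' @param n grid size
#' @return list with \code{grid}, \code{height} and \code{bw}
#' @export
kdeDensity <- function(values, logTransform = FALSE, n = 512L) {
    values <- values[!is.na(values)]
    if (length(values) < 2L) stop("need at least 2 values")
    if (logTransform) {
        if (any(values <= 0)) stop("log transform requires positive values")
        values <- log2(values)
    }
    if (stats::sd(values) == 0) stop("zero variance: density degenerate")
    d <- stats::density(values, bw = "nrd0", n = n)
    area <- sum(diff(d$x) * (utils::head(d$y, -1L) + utils::tail(d$y, -1L)) / 2)
    list(grid = d$x, height = d$y / area, bw = d$bw)
}
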