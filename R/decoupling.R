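#' Per-gene protein-transcript decoupling score
#'
#' The decoupling score of a gene over a contrast is the difference of its
#' protein and transcript log2 fold changes,
#' \deqn{D = \Delta_{prot} - \Delta_{rna},}
#' i.e. the log of the linear-scale ratio of the two fold changes. Positive
#' decoupling means the protein increases more (or decreases less) than
#' transcript regulation predicts; negative decoupling the converse. A
#' literal ratio of signed log fold changes would invert this sign whenever
#' both changes are negative, so the log-scale difference is the form that
#' honours the sign semantics in all four sign combinations.
#'
#' @param protLog2fc,rnaLog2fc finite numeric vectors, aligned per gene
#' @return numeric vector of signed scores (log2 units)
#' @examples
#' decouplingScore(c(1, 2, -2), c(1, 1, -1))  # 0, +1, -1
#' @export
decouplingScore <- function(protLog2fc, rnaLog2fc) {
    if (any(is.na(protLog2fc)) || any(is.na(rnaLog2fc)))
        stop("fold changes must be finite (no NA/NaN)")
    protLog2fc - rnaLog2fc
}

#' Per-gene correlation of expression with age
#'
#' For every gene, the Spearman correlation between its per-sample values
#' (RPKM for count layers, intensity for protein) and the samples' numeric
#' age. Being rank-based, the result is invariant to any strictly
#' increasing recoding of the ages; the default day encoding (21, 150, 540)
#' is one such choice. Genes constant across samples have undefined rho and
#' are reported as \code{NA}; their number is in
#' \code{metadata(result)$n_undefined}.
#'
#' @param object an [OmicsLayer-class]; may be restricted to one
#'   compartment first (see [studyLayer()] / subsetting)
#' @param valueKind \code{"rpkm"} (count layers) or \code{"intensity"}
#'   (use values as stored)
#' @return [S4Vectors::DataFrame] with \code{gene_id}, \code{rho}, \code{n}
#' @export
perGeneAgeCorrelation <- function(object,
                                  valueKind = c("rpkm", "intensity")) {
    valueKind <- match.arg(valueKind)
    stopifnot(is(object, "OmicsLayer"))
    ages <- colData(object)$age_days
    nAges <- length(unique(ages))
    if (nAges < 2L) stop("need at least 2 distinct age groups")
    if (nAges == 2L)
        warning("only 2 distinct ages: age trends are poorly constrained")
    if (ncol(object) < 6L)
        warning("fewer than 6 samples per gene: rho estimates are noisy")
    v <- if (valueKind == "rpkm") rpkm(object) else assay(object, "values")
    ageRank <- rank(ages)
    rho <- apply(v, 1L, function(x) {
        if (stats::sd(x) == 0) return(NA_real_)
        stats::cor(rank(x), ageRank)
    })
    out <- DataFrame(gene_id = rownames(v), rho = unname(rho),
                     n = ncol(v), row.names = rownames(v))
    metadata(out) <- list(n_undefined = sum(is.na(rho)))
    if (metadata(out)$n_undefined > 0)
        warning(metadata(out)$n_undefined,
                " constant gene(s) with undefined rho")
    out
}

#' RNA-protein coupling per compartment, age and replicate
#'
#' For each (compartment, age) design cell, pairs RNA and protein samples
#' and computes the Spearman correlation across the shared gene set between
#' transcript RPKM and protein intensity. The default pairing matches
#' replicate k of the RNA layer with replicate k of the protein layer
#' (one rho per replicate); \code{pairing = "all"} instead uses every RNA
#' x protein sample combination within the cell.
#'
#' @param rna rna-layer [OmicsLayer-class] with gene lengths
#' @param prot protein-layer [OmicsLayer-class]
#' @param pairing \code{"matched"} or \code{"all"}
#' @return data.frame with \code{compartment}, \code{age_group},
#'   \code{replicate} (or pair label), \code{rho}, \code{n}
#' @seealso [twoWayAnova()] for testing compartment and age effects on the
#'   resulting correlations
#' @export
rnaProteinCoupling <- function(rna, prot, pairing = c("matched", "all")) {
    pairing <- match.arg(pairing)
    stopifnot(is(rna, "OmicsLayer"), is(prot, "OmicsLayer"))
    shared <- intersect(rownames(rna), rownames(prot))
    if (!length(shared)) stop("no shared genes between layers")
    rv <- rpkm(rna)[shared, , drop = FALSE]
    pv <- assay(prot, "values")[shared, , drop = FALSE]
    cdR <- colData(rna); cdP <- colData(prot)
    out <- list()
    for (comp in levels(droplevels(cdR$compartment))) {
        for (age in intersect(.AGE_LEVELS,
                              as.character(unique(cdR$age_group)))) {
            ri <- which(.sampleIndex(rna, comp, age))
            pi <- which(.sampleIndex(prot, comp, age))
            if (!length(ri) || !length(pi)) next
            pairs <- if (pairing == "matched") {
                reps <- intersect(cdR$replicate[ri], cdP$replicate[pi])
                lapply(reps, function(k)
                    c(ri[cdR$replicate[ri] == k][1L],
                      pi[cdP$replicate[pi] == k][1L]))
            } else {
                unlist(lapply(ri, function(i) lapply(pi, function(j)
                    c(i, j))), recursive = FALSE)
            }
            for (pr in pairs) {
                rho <- stats::cor(rv[, pr[1L]], pv[, pr[2L]],
                                  method = "spearman")
                out[[length(out) + 1L]] <- data.frame(
                    compartment = comp, age_group = age,
                    replicate = as.character(cdR$replicate[pr[1L]]),
                    pair = paste(colnames(rna)[pr[1L]],
                                 colnames(prot)[pr[2L]], sep = "~"),
                    rho = rho, n = length(shared),
                    stringsAsFactors = FALSE)
            }
        }
    }
    res <- do.call(rbind, out)
    res$age_group <- factor(res$age_group, levels = .AGE_LEVELS,
                            ordered = TRUE)
    res
}

#' Balanced two-way fixed-effects ANOVA
#'
#' Two-way ANOVA with interaction on a (near-)balanced design, e.g. of
#' coupling correlations over compartment and age. Under balance the
#' sequential (type-I) decomposition coincides with type-II, so the plain
#' \code{aov} fit is reported. Designs with an empty cell or a
#' single-level factor are rejected. If the residual variance is exactly
#' zero the F statistics degenerate; terms with positive sums of squares
#' are then reported with p = 0 and the result is flagged.
#'
#' @param values numeric response vector
#' @param factorA,factorB factor labels, same length as \code{values}
#' @return data.frame with one row per term (\code{A}, \code{B},
#'   \code{A:B}): \code{df}, \code{sumsq}, \code{F}, \code{p}; attribute
#'   \code{degenerate} flags a zero-residual fit
#' @export
twoWayAnova <- function(values, factorA, factorB) {
    A <- factor(factorA); B <- factor(factorB)
    if (nlevels(A) < 2L || nlevels(B) < 2L)
        stop("each factor needs at least 2 levels")
    if (any(table(A, B) == 0L))
        stop("empty design cell: the balanced contract is violated")
    fit <- stats::aov(values ~ A * B)
    tab <- summary(fit)[[1L]]
    terms <- trimws(rownames(tab))
    resid <- tab[terms == "Residuals", , drop = FALSE]
    eff <- tab[terms != "Residuals", , drop = FALSE]
    degenerate <- resid[["Mean Sq"]] < .Machine$double.eps^0.75
    Fv <- eff[["F value"]]; pv <- eff[["Pr(>F)"]]
    if (degenerate) {
        pos <- eff[["Sum Sq"]] > .Machine$double.eps^0.75
        Fv <- ifelse(pos, Inf, 0)
        pv <- ifelse(pos, 0, 1)
    }
    out <- data.frame(term = trimws(rownames(eff)),
                      df = eff[["Df"]], sumsq = eff[["Sum Sq"]],
                      F = Fv, p = pv, stringsAsFactors = FALSE)
    attr(out, "degenerate") <- degenerate
    out
}
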