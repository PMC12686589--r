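#' Combine p-values by Fisher's method
#'
#' \deqn{X = -2 \sum_{i=1}^k \ln p_i \sim \chi^2_{2k}}
#' under the joint null; the combined p-value is the upper-tail probability
#' of \eqn{X}. For \eqn{k = 1} the identity
#' \eqn{P(\chi^2_2 > -2\ln p) = p} returns the input unchanged. The
#' statistic is monotone: lowering any input can only lower the output.
#'
#' @param pvals numeric vector of k >= 1 p-values in (0, 1]
#' @return the combined p-value
#' @examples
#' fisherCombine(c(0.05, 0.05))
#' @export
fisherCombine <- function(pvals) {
    if (!length(pvals)) stop("empty p-value vector")
    if (anyNA(pvals) || any(pvals <= 0) || any(pvals > 1))
        stop("p-values must lie in (0, 1]")
    x <- -2 * sum(log(pvals))
    stats::pchisq(x, df = 2 * length(pvals), lower.tail = FALSE)
}

#' Quadrant of a (transcript, protein) fold-change pair
#'
#' Quadrants are named clockwise from the upper right of the transcript
#' (x) vs protein (y) plane: Q1 = both up, Q2 = transcript up / protein
#' down, Q3 = both down, Q4 = transcript down / protein up. A fold change
#' of exactly zero puts the gene on the boundary.
#'
#' @param rnaLog2fc,protLog2fc finite numeric vectors (recycled together)
#' @return factor with levels Q1, Q2, Q3, Q4, boundary
#' @examples
#' assignQuadrants(c(1, 1, -1, -1, 0), c(2, -1, -1, 1, 3))
#' @export
assignQuadrants <- function(rnaLog2fc, protLog2fc) {
    if (any(is.na(rnaLog2fc)) || any(is.na(protLog2fc)))
        stop("fold changes must be finite (no NA/NaN)")
    q <- ifelse(rnaLog2fc > 0 & protLog2fc > 0, "Q1",
         ifelse(rnaLog2fc > 0 & protLog2fc < 0, "Q2",
         ifelse(rnaLog2fc < 0 & protLog2fc < 0, "Q3",
         ifelse(rnaLog2fc < 0 & protLog2fc > 0, "Q4", "boundary"))))
    factor(q, levels = .QUADRANTS)
}

#' Join transcript and protein contrasts into a matched table
#'
#' Inner join of two differential-result tables on \code{gene_id}. The two
#' adjusted p-values are combined per gene with Fisher's method (this is
#' applied to BH-adjusted p-values by design, mirroring the upstream
#' meta-analysis convention; set \code{combineOn = "p"} for raw-p
#' combination), BH-adjusted across the joined genes, and each gene receives
#' its quadrant from the sign pair of the fold changes.
#'
#' @param rna,prot [S4Vectors::DataFrame]s as returned by
#'   [runDifferential()] (need \code{gene_id}, \code{log2fc}, \code{p},
#'   \code{padj})
#' @param combineOn combine \code{"padj"} (default) or raw \code{"p"}
#' @return a \code{MatchedTable}: DataFrame with \code{gene_id},
#'   \code{rna_log2fc}, \code{rna_padj}, \code{prot_log2fc},
#'   \code{prot_padj}, \code{combined_p}, \code{combined_padj},
#'   \code{quadrant}
#' @export
matchOmics <- function(rna, prot, combineOn = c("padj", "p")) {
    combineOn <- match.arg(combineOn)
    if (anyDuplicated(rna$gene_id))
        stop("duplicate gene_id in the rna table")
    if (anyDuplicated(prot$gene_id))
        stop("duplicate gene_id in the protein table")
    shared <- intersect(rna$gene_id, prot$gene_id)
    r <- rna[match(shared, rna$gene_id), ]
    p <- prot[match(shared, prot$gene_id), ]
    pr <- if (combineOn == "padj") r$padj else r$p
    pp <- if (combineOn == "padj") p$padj else p$p
    comb <- mapply(function(x, y) fisherCombine(c(x, y)), pr, pp)
    if (!length(shared))
        return(DataFrame(gene_id = character(), rna_log2fc = numeric(),
                         rna_padj = numeric(), prot_log2fc = numeric(),
                         prot_padj = numeric(), combined_p = numeric(),
                         combined_padj = numeric(),
                         quadrant = factor(character(),
                                           levels = .QUADRANTS)))
    DataFrame(gene_id = shared,
              rna_log2fc = r$log2fc, rna_padj = r$padj,
              prot_log2fc = p$log2fc, prot_padj = p$padj,
              combined_p = unname(comb),
              combined_padj = bhAdjust(comb),
              quadrant = assignQuadrants(r$log2fc, p$log2fc),
              row.names = shared)
}

#' Select significant genes from a matched table
#'
#' \code{"fisher"} keeps genes whose Fisher-combined adjusted p-value falls
#' below \code{alpha}; \code{"intersection"} is the stringent variant that
#' requires both the transcript and the protein adjusted p-value to fall
#' below \code{alpha} separately.
#'
#' @param matched a MatchedTable from [matchOmics()]
#' @param alpha significance threshold in (0, 1)
#' @param method \code{"fisher"} or \code{"intersection"}
#' @return the selected subset of \code{matched}
#' @export
selectSignificant <- function(matched, alpha = 0.05,
                              method = c("fisher", "intersection")) {
    method <- match.arg(method)
    if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
    keep <- if (method == "fisher") matched$combined_padj < alpha
            else matched$rna_padj < alpha & matched$prot_padj < alpha
    ## alpha = 1 keeps everything under either rule (padj <= 1 always)
    if (alpha == 1) keep <- rep(TRUE, nrow(matched))
    matched[keep, , drop = FALSE]
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact two-sided p-value under the hypergeometric null with all margins
#' fixed, using the probability-mass rule: the p-value sums the
#' probabilities of every table (with the observed margins) whose
#' probability does not exceed the observed table's. Probabilities are
#' evaluated in log space for numerical stability of extreme tables.
#'
#' @param a,b,c,d the four non-negative integer cells, rows
#'   \code{(a, b)} and \code{(c, d)}; alternatively \code{a} may be a 2x2
#'   matrix
#' @return the two-sided p-value
#' @examples
#' fisherExact2x2(2, 0, 0, 2)            # 1/3
#' fisherExact2x2(matrix(c(60, 261, 498, 344), 2))
#' @export
fisherExact2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
    if (is.matrix(a)) {
        if (!all(dim(a) == 2L)) stop("table must be 2x2")
        d <- a[2L, 2L]; c <- a[2L, 1L]; b <- a[1L, 2L]; a <- a[1L, 1L]
    }
    cells <- c(a, b, c, d)
    if (anyNA(cells) || any(cells < 0) || any(cells != round(cells)))
        stop("cells must be non-negative integers")
    if (sum(cells) == 0) stop("table total must be positive")
    r1 <- a + b; r2 <- c + d; k <- a + c
    support <- max(0, k - r2):min(k, r1)
    logp <- stats::dhyper(support, r1, r2, k, log = TRUE)
    obs <- logp[support == a]
    ## relative tolerance guards against ties broken by rounding
    sum(exp(logp[logp <= obs + 1e-7]))
}

#' Test quadrant distribution for sign association
#'
#' Reduces the four quadrant counts of a matched table to the 2x2 table of
#' transcript sign by protein sign (boundary genes excluded) and returns the
#' two-sided Fisher's exact p-value. A small p indicates the quadrant
#' occupancy departs from independence of the two sign axes, i.e. a
#' non-uniform quadrant map.
#'
#' @param matched a MatchedTable from [matchOmics()]
#' @return list with \code{table} (the 2x2 sign table) and \code{p}
#' @export
quadrantAssociationTest <- function(matched) {
    if (!nrow(matched)) stop("empty matched table")
    q <- table(matched$quadrant)
    if (sum(q[c("Q1", "Q2", "Q3", "Q4")]) == 0)
        stop("all genes on the quadrant boundary")
    tab <- matrix(c(q[["Q1"]], q[["Q2"]], q[["Q4"]], q[["Q3"]]),
                  nrow = 2L, byrow = TRUE,
                  dimnames = list(rna = c("up", "down"),
                                  protein = c("up", "down")))
    list(table = tab, p = fisherExact2x2(tab))
}

#' Spearman coupling correlation of two fold-change vectors
#'
#' Rank correlation (average ranks on ties) between per-gene fold changes
#' measured in two compartments or layers, with the large-sample t
#' approximation for the p-value. Being rank-based, the result is invariant
#' under strictly monotone transforms of either vector.
#'
#' @param fcX,fcY numeric vectors aligned on the same genes, length >= 3
#' @return list with \code{rho}, \code{p} and \code{n}
#' @examples
#' couplingCorrelation(c(1, 2, 3, 4), c(2, 1, 4, 3))  # rho = 0.6
#' @export
couplingCorrelation <- function(fcX, fcY) {
    if (length(fcX) != length(fcY)) stop("vectors must be aligned")
    ok <- !is.na(fcX) & !is.na(fcY)
    fcX <- fcX[ok]; fcY <- fcY[ok]
    n <- length(fcX)
    if (n < 3L) stop("need at least 3 paired values")
    if (stats::sd(fcX) == 0 || stats::sd(fcY) == 0)
        stop("constant vector: rho undefined")
    rho <- stats::cor(rank(fcX), rank(fcY))
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- if (abs(rho) == 1) 0
         else 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
    list(rho = rho, p = p, n = n)
}
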