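#' Set-versus-background t-test on per-gene scores
#'
#' Tests whether the mean per-gene score (fold change, age-trend rho,
#' decoupling score, ...) of a gene set differs from the background, by a
#' Welch two-sample t-test of set members against non-members. The
#' background defaults to the universe minus the set, which keeps the two
#' samples disjoint; \code{background = "universe"} uses every universe
#' gene instead. Both one-sided p-values are reported alongside the
#' two-sided one.
#'
#' @param scores named numeric vector of per-gene scores (names = gene IDs)
#' @param geneSet character vector of member gene IDs
#' @param universe gene universe; defaults to \code{names(scores)}
#' @param background \code{"disjoint"} (default) or \code{"universe"}
#' @return list with \code{t}, \code{p}, \code{p_up}, \code{p_down},
#'   \code{direction} (\code{"up"}/\code{"down"}), \code{set_size}
#' @export
gageTest <- function(scores, geneSet, universe = names(scores),
                     background = c("disjoint", "universe")) {
    background <- match.arg(background)
    if (is.null(names(scores))) stop("scores must be named by gene ID")
    universe <- intersect(universe, names(scores))
    inSet <- intersect(geneSet, universe)
    if (length(inSet) < 2L)
        stop("gene set has fewer than 2 members in the universe")
    bg <- if (background == "disjoint") setdiff(universe, inSet)
          else universe
    if (length(bg) < 2L) stop("background has fewer than 2 genes")
    x <- scores[inSet]; y <- scores[bg]
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
        tt <- if (mean(x) == mean(y)) list(stat = 0, p = 1)
              else list(stat = sign(mean(x) - mean(y)) * Inf, p = 0)
        pUp <- if (tt$stat > 0) 0 else if (tt$stat < 0) 1 else 0.5
    } else {
        w <- .welchRows(matrix(x, nrow = 1L), matrix(y, nrow = 1L))
        tt <- list(stat = w$stat, p = w$p)
        df <- tryCatch(stats::t.test(x, y)$parameter, error = function(e) NA)
        pUp <- stats::pt(tt$stat, df = df, lower.tail = FALSE)
    }
    list(t = unname(tt$stat), p = unname(tt$p),
         p_up = unname(pUp), p_down = unname(1 - pUp),
         direction = if (mean(x) >= mean(y)) "up" else "down",
         set_size = length(inSet))
}

#' Hypergeometric overrepresentation test
#'
#' Upper-tail probability of drawing at least the observed overlap between
#' a hit list and a gene set from the universe, plus the fold enrichment
#' \eqn{(k/|hits|)/(|set|/|universe|)}. An empty hit list returns p = 1 by
#' convention (flagged in the result).
#'
#' @param hits character vector of significant gene IDs (subset of the
#'   universe)
#' @param geneSet character vector of set member IDs
#' @param universe the gene universe
#' @return list with \code{overlap}, \code{fold_enrichment}, \code{p},
#'   \code{empty_hits}
#' @export
oraTest <- function(hits, geneSet, universe) {
    hits <- unique(hits)
    if (length(setdiff(hits, universe)))
        stop("hits must be a subset of the universe")
    set <- intersect(unique(geneSet), universe)
    N <- length(unique(universe)); m <- length(set); nh <- length(hits)
    if (nh == 0L)
        return(list(overlap = 0L, fold_enrichment = NA_real_, p = 1,
                    empty_hits = TRUE))
    k <- length(intersect(hits, set))
    p <- stats::phyper(k - 1L, m, N - m, nh, lower.tail = FALSE)
    list(overlap = k,
         fold_enrichment = (k / nh) / (m / N),
         p = p, empty_hits = FALSE)
}

#' Run a gene-set test over a whole collection
#'
#' Applies [gageTest()] (on a named score vector) or [oraTest()] (on a hit
#' list plus explicit universe) to every set of the collection after
#' filtering it against the universe at the collection's minimum size, then
#' BH-adjusts across sets. Rows are ordered by p-value with ties broken by
#' set name, so the output is deterministic.
#'
#' @param x named score vector (gage) or character hit vector (ora)
#' @param collection a [GeneSetCollection-class]
#' @param method \code{"gage"} or \code{"ora"}
#' @param universe required for \code{"ora"}; defaults to
#'   \code{names(x)} for \code{"gage"}
#' @param ... passed to the per-set test
#' @return [S4Vectors::DataFrame] with \code{set_name}, \code{set_size},
#'   \code{stat} (t or fold enrichment), \code{direction}, \code{p},
#'   \code{p_up}, \code{p_down} (gage only), \code{padj}
#' @export
enrichCollection <- function(x, collection, method = c("gage", "ora"),
                             universe = NULL, ...) {
    method <- match.arg(method)
    stopifnot(is(collection, "GeneSetCollection"))
    if (method == "gage") {
        if (is.null(universe)) universe <- names(x)
    } else if (is.null(universe))
        stop("ora needs an explicit universe")
    coll <- filterGeneSets(collection, universe)
    if (!length(coll)) stop("no gene set survives universe filtering")
    sets <- geneSets(coll)
    rows <- lapply(names(sets), function(nm) {
        if (method == "gage") {
            r <- gageTest(x, sets[[nm]], universe, ...)
            data.frame(set_name = nm, set_size = r$set_size, stat = r$t,
                       direction = r$direction, p = r$p,
                       p_up = r$p_up, p_down = r$p_down,
                       stringsAsFactors = FALSE)
        } else {
            r <- oraTest(x, sets[[nm]], universe)
            data.frame(set_name = nm, set_size = length(sets[[nm]]),
                       stat = r$fold_enrichment,
                       direction = NA_character_, p = r$p,
                       p_up = NA_real_, p_down = NA_real_,
                       stringsAsFactors = FALSE)
        }
    })
    out <- do.call(rbind, rows)
    out$padj <- bhAdjust(out$p)
    out <- out[order(out$p, out$set_name), , drop = FALSE]
    rownames(out) <- out$set_name
    DataFrame(out)
}

#' Compare the unique fractions of two list overlaps
#'
#' Given two overlap decompositions (unique vs shared counts), reports each
#' pair's unique percentage and the two-sided Fisher's exact p-value for
#' the 2x2 table \code{[[unique1, shared1], [unique2, shared2]]} -- the
#' comparison used to ask whether, e.g., differentially spliced genes
#' escape differential expression more often in one age contrast than in
#' another.
#'
#' @param unique1,shared1 counts of the first decomposition
#' @param unique2,shared2 counts of the second
#' @return list with \code{pct1}, \code{pct2} (percentages) and \code{p}
#' @examples
#' overlapComparison(60, 498, 261, 344)
#' @export
overlapComparison <- function(unique1, shared1, unique2, shared2) {
    cells <- c(unique1, shared1, unique2, shared2)
    if (any(cells < 0)) stop("counts must be non-negative")
    if (unique1 + shared1 == 0 || unique2 + shared2 == 0)
        stop("each pair needs a positive total")
    list(pct1 = 100 * unique1 / (unique1 + shared1),
         pct2 = 100 * unique2 / (unique2 + shared2),
         p = fisherExact2x2(unique1, shared1, unique2, shared2))
}
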