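#' Compartment-enrichment quadrant map
#'
#' The package's central integration: contrasts SYN vs TH at one age in the
#' transcript and protein layers, joins the two contrasts per gene with
#' Fisher-combined significance ([matchOmics()]), and summarizes the
#' quadrant occupancy (sign-association test) and the transcript-protein
#' fold-change correlation, on all matched genes and on the significant
#' subset.
#'
#' @param rna rna-layer [OmicsLayer-class]
#' @param prot protein-layer [OmicsLayer-class]
#' @param ageGroup age of the contrast (default adult, \code{"5m"})
#' @param alpha significance level for the selected subset
#' @param method selection rule, see [selectSignificant()]
#' @return list: \code{matched} (the full MatchedTable),
#'   \code{selected} (significant subset), \code{quadrant_counts},
#'   \code{association} (2x2 sign table and Fisher p),
#'   \code{correlation_all} / \code{correlation_selected} (Spearman rho of
#'   the fold-change scatter)
#' @export
quadrantMap <- function(rna, prot, ageGroup = "5m", alpha = 0.05,
                        method = c("fisher", "intersection")) {
    method <- match.arg(method)
    mt <- matchOmics(diffCompartments(rna, ageGroup),
                     diffCompartments(prot, ageGroup))
    sel <- selectSignificant(mt, alpha, method)
    list(matched = mt,
         selected = sel,
         quadrant_counts = table(mt$quadrant),
         association = quadrantAssociationTest(mt),
         correlation_all = couplingCorrelation(mt$rna_log2fc,
                                               mt$prot_log2fc),
         correlation_selected = if (nrow(sel) >= 3L)
             couplingCorrelation(sel$rna_log2fc, sel$prot_log2fc)
         else NULL)
}

#' Compartment-coupling correlation for one age contrast
#'
#' Asks how similarly the two compartments regulate genes over an age
#' transition: computes the per-gene fold changes of the \code{to}-vs-
#' \code{from} contrast separately in TH and SYN, selects the regulated
#' genes, and returns the Spearman correlation between the two fold-change
#' vectors. Development-stage contrasts are expected to correlate strongly
#' (synaptic regulation driven by the soma); aging contrasts to decouple.
#'
#' Gene selection requires nominal evidence of regulation in both
#' compartments (p below \code{alpha} in each, a joint null rate of
#' \code{alpha^2}) among well-measured genes (normalized base mean at least
#' \code{minBaseMean} in both contrasts). With an unmoderated t-test at few
#' replicates, this concordance requirement is what keeps noise-selected
#' genes from diluting the correlation; see the methods vignette.
#'
#' @param object a count [OmicsLayer-class] spanning both compartments
#' @param from,to the age contrast (\code{to} vs \code{from})
#' @param alpha per-compartment nominal significance (default 0.2; joint
#'   0.04)
#' @param minBaseMean expression floor on the normalized base mean
#' @return list with \code{rho}, \code{p}, \code{n} and the selected
#'   fold-change table \code{fc} (gene_id, fc_TH, fc_SYN)
#' @export
couplingTrajectory <- function(object, from = "3w", to = "5m",
                               alpha = 0.2, minBaseMean = 50) {
    dTH <- diffAges(object, "TH", from, to)
    dSYN <- diffAges(object, "SYN", from, to)
    shared <- intersect(dTH$gene_id, dSYN$gene_id)
    dTH <- dTH[match(shared, dTH$gene_id), ]
    dSYN <- dSYN[match(shared, dSYN$gene_id), ]
    keep <- dTH$p < alpha & dSYN$p < alpha &
        dTH$base_mean >= minBaseMean & dSYN$base_mean >= minBaseMean
    fc <- DataFrame(gene_id = shared[keep],
                    fc_TH = dTH$log2fc[keep], fc_SYN = dSYN$log2fc[keep])
    cc <- couplingCorrelation(fc$fc_TH, fc$fc_SYN)
    c(cc, list(fc = fc))
}

#' Per-gene decoupling over an age contrast
#'
#' Runs the \code{to}-vs-\code{from} differential in the transcript and
#' protein layers of one compartment, joins them per gene and attaches the
#' decoupling score ([decouplingScore()]).
#'
#' @param rna rna-layer [OmicsLayer-class]
#' @param prot protein-layer [OmicsLayer-class]
#' @param compartment \code{"TH"} or \code{"SYN"}
#' @param from,to the age contrast
#' @return [S4Vectors::DataFrame] with \code{gene_id}, \code{rna_log2fc},
#'   \code{prot_log2fc}, \code{decoupling}
#' @export
decouplingAnalysis <- function(rna, prot, compartment = "SYN",
                               from = "5m", to = "18m") {
    dr <- diffAges(rna, compartment, from, to)
    dp <- diffAges(prot, compartment, from, to)
    shared <- intersect(dr$gene_id, dp$gene_id)
    dr <- dr[match(shared, dr$gene_id), ]
    dp <- dp[match(shared, dp$gene_id), ]
    DataFrame(gene_id = shared,
              rna_log2fc = dr$log2fc, prot_log2fc = dp$log2fc,
              decoupling = decouplingScore(dp$log2fc, dr$log2fc),
              row.names = shared)
}

#' Rank-based AUROC
#'
#' Area under the ROC curve of a score for a binary label, via the
#' Mann-Whitney identity: the probability that a random positive outscores
#' a random negative (ties split evenly).
#'
#' @param scores numeric scores (higher = more positive-like)
#' @param labels logical vector, \code{TRUE} = positive
#' @return AUROC in [0, 1]
#' @export
aurocScore <- function(scores, labels) {
    stopifnot(length(scores) == length(labels), is.logical(labels))
    ok <- !is.na(scores)
    scores <- scores[ok]; labels <- labels[ok]
    nPos <- sum(labels); nNeg <- sum(!labels)
    if (nPos == 0L || nNeg == 0L) stop("need both classes")
    (mean(rank(scores)[labels]) - (nPos + 1) / 2) / nNeg
}
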