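#' Parameters for the synthetic soma/synapse study
#'
#' Builds the parameter list consumed by [simulateStudy()]. Defaults encode
#' the study design the generator emulates: three ages (3 weeks, 5 months,
#' 18 months), two compartments (total homogenate TH, synaptosome SYN),
#' three layers (transcript counts, ribosome-associated transcript counts,
#' protein intensities) with \code{nReps} replicates per design cell, and a
#' gene population structured into functional classes whose compartment and
#' aging behavior mirrors the biology the pipeline is built to detect:
#' synaptic genes enriched in SYN at both levels; ribosomal and respiratory
#' genes with SYN-enriched transcripts but SYN-depleted proteins
#' (translational repression); vesicle genes with the converse pattern;
#' nuclear genes depleted on both axes.
#'
#' Development effects (3w to 5m) are drawn once per affected gene and
#' applied to both compartments -- development is compartment-coupled.
#' Aging effects (5m to 18m) are drawn independently per compartment --
#' aging is decoupled -- except for the programmed ribosomal/respiratory
#' pattern: transcripts up and proteins down in TH, transcripts down and
#' proteins up in SYN. The translational repression of ribosomal and
#' respiratory genes in SYN (log2 offset \code{teRepressionLog2} on the
#' ribosome-associated layer) is present at 3w and 5m and released at 18m,
#' so the old-age protein gain coincides with a gain in translational
#' efficiency.
#'
#' @param nGenes number of genes (default 2000)
#' @param nReps replicates per (compartment, age, layer) cell (default 4,
#'   minimum 2)
#' @param classFractions named fractions over the six gene classes; must sum
#'   to 1
#' @param baseLog2Mean,baseLog2Sd per-gene baseline log2 expression is drawn
#'   Normal(\code{baseLog2Mean}, \code{baseLog2Sd})
#' @param dispersion function of the NB mean returning the dispersion
#'   \eqn{\phi} (variance \eqn{\mu + \phi \mu^2}); default
#'   \eqn{0.1 + 1/\mu}
#' @param compartmentEffectsLog2 per-class log2 SYN-vs-TH effects, a named
#'   list of \code{c(rna, protein)} pairs
#' @param devEffectFraction,devEffectSdLog2 fraction of genes with a
#'   development effect, and the SD of its Normal(0, sd) draw
#' @param agingEffectFraction,agingEffectSdLog2 same for the independent
#'   per-compartment aging effects of non-programmed genes
#' @param agingEffectsLog2 programmed aging effects for the
#'   ribosomal/respiratory classes: named vector with elements
#'   \code{rna_TH}, \code{rna_SYN}, \code{protein_TH}, \code{protein_SYN}
#' @param teRepressionLog2 log2 offset of the SYN ribosome-associated layer
#'   for ribosomal/respiratory genes at 3w and 5m (default -1.5)
#' @param proteinCouplingSlope slope tying baseline protein log2 intensity
#'   to baseline transcript abundance (default 0.8)
#' @param proteinInterceptLog2 baseline protein log2 intensity intercept
#' @param proteinNoiseSdLog2 per-sample log2 noise of protein intensities
#' @param proteomeDepthFraction fraction of genes detected in the proteome
#'   (the rest are absent from the protein matrices, not zero)
#' @param libSizeSpreadLog2 half-range of the per-sample log2 depth factor;
#'   the default 0.5 keeps library sizes within a 2-fold spread, enough to
#'   exercise normalization without degeneracy
#' @param seed integer seed; the same seed reproduces the study bit for bit
#' @return a list of class \code{"SimParams"}
#' @export
simParams <- function(nGenes = 2000L, nReps = 4L,
                      classFractions = c(synaptic = 0.15, ribosomal = 0.05,
                                         respiratory = 0.05, vesicle = 0.05,
                                         nuclear = 0.10, background = 0.60),
                      baseLog2Mean = 5, baseLog2Sd = 2,
                      dispersion = function(mu) 0.1 + 1 / mu,
                      compartmentEffectsLog2 = list(
                          synaptic = c(rna = 1, protein = 1),
                          ribosomal = c(rna = 1, protein = -1),
                          respiratory = c(rna = 1, protein = -1),
                          vesicle = c(rna = -1, protein = 1),
                          nuclear = c(rna = -1, protein = -1),
                          background = c(rna = 0, protein = 0)),
                      devEffectFraction = 0.30, devEffectSdLog2 = 0.5,
                      agingEffectFraction = 0.30, agingEffectSdLog2 = 0.5,
                      agingEffectsLog2 = c(rna_TH = 0.5, rna_SYN = -0.75,
                                           protein_TH = -0.75,
                                           protein_SYN = 0.75),
                      teRepressionLog2 = -1.5,
                      proteinCouplingSlope = 0.8,
                      proteinInterceptLog2 = 16,
                      proteinNoiseSdLog2 = 0.5,
                      proteomeDepthFraction = 0.6,
                      libSizeSpreadLog2 = 0.5,
                      seed = 1L) {
    p <- list(nGenes = as.integer(nGenes), nReps = as.integer(nReps),
              classFractions = classFractions,
              baseLog2Mean = baseLog2Mean, baseLog2Sd = baseLog2Sd,
              dispersion = dispersion,
              compartmentEffectsLog2 = compartmentEffectsLog2,
              devEffectFraction = devEffectFraction,
              devEffectSdLog2 = devEffectSdLog2,
              agingEffectFraction = agingEffectFraction,
              agingEffectSdLog2 = agingEffectSdLog2,
              agingEffectsLog2 = agingEffectsLog2,
              teRepressionLog2 = teRepressionLog2,
              proteinCouplingSlope = proteinCouplingSlope,
              proteinInterceptLog2 = proteinInterceptLog2,
              proteinNoiseSdLog2 = proteinNoiseSdLog2,
              proteomeDepthFraction = proteomeDepthFraction,
              libSizeSpreadLog2 = libSizeSpreadLog2,
              seed = as.integer(seed))
    class(p) <- "SimParams"
    .checkSimParams(p)
    p
}

.checkSimParams <- function(p) {
    if (abs(sum(p$classFractions) - 1) > 1e-8)
        stop("class fractions must sum to 1")
    if (any(p$classFractions < 0) || any(p$classFractions > 1))
        stop("class fractions must lie in [0, 1]")
    if (p$nReps < 2L)
        stop("nReps must be at least 2 for any statistical contrast")
    if (p$dispersion(100) <= 0)
        stop("dispersion must be positive")
    invisible(TRUE)
}

## deterministic class assignment: contiguous blocks sized round(n * f),
## remainder absorbed by the last (background) class
.assignClasses <- function(nGenes, fractions) {
    k <- length(fractions)
    sizes <- round(nGenes * fractions)
    sizes[k] <- nGenes - sum(sizes[-k])
    if (sizes[k] < 0) stop("class fractions incompatible with nGenes")
    rep(names(fractions), times = sizes)
}

.nbCounts <- function(log2mu, nReps, dispersion, spread) {
    n <- length(log2mu)
    vapply(seq_len(nReps), function(r) {
        depth <- 2^stats::runif(1L, -spread, spread)
        mu <- depth * 2^log2mu
        stats::rnbinom(n, mu = mu, size = 1 / dispersion(mu))
    }, numeric(n))
}

.lnIntensities <- function(log2int, nReps, noiseSd) {
    n <- length(log2int)
    vapply(seq_len(nReps), function(r)
        2^(log2int + stats::rnorm(n, 0, noiseSd)), numeric(n))
}

#' Simulate a complete soma/synapse multi-omics study
#'
#' Draws the three measurement layers of the emulated study design --
#' negative-binomial transcript and ribosome-associated counts, log-normal
#' protein intensities -- for both compartments and three ages, together
#' with the per-gene ground truth needed to score recovery. See
#' [simParams()] for the generative model. Only the top
#' \code{proteomeDepthFraction} of genes by realized mean intensity appear
#' in the protein layer; the rest are genuinely missing, mimicking partial
#' proteome coverage.
#'
#' @param params a \code{"SimParams"} list from [simParams()]
#' @return a [SimStudy-class] with slots \code{rna}, \code{ribo},
#'   \code{protein} (each an [OmicsLayer-class] spanning TH and SYN at
#'   3w/5m/18m) and \code{truth}, a per-gene table of programmed class and
#'   effects
#' @examples
#' study <- simulateStudy(simParams(nGenes = 200, seed = 7))
#' studyLayer(study, "rna")
#' head(simTruth(study))
#' @export
simulateStudy <- function(params = simParams()) {
    stopifnot(inherits(params, "SimParams"))
    .checkSimParams(params)
    p <- params
    set.seed(p$seed)
    n <- p$nGenes
    cls <- .assignClasses(n, p$classFractions)
    genes <- sprintf("gene%05d", seq_len(n))
    rr <- cls %in% c("ribosomal", "respiratory")

    base <- stats::rnorm(n, p$baseLog2Mean, p$baseLog2Sd)
    lengths <- stats::setNames(round(stats::rlnorm(n, log(1500), 0.5)), genes)

    compRna <- vapply(p$compartmentEffectsLog2, `[[`, numeric(1), "rna")[cls]
    compProt <- vapply(p$compartmentEffectsLog2, `[[`,
                       numeric(1), "protein")[cls]

    devAff <- stats::runif(n) < p$devEffectFraction
    dev <- ifelse(devAff, stats::rnorm(n, 0, p$devEffectSdLog2), 0)

    drawAging <- function() {
        aff <- stats::runif(n) < p$agingEffectFraction
        ifelse(aff, stats::rnorm(n, 0, p$agingEffectSdLog2), 0)
    }
    agRnaTH <- ifelse(rr, p$agingEffectsLog2[["rna_TH"]], drawAging())
    agRnaSYN <- ifelse(rr, p$agingEffectsLog2[["rna_SYN"]], drawAging())
    agProtTH <- ifelse(rr, p$agingEffectsLog2[["protein_TH"]], drawAging())
    agProtSYN <- ifelse(rr, p$agingEffectsLog2[["protein_SYN"]], drawAging())

    teOffset <- ifelse(rr, p$teRepressionLog2, 0)

    ## log2 means per (compartment, age); dev applies from 5m on (coupled),
    ## aging on top at 18m (decoupled)
    rnaMu <- list(
        TH = list(`3w` = base, `5m` = base + dev,
                  `18m` = base + dev + agRnaTH),
        SYN = list(`3w` = base + compRna, `5m` = base + compRna + dev,
                   `18m` = base + compRna + dev + agRnaSYN))
    ## ribosome-associated means track the transcript means; the repression
    ## offset acts in SYN before old age and is released at 18m
    riboMu <- list(
        TH = rnaMu$TH,
        SYN = list(`3w` = rnaMu$SYN$`3w` + teOffset,
                   `5m` = rnaMu$SYN$`5m` + teOffset,
                   `18m` = rnaMu$SYN$`18m`))
    protBase <- p$proteinInterceptLog2 + p$proteinCouplingSlope * base
    protDev <- p$proteinCouplingSlope * dev
    protMu <- list(
        TH = list(`3w` = protBase, `5m` = protBase + protDev,
                  `18m` = protBase + protDev + agProtTH),
        SYN = list(`3w` = protBase + compProt,
                   `5m` = protBase + compProt + protDev,
                   `18m` = protBase + compProt + protDev + agProtSYN))

    buildLayer <- function(muList, layer, drawFun) {
        mats <- list(); meta <- list()
        for (comp in .COMPARTMENTS) {
            for (age in .AGE_LEVELS) {
                m <- drawFun(muList[[comp]][[age]])
                ids <- sprintf("%s_%s_%s_r%d", layer, comp, age,
                               seq_len(p$nReps))
                colnames(m) <- ids
                mats[[length(mats) + 1L]] <- m
                meta[[length(meta) + 1L]] <- data.frame(
                    sample_id = ids, compartment = comp, age_group = age,
                    replicate = seq_len(p$nReps),
                    stringsAsFactors = FALSE)
            }
        }
        vals <- do.call(cbind, mats)
        rownames(vals) <- genes
        list(values = vals, meta = do.call(rbind, meta))
    }

    rnaL <- buildLayer(rnaMu, "rna", function(mu)
        .nbCounts(mu, p$nReps, p$dispersion, p$libSizeSpreadLog2))
    riboL <- buildLayer(riboMu, "ribo", function(mu)
        .nbCounts(mu, p$nReps, p$dispersion, p$libSizeSpreadLog2))
    protL <- buildLayer(protMu, "protein", function(mu)
        .lnIntensities(mu, p$nReps, p$proteinNoiseSdLog2))

    nDet <- floor(p$proteomeDepthFraction * n)
    detected <- rank(-rowMeans(log2(protL$values)),
                     ties.method = "first") <= nDet
    protVals <- protL$values[detected, , drop = FALSE]

    truth <- DataFrame(
        gene_id = genes, class = cls,
        comp_rna_log2 = unname(compRna), comp_protein_log2 = unname(compProt),
        dev_log2 = dev,
        aging_rna_TH_log2 = agRnaTH, aging_rna_SYN_log2 = agRnaSYN,
        aging_protein_TH_log2 = agProtTH, aging_protein_SYN_log2 = agProtSYN,
        te_offset_log2 = teOffset,
        protein_detected = unname(detected),
        row.names = genes)

    new("SimStudy",
        rna = OmicsLayer(rnaL$values, rnaL$meta, "rna", lengths),
        ribo = OmicsLayer(riboL$values, riboL$meta, "ribo", lengths),
        protein = OmicsLayer(protVals, protL$meta, "protein"),
        truth = truth,
        params = unclass(p))
}

#' @describeIn simulateStudy extract one layer of the study, optionally
#'   restricted to a compartment and/or age group.
#' @param object a [SimStudy-class]
#' @param layer \code{"rna"}, \code{"ribo"} or \code{"protein"}
#' @param compartment,ageGroup optional restriction
#' @export
setMethod("studyLayer", "SimStudy",
          function(object, layer, compartment = NULL, ageGroup = NULL) {
    layer <- match.arg(layer, .LAYERS)
    x <- slot(object, layer)
    keep <- .sampleIndex(x, compartment, ageGroup)
    x[, keep]
})

#' @describeIn simulateStudy the per-gene ground-truth table.
#' @export
setMethod("simTruth", "SimStudy", function(object) object@truth)

setMethod("show", "SimStudy", function(object) {
    cat(sprintf("SimStudy: %d genes, %d replicates per cell, seed %d\n",
                object@params$nGenes, object@params$nReps,
                object@params$seed))
    cat(sprintf("  layers: rna (%d samples), ribo (%d), protein (%d genes x %d)\n",
                ncol(object@rna), ncol(object@ribo),
                nrow(object@protein), ncol(object@protein)))
})

#' Ground-truth labels for recovery questions
#'
#' Maps the simulator's truth table to the labels a recovery analysis is
#' scored against.
#'
#' \describe{
#'   \item{\code{quadrant_adult_SYNvsTH}}{per-gene programmed quadrant of
#'     the adult SYN-vs-TH map, from the sign pair of the programmed
#'     (transcript, protein) compartment effects; background genes sit on
#'     the boundary.}
#'   \item{\code{decoupled_aging_SYN}}{logical: gene belongs to a class with
#'     programmed aging decoupling in SYN (ribosomal or respiratory).}
#'   \item{\code{te_repressed_young}}{logical: gene carries the programmed
#'     translational-repression offset (ribosomal or respiratory).}
#' }
#'
#' @param truth the truth table of a [SimStudy-class] (see [simTruth()])
#' @param question one of the labels above
#' @return named vector (factor of quadrants, or logical), one entry per gene
#' @export
truthLabels <- function(truth,
                        question = c("quadrant_adult_SYNvsTH",
                                     "decoupled_aging_SYN",
                                     "te_repressed_young")) {
    question <- tryCatch(match.arg(question), error = function(e)
        stop("unknown question; supported: quadrant_adult_SYNvsTH, ",
             "decoupled_aging_SYN, te_repressed_young"))
    res <- switch(question,
        quadrant_adult_SYNvsTH = assignQuadrants(truth$comp_rna_log2,
                                                 truth$comp_protein_log2),
        decoupled_aging_SYN = truth$class %in% c("ribosomal", "respiratory"),
        te_repressed_young = truth$te_offset_log2 < 0)
    stats::setNames(res, truth$gene_id)
}
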