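test_that("decoupling score honours the sign semantics case by case", {
    expect_equal(decouplingScore(1, 1), 0)
    expect_equal(decouplingScore(2, 1), 1)    # protein increases more
    expect_equal(decouplingScore(-2, -1), -1) # protein decreases more
    expect_equal(decouplingScore(-1, -2), 1)  # protein reduced less
    expect_equal(decouplingScore(1, 2), -1)   # protein increases less
    # identity and antisymmetry
    x <- seq(-3, 3, by = 0.5)
    expect_true(all(decouplingScore(x, x) == 0))
    expect_equal(decouplingScore(x, rev(x)), -decouplingScore(rev(x), x))
    expect_error(decouplingScore(NaN, 1), "finite")
})

test_that("per-gene age correlation is rank-invariant to the age encoding", {
    v <- mat(c(2, 5, 64, 4, 5, 32, 8, 5, 16), nrow = 3,
             genes = c("g1", "g2", "g3"))
    v <- rbind(v, filler = 1000 - colSums(v))
    meta <- data.frame(sample_id = colnames(v), compartment = "TH",
                       age_group = c("3w", "5m", "18m"),
                       replicate = 1)
    gl <- setNames(rep(1000, 4), rownames(v))
    ol <- OmicsLayer(v, meta, "rna", gl)
    res <- suppressWarnings(perGeneAgeCorrelation(ol))
    expect_equal(res["g1", "rho"], 1)   # strictly increasing with age
    expect_equal(res["g3", "rho"], -1)  # strictly decreasing
    expect_true(is.na(res["g2", "rho"]))  # constant: undefined, counted
    expect_equal(S4Vectors::metadata(res)$n_undefined, 1)
    # alternative monotone age encoding leaves rho untouched
    meta2 <- meta; meta2$age_days <- c(1, 2, 3)
    ol2 <- OmicsLayer(v, meta2, "rna", gl)
    res2 <- suppressWarnings(perGeneAgeCorrelation(ol2))
    expect_equal(res2$rho, res$rho)
    # fewer than 2 distinct ages is an error
    meta3 <- meta; meta3$age_group <- "5m"; meta3$replicate <- 1:3
    expect_error(perGeneAgeCorrelation(OmicsLayer(v, meta3, "rna", gl)),
                 "distinct age")
})

test_that("per-gene age correlations recover programmed SYN aging trends", {
    study <- simulateStudy(simParams(seed = 13))
    tr <- simTruth(study)
    prot <- studyLayer(study, "protein", compartment = "SYN")
    rho <- suppressWarnings(perGeneAgeCorrelation(prot, "intensity"))
    ribo <- intersect(rownames(prot), tr$gene_id[tr$class == "ribosomal"])
    bg <- intersect(rownames(prot), tr$gene_id[tr$class == "background"])
    # ribosomal proteins rise with age in SYN (+0.75 programmed at 18m)
    expect_gt(mean(rho[ribo, "rho"]), mean(rho[bg, "rho"]) + 0.2)
})

test_that("rna-protein coupling is 1 for monotone layers and ~0 when shuffled", {
    study <- simulateStudy(simParams(nGenes = 2000, seed = 14))
    rna <- studyLayer(study, "rna")
    rv <- rpkm(rna)
    # build a fake protein layer as a monotone transform of RNA RPKM;
    # sample IDs are kept so replicate-matched pairing lines up
    pv <- sqrt(rv) + 1
    meta <- data.frame(sample_id = colnames(rna),
                       as.data.frame(colData(rna))[, c("compartment",
                                                       "age_group",
                                                       "replicate")])
    prot <- OmicsLayer(pv, meta, "protein")
    cc <- rnaProteinCoupling(rna, prot)
    expect_true(all(abs(cc$rho - 1) < 1e-8))
    expect_equal(nrow(cc), 24)  # 2 compartments x 3 ages x 4 replicates
    # independent values decorrelate
    set.seed(1)
    pv2 <- pv[sample(nrow(pv)), ]
    rownames(pv2) <- rownames(pv)
    prot2 <- OmicsLayer(pv2, meta, "protein")
    cc2 <- rnaProteinCoupling(rna, prot2)
    expect_lt(mean(abs(cc2$rho)), 0.05)
    expect_lt(max(abs(cc2$rho)), 0.1)
    # all-pairs pairing yields nReps^2 correlations per cell
    ccA <- rnaProteinCoupling(rna, prot, pairing = "all")
    expect_equal(nrow(ccA), 6 * 16)
})

test_that("coupling declines with age on simulated defaults", {
    study <- simulateStudy(simParams(seed = 15))
    cc <- rnaProteinCoupling(studyLayer(study, "rna"),
                             studyLayer(study, "protein"))
    m <- tapply(cc$rho, list(cc$compartment, as.character(cc$age_group)),
                mean)
    # independent aging effects decorrelate transcript and protein at 18m.
    # The clean readout is TH: in SYN the programmed ribosomal/respiratory
    # aging pattern moves those genes back toward the diagonal and partly
    # offsets the decline, so only the TH decline is asserted.
    expect_gt(m["TH", "3w"], m["TH", "18m"])
    expect_gt(m["TH", "5m"], m["TH", "18m"])
})

test_that("two-way ANOVA matches a hand-computed balanced table", {
    # 2x3 balanced design, n = 2 per cell, integer data
    A <- rep(c("a1", "a2"), each = 6)
    B <- rep(rep(c("b1", "b2", "b3"), each = 2), 2)
    y <- c(3, 5, 6, 8, 9, 11, 4, 6, 8, 10, 13, 15)
    res <- twoWayAnova(y, A, B)
    # oracle: direct sums of squares from cell/marginal means
    gm <- mean(y)
    ssA <- 6 * sum((tapply(y, A, mean) - gm)^2)
    ssB <- 4 * sum((tapply(y, B, mean) - gm)^2)
    cellm <- tapply(y, interaction(A, B), mean)
    ssCells <- 2 * sum((cellm - gm)^2)
    ssAB <- ssCells - ssA - ssB
    ssE <- sum((y - cellm[interaction(A, B)])^2)
    expect_equal(res$sumsq, c(ssA, ssB, ssAB))
    expect_equal(res$F[1], (ssA / 1) / (ssE / 6))
    expect_equal(res$p[1], pf(res$F[1], 1, 6, lower.tail = FALSE))
    expect_false(attr(res, "degenerate"))
})

test_that("two-way ANOVA flags degenerate designs and rejects bad input", {
    A <- rep(c("a1", "a2"), each = 4)
    B <- rep(c("b1", "b2"), 4)
    expect_error(twoWayAnova(rnorm(8), rep("a1", 8), B), "2 levels")
    # zero within-cell variance with a real A effect: F -> Inf, p -> 0
    y <- ifelse(A == "a2", 1, 0)
    res <- twoWayAnova(y, A, B)
    expect_true(attr(res, "degenerate"))
    expect_equal(res$p[res$term == "A"], 0)
    expect_equal(res$p[res$term == "B"], 1)
    # constant response: all F = 0, p = 1
    res0 <- twoWayAnova(rep(2, 8), A, B)
    expect_true(all(res0$p == 1))
    # empty cell violates the balanced contract
    expect_error(twoWayAnova(rnorm(6), c("a1", "a1", "a1", "a1", "a2", "a2"),
                             c("b1", "b2", "b1", "b2", "b1", "b1")),
                 "empty")
})
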