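test_that("median-of-ratios size factors match hand computations", {
    v <- mat(c(10, 20, 40, 10, 20, 40), nrow = 3)
    expect_equal(unname(sizeFactors(tinyLayer(v))), c(1, 1))

    v2 <- mat(c(10, 20, 40, 20, 40, 80), nrow = 3)
    # sample2 = 2 x sample1: geometric-mean scaling gives (1/sqrt(2), sqrt(2))
    expect_equal(unname(sizeFactors(tinyLayer(v2))),
                 c(1 / sqrt(2), sqrt(2)))

    # a gene with a zero is excluded from the reference set
    v3 <- rbind(v2, g4 = c(0, 1000))
    expect_equal(unname(sizeFactors(tinyLayer(v3))),
                 c(1 / sqrt(2), sqrt(2)))

    # no all-positive gene: total-count fallback with a warning
    v4 <- mat(c(0, 5, 5, 0), nrow = 2)
    expect_warning(sf <- sizeFactors(tinyLayer(v4)), "total-count")
    expect_equal(unname(sf), c(1, 1))
})

test_that("size factors agree with the DESeq2 reference implementation", {
    skip_if_not_installed("DESeq2")
    set.seed(42)
    # odd gene count: the median is an exact order statistic, so the
    # linear-space and log-space median-of-ratios conventions coincide
    v <- matrix(rnbinom(606, mu = 50, size = 5) + 1, nrow = 101)
    rownames(v) <- paste0("g", 1:101); colnames(v) <- paste0("s", 1:6)
    mine <- sizeFactors(tinyLayer(v))
    ref <- DESeq2::estimateSizeFactorsForMatrix(v)
    ref <- ref / exp(mean(log(ref)))  # rescale to geometric mean 1
    expect_equal(unname(mine), unname(ref), tolerance = 1e-10)
})

test_that("rpkm follows its defining formula and invariances", {
    v <- mat(c(10, 0, 200, 30, 7, 120), nrow = 3)
    gl <- setNames(c(1000, 500, 2500), rownames(v))
    # pad totals: add a filler gene so sample totals are controlled
    v2 <- rbind(v, filler = 1e6 - colSums(v))
    gl2 <- c(gl, filler = 1000)
    ol <- tinyLayer(v2, lengths = gl2, compartment = c("TH", "TH"))
    r <- rpkm(ol)
    expect_equal(r["g1", 1], 10)          # 10 / (1 * 1)
    expect_equal(r["g2", 1], 0)
    # 200 / (2.5 * 1) = 80 at total 1e6; spec arithmetic case at 4e7:
    v3 <- rbind(g1 = c(200), filler = 4e7 - 200)
    colnames(v3) <- "s1"
    ol3 <- tinyLayer(v3, lengths = c(g1 = 2500, filler = 1000),
                     compartment = "TH")
    expect_equal(rpkm(ol3)["g1", 1], 2.0)
    # scaling one sample's counts leaves its RPKM column unchanged
    v4 <- v2; v4[, 2] <- v4[, 2] * 7
    r4 <- rpkm(tinyLayer(v4, lengths = gl2, compartment = c("TH", "TH")))
    expect_equal(r4[, 2], r[, 2])
    # missing lengths fail naming the gene
    expect_error(rpkm(tinyLayer(v2, lengths = gl2[-1],
                                compartment = c("TH", "TH"))), "g1")
})

test_that("differential matches hand-computed Welch results", {
    # 3 vs 3 'protein' samples so values are used as-is (pseudocount 0)
    y <- mat(2^c(1, 2, 3, 3, 4, 5), nrow = 1)
    ol <- tinyLayer(y, layer = "protein",
                    compartment = rep(c("TH", "SYN"), each = 3))
    res <- runDifferential(ol, paste0("s", 1:3), paste0("s", 4:6))
    o <- handWelch(c(1, 2, 3), c(3, 4, 5))
    expect_equal(res$log2fc, 2)
    expect_equal(res$stat, o$t)            # -2.449...
    expect_equal(res$stat, -2.449, tolerance = 1e-3)
    expect_equal(res$p, o$p)

    # identical groups: zero statistic convention
    y2 <- mat(rep(2^c(1, 2, 3), 2), nrow = 1)
    ol2 <- tinyLayer(y2, layer = "protein",
                     compartment = rep(c("TH", "SYN"), each = 3))
    res2 <- runDifferential(ol2, paste0("s", 1:3), paste0("s", 4:6))
    expect_equal(res2$log2fc, 0)
    expect_equal(res2$p, 1)
})

test_that("differential enforces its group contract", {
    v <- mat(rpois(40, 20), nrow = 5)
    ol <- tinyLayer(v)
    expect_error(runDifferential(ol, paste0("s", 1:4), paste0("s", 4:8)),
                 "disjoint")
    expect_error(runDifferential(ol, "s1", paste0("s", 5:8)),
                 "at least 2")
    # all-zero genes are excluded from testing
    v2 <- v; v2[3, ] <- 0
    res <- runDifferential(tinyLayer(v2), paste0("s", 1:4), paste0("s", 5:8))
    expect_false("g3" %in% res$gene_id)
})

test_that("BH adjustment matches the naive step-up oracle", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
    expect_equal(bhAdjust(c(0.01, 0.04, 0.9)), c(0.03, 0.06, 0.9))
    expect_equal(bhAdjust(0.05), 0.05)
    set.seed(1)
    for (i in 1:25) {
        p <- runif(sample(5:200, 1))
        expect_equal(bhAdjust(p), naiveBH(p))
    }
    expect_error(bhAdjust(c(0.5, 0)), "\\(0, 1\\]")
    expect_error(bhAdjust(c(0.5, 1.2)), "\\(0, 1\\]")
    # idempotent-monotone property: readjusting never lowers values
    set.seed(2)
    p <- runif(100)
    expect_true(all(bhAdjust(bhAdjust(p)) >= bhAdjust(p)))
})

test_that("differential p-values are calibrated on label-permuted data", {
    # a study with every effect zeroed: SYN vs TH at 5m is a true 4v4 null
    nullParams <- simParams(
        nGenes = 2000,
        compartmentEffectsLog2 = lapply(simParams()$compartmentEffectsLog2,
                                        function(x) x * 0),
        devEffectFraction = 0, agingEffectFraction = 0,
        agingEffectsLog2 = c(rna_TH = 0, rna_SYN = 0,
                             protein_TH = 0, protein_SYN = 0),
        teRepressionLog2 = 0, seed = 8)
    study <- simulateStudy(nullParams)
    res <- diffCompartments(studyLayer(study, "rna"), "5m")
    ks <- suppressWarnings(ks.test(res$p, "punif"))
    expect_gt(ks$p.value, 0.01)
})
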