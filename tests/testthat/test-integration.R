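test_that("Fisher's method obeys its closed forms and monotonicity", {
    expect_equal(fisherCombine(c(1, 1)), 1)
    # k = 1 is the identity: chi^2_2 survival at -2 log p equals p
    for (p in c(0.3, 0.05, 1e-6, 1)) expect_equal(fisherCombine(p), p)
    # (0.05, 0.05): X = -4 log(0.05) = 11.9829...; chi^2_4 upper tail
    x <- -2 * sum(log(c(0.05, 0.05)))
    expect_equal(x, 11.98293, tolerance = 1e-6)
    expect_equal(fisherCombine(c(0.05, 0.05)),
                 pchisq(x, df = 4, lower.tail = FALSE))
    expect_error(fisherCombine(numeric()), "empty")
    expect_error(fisherCombine(c(0.5, 0)), "\\(0, 1\\]")
    # monotone: lowering any input never raises the output
    set.seed(4)
    for (i in 1:20) {
        p <- runif(3, 0.01, 1)
        j <- sample(3, 1)
        q <- p; q[j] <- p[j] * runif(1)
        expect_lte(fisherCombine(q), fisherCombine(p))
    }
})

test_that("quadrants follow the clockwise-from-upper-right convention", {
    expect_equal(as.character(assignQuadrants(1, 2)), "Q1")
    expect_equal(as.character(assignQuadrants(1, -1)), "Q2")
    expect_equal(as.character(assignQuadrants(-1, -1)), "Q3")
    expect_equal(as.character(assignQuadrants(-1, 1)), "Q4")
    expect_equal(as.character(assignQuadrants(0, 1)), "boundary")
    expect_error(assignQuadrants(NaN, 1), "finite")
})

.mkDiff <- function(ids, fc, p) {
    S4Vectors::DataFrame(gene_id = ids, log2fc = fc, stat = 0,
                         p = p, padj = bhAdjust(p))
}

test_that("matchOmics joins, combines and conserves quadrant counts", {
    rna <- .mkDiff(paste0("g", 1:5), c(1, -1, 2, 0.5, -2),
                   c(0.01, 0.2, 0.03, 0.5, 0.04))
    prot <- .mkDiff(paste0("g", c(2, 3, 5)), c(1, -0.5, -1),
                    c(0.05, 0.01, 0.6))
    mt <- matchOmics(rna, prot)
    expect_identical(mt$gene_id, paste0("g", c(2, 3, 5)))
    # combined p recomputed independently per row
    for (i in seq_len(nrow(mt)))
        expect_equal(mt$combined_p[i],
                     fisherCombine(c(mt$rna_padj[i], mt$prot_padj[i])))
    # conservation: quadrants plus boundary = all matched genes
    expect_equal(sum(table(mt$quadrant)), nrow(mt))
    # disjoint tables give an empty join
    expect_equal(nrow(matchOmics(rna[1:2, ], prot[3, , drop = FALSE])), 0)
    dup <- rbind(rna, rna[1, ])
    expect_error(matchOmics(dup, prot), "duplicate")
})

test_that("significance selection honours both rules and the alpha edge", {
    rna <- .mkDiff(paste0("g", 1:3), c(1, 1, 1), c(0.001, 0.01, 0.9))
    prot <- .mkDiff(paste0("g", 1:3), c(1, 1, 1), c(0.002, 0.5, 0.9))
    mt <- matchOmics(rna, prot)
    fis <- selectSignificant(mt, 0.05, "fisher")
    int <- selectSignificant(mt, 0.05, "intersection")
    # g2 (rna strong, protein weak) can survive fisher but not intersection
    expect_false("g2" %in% int$gene_id)
    expect_true(all(int$gene_id %in% fis$gene_id))
    expect_true(all(fis$combined_padj < 0.05))
    # alpha = 1 keeps everything under both rules
    expect_equal(nrow(selectSignificant(mt, 1, "fisher")), 3)
    expect_equal(nrow(selectSignificant(mt, 1, "intersection")), 3)
})

test_that("fisherExact2x2 matches enumeration and handles extremes", {
    expect_equal(fisherExact2x2(1, 1, 1, 1), 1)
    expect_equal(fisherExact2x2(2, 0, 0, 2), 1 / 3)
    # matrix input, same convention as the cellwise call
    expect_equal(fisherExact2x2(matrix(c(2, 0, 0, 2), 2, byrow = TRUE)),
                 1 / 3)
    expect_error(fisherExact2x2(-1, 1, 1, 1), "non-negative")
    # independent cross-check against stats::fisher.test on random tables
    set.seed(9)
    for (i in 1:50) {
        cells <- rpois(4, sample(c(2, 10, 40), 1))
        if (sum(cells) == 0) next
        mine <- fisherExact2x2(cells[1], cells[2], cells[3], cells[4])
        ref <- fisher.test(matrix(cells, 2, byrow = TRUE))$p.value
        expect_equal(mine, ref, tolerance = 1e-10)
        expect_equal(mine, enumFisher2x2(cells[1], cells[2],
                                         cells[3], cells[4]),
                     tolerance = 1e-10)
    }
})

test_that("quadrant association reduces to the sign 2x2 exact test", {
    mk <- function(q1, q2, q3, q4) {
        fcR <- c(rep(1, q1 + q2), rep(-1, q3 + q4))
        fcP <- c(rep(1, q1), rep(-1, q2 + q3), rep(1, q4))
        n <- q1 + q2 + q3 + q4
        S4Vectors::DataFrame(gene_id = paste0("g", seq_len(n)),
                             rna_log2fc = fcR, prot_log2fc = fcP,
                             quadrant = assignQuadrants(fcR, fcP))
    }
    balanced <- quadrantAssociationTest(mk(10, 10, 10, 10))
    expect_equal(balanced$p, 1)
    expect_equal(unname(balanced$table["up", "up"]), 10)
    expect_equal(quadrantAssociationTest(mk(1, 1, 1, 1))$p, 1)
    # full association: compare against the enumeration oracle
    extreme <- quadrantAssociationTest(mk(50, 0, 50, 0))
    expect_equal(extreme$p, enumFisher2x2(50, 0, 0, 50))
    expect_lt(extreme$p, 1e-25)
})

test_that("coupling correlation is rank-based with the t-approximate p", {
    up <- couplingCorrelation(1:10, (1:10)^3)
    expect_equal(up$rho, 1); expect_equal(up$p, 0)
    expect_equal(couplingCorrelation(1:10, -(1:10))$rho, -1)
    hand <- couplingCorrelation(c(1, 2, 3, 4), c(2, 1, 4, 3))
    expect_equal(hand$rho, 0.6)  # 1 - 6*4/(4*15)
    expect_error(couplingCorrelation(1:2, 2:1), "at least 3")
    expect_error(couplingCorrelation(rep(1, 5), 1:5), "constant")
    # invariance under strictly monotone transforms
    set.seed(10)
    x <- rnorm(30); y <- x + rnorm(30)
    base <- couplingCorrelation(x, y)$rho
    expect_equal(couplingCorrelation(exp(x), y)$rho, base)
    expect_equal(couplingCorrelation(x, atan(y))$rho, base)
})
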