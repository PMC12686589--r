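# Independent oracles kept deliberately separate from the implementation:
# plain-arithmetic re-derivations used to freeze expected values.

# Benjamini-Hochberg by the literal step-up definition
naiveBH <- function(p) {
    m <- length(p)
    o <- order(p, decreasing = TRUE)
    ro <- order(o)
    adj <- pmin(1, cummin(m / (m:1) * p[o]))[ro]
    adj
}

# two-sided Fisher exact p by exhaustive enumeration with choose()
enumFisher2x2 <- function(a, b, c, d) {
    r1 <- a + b; r2 <- c + d; k <- a + c; n <- r1 + r2
    xs <- max(0, k - r2):min(k, r1)
    probs <- choose(r1, xs) * choose(r2, k - xs) / choose(n, k)
    obs <- probs[xs == a]
    sum(probs[probs <= obs * (1 + 1e-7)])
}

# Welch t, df and p from the closed forms
handWelch <- function(x, y) {
    vx <- var(x); vy <- var(y)
    se2 <- vx / length(x) + vy / length(y)
    t <- (mean(x) - mean(y)) / sqrt(se2)
    df <- se2^2 / ((vx / length(x))^2 / (length(x) - 1) +
                   (vy / length(y))^2 / (length(y) - 1))
    list(t = t, df = df, p = 2 * pt(abs(t), df, lower.tail = FALSE))
}

# a minimal OmicsLayer for unit tests: two compartments, one age
tinyLayer <- function(values, layer = "rna", lengths = NULL,
                      compartment = NULL, age = "5m") {
    ns <- ncol(values)
    if (is.null(compartment))
        compartment <- rep(c("TH", "SYN"), each = ns / 2)
    meta <- data.frame(sample_id = colnames(values),
                       compartment = compartment,
                       age_group = age,
                       replicate = ave(seq_len(ns),
                                       compartment, age,
                                       FUN = seq_along),
                       stringsAsFactors = FALSE)
    OmicsLayer(values, meta, layer = layer, geneLengths = lengths)
}

# deterministic matrix helper
mat <- function(x, nrow, genes = NULL, samples = NULL) {
    m <- matrix(x, nrow = nrow)
    rownames(m) <- if (is.null(genes)) paste0("g", seq_len(nrow)) else genes
    colnames(m) <- if (is.null(samples)) paste0("s", seq_len(ncol(m)))
                   else samples
    m
}
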