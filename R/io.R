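#' Read an expression table and its sample metadata
#'
#' Reads a tab-separated gene-by-sample table (first column gene IDs, header
#' row of sample IDs) together with a tab-separated metadata table (one row
#' per sample: \code{sample_id}, \code{compartment}, \code{age_group},
#' \code{replicate}, optionally \code{age_days}). Samples are reordered to
#' the metadata order. Rows sharing a gene ID are collapsed: summed for count
#' layers (counts are additive), element-wise maximum for protein
#' intensities (they are not).
#'
#' @param valuesPath path to the TSV value matrix
#' @param metaPath path to the TSV sample metadata
#' @param layer \code{"rna"}, \code{"ribo"} or \code{"protein"}
#' @param lengthsPath optional TSV with columns \code{gene_id},
#'   \code{length}; lengths may also be supplied later, but RPKM will fail
#'   without them.
#' @return an [OmicsLayer-class]
#' @seealso [writeExpressionTable()]
#' @export
readExpressionTable <- function(valuesPath, metaPath,
                                layer = c("rna", "ribo", "protein"),
                                lengthsPath = NULL) {
    layer <- match.arg(layer)
    tab <- utils::read.delim(valuesPath, header = TRUE, sep = "\t",
                             check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 2L)
        stop("value table needs a gene ID column plus at least one sample")
    genes <- as.character(tab[[1L]])
    vals <- as.matrix(tab[, -1L, drop = FALSE])
    storage.mode(vals) <- "double"
    if (anyNA(vals)) stop("value table contains missing values")
    if (any(vals < 0)) stop("value table contains negative values")
    meta <- utils::read.delim(metaPath, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
    if (!"sample_id" %in% colnames(meta))
        stop("metadata must have a sample_id column")
    miss <- setdiff(colnames(vals), meta$sample_id)
    if (length(miss))
        stop("sample(s) absent from metadata: ", paste(miss, collapse = ", "))
    meta <- meta[meta$sample_id %in% colnames(vals), , drop = FALSE]
    vals <- vals[, meta$sample_id, drop = FALSE]
    ## collapse duplicate gene IDs
    if (anyDuplicated(genes)) {
        f <- if (layer == "protein") max else sum
        vals <- do.call(rbind,
                        lapply(split(seq_along(genes), genes), function(i)
                            apply(vals[i, , drop = FALSE], 2L, f)))
        ## split() orders by factor level; restore first-appearance order
        vals <- vals[unique(genes), , drop = FALSE]
    } else {
        rownames(vals) <- genes
    }
    gl <- NULL
    if (!is.null(lengthsPath)) {
        lt <- utils::read.delim(lengthsPath, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
        gl <- stats::setNames(as.numeric(lt[[2L]]), as.character(lt[[1L]]))
    }
    OmicsLayer(vals, meta, layer = layer, geneLengths = gl)
}

#' Write an OmicsLayer back to TSV tables
#'
#' Inverse of [readExpressionTable()]: writes the value matrix (gene IDs in
#' the first column, \code{gene_id}), the sample metadata, and optionally the
#' gene lengths as tab-separated files. A read/write round trip preserves
#' genes, samples and values exactly.
#'
#' @param object an [OmicsLayer-class]
#' @param valuesPath,metaPath,lengthsPath output file paths
#'   (\code{lengthsPath} optional)
#' @return invisibly, \code{object}
#' @export
writeExpressionTable <- function(object, valuesPath, metaPath,
                                 lengthsPath = NULL) {
    stopifnot(is(object, "OmicsLayer"))
    v <- assay(object, "values")
    df <- data.frame(gene_id = rownames(v), v, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, valuesPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    cd <- as.data.frame(colData(object))
    meta <- data.frame(sample_id = rownames(cd), cd, check.names = FALSE,
                       stringsAsFactors = FALSE)
    utils::write.table(meta, metaPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (!is.null(lengthsPath)) {
        gl <- geneLengths(object)
        if (!is.null(gl))
            utils::write.table(
                data.frame(gene_id = names(gl), length = unname(gl)),
                lengthsPath, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    invisible(object)
}

#' Read gene sets from a GMT file
#'
#' One set per line, tab-separated: name, description, then member gene IDs.
#' Duplicate members within a set are counted once. When a \code{universe}
#' is given, members are intersected with it and sets retaining fewer than
#' \code{minSize} members are dropped (gene-set tests are unstable below a
#' handful of genes; the conventional floor of 5 is the default).
#'
#' @param path GMT file path
#' @param universe optional character vector of analyzable gene IDs
#' @param minSize minimum number of members (post-intersection) to retain
#' @return a [GeneSetCollection-class]
#' @export
readGeneSets <- function(path, universe = NULL, minSize = 5L) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop("empty GMT file: ", path)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- lengths(parts) < 3L
    if (any(bad))
        stop("GMT line without members at line ", which(bad)[1L])
    nm <- vapply(parts, `[[`, character(1), 1L)
    if (anyDuplicated(nm))
        stop("duplicate set name: ", nm[duplicated(nm)][1L])
    sets <- lapply(parts, function(p) unique(p[-(1:2)]))
    names(sets) <- nm
    coll <- new("GeneSetCollection", sets = sets,
                minSize = as.integer(minSize))
    if (!is.null(universe))
        coll <- filterGeneSets(coll, universe, minSize)
    coll
}

#' Filter a gene-set collection against a universe
#'
#' Intersects every set with \code{universe} and drops sets that retain
#' fewer than \code{minSize} members. Filtering is idempotent: applying it
#' twice with the same universe and size gives the same collection.
#'
#' @param collection a [GeneSetCollection-class]
#' @param universe character vector of gene IDs
#' @param minSize minimum retained size (defaults to the collection's)
#' @return a filtered [GeneSetCollection-class]
#' @export
filterGeneSets <- function(collection, universe, minSize = NULL) {
    stopifnot(is(collection, "GeneSetCollection"))
    if (is.null(minSize)) minSize <- collection@minSize
    sets <- lapply(collection@sets, intersect, y = universe)
    sets <- sets[lengths(sets) >= minSize]
    new("GeneSetCollection", sets = sets, minSize = as.integer(minSize))
}

#' @describeIn readGeneSets accessor: the named list of gene sets
#' @param object a GeneSetCollection
#' @export
setMethod("geneSets", "GeneSetCollection", function(object) object@sets)

#' @describeIn readGeneSets accessor: the minimum set size
#' @export
setMethod("minSize", "GeneSetCollection", function(object) object@minSize)

#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@sets))

#' @export
setMethod("names", "GeneSetCollection", function(x) names(x@sets))

setMethod("show", "GeneSetCollection", function(object) {
    cat(sprintf("GeneSetCollection: %d sets (minSize = %d)\n",
                length(object@sets), object@minSize))
    if (length(object@sets)) {
        sz <- lengths(object@sets)
        cat(sprintf("  sizes: %d-%d (median %g)\n",
                    min(sz), max(sz), stats::median(sz)))
    }
})
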