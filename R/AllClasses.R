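#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<-
#'   assayNames colData colData<- rowData rowData<-
NULL

#' DGEDataSet: container for a quantitative-trait DGE analysis
#'
#' `DGEDataSet` extends [SummarizedExperiment::SummarizedExperiment] and holds
#' a raw gene x sample read-count matrix (assay `"counts"`), optional gene
#' lengths (`rowData$geneLength`), per-sample traits and covariates
#' (`colData`), size factors (`colData$sizeFactor` once estimated) and the
#' log2 size-factor-normalized expression matrix (assay `"logExpr"` once
#' [normalizeLog2()] has been called).
#'
#' @slot ... inherited from `SummarizedExperiment`.
#'
#' @seealso [DGEDataSet()] the constructor, [estimateSizeFactors()],
#'   [normalizeLog2()], [runLMM()]
#' @export
setClass("DGEDataSet", contains = "SummarizedExperiment")

setValidity("DGEDataSet", function(object) {
    msg <- NULL
    if (!("counts" %in% assayNames(object)))
        msg <- c(msg, "assay 'counts' is required")
    else {
        k <- assay(object, "counts")
        if (any(k < 0)) msg <- c(msg, "count matrix contains negative entries")
        if (any(!is.finite(k))) msg <- c(msg, "count matrix contains non-finite entries")
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "gene identifiers must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample identifiers must be present and unique")
    if (nrow(object) < 1L) msg <- c(msg, "at least one gene is required")
    if (ncol(object) < 2L) msg <- c(msg, "at least two samples are required")
    if (!is.null(rowData(object)$geneLength)) {
        len <- rowData(object)$geneLength
        if (any(!is.na(len) & len <= 0))
            msg <- c(msg, "gene lengths must be positive")
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct a DGEDataSet
#'
#' @param counts integer-like gene x sample matrix of raw read counts with
#'   row (gene) and column (sample) names.
#' @param colData optional `DataFrame`/`data.frame` of per-sample traits and
#'   covariates, one row per sample, rownames matching `colnames(counts)`.
#' @param geneLengths optional numeric vector of gene lengths in bases,
#'   either named by gene id or aligned to `rownames(counts)`; required only
#'   for TPM-based gene filtering.
#'
#' @return A [DGEDataSet-class] object.
#' @examples
#' k <- matrix(rpois(40, 20), nrow = 10,
#'             dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
#' dds <- DGEDataSet(k)
#' dds
#' @export
DGEDataSet <- function(counts, colData = NULL, geneLengths = NULL) {
    counts <- as.matrix(counts)
    if (is.null(rownames(counts)))
        rownames(counts) <- paste0("gene", seq_len(nrow(counts)))
    if (is.null(colnames(counts)))
        colnames(counts) <- paste0("sample", seq_len(ncol(counts)))
    storage.mode(counts) <- "double"
    if (is.null(colData)) {
        colData <- DataFrame(row.names = colnames(counts))
    } else {
        colData <- as(colData, "DataFrame")
        if (!is.null(rownames(colData))) {
            missing <- setdiff(colnames(counts), rownames(colData))
            if (length(missing))
                stop("colData lacks rows for samples: ",
                     paste(missing, collapse = ", "))
            colData <- colData[colnames(counts), , drop = FALSE]
        } else if (nrow(colData) != ncol(counts)) {
            stop("colData has ", nrow(colData), " rows but counts has ",
                 ncol(counts), " samples")
        }
    }
    rd <- DataFrame(row.names = rownames(counts))
    if (!is.null(geneLengths)) {
        if (!is.null(names(geneLengths))) {
            missing <- setdiff(rownames(counts), names(geneLengths))
            if (length(missing))
                stop("geneLengths lacks entries for genes: ",
                     paste(head(missing, 5L), collapse = ", "))
            geneLengths <- geneLengths[rownames(counts)]
        } else if (length(geneLengths) != nrow(counts)) {
            stop("geneLengths must align with rows of counts")
        }
        rd$geneLength <- as.numeric(geneLengths)
    }
    se <- SummarizedExperiment(assays = list(counts = counts),
                               colData = colData, rowData = rd)
    new("DGEDataSet", se)
}

#' @describeIn DGEDataSet-class raw count matrix accessor
#' @param object a `DGEDataSet`
#' @export
setMethod("counts", "DGEDataSet", function(object) assay(object, "counts"))

#' @describeIn DGEDataSet-class per-sample size factors (NULL before
#'   [estimateSizeFactors()])
#' @export
setMethod("sizeFactors", "DGEDataSet", function(object) {
    sf <- colData(object)$sizeFactor
    if (is.null(sf)) return(NULL)
    stats::setNames(sf, colnames(object))
})

#' @describeIn DGEDataSet-class set per-sample size factors
#' @param value numeric vector of positive size factors, one per sample
#' @export
setReplaceMethod("sizeFactors", "DGEDataSet", function(object, value) {
    if (length(value) != ncol(object))
        stop("need one size factor per sample")
    if (any(!is.finite(value)) || any(value <= 0))
        stop("size factors must be finite and strictly positive")
    colData(object)$sizeFactor <- as.numeric(value)
    object
})

#' Gene lengths stored in a DGEDataSet
#' @param object a `DGEDataSet`
#' @return named numeric vector of gene lengths, or NULL if absent.
#' @export
geneLengths <- function(object) {
    len <- rowData(object)$geneLength
    if (is.null(len)) return(NULL)
    stats::setNames(len, rownames(object))
}

#' Log2 normalized expression matrix
#'
#' Returns the `"logExpr"` assay produced by [normalizeLog2()].
#' @param object a `DGEDataSet`
#' @return gene x sample numeric matrix of log2(count/sizeFactor + 1) values.
#' @export
normalizedExpression <- function(object) {
    if (!("logExpr" %in% assayNames(object)))
        stop("no normalized expression found; run estimateSizeFactors() and normalizeLog2() first")
    assay(object, "logExpr")
}

setMethod("show", "DGEDataSet", function(object) {
    cat("DGEDataSet with", nrow(object), "genes and", ncol(object), "samples\n")
    cat("assays:", paste(assayNames(object), collapse = ", "), "\n")
    sf <- sizeFactors(object)
    cat("size factors:",
        if (is.null(sf)) "not estimated" else
            paste0("range [", signif(min(sf), 4), ", ", signif(max(sf), 4), "]"),
        "\n")
    if (ncol(colData(object)))
        cat("colData:", paste(colnames(colData(object)), collapse = ", "), "\n")
    fr <- metadata(object)$filterReport
    if (!is.null(fr))
        cat("filters applied:", length(fr), "\n")
    invisible(NULL)
})

#' DGEResults: per-gene association test results
#'
#' A `DFrame` subclass with one row per tested gene and columns `gene_id`,
#' `chr`, `beta`, `se`, `stat`, `pvalue`, `gammaHat` (LMM only, NA
#' otherwise), `flag`, `method` and `model` (the regression direction:
#' `"trait~expression"` for LMM/OLS/robust, `"expression~trait"` for voom).
#'
#' @export
setClass("DGEResults", contains = "DFrame")

.resultColumns <- c("gene_id", "chr", "beta", "se", "stat", "pvalue",
                    "gammaHat", "flag", "method", "model")

setValidity("DGEResults", function(object) {
    msg <- NULL
    missing <- setdiff(.resultColumns, colnames(object))
    if (length(missing))
        msg <- c(msg, paste("missing columns:", paste(missing, collapse = ", ")))
    if ("pvalue" %in% colnames(object)) {
        p <- object$pvalue
        ok <- is.na(p) | (p > 0 & p <= 1)
        if (!all(ok)) msg <- c(msg, "p-values must lie in (0, 1]")
    }
    if (is.null(msg)) TRUE else msg
})

.DGEResults <- function(df, method, model, extraMeta = list()) {
    df$method <- method
    df$model <- model
    for (nm in setdiff(.resultColumns, colnames(df))) df[[nm]] <- NA
    df <- df[, .resultColumns]
    out <- new("DGEResults", as(df, "DFrame"))
    metadata(out) <- c(list(method = method, model = model), extraMeta)
    out
}

setMethod("show", "DGEResults", function(object) {
    cat("DGEResults:", nrow(object), "genes, method =",
        metadata(object)$method %||% unique(object$method), "\n")
    cat("model:", metadata(object)$model %||% unique(object$model), "\n")
    p <- object$pvalue
    cat(sprintf("p-value range: [%.3g, %.3g]; %d flagged rows\n",
                suppressWarnings(min(p, na.rm = TRUE)),
                suppressWarnings(max(p, na.rm = TRUE)),
                sum(!is.na(object$flag) & object$flag != "")))
    callNextMethod()
})

`%||%` <- function(a, b) if (is.null(a)) b else a
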