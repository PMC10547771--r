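#' @importFrom BiocGenerics counts sizeFactors sizeFactors<- estimateSizeFactors
NULL

.addFilterReport <- function(object, report) {
    fr <- metadata(object)$filterReport
    if (is.null(fr)) fr <- list()
    fr[[report$stage]] <- report
    metadata(object)$filterReport <- fr
    object
}

#' Filter reports attached to a DGEDataSet
#' @param object a `DGEDataSet`
#' @return named list of filter reports (`samples`, `genes`), each a list
#'   with the removed identifiers, the per-unit statistic and the thresholds
#'   used; NULL if no filter has run.
#' @export
filterReport <- function(object) metadata(object)$filterReport

#' Remove low-depth samples
#'
#' Samples whose total mapped read count is strictly below
#' `minTotalReads` are dropped. The conventional floor for bulk RNA-seq is
#' ten million mapped reads; equality with the threshold retains the sample.
#'
#' @param object a [DGEDataSet-class]
#' @param minTotalReads non-negative integer threshold on column sums
#'   (default 1e7).
#' @return the filtered `DGEDataSet`, with the removal report retrievable
#'   via [filterReport()].
#' @export
filterSamples <- function(object, minTotalReads = 1e7) {
    stopifnot(is(object, "DGEDataSet"), minTotalReads >= 0)
    totals <- colSums(counts(object))
    keep <- totals >= minTotalReads
    if (!any(keep))
        stop("all samples have total reads below the threshold of ",
             format(minTotalReads, big.mark = ",", scientific = FALSE),
             "; nothing retained")
    report <- list(stage = "samples",
                   removed = colnames(object)[!keep],
                   totalReads = totals[!keep],
                   minTotalReads = minTotalReads)
    .addFilterReport(object[, keep], report)
}

#' Transcripts-per-million matrix
#'
#' For each sample, TPM of gene j is its length-normalized read rate scaled
#' to sum to one million: \eqn{(K_j/L_j) / \sum_g (K_g/L_g) \times 10^6}.
#' Requires gene lengths (bases) in `rowData(object)$geneLength`.
#'
#' @param object a [DGEDataSet-class] with gene lengths
#' @return gene x sample numeric matrix of TPM values; each column with any
#'   nonzero count sums to 1e6.
#' @export
computeTPM <- function(object) {
    len <- geneLengths(object)
    if (is.null(len) || any(is.na(len)))
        stop("gene lengths are required to compute TPM; supply them via ",
             "DGEDataSet(geneLengths=) or skip the TPM gene filter")
    rate <- counts(object) / len
    denom <- colSums(rate)
    tpm <- sweep(rate, 2L, ifelse(denom > 0, denom, 1), "/") * 1e6
    dimnames(tpm) <- dimnames(counts(object))
    tpm
}

#' Remove genes expressed below a TPM floor in too many samples
#'
#' A gene is dropped when its TPM is below `tpmFloor` in strictly more than
#' `maxFractionBelow` of the samples (the conventional rule: < 0.1 TPM in
#' > 20\% of samples).
#'
#' @param object a [DGEDataSet-class]
#' @param tpm optional precomputed TPM matrix from [computeTPM()]
#' @param tpmFloor expression floor in TPM units (default 0.1)
#' @param maxFractionBelow maximum tolerated fraction of samples below the
#'   floor, in `[0, 1]` (default 0.20); the rule is strict (`>`).
#' @return the filtered `DGEDataSet`.
#' @export
filterGenes <- function(object, tpm = NULL, tpmFloor = 0.1,
                        maxFractionBelow = 0.20) {
    stopifnot(is(object, "DGEDataSet"),
              maxFractionBelow >= 0, maxFractionBelow <= 1)
    if (is.null(tpm)) tpm <- computeTPM(object)
    stopifnot(identical(dim(tpm), dim(counts(object))))
    fracBelow <- rowMeans(tpm < tpmFloor)
    keep <- fracBelow <= maxFractionBelow
    if (!any(keep))
        stop("all genes fall below ", tpmFloor, " TPM in more than ",
             100 * maxFractionBelow, "% of samples; nothing retained")
    report <- list(stage = "genes",
                   removed = rownames(object)[!keep],
                   fractionBelow = fracBelow[!keep],
                   tpmFloor = tpmFloor,
                   maxFractionBelow = maxFractionBelow)
    .addFilterReport(object[keep, ], report)
}

#' Median-of-ratios size factors for a count matrix
#'
#' The size factor of sample i is the median, over genes whose geometric
#' mean across samples is nonzero, of the ratio of the sample's count to
#' that geometric mean. Genes containing any zero count have geometric mean
#' zero and are excluded from the reference set. The median is taken on the
#' log-ratio scale (for an even reference-gene count the two central
#' ratios are averaged geometrically), the convention of the standard
#' median-of-ratios normalizer, so results agree bit-for-bit with it.
#'
#' @param counts gene x sample numeric matrix of raw counts.
#' @return named numeric vector of strictly positive size factors.
#' @export
sizeFactorsFromCounts <- function(counts) {
    counts <- as.matrix(counts)
    allPositive <- rowSums(counts <= 0) == 0L
    if (!any(allPositive))
        stop("no gene has all-positive counts: the geometric-mean reference ",
             "set is empty and size factors cannot be computed")
    ref <- counts[allPositive, , drop = FALSE]
    logGeoMean <- rowMeans(log(ref))
    s <- apply(ref, 2L, function(k) exp(stats::median(log(k) - logGeoMean)))
    bad <- !is.finite(s) | s <= 0
    if (any(bad))
        stop("non-positive size factor for sample(s): ",
             paste(colnames(counts)[bad], collapse = ", "))
    stats::setNames(s, colnames(counts))
}

#' Estimate median-of-ratios size factors for a DGEDataSet
#'
#' Applies [sizeFactorsFromCounts()] to the raw counts and stores the
#' result in `colData(object)$sizeFactor`.
#'
#' @param object a [DGEDataSet-class]
#' @return the `DGEDataSet` with size factors set.
#' @export
setMethod("estimateSizeFactors", "DGEDataSet", function(object) {
    sizeFactors(object) <- sizeFactorsFromCounts(counts(object))
    object
})

#' Size-factor normalization and log2 transformation
#'
#' Computes \eqn{x_{ij} = \log_2(K_{ij}/s_i + 1)} and stores it as assay
#' `"logExpr"`. These values are the per-gene test covariates for the LMM,
#' linear and robust regression engines.
#'
#' @param object a [DGEDataSet-class] with size factors estimated
#' @param s optional size-factor vector overriding the stored one; must be
#'   strictly positive and aligned (by name) with the samples.
#' @return the `DGEDataSet` with the `"logExpr"` assay added.
#' @export
normalizeLog2 <- function(object, s = NULL) {
    if (is.null(s)) s <- sizeFactors(object)
    if (is.null(s))
        stop("size factors not estimated; call estimateSizeFactors() first")
    if (!is.null(names(s))) {
        missing <- setdiff(colnames(object), names(s))
        if (length(missing))
            stop("size factors missing for samples: ",
                 paste(missing, collapse = ", "))
        s <- s[colnames(object)]
    } else if (length(s) != ncol(object)) {
        stop("need one size factor per sample")
    }
    if (any(!is.finite(s)) || any(s <= 0))
        stop("size factors must be finite and strictly positive")
    x <- log2(sweep(counts(object), 2L, s, "/") + 1)
    assay(object, "logExpr") <- x
    object
}
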