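# Calibration diagnostics: genomic control, QQ data, thresholds, and
# volcano/Manhattan table export.

.checkPvalues <- function(pvals) {
    pvals <- as.numeric(pvals)
    pvals <- pvals[!is.na(pvals)]
    if (!length(pvals)) stop("no p-values supplied")
    if (any(pvals <= 0 | pvals > 1)) stop("p-values must lie in (0, 1]")
    pvals
}

#' Genomic control inflation factor
#'
#' Converts each p-value to its implied 1-df chi-square statistic and
#' divides the median by the 1-df chi-square median (0.4549...). Lambda
#' near 1 indicates calibrated null p-values; lambda > 1 indicates
#' inflation. p-values of exactly 1 map to chi-square 0; underflowed
#' p-values are floored at 1e-300.
#'
#' @param pvals numeric p-values in (0, 1]; NAs are dropped.
#' @return the genomic control factor lambda (positive scalar).
#' @export
genomicControlLambda <- function(pvals) {
    pvals <- .checkPvalues(pvals)
    pvals <- pmax(pvals, 1e-300)
    chisq <- stats::qchisq(pvals, df = 1, lower.tail = FALSE)
    stats::median(chisq) / stats::qchisq(0.5, df = 1)
}

#' QQ-plot data for a set of p-values
#'
#' Pairs sorted observed -log10 p with the median-unbiased expected
#' quantiles -log10((i - 0.5)/m) of the uniform, and annotates the genomic
#' control lambda.
#'
#' @param pvals numeric p-values in (0, 1].
#' @param method optional method tag carried into the report.
#' @param trait optional trait name carried into the report.
#' @return list of class `"CalibrationReport"` with `lambda`, `nTests`,
#'   `expected` and `observed` (-log10 scale, sorted increasing), `method`,
#'   `trait`.
#' @export
qqPoints <- function(pvals, method = NA_character_, trait = NA_character_) {
    pvals <- .checkPvalues(pvals)
    m <- length(pvals)
    observed <- sort(-log10(pmax(pvals, 1e-300)))
    expected <- sort(-log10((seq_len(m) - 0.5) / m))
    structure(list(lambda = genomicControlLambda(pvals), nTests = m,
                   expected = expected, observed = observed,
                   method = method, trait = trait),
              class = "CalibrationReport")
}

#' @export
print.CalibrationReport <- function(x, ...) {
    cat("CalibrationReport:", x$nTests, "tests",
        if (!is.na(x$method)) paste0("(", x$method, ")"), "\n")
    cat(sprintf("genomic control lambda = %.4f\n", x$lambda))
    invisible(x)
}

#' Quick base-graphics QQ plot of DGE p-values
#'
#' @param x a `CalibrationReport` from [qqPoints()] or a p-value vector.
#' @param ... passed to [plot()].
#' @export
plotQQ <- function(x, ...) {
    if (!inherits(x, "CalibrationReport")) x <- qqPoints(x)
    lim <- range(0, x$expected, x$observed)
    plot(x$expected, x$observed, xlim = lim, ylim = lim,
         xlab = expression(Expected ~ -log[10](p)),
         ylab = expression(Observed ~ -log[10](p)),
         main = sprintf("%s  (lambda = %.2f)",
                        if (is.na(x$method)) "QQ" else x$method, x$lambda),
         pch = 20, ...)
    abline(0, 1, col = "red")
    invisible(x)
}

#' Bonferroni family-wise significance threshold
#'
#' @param alpha family-wise error rate in (0, 1) (default 0.05).
#' @param m number of tests (>= 1).
#' @return the per-test threshold `alpha / m`.
#' @examples
#' bonferroniThreshold(0.05, 37)   # 0.00135..., the replication threshold
#' @export
bonferroniThreshold <- function(alpha = 0.05, m) {
    stopifnot(length(alpha) == 1L, alpha > 0, alpha < 1,
              length(m) == 1L, m >= 1, m == as.integer(m))
    alpha / m
}

#' Volcano-plot table with regulation calls
#'
#' Annotates a result table with -log10 p and a regulation call: `"up"`
#' when beta > `effectCut` and p < `pCut`, `"down"` when beta <
#' `-effectCut` and p < `pCut`, `"none"` otherwise; the five smallest-p
#' genes in each direction are labelled.
#'
#' @param results a [DGEResults-class] or data.frame with `gene_id`,
#'   `beta`, `pvalue`.
#' @param effectCut absolute effect-size cutoff (default 0.05).
#' @param pCut p-value cutoff (default 0.05).
#' @return `data.frame` with added `negLog10P`, `regulation`, `label`
#'   columns.
#' @export
volcanoTable <- function(results, effectCut = 0.05, pCut = 0.05) {
    df <- as.data.frame(results)
    if (!nrow(df)) stop("empty result table")
    df$negLog10P <- -log10(pmax(df$pvalue, 1e-300))
    df$regulation <- "none"
    up <- !is.na(df$beta) & df$beta > effectCut & df$pvalue < pCut
    dn <- !is.na(df$beta) & df$beta < -effectCut & df$pvalue < pCut
    df$regulation[up] <- "up"
    df$regulation[dn] <- "down"
    df$label <- NA_character_
    for (dir in c("up", "down")) {
        idx <- which(df$regulation == dir)
        top <- idx[order(df$pvalue[idx])][seq_len(min(5L, length(idx)))]
        df$label[top] <- df$gene_id[top]
    }
    df
}

#' Manhattan-plot table with cumulative positions
#'
#' Lays genes out along a cumulative axis, one contiguous block per
#' chromosome (input order preserved within blocks), and echoes the
#' requested significance thresholds. The five smallest-p genes are
#' labelled.
#'
#' @param results a [DGEResults-class] or data.frame with `gene_id`, `chr`,
#'   `pvalue`; `chr` must be present (use [volcanoTable()] otherwise).
#' @param thresholds numeric p-value thresholds to echo (default the
#'   conventional 3.49e-6 Bonferroni line and the 1e-4 suggestive line).
#' @return list with `table` (`gene_id`, `chr`, `position`, `negLog10P`,
#'   `label`) and `thresholds`.
#' @export
manhattanTable <- function(results, thresholds = c(3.49e-6, 1e-4)) {
    df <- as.data.frame(results)
    if (is.null(df$chr) || all(is.na(df$chr)))
        stop("chromosome annotation is missing; use volcanoTable() instead")
    chrLevels <- unique(df$chr)
    offset <- 0
    df$position <- NA_real_
    for (ch in chrLevels) {
        idx <- which(df$chr == ch)
        df$position[idx] <- offset + seq_along(idx)
        offset <- offset + length(idx)
    }
    df$negLog10P <- -log10(pmax(df$pvalue, 1e-300))
    df$label <- NA_character_
    top <- order(df$pvalue)[seq_len(min(5L, nrow(df)))]
    df$label[top] <- df$gene_id[top]
    list(table = df[, c("gene_id", "chr", "position", "negLog10P",
                        "pvalue", "label")],
         thresholds = thresholds)
}
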