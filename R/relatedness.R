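#' Expression-derived sample-sample relatedness matrix
#'
#' Builds the n x n relatedness (kinship-style) matrix used as the LMM
#' random-effect covariance kernel, from all gene expressions. A pervasive
#' latent factor loading on many genes surfaces as a leading eigenvector of
#' M, which is how the mixed model absorbs unknown confounding.
#'
#' Two constructions are offered, mirroring the centered and standardized
#' kinship conventions of genetic association tools:
#' \describe{
#'   \item{`"centered"` (default)}{each gene is centered across samples and
#'     \eqn{M = X_c' X_c / p}, rescaled to unit average diagonal. Genes
#'     with stronger (co)variation - exactly the genes that carry a shared
#'     latent factor - contribute proportionally more, which concentrates
#'     the confounder in the leading eigenvalue. Rescaling by a constant is
#'     exactly absorbed by the variance ratio gamma.}
#'   \item{`"standardized"`}{each gene is standardized (mean 0, sd 1) and M
#'     is the Pearson correlation between sample columns of the
#'     standardized matrix; M then has unit diagonal. Every gene
#'     contributes equally, which dilutes strong confounders.}
#' }
#'
#' @param expr gene x sample numeric matrix of (log2-normalized) expression,
#'   or a [DGEDataSet-class] carrying the `"logExpr"` assay.
#' @param method `"centered"` (default) or `"standardized"`.
#' @return n x n symmetric positive-semidefinite numeric matrix with sample
#'   ids as dimnames.
#' @export
computeRelatedness <- function(expr,
                               method = c("centered", "standardized")) {
    method <- match.arg(method)
    if (is(expr, "DGEDataSet")) expr <- normalizedExpression(expr)
    expr <- as.matrix(expr)
    if (ncol(expr) < 2L) stop("at least two samples are required")
    sds <- apply(expr, 1L, stats::sd)
    variable <- sds > 0
    if (sum(variable) < 2L)
        stop("fewer than two genes with nonzero variance; cannot build a ",
             "relatedness matrix")
    if (method == "standardized") {
        if (any(!variable))
            warning(sum(!variable), " zero-variance gene(s) dropped from ",
                    "the relatedness matrix")
        g <- (expr[variable, , drop = FALSE] -
                  rowMeans(expr[variable, , drop = FALSE])) / sds[variable]
        m <- stats::cor(g)
    } else {
        xc <- expr - rowMeans(expr)
        m <- crossprod(xc) / nrow(expr)
        m <- m / mean(diag(m))
    }
    m <- (m + t(m)) / 2
    dimnames(m) <- list(colnames(expr), colnames(expr))
    m
}

.checkRelatedness <- function(m) {
    if (!is.matrix(m) || nrow(m) != ncol(m))
        stop("relatedness matrix must be square")
    if (max(abs(m - t(m))) > 1e-8)
        stop("relatedness matrix is not symmetric")
    invisible(m)
}

#' Eigendecomposition of a relatedness matrix
#'
#' Decomposes M = U diag(d) U' with orthonormal U. Tiny negative
#' eigenvalues (>= -1e-8, numerical round-off of a PSD matrix) are clamped
#' to zero so that gamma*d + 1 is always a valid marginal variance.
#'
#' @param m symmetric n x n relatedness matrix.
#' @return list with `values` (decreasing, clamped at 0) and `vectors`
#'   (orthonormal columns).
#' @export
eigenRelatedness <- function(m) {
    .checkRelatedness(m)
    e <- eigen(m, symmetric = TRUE)
    neg <- e$values < 0
    if (any(e$values < -1e-6))
        warning("relatedness matrix has eigenvalue ", min(e$values),
                "; clamping to zero")
    e$values[neg] <- 0
    list(values = e$values, vectors = e$vectors)
}

#' Write a relatedness matrix as plain text
#'
#' Whitespace-delimited square matrix without headers, interoperable with
#' the square relatedness-matrix files consumed by GEMMA-style association
#' tools.
#'
#' @param m relatedness matrix
#' @param path output file path
#' @export
writeRelatedness <- function(m, path) {
    .checkRelatedness(m)
    utils::write.table(format(m, digits = 12, scientific = FALSE,
                              trim = TRUE),
                       path, quote = FALSE, sep = "\t",
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read a plain-text square relatedness matrix
#'
#' @param path file written by [writeRelatedness()] or any whitespace
#'   delimited square numeric matrix without headers.
#' @param sampleIds optional sample identifiers to attach as dimnames.
#' @return symmetric numeric matrix.
#' @export
readRelatedness <- function(path, sampleIds = NULL) {
    m <- as.matrix(utils::read.table(path, header = FALSE))
    dimnames(m) <- NULL
    if (nrow(m) != ncol(m)) stop("file does not contain a square matrix")
    if (!is.null(sampleIds)) {
        if (length(sampleIds) != nrow(m))
            stop("sampleIds length does not match matrix dimension")
        dimnames(m) <- list(sampleIds, sampleIds)
    }
    .checkRelatedness(m)
    m
}
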