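# Standard linear regression engine: y = W a + x_j b_j + e, e ~ N(0, s^2 I).
# Vectorized over genes through the Frisch-Waugh-Lovell projection.

#' Single-gene linear regression Wald test
#'
#' Least-squares fit of the trait on covariates plus one gene; the Wald
#' statistic beta/se is referred, by default, to the standard normal (the
#' classical large-sample reference for this test); `reference = "t"`
#' switches to a t on n - c - 1 degrees of freedom.
#'
#' @param y trait vector.
#' @param W covariate matrix including intercept.
#' @param x gene expression vector.
#' @param reference `"normal"` (default) or `"t"`.
#' @param geneId identifier for the result row.
#' @return one-row `data.frame` with gene_id, beta, se, stat, pvalue, flag.
#' @export
olsWaldTest <- function(y, W, x, reference = c("normal", "t"),
                        geneId = "gene") {
    reference <- match.arg(reference)
    res <- .olsScan(matrix(x, nrow = 1L,
                           dimnames = list(geneId, NULL)),
                    y, W, reference)
    res
}

# expr: genes x samples. Returns data.frame over genes.
.olsScan <- function(expr, y, W, reference = "normal") {
    n <- length(y)
    c <- ncol(W)
    Q <- qr.Q(qr(W))
    ry <- y - Q %*% crossprod(Q, y)
    X <- t(expr)                          # n x p
    RX <- X - Q %*% crossprod(Q, X)
    sxx <- colSums(RX^2)
    ok <- sxx > 1e-10 * pmax(colSums(X^2), 1)
    beta <- se <- stat <- rep(NA_real_, nrow(expr))
    p <- rep(1, nrow(expr))
    flag <- ifelse(ok, "", "collinear")
    sxy <- colSums(RX * as.numeric(ry))
    beta[ok] <- sxy[ok] / sxx[ok]
    rss <- sum(ry^2) - beta^2 * sxx
    df <- n - c - 1
    if (df <= 0) stop("not enough samples for the covariate count")
    sigma2 <- pmax(rss, 0) / df
    se[ok] <- sqrt(sigma2[ok] / sxx[ok])
    stat[ok] <- beta[ok] / se[ok]
    praw <- if (reference == "normal") 2 * stats::pnorm(-abs(stat))
            else 2 * stats::pt(-abs(stat), df = df)
    p[ok] <- pmax(pmin(praw[ok], 1), .Machine$double.xmin)
    data.frame(gene_id = rownames(expr), beta = beta, se = se, stat = stat,
               pvalue = p, flag = flag, stringsAsFactors = FALSE)
}

#' Genome-wide linear regression differential expression scan
#'
#' @inheritParams runLMM
#' @param reference reference distribution for the Wald statistic:
#'   `"normal"` (default) or `"t"`.
#' @return a [DGEResults-class] (method `"ols"`, model
#'   `"trait~expression"`).
#' @export
runOLS <- function(object, trait, covariates = character(), chr = NULL,
                   reference = c("normal", "t")) {
    reference <- match.arg(reference)
    inp <- .resolveEngineInputs(object, trait, covariates, chr)
    df <- .olsScan(inp$expr, inp$y, inp$W, reference)
    df$chr <- inp$chr
    df$gammaHat <- NA_real_
    .DGEResults(df[, c("gene_id", "chr", "beta", "se", "stat", "pvalue",
                       "gammaHat", "flag")],
                method = "ols", model = "trait~expression",
                extraMeta = list(trait = inp$traitName, n = length(inp$y),
                                 reference = reference))
}
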