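# Two-group engine: median-dichotomized trait, voom-style precision
# weights from the empirical mean-variance trend, and an empirical-Bayes
# moderated t on per-gene weighted regressions of expression on the group.

#' Dichotomize a quantitative trait at its median
#'
#' Samples strictly greater than the median are assigned 1, all others
#' (including exact ties with the median) 0.
#'
#' @param y numeric trait vector.
#' @return list with `yD` (0/1 vector) and `cutoff` (the median).
#' @export
dichotomizeMedian <- function(y) {
    if (stats::var(y) == 0) stop("trait is constant and cannot be dichotomized")
    cutoff <- stats::median(y)
    yD <- as.numeric(y > cutoff)
    if (all(yD == 0) || all(yD == 1))
        stop("median dichotomization produced an empty class (heavy ties ",
             "at the median); jitter the trait or choose another cutoff")
    list(yD = yD, cutoff = cutoff)
}

#' Voom-style precision weights from the mean-variance trend
#'
#' Converts counts to log2 counts-per-million with a 0.5 offset
#' (library sizes + 1), fits each gene by least squares on `design`,
#' regresses the square-root residual standard deviations on average
#' log2 count by lowess, and inverts the interpolated trend at the fitted
#' values to obtain per-observation inverse-variance weights.
#'
#' @param counts gene x sample raw count matrix (filtered).
#' @param design n x q design matrix (covariates plus the dichotomized
#'   trait).
#' @param span lowess span (default 0.5).
#' @return list of class `"VoomFit"`: `E` (log2-cpm matrix), `weights`
#'   (positive, same dim), `trend` (the lowess curve), `design`.
#' @export
voomTransform <- function(counts, design, span = 0.5) {
    counts <- as.matrix(counts)
    n <- ncol(counts)
    p <- nrow(counts)
    design <- as.matrix(design)
    if (n < 4L) stop("voom weights need at least 4 samples")
    if (p < 10L) stop("too few genes to estimate a mean-variance trend")
    libSize <- colSums(counts)
    E <- t(log2(t(counts + 0.5) / (libSize + 1) * 1e6))
    qrD <- qr(design)
    q <- qrD$rank
    if (q < ncol(design)) stop("voom design matrix is rank deficient")
    coef <- t(qr.coef(qrD, t(E)))                 # p x q
    fitted <- coef %*% t(design)                  # p x n, log2-cpm scale
    resid <- E - fitted
    sigma <- sqrt(rowSums(resid^2) / (n - q))
    Amean <- rowMeans(E)
    sx <- Amean + mean(log2(libSize + 1)) - log2(1e6)
    sy <- sqrt(sigma)
    lo <- stats::lowess(sx, sy, f = span)
    trendFun <- stats::approxfun(lo, rule = 2, ties = mean)
    fittedCount <- log2(1e-6 * t(t(2^fitted) * (libSize + 1)))
    w <- 1 / pmax(trendFun(fittedCount), 1e-6)^4
    dim(w) <- dim(counts)
    dimnames(w) <- dimnames(counts)
    dimnames(E) <- dimnames(counts)
    structure(list(E = E, weights = w, trend = lo, design = design,
                   span = span),
              class = "VoomFit")
}

#' @export
print.VoomFit <- function(x, ...) {
    cat("VoomFit:", nrow(x$E), "genes x", ncol(x$E), "samples\n")
    cat(sprintf("weight range: [%.3g, %.3g]\n", min(x$weights),
                max(x$weights)))
    invisible(x)
}

# Solve trigamma(y) = x by Newton iteration (monotone, convex in 1/y).
.trigammaInverse <- function(x) {
    vapply(x, function(xi) {
        if (!is.finite(xi) || xi <= 0) return(Inf)
        if (xi > 1e7) return(1 / sqrt(xi))
        if (xi < 1e-6) return(1 / xi)
        y <- 0.5 + 1 / xi
        for (i in 1:50) {
            tri <- trigamma(y)
            dif <- tri * (1 - tri / xi) / psigamma(y, deriv = 2L)
            y <- y + dif
            if (-dif / y < 1e-8) break
        }
        y
    }, numeric(1))
}

#' Empirical-Bayes shrinkage of residual variances
#'
#' Models the per-gene residual variances as scaled inverse-chi-square
#' draws around a common prior and estimates the prior scale `s2Prior` and
#' degrees of freedom `dfPrior` by matching the mean and variance of the
#' log variances (the moment identities of the log F distribution, solved
#' with a trigamma inverse). Posterior variances are the
#' degrees-of-freedom-weighted average of gene and prior variance.
#'
#' @param s2 per-gene residual variances.
#' @param df residual degrees of freedom (scalar or per gene).
#' @param dfPrior,s2Prior optional overrides; `dfPrior = Inf` shrinks
#'   completely to `s2Prior`, `dfPrior = 0` performs no shrinkage.
#' @return list with `s2Post`, `dfPrior`, `s2Prior`.
#' @export
squeezeVariances <- function(s2, df, dfPrior = NULL, s2Prior = NULL) {
    stopifnot(all(df > 0))
    if (is.null(dfPrior) || is.null(s2Prior)) {
        ok <- s2 > 0
        if (sum(ok) < 2L) stop("need at least two positive variances")
        z <- log(s2[ok])
        dfv <- rep_len(df, length(s2))[ok]
        e <- z - digamma(dfv / 2) + log(dfv / 2)
        evar <- stats::var(e) - mean(trigamma(dfv / 2))
        if (is.null(dfPrior)) {
            dfPrior <- if (evar > 0) 2 * .trigammaInverse(evar) else Inf
        }
        if (is.null(s2Prior)) {
            s2Prior <- if (is.finite(dfPrior))
                exp(mean(e) + digamma(dfPrior / 2) - log(dfPrior / 2))
            else exp(mean(e))
        }
    }
    s2Post <- if (is.infinite(dfPrior)) rep_len(s2Prior, length(s2))
              else (dfPrior * s2Prior + df * s2) / (dfPrior + df)
    list(s2Post = s2Post, dfPrior = dfPrior, s2Prior = s2Prior)
}

#' Moderated t-test of a dichotomized trait effect on expression
#'
#' Per-gene (optionally weighted) least squares of expression on the
#' covariates plus the 0/1 trait, followed by empirical-Bayes variance
#' shrinkage; the moderated t uses the posterior variance and
#' `df_residual + dfPrior` degrees of freedom.
#'
#' @param E gene x sample expression matrix (log2 scale), or a `"VoomFit"`.
#' @param yD 0/1 dichotomized trait (or result of [dichotomizeMedian()]).
#' @param W covariate matrix including intercept.
#' @param weights optional positive gene x sample weight matrix (taken from
#'   the `VoomFit` when `E` is one).
#' @param dfPrior,s2Prior optional shrinkage overrides (see
#'   [squeezeVariances()]).
#' @return `data.frame` with per-gene beta (log2 fold change), se, stat,
#'   pvalue and flag; shrinkage parameters in attributes `dfPrior`,
#'   `s2Prior`.
#' @export
moderatedTTest <- function(E, yD, W, weights = NULL, dfPrior = NULL,
                           s2Prior = NULL) {
    if (inherits(E, "VoomFit")) {
        if (is.null(weights)) weights <- E$weights
        E <- E$E
    }
    if (is.list(yD)) yD <- yD$yD
    stopifnot(all(yD %in% c(0, 1)))
    if (sum(yD == 0) < 2L || sum(yD == 1) < 2L)
        stop("each trait class needs at least two samples")
    W <- as.matrix(W)
    X <- cbind(W, yD = yD)
    n <- ncol(E)
    q <- ncol(X)
    df <- n - q
    if (df <= 0) stop("nonpositive residual degrees of freedom")
    p <- nrow(E)
    beta <- se2 <- s2 <- rep(NA_real_, p)
    for (j in seq_len(p)) {
        wj <- if (is.null(weights)) rep(1, n) else weights[j, ]
        fit <- stats::lm.wfit(X, E[j, ], wj)
        if (any(is.na(fit$coefficients))) next
        beta[j] <- fit$coefficients[q]
        rss <- sum(wj * fit$residuals^2)
        s2[j] <- rss / df
        XtWX <- crossprod(X, X * wj)
        se2[j] <- solve(XtWX)[q, q]       # unscaled variance of beta
    }
    ok <- !is.na(beta) & s2 > 0
    sq <- squeezeVariances(s2[ok], df, dfPrior = dfPrior, s2Prior = s2Prior)
    s2Post <- rep(NA_real_, p)
    s2Post[ok] <- sq$s2Post
    seMod <- sqrt(se2 * s2Post)
    stat <- beta / seMod
    dfTotal <- df + sq$dfPrior
    pval <- rep(1, p)
    pval[ok] <- pmax(pmin(2 * stats::pt(-abs(stat[ok]), df = dfTotal), 1),
                     .Machine$double.xmin)
    out <- data.frame(gene_id = rownames(E) %||% paste0("gene", seq_len(p)),
                      beta = beta, se = seMod, stat = stat, pvalue = pval,
                      flag = ifelse(ok, "", "collinear"),
                      stringsAsFactors = FALSE)
    attr(out, "dfPrior") <- sq$dfPrior
    attr(out, "s2Prior") <- sq$s2Prior
    out
}

#' Genome-wide voom + moderated-t scan on a median-dichotomized trait
#'
#' Dichotomizes the trait at its median (strictly greater -> 1), computes
#' voom precision weights from the raw counts with the full design, fits
#' per-gene weighted regressions of log2-cpm on covariates plus the group
#' indicator, and applies the empirical-Bayes moderated t. Note the
#' regression direction is expression on trait (log2-fold-change betas),
#' opposite to the LMM/OLS/robust engines.
#'
#' @inheritParams runLMM
#' @param span lowess span for the mean-variance trend (default 0.5).
#' @return a [DGEResults-class] (method `"voom"`, model
#'   `"expression~trait"`).
#' @export
runVoom <- function(object, trait, covariates = character(), chr = NULL,
                    span = 0.5) {
    inp <- .resolveEngineInputs(object, trait, covariates, chr,
                                needExpr = FALSE)
    k <- if (is(object, "DGEDataSet")) counts(object) else
        stop("runVoom needs a DGEDataSet (raw counts are required)")
    if (is.null(inp$chr)) inp$chr <- rep(NA_character_, nrow(k))
    dich <- dichotomizeMedian(inp$y)
    design <- cbind(inp$W, yD = dich$yD)
    vf <- voomTransform(k, design, span = span)
    df <- moderatedTTest(vf, dich$yD, inp$W)
    res <- df
    res$chr <- inp$chr
    res$gammaHat <- NA_real_
    .DGEResults(res[, c("gene_id", "chr", "beta", "se", "stat", "pvalue",
                        "gammaHat", "flag")],
                method = "voom", model = "expression~trait",
                extraMeta = list(trait = inp$traitName, n = length(inp$y),
                                 dfPrior = attr(df, "dfPrior"),
                                 s2Prior = attr(df, "s2Prior"),
                                 cutoff = dich$cutoff))
}
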