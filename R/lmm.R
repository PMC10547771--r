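# Linear mixed model engine.
#
# Model per gene j:  y = W a + x_j b_j + u + e,
#   u ~ N(0, (gamma/tau) M),  e ~ N(0, (1/tau) I).
# With M = U diag(d) U', rotating all inputs by U' makes the marginal
# covariance diagonal, diag(gamma*d + 1)/tau, so each REML evaluation is
# O(n q^2) instead of O(n^3).

#' Profiled REML log-likelihood of the per-gene LMM
#'
#' Evaluates the restricted log-likelihood of the variance ratio `gamma`
#' with the error precision tau profiled out analytically, in the rotated
#' (eigen) basis.
#'
#' @param gamma non-negative variance-component ratio (random effect vs
#'   error).
#' @param yRot response rotated by `t(U)`.
#' @param XRot full fixed-effect design (covariates incl. intercept plus the
#'   tested gene), rotated by `t(U)`.
#' @param d eigenvalues of the relatedness matrix (clamped at 0).
#' @return the REML log-likelihood (including constants, so it is directly
#'   comparable with a dense-matrix evaluation).
#' @export
remlLogLik <- function(gamma, yRot, XRot, d) {
    n <- length(yRot)
    q <- ncol(XRot)
    v <- gamma * d + 1
    vi <- 1 / v
    Xvi <- XRot * vi
    A <- crossprod(XRot, Xvi)           # X' V^-1 X
    b <- crossprod(Xvi, yRot)           # X' V^-1 y
    R <- tryCatch(chol(A), error = function(e)
        stop("singular weighted design in REML evaluation"))
    beta <- backsolve(R, forwardsolve(t(R), b))
    quad <- sum(yRot^2 * vi) - sum(b * beta)   # y' P y
    if (quad <= 0) return(-Inf)
    logDetV <- sum(log(v))
    logDetA <- 2 * sum(log(diag(R)))
    XtX <- crossprod(XRot)
    logDetXtX <- determinant(XtX, logarithm = TRUE)$modulus
    0.5 * (n - q) * log((n - q) / (2 * pi)) - 0.5 * (n - q) -
        0.5 * logDetV - 0.5 * logDetA + 0.5 * as.numeric(logDetXtX) -
        0.5 * (n - q) * log(quad)
}

# Fast internal REML core: returns loglik and, optionally, the GLS pieces.
# logDetXtX is gamma-free and precomputed once per gene.
.remlEval <- function(gamma, yRot, XRot, d, logDetXtX, n, q, fit = FALSE) {
    v <- gamma * d + 1
    vi <- 1 / v
    Xvi <- XRot * vi
    A <- crossprod(XRot, Xvi)
    b <- crossprod(Xvi, yRot)
    R <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(R)) return(NULL)
    beta <- backsolve(R, forwardsolve(t(R), b))
    quad <- sum(yRot^2 * vi) - sum(b * beta)
    if (quad <= 0) return(NULL)
    ll <- 0.5 * (n - q) * log((n - q) / (2 * pi)) - 0.5 * (n - q) -
        0.5 * sum(log(v)) - sum(log(diag(R))) + 0.5 * logDetXtX -
        0.5 * (n - q) * log(quad)
    if (!fit) return(list(ll = ll))
    Ainv <- chol2inv(R)
    tauInv <- quad / (n - q)            # REML residual variance
    list(ll = ll, beta = as.numeric(beta), covBeta = Ainv * tauInv,
         tauHat = 1 / tauInv, quad = quad)
}

#' REML estimation of the LMM variance-component ratio
#'
#' Maximizes the profiled REML log-likelihood over a log10 grid on
#' `gammaRange`, then refines the best bracket by golden-section /
#' parabolic search ([stats::optimize]) on the log10 scale.
#'
#' @param yRot,XRot,d rotated inputs as in [remlLogLik()].
#' @param gammaRange search interval for gamma (default `c(1e-5, 1e5)`).
#' @param nGrid number of coarse grid points (default 50).
#' @return list with `gammaHat`, `logLik` at the optimum, the grid maximum
#'   `gridLogLik`, and `flag` ("" or "grid_fallback").
#' @export
estimateGamma <- function(yRot, XRot, d, gammaRange = c(1e-5, 1e5),
                          nGrid = 50L) {
    n <- length(yRot)
    q <- ncol(XRot)
    logDetXtX <- as.numeric(determinant(crossprod(XRot), TRUE)$modulus)
    lg <- seq(log10(gammaRange[1]), log10(gammaRange[2]), length.out = nGrid)
    f <- function(l) {
        r <- .remlEval(10^l, yRot, XRot, d, logDetXtX, n, q)
        if (is.null(r)) -Inf else r$ll
    }
    gridLL <- vapply(lg, f, numeric(1))
    i <- which.max(gridLL)
    lo <- lg[max(1L, i - 1L)]
    hi <- lg[min(nGrid, i + 1L)]
    opt <- tryCatch(stats::optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-4),
                    error = function(e) NULL)
    flag <- ""
    if (is.null(opt) || opt$objective < gridLL[i]) {
        gammaHat <- 10^lg[i]
        ll <- gridLL[i]
        if (is.null(opt)) flag <- "grid_fallback"
    } else {
        gammaHat <- 10^opt$maximum
        ll <- opt$objective
    }
    list(gammaHat = gammaHat, logLik = ll, gridLogLik = max(gridLL),
         flag = flag)
}

#' Single-gene LMM Wald test
#'
#' Estimates gamma by REML (unless supplied), computes generalized
#' least-squares estimates of the fixed effects at `gammaHat`, and tests
#' H0: beta_j = 0 with a t reference on n - c - 1 degrees of freedom
#' (c = number of covariate columns including the intercept).
#'
#' @param y trait vector.
#' @param W covariate matrix including an intercept column.
#' @param x gene expression vector (test covariate).
#' @param eig eigendecomposition of M from [eigenRelatedness()].
#' @param gamma optional fixed gamma (skips REML estimation).
#' @param geneId identifier for the result row.
#' @return one-row `data.frame` with gene_id, beta, se, stat, pvalue,
#'   gammaHat, logLik and flag.
#' @export
lmmWaldTest <- function(y, W, x, eig, gamma = NULL, geneId = "gene") {
    U <- eig$vectors
    d <- eig$values
    n <- length(y)
    stopifnot(nrow(W) == n, length(x) == n, length(d) == n)
    yRot <- as.numeric(crossprod(U, y))
    XRot <- crossprod(U, cbind(W, x))
    .lmmWaldRotated(yRot, XRot, d, n, ncol(W), gamma = gamma,
                    geneId = geneId)
}

.lmmWaldRotated <- function(yRot, XRot, d, n, c, gamma = NULL,
                            geneId = "gene", warn = TRUE) {
    q <- ncol(XRot)
    flagged <- function(flag) data.frame(
        gene_id = geneId, beta = NA_real_, se = NA_real_, stat = NA_real_,
        pvalue = 1, gammaHat = NA_real_, logLik = NA_real_, flag = flag,
        stringsAsFactors = FALSE)
    # collinearity of the gene with W: residual norm of x after projecting
    # onto the covariates (rotation preserves inner products)
    Wr <- XRot[, seq_len(c), drop = FALSE]
    xr <- XRot[, q]
    cf <- tryCatch(qr.coef(qr(Wr), xr), error = function(e) NULL)
    resNorm2 <- if (is.null(cf)) 0 else sum((xr - Wr %*% cf)^2)
    if (!is.finite(resNorm2) || resNorm2 < 1e-10 * max(sum(xr^2), 1)) {
        if (warn) warning("gene ", geneId,
                          " is (near) collinear with the covariates; flagged")
        return(flagged("collinear"))
    }
    logDetXtX <- as.numeric(determinant(crossprod(XRot), TRUE)$modulus)
    flag <- ""
    if (is.null(gamma)) {
        est <- estimateGamma(yRot, XRot, d)
        gamma <- est$gammaHat
        flag <- est$flag
    }
    r <- .remlEval(gamma, yRot, XRot, d, logDetXtX, n, q, fit = TRUE)
    if (is.null(r)) return(flagged("singular"))
    beta <- r$beta[q]
    se <- sqrt(r$covBeta[q, q])
    stat <- beta / se
    df <- n - c - 1
    p <- 2 * stats::pt(-abs(stat), df = df)
    p <- max(p, .Machine$double.xmin)
    data.frame(gene_id = geneId, beta = beta, se = se, stat = stat,
               pvalue = p, gammaHat = gamma, logLik = r$ll, flag = flag,
               stringsAsFactors = FALSE)
}

#' Genome-wide LMM differential expression scan
#'
#' Runs the per-gene LMM Wald test over every gene of the normalized
#' expression matrix. The relatedness matrix is eigendecomposed once and
#' the rotation reused for all genes; gamma is re-estimated per gene
#' because the tested gene enters the fixed effects.
#'
#' @param object a [DGEDataSet-class] with normalized expression, or a gene
#'   x sample expression matrix.
#' @param trait trait name in `colData(object)`, or a numeric vector.
#' @param covariates covariate names in `colData(object)` (intercept is
#'   always included), or a design matrix `W` whose first column is the
#'   intercept.
#' @param relatedness optional precomputed relatedness matrix (default:
#'   computed from all genes of the expression matrix).
#' @param chr optional chromosome labels per gene.
#' @return a [DGEResults-class] table with one row per gene (method
#'   `"lmm"`, model `"trait~expression"`).
#' @export
runLMM <- function(object, trait, covariates = character(),
                   relatedness = NULL, chr = NULL) {
    inp <- .resolveEngineInputs(object, trait, covariates, chr)
    expr <- inp$expr
    y <- inp$y
    W <- inp$W
    n <- length(y)
    if (is.null(relatedness)) relatedness <- computeRelatedness(expr)
    if (!is.null(colnames(relatedness)) &&
        !identical(colnames(relatedness), colnames(expr)))
        stop("relatedness matrix sample ids do not match the expression ",
             "matrix: ", paste(head(setdiff(colnames(expr),
                                            colnames(relatedness)), 5L),
                               collapse = ", "))
    eig <- eigenRelatedness(relatedness)
    U <- eig$vectors
    d <- eig$values
    yRot <- as.numeric(crossprod(U, y))
    WRot <- crossprod(U, W)
    XallRot <- crossprod(U, t(expr))     # n x p, one column per gene
    rows <- vector("list", nrow(expr))
    for (j in seq_len(nrow(expr))) {
        xr <- XallRot[, j]
        if (stats::sd(expr[j, ]) == 0) {
            rows[[j]] <- data.frame(
                gene_id = rownames(expr)[j], beta = NA_real_, se = NA_real_,
                stat = NA_real_, pvalue = 1, gammaHat = NA_real_,
                logLik = NA_real_, flag = "constant",
                stringsAsFactors = FALSE)
            next
        }
        rows[[j]] <- .lmmWaldRotated(yRot, cbind(WRot, xr), d, n, ncol(W),
                                     geneId = rownames(expr)[j],
                                     warn = FALSE)
    }
    df <- do.call(rbind, rows)
    nflag <- sum(df$flag != "")
    if (nflag) warning(nflag, " gene(s) flagged (constant/collinear/",
                       "singular); their p-values are set to 1")
    df$chr <- inp$chr
    .DGEResults(df[, c("gene_id", "chr", "beta", "se", "stat", "pvalue",
                       "gammaHat", "flag")],
                method = "lmm", model = "trait~expression",
                extraMeta = list(trait = inp$traitName, n = n,
                                 nCovariates = ncol(W)))
}

# Shared input resolution for all engines: expression matrix, trait vector,
# covariate design with intercept, chromosome labels.
.resolveEngineInputs <- function(object, trait, covariates, chr = NULL,
                                 needExpr = TRUE) {
    if (is(object, "DGEDataSet")) {
        expr <- if (needExpr) normalizedExpression(object) else NULL
        cd <- colData(object)
        if (is.character(trait) && length(trait) == 1L) {
            if (!trait %in% colnames(cd))
                stop("trait '", trait, "' not found in colData")
            traitName <- trait
            y <- cd[[trait]]
        } else {
            traitName <- "trait"
            y <- as.numeric(trait)
        }
        if (is.character(covariates)) {
            missing <- setdiff(covariates, colnames(cd))
            if (length(missing))
                stop("covariate column(s) not found in colData: ",
                     paste(missing, collapse = ", "))
            W <- .buildDesign(as.data.frame(cd[, covariates, drop = FALSE]))
        } else {
            W <- as.matrix(covariates)
        }
        if (is.null(chr)) chr <- rowData(object)$chr
        genes <- rownames(object)
    } else {
        expr <- if (needExpr) as.matrix(object) else NULL
        y <- as.numeric(trait)
        W <- if (is.character(covariates) && !length(covariates))
            matrix(1, length(y), 1L, dimnames = list(NULL, "intercept"))
        else as.matrix(covariates)
        traitName <- "trait"
        genes <- rownames(expr)
    }
    n <- length(y)
    if (!all(is.finite(y))) stop("trait contains non-finite values")
    if (stats::var(y) == 0) stop("trait is constant")
    if (nrow(W) != n) stop("covariate matrix row count does not match trait")
    if (!all(W[, 1L] == 1)) stop("first covariate column must be the intercept")
    if (qr(W)$rank < ncol(W)) stop("covariate matrix is rank deficient")
    if (needExpr && ncol(expr) != n)
        stop("expression matrix sample count does not match trait length")
    if (is.null(chr) && needExpr) chr <- rep(NA_character_, nrow(expr))
    list(expr = expr, y = y, W = W, chr = chr, traitName = traitName,
         genes = genes)
}

# Expand a covariate data.frame into a numeric design matrix with intercept:
# factors/characters become treatment-coded indicator columns.
.buildDesign <- function(df) {
    n <- nrow(df)
    if (!ncol(df))
        return(matrix(1, n, 1L, dimnames = list(NULL, "intercept")))
    mm <- stats::model.matrix(~ ., data = df)
    colnames(mm)[1L] <- "intercept"
    attr(mm, "assign") <- NULL
    attr(mm, "contrasts") <- NULL
    mm
}
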