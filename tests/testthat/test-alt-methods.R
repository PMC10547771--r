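# Linear, robust and voom comparison engines.

test_that("OLS Wald test matches the normal-equation solution", {
    # n = 5 worked fixture solved by hand via the normal equations
    y <- c(1.2, 0.7, 2.9, 1.8, 2.4)
    W <- cbind(1, c(0, 1, 0, 1, 0))
    x <- c(0.5, 1.0, 2.0, 1.5, 2.5)
    X <- cbind(W, x)
    betaHat <- solve(crossprod(X), crossprod(X, y))
    rss <- sum((y - X %*% betaHat)^2)
    seHat <- sqrt(rss / (5 - 3) * solve(crossprod(X))[3, 3])
    row <- olsWaldTest(y, W, x)
    expect_equal(row$beta, betaHat[3], tolerance = 1e-10)
    expect_equal(row$se, seHat, tolerance = 1e-10)
    expect_equal(row$pvalue, 2 * pnorm(-abs(betaHat[3] / seHat)),
                 tolerance = 1e-10)

    # perfect fit: beta 1, p capped at the smallest positive double
    yy <- c(0.3, 1.1, 2.2, 3.3, 4.1)
    rowP <- olsWaldTest(yy, matrix(1, 5, 1), yy)
    expect_equal(rowP$beta, 1, tolerance = 1e-10)
    expect_identical(rowP$pvalue, .Machine$double.xmin)
})

test_that("OLS p-values are uniform under an independent trait", {
    set.seed(50)
    n <- 200
    expr <- matrix(rnorm(2000 * n), 2000, n,
                   dimnames = list(sprintf("g%04d", 1:2000), NULL))
    colnames(expr) <- paste0("s", seq_len(n))
    y <- rnorm(n)
    res <- runOLS(expr, y)
    ks <- suppressWarnings(ks.test(res$pvalue, "punif"))
    expect_lt(unname(ks$statistic), 1.63 / sqrt(2000))
})

test_that("Huber weight function matches its printed form", {
    expect_identical(huberWeight(0, 1.5), 1)
    expect_identical(huberWeight(1.5, 1.5), 1)     # boundary: |e| = k
    expect_identical(huberWeight(-1.5, 1.5), 1)
    expect_equal(huberWeight(3, 1.5), 0.5)         # |e| = 2k -> k/|e|
    expect_equal(huberWeight(-6, 1.5), 0.25)
})

test_that("Huber IRLS agrees with OLS on clean data and with huge k", {
    set.seed(51)
    n <- 30
    X <- cbind(1, rnorm(n), rnorm(n))
    # residuals bounded away from the Huber elbow (|e|max < 1.345*MAD/0.6745)
    # so every weight is exactly 1 and IRLS must reproduce least squares
    noise <- sample(c(-1, 1), n, replace = TRUE) * runif(n, 0.5, 0.9) * 0.01
    y <- as.numeric(X %*% c(1, 2, -1)) + noise
    ols <- qr.coef(qr(X), y)
    fit <- huberFit(y, X)
    expect_equal(unname(fit$coefficients), unname(ols), tolerance = 1e-6)
    expect_true(fit$converged)

    # k -> infinity: weights never trip, exactly OLS
    yOut <- y
    yOut[1] <- yOut[1] + 50
    fitInf <- huberFit(yOut, X, kMultiplier = 1e8)
    expect_equal(unname(fitInf$coefficients),
                 unname(qr.coef(qr(X), yOut)), tolerance = 1e-8)
})

test_that("Huber fit resists a gross outlier and minimizes its objective", {
    set.seed(52)
    n <- 20
    x <- rnorm(n)
    X <- cbind(1, x)
    yClean <- 1 + 0.5 * x + rnorm(n, sd = 0.3)
    slopeClean <- qr.coef(qr(X), yClean)[2]
    yBad <- yClean
    yBad[7] <- yBad[7] + 30
    slopeBadOLS <- qr.coef(qr(X), yBad)[2]
    fit <- huberFit(yBad, X)
    expect_lt(abs(fit$coefficients[2] - slopeClean),
              abs(slopeBadOLS - slopeClean))

    # objective at the IRLS solution matches a generic numerical minimizer
    # of sum(rho) at the fit's final tuning constant
    k <- fit$k
    obj <- function(b) {
        e <- yBad - X %*% b
        sum(ifelse(abs(e) < k, 0.5 * e^2, k * abs(e) - 0.5 * k^2))
    }
    brute <- optim(qr.coef(qr(X), yBad), obj, method = "BFGS",
                   control = list(reltol = 1e-14, maxit = 1000))
    expect_equal(fit$objective, brute$value, tolerance = 1e-6)
    expect_lte(fit$objective, obj(qr.coef(qr(X), yBad)) + 1e-12)

    # determinism
    fit2 <- huberFit(yBad, X)
    expect_identical(fit$coefficients, fit2$coefficients)

    # independent implementation: MASS::rlm with MAD scale
    skip_if_not_installed("MASS")
    rlmFit <- MASS::rlm(X, yBad, psi = MASS::psi.huber, scale.est = "MAD",
                        maxit = 100)
    expect_equal(unname(fit$coefficients), unname(coef(rlmFit)),
                 tolerance = 1e-3)
})

test_that("robust Wald test is calibrated, powered and deterministic", {
    set.seed(53)
    n <- 100
    # null calibration over 1,000 simulated genes
    W <- matrix(1, n, 1)
    ps <- replicate(1000, {
        y <- rnorm(n)
        x <- rnorm(n)
        robustWaldTest(huberFit(y, cbind(W, x)), cbind(W, x))$pvalue
    })
    ks <- suppressWarnings(ks.test(ps, "punif"))
    expect_lt(unname(ks$statistic), 1.63 / sqrt(1000))

    # strong true effect
    set.seed(54)
    x <- rnorm(n)
    y <- 2 * x + rnorm(n)
    X <- cbind(W, x)
    row <- robustWaldTest(huberFit(y, X), X)
    expect_lt(row$pvalue, 1e-6)
    row2 <- robustWaldTest(huberFit(y, X), X)
    expect_identical(row$pvalue, row2$pvalue)
})

test_that("median dichotomization follows the strictly-greater rule", {
    expect_equal(dichotomizeMedian(c(1, 2, 3, 4))$yD, c(0, 0, 1, 1))
    expect_equal(dichotomizeMedian(c(1, 2, 2, 3))$yD, c(0, 0, 0, 1))
    set.seed(55)
    y <- sample(rnorm(40))                    # unique values, n even
    expect_equal(sum(dichotomizeMedian(y)$yD), 20)
    expect_error(dichotomizeMedian(rep(1, 6)), "constant")
    # heavy ties at the maximum leave the upper class empty
    expect_error(dichotomizeMedian(c(1, 2, 2, 2)), "empty class")
})

test_that("voom weights match limma::voom exactly", {
    skip_if_not_installed("limma")
    dds <- toyDataset(p = 200, n = 16, seed = 56)
    k <- counts(dds)
    y <- colData(dds)$trait
    yd <- dichotomizeMedian(y)$yD
    design <- cbind(1, yd)
    vf <- voomTransform(k, design)
    ref <- limma::voom(k, design)
    expect_equal(vf$E, ref$E, tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(vf$weights, ref$weights, tolerance = 1e-8,
                 ignore_attr = TRUE)
})

test_that("voom weights follow the mean-variance trend", {
    # identical count distributions for all genes: the true trend is flat, so
    # with enough genes/samples for the smoother the weights are near-constant
    set.seed(57)
    nS <- 80
    k <- matrix(rnbinom(2000 * nS, mu = 100, size = 100), 2000, nS,
                dimnames = list(sprintf("g%04d", 1:2000),
                                paste0("s", 1:nS)))
    design <- cbind(1, rep(0:1, nS / 2))
    vf <- voomTransform(k, design)
    expect_lt(sd(vf$weights) / mean(vf$weights), 0.05)

    # doubling all counts keeps weights positive and finite
    vf2 <- voomTransform(2 * k, design)
    expect_true(all(is.finite(vf2$weights) & vf2$weights > 0))

    # decreasing mean-variance trend: weights increase with abundance
    set.seed(58)
    design <- cbind(1, rep(0:1, 6))
    mu <- exp(seq(log(20), log(2000), length.out = 400))
    k3 <- t(vapply(mu, function(m)
        rnbinom(12, mu = m, size = 1 / 0.05), numeric(12)))
    dimnames(k3) <- list(sprintf("g%03d", 1:400), paste0("s", 1:12))
    vf3 <- voomTransform(k3, design)
    meanW <- rowMeans(vf3$weights)
    lowThird <- meanW[1:130]
    topThird <- meanW[271:400]
    expect_gt(median(topThird), median(lowThird))
})

test_that("variance squeezing has the right limits and recovers the prior", {
    set.seed(59)
    df <- 10
    s2 <- rchisq(500, df) / df * 2            # true common variance 2
    sq <- squeezeVariances(s2, df)
    expect_lt(abs(sq$s2Prior - 2) / 2, 0.2)

    # complete shrinkage
    sqInf <- squeezeVariances(s2, df, dfPrior = Inf, s2Prior = 3)
    expect_true(all(sqInf$s2Post == 3))

    # no shrinkage: posterior equals the per-gene variance
    sq0 <- squeezeVariances(s2, df, dfPrior = 0, s2Prior = 3)
    expect_equal(sq0$s2Post, s2, tolerance = 1e-12)
})

test_that("moderated t matches limma's empirical Bayes pipeline", {
    skip_if_not_installed("limma")
    dds <- toyDataset(p = 300, n = 20, seed = 60)
    k <- counts(dds)
    y <- colData(dds)$trait
    yd <- dichotomizeMedian(y)$yD
    W <- matrix(1, 20, 1)
    design <- cbind(W, yd = yd)
    v <- limma::voom(k, design)
    ebfit <- limma::eBayes(limma::lmFit(v, design))
    mine <- moderatedTTest(voomTransform(k, design), yd, W)
    expect_equal(attr(mine, "dfPrior"), ebfit$df.prior, tolerance = 1e-6)
    expect_equal(attr(mine, "s2Prior"), ebfit$s2.prior, tolerance = 1e-6)
    expect_equal(mine$stat, ebfit$t[, "yd"], tolerance = 1e-6,
                 ignore_attr = TRUE)
    expect_equal(mine$pvalue, ebfit$p.value[, "yd"], tolerance = 1e-6,
                 ignore_attr = TRUE)

    # dfPrior = 0 reduces the moderated t to the ordinary t
    plain <- moderatedTTest(v$E, yd, W, dfPrior = 0, s2Prior = 1)
    fit1 <- lm(v$E[1, ] ~ yd)
    expect_equal(plain$stat[1], summary(fit1)$coefficients["yd", "t value"],
                 tolerance = 1e-8)
})

test_that("all engines expose the regression direction and keep every gene", {
    dds <- toyDataset(p = 30, n = 20, seed = 61)
    resL <- runLMM(dds, "trait")
    resO <- runOLS(dds, "trait")
    resH <- runHuber(dds, "trait")
    resV <- runVoom(dds, "trait")
    for (res in list(resL, resO, resH)) {
        expect_identical(unique(res$model), "trait~expression")
        expect_identical(nrow(res), 30L)
        expect_true(all(res$pvalue > 0 & res$pvalue <= 1))
    }
    expect_identical(unique(resV$model), "expression~trait")
    expect_identical(nrow(resV), 30L)
    expect_true(all(resV$pvalue > 0 & resV$pvalue <= 1))
    expect_setequal(unique(c(resL$method, resO$method, resH$method,
                             resV$method)),
                    c("lmm", "ols", "robust", "voom"))
})
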