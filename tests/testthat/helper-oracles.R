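# Independent oracles and fixture builders shared across tests.
# The oracles deliberately use dense, brute-force linear algebra so they
# share no code path with the package's rotated/vectorized implementations.

suppressPackageStartupMessages(library(SummarizedExperiment))

# Dense REML log-likelihood of the LMM with Sigma = gamma*M + I and the
# error precision profiled out (REML), evaluated without any rotation.
denseREMLLogLik <- function(gamma, y, X, M) {
    n <- length(y)
    q <- ncol(X)
    H <- gamma * M + diag(n)
    Hi <- solve(H)
    A <- t(X) %*% Hi %*% X
    b <- t(X) %*% Hi %*% y
    beta <- solve(A, b)
    quad <- drop(t(y) %*% Hi %*% y - t(b) %*% beta)
    0.5 * (n - q) * log((n - q) / (2 * pi)) - 0.5 * (n - q) -
        0.5 * as.numeric(determinant(H, TRUE)$modulus) -
        0.5 * as.numeric(determinant(A, TRUE)$modulus) +
        0.5 * as.numeric(determinant(crossprod(X), TRUE)$modulus) -
        0.5 * (n - q) * log(quad)
}

# Dense generalized-least-squares estimate and standard error of the last
# design column at a fixed gamma (REML residual variance).
denseGLS <- function(gamma, y, X, M) {
    n <- length(y)
    q <- ncol(X)
    H <- gamma * M + diag(n)
    Hi <- solve(H)
    A <- t(X) %*% Hi %*% X
    b <- t(X) %*% Hi %*% y
    beta <- solve(A, b)
    quad <- drop(t(y) %*% Hi %*% y - t(b) %*% beta)
    tauInv <- quad / (n - q)
    covB <- solve(A) * tauInv
    list(beta = beta[q], se = sqrt(covB[q, q]))
}

# Random positive-semidefinite matrix with unit-ish diagonal.
randomPSD <- function(n, seed = 1) {
    set.seed(seed)
    A <- matrix(rnorm(n * 2 * n), 2 * n, n)
    M <- crossprod(A) / (2 * n)
    M / mean(diag(M))
}

# Small count fixture with reproducible Poisson counts.
toyCounts <- function(p, n, lambda = 50, seed = 1) {
    set.seed(seed)
    k <- matrix(rpois(p * n, lambda), p, n,
                dimnames = list(sprintf("g%02d", seq_len(p)),
                                sprintf("s%02d", seq_len(n))))
    k
}

# A small normalized dataset plus trait for engine-level tests.
toyDataset <- function(p = 50, n = 20, seed = 1) {
    dds <- simulateDGE(nSamples = n, nGenes = p, nbDispersion = 0.1,
                       librarySizeLogSD = 0.2, seed = seed)
    normalizeLog2(estimateSizeFactors(dds))
}
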