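# Synthetic data generator: negative-binomial counts with sample-specific
# library sizes, gene-specific baseline abundances, a pervasive latent
# confounder loading on both genes and the trait, and optional true
# gene -> trait effects. This is the test bed on which the calibration
# contrast between the LMM and the unadjusted engines is measured.

# Negative-binomial sampler in the mean/dispersion parameterization
# variance = mu + alpha * mu^2; alpha = 0 is the Poisson limit.
.rnbinomDisp <- function(n, mu, alpha) {
    stopifnot(alpha >= 0)
    if (alpha == 0) stats::rpois(n, lambda = mu)
    else stats::rnbinom(n, mu = mu, size = 1 / alpha)
}

# Expand one master seed into named substreams so adding a component never
# perturbs the draws of the others. Order of names is fixed.
.substreamSeeds <- function(seed) {
    set.seed(seed)
    vals <- sample.int(.Machine$integer.max - 1L, 6L)
    stats::setNames(vals, c("libSizes", "baseMeans", "confounder",
                            "counts", "covariates", "trait"))
}

#' Simulate an RNA-seq count data set with a latent confounder
#'
#' Generative model: a latent factor \eqn{u_i \sim N(0,1)} per sample;
#' per-gene loadings \eqn{l_j \sim N(0, \sigma_l^2)}; log2-scale signal
#' \eqn{z_{ij} = b_j + l_j u_i + e_{ij}} with \eqn{e_{ij} \sim N(0,1)} and
#' baseline \eqn{b_j \sim U(\mathrm{baseLogMeanRange})}; counts
#' \eqn{K_{ij} \sim NB(\mu = s_i 2^{z_{ij}}, \alpha)} with
#' variance = mean + alpha * mean^2 and log-normal library-size factors
#' \eqn{s_i}. The trait is built on the log2-scale signal:
#' \eqn{y_i = W_i \eta + \sqrt{\mathrm{share}}\, u_i +
#' \beta \sum_{j \in C} z_{ij} + \sqrt{1-\mathrm{share}}\, \epsilon_i},
#' so with no causal genes the confounder contributes exactly `share` of
#' the trait variance.
#'
#' @param nSamples,nGenes dimensions.
#' @param nbDispersion NB dispersion alpha (variance = mean + alpha *
#'   mean^2); 0 gives Poisson counts.
#' @param baseLogMeanRange range of per-gene baseline log2 mean counts.
#' @param librarySizeLogSD sd of log library-size factors.
#' @param confounderLoadingVar variance of the per-gene confounder
#'   loadings l_j (0 switches the confounder off).
#' @param confounderTraitShare fraction of trait variance contributed by
#'   the confounder, in `[0, 1)`.
#' @param nCausal number of genes with true effects on the trait.
#' @param causalEffect trait units per log2-expression unit for each
#'   causal gene.
#' @param covariateSpec `"none"` (intercept-only) or `"binary_continuous"`
#'   (one balanced binary covariate with effect 0.5 and one standardized
#'   continuous covariate with effect 0.3).
#' @param seed master seed; all randomness derives from it through named
#'   substreams.
#' @return a [DGEDataSet-class] with the trait (`colData$trait`), any
#'   covariates, and `metadata(x)$truth`: causal gene ids, loadings,
#'   confounder values, library-size factors, true effects and the full
#'   config echo.
#' @export
simulateDGE <- function(nSamples, nGenes, nbDispersion = 0.1,
                        baseLogMeanRange = c(3, 8),
                        librarySizeLogSD = 0.3,
                        confounderLoadingVar = 0,
                        confounderTraitShare = 0,
                        nCausal = 0L, causalEffect = 0,
                        covariateSpec = c("none", "binary_continuous"),
                        seed = 1L) {
    covariateSpec <- match.arg(covariateSpec)
    stopifnot(nSamples >= 2, nGenes >= 1, nbDispersion >= 0,
              librarySizeLogSD >= 0, confounderLoadingVar >= 0,
              nCausal <= nGenes)
    if (confounderTraitShare < 0 || confounderTraitShare >= 1)
        stop("confounderTraitShare must lie in [0, 1)")
    seeds <- .substreamSeeds(seed)

    set.seed(seeds["libSizes"])
    s <- stats::rlnorm(nSamples, 0, librarySizeLogSD)

    set.seed(seeds["baseMeans"])
    b <- stats::runif(nGenes, baseLogMeanRange[1], baseLogMeanRange[2])

    set.seed(seeds["confounder"])
    u <- stats::rnorm(nSamples)
    l <- stats::rnorm(nGenes, 0, sqrt(confounderLoadingVar))

    set.seed(seeds["counts"])
    z <- b + outer(l, u) + matrix(stats::rnorm(nGenes * nSamples),
                                  nGenes, nSamples)
    mu <- sweep(2^z, 2L, s, "*")
    k <- matrix(.rnbinomDisp(nGenes * nSamples, mu, nbDispersion),
                nGenes, nSamples)

    set.seed(seeds["covariates"])
    covEffects <- numeric(0)
    covDf <- NULL
    if (covariateSpec == "binary_continuous") {
        covDf <- data.frame(
            group = stats::rbinom(nSamples, 1L, 0.5),
            score = as.numeric(scale(stats::rnorm(nSamples))))
        covEffects <- c(group = 0.5, score = 0.3)
    }

    set.seed(seeds["trait"])
    causal <- if (nCausal > 0) sort(sample.int(nGenes, nCausal)) else integer(0)
    causalPart <- if (nCausal > 0)
        causalEffect * colSums(z[causal, , drop = FALSE]) else 0
    y <- sqrt(confounderTraitShare) * u + causalPart +
        sqrt(1 - confounderTraitShare) * stats::rnorm(nSamples)
    if (!is.null(covDf))
        y <- y + as.matrix(covDf) %*% covEffects

    geneIds <- sprintf("gene%04d", seq_len(nGenes))
    sampleIds <- sprintf("sample%03d", seq_len(nSamples))
    dimnames(k) <- list(geneIds, sampleIds)
    cd <- data.frame(trait = as.numeric(y), row.names = sampleIds)
    if (!is.null(covDf)) cd <- cbind(cd, covDf)
    dds <- DGEDataSet(k, colData = cd)
    metadata(dds)$truth <- list(
        causalGenes = geneIds[causal],
        loadings = stats::setNames(l, geneIds),
        confounder = stats::setNames(u, sampleIds),
        libSizeFactors = stats::setNames(s, sampleIds),
        baseLogMeans = stats::setNames(b, geneIds),
        trueEffects = stats::setNames(rep(causalEffect, length(causal)),
                                      geneIds[causal]),
        config = list(nSamples = nSamples, nGenes = nGenes,
                      nbDispersion = nbDispersion,
                      baseLogMeanRange = baseLogMeanRange,
                      librarySizeLogSD = librarySizeLogSD,
                      confounderLoadingVar = confounderLoadingVar,
                      confounderTraitShare = confounderTraitShare,
                      nCausal = nCausal, causalEffect = causalEffect,
                      covariateSpec = covariateSpec, seed = seed))
    dds
}

#' Canonical confounded null scenario
#'
#' The fixed scenario behind the calibration contrast: n = 300 samples,
#' p = 2,000 genes, confounder loading variance 0.6, 40\% of trait
#' variance from the confounder, NB dispersion 0.1, library-size log-sd
#' 0.3, no causal genes, intercept-only covariates. Every gene is null,
#' yet each is correlated with the trait through the shared latent factor,
#' so unadjusted tests inflate while the LMM stays calibrated.
#'
#' @param seed master seed.
#' @return a [DGEDataSet-class]; see [simulateDGE()].
#' @export
scenarioNullConfounded <- function(seed = 1L) {
    simulateDGE(nSamples = 300L, nGenes = 2000L, nbDispersion = 0.1,
                librarySizeLogSD = 0.3, confounderLoadingVar = 0.6,
                confounderTraitShare = 0.4, nCausal = 0L,
                covariateSpec = "none", seed = seed)
}

#' Confounded scenario with spiked-in causal genes
#'
#' Same structure as [scenarioNullConfounded()] plus `nCausal` genes with
#' a true effect of `causalEffect` trait units per log2-expression unit,
#' for power / ranking checks against the recorded truth.
#'
#' @param seed master seed.
#' @param nCausal number of causal genes (default 20).
#' @param causalEffect per-gene effect size (default 0.2).
#' @return a [DGEDataSet-class]; see [simulateDGE()].
#' @export
scenarioSpiked <- function(seed = 1L, nCausal = 20L, causalEffect = 0.2) {
    simulateDGE(nSamples = 300L, nGenes = 2000L, nbDispersion = 0.1,
                librarySizeLogSD = 0.3, confounderLoadingVar = 0.6,
                confounderTraitShare = 0.4, nCausal = nCausal,
                causalEffect = causalEffect, covariateSpec = "none",
                seed = seed)
}
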