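# Reading/writing the pipeline's plain-text interchange formats and the
# end-to-end pipeline driver.

#' Read a raw count matrix
#'
#' Supports TSV (header row of sample ids, first column gene ids) and
#' MatrixMarket triplets (with separate one-id-per-line gene and sample id
#' files).
#'
#' @param path count file (`.tsv`/`.txt` or `.mtx`).
#' @param geneIds,sampleIds id files, required for MTX input.
#' @param geneLengthsPath optional two-column TSV (gene_id, length).
#' @return a [DGEDataSet-class] (no colData yet).
#' @export
readCounts <- function(path, geneIds = NULL, sampleIds = NULL,
                       geneLengthsPath = NULL) {
    if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
        if (is.null(geneIds) || is.null(sampleIds))
            stop("MTX input requires geneIds and sampleIds files")
        m <- as.matrix(Matrix::readMM(path))
        rownames(m) <- readLines(geneIds)
        colnames(m) <- readLines(sampleIds)
    } else {
        df <- utils::read.delim(path, check.names = FALSE,
                                stringsAsFactors = FALSE)
        m <- as.matrix(df[, -1L, drop = FALSE])
        rownames(m) <- df[[1L]]
    }
    lengths <- NULL
    if (!is.null(geneLengthsPath)) {
        ldf <- utils::read.delim(geneLengthsPath, header = TRUE,
                                 stringsAsFactors = FALSE)
        lengths <- stats::setNames(as.numeric(ldf[[2L]]), ldf[[1L]])
    }
    DGEDataSet(m, geneLengths = lengths)
}

#' Write a numeric matrix as TSV with gene ids in the first column
#'
#' @param m matrix with dimnames.
#' @param path output path.
#' @param idColumn header of the first column (default "gene_id").
#' @export
writeMatrixTSV <- function(m, path, idColumn = "gene_id") {
    df <- data.frame(rownames(m), format(m, digits = 12, trim = TRUE),
                     check.names = FALSE, stringsAsFactors = FALSE)
    colnames(df) <- c(idColumn, colnames(m))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a per-sample phenotype/covariate table
#'
#' Expects a TSV with a `sample_id` column, a numeric trait column and any
#' further covariate columns. Samples are aligned by id to `sampleIds`
#' when given (order-insensitive); categorical covariates are expanded to
#' indicator columns and an intercept is prepended.
#'
#' @param path phenotype TSV.
#' @param trait name of the trait column.
#' @param covariates character vector of covariate column names (may be
#'   empty: intercept-only design).
#' @param sampleIds optional sample ids (e.g. `colnames(dds)`) to align to.
#' @return list with `trait` (named numeric vector), `W` (design matrix
#'   with intercept) and `sampleIds`.
#' @export
readPhenotypes <- function(path, trait, covariates = character(),
                           sampleIds = NULL) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!"sample_id" %in% colnames(df))
        stop("phenotype file must contain a 'sample_id' column")
    if (anyDuplicated(df$sample_id))
        stop("duplicate sample ids in phenotype file")
    if (!trait %in% colnames(df))
        stop("trait column '", trait, "' not found")
    if (!is.null(sampleIds)) {
        missing <- setdiff(sampleIds, df$sample_id)
        if (length(missing))
            stop("phenotype file lacks samples: ",
                 paste(head(missing, 5L), collapse = ", "))
        df <- df[match(sampleIds, df$sample_id), , drop = FALSE]
    }
    y <- df[[trait]]
    if (!is.numeric(y)) stop("trait column '", trait, "' is not numeric")
    missingCov <- setdiff(covariates, colnames(df))
    if (length(missingCov))
        stop("covariate column(s) not found: ",
             paste(missingCov, collapse = ", "))
    W <- .buildDesign(df[, covariates, drop = FALSE])
    rownames(W) <- df$sample_id
    list(trait = stats::setNames(y, df$sample_id), W = W,
         sampleIds = df$sample_id)
}

#' Write a DGEResults table as TSV
#'
#' @param results a [DGEResults-class].
#' @param path output path.
#' @export
writeResults <- function(results, path) {
    df <- as.data.frame(results)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) signif(x, 12))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a DGEResults TSV back
#' @param path file written by [writeResults()].
#' @return a [DGEResults-class].
#' @export
readResults <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    method <- unique(df$method)
    model <- unique(df$model)
    df$chr <- as.character(df$chr)
    df$flag[is.na(df$flag)] <- ""
    .DGEResults(df, method = method, model = model)
}

#' Read a pipeline run configuration
#'
#' YAML file with keys: `counts`, `phenotypes`, `trait`, `covariates`,
#' `methods` (subset of lmm/ols/robust/voom), `gene_lengths`,
#' `min_total_reads`, `tpm_floor`, `max_fraction_below`, `alpha`,
#' `out_dir`, `seed`, plus optional engine constants
#' (`huber_k`, `voom_span`, `ols_reference`, `effect_cut`, `p_cut`).
#'
#' @param path YAML config file.
#' @return named list with defaults filled in.
#' @export
readRunConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    defaults <- list(methods = c("lmm", "ols", "robust", "voom"),
                     covariates = character(),
                     gene_lengths = NULL,
                     min_total_reads = 1e7, tpm_floor = 0.1,
                     max_fraction_below = 0.20, alpha = 0.05,
                     huber_k = 1.345, voom_span = 0.5,
                     ols_reference = "normal",
                     effect_cut = 0.05, p_cut = 0.05,
                     out_dir = "lmmdge_out", seed = 1L)
    for (nm in names(defaults))
        if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
    bad <- setdiff(cfg$methods, c("lmm", "ols", "robust", "voom"))
    if (length(bad)) stop("unknown method(s): ", paste(bad, collapse = ", "))
    if (!length(cfg$methods)) stop("at least one method is required")
    cfg
}

#' Run one engine on a prepared data set
#'
#' Thin dispatcher over [runLMM()], [runOLS()], [runHuber()], [runVoom()].
#'
#' @param object a [DGEDataSet-class] with normalized expression.
#' @param method one of `"lmm"`, `"ols"`, `"robust"`, `"voom"`.
#' @param trait,covariates passed through to the engine.
#' @param relatedness optional precomputed relatedness matrix (LMM only).
#' @param ... further engine-specific arguments.
#' @return a [DGEResults-class].
#' @export
runEngine <- function(object, method, trait, covariates = character(),
                      relatedness = NULL, ...) {
    switch(match.arg(method, c("lmm", "ols", "robust", "voom")),
           lmm = runLMM(object, trait, covariates,
                        relatedness = relatedness, ...),
           ols = runOLS(object, trait, covariates, ...),
           robust = runHuber(object, trait, covariates, ...),
           voom = runVoom(object, trait, covariates, ...))
}

#' End-to-end DGE pipeline
#'
#' Reads counts and phenotypes, applies the sample and (when gene lengths
#' are available) TPM gene filters, normalizes, builds the relatedness
#' matrix, runs the requested engines, and writes all artifacts (filter
#' report, size factors, normalized matrix, relatedness matrix, per-method
#' result TSVs, calibration report with lambda per method, volcano and
#' Manhattan tables, JSON manifest) to `cfg$out_dir`.
#'
#' @param cfg configuration list from [readRunConfig()], or a path to a
#'   YAML config file.
#' @return invisibly, a list with the per-method results, lambdas and the
#'   manifest.
#' @export
runPipeline <- function(cfg) {
    if (is.character(cfg)) cfg <- readRunConfig(cfg)
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    logmsg <- function(...) message("[lmmdge] ", ...)

    logmsg("reading counts from ", cfg$counts)
    dds <- readCounts(cfg$counts, geneLengthsPath = cfg$gene_lengths)
    logmsg(nrow(dds), " genes x ", ncol(dds), " samples")

    logmsg("filtering samples (min total reads ", cfg$min_total_reads, ")")
    dds <- filterSamples(dds, cfg$min_total_reads)
    if (!is.null(geneLengths(dds))) {
        logmsg("filtering genes (< ", cfg$tpm_floor, " TPM in > ",
               100 * cfg$max_fraction_below, "% samples)")
        dds <- filterGenes(dds, tpmFloor = cfg$tpm_floor,
                           maxFractionBelow = cfg$max_fraction_below)
    } else {
        logmsg("no gene lengths supplied; skipping the TPM gene filter")
    }
    fr <- filterReport(dds)
    frLines <- unlist(lapply(fr, function(r)
        paste0(r$stage, "\t", paste(r$removed, collapse = ","))))
    writeLines(c("stage\tremoved", frLines %||% character()),
               file.path(cfg$out_dir, "filter_report.tsv"))

    logmsg("reading phenotypes from ", cfg$phenotypes)
    ph <- readPhenotypes(cfg$phenotypes, cfg$trait, cfg$covariates,
                         sampleIds = colnames(dds))
    colData(dds)[[cfg$trait]] <- ph$trait

    logmsg("estimating size factors and normalizing")
    dds <- estimateSizeFactors(dds)
    dds <- normalizeLog2(dds)
    utils::write.table(
        data.frame(sample_id = colnames(dds),
                   size_factor = signif(sizeFactors(dds), 12)),
        file.path(cfg$out_dir, "size_factors.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    writeMatrixTSV(signif(normalizedExpression(dds), 12),
                   file.path(cfg$out_dir, "normalized.tsv"))

    relatedness <- NULL
    if ("lmm" %in% cfg$methods) {
        logmsg("building the relatedness matrix")
        relatedness <- computeRelatedness(dds)
        writeRelatedness(relatedness,
                         file.path(cfg$out_dir, "relatedness.txt"))
    }

    results <- list()
    lambdas <- numeric(0)
    for (m in cfg$methods) {
        logmsg("running engine: ", m)
        res <- switch(m,
            lmm = runLMM(dds, cfg$trait, cfg$covariates,
                         relatedness = relatedness),
            ols = runOLS(dds, cfg$trait, cfg$covariates,
                         reference = cfg$ols_reference),
            robust = runHuber(dds, cfg$trait, cfg$covariates,
                              kMultiplier = cfg$huber_k),
            voom = runVoom(dds, cfg$trait, cfg$covariates,
                           span = cfg$voom_span))
        results[[m]] <- res
        writeResults(res, file.path(cfg$out_dir,
                                    paste0("results_", m, ".tsv")))
        lambdas[m] <- genomicControlLambda(res$pvalue)
        logmsg(sprintf("  lambda(%s) = %.3f", m, lambdas[m]))
        vt <- volcanoTable(res, cfg$effect_cut, cfg$p_cut)
        utils::write.table(vt, file.path(cfg$out_dir,
                                         paste0("volcano_", m, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        if (!all(is.na(res$chr))) {
            mt <- manhattanTable(res,
                                 thresholds = c(bonferroniThreshold(
                                     cfg$alpha, nrow(res)), 1e-4))
            utils::write.table(mt$table,
                               file.path(cfg$out_dir,
                                         paste0("manhattan_", m, ".tsv")),
                               sep = "\t", quote = FALSE, row.names = FALSE)
        }
    }
    calib <- data.frame(method = names(lambdas),
                        lambda = signif(lambdas, 12),
                        n_tests = nrow(dds),
                        bonferroni = bonferroniThreshold(cfg$alpha,
                                                         nrow(dds)))
    utils::write.table(calib, file.path(cfg$out_dir, "calibration.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    manifest <- list(package = "lmmdge",
                     version = as.character(utils::packageVersion("lmmdge")),
                     r_version = R.version.string,
                     config = cfg[setdiff(names(cfg), "out_dir")],
                     outputs = list.files(cfg$out_dir),
                     lambdas = as.list(lambdas),
                     n_genes = nrow(dds), n_samples = ncol(dds))
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    logmsg("done; outputs in ", cfg$out_dir)
    invisible(list(results = results, lambdas = lambdas,
                   manifest = manifest, dds = dds))
}
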