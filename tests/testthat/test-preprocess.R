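test_that("sample filtering obeys the strict < threshold and reports removals", {
    k <- cbind(s1 = c(5e6, 4999999), s2 = c(5e6, 5e6), s3 = c(6e6, 6e6))
    rownames(k) <- c("gA", "gB")
    dds <- DGEDataSet(k)

    # vacuous threshold leaves everything in place
    expect_identical(counts(filterSamples(dds, 0)), counts(dds))

    # totals (9,999,999; 10,000,000; 12,000,000): equality is retained
    expect_identical(colnames(filterSamples(dds, 1e7)), c("s2", "s3"))
    rep <- filterReport(filterSamples(dds, 1e7))$samples
    expect_identical(rep$removed, "s1")
    expect_equal(unname(rep$totalReads), 9999999)

    # brute-force oracle on a random matrix, threshold at a middle total
    k2 <- toyCounts(20, 5, seed = 42)
    dds2 <- DGEDataSet(k2)
    thr <- sort(colSums(k2))[3]
    kept <- filterSamples(dds2, thr)
    expect_identical(colnames(kept),
                     colnames(k2)[colSums(k2) >= thr])

    # idempotence
    expect_identical(counts(filterSamples(kept, thr)), counts(kept))

    # removing everything is a hard error naming the threshold
    expect_error(filterSamples(dds, 1e9), "1,000,000,000")
})

test_that("TPM columns are length-normalized rates summing to one million", {
    one <- DGEDataSet(matrix(c(7, 3), 1, 2,
                             dimnames = list("g1", c("s1", "s2"))),
                      geneLengths = c(g1 = 500))
    expect_true(all(computeTPM(one) == 1e6))

    two <- DGEDataSet(matrix(10, 2, 3,
                             dimnames = list(c("g1", "g2"),
                                             c("s1", "s2", "s3"))),
                      geneLengths = c(g1 = 1000, g2 = 2000))
    tpm <- computeTPM(two)
    expect_equal(unname(tpm["g1", ]), rep(2e6 / 3, 3))
    expect_equal(unname(tpm["g2", ]), rep(1e6 / 3, 3))

    # brute-force double loop oracle on a 10 x 4 matrix
    k <- toyCounts(10, 4, seed = 7)
    len <- seq(200, 2000, length.out = 10)
    dds <- DGEDataSet(k, geneLengths = setNames(len, rownames(k)))
    got <- computeTPM(dds)
    for (i in seq_len(4)) {
        rate <- k[, i] / len
        expect_equal(unname(got[, i]), unname(rate / sum(rate) * 1e6),
                     tolerance = 1e-12)
    }
    expect_equal(unname(colSums(got)), rep(1e6, 4), tolerance = 1e-6)

    expect_error(computeTPM(DGEDataSet(k)), "lengths")
})

test_that("gene filtering drops genes below the floor in > the allowed fraction", {
    n <- 10
    k <- toyCounts(15, n, seed = 3)
    dds <- DGEDataSet(k, geneLengths = setNames(rep(1000, 15), rownames(k)))
    tpm <- computeTPM(dds)

    # construct a fake TPM matrix with a known below-floor indicator
    tpmFake <- matrix(1, 15, n, dimnames = dimnames(k))
    below <- rbind(c(1, 0), c(2, 0), c(3, 2), c(4, 2), c(5, 3), c(6, 5),
                   c(7, 10))
    for (r in seq_len(nrow(below)))
        if (below[r, 2] > 0) tpmFake[below[r, 1], seq_len(below[r, 2])] <- 0.01

    out <- filterGenes(dds, tpm = tpmFake, tpmFloor = 0.1,
                       maxFractionBelow = 0.20)
    nBelow <- rowSums(tpmFake < 0.1)
    expect_identical(rownames(out), rownames(k)[nBelow / n <= 0.20])
    # exactly 2/10 = 0.20 is retained (strict > rule)
    expect_true("g03" %in% rownames(out) && "g04" %in% rownames(out))
    expect_false("g06" %in% rownames(out))

    # a gene above the floor everywhere is always retained
    expect_true("g01" %in% rownames(out))

    # idempotence on true TPM
    f1 <- filterGenes(dds, tpm = tpm)
    f2 <- filterGenes(f1)
    expect_identical(counts(f2), counts(f1))

    expect_error(filterGenes(dds, tpm = matrix(0, 15, n,
                                               dimnames = dimnames(k))),
                 "nothing retained")
})

test_that("median-of-ratios size factors match direct evaluation", {
    # identical columns: all ratios are 1
    k <- matrix(c(2, 4, 8), 3, 4, dimnames = list(paste0("g", 1:3),
                                                  paste0("s", 1:4)))
    expect_equal(unname(sizeFactorsFromCounts(k)), rep(1, 4))

    # worked fixture: columns (2,4,8) and (4,8,16)
    k2 <- cbind(s1 = c(2, 4, 8), s2 = c(4, 8, 16))
    rownames(k2) <- paste0("g", 1:3)
    s <- sizeFactorsFromCounts(k2)
    expect_equal(unname(s), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
    expect_equal(unname(round(s, 4)), c(0.7071, 1.4142))

    # a gene with a zero count has geometric mean 0 and is excluded
    k3 <- rbind(k2, g4 = c(0, 100))
    expect_equal(unname(sizeFactorsFromCounts(k3)), unname(s))

    # error when no gene has all-positive counts
    expect_error(sizeFactorsFromCounts(cbind(c(0, 5), c(3, 0))),
                 "geometric")
})

test_that("size factors scale, permute and cross-check against DESeq2", {
    k <- toyCounts(30, 6, seed = 11) + 1     # all positive
    s <- sizeFactorsFromCounts(k)

    # scaling one sample's counts by c: the geometric-mean reference itself
    # picks up a factor c^(1/n), so size-factor *ratios* against every other
    # sample scale by c exactly, and relative normalized expression is
    # preserved
    k2 <- k
    k2[, 3] <- k2[, 3] * 5
    s2 <- sizeFactorsFromCounts(k2)
    expect_equal(unname(s2[3] / s2[-3]), unname(5 * s[3] / s[-3]),
                 tolerance = 1e-12)
    # every other sample shares one common rescaling (5^(-1/6))
    expect_equal(unname(s2[-3] / s[-3]), rep(5^(-1 / 6), 5),
                 tolerance = 1e-12)
    # normalized counts change only through that common factor
    x1 <- sweep(k, 2, s, "/")
    x2 <- sweep(k2, 2, s2, "/")
    expect_equal(x2, x1 * 5^(1 / 6), tolerance = 1e-12)

    # permutation equivariance
    perm <- c(4, 1, 6, 2, 5, 3)
    expect_equal(unname(sizeFactorsFromCounts(k[, perm])),
                 unname(s[perm]), tolerance = 1e-12)

    # independent implementation of the same estimator
    skip_if_not_installed("DESeq2")
    expect_equal(unname(sizeFactorsFromCounts(k)),
                 unname(DESeq2::estimateSizeFactorsForMatrix(k)),
                 tolerance = 1e-10)
})

test_that("log2 normalization applies the offset-1 formula entrywise", {
    k <- cbind(s1 = c(0, 3), s2 = c(6, 12))
    rownames(k) <- c("g1", "g2")
    dds <- DGEDataSet(k)
    sizeFactors(dds) <- c(1, 2)
    x <- normalizedExpression(normalizeLog2(dds))
    expect_equal(x["g1", "s1"], 0)          # log2(0/1 + 1)
    expect_equal(x["g2", "s1"], 2)          # log2(3/1 + 1)
    expect_equal(x["g1", "s2"], 2)          # log2(6/2 + 1)

    # random matrix, direct formula
    k2 <- toyCounts(12, 5, seed = 5)
    dds2 <- estimateSizeFactors(DGEDataSet(k2))
    s <- sizeFactors(dds2)
    x2 <- normalizedExpression(normalizeLog2(dds2))
    expect_equal(x2, log2(sweep(k2, 2, s, "/") + 1), tolerance = 1e-12)
    expect_true(all(x2 >= 0))

    # misaligned size-factor names are an error
    expect_error(normalizeLog2(dds, s = c(bad1 = 1, bad2 = 2)), "missing")
})
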