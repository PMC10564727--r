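rawSCE <- function(counts) {
    SingleCellExperiment(assays = list(counts = counts))
}

test_that("qcFilter applies the three criteria and reports removals", {
    counts <- rbind(MT1 = c(2, 30, 5), G1 = c(50, 50, 50), G2 = c(48, 20, 45))
    colnames(counts) <- paste0("c", 1:3)
    m <- rawSCE(counts)
    # mito fractions 0.02, 0.3, 0.05 with max 0.1 -> cells 1 and 3 kept
    out <- qcFilter(m, qcThresholds(maxMitoFraction = 0.1), mitoGenes = "MT1")
    expect_identical(colnames(out), c("c1", "c3"))
    expect_equal(as.matrix(assay(out, "counts")), counts[, c(1, 3)])
    # identity thresholds keep everything
    out2 <- qcFilter(m, qcThresholds(), mitoGenes = "MT1")
    expect_identical(ncol(out2), 3L)
    # zero-count cell removed by the minimum-count rule
    z <- rawSCE(cbind(c1 = c(A = 0, B = 0), c2 = c(A = 2, B = 1)))
    kept <- qcFilter(z, qcThresholds(minTotalCounts = 1))
    expect_identical(colnames(kept), "c2")
    expect_error(qcFilter(z, qcThresholds(minTotalCounts = 100)), "all cells")
})

test_that("normalization follows the 1e4 log1p formula and skips constant genes", {
    counts <- matrix(10, nrow = 10, ncol = 2,
                     dimnames = list(paste0("g", 1:10), c("c1", "c2")))
    counts[2:10, 1] <- 10  # totals 100 and 200
    counts[2:10, 2] <- c(30, 30, 30, 30, 20, 20, 10, 10, 10)
    m <- rawSCE(counts)
    totals <- colSums(counts)
    expect_identical(unname(totals), c(100, 200))
    norm <- normalizeSelectHVG(m, nHVG = 5)
    expect_equal(assay(norm, "logcounts")["g1", "c1"], log1p(10 / 100 * 1e4))
    expect_equal(assay(norm, "logcounts")["g1", "c2"], log1p(10 / 200 * 1e4))
    # constant gene is never an HVG when nHVG < nGenes
    const <- matrix(rpois(300, 5), 15, 20,
                    dimnames = list(paste0("g", 1:15), paste0("c", 1:20)))
    const["g3", ] <- 7
    n2 <- normalizeSelectHVG(rawSCE(const), nHVG = 10)
    expect_false("g3" %in% hvgGenes(n2))
    expect_warning(normalizeSelectHVG(rawSCE(const), nHVG = 50), "clamp")
})

test_that("fitPCA is an exact SVD with the documented conventions", {
    set.seed(1)
    # rank-1 matrix: all variance on PC1
    u <- rnorm(30)
    v <- rnorm(8)
    logc <- outer(abs(v), abs(u)) * 3
    dimnames(logc) <- list(paste0("g", 1:8), paste0("c", 1:30))
    m <- SingleCellExperiment(assays = list(counts = logc, logcounts = logc))
    pca <- fitPCA(m, rownames(m), nComponents = 8)
    expect_lt(sum(pcaVariance(pca)[-1]), 1e-8)
    # reconstruction with all components reproduces the scaled matrix
    full_logc <- matrix(rnorm(8 * 30), 8, 30,
                        dimnames = dimnames(logc))
    m2 <- SingleCellExperiment(assays = list(counts = full_logc,
                                             logcounts = full_logc))
    pca2 <- fitPCA(m2, rownames(m2), nComponents = 8)
    scaled <- limbatlas:::.scale_genes(full_logc)
    rec <- pcaScores(pca2) %*% t(pcaLoadings(pca2))
    expect_lt(max(abs(rec - t(scaled))), 1e-6)
    # scores equal scaled matrix times loadings
    expect_lt(max(abs(pcaScores(pca2) - t(scaled) %*% pcaLoadings(pca2))), 1e-6)
    # explained variances match a brute-force covariance eigendecomposition
    hand <- matrix(c(1, 2, 0, 4, 3, 3, 2, 2, 5, 1, 0, 2), nrow = 4,
                   dimnames = list(paste0("c", 1:4), paste0("g", 1:3)))
    mh <- SingleCellExperiment(assays = list(counts = t(hand),
                                             logcounts = t(hand)))
    pcah <- suppressWarnings(fitPCA(mh, paste0("g", 1:3), nComponents = 3))
    xs <- limbatlas:::.scale_genes(t(hand))
    ev <- eigen(cov(t(xs)), symmetric = TRUE)$values
    expect_equal(unname(pcaVariance(pcah)), ev[seq_along(pcaVariance(pcah))],
                 tolerance = 1e-8)
    # loading columns are unit norm and sign convention holds
    expect_equal(unname(sqrt(colSums(pcaLoadings(pcah)^2))),
                 rep(1, ncol(pcaLoadings(pcah))))
    for (j in seq_len(ncol(pcaLoadings(pcah)))) {
        col <- pcaLoadings(pcah)[, j]
        expect_gt(col[which.max(abs(col))], 0)
    }
})

test_that("cell-cycle scores separate a constructed S-phase cell", {
    set.seed(2)
    counts <- matrix(rpois(20 * 12, 5), 20, 12,
                     dimnames = list(paste0("g", 1:20), paste0("c", 1:12)))
    s_genes <- paste0("g", 1:4)
    g2m_genes <- paste0("g", 5:8)
    counts[s_genes, "c1"] <- 80  # strong S signal in cell 1
    m <- normalizeSelectHVG(rawSCE(counts), nHVG = 10)
    cc <- scoreCellCycle(m, s_genes, g2m_genes, seed = 1)
    expect_gt(cc["c1", "sScore"], 0)
    expect_gt(cc["c1", "sScore"], cc["c1", "g2mScore"])
    expect_identical(cc["c1", "phase"], "S")
    # all-zero set and controls give score 0 and phase G1
    zero <- matrix(0, 6, 3, dimnames = list(paste0("g", 1:6), paste0("c", 1:3)))
    mz <- SingleCellExperiment(assays = list(counts = zero, logcounts = zero))
    ccz <- scoreCellCycle(mz, "g1", "g2", seed = 1)
    expect_equal(ccz$sScore, rep(0, 3))
    expect_identical(unique(ccz$phase), "G1")
    # duplicating the population leaves scores unchanged (mean-based)
    mdup <- normalizeSelectHVG(rawSCE(cbind(counts, counts)), nHVG = 10)
    ccd <- scoreCellCycle(mdup, s_genes, g2m_genes, seed = 1)
    expect_equal(ccd[1:12, "sScore"], ccd[13:24, "sScore"])
    expect_error(scoreCellCycle(m, "absent_gene", g2m_genes), "no gene")
})

test_that("cycle-PC correction flags, removes and refits as specified", {
    panel <- fxSmallPanel()
    d <- fxSmallNormalized()$species2
    pca <- fitPCA(d, nComponents = 20)
    cyc <- panel$genes$symbols[c(panel$genes$cycleS, panel$genes$cycleG2M)]
    # infinite threshold: no flags, model returned unchanged
    res_inf <- correctCyclePCs(d, pca, cyc, threshold = Inf)
    expect_length(flaggedPCs(res_inf$report), 0)
    expect_identical(pcaLoadings(res_inf$model), pcaLoadings(pca))
    # no cycle gene among genes used: all sums zero
    res_none <- correctCyclePCs(d, pca, c("not_a_gene"), threshold = 0.5)
    expect_true(all(res_none$report@pcLoadingSums == 0))
    expect_length(flaggedPCs(res_none$report), 0)
    # a real correction removes the union of per-PC top-10% sets
    res <- correctCyclePCs(d, pca, cyc, threshold = 3)
    if (length(flaggedPCs(res$report))) {
        n_top <- ceiling(0.1 * length(pcaGenes(pca)))
        loads <- pcaLoadings(pca)
        genes <- pcaGenes(pca)
        expected <- unique(unlist(lapply(flaggedPCs(res$report), function(pc)
            genes[order(-abs(loads[, pc]), genes)][seq_len(n_top)])))
        expect_setequal(removedGenes(res$report), expected)
        expect_identical(sort(pcaGenes(res$model)),
                         sort(setdiff(genes, expected)))
    }
})

test_that("Louvain clustering recovers separated blobs deterministically", {
    set.seed(3)
    blob <- rbind(matrix(rnorm(100 * 5), 100, 5),
                  matrix(rnorm(100 * 5, mean = 10), 100, 5))
    fake <- methods::new("PCAModel",
                         loadings = diag(5)[, 1:5] / 1,
                         scores = blob,
                         varExplained = rep(1, 5),
                         genes = paste0("g", 1:5))
    rownames(fake@scores) <- paste0("c", 1:200)
    cl <- clusterCells(fake, nPCs = 5, k = 20, seed = 1)
    truth <- rep(0:1, each = 100)
    expect_equal(mclust::adjustedRandIndex(cl, truth), 1)
    cl2 <- clusterCells(fake, nPCs = 5, k = 20, seed = 1)
    expect_identical(cl, cl2)
    # resolution -> 0 merges a connected graph into one cluster
    cl0 <- clusterCells(fake, nPCs = 5, k = 150, resolution = 0.001, seed = 1)
    expect_identical(length(unique(cl0)), 1L)
    expect_error(clusterCells(fake, k = 500), "smaller")
})

test_that("the 2-D embedding is deterministic and separates blobs", {
    set.seed(4)
    blob <- rbind(matrix(rnorm(60 * 6), 60, 6),
                  matrix(rnorm(60 * 6, mean = 12), 60, 6))
    rownames(blob) <- paste0("c", 1:120)
    fake <- methods::new("PCAModel", loadings = diag(6),
                         scores = blob, varExplained = rep(1, 6),
                         genes = paste0("g", 1:6))
    emb <- embedCells(fake, nPCs = 6, seed = 5)
    expect_identical(dim(emb), c(120L, 2L))
    expect_identical(emb, embedCells(fake, nPCs = 6, seed = 5))
    grp <- rep(1:2, each = 60)
    d <- as.matrix(dist(emb))
    intra <- mean(d[grp == 1, grp == 1])
    inter <- mean(d[grp == 1, grp == 2])
    expect_gt(inter, intra)
})

test_that("cluster downsampling halves only oversized clusters", {
    counts <- matrix(1, 2, 2101)
    rownames(counts) <- c("g1", "g2")
    colnames(counts) <- paste0("c", seq_len(2101))
    m <- rawSCE(counts)
    labels <- rep(c(0, 1, 2), c(1200, 400, 501))
    out <- downsampleClusters(m, labels, cap = 500, seed = 1)
    kept <- table(labels[match(colnames(out), colnames(m))])
    expect_identical(unname(kept["0"]), 600L)   # 1200 -> 600
    expect_identical(unname(kept["1"]), 400L)   # below cap untouched
    expect_identical(unname(kept["2"]), 251L)   # ceil(501 / 2)
})

test_that("clustering the default development data recovers the true types", {
    panel <- fxSmallPanel()
    d <- fxSmallNormalized()$species1
    pca <- fitPCA(d, nComponents = 20)
    cyc <- panel$genes$symbols[c(panel$genes$cycleS, panel$genes$cycleG2M)]
    cc <- correctCyclePCs(d, pca, cyc, threshold = 3)
    cl <- clusterCells(cc$model, nPCs = 15, k = 20, seed = 1)
    ari <- mclust::adjustedRandIndex(cl, colData(d)$true_type)
    expect_gte(ari, 0.9)
})
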