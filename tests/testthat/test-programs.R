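mkExpr <- function(x) {
    SingleCellExperiment(assays = list(counts = x, logcounts = x))
}

test_that("rank-sum DEG handles identical groups and matches enumeration", {
    x <- matrix(rep(c(1, 2, 3, 1, 2, 3), each = 2), nrow = 2,
                dimnames = list(c("g1", "g2"), paste0("c", 1:6)))
    res <- wilcoxonDEG(mkExpr(x), paste0("c", 1:3), paste0("c", 4:6))
    expect_equal(res$p, rep(1, 2))
    # separated groups: exact two-sided p = 0.1; normal approx within 0.06
    y <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 1,
                dimnames = list("g1", paste0("c", 1:6)))
    resy <- wilcoxonDEG(mkExpr(y), paste0("c", 1:3), paste0("c", 4:6))
    exact <- oracleExactRankSum(c(1, 2, 3), c(4, 5, 6))
    expect_equal(exact, 0.1)
    expect_lt(abs(resy$p - exact), 0.06)
    expect_error(wilcoxonDEG(mkExpr(y), "c1", "c1"), "overlap")
    expect_error(wilcoxonDEG(mkExpr(y), character(), "c1"), "non-empty")
})

test_that("normal-approximation p values track exact enumeration on small toys", {
    set.seed(11)
    for (i in 1:25) {
        nA <- sample(2:4, 1)
        nB <- sample(3:4, 1)
        vals <- sample(seq_len(nA + nB))  # distinct ranks
        x <- matrix(vals, nrow = 1,
                    dimnames = list("g", paste0("c", seq_along(vals))))
        res <- wilcoxonDEG(mkExpr(x), paste0("c", seq_len(nA)),
                           paste0("c", nA + seq_len(nB)))
        exact <- oracleExactRankSum(vals[seq_len(nA)], vals[nA + seq_len(nB)])
        expect_lt(abs(res$p - exact), 0.06)
    }
})

test_that("BH adjustment matches the hand formula", {
    expect_equal(p.adjust(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))
    expect_equal(oracleBH(c(0.01, 0.02, 0.03)), rep(0.03, 3))
    base <- c(0.001, 0.02, 0.04, 0.2, 0.9)
    for (perm in combinat_perms <- list(1:5, 5:1, c(2, 4, 1, 5, 3),
                                        c(3, 1, 5, 2, 4))) {
        p <- base[perm]
        expect_equal(p.adjust(p, "BH"), oracleBH(p))
    }
})

test_that("marker intersection requires significance and positive fold in all tables", {
    t1 <- data.frame(gene = c("a", "b", "c"), log2FC = c(2, 1, -1),
                     padj = c(0.01, 0.04, 0.001))
    t2 <- data.frame(gene = c("a", "b", "c"), log2FC = c(1.5, 0.5, 2),
                     padj = c(0.01, 0.2, 0.01))
    out <- intersectMarkers(list(t1, t2))
    expect_identical(out, "a")  # b fails padj in t2; c fails sign in t1
    t3 <- data.frame(gene = c("a", "b"), log2FC = c(3, 2),
                     padj = c(0.01, 0.01))
    t4 <- data.frame(gene = c("a", "b"), log2FC = c(1, 2.5),
                     padj = c(0.04, 0.01))
    # sorted by minimum fold change descending: b (min 2) before a (min 1)
    expect_identical(intersectMarkers(list(t3, t4)), c("b", "a"))
})

test_that("planted AER markers are recovered by the DEG intersection", {
    panel <- fxSmallPanel()
    d <- fxSmallNormalized()$species1
    ty <- colData(d)$true_type
    aer <- colnames(d)[ty == "AER"]
    ecto_other <- colnames(d)[ty == "Goblet"]
    rest <- colnames(d)[ty != "AER"]
    deg_all <- wilcoxonDEG(d, aer, rest)
    deg_ecto <- wilcoxonDEG(d, aer, ecto_other)
    markers <- intersectMarkers(list(deg_all, deg_ecto))
    prog <- intersect(panel$genes$symbols[panel$genes$program], rownames(d))
    recall <- mean(prog %in% markers)
    expect_gte(recall, 0.8)
})

test_that("consensus NMF reconstructs a rank-1 matrix and orders errors by k", {
    set.seed(12)
    w <- runif(40, 1, 2)
    h <- runif(25, 0, 3)
    x <- outer(w, h)
    res <- consensusNMF(x, kRange = 1:3, nRestarts = 4, seed = 1,
                        maxIter = 300)
    expect_lt(res$errors[["1"]] / sqrt(sum(x^2)), 1e-4)
    noisy <- x + matrix(runif(1000, 0, 0.5), 40, 25)
    res_noisy <- consensusNMF(noisy, kRange = 1:3, nRestarts = 4, seed = 1,
                              maxIter = 300)
    expect_gt(res_noisy$errors[["1"]], res$errors[["1"]])
    # median restart reconstruction error is non-increasing in k
    med <- vapply(res_noisy$restartErrors, median, 0)
    expect_true(all(diff(med) <= 0.02 * med[[1]]))
    expect_warning(consensusNMF(x, kRange = c(2, 100), nRestarts = 2,
                                seed = 1, maxIter = 50), "clamp")
})

test_that("module specificity calls follow the fold rule on hand tables", {
    # 3 modules x 4 clusters of mean usage, 2 cells per cluster
    labels <- rep(c("AER", "CT", "Ecto", "Mus"), each = 2)
    usage <- cbind(
        m1 = rep(c(1.0, 0.1, 0.1, 0.1), each = 2),  # specific (10x)
        m2 = rep(c(0.6, 0.4, 0.1, 0.1), each = 2),  # 1.5x only
        m3 = rep(c(0.5, 0.5, 0.5, 0.5), each = 2)   # uniform
    )
    called <- callSpecificModules(usage, labels, "AER", fold = 2)
    expect_identical(unname(called), 1L)
    expect_error(callSpecificModules(usage, labels, "absent"), "absent")
    # module used only by the target is always called
    usage2 <- cbind(m1 = rep(c(1, 0, 0, 0), each = 2))
    expect_identical(unname(callSpecificModules(usage2, labels, "AER")), 1L)
})

test_that("gene-set projection subsets cells and genes as specified", {
    panel <- fxSmallPanel()
    d <- fxSmallNormalized()$species1
    labels <- colData(d)$true_type
    prog <- panel$genes$symbols[panel$genes$program]
    proj <- projectOnGenesets(d, list(aer = prog), labels,
                              keepClusters = c("AER", "CT"),
                              topN = 100, nPCs = 10, seed = 1)[[1]]
    expect_identical(sort(proj$cells),
                     sort(colnames(d)[labels %in% c("AER", "CT")]))
    expect_true(all(proj$genes %in% prog))
    expect_identical(dim(proj$embedding), c(length(proj$cells), 2L))
    expect_error(projectOnGenesets(d, list(x = c("nope1", "nope2")), labels,
                                   keepClusters = c("AER", "CT")),
                 "fewer than 10")
    expect_error(projectOnGenesets(d, list(aer = prog), labels,
                                   keepClusters = "NotAType"), "no cell")
})

test_that("cross-lineage aggregation scores extremes and is rotation invariant", {
    set.seed(13)
    epi <- matrix(rnorm(40 * 3), 40, 3)
    meso_far <- matrix(rnorm(40 * 3, mean = 30), 40, 3)
    coords <- rbind(epi, meso_far)
    rownames(coords) <- paste0("c", 1:80)
    lineage <- rep(c("ectoderm", "mesoderm"), each = 40)
    res <- crossLineageAggregation(coords, lineage, k = 10)
    expect_equal(res$score, 0)
    # mesodermal cells duplicated onto epithelial coordinates
    coords2 <- rbind(epi, epi + matrix(rnorm(120, sd = 1e-3), 40, 3))
    rownames(coords2) <- paste0("c", 1:80)
    res2 <- crossLineageAggregation(coords2, lineage, k = 10)
    expect_equal(res2$score, 1)
    # rigid rotation leaves the score unchanged
    theta <- 0.7
    rot <- diag(3)
    rot[1:2, 1:2] <- matrix(c(cos(theta), sin(theta),
                              -sin(theta), cos(theta)), 2)
    res3 <- crossLineageAggregation(coords2 %*% rot, lineage, k = 10)
    expect_equal(res3$score, res2$score)
    expect_error(crossLineageAggregation(coords, lineage, k = 100), "smaller")
    expect_error(crossLineageAggregation(coords, rep("ectoderm", 80)),
                 "both lineages")
})

test_that("hypergeometric over-representation matches closed forms", {
    universe <- paste0("g", 1:20)
    # forced overlap: hits = set = universe
    res <- oraHypergeometric(universe, list(all = universe), universe)
    expect_equal(res$p, 1)
    # universe 20, set 5, hits 5, overlap 5 -> 1 / C(20, 5)
    res2 <- oraHypergeometric(paste0("g", 1:5), list(s = paste0("g", 1:5)),
                              universe)
    expect_equal(res2$p, 1 / choose(20, 5))
    # zero overlap: upper tail including 0 is 1
    res3 <- oraHypergeometric(paste0("g", 1:5), list(s = paste0("g", 6:10)),
                              universe)
    expect_equal(res3$p, 1)
    expect_warning(
        oraHypergeometric(paste0("g", 1:5),
                          list(s = c("g6", "outside")), universe),
        "intersected")
    expect_error(oraHypergeometric("outside", list(s = universe), universe),
                 "subset")
})
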