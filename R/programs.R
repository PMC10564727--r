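#' Wilcoxon rank-sum differential expression between two cell groups
#'
#' Per gene, on normalized (`logcounts`) values: the mid-rank Mann-Whitney
#' U statistic with normal approximation, tie correction and continuity
#' correction, two-sided p values, Benjamini-Hochberg adjustment across all
#' tested genes, the log2 fold change of group means (pseudocount 1), and
#' the fraction of expressing cells per group.
#'
#' @param m `SingleCellExperiment` with `logcounts`.
#' @param cellsA,cellsB disjoint, non-empty cell id (or index) vectors.
#' @param alpha significance level on the adjusted p value.
#' @return `data.frame` with columns `gene`, `log2FC`, `U`, `p`, `padj`,
#'   `pctA`, `pctB`, `significant`, ordered by decreasing `log2FC`.
#' @export
wilcoxonDEG <- function(m, cellsA, cellsB, alpha = 0.05) {
    logc <- .logcounts(m)
    if (is.character(cellsA)) cellsA <- match(cellsA, colnames(logc))
    if (is.character(cellsB)) cellsB <- match(cellsB, colnames(logc))
    if (!length(cellsA) || !length(cellsB))
        stop("both cell groups must be non-empty")
    if (length(intersect(cellsA, cellsB)))
        stop("cell groups overlap")
    a <- .as_dense(logc[, cellsA, drop = FALSE])
    b <- .as_dense(logc[, cellsB, drop = FALSE])
    nA <- ncol(a)
    nB <- ncol(b)
    N <- nA + nB
    comb <- cbind(a, b)
    stats_gene <- function(x) {
        r <- rank(x, ties.method = "average")
        RA <- sum(r[seq_len(nA)])
        U <- RA - nA * (nA + 1) / 2
        ties <- table(x)
        tie_term <- sum(ties^3 - ties)
        sigma2 <- nA * nB / 12 * ((N + 1) - tie_term / (N * (N - 1)))
        if (sigma2 <= 0) return(c(U = U, p = 1))
        mu <- nA * nB / 2
        z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
        c(U = U, p = min(1, 2 * stats::pnorm(-abs(z))))
    }
    st <- t(apply(comb, 1, stats_gene))
    lfc <- log2(rowMeans(a) + 1) - log2(rowMeans(b) + 1)
    res <- data.frame(
        gene = rownames(logc), log2FC = lfc,
        U = st[, "U"], p = st[, "p"],
        padj = stats::p.adjust(st[, "p"], method = "BH"),
        pctA = rowMeans(a > 0), pctB = rowMeans(b > 0),
        row.names = NULL, stringsAsFactors = FALSE
    )
    res$significant <- res$padj < alpha
    res[order(-res$log2FC, res$gene), ]
}

#' Intersect upregulated markers across comparisons
#'
#' Genes with positive log2 fold change and adjusted p < 0.05 in every
#' supplied table, sorted by their minimum fold change (descending).
#'
#' @param degTables list of at least two [wilcoxonDEG()] tables.
#' @param padjCutoff adjusted-p threshold.
#' @return character vector of shared marker genes.
#' @export
intersectMarkers <- function(degTables, padjCutoff = 0.05) {
    stopifnot(length(degTables) >= 2)
    up_sets <- lapply(degTables, function(t)
        t$gene[t$log2FC > 0 & t$padj < padjCutoff])
    shared <- Reduce(intersect, up_sets)
    if (!length(shared)) return(character())
    min_fc <- vapply(shared, function(g) {
        min(vapply(degTables, function(t) t$log2FC[match(g, t$gene)], 0))
    }, 0)
    shared[order(-min_fc, shared, method = "radix")]
}

#' Prepare the nonnegative input matrix for consensus NMF
#'
#' Normalized expression restricted to the given genes, scaled to unit
#' variance per gene (no centring) — negative values cannot arise, matching
#' the nonnegativity requirement.
#'
#' @param m `SingleCellExperiment` with `logcounts`, or a matrix.
#' @param genes genes to keep (default: HVGs, else all).
#' @return cells x genes nonnegative matrix.
#' @export
nmfInputMatrix <- function(m, genes = NULL) {
    logc <- if (methods::is(m, "SummarizedExperiment")) {
        .logcounts(m)
    } else .as_dense(m)
    if (is.null(genes))
        genes <- if (methods::is(m, "SummarizedExperiment") &&
                     !is.null(hvgGenes(m))) hvgGenes(m) else rownames(logc)
    logc <- .as_dense(logc[intersect(genes, rownames(logc)), , drop = FALSE])
    sdv <- apply(logc, 1, sd)
    keep <- sdv > 0
    x <- logc[keep, , drop = FALSE] / sdv[keep]
    t(x)
}

# one NMF run by multiplicative updates (Frobenius loss)
.nmf_run <- function(x, k, max_iter = 200, eps = 1e-9) {
    n <- nrow(x)
    p <- ncol(x)
    w <- matrix(stats::runif(n * k, 1e-4, 1), n, k)
    h <- matrix(stats::runif(k * p, 1e-4, 1), k, p)
    for (it in seq_len(max_iter)) {
        h <- h * (crossprod(w, x) / (crossprod(w) %*% h + eps))
        w <- w * (x %*% t(h)) / (w %*% tcrossprod(h) + eps)
    }
    list(w = w, h = h)
}

# nonnegative least squares refit of usages against fixed spectra
.nnls_usages <- function(x, spectra) {
    a <- t(spectra)                       # genes x k
    res <- apply(x, 1, function(b) pracma::lsqnonneg(a, b)$x)
    if (is.null(dim(res))) matrix(res, ncol = 1) else t(res)
}

#' Consensus non-negative matrix factorization over a range of module counts
#'
#' For each `k`, `nRestarts` seeded NMF runs are pooled; each run's spectra
#' (unit L2 rows) are collected, outlier spectra (mean distance to their 3
#' nearest pooled neighbours above the 90th percentile) are dropped, the
#' remainder is clustered by seeded k-means, and per-cluster median spectra
#' are the consensus modules. Usages are refitted by non-negative least
#' squares; the reconstruction error is Frobenius, and stability is the
#' mean silhouette width of the pooled spectra against their k-means
#' clusters. The selected `k` minimizes the error among values whose
#' stability is at least 80 percent of the maximum stability.
#'
#' @param x cells x genes nonnegative matrix (see [nmfInputMatrix()]).
#' @param kRange integer vector of module counts to test.
#' @param nRestarts NMF restarts pooled per `k`.
#' @param seed integer seed.
#' @param maxIter multiplicative-update iterations per restart.
#' @return list with `models` (a [ConsensusModules] per `k`), `selectedK`,
#'   per-k consensus `errors` and `stabilities`, and `restartErrors` (the
#'   raw per-restart reconstruction errors, whose median is non-increasing
#'   in `k`; the consensus error need not be on rank-deficient data).
#' @export
consensusNMF <- function(x, kRange = 5:17, nRestarts = 20L, seed = 0L,
                         maxIter = 200L) {
    x <- .as_dense(x)
    if (any(x < 0)) stop("input must be nonnegative")
    seed <- .check_seed(seed)
    maxk <- min(dim(x))
    if (any(kRange > maxk)) {
        warning("kRange exceeds min(cells, genes); clamping")
        kRange <- kRange[kRange <= maxk]
    }
    models <- list()
    restart_errors <- list()
    for (k in kRange) {
        set.seed(seed + k)
        runs <- lapply(seq_len(nRestarts), function(r) {
            fit <- .nmf_run(x, k, max_iter = maxIter)
            sp <- fit$h
            norms <- sqrt(rowSums(sp^2))
            list(spectra = sp / pmax(norms, 1e-12),
                 error = sqrt(sum((x - fit$w %*% fit$h)^2)))
        })
        restart_errors[[as.character(k)]] <-
            vapply(runs, function(r) r$error, 0)
        pooled <- do.call(rbind, lapply(runs, function(r) r$spectra))
        if (k > 1 && nrow(pooled) > 4) {
            d <- as.matrix(dist(pooled))
            diag(d) <- Inf
            nn_mean <- apply(d, 1, function(r) mean(sort(r)[seq_len(3)]))
            keep <- nn_mean <= quantile(nn_mean, 0.9)
            pooled_f <- pooled[keep, , drop = FALSE]
        } else pooled_f <- pooled
        if (k == 1) {
            consensus <- matrix(apply(pooled_f, 2, median), nrow = 1)
            stability <- 1
        } else {
            km <- stats::kmeans(pooled_f, centers = k, nstart = 10,
                                iter.max = 50)
            consensus <- do.call(rbind, lapply(seq_len(k), function(g)
                apply(pooled_f[km$cluster == g, , drop = FALSE], 2, median)))
            sil <- cluster::silhouette(km$cluster, dist(pooled_f))
            stability <- mean(sil[, "sil_width"])
        }
        consensus <- consensus / pmax(sqrt(rowSums(consensus^2)), 1e-12)
        colnames(consensus) <- colnames(x)
        usages <- .nnls_usages(x, consensus)
        rownames(usages) <- rownames(x)
        err <- sqrt(sum((x - usages %*% consensus)^2))
        models[[as.character(k)]] <- methods::new(
            "ConsensusModules", k = as.integer(k), spectra = consensus,
            usages = usages, error = err, stability = stability,
            nRestarts = as.integer(nRestarts), seed = seed
        )
    }
    errors <- vapply(models, function(m) m@error, 0)
    stabilities <- vapply(models, function(m) m@stability, 0)
    ok <- stabilities >= 0.8 * max(stabilities)
    selected <- as.integer(names(models)[ok][which.min(errors[ok])])
    list(models = models, selectedK = selected,
         errors = errors, stabilities = stabilities,
         restartErrors = restart_errors)
}

#' Call modules specific to a target cluster
#'
#' A module is target-specific when its mean usage in the target cluster is
#' at least `fold` times the maximum mean usage over every other cluster.
#'
#' @param usages cells x modules usage matrix.
#' @param labels per-cell cluster labels.
#' @param target the target cluster.
#' @param fold specificity fold threshold.
#' @return integer vector of module indices.
#' @export
callSpecificModules <- function(usages, labels, target, fold = 2.0) {
    stopifnot(nrow(usages) == length(labels))
    if (!target %in% labels) stop("target cluster '", target, "' is absent")
    means <- apply(usages, 2, function(u) tapply(u, labels, mean))
    tgt <- means[as.character(target), ]
    other <- apply(means[setdiff(rownames(means), as.character(target)), ,
                         drop = FALSE], 2, max)
    which(tgt >= fold * other)
}

#' Project cells onto AER-program gene sets
#'
#' Subsets cells to the given clusters, restricts genes to the top `topN`
#' members of each gene set present in the data (sets are ordered vectors:
#' DEG lists by fold change, module spectra by weight), scales, runs PCA,
#' and builds the kNN graph and a 2-D embedding on the first `nPCs`.
#'
#' @param m `SingleCellExperiment` with `logcounts`.
#' @param geneSets named list of ordered gene vectors.
#' @param labels per-cell cluster labels aligned with `colnames(m)`.
#' @param keepClusters clusters to retain.
#' @param topN genes used per set.
#' @param nPCs components for the graph/embedding.
#' @param k neighbours for the graph.
#' @param seed integer seed.
#' @return named list (one per gene set) with `pca`, `embedding`, `graph`,
#'   `cells` and `genes`.
#' @export
projectOnGenesets <- function(m, geneSets, labels, keepClusters,
                              topN = 500L, nPCs = 30L, k = 15L, seed = 0L) {
    stopifnot(length(labels) == ncol(m))
    keep <- labels %in% keepClusters
    if (!any(keep)) stop("no cell belongs to the requested clusters")
    sub <- m[, keep]
    lapply(geneSets, function(set) {
        genes <- intersect(head(set, topN), rownames(sub))
        if (length(genes) < 10)
            stop("fewer than 10 gene-set members present in the data")
        pca <- fitPCA(sub, genes, nComponents = min(nPCs, length(genes)))
        npc <- min(nPCs, ncol(pcaScores(pca)))
        graph <- .knn_graph(pcaScores(pca)[, seq_len(npc), drop = FALSE],
                            min(k, ncol(sub) - 1))
        emb <- embedCells(pca, nPCs = npc, seed = seed)
        list(pca = pca, embedding = emb, graph = graph,
             cells = colnames(sub), genes = genes)
    })
}

#' Cross-lineage aggregation score
#'
#' Quantifies how strongly mesodermal cells co-aggregate with epithelial
#' (AER/AEC) cells in a gene-set-restricted PC space: for each mesodermal
#' cell, the fraction of its k nearest neighbours that are epithelial; the
#' score is the fraction of mesodermal cells whose epithelial-neighbour
#' fraction is at least 0.5.
#'
#' @param coords cells x components coordinate matrix.
#' @param lineage per-cell lineage labels.
#' @param epithelial lineage values treated as epithelial.
#' @param mesodermal lineage values treated as mesodermal.
#' @param k neighbours (must be < number of cells).
#' @return list with `score` in [0, 1] and `neighborFraction` per
#'   mesodermal cell.
#' @export
crossLineageAggregation <- function(coords, lineage,
                                    epithelial = "ectoderm",
                                    mesodermal = "mesoderm", k = 15L) {
    stopifnot(nrow(coords) == length(lineage))
    if (k >= nrow(coords)) stop("k must be smaller than the number of cells")
    is_epi <- lineage %in% epithelial
    is_meso <- lineage %in% mesodermal
    if (!any(is_epi) || !any(is_meso))
        stop("both lineages must be present")
    nn <- .knn_indices(coords, k)
    frac <- rowMeans(matrix(is_epi[nn], nrow = nrow(nn)))
    meso_frac <- frac[is_meso]
    names(meso_frac) <- rownames(coords)[is_meso]
    list(score = mean(meso_frac >= 0.5), neighborFraction = meso_frac)
}

#' Hypergeometric over-representation of gene sets in a hit list
#'
#' Upper-tail hypergeometric p value for the overlap of the hits with each
#' set, BH-adjusted across sets.
#'
#' @param hits character vector of hit genes (must be within the universe).
#' @param sets named list of gene sets.
#' @param universe background gene universe.
#' @return `data.frame` with `set`, `overlap`, `setSize`, `p`, `padj`.
#' @export
oraHypergeometric <- function(hits, sets, universe) {
    if (!all(hits %in% universe))
        stop("hits must be a subset of the universe")
    hits <- unique(hits)
    universe <- unique(universe)
    res <- do.call(rbind, lapply(names(sets), function(nm) {
        set <- unique(sets[[nm]])
        if (!all(set %in% universe)) {
            warning("set '", nm, "' intersected with the universe")
            set <- intersect(set, universe)
        }
        ov <- length(intersect(hits, set))
        p <- stats::phyper(ov - 1, length(set),
                           length(universe) - length(set),
                           length(hits), lower.tail = FALSE)
        data.frame(set = nm, overlap = ov, setSize = length(set), p = p,
                   stringsAsFactors = FALSE)
    }))
    res$padj <- stats::p.adjust(res$p, method = "BH")
    res
}
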