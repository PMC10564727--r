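#' QC thresholds for cell filtering
#'
#' @param maxMitoFraction maximum mitochondrial count fraction.
#' @param minTotalCounts,maxTotalCounts bounds on total counts per cell.
#' @param minGenesDetected,maxGenesDetected bounds on genes detected.
#' @return a validated list of class `"QCThresholds"`.
#' @export
qcThresholds <- function(maxMitoFraction = 1, minTotalCounts = 0,
                         maxTotalCounts = Inf, minGenesDetected = 0,
                         maxGenesDetected = Inf) {
    if (maxMitoFraction < 0 || maxMitoFraction > 1)
        stop("maxMitoFraction must lie in [0, 1]")
    if (minTotalCounts > maxTotalCounts || minGenesDetected > maxGenesDetected)
        stop("min thresholds must not exceed max thresholds")
    structure(list(maxMitoFraction = maxMitoFraction,
                   minTotalCounts = minTotalCounts,
                   maxTotalCounts = maxTotalCounts,
                   minGenesDetected = minGenesDetected,
                   maxGenesDetected = maxGenesDetected),
              class = "QCThresholds")
}

#' Filter cells on mitochondrial fraction, total counts and genes detected
#'
#' Keeps exactly the cells satisfying all three criteria; surviving counts
#' are untouched. The number of cells failing each criterion is recorded in
#' `metadata()$qc_removed`.
#'
#' @param m `SingleCellExperiment` with counts.
#' @param thresholds a [qcThresholds()] object.
#' @param mitoGenes character vector of mitochondrial gene ids.
#' @return the filtered `SingleCellExperiment`.
#' @export
qcFilter <- function(m, thresholds, mitoGenes = character()) {
    counts <- .counts(m)
    totals <- Matrix::colSums(counts)
    detected <- Matrix::colSums(counts > 0)
    mito <- intersect(mitoGenes, rownames(counts))
    mito_frac <- if (length(mito)) {
        Matrix::colSums(counts[mito, , drop = FALSE]) / pmax(totals, 1)
    } else rep(0, ncol(counts))
    ok_mito <- mito_frac <= thresholds$maxMitoFraction
    ok_counts <- totals >= thresholds$minTotalCounts &
        totals <= thresholds$maxTotalCounts
    ok_genes <- detected >= thresholds$minGenesDetected &
        detected <= thresholds$maxGenesDetected
    keep <- ok_mito & ok_counts & ok_genes
    if (!any(keep)) stop("all cells removed by QC filtering")
    out <- m[, keep]
    metadata(out)$qc_removed <- c(mito = sum(!ok_mito),
                                  total_counts = sum(!ok_counts),
                                  genes_detected = sum(!ok_genes))
    out
}

#' Normalize counts and select highly variable genes
#'
#' Adds a `logcounts` assay with `log1p(count / cell_total * 1e4)` and
#' selects the top `nHVG` genes by standardized variance: raw-count
#' variances are regressed on means with a loess trend in log10 space, each
#' gene's counts are z-scored against the trend-expected standard deviation,
#' clipped at `sqrt(n cells)`, and the variance of the clipped z-scores is
#' the ranking statistic.
#'
#' @param m `SingleCellExperiment` with counts.
#' @param nHVG number of highly variable genes (clamped with a warning when
#'   it exceeds the gene count).
#' @return `m` with a `logcounts` assay and `metadata()` fields `hvg`
#'   (HVG ids in rank order) and `hvg_rank` (rank per selected gene).
#' @export
normalizeSelectHVG <- function(m, nHVG = 2000L) {
    counts <- .as_dense(.counts(m))
    totals <- colSums(counts)
    totals[totals == 0] <- 1
    logc <- log1p(sweep(counts, 2, totals, "/") * 1e4)
    n <- ncol(counts)
    if (nHVG > nrow(counts)) {
        warning("nHVG exceeds the number of genes; clamping to ", nrow(counts))
        nHVG <- nrow(counts)
    }
    mu <- rowMeans(counts)
    v <- apply(counts, 1, var)
    usable <- mu > 0 & v > 0
    std_var <- rep(0, nrow(counts))
    if (sum(usable) > 10) {
        # loess may warn about near-singular neighbourhoods on tiny inputs;
        # the trend fit itself is still usable
        fit <- suppressWarnings(
            stats::loess(log10(v[usable]) ~ log10(mu[usable]), span = 0.3))
        exp_sd <- sqrt(10^suppressWarnings(
            stats::predict(fit, log10(mu[usable]))))
        z <- (counts[usable, , drop = FALSE] - mu[usable]) / exp_sd
        clip <- sqrt(n)
        z[z > clip] <- clip
        z[z < -clip] <- -clip
        std_var[usable] <- rowSums((z - rowMeans(z))^2) / (n - 1)
    }
    names(std_var) <- rownames(counts)
    ord <- order(-std_var, rownames(counts), method = "radix")
    hvg <- rownames(counts)[ord[seq_len(nHVG)]]
    if (methods::is(m, "SummarizedExperiment")) {
        assay(m, "logcounts") <- logc
        metadata(m)$hvg <- hvg
        metadata(m)$hvg_rank <- stats::setNames(seq_along(hvg), hvg)
        metadata(m)$std_var <- std_var
        m
    } else {
        list(logcounts = logc, hvg = hvg)
    }
}

#' @rdname normalizeSelectHVG
#' @export
hvgGenes <- function(m) metadata(m)$hvg

#' Exact principal component analysis of the scaled expression matrix
#'
#' Per-gene z-scores (clipped at +/-10) of the `logcounts` assay over the
#' supplied genes are decomposed by an exact truncated SVD (via the
#' eigendecomposition of the smaller Gram matrix). Loadings follow the sign
#' convention that each column's largest-magnitude entry is positive.
#'
#' @param m `SingleCellExperiment` with a `logcounts` assay.
#' @param genes genes to use (typically the HVGs).
#' @param nComponents number of components (clamped with a warning).
#' @return a [PCAModel].
#' @export
fitPCA <- function(m, genes = hvgGenes(m), nComponents = 50L) {
    logc <- .logcounts(m)
    genes <- intersect(genes, rownames(logc))
    if (!length(genes)) stop("none of the requested genes are present")
    maxk <- min(ncol(logc), length(genes))
    if (nComponents > maxk) {
        warning("nComponents exceeds min(cells, genes); clamping to ", maxk)
        nComponents <- maxk
    }
    scaled <- .scale_genes(logc[genes, , drop = FALSE])
    res <- .exact_pca(t(scaled), nComponents)
    rownames(res$loadings) <- genes
    colnames(res$loadings) <- paste0("PC", seq_len(ncol(res$loadings)))
    rownames(res$scores) <- colnames(logc)
    colnames(res$scores) <- colnames(res$loadings)
    methods::new("PCAModel", loadings = res$loadings, scores = res$scores,
                 varExplained = res$varExplained, genes = genes)
}

#' Per-cell S and G2M phase scores
#'
#' Seurat-style module scoring: a cell's score for a phase gene set is the
#' mean normalized expression of the set genes minus the mean of a
#' size-matched control set sampled (seeded) from 25 mean-expression-matched
#' bins. Phase is "S" when the S score exceeds both the G2M score and zero,
#' "G2M" when the G2M score is at least the S score and positive, else "G1".
#'
#' @param m `SingleCellExperiment` with a `logcounts` assay.
#' @param sGenes,g2mGenes phase gene sets.
#' @param nBins number of mean-expression bins for control sampling.
#' @param seed seed for control sampling.
#' @return `data.frame` with `sScore`, `g2mScore` and `phase` per cell.
#' @export
scoreCellCycle <- function(m, sGenes, g2mGenes, nBins = 25L, seed = 0L) {
    logc <- .logcounts(m)
    set.seed(.check_seed(seed))
    all_genes <- rownames(logc)
    gene_means <- rowMeans(logc)
    bins <- if (nBins >= 2) {
        cut(rank(gene_means, ties.method = "first"), breaks = nBins,
            labels = FALSE)
    } else rep(1L, length(gene_means))
    pool <- setdiff(all_genes, c(sGenes, g2mGenes))
    pool_bins <- bins[match(pool, all_genes)]
    score_set <- function(set) {
        present <- intersect(set, all_genes)
        if (!length(present))
            stop("no gene of the phase set is present in the matrix")
        ctrl <- vapply(present, function(g) {
            b <- bins[match(g, all_genes)]
            # expression-matched bin; fall back to the nearest occupied bin
            cand <- pool[abs(pool_bins - b) == min(abs(pool_bins - b))]
            if (!length(cand)) g else cand[sample.int(length(cand), 1L)]
        }, "")
        colMeans(logc[present, , drop = FALSE]) -
            colMeans(logc[ctrl, , drop = FALSE])
    }
    s <- score_set(sGenes)
    g2m <- score_set(g2mGenes)
    phase <- ifelse(s > g2m & s > 0, "S",
                    ifelse(g2m >= s & g2m > 0, "G2M", "G1"))
    out <- data.frame(sScore = s, g2mScore = g2m, phase = phase)
    rownames(out) <- make.unique(colnames(logc))
    out
}

#' Remove cell-cycle-correlated principal components
#'
#' For each PC the absolute loadings of the cycle genes are summed; PCs
#' whose sum exceeds `threshold` are flagged as cycle-correlated. The top
#' 10 percent of genes by absolute loading (ceiling) of each flagged PC are
#' removed (as a union) from the gene list and the PCA is refitted.
#'
#' @param m `SingleCellExperiment` with a `logcounts` assay.
#' @param pca the [PCAModel] fitted on `m`.
#' @param cycleGenes cell-cycle gene ids.
#' @param threshold flagging threshold on the summed absolute loading.
#' @param sGenes,g2mGenes optional phase sets; when given, per-cell phase
#'   scores are included in the report.
#' @param seed seed for the control sampling of the phase scores.
#' @return list with `model` (the corrected, or unchanged, [PCAModel]) and
#'   `report` (a [CycleReport]).
#' @export
correctCyclePCs <- function(m, pca, cycleGenes, threshold,
                            sGenes = NULL, g2mGenes = NULL, seed = 0L) {
    genes <- pcaGenes(pca)
    cyc <- intersect(cycleGenes, genes)
    loads <- pcaLoadings(pca)
    sums <- if (length(cyc)) {
        colSums(abs(loads[cyc, , drop = FALSE]))
    } else rep(0, ncol(loads))
    names(sums) <- colnames(loads)
    flagged <- which(sums > threshold)
    removed <- character()
    model <- pca
    if (length(flagged)) {
        n_top <- ceiling(0.10 * length(genes))
        removed <- unique(unlist(lapply(flagged, function(pc) {
            genes[order(-abs(loads[, pc]), genes,
                        method = "radix")][seq_len(n_top)]
        })))
        keep <- setdiff(genes, removed)
        if (!length(keep))
            stop("cycle correction removed every gene in the model")
        model <- fitPCA(m, keep, nComponents = ncol(loads))
    }
    s <- g2m <- numeric(0)
    phase <- character(0)
    if (!is.null(sGenes) && !is.null(g2mGenes)) {
        cc <- scoreCellCycle(m, sGenes, g2mGenes, seed = seed)
        s <- cc$sScore
        g2m <- cc$g2mScore
        phase <- cc$phase
    }
    report <- methods::new("CycleReport", pcLoadingSums = sums,
                           threshold = threshold,
                           flaggedPCs = as.integer(flagged),
                           removedGenes = removed,
                           sScore = s, g2mScore = g2m, phase = phase)
    list(model = model, report = report)
}

#' Louvain clustering on the kNN graph of PC scores
#'
#' Builds the Euclidean k-nearest-neighbour graph on the first `nPCs` cell
#' scores and runs Louvain community detection at the given resolution.
#' Deterministic for a fixed seed; labels are contiguous integers from 0,
#' ordered by decreasing cluster size.
#'
#' @param pca a [PCAModel].
#' @param nPCs number of leading components to use.
#' @param k neighbours per cell (must be < number of cells).
#' @param resolution Louvain resolution.
#' @param seed integer seed.
#' @return named integer vector of cluster labels with a `"params"`
#'   attribute.
#' @export
clusterCells <- function(pca, nPCs = 15L, k = 20L, resolution = 1.0,
                         seed = 0L) {
    scores <- pcaScores(pca)
    if (k >= nrow(scores)) stop("k must be smaller than the number of cells")
    nPCs <- min(nPCs, ncol(scores))
    x <- scores[, seq_len(nPCs), drop = FALSE]
    g <- .knn_graph(x, k)
    set.seed(.check_seed(seed))
    comm <- igraph::cluster_louvain(g, resolution = resolution)
    labels <- .relabel_clusters(igraph::membership(comm))
    names(labels) <- rownames(scores)
    attr(labels, "params") <- list(nPCs = nPCs, k = k,
                                   resolution = resolution, seed = seed)
    labels
}

#' Two-dimensional embedding of cells for reporting
#'
#' A neighbourhood-preserving 2-D layout of the first `nPCs` scores (UMAP
#' via the uwot package when available; otherwise the variance-scaled first
#' two components). Deterministic for a fixed seed, and intended for
#' visual reporting only — no downstream computation depends on it.
#'
#' @inheritParams clusterCells
#' @return cells x 2 coordinate matrix.
#' @export
embedCells <- function(pca, nPCs = 15L, seed = 0L) {
    scores <- pcaScores(pca)
    if (nPCs > ncol(scores)) {
        warning("nPCs exceeds available components; clamping to ", ncol(scores))
        nPCs <- ncol(scores)
    }
    x <- scores[, seq_len(nPCs), drop = FALSE]
    if (requireNamespace("uwot", quietly = TRUE) && nrow(x) > 20) {
        set.seed(.check_seed(seed))
        emb <- uwot::umap(x, n_neighbors = min(15, nrow(x) - 1),
                          n_threads = 1, n_sgd_threads = 0)
    } else {
        emb <- x[, seq_len(min(2L, ncol(x))), drop = FALSE]
        if (ncol(emb) < 2) emb <- cbind(emb, 0)
        emb <- scale(emb)
    }
    dimnames(emb) <- list(rownames(scores), c("DIM1", "DIM2"))
    emb
}

#' Downsample oversized clusters to half
#'
#' Clusters with more than `cap` cells are sampled without replacement to
#' `ceiling(n / 2)`; smaller clusters are untouched.
#'
#' @param m `SingleCellExperiment`.
#' @param labels per-cell cluster labels aligned with `colnames(m)`.
#' @param cap size above which a cluster is halved.
#' @param seed integer seed.
#' @return the downsampled `SingleCellExperiment`.
#' @export
downsampleClusters <- function(m, labels, cap = 500L, seed = 0L) {
    stopifnot(length(labels) == ncol(m))
    set.seed(.check_seed(seed))
    keep <- unlist(lapply(split(seq_len(ncol(m)), labels), function(idx) {
        if (length(idx) > cap) sort(sample(idx, ceiling(length(idx) / 2))) else idx
    }), use.names = FALSE)
    m[, sort(keep)]
}
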