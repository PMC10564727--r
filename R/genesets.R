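#' Per-cell AUC gene-set enrichment score
#'
#' For each cell, genes are ranked by decreasing raw count (ties resolved
#' deterministically by the fixed gene order). With `T =
#' ceiling(topFraction * nGenes)`, the recovery curve counts the set
#' members among the top 1..T ranked genes; the score is the area under
#' that curve divided by its maximum possible area (all members at the top
#' of the ranking), giving a value in [0, 1].
#'
#' @param m `SingleCellExperiment` or genes x cells matrix of raw counts.
#' @param geneSet character vector of member symbols (or a named list of
#'   length 1).
#' @param setName name of the set (for reporting).
#' @param topFraction fraction of the ranking examined.
#' @return an [EnrichmentResult].
#' @export
aucellScore <- function(m, geneSet, setName = "geneset", topFraction = 0.05) {
    if (is.list(geneSet)) {
        if (length(geneSet) != 1) stop("supply a single gene set")
        setName <- names(geneSet)
        geneSet <- geneSet[[1]]
    }
    counts <- .as_dense(.counts(m))
    genes <- rownames(counts)
    members <- which(genes %in% geneSet)
    if (!length(members))
        stop("no member of gene set '", setName, "' is present in the matrix")
    nG <- nrow(counts)
    top <- ceiling(topFraction * nG)
    k <- length(members)
    max_auc <- sum(pmin(seq_len(top), k))
    is_member <- logical(nG)
    is_member[members] <- TRUE
    scores <- apply(counts, 2, function(x) {
        ord <- order(-x, seq_len(nG), method = "radix")
        curve <- cumsum(is_member[ord])[seq_len(top)]
        sum(curve) / max_auc
    })
    names(scores) <- colnames(counts)
    methods::new("EnrichmentResult", scores = scores, setName = setName,
                 geneSet = unique(geneSet), genesUsed = genes[members],
                 topFraction = topFraction)
}

#' Cluster-level summaries with dot-plot normalizations
#'
#' Summarizes per-cell values (a genes x cells matrix of expression, or a
#' single numeric vector such as enrichment scores) per cluster: the mean,
#' the percentage of cells with a non-zero value, the mean normalized to
#' the maximum over clusters within each dataset, and the mean normalized
#' to the maximum over all clusters per feature.
#'
#' @param values genes x cells matrix, or a per-cell numeric vector.
#' @param clusters per-cell cluster labels.
#' @param datasets per-cell dataset ids (a single dataset when `NULL`).
#' @return `data.frame` with columns `dataset`, `cluster`, `feature`,
#'   `mean`, `pctNonzero`, `normDataset`, `normFeature`.
#' @export
summarizeByCluster <- function(values, clusters, datasets = NULL) {
    if (is.null(dim(values))) {
        values <- matrix(values, nrow = 1,
                         dimnames = list("value", names(values)))
    }
    values <- .as_dense(values)
    n <- ncol(values)
    stopifnot(length(clusters) == n)
    if (is.null(datasets)) datasets <- rep("dataset1", n)
    if (is.factor(clusters) && !all(levels(clusters) %in% clusters))
        warning("empty clusters excluded from the summary")
    key <- paste(datasets, clusters, sep = "\r")
    ukey <- unique(key)
    res <- do.call(rbind, lapply(ukey, function(kk) {
        idx <- which(key == kk)
        parts <- strsplit(kk, "\r", fixed = TRUE)[[1]]
        data.frame(dataset = parts[1], cluster = parts[2],
                   feature = rownames(values),
                   mean = rowMeans(values[, idx, drop = FALSE]),
                   pctNonzero = rowMeans(values[, idx, drop = FALSE] != 0),
                   stringsAsFactors = FALSE, row.names = NULL)
    }))
    res$normDataset <- stats::ave(res$mean,
                                  paste(res$dataset, res$feature, sep = "\r"),
                                  FUN = function(x) x / max(max(x), 1e-300))
    res$normFeature <- stats::ave(res$mean, res$feature,
                                  FUN = function(x) x / max(max(x), 1e-300))
    res$normDataset[res$mean == 0] <- 0
    res$normFeature[res$mean == 0] <- 0
    res
}

#' Fraction of cells co-expressing a marker panel
#'
#' Fraction of cells with a non-zero raw count for at least `minGenes`
#' members of the panel.
#'
#' @param m `SingleCellExperiment` or genes x cells count matrix.
#' @param panel character vector of panel genes.
#' @param minGenes minimum number of expressed panel genes.
#' @return numeric(1) fraction in [0, 1].
#' @export
markerCoexpression <- function(m, panel, minGenes) {
    if (minGenes > length(panel))
        stop("minGenes exceeds the panel size")
    counts <- .counts(m)
    present <- intersect(panel, rownames(counts))
    n_expr <- if (length(present)) {
        Matrix::colSums(counts[present, , drop = FALSE] > 0)
    } else rep(0, ncol(counts))
    mean(n_expr >= minGenes)
}
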