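#' Rank integration features across datasets
#'
#' Genes are ranked primarily by the number of datasets in which they were
#' selected as highly variable (descending), with ties broken by the mean
#' within-dataset HVG rank (ascending) and then lexicographically. Only
#' genes present in every dataset qualify; the top `n` are returned.
#'
#' @param ms list of `SingleCellExperiment`s processed with
#'   [normalizeSelectHVG()] (each carries its HVG list in `metadata()`).
#' @param n number of features to return (all qualifying genes, with a
#'   warning, when fewer are available).
#' @return character vector of feature genes, best first.
#' @export
selectIntegrationFeatures <- function(ms, n = 3000L) {
    stopifnot(length(ms) >= 1)
    universe <- rownames(ms[[1]])
    for (m in ms[-1]) universe <- intersect(universe, rownames(m))
    hvg_lists <- lapply(ms, hvgGenes)
    if (any(vapply(hvg_lists, is.null, TRUE)))
        stop("every dataset needs an HVG list; run normalizeSelectHVG() first")
    n_sel <- vapply(universe, function(g) {
        sum(vapply(hvg_lists, function(h) g %in% h, TRUE))
    }, 0L)
    mean_rank <- vapply(universe, function(g) {
        r <- vapply(hvg_lists, function(h) match(g, h), 0L)
        r <- r[!is.na(r)]
        if (length(r)) mean(r) else Inf
    }, 0)
    qual <- universe[n_sel > 0]
    ord <- order(-n_sel[qual], mean_rank[qual], qual, method = "radix")
    ranked <- qual[ord]
    if (length(ranked) < n) {
        warning("only ", length(ranked), " qualifying features available")
        return(ranked)
    }
    ranked[seq_len(n)]
}

#' Integrate datasets by mutual-nearest-neighbour anchors
#'
#' A reference integration method behind a pluggable contract: features are
#' z-scaled per dataset, all cells are projected into a joint PCA, and
#' datasets are merged iteratively (largest first). At each merge, mutual
#' nearest neighbours between the merged set and the incoming dataset are
#' used as anchors; each incoming cell is corrected by the Gaussian-kernel
#' weighted mean of its anchors' displacement vectors.
#'
#' @param ms list of `SingleCellExperiment`s sharing the feature space,
#'   with `logcounts`.
#' @param features character vector of feature genes.
#' @param kAnchor neighbours per side for the mutual-NN anchor search.
#' @param nComponents joint PCA dimensionality.
#' @param seed integer seed.
#' @return list with `coords` (cells x components corrected coordinates),
#'   `dataset` (per-cell dataset id), `method` and `features`.
#' @export
mnnIntegrate <- function(ms, features, kAnchor = 20L, nComponents = 30L,
                         seed = 0L) {
    stopifnot(length(ms) >= 1)
    set.seed(.check_seed(seed))
    ids <- names(ms)
    if (is.null(ids)) ids <- paste0("dataset", seq_along(ms))
    scaled <- lapply(ms, function(m) {
        logc <- .logcounts(m)
        miss <- setdiff(features, rownames(logc))
        if (length(miss))
            stop("features missing from a dataset: ",
                 paste(head(miss, 5), collapse = ", "))
        .scale_genes(logc[features, , drop = FALSE])
    })
    joint <- do.call(cbind, scaled)                  # features x all cells
    dataset <- rep(ids, vapply(scaled, ncol, 0L))
    x <- t(joint)
    x <- sweep(x, 2, colMeans(x))                     # joint centring
    pca <- .exact_pca(x, min(nComponents, dim(x)))
    coords <- pca$scores
    rownames(coords) <- unlist(lapply(ms, colnames), use.names = FALSE)

    if (length(ms) == 1)
        return(list(coords = coords, dataset = dataset, method = "mnn",
                    features = features))

    sizes <- vapply(ms, ncol, 0L)
    order_ids <- ids[order(-sizes, ids)]
    merged_idx <- which(dataset == order_ids[1])
    for (id in order_ids[-1]) {
        inc_idx <- which(dataset == id)
        ref <- coords[merged_idx, , drop = FALSE]
        inc <- coords[inc_idx, , drop = FALSE]
        k <- min(kAnchor, nrow(ref) - 1, nrow(inc) - 1)
        d2 <- .pairwise_sqdist(inc, ref)
        nn_ir <- t(apply(d2, 1, function(r) order(r)[seq_len(k)]))
        nn_ri <- t(apply(d2, 2, function(r) order(r)[seq_len(k)]))
        mut <- matrix(FALSE, nrow(ref), nrow(inc))
        mut[cbind(rep(seq_len(nrow(ref)), each = k), as.vector(t(nn_ri)))] <- TRUE
        inc_i <- rep(seq_len(nrow(inc)), each = k)
        ref_j <- as.vector(t(nn_ir))
        keep_pair <- mut[cbind(ref_j, inc_i)]
        pairs <- cbind(inc_i[keep_pair], ref_j[keep_pair])
        if (nrow(pairs) == 0) {
            warning("no mutual-nearest-neighbour anchors between '", id,
                    "' and the merged set; appending uncorrected")
        } else {
            disp <- ref[pairs[, 2], , drop = FALSE] -
                inc[pairs[, 1], , drop = FALSE]
            anchor_pos <- inc[pairs[, 1], , drop = FALSE]
            dca <- .pairwise_sqdist(inc, anchor_pos)
            sigma2 <- stats::median(apply(dca, 1, min))
            if (!is.finite(sigma2) || sigma2 <= 0) sigma2 <- 1
            w <- exp(-dca / (2 * sigma2))
            w <- w / pmax(rowSums(w), 1e-12)
            coords[inc_idx, ] <- inc + w %*% disp
        }
        merged_idx <- c(merged_idx, inc_idx)
    }
    list(coords = coords, dataset = dataset, method = "mnn",
         features = features)
}

#' Confusion matrix between reference and atlas cluster labels
#'
#' Counts of cells per (reference cluster, atlas cluster) pair; the
#' normalized matrix divides each atlas cluster's column by its maximum
#' count, so every nonempty column has maximum 1.
#'
#' @param referenceLabels named vector of per-cell reference labels.
#' @param atlasLabels named vector of per-cell atlas labels (same cells).
#' @return list with `counts` and `normalized` matrices
#'   (reference x atlas).
#' @export
integrationAccuracy <- function(referenceLabels, atlasLabels) {
    cells <- intersect(names(referenceLabels), names(atlasLabels))
    if (!length(cells))
        stop("reference and atlas labels share no cells")
    counts <- table(reference = referenceLabels[cells],
                    atlas = atlasLabels[cells])
    counts <- unclass(counts)
    cmax <- apply(counts, 2, max)
    normalized <- sweep(counts, 2, pmax(cmax, 1), "/")
    list(counts = counts, normalized = normalized)
}

#' Per-cluster composition fractions
#'
#' Fraction of each cluster's cells contributed by each dataset or species;
#' fractions per cluster sum to 1.
#'
#' @param labels per-cell cluster labels.
#' @param ids per-cell dataset or species ids (aligned).
#' @return matrix clusters x ids of fractions.
#' @export
clusterComposition <- function(labels, ids) {
    stopifnot(length(labels) == length(ids))
    tab <- unclass(table(cluster = labels, id = ids))
    sweep(tab, 1, pmax(rowSums(tab), 1), "/")
}

#' @rdname clusterComposition
#' @param composition output of `clusterComposition()`.
#' @param cluster cluster to query.
#' @param group character vector of ids to sum over.
#' @return numeric(1) grouped fraction.
#' @export
compositionFraction <- function(composition, cluster, group) {
    row <- composition[as.character(cluster), , drop = TRUE]
    sum(row[intersect(group, names(row))])
}
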