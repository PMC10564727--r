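#' Build the feature matrix for cluster-similarity scoring
#'
#' Three feature inputs are supported, mirroring common practice for
#' neighbour-voting replicability analysis:
#' \describe{
#'   \item{`binned_variance`}{genes in the top variance quartile within each
#'     of 10 mean-expression bins in every dataset (the variable-gene rule
#'     of MetaNeighbor); the quartile size is `ceiling(bin size / 4)`.}
#'   \item{`hvg_top_n`}{the top `n` genes of the integration-feature
#'     ranking ([selectIntegrationFeatures()]).}
#'   \item{`pc_top_n`}{the first `n` joint principal-component scores.}
#' }
#'
#' @param ms list of `SingleCellExperiment`s with `logcounts` (and HVG
#'   metadata for `hvg_top_n`).
#' @param mode one of `"binned_variance"`, `"hvg_top_n"`, `"pc_top_n"`.
#' @param n feature count for the `hvg_top_n` / `pc_top_n` modes.
#' @param nBins mean-expression bins for `binned_variance`.
#' @param seed seed for the joint PCA mode.
#' @return features x cells matrix with attributes `datasets` (per-cell
#'   dataset id) and `mode`.
#' @export
selectSimilarityFeatures <- function(ms, mode = c("binned_variance",
                                                  "hvg_top_n", "pc_top_n"),
                                     n = 3000L, nBins = 10L, seed = 0L) {
    mode <- match.arg(mode)
    ids <- names(ms)
    if (is.null(ids)) ids <- paste0("dataset", seq_along(ms))
    datasets <- rep(ids, vapply(ms, ncol, 0L))
    common <- rownames(ms[[1]])
    for (m in ms[-1]) common <- intersect(common, rownames(m))

    if (mode == "binned_variance") {
        selected <- lapply(ms, function(m) {
            logc <- .logcounts(m)[common, , drop = FALSE]
            mu <- rowMeans(logc)
            v <- apply(logc, 1, var)
            bins <- if (nBins >= 2) {
                cut(rank(mu, ties.method = "first"), breaks = nBins,
                    labels = FALSE)
            } else rep(1L, length(mu))
            unlist(lapply(split(seq_along(mu), bins), function(idx) {
                q <- ceiling(length(idx) / 4)
                ord <- idx[order(-v[idx], common[idx], method = "radix")]
                sel <- ord[seq_len(q)]
                common[sel[v[sel] > 0]]
            }), use.names = FALSE)
        })
        genes <- Reduce(intersect, selected)
        if (!length(genes)) stop("no gene passes the binned-variance rule in every dataset")
        feat <- do.call(cbind, lapply(ms, function(m)
            .as_dense(.logcounts(m)[genes, , drop = FALSE])))
    } else if (mode == "hvg_top_n") {
        genes <- selectIntegrationFeatures(ms, n = n)
        feat <- do.call(cbind, lapply(ms, function(m)
            .as_dense(.logcounts(m)[genes, , drop = FALSE])))
    } else {
        hvgs <- unique(unlist(lapply(ms, hvgGenes)))
        feats <- if (length(hvgs)) intersect(common, hvgs) else common
        scaled <- do.call(cbind, lapply(ms, function(m)
            .scale_genes(.logcounts(m)[feats, , drop = FALSE])))
        x <- t(scaled)
        x <- sweep(x, 2, colMeans(x))
        pca <- .exact_pca(x, min(n, dim(x)))
        feat <- t(pca$scores)
        rownames(feat) <- paste0("PC", seq_len(nrow(feat)))
    }
    colnames(feat) <- unlist(lapply(ms, colnames), use.names = FALSE)
    attr(feat, "datasets") <- datasets
    attr(feat, "mode") <- mode
    feat
}

#' Neighbour-voting AUROC between cluster pairs across datasets
#'
#' MetaNeighbor-style unsupervised replicability: a cell-cell Spearman
#' correlation network is built across the features, each cell's
#' correlation vector is rank-standardized to (0, 1] (self excluded), and
#' for an ordered cluster pair (A in dataset 1, B in dataset 2) the cells
#' of dataset 2 are voted for by their mean rank-standardized connectivity
#' to the cells of A. The AUROC is the mid-rank Mann-Whitney probability
#' that B cells outrank the other cells of dataset 2; the reported score is
#' the mean of the two directions. Pairs within a dataset are `NA`, as are
#' pairs involving a dataset with a single cluster (no negatives).
#'
#' @param features features x cells matrix (see
#'   [selectSimilarityFeatures()]).
#' @param datasets per-cell dataset ids (defaults to the matrix attribute).
#' @param clusters per-cell cluster labels.
#' @return a [ClusterSimilarity].
#' @export
neighborVotingAUROC <- function(features, datasets = attr(features, "datasets"),
                                clusters) {
    stopifnot(ncol(features) == length(datasets),
              ncol(features) == length(clusters))
    ds <- as.character(datasets)
    cl <- as.character(clusters)
    uds <- unique(ds)
    if (length(uds) < 2) stop("at least two datasets are required")

    rk <- apply(features, 2, rank, ties.method = "average")
    cors <- stats::cor(rk)                        # Spearman via ranked columns
    diag(cors) <- NA
    conn <- t(apply(cors, 1, function(v) {
        r <- rank(v, ties.method = "average", na.last = "keep")
        r / max(r, na.rm = TRUE)
    }))

    pairs <- unique(data.frame(ds = ds, cl = cl, stringsAsFactors = FALSE))
    pairs <- pairs[order(pairs$ds, pairs$cl), ]
    labs <- paste(pairs$ds, pairs$cl, sep = "|")
    nP <- nrow(pairs)
    auroc <- matrix(NA_real_, nP, nP, dimnames = list(labs, labs))
    diag(auroc) <- 1

    one_direction <- function(train_cells, test_ds, pos_cl) {
        test_cells <- which(ds == test_ds)
        votes <- rowMeans(conn[test_cells, train_cells, drop = FALSE],
                          na.rm = TRUE)
        pos <- cl[test_cells] == pos_cl
        n1 <- sum(pos)
        n0 <- sum(!pos)
        if (n1 == 0 || n0 == 0) return(NA_real_)
        r <- rank(votes, ties.method = "average")
        (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    }

    for (i in seq_len(nP - 1)) {
        for (j in seq(i + 1, nP)) {
            if (pairs$ds[i] == pairs$ds[j]) next
            a <- one_direction(which(ds == pairs$ds[i] & cl == pairs$cl[i]),
                               pairs$ds[j], pairs$cl[j])
            b <- one_direction(which(ds == pairs$ds[j] & cl == pairs$cl[j]),
                               pairs$ds[i], pairs$cl[i])
            val <- mean(c(a, b))   # missing if either direction lacks negatives
            auroc[i, j] <- auroc[j, i] <- val
        }
    }
    methods::new("ClusterSimilarity", auroc = auroc,
                 datasets = pairs$ds, clusters = pairs$cl,
                 mode = if (is.null(attr(features, "mode"))) "custom"
                        else attr(features, "mode"))
}
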