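# Internal numeric helpers shared across modules.

#' @importFrom SummarizedExperiment assay assays assay<- colData rowData
#' @importFrom SingleCellExperiment SingleCellExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

# counts accessor tolerant of plain matrices
.counts <- function(m) {
    if (methods::is(m, "SummarizedExperiment")) assay(m, "counts") else m
}

.logcounts <- function(m) {
    if (methods::is(m, "SummarizedExperiment")) {
        if (!"logcounts" %in% names(assays(m)))
            stop("no 'logcounts' assay; run normalizeSelectHVG() first")
        assay(m, "logcounts")
    } else m
}

.as_dense <- function(x) as.matrix(x)

# per-gene z-score of a genes x cells matrix, clipped; zero-variance genes -> 0
.scale_genes <- function(x, clip = 10) {
    x <- .as_dense(x)
    mu <- rowMeans(x)
    sdv <- sqrt(rowSums((x - mu)^2) / max(1L, ncol(x) - 1L))
    sdv[sdv == 0] <- Inf
    z <- (x - mu) / sdv
    z[z > clip] <- clip
    z[z < -clip] <- -clip
    z
}

# exact PCA of a cells x genes matrix (already centred/scaled per gene).
# Uses the eigendecomposition of the smaller Gram matrix; deterministic.
# Sign convention: largest-|.| entry of each loading column is positive.
.exact_pca <- function(x, n_components) {
    n <- nrow(x)
    p <- ncol(x)
    k <- min(n_components, n, p)
    if (p <= n) {
        cv <- crossprod(x)                     # p x p
        eig <- eigen(cv, symmetric = TRUE)
        ev <- pmax(eig$values, 0)
        loadings <- eig$vectors[, seq_len(k), drop = FALSE]
        scores <- x %*% loadings
    } else {
        gm <- tcrossprod(x)                    # n x n
        eig <- eigen(gm, symmetric = TRUE)
        ev <- pmax(eig$values, 0)
        u <- eig$vectors[, seq_len(k), drop = FALSE]
        d <- sqrt(ev[seq_len(k)])
        d[d < 1e-12] <- 1e-12
        loadings <- crossprod(x, u) / rep(d, each = p)
        # re-normalize for numerical safety
        loadings <- sweep(loadings, 2, sqrt(colSums(loadings^2)), "/")
        scores <- x %*% loadings
    }
    flip <- apply(loadings, 2, function(v) sign(v[which.max(abs(v))]))
    flip[flip == 0] <- 1
    loadings <- sweep(loadings, 2, flip, "*")
    scores <- sweep(scores, 2, flip, "*")
    var_exp <- ev[seq_len(k)] / max(1L, n - 1L)
    list(loadings = loadings, scores = scores, varExplained = var_exp)
}

# k nearest neighbours by Euclidean distance (self excluded).
# Returns an n x k matrix of indices. Ties broken by lowest index.
.knn_indices <- function(x, k) {
    n <- nrow(x)
    if (k >= n) stop("k must be smaller than the number of points")
    d2 <- .pairwise_sqdist(x, x)
    diag(d2) <- Inf
    t(apply(d2, 1, function(row) order(row)[seq_len(k)]))
}

.pairwise_sqdist <- function(a, b) {
    an <- rowSums(a^2)
    bn <- rowSums(b^2)
    d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
    d2[d2 < 0] <- 0
    d2
}

# undirected unweighted kNN graph
.knn_graph <- function(x, k) {
    nn <- .knn_indices(x, k)
    n <- nrow(x)
    edges <- cbind(rep(seq_len(n), each = k), as.vector(t(nn)))
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    igraph::simplify(g)
}

# mid-rank ranks of x (average ties), NA kept as NA
.midranks <- function(x) rank(x, ties.method = "average", na.last = "keep")

# relabel cluster memberships as contiguous 0-based integers by decreasing size
.relabel_clusters <- function(member) {
    tab <- sort(table(member), decreasing = TRUE)
    map <- stats::setNames(seq_along(tab) - 1L, names(tab))
    unname(map[as.character(member)])
}

.check_seed <- function(seed) {
    if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
        stop("'seed' must be a single number")
    as.integer(seed %% .Machine$integer.max)
}
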