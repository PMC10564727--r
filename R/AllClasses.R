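#' @import methods
#' @importFrom stats var sd cor dist prcomp quantile median rnbinom rlnorm
#'   runif rnorm pnorm phyper p.adjust setNames kmeans aggregate
#' @importFrom utils head read.delim write.table
NULL

#' Principal component model of a scaled expression matrix
#'
#' Holds the exact truncated singular value decomposition of a per-gene
#' z-scored expression matrix: gene loadings (unit-norm columns), per-cell
#' scores, and the variance explained by each component, together with the
#' genes the model was fitted on.
#'
#' @slot loadings genes x components matrix; columns have unit L2 norm.
#' @slot scores cells x components matrix of cell coordinates.
#' @slot varExplained numeric vector, variance explained per component,
#'   non-increasing.
#' @slot genes character vector of gene identifiers used for the fit.
#'
#' @seealso [fitPCA()], [correctCyclePCs()]
#' @export
setClass("PCAModel",
    representation(
        loadings = "matrix",
        scores = "matrix",
        varExplained = "numeric",
        genes = "character"
    )
)

setValidity("PCAModel", function(object) {
    msg <- NULL
    if (ncol(object@loadings) != ncol(object@scores))
        msg <- c(msg, "loadings and scores must have the same number of components")
    if (nrow(object@loadings) != length(object@genes))
        msg <- c(msg, "loadings rows must match genes")
    if (length(object@varExplained) != ncol(object@loadings))
        msg <- c(msg, "varExplained length must match component count")
    if (ncol(object@loadings) > 0) {
        norms <- sqrt(colSums(object@loadings^2))
        if (any(abs(norms - 1) > 1e-6))
            msg <- c(msg, "loading columns must be unit-norm (tolerance 1e-6)")
        if (is.unsorted(-object@varExplained))
            msg <- c(msg, "components must be ordered by decreasing explained variance")
    }
    if (is.null(msg)) TRUE else msg
})

#' @describeIn PCAModel compact display
#' @param object a `PCAModel`
#' @export
setMethod("show", "PCAModel", function(object) {
    cat("PCAModel:", nrow(object@scores), "cells x", ncol(object@scores),
        "components over", length(object@genes), "genes\n")
    k <- min(5L, length(object@varExplained))
    if (k > 0) {
        tot <- sum(object@varExplained)
        cat("  var explained (first", k, "): ",
            paste(sprintf("%.1f%%", 100 * object@varExplained[seq_len(k)] / tot),
                  collapse = " "), "\n")
    }
})

#' @rdname PCAModel
#' @param x a `PCAModel`
#' @export
pcaLoadings <- function(x) x@loadings

#' @rdname PCAModel
#' @export
pcaScores <- function(x) x@scores

#' @rdname PCAModel
#' @export
pcaVariance <- function(x) x@varExplained

#' @rdname PCAModel
#' @export
pcaGenes <- function(x) x@genes

#' Report of the cell-cycle-correlated PC correction
#'
#' Records, for a fitted [PCAModel], the summed absolute cycle-gene loading
#' per principal component, the threshold used to flag cycle-correlated PCs,
#' the flagged components, and the genes (top 10 percent by absolute loading of
#' each flagged PC) removed before the model was refitted, together with the
#' per-cell S and G2M scores used for diagnosis.
#'
#' @slot pcLoadingSums numeric, per-PC sum of absolute cycle-gene loadings.
#' @slot threshold numeric(1) flagging threshold.
#' @slot flaggedPCs integer indices of cycle-correlated PCs.
#' @slot removedGenes character, union of per-PC top-10-percent loading genes.
#' @slot sScore,g2mScore numeric per-cell phase scores.
#' @slot phase character per-cell phase call ("G1", "S", "G2M").
#' @export
setClass("CycleReport",
    representation(
        pcLoadingSums = "numeric",
        threshold = "numeric",
        flaggedPCs = "integer",
        removedGenes = "character",
        sScore = "numeric",
        g2mScore = "numeric",
        phase = "character"
    )
)

setValidity("CycleReport", function(object) {
    msg <- NULL
    expect <- which(object@pcLoadingSums > object@threshold)
    if (!identical(as.integer(expect), sort(object@flaggedPCs)))
        msg <- c(msg, "flaggedPCs must be exactly the PCs whose loading sum exceeds the threshold")
    if (length(object@sScore) != length(object@g2mScore) ||
        (length(object@phase) && length(object@phase) != length(object@sScore)))
        msg <- c(msg, "per-cell score/phase lengths disagree")
    if (is.null(msg)) TRUE else msg
})

#' @describeIn CycleReport compact display
#' @param object a `CycleReport`
#' @export
setMethod("show", "CycleReport", function(object) {
    cat("CycleReport: threshold", object@threshold, "-",
        length(object@flaggedPCs), "PC(s) flagged,",
        length(object@removedGenes), "gene(s) removed\n")
})

#' @rdname CycleReport
#' @param x a `CycleReport`
#' @export
flaggedPCs <- function(x) x@flaggedPCs

#' @rdname CycleReport
#' @export
removedGenes <- function(x) x@removedGenes

#' Pairwise cluster replicability scores
#'
#' Symmetric matrix of neighbour-voting AUROC scores between (dataset,
#' cluster) pairs. Scores lie in [0, 1]; the diagonal is 1 by convention;
#' pairs that cannot be scored (same dataset, or a dataset with a single
#' cluster, which yields no negatives) are `NA`.
#'
#' @slot auroc symmetric numeric matrix with "dataset|cluster" dimnames.
#' @slot datasets character, dataset of each row.
#' @slot clusters character, cluster of each row.
#' @slot mode feature mode used ("binned_variance", "hvg_top_n", "pc_top_n").
#' @export
setClass("ClusterSimilarity",
    representation(
        auroc = "matrix",
        datasets = "character",
        clusters = "character",
        mode = "character"
    )
)

setValidity("ClusterSimilarity", function(object) {
    msg <- NULL
    a <- object@auroc
    if (nrow(a) != ncol(a)) msg <- c(msg, "auroc matrix must be square")
    if (nrow(a) != length(object@datasets) || nrow(a) != length(object@clusters))
        msg <- c(msg, "datasets/clusters must label every row")
    vals <- a[!is.na(a)]
    if (length(vals) && (min(vals) < -1e-12 || max(vals) > 1 + 1e-12))
        msg <- c(msg, "AUROC entries must lie in [0, 1]")
    if (nrow(a) && any(abs(diag(a) - 1) > 1e-12))
        msg <- c(msg, "diagonal must be 1")
    off <- a[upper.tri(a)] - t(a)[upper.tri(a)]
    if (length(off) && any(abs(off[!is.na(off)]) > 1e-12))
        msg <- c(msg, "auroc matrix must be symmetric")
    if (is.null(msg)) TRUE else msg
})

#' @describeIn ClusterSimilarity compact display
#' @param object a `ClusterSimilarity`
#' @export
setMethod("show", "ClusterSimilarity", function(object) {
    cat("ClusterSimilarity (", object@mode, "): ",
        nrow(object@auroc), " (dataset, cluster) pairs\n", sep = "")
    v <- object@auroc[upper.tri(object@auroc)]
    v <- v[!is.na(v)]
    if (length(v))
        cat("  cross-dataset AUROC: median", sprintf("%.3f", median(v)),
            "max", sprintf("%.3f", max(v)), "\n")
})

#' @rdname ClusterSimilarity
#' @param x a `ClusterSimilarity`
#' @export
aurocMatrix <- function(x) x@auroc

#' Consensus NMF decomposition at a fixed number of modules
#'
#' One consensus non-negative matrix factorization: repeated seeded NMF
#' restarts are pooled, outlier spectra dropped, the remainder clustered,
#' and per-cluster median spectra (unit L2 rows) kept as consensus modules.
#' Cell usages are refitted by non-negative least squares against the
#' consensus spectra.
#'
#' @slot k integer, number of modules.
#' @slot spectra k x genes nonnegative matrix, rows unit L2-norm.
#' @slot usages cells x k nonnegative matrix.
#' @slot error numeric(1), Frobenius reconstruction error.
#' @slot stability numeric(1), mean silhouette width of the pooled spectra.
#' @slot nRestarts integer, restarts pooled.
#' @slot seed integer seed used.
#' @export
setClass("ConsensusModules",
    representation(
        k = "integer",
        spectra = "matrix",
        usages = "matrix",
        error = "numeric",
        stability = "numeric",
        nRestarts = "integer",
        seed = "integer"
    )
)

setValidity("ConsensusModules", function(object) {
    msg <- NULL
    if (nrow(object@spectra) != object@k || ncol(object@usages) != object@k)
        msg <- c(msg, "spectra rows and usage columns must equal k")
    if (any(object@spectra < -1e-12) || any(object@usages < -1e-12))
        msg <- c(msg, "spectra and usages must be nonnegative")
    norms <- sqrt(rowSums(object@spectra^2))
    if (any(abs(norms - 1) > 1e-6))
        msg <- c(msg, "spectra rows must have unit L2 norm")
    if (is.null(msg)) TRUE else msg
})

#' @describeIn ConsensusModules compact display
#' @param object a `ConsensusModules`
#' @export
setMethod("show", "ConsensusModules", function(object) {
    cat("ConsensusModules: k =", object@k, "over", ncol(object@spectra),
        "genes;", nrow(object@usages), "cells\n")
    cat(sprintf("  error %.4g, stability %.3f (%d restarts)\n",
                object@error, object@stability, object@nRestarts))
})

#' @rdname ConsensusModules
#' @param x a `ConsensusModules`
#' @export
moduleSpectra <- function(x) x@spectra

#' @rdname ConsensusModules
#' @export
moduleUsages <- function(x) x@usages

#' Per-cell gene-set enrichment scores
#'
#' AUC-based recovery-curve scores in [0, 1], one per cell, for a single
#' gene set, as produced by [aucellScore()].
#'
#' @slot scores named numeric vector, one score in [0, 1] per cell.
#' @slot setName gene set name.
#' @slot geneSet member symbols as supplied.
#' @slot genesUsed members present in the scored matrix.
#' @slot topFraction fraction of the ranking used for the recovery curve.
#' @export
setClass("EnrichmentResult",
    representation(
        scores = "numeric",
        setName = "character",
        geneSet = "character",
        genesUsed = "character",
        topFraction = "numeric"
    )
)

setValidity("EnrichmentResult", function(object) {
    msg <- NULL
    if (length(object@scores) &&
        (min(object@scores) < -1e-12 || max(object@scores) > 1 + 1e-12))
        msg <- c(msg, "scores must lie in [0, 1]")
    if (!all(object@genesUsed %in% object@geneSet))
        msg <- c(msg, "genesUsed must be a subset of the gene set")
    if (is.null(msg)) TRUE else msg
})

#' @describeIn EnrichmentResult compact display
#' @param object an `EnrichmentResult`
#' @export
setMethod("show", "EnrichmentResult", function(object) {
    cat("EnrichmentResult '", object@setName, "': ", length(object@scores),
        " cells, ", length(object@genesUsed), "/", length(object@geneSet),
        " set genes used, top fraction ", object@topFraction, "\n", sep = "")
})

#' @rdname EnrichmentResult
#' @param x an `EnrichmentResult`
#' @export
enrichmentScores <- function(x) x@scores
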