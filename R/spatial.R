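#' Read a Visium-style spot matrix and positions table
#'
#' Reads an MTX bundle of spot counts and a `tissue_positions.csv`
#' (barcode, in_tissue, array_row, array_col, pixel row, pixel col; header
#' optional) and retains the spots flagged as in-tissue.
#'
#' @param matrixDir directory with `matrix.mtx`, `features.tsv`,
#'   `barcodes.tsv`.
#' @param positionsPath path to `tissue_positions.csv`.
#' @return list with `spots` (a `SingleCellExperiment`) and `positions`
#'   (a `data.frame` aligned with the retained spots).
#' @export
readSpots <- function(matrixDir, positionsPath) {
    sce <- readCountsMTX(matrixDir, dataset = "visium")
    first <- readLines(positionsPath, n = 1)
    has_header <- grepl("barcode", first, fixed = TRUE)
    pos <- utils::read.csv(positionsPath, header = has_header,
                           stringsAsFactors = FALSE)
    names(pos) <- c("barcode", "in_tissue", "array_row", "array_col",
                    "pxl_row_in_fullres", "pxl_col_in_fullres")
    if (anyDuplicated(pos$barcode)) stop("duplicated spot barcodes")
    missing <- setdiff(colnames(sce), pos$barcode)
    if (length(missing))
        stop("barcodes absent from the positions table, e.g.: ",
             paste(head(missing, 5), collapse = ", "))
    pos <- pos[match(colnames(sce), pos$barcode), ]
    keep <- pos$in_tissue == 1
    if (!any(keep)) stop("no spot is flagged as in-tissue")
    list(spots = sce[, keep], positions = pos[keep, ])
}

#' Write a synthetic spatial section in Visium-style text formats
#'
#' @param section output of [generateSpatialSection()].
#' @param dir output directory.
#' @export
writeSpatialSection <- function(section, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeCountsMTX(section$spots, dir)
    write.table(section$positions, file.path(dir, "tissue_positions.csv"),
                sep = ",", quote = FALSE, row.names = FALSE)
    writeTruthTable(as.data.frame(colData(section$spots)),
                    file.path(dir, "spot_truth.tsv"))
    invisible(dir)
}

#' Cluster spatial spots with the standard expression pipeline
#'
#' Log-normalization, HVG selection, PCA on the top `nPCs` components and
#' Louvain clustering of the spot kNN graph — the same stack used for
#' single cells, applied to spots.
#'
#' @param spots `SingleCellExperiment` over spots.
#' @param nHVG highly variable genes to use.
#' @param nPCs leading components for the graph.
#' @param k neighbours per spot.
#' @param resolution Louvain resolution (coarse by default: a section
#'   carries few tissue domains).
#' @param seed integer seed.
#' @return named integer cluster labels (see [clusterCells()]).
#' @export
clusterSpots <- function(spots, nHVG = 2000L, nPCs = 30L, k = 20L,
                         resolution = 0.3, seed = 0L) {
    if (ncol(spots) < 2) stop("at least two spots are required")
    spots <- suppressWarnings(normalizeSelectHVG(spots, nHVG = nHVG))
    pca <- suppressWarnings(fitPCA(spots, nComponents = nPCs))
    clusterCells(pca, nPCs = min(nPCs, ncol(pcaScores(pca))),
                 k = min(k, ncol(spots) - 1),
                 resolution = resolution, seed = seed)
}

#' Gene/score overlay table for spatial visualization
#'
#' One row per retained spot per requested gene (or per supplied score
#' vector), with grid coordinates and the value normalized to [0, 1] over
#' spots.
#'
#' @param spots `SingleCellExperiment` over spots with `logcounts` (raw
#'   counts are normalized on the fly if needed).
#' @param positions positions `data.frame` aligned with the spots.
#' @param genes genes to overlay (absent genes are skipped with a warning).
#' @param scores optional named list of per-spot numeric vectors to overlay
#'   instead of (or in addition to) genes.
#' @return `data.frame` with `spot`, `x`, `y`, `feature`, `value`,
#'   `normValue`.
#' @export
overlayTable <- function(spots, positions, genes = character(),
                         scores = NULL) {
    stopifnot(nrow(positions) == ncol(spots))
    logc <- if (methods::is(spots, "SummarizedExperiment") &&
                "logcounts" %in% names(assays(spots))) {
        assay(spots, "logcounts")
    } else {
        counts <- .as_dense(.counts(spots))
        tot <- pmax(colSums(counts), 1)
        log1p(sweep(counts, 2, tot, "/") * 1e4)
    }
    vals <- list()
    for (g in genes) {
        if (!g %in% rownames(logc)) {
            warning("gene '", g, "' absent; skipped")
            next
        }
        vals[[g]] <- as.numeric(logc[g, ])
    }
    for (nm in names(scores)) vals[[nm]] <- as.numeric(scores[[nm]])
    if (!length(vals)) stop("nothing to overlay")
    do.call(rbind, lapply(names(vals), function(nm) {
        v <- vals[[nm]]
        data.frame(spot = colnames(spots),
                   x = positions$pxl_col_in_fullres,
                   y = positions$pxl_row_in_fullres,
                   feature = nm, value = v,
                   normValue = if (max(v) > 0) v / max(v) else v,
                   stringsAsFactors = FALSE, row.names = NULL)
    }))
}
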