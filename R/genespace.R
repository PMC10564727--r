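#' Collapse homeologs and duplicate transcripts onto shared symbols
#'
#' For every shared symbol mapped by two or more source genes of the
#' dataset's species, keeps only the source row with the greatest total raw
#' count across all cells ("higher expression" read at gene level: a
#' per-cell maximum would create chimeric rows), and relabels kept rows by
#' their shared symbol. Ties in total count are broken toward the
#' lexicographically smaller source gene id, for determinism.
#'
#' @param m `SingleCellExperiment` with a `counts` assay; rownames are
#'   source gene ids; `metadata(m)$species` identifies the species.
#' @param orth orthology `data.frame` as from [readOrthology()].
#' @return the collapsed `SingleCellExperiment` with unique shared-symbol
#'   rownames; `metadata()$collapsed_from` records the kept source id per
#'   symbol.
#' @export
collapseDuplicates <- function(m, orth) {
    species <- metadata(m)$species
    sub <- orth[orth$species %in% species, , drop = FALSE]
    map <- stats::setNames(sub$shared_symbol, sub$source_gene_id)
    missing <- setdiff(rownames(m), names(map))
    if (length(missing))
        stop("gene ids absent from the orthology table for species '", species,
             "': ", paste(head(missing, 5), collapse = ", "),
             if (length(missing) > 5) sprintf(" (and %d more)", length(missing) - 5))
    counts <- .counts(m)
    symbols <- unname(map[rownames(m)])
    totals <- Matrix::rowSums(counts)
    ord <- order(symbols, -totals, rownames(m), method = "radix")
    keep <- ord[!duplicated(symbols[ord])]
    keep <- sort(keep)   # preserve original row order
    out <- m[keep, ]
    kept_src <- rownames(out)
    rownames(out) <- symbols[keep]
    metadata(out)$collapsed_from <- stats::setNames(kept_src, symbols[keep])
    out
}

#' Restrict datasets to the shared one-to-one gene space
#'
#' Intersects the (already collapsed) shared symbols present in every
#' dataset and returns each matrix restricted to that intersection, in an
#' identical gene order (the order of the first dataset). The retained gene
#' count is recorded in each output's `metadata()$retained_genes`.
#'
#' @param ms list of collapsed `SingleCellExperiment`s.
#' @return list of `SingleCellExperiment`s over the common gene space.
#' @export
buildSharedSpace <- function(ms) {
    stopifnot(length(ms) >= 1)
    common <- rownames(ms[[1]])
    for (m in ms[-1]) common <- intersect(common, rownames(m))
    if (!length(common))
        stop("the shared gene space is empty")
    lapply(ms, function(m) {
        out <- m[common, ]
        metadata(out)$retained_genes <- length(common)
        out
    })
}
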