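#' Read a 10x-style MTX bundle into a SingleCellExperiment
#'
#' Reads `matrix.mtx` (genes x cells, MatrixMarket triplet), `features.tsv`
#' (gene id, optionally name and type) and `barcodes.tsv` from a directory
#' and returns a [SingleCellExperiment::SingleCellExperiment] with a sparse
#' `counts` assay, genes as rows and cells as columns.
#'
#' @param dir directory containing `matrix.mtx`, `features.tsv`,
#'   `barcodes.tsv` (uncompressed).
#' @param dataset optional dataset identifier stored in `metadata()`.
#' @param species optional species identifier stored in `metadata()`.
#' @return a `SingleCellExperiment`.
#' @export
readCountsMTX <- function(dir, dataset = basename(dir), species = NA_character_) {
    mtx <- file.path(dir, "matrix.mtx")
    feats <- file.path(dir, "features.tsv")
    bcs <- file.path(dir, "barcodes.tsv")
    for (f in c(mtx, feats, bcs))
        if (!file.exists(f)) stop("missing file: ", f)
    m <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
    ft <- read.delim(feats, header = FALSE, stringsAsFactors = FALSE)
    bc <- read.delim(bcs, header = FALSE, stringsAsFactors = FALSE)[[1]]
    if (nrow(ft) != nrow(m) || length(bc) != ncol(m))
        stop("feature/barcode dimensions do not match the matrix")
    rownames(m) <- ft[[1]]
    colnames(m) <- bc
    sce <- SingleCellExperiment(assays = list(counts = m))
    if (ncol(ft) > 1) rowData(sce)$name <- ft[[2]]
    metadata(sce)$dataset <- dataset
    metadata(sce)$species <- species
    sce
}

#' Write a SingleCellExperiment's counts as a 10x-style MTX bundle
#'
#' @param sce a `SingleCellExperiment` (or genes x cells matrix) with counts.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
writeCountsMTX <- function(sce, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    m <- .counts(sce)
    Matrix::writeMM(methods::as(Matrix::Matrix(m, sparse = TRUE), "generalMatrix"),
                    file.path(dir, "matrix.mtx"))
    write.table(data.frame(id = rownames(m), name = rownames(m)),
                file.path(dir, "features.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    write.table(data.frame(bc = colnames(m)), file.path(dir, "barcodes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    invisible(dir)
}

#' Read an orthology table
#'
#' Expects a TSV with columns `source_gene_id`, `species`, `shared_symbol`,
#' `group_tag` (homeolog subgenome such as "L"/"S", or a transcript index).
#'
#' @param path TSV file path.
#' @return a `data.frame` with the four columns above.
#' @export
readOrthology <- function(path) {
    tab <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("source_gene_id", "species", "shared_symbol", "group_tag")
    if (!all(need %in% names(tab)))
        stop("orthology table must have columns: ", paste(need, collapse = ", "))
    if (anyDuplicated(tab[, c("species", "source_gene_id")]))
        stop("(species, source_gene_id) pairs must be unique")
    if (any(!nzchar(tab$shared_symbol)))
        stop("shared_symbol entries must be non-empty")
    tab[need]
}

#' @rdname readOrthology
#' @param orth orthology `data.frame`.
#' @export
writeOrthology <- function(orth, path) {
    write.table(orth, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file: one set per line, tab-separated
#'   (name, description, members...).
#' @return named list of character vectors.
#' @export
readGMT <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    sets <- lapply(strsplit(lines, "\t"), function(x) unique(x[-c(1, 2)]))
    names(sets) <- vapply(strsplit(lines, "\t"), `[`, "", 1)
    sets
}

#' @rdname readGMT
#' @param sets named list of character vectors.
#' @export
writeGMT <- function(sets, path) {
    lines <- vapply(names(sets), function(nm) {
        paste(c(nm, nm, sets[[nm]]), collapse = "\t")
    }, "")
    writeLines(lines, path)
    invisible(path)
}

#' Write or read a cell-level truth table as TSV
#'
#' @param truth `data.frame` with one row per generated cell.
#' @param path TSV path.
#' @export
writeTruthTable <- function(truth, path) {
    write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeTruthTable
#' @export
readTruthTable <- function(path) {
    read.delim(path, stringsAsFactors = FALSE)
}

#' Write a synthetic-data configuration as YAML
#'
#' @param config a [synthConfig()] object.
#' @param path output path.
#' @export
writeSynthConfig <- function(config, path) {
    vals <- unclass(config)
    vals$sharedTypes <- as.list(vals$sharedTypes)   # keep names in YAML
    yaml::write_yaml(vals, path)
    invisible(path)
}

#' @rdname writeSynthConfig
#' @export
readSynthConfig <- function(path) {
    vals <- yaml::read_yaml(path)
    vals <- vals[intersect(names(vals), names(formals(synthConfig)))]
    if (!is.null(vals$sharedTypes)) vals$sharedTypes <- unlist(vals$sharedTypes)
    do.call(synthConfig, vals)
}
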