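#' Read a gene-by-cell count matrix from MatrixMarket + TSV sidecars
#'
#' The on-disk layout is a MatrixMarket coordinate file
#' (\code{\%\%MatrixMarket matrix coordinate integer general}) holding the
#' counts, plus two tab-delimited sidecars: a gene table with a
#' \code{gene_id} column (one row per matrix row, in order) and a cell table
#' with columns \code{cell_id}, \code{mouse_id}, \code{timepoint},
#' \code{condition}, \code{sex} (one row per matrix column, in order).
#'
#' @param matrixPath path to the MatrixMarket counts file
#' @param genesPath path to the gene sidecar TSV
#' @param cellsPath path to the cell metadata sidecar TSV
#' @return A \linkS4class{MesenchymeCounts} object.
#' @seealso \code{\link{writeCounts}}
#' @export
readCounts <- function(matrixPath, genesPath, cellsPath) {
    m <- tryCatch(Matrix::readMM(matrixPath),
                  error = function(e) stop("not a readable MatrixMarket file: ",
                                           matrixPath, " (", conditionMessage(e), ")"))
    genes <- utils::read.delim(genesPath, stringsAsFactors = FALSE,
                               comment.char = "#", check.names = FALSE,
                               colClasses = "character")
    cells <- utils::read.delim(cellsPath, stringsAsFactors = FALSE,
                               comment.char = "#", check.names = FALSE,
                               colClasses = "character")
    if (!"gene_id" %in% colnames(genes))
        stop("gene sidecar lacks a 'gene_id' column: ", genesPath)
    need <- c("cell_id", REQUIRED_CELL_META)
    missing_cols <- setdiff(need, colnames(cells))
    if (length(missing_cols))
        stop("cell sidecar lacks column(s): ",
             paste(missing_cols, collapse = ", "), ": ", cellsPath)
    if (nrow(genes) != nrow(m) || nrow(cells) != ncol(m))
        stop("dimension mismatch: matrix is ", nrow(m), " x ", ncol(m),
             " but sidecars describe ", nrow(genes), " genes and ",
             nrow(cells), " cells")
    v <- m@x
    if (length(v) && (any(v < 0) || any(v != round(v))))
        stop("counts must be non-negative integers: ", matrixPath)
    if (anyDuplicated(genes$gene_id))
        stop("duplicate gene_id in ", genesPath)
    if (anyDuplicated(cells$cell_id))
        stop("duplicate cell_id in ", cellsPath)
    counts <- as.matrix(m)
    storage.mode(counts) <- "integer"
    dimnames(counts) <- list(genes$gene_id, cells$cell_id)
    meta <- cells[, setdiff(colnames(cells), "cell_id"), drop = FALSE]
    MesenchymeCounts(counts, meta)
}

#' Write a count matrix as MatrixMarket + TSV sidecars
#'
#' Inverse of \code{\link{readCounts}}; \code{readCounts(writeCounts(x))}
#' reproduces the object exactly (integer counts, metadata, ordering).
#'
#' @param x a \linkS4class{MesenchymeCounts}
#' @param matrixPath,genesPath,cellsPath output paths
#' @return invisibly, the three paths
#' @export
writeCounts <- function(x, matrixPath, genesPath, cellsPath) {
    stopifnot(methods::is(x, "MesenchymeCounts"))
    m <- SummarizedExperiment::assay(x, "counts")
    sm <- methods::as(methods::as(Matrix::Matrix(denseMatrix(m), sparse = TRUE),
                                  "generalMatrix"), "CsparseMatrix")
    Matrix::writeMM(sm, matrixPath)
    utils::write.table(data.frame(gene_id = rownames(x)),
                       genesPath, sep = "\t", quote = FALSE, row.names = FALSE)
    meta <- as.data.frame(SummarizedExperiment::colData(x))
    cells <- cbind(data.frame(cell_id = colnames(x)), meta)
    utils::write.table(cells, cellsPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(c(matrixPath, genesPath, cellsPath))
}

#' Read a ligand-receptor pair table
#'
#' Expects a tab-delimited file with header columns \code{pair_id},
#' \code{ligand_gene}, \code{receptor_gene}. File order is preserved; an
#' empty file yields an empty database.
#'
#' @param path path to the TSV file
#' @return An \linkS4class{LRPairs} object.
#' @export
readLRPairs <- function(path) {
    p <- utils::read.delim(path, stringsAsFactors = FALSE,
                           comment.char = "#", check.names = FALSE)
    need <- c("pair_id", "ligand_gene", "receptor_gene")
    missing_cols <- setdiff(need, colnames(p))
    if (length(missing_cols))
        stop("ligand-receptor table lacks column(s): ",
             paste(missing_cols, collapse = ", "), ": ", path)
    LRPairs(p[, need])
}

#' Write a ligand-receptor pair table
#'
#' @param x an \linkS4class{LRPairs}
#' @param path output TSV path
#' @return invisibly, \code{path}
#' @export
writeLRPairs <- function(x, path) {
    stopifnot(methods::is(x, "LRPairs"))
    utils::write.table(x@pairs, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Write a result table as TSV with a provenance header
#'
#' All pipeline result tables (differential expression, annotation,
#' interactions, bootstrap draws) are written tab-delimited with a header
#' row, optional \code{#}-prefixed provenance lines, and floating point at
#' full double precision (at least 10 significant digits), so that
#' \code{\link{readResultTable}} round-trips values within 1e-9.
#'
#' @param records a data.frame
#' @param path output path
#' @param provenance optional named character vector written as
#'   \code{# key=value} comment lines before the header
#' @return invisibly, \code{path}
#' @export
writeResultTable <- function(records, path, provenance = NULL) {
    records <- as.data.frame(records, stringsAsFactors = FALSE)
    con <- tryCatch(file(path, open = "wt"),
                    error = function(e) stop("cannot write to ", path, ": ",
                                             conditionMessage(e)))
    on.exit(close(con))
    if (length(provenance))
        writeLines(paste0("# ", names(provenance), "=", provenance), con)
    is_dbl <- vapply(records, is.double, logical(1))
    out <- records
    out[is_dbl] <- lapply(records[is_dbl], function(z)
        formatC(z, digits = 15, format = "g"))
    utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a result table written by \code{\link{writeResultTable}}
#'
#' @param path path to the TSV file
#' @return a data.frame (provenance comment lines are skipped)
#' @export
readResultTable <- function(path) {
    utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                      check.names = FALSE)
}
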