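#' @import methods
#' @importClassesFrom SingleCellExperiment SingleCellExperiment
NULL

#' Valid developmental time points and oxygen conditions
#'
#' The experimental design covers the late saccular to late alveolar stages
#' of mouse lung development (E18.5, P1, P7, P21) in two arms: normoxia and
#' postnatal hyperoxia (80\% FiO2 from birth, sampled at P7).
#'
#' @name design-levels
#' @keywords internal
TIMEPOINT_LEVELS <- c("E18.5", "P1", "P7", "P21")

#' @rdname design-levels
#' @keywords internal
CONDITION_LEVELS <- c("normoxia", "hyperoxia")

#' @rdname design-levels
#' @keywords internal
SEX_LEVELS <- c("F", "M", "unknown")

REQUIRED_CELL_META <- c("mouse_id", "timepoint", "condition", "sex")

#' MesenchymeCounts: raw gene-by-cell counts with per-cell design metadata
#'
#' An S4 container extending \linkS4class{SingleCellExperiment}. The
#' \code{"counts"} assay holds raw, non-negative, integer-valued read counts
#' (genes in rows, cells in columns). \code{colData} must carry the study
#' design for every cell: \code{mouse_id}, \code{timepoint} (one of E18.5,
#' P1, P7, P21), \code{condition} (normoxia or hyperoxia) and \code{sex}
#' (F, M or unknown). Gene identifiers are case-sensitive mouse gene
#' symbols; no identifier mapping is performed.
#'
#' CPM normalization (\code{\link{cpmNormalize}}) adds a \code{"cpm"} assay
#' to the same object; zero-total cells are legal in the raw object (quality
#' control removes them) but are rejected at normalization time.
#'
#' @seealso \code{\link{MesenchymeCounts}}, \code{\link{readCounts}},
#'   \code{\link{filterCells}}, \code{\link{cpmNormalize}}
#' @export
setClass("MesenchymeCounts", contains = "SingleCellExperiment")

setValidity("MesenchymeCounts", function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        return("assay 'counts' is required")
    m <- SummarizedExperiment::assay(object, "counts")
    if (is.null(rownames(object)) || is.null(colnames(object)))
        msg <- c(msg, "gene and cell identifiers (dimnames) are required")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicate gene identifiers")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicate cell identifiers")
    v <- if (methods::is(m, "sparseMatrix")) m@x else m
    if (length(v) && (anyNA(v) || any(v < 0)))
        msg <- c(msg, "counts must be non-negative")
    if (length(v) && any(v != round(v)))
        msg <- c(msg, "counts must be integer-valued")
    cd <- SummarizedExperiment::colData(object)
    missing_cols <- setdiff(REQUIRED_CELL_META, colnames(cd))
    if (length(missing_cols)) {
        msg <- c(msg, paste0("missing cell metadata column(s): ",
                             paste(missing_cols, collapse = ", ")))
    } else if (ncol(object) > 0) {
        if (!all(cd$timepoint %in% TIMEPOINT_LEVELS))
            msg <- c(msg, paste0("timepoint must be one of: ",
                                 paste(TIMEPOINT_LEVELS, collapse = ", ")))
        if (!all(cd$condition %in% CONDITION_LEVELS))
            msg <- c(msg, paste0("condition must be one of: ",
                                 paste(CONDITION_LEVELS, collapse = ", ")))
        if (!all(cd$sex %in% SEX_LEVELS))
            msg <- c(msg, paste0("sex must be one of: ",
                                 paste(SEX_LEVELS, collapse = ", ")))
        if (anyNA(cd$timepoint) || anyNA(cd$condition))
            msg <- c(msg, "every cell needs a timepoint and a condition")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a MesenchymeCounts object
#'
#' @param counts numeric matrix (or sparse Matrix) of non-negative integer
#'   read counts, genes x cells. Dimnames are used as gene/cell identifiers
#'   unless \code{geneIds}/\code{cellIds} are given.
#' @param cellMeta data.frame with one row per cell and columns
#'   \code{mouse_id}, \code{timepoint}, \code{condition}, \code{sex}.
#' @param geneIds,cellIds optional identifier vectors overriding dimnames.
#' @return A validated \linkS4class{MesenchymeCounts} object.
#' @examples
#' cm <- MesenchymeCounts(
#'   matrix(0:5, nrow = 3, dimnames = list(paste0("g", 1:3), c("c1", "c2"))),
#'   data.frame(mouse_id = "m1", timepoint = "P7",
#'              condition = "normoxia", sex = "F"))
#' @export
MesenchymeCounts <- function(counts, cellMeta, geneIds = NULL, cellIds = NULL) {
    if (!is.null(geneIds)) rownames(counts) <- geneIds
    if (!is.null(cellIds)) colnames(counts) <- cellIds
    cellMeta <- as.data.frame(cellMeta, stringsAsFactors = FALSE)
    if (nrow(cellMeta) == 1L && ncol(counts) > 1L)
        cellMeta <- cellMeta[rep(1L, ncol(counts)), , drop = FALSE]
    if (nrow(cellMeta) != ncol(counts))
        stop("cellMeta must have one row per cell (", ncol(counts),
             " cells, ", nrow(cellMeta), " metadata rows)")
    if (anyDuplicated(colnames(counts)))
        stop("duplicate cell identifiers")
    if (anyDuplicated(rownames(counts)))
        stop("duplicate gene identifiers")
    rownames(cellMeta) <- colnames(counts)
    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = counts),
        colData = S4Vectors::DataFrame(cellMeta, check.names = FALSE))
    methods::validObject(out <- methods::new("MesenchymeCounts", sce))
    out
}

#' @describeIn MesenchymeCounts compact display
#' @param object a \code{MesenchymeCounts}
#' @export
setMethod("show", "MesenchymeCounts", function(object) {
    cat("MesenchymeCounts:", nrow(object), "genes x", ncol(object), "cells\n")
    if (ncol(object)) {
        tb <- table(timepoint = factor(colData(object)$timepoint,
                                       TIMEPOINT_LEVELS),
                    condition = factor(colData(object)$condition,
                                       CONDITION_LEVELS))
        print(tb[rowSums(tb) > 0, colSums(tb) > 0, drop = FALSE])
    }
    cat("assays:", paste(SummarizedExperiment::assayNames(object),
                         collapse = ", "), "\n")
    invisible(NULL)
})

#' LRPairs: a ligand-receptor pair table
#'
#' Wraps a data.frame with columns \code{pair_id}, \code{ligand_gene} and
#' \code{receptor_gene}. Pair identifiers are unique; gene symbols need not
#' be present in a given count matrix (absent genes simply count as 0\%
#' expressing). Export pairs from any ligand-receptor resource into this
#' schema; none is bundled.
#'
#' @seealso \code{\link{readLRPairs}}, \code{\link{detectInteractions}}
#' @export
setClass("LRPairs", representation(pairs = "data.frame"))

setValidity("LRPairs", function(object) {
    p <- object@pairs
    need <- c("pair_id", "ligand_gene", "receptor_gene")
    if (!all(need %in% colnames(p)))
        return(paste0("pairs needs columns: ", paste(need, collapse = ", ")))
    msg <- character()
    if (anyDuplicated(p$pair_id))
        msg <- c(msg, "duplicate pair_id")
    if (nrow(p) && (any(!nzchar(p$ligand_gene)) || any(!nzchar(p$receptor_gene)) ||
                    anyNA(p$ligand_gene) || anyNA(p$receptor_gene)))
        msg <- c(msg, "ligand and receptor gene symbols must be non-empty")
    if (length(msg)) msg else TRUE
})

#' Construct an LRPairs database
#'
#' @param pairs data.frame with columns \code{pair_id}, \code{ligand_gene},
#'   \code{receptor_gene} (file order is preserved).
#' @return An \linkS4class{LRPairs} object.
#' @export
LRPairs <- function(pairs) {
    pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
    methods::new("LRPairs", pairs = pairs)
}

#' @describeIn LRPairs number of pairs
#' @param x an \code{LRPairs}
#' @export
setMethod("length", "LRPairs", function(x) nrow(x@pairs))

#' Pair table accessor
#'
#' @param x an \linkS4class{LRPairs} object
#' @return the underlying data.frame of pairs
#' @export
lrPairs <- function(x) {
    stopifnot(methods::is(x, "LRPairs"))
    x@pairs
}

#' @describeIn LRPairs compact display
#' @param object an \code{LRPairs}
#' @export
setMethod("show", "LRPairs", function(object) {
    cat("LRPairs with", nrow(object@pairs), "ligand-receptor pairs\n")
    invisible(NULL)
})

#' CellEmbedding: a low-dimensional embedding of cells
#'
#' Principal-component scores of the log-transformed, feature-restricted
#' CPM matrix (cells in rows). \code{varExplained} gives the fraction of
#' variance captured by each component; \code{featureGenes} records the
#' genes the embedding was computed on; \code{source} optionally tags each
#' cell with its dataset of origin (used by \code{\link{harmonizeEmbed}}).
#'
#' @seealso \code{\link{embedPCA}}, \code{\link{clusterLeiden}}
#' @export
setClass("CellEmbedding", representation(
    coords = "matrix",
    featureGenes = "character",
    varExplained = "numeric",
    params = "list",
    source = "character"))

setValidity("CellEmbedding", function(object) {
    msg <- character()
    if (is.null(rownames(object@coords)))
        msg <- c(msg, "coords must carry cell identifiers as rownames")
    if (length(object@source) &&
        length(object@source) != nrow(object@coords))
        msg <- c(msg, "source tags must cover all cells")
    if (length(msg)) msg else TRUE
})

#' @describeIn CellEmbedding number of cells
#' @param x a \code{CellEmbedding}
#' @export
setMethod("dim", "CellEmbedding", function(x) dim(x@coords))

#' Embedding coordinate accessor
#'
#' @param x a \linkS4class{CellEmbedding}
#' @return matrix of cell coordinates (cells x components)
#' @export
embeddingCoords <- function(x) {
    stopifnot(methods::is(x, "CellEmbedding"))
    x@coords
}

#' Source tags of a (joint) embedding
#'
#' @param x a \linkS4class{CellEmbedding}
#' @return character vector tagging each cell with its dataset of origin
#'   (empty for single-dataset embeddings)
#' @export
embeddingSource <- function(x) {
    stopifnot(methods::is(x, "CellEmbedding"))
    x@source
}

#' @describeIn CellEmbedding compact display
#' @param object a \code{CellEmbedding}
#' @export
setMethod("show", "CellEmbedding", function(object) {
    cat("CellEmbedding:", nrow(object@coords), "cells x",
        ncol(object@coords), "components\n")
    cat(sprintf("top component explains %.1f%% of variance\n",
                100 * object@varExplained[1]))
    if (length(object@source))
        print(table(source = object@source))
    invisible(NULL)
})
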