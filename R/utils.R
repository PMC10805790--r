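# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            get(".Random.seed", envir = globalenv()) else NULL
        on.exit({
            if (is.null(old)) {
                if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
                    rm(".Random.seed", envir = globalenv())
            } else assign(".Random.seed", old, envir = globalenv())
        })
        set.seed(seed)
    }
    force(expr)
}

# Dense numeric matrix from whatever the assay holds.
denseMatrix <- function(m) {
    if (methods::is(m, "sparseMatrix")) as.matrix(m) else m
}

rawCounts <- function(x) {
    stopifnot(methods::is(x, "MesenchymeCounts"))
    denseMatrix(SummarizedExperiment::assay(x, "counts"))
}

# CPM assay, with a helpful error when normalization has not been run.
cpmAssay <- function(x) {
    if (!"cpm" %in% SummarizedExperiment::assayNames(x))
        stop("no 'cpm' assay: run cpmNormalize() (after filterCells()) first")
    denseMatrix(SummarizedExperiment::assay(x, "cpm"))
}

# Logical index of cells in a (timepoint, condition) stratum.
stratumIndex <- function(meta, timepoint, condition) {
    if (!timepoint %in% TIMEPOINT_LEVELS)
        stop("unknown timepoint: ", timepoint)
    if (!condition %in% CONDITION_LEVELS)
        stop("unknown condition: ", condition)
    meta$timepoint == timepoint & meta$condition == condition
}

# Resolve a cell selector (character ids or logical/integer index) to ids.
resolveCells <- function(x, cells) {
    ids <- colnames(x)
    if (is.character(cells)) {
        bad <- setdiff(cells, ids)
        if (length(bad))
            stop("unknown cell id(s): ", paste(utils::head(bad, 3), collapse = ", "))
        cells
    } else ids[cells]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
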