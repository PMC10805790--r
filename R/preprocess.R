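#' Cell-level quality control
#'
#' Discards cells with fewer than \code{minReads} total counts or fewer
#' than \code{minGenes} detected genes (count > 0). The thresholds are
#' strict "less than" cut-offs, so boundary cells (exactly 50,000 counts or
#' exactly 400 genes) are retained. The gene axis is unchanged and the
#' operation is idempotent.
#'
#' @param x a \linkS4class{MesenchymeCounts}
#' @param minReads minimum total counts per cell (default 50,000)
#' @param minGenes minimum detected genes per cell (default 400)
#' @return the filtered \linkS4class{MesenchymeCounts} (possibly 0 cells)
#' @export
filterCells <- function(x, minReads = 50000, minGenes = 400) {
    stopifnot(methods::is(x, "MesenchymeCounts"),
              minReads > 0, minGenes > 0)
    if (ncol(x) == 0) return(x)
    m <- rawCounts(x)
    keep <- colSums(m) >= minReads & colSums(m > 0) >= minGenes
    x[, keep]
}

#' Counts-per-million normalization
#'
#' Scales every cell to a total of one million: \code{cpm[g, c] =
#' counts[g, c] / total(c) * 1e6}. Adds a \code{"cpm"} assay to the object;
#' all downstream statistics consume this assay. Cells with zero total
#' counts are rejected -- run \code{\link{filterCells}} first.
#'
#' @param x a \linkS4class{MesenchymeCounts}
#' @return \code{x} with a \code{"cpm"} assay added
#' @export
cpmNormalize <- function(x) {
    stopifnot(methods::is(x, "MesenchymeCounts"))
    m <- rawCounts(x)
    tot <- colSums(m)
    if (any(tot == 0))
        stop(sum(tot == 0), " cell(s) have zero total counts; ",
             "run filterCells() before cpmNormalize()")
    SummarizedExperiment::assay(x, "cpm") <- sweep(m, 2, tot, "/") * 1e6
    x
}

#' CPM assay accessor
#'
#' @param x a \linkS4class{MesenchymeCounts} that has been through
#'   \code{\link{cpmNormalize}}
#' @return dense matrix of counts-per-million values (genes x cells)
#' @export
cpmValues <- function(x) cpmAssay(x)

# Per-group Fano factors (variance/mean of CPM; 0 where the mean is 0).
fanoByGroup <- function(cpm, group) {
    groups <- unique(group)
    out <- matrix(0, nrow = nrow(cpm), ncol = length(groups),
                  dimnames = list(rownames(cpm), groups))
    for (g in groups) {
        sub <- cpm[, group == g, drop = FALSE]
        n <- ncol(sub)
        mu <- rowMeans(sub)
        v <- (rowSums(sub^2) - n * mu^2) / (n - 1)
        f <- ifelse(mu > 0, v / mu, 0)
        out[, g] <- pmax(f, 0)
    }
    out
}

#' Select highly variable genes by Fano factor across mice
#'
#' For every mouse, each gene's Fano factor (variance/mean of CPM; genes
#' with zero mean score 0) is ranked, and a gene is "high" in that mouse if
#' it ranks in the mouse's top \code{nFeatures}. Genes high in at least
#' \code{majorityFraction} of mice are returned, ranked by the number of
#' mice supporting them, then by median Fano factor across mice, with ties
#' broken by gene symbol. The result is invariant to cell ordering and
#' mouse relabeling.
#'
#' @param x a CPM-normalized \linkS4class{MesenchymeCounts}
#' @param nFeatures number of features to select (default 500)
#' @param majorityFraction minimum fraction of mice in which a gene must
#'   rank high (default 0.5)
#' @return character vector of at most \code{nFeatures} gene symbols
#' @export
selectFeatures <- function(x, nFeatures = 500, majorityFraction = 0.5) {
    stopifnot(methods::is(x, "MesenchymeCounts"),
              majorityFraction > 0, majorityFraction <= 1)
    cpm <- cpmAssay(x)
    mouse <- SummarizedExperiment::colData(x)$mouse_id
    sizes <- table(mouse)
    if (any(sizes < 2))
        stop("every mouse needs >= 2 cells for variance estimation (",
             paste(names(sizes)[sizes < 2], collapse = ", "), ")")
    fano <- fanoByGroup(cpm, mouse)
    nMice <- ncol(fano)
    k <- min(nFeatures, nrow(fano))
    high <- apply(fano, 2, function(f) {
        ord <- order(-f, rownames(fano))
        sel <- logical(length(f))
        sel[ord[seq_len(k)]] <- TRUE
        sel
    })
    support <- rowSums(high)
    medFano <- apply(fano, 1, stats::median)
    qualify <- support / nMice >= majorityFraction
    if (!any(qualify))
        stop("no gene ranks high in ", majorityFraction,
             " of mice; lower majorityFraction")
    cand <- rownames(fano)[qualify]
    ord <- order(-support[qualify], -medFano[qualify], cand)
    utils::head(cand[ord], nFeatures)
}

#' PCA embedding of log-transformed CPM
#'
#' Restricts the CPM matrix to \code{features}, applies
#' \code{log10(cpm + pseudocount)}, and projects the cells onto the top
#' \code{nPCs} principal components (gene-centered, no unit-variance
#' scaling). The sign of each component is fixed so that its
#' largest-magnitude gene loading is positive, making the embedding fully
#' deterministic.
#'
#' @param x a CPM-normalized \linkS4class{MesenchymeCounts}
#' @param features gene symbols to embed on (e.g. from
#'   \code{\link{selectFeatures}})
#' @param nPCs number of principal components (default 25)
#' @param pseudocount added before the log (default 0.1)
#' @return a \linkS4class{CellEmbedding}
#' @export
embedPCA <- function(x, features, nPCs = 25, pseudocount = 0.1) {
    stopifnot(methods::is(x, "MesenchymeCounts"), pseudocount > 0)
    cpm <- cpmAssay(x)
    bad <- setdiff(features, rownames(cpm))
    if (length(bad))
        stop("feature gene(s) absent from the matrix: ",
             paste(utils::head(bad, 3), collapse = ", "))
    if (nPCs >= min(length(features), ncol(x)))
        stop("nPCs must be smaller than min(n_features, n_cells)")
    lx <- t(log10(cpm[features, , drop = FALSE] + pseudocount))
    pc <- stats::prcomp(lx, center = TRUE, scale. = FALSE, rank. = nPCs)
    for (j in seq_len(ncol(pc$rotation))) {
        i <- which.max(abs(pc$rotation[, j]))
        if (pc$rotation[i, j] < 0) {
            pc$rotation[, j] <- -pc$rotation[, j]
            pc$x[, j] <- -pc$x[, j]
        }
    }
    ve <- pc$sdev^2 / sum(pc$sdev^2)
    methods::new("CellEmbedding",
        coords = pc$x,
        featureGenes = features,
        varExplained = ve[seq_len(nPCs)],
        params = list(nPCs = nPCs, pseudocount = pseudocount),
        source = character())
}

#' Two-dimensional t-SNE view of an embedding
#'
#' Visualization only: statistics are always computed on the PCA
#' coordinates, never on the t-SNE plane. Deterministic for a fixed seed.
#'
#' @param embedding a \linkS4class{CellEmbedding}
#' @param seed integer seed
#' @param perplexity t-SNE perplexity (capped at \code{(n - 1) / 3})
#' @return matrix (cells x 2) of t-SNE coordinates
#' @export
embedTSNE <- function(embedding, seed = 0L, perplexity = 30) {
    stopifnot(methods::is(embedding, "CellEmbedding"))
    co <- embedding@coords
    perplexity <- min(perplexity, floor((nrow(co) - 1) / 3))
    out <- withSeed(seed,
        Rtsne::Rtsne(co, dims = 2, pca = FALSE,
                     perplexity = perplexity, check_duplicates = FALSE))
    y <- out$Y
    rownames(y) <- rownames(co)
    colnames(y) <- c("tsne1", "tsne2")
    y
}
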