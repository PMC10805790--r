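# Two-sample KS statistic: sup |ECDF_a - ECDF_b|, ties handled by
# evaluating only at the last index of each tied run in the pooled sort.
ksStatistic <- function(a, b) {
    n1 <- length(a); n2 <- length(b)
    pooled <- c(a, b)
    o <- order(pooled)
    steps <- ifelse(o <= n1, 1 / n1, -1 / n2)
    z <- cumsum(steps)
    sorted <- pooled[o]
    keep <- c(diff(sorted) != 0, TRUE)
    max(abs(z[keep]))
}

# Two-sided p-value: exact (ties-aware) when both samples are small,
# otherwise the asymptotic Kolmogorov tail with the effective-n correction.
ksPValue <- function(d, n1, n2, pooled = NULL, exactMax = 25) {
    if (n1 <= exactMax && n2 <= exactMax) {
        p <- stats::psmirnov(d, sizes = c(n1, n2), z = pooled,
                             two.sided = TRUE, lower.tail = FALSE)
    } else {
        t <- sqrt(n1 * n2 / (n1 + n2)) * d
        if (t < 1e-3) return(1)
        k <- seq_len(100)
        p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))
    }
    min(1, max(p, .Machine$double.xmin))
}

signedKS <- function(a, b) {
    d <- ksStatistic(a, b)
    s <- sign(mean(a) - mean(b))
    if (s == 0) s <- 1
    d * s
}

#' Kolmogorov-Smirnov differential expression
#'
#' Per gene, the two-sample KS statistic (sup of the absolute ECDF
#' difference) between the CPM distributions of two disjoint cell sets,
#' with a signed variant (sign of the mean difference, A minus B), a
#' two-sided p-value (exact and ties-aware when both groups have at most 25
#' cells, asymptotic otherwise), Bonferroni adjustment over the tested gene
#' set, and an average log2 fold change with pseudocount 0.1 on the means.
#'
#' @param x a CPM-normalized \linkS4class{MesenchymeCounts}
#' @param cellsA,cellsB disjoint cell selections (ids, or logical/integer
#'   index), each with at least 2 cells
#' @param genes optional gene subset (default: all genes); Bonferroni m is
#'   the number of genes actually tested
#' @return data.frame with columns \code{gene}, \code{ks_stat},
#'   \code{signed_ks}, \code{p_value}, \code{p_adj}, \code{log2fc}
#' @examples
#' # a gene identical in both groups has ks_stat 0 and p 1; a gene with
#' # complete separation has ks_stat 1
#' @export
ksDE <- function(x, cellsA, cellsB, genes = NULL) {
    cpm <- cpmAssay(x)
    cellsA <- resolveCells(x, cellsA)
    cellsB <- resolveCells(x, cellsB)
    if (length(intersect(cellsA, cellsB)))
        stop("cellsA and cellsB must be disjoint")
    if (length(cellsA) < 2 || length(cellsB) < 2)
        stop("each group needs at least 2 cells")
    if (is.null(genes)) genes <- rownames(cpm)
    empty <- data.frame(gene = character(), ks_stat = numeric(),
                        signed_ks = numeric(), p_value = numeric(),
                        p_adj = numeric(), log2fc = numeric(),
                        stringsAsFactors = FALSE)
    if (!length(genes)) return(empty)
    bad <- setdiff(genes, rownames(cpm))
    if (length(bad))
        stop("gene(s) absent from the matrix: ",
             paste(utils::head(bad, 3), collapse = ", "))
    A <- cpm[genes, cellsA, drop = FALSE]
    B <- cpm[genes, cellsB, drop = FALSE]
    n1 <- length(cellsA); n2 <- length(cellsB)
    m <- length(genes)
    stat <- numeric(m); signed <- numeric(m); p <- numeric(m)
    fc <- numeric(m)
    for (i in seq_len(m)) {
        a <- A[i, ]; b <- B[i, ]
        d <- ksStatistic(a, b)
        s <- sign(mean(a) - mean(b))
        if (s == 0) s <- 1
        stat[i] <- d
        signed[i] <- d * s
        p[i] <- ksPValue(d, n1, n2, pooled = c(a, b))
        fc[i] <- log2((mean(a) + 0.1) / (mean(b) + 0.1))
    }
    data.frame(gene = genes, ks_stat = stat, signed_ks = signed,
               p_value = p, p_adj = pmin(1, m * p), log2fc = fc,
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Rank differentially expressed genes
#'
#' Two selection modes: \code{"by_stat"} takes the \code{topN} genes by
#' absolute KS statistic; \code{"by_fc_above_ks"} keeps genes whose KS
#' statistic is at least \code{ksMin} (default 0.3) and ranks them by
#' absolute average fold change. Ties are broken by gene symbol.
#'
#' @param de a \code{\link{ksDE}} result
#' @param mode selection mode (see above)
#' @param ksMin KS-statistic floor for \code{"by_fc_above_ks"}
#' @param topN maximum number of genes returned (default all qualifying)
#' @return ordered character vector of gene symbols
#' @export
rankGenes <- function(de, mode = c("by_stat", "by_fc_above_ks"),
                      ksMin = 0.3, topN = Inf) {
    mode <- match.arg(mode)
    stopifnot(ksMin >= 0, ksMin <= 1)
    if (mode == "by_stat") {
        ord <- order(-abs(de$ks_stat), de$gene)
        out <- de$gene[ord]
    } else {
        keep <- de[de$ks_stat >= ksMin, , drop = FALSE]
        out <- keep$gene[order(-abs(keep$log2fc), keep$gene)]
    }
    if (is.finite(topN)) out <- utils::head(out, topN)
    out
}

#' Transcription-factor quadrant fingerprint
#'
#' Scores each transcription factor by its signed KS enrichment in a focal
#' population against two reference populations: \code{enrich_x} (focal vs
#' ref1) and \code{enrich_y} (focal vs ref2). Factors positive on both axes
#' are specific to the focal type (\code{specific_up}); negative on both,
#' specifically absent from it (\code{specific_down}); one-sided
#' enrichments are \code{mixed_x} / \code{mixed_y}. Only factors expressed
#' (CPM > 0 in at least one cell of the three populations) are scored;
#' factors absent from the matrix are skipped with a warning.
#'
#' @param x a CPM-normalized \linkS4class{MesenchymeCounts}
#' @param focalCells,ref1Cells,ref2Cells three disjoint cell selections,
#'   each with at least 2 cells
#' @param tfGenes transcription-factor gene symbols to score
#' @return data.frame with columns \code{gene}, \code{enrich_x},
#'   \code{enrich_y}, \code{quadrant}
#' @export
tfQuadrant <- function(x, focalCells, ref1Cells, ref2Cells, tfGenes) {
    cpm <- cpmAssay(x)
    focalCells <- resolveCells(x, focalCells)
    ref1Cells <- resolveCells(x, ref1Cells)
    ref2Cells <- resolveCells(x, ref2Cells)
    sets <- list(focalCells, ref1Cells, ref2Cells)
    for (i in 1:2) for (j in (i + 1):3)
        if (length(intersect(sets[[i]], sets[[j]])))
            stop("focal and reference cell sets must be disjoint")
    if (any(lengths(sets) < 2))
        stop("each population needs at least 2 cells")
    absent <- setdiff(tfGenes, rownames(cpm))
    if (length(absent)) {
        warning("skipping ", length(absent),
                " factor(s) absent from the matrix: ",
                paste(utils::head(absent, 5), collapse = ", "))
        tfGenes <- setdiff(tfGenes, absent)
    }
    allCells <- unlist(sets)
    expressed <- tfGenes[rowSums(cpm[tfGenes, allCells, drop = FALSE] > 0) > 0]
    ex <- vapply(expressed, function(g)
        signedKS(cpm[g, focalCells], cpm[g, ref1Cells]), numeric(1))
    ey <- vapply(expressed, function(g)
        signedKS(cpm[g, focalCells], cpm[g, ref2Cells]), numeric(1))
    quadrant <- ifelse(ex > 0 & ey > 0, "specific_up",
                ifelse(ex < 0 & ey < 0, "specific_down",
                ifelse(ex >= ey, "mixed_x", "mixed_y")))
    data.frame(gene = expressed, enrich_x = unname(ex),
               enrich_y = unname(ey), quadrant = unname(quadrant),
               stringsAsFactors = FALSE, row.names = NULL)
}
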