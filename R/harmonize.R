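#' Co-embed a query dataset with a reference atlas
#'
#' Joint PCA on the intersected, feature-selected gene space of both
#' datasets, followed by batch-balanced nearest-neighbor smoothing: each
#' cell's coordinates are averaged with those of its \code{k} nearest
#' neighbors drawn from each source separately, which pulls matching cell
#' states from the two sources together without letting the larger source
#' dominate. With \code{k = 0} the result is plain joint PCA. Deterministic.
#'
#' @param query,atlas two CPM-ready \linkS4class{MesenchymeCounts} objects
#'   (CPM is computed internally on the shared gene space)
#' @param k neighbors per source for the smoothing (default 10)
#' @param nFeatures,nPCs,pseudocount embedding parameters as in
#'   \code{\link{selectFeatures}} / \code{\link{embedPCA}}
#' @param sourceNames length-2 names for the two datasets
#' @return a \linkS4class{CellEmbedding} whose \code{source} tags partition
#'   the cells; cell ids are prefixed with the source name when the two
#'   datasets share identifiers
#' @export
harmonizeEmbed <- function(query, atlas, k = 10, nFeatures = 500,
                           nPCs = 25, pseudocount = 0.1,
                           sourceNames = c("query", "atlas")) {
    stopifnot(methods::is(query, "MesenchymeCounts"),
              methods::is(atlas, "MesenchymeCounts"))
    shared <- intersect(rownames(query), rownames(atlas))
    if (!length(shared))
        stop("query and atlas share no genes")
    if (k > 0 && (ncol(query) < k || ncol(atlas) < k))
        stop("each source needs at least k = ", k, " cells")
    qids <- colnames(query)
    aids <- colnames(atlas)
    if (length(intersect(qids, aids))) {
        qids <- paste0(sourceNames[1], ":", qids)
        aids <- paste0(sourceNames[2], ":", aids)
    }
    qc <- rawCounts(query)[shared, , drop = FALSE]
    ac <- rawCounts(atlas)[shared, , drop = FALSE]
    counts <- cbind(qc, ac)
    colnames(counts) <- c(qids, aids)
    tot <- colSums(counts)
    if (any(tot == 0))
        stop("cells with zero counts on the shared gene space; filter first")
    cpm <- sweep(counts, 2, tot, "/") * 1e6
    src <- c(rep(sourceNames[1], length(qids)), rep(sourceNames[2], length(aids)))
    mouse <- paste(src, c(SummarizedExperiment::colData(query)$mouse_id,
                          SummarizedExperiment::colData(atlas)$mouse_id),
                   sep = ":")
    fano <- fanoByGroup(cpm, mouse)
    kTop <- min(nFeatures, nrow(fano))
    high <- apply(fano, 2, function(f) {
        ord <- order(-f, rownames(fano))
        sel <- logical(length(f))
        sel[ord[seq_len(kTop)]] <- TRUE
        sel
    })
    support <- rowSums(high)
    qualify <- support / ncol(fano) >= 0.5
    if (!any(qualify)) qualify <- support > 0
    cand <- rownames(fano)[qualify]
    medFano <- apply(fano, 1, stats::median)
    features <- utils::head(
        cand[order(-support[qualify], -medFano[qualify], cand)], nFeatures)
    if (nPCs >= min(length(features), ncol(cpm)))
        stop("nPCs must be smaller than min(n_features, n_cells)")
    lx <- t(log10(cpm[features, , drop = FALSE] + pseudocount))
    pc <- stats::prcomp(lx, center = TRUE, scale. = FALSE, rank. = nPCs)
    for (j in seq_len(ncol(pc$rotation))) {
        i <- which.max(abs(pc$rotation[, j]))
        if (pc$rotation[i, j] < 0) pc$x[, j] <- -pc$x[, j]
    }
    co <- pc$x
    if (k > 0) {
        isQ <- src == sourceNames[1]
        nnQ <- RANN::nn2(co[isQ, , drop = FALSE], co, k = k)$nn.idx
        nnA <- RANN::nn2(co[!isQ, , drop = FALSE], co, k = k)$nn.idx
        idxQ <- which(isQ)
        idxA <- which(!isQ)
        sm <- co
        for (i in seq_len(nrow(co))) {
            nb <- c(idxQ[nnQ[i, ]], idxA[nnA[i, ]])
            sm[i, ] <- colMeans(co[c(i, nb), , drop = FALSE])
        }
        co <- sm
    }
    methods::new("CellEmbedding",
        coords = co, featureGenes = features,
        varExplained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(ncol(co))],
        params = list(nPCs = nPCs, pseudocount = pseudocount, k = k),
        source = src)
}

#' Reannotate atlas cells inside a rigidly expanded PCA ellipse
#'
#' Fits the mean and covariance of the focal cells in the top
#' \code{nDims} joint-PC coordinates and returns the other-source cells
#' whose Mahalanobis distance from that mean is at most
#' \code{expansion * sqrt(qchisq(quantile, nDims))} -- i.e. the cells of
#' the other dataset that fall inside the focal population's expanded
#' confidence ellipse. Membership is monotone in \code{expansion}.
#'
#' @param joint a joint \linkS4class{CellEmbedding}
#'   (from \code{\link{harmonizeEmbed}})
#' @param focalCells cell ids defining the ellipse (>= nDims + 1 cells)
#' @param otherCells cell ids to test for membership
#' @param nDims number of leading components used (default 2)
#' @param expansion rigid expansion factor of the ellipse radius
#'   (default 1.5; >= 1)
#' @param quantile chi-square coverage of the unexpanded ellipse
#'   (default 0.95)
#' @return character vector: the subset of \code{otherCells} inside the
#'   expanded ellipse
#' @export
ellipseReannotate <- function(joint, focalCells, otherCells, nDims = 2,
                              expansion = 1.5, quantile = 0.95) {
    stopifnot(methods::is(joint, "CellEmbedding"),
              expansion >= 1, quantile > 0, quantile < 1)
    co <- joint@coords[, seq_len(nDims), drop = FALSE]
    bad <- setdiff(c(focalCells, otherCells), rownames(co))
    if (length(bad))
        stop("cell id(s) absent from the embedding: ",
             paste(utils::head(bad, 3), collapse = ", "))
    if (length(focalCells) < nDims + 1)
        stop("need at least nDims + 1 = ", nDims + 1, " focal cells")
    f <- co[focalCells, , drop = FALSE]
    mu <- colMeans(f)
    S <- stats::cov(f)
    Sinv <- tryCatch(solve(S), error = function(e)
        stop("singular focal covariance; use fewer dimensions or ",
             "regularize the ellipse"))
    if (kappa(S) > 1e12)
        stop("singular focal covariance; use fewer dimensions or ",
             "regularize the ellipse")
    d2 <- stats::mahalanobis(co[otherCells, , drop = FALSE], mu, S)
    r <- expansion * sqrt(stats::qchisq(quantile, df = nDims))
    otherCells[d2 <= r^2]
}
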