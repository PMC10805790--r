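#' Leiden clustering on a k-nearest-neighbor graph
#'
#' Builds the exact kNN graph (Euclidean distance in PC space), symmetrizes
#' it, and runs Leiden community detection with the modularity objective.
#' Labels are renumbered by decreasing cluster size and the result is
#' deterministic for a fixed seed.
#'
#' @param embedding a \linkS4class{CellEmbedding}
#' @param nNeighbors neighbors per cell in the kNN graph (default 15)
#' @param resolution Leiden resolution; larger gives more clusters
#'   (default 1.5 -- mild over-clustering is harmless here because cluster
#'   labels come from marker rules, while merged clusters are not)
#' @param seed integer seed
#' @return integer cluster labels named by cell id (1 = largest cluster)
#' @export
clusterLeiden <- function(embedding, nNeighbors = 15, resolution = 1.5,
                          seed = 0L) {
    stopifnot(methods::is(embedding, "CellEmbedding"))
    co <- embedding@coords
    n <- nrow(co)
    if (nNeighbors >= n)
        stop("nNeighbors (", nNeighbors, ") must be smaller than the number",
             " of cells (", n, ")")
    nn <- RANN::nn2(co, k = nNeighbors + 1)$nn.idx[, -1, drop = FALSE]
    edges <- cbind(rep(seq_len(n), times = nNeighbors), as.vector(nn))
    g <- igraph::simplify(igraph::graph_from_edgelist(edges, directed = FALSE))
    cl <- withSeed(seed, igraph::cluster_leiden(
        g, objective_function = "modularity", resolution = resolution,
        n_iterations = 5))
    lab <- as.integer(igraph::membership(cl))
    sizes <- table(lab)
    remap <- stats::setNames(seq_along(sizes),
                             names(sort(sizes, decreasing = TRUE)))
    out <- remap[as.character(lab)]
    names(out) <- rownames(co)
    out
}
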