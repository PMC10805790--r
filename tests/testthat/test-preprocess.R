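test_that("filterCells keeps boundary cells and drops below-threshold cells", {
    # three cells: exactly at both thresholds; 49,999 counts with plenty of
    # genes; 50,000 counts but 399 genes
    nGenes <- 500
    m <- matrix(0L, nGenes, 3)
    m[1:400, 1] <- 125L            # 50,000 counts over exactly 400 genes
    m[1:500, 2] <- 99L; m[1, 2] <- 99L + (49999L - 49500L)  # 49,999 total
    m[1:399, 3] <- 125L; m[1, 3] <- 125L + 125L             # 50,000 / 399
    cm <- makeCounts(m)
    stopifnot(colSums(m)[1] == 50000, colSums(m > 0)[1] == 400,
              colSums(m)[2] == 49999, colSums(m)[3] == 50000,
              colSums(m > 0)[3] == 399)
    kept <- colnames(filterCells(cm))
    expect_identical(kept, "c001")
})

test_that("filterCells equals a brute-force per-cell loop and is idempotent", {
    sim <- simulateCounts(miniSpec(seed = 9, nPerStratum = 150,
                                   nGenes = 500, lowqRate = 0.2))
    cm <- sim$counts
    m <- as.matrix(counts(cm))
    survivors <- character()
    for (j in seq_len(ncol(m))) {
        if (sum(m[, j]) >= 50000 && sum(m[, j] > 0) >= 400)
            survivors <- c(survivors, colnames(m)[j])
    }
    filt <- filterCells(cm)
    expect_identical(colnames(filt), survivors)
    expect_identical(colnames(filterCells(filt)), survivors)
    # permutation invariance: same surviving set
    perm <- sample(ncol(cm))
    expect_setequal(colnames(filterCells(cm[, perm])), survivors)
    # empty input is legal
    expect_equal(ncol(filterCells(cm[, integer(0)])), 0L)
})

test_that("cpmNormalize scales every cell to one million", {
    one <- makeCounts(matrix(c(7L, 0L), 2, 1))
    expect_equal(cpmValues(cpmNormalize(one))[1, 1], 1e6)
    four <- makeCounts(matrix(c(3L, 3L, 3L, 3L), 4, 1))
    expect_equal(unname(cpmValues(cpmNormalize(four))[, 1]), rep(250000, 4))
    # random matrix: all column sums 1e6; within-cell ratios preserved
    set.seed(10)
    m <- matrix(rnbinom(600, mu = 40, size = 1), 30, 20)
    m[1, ] <- m[1, ] + 1L  # no zero-total cells
    cm <- cpmNormalize(makeCounts(m))
    expect_equal(unname(colSums(cpmValues(cm))), rep(1e6, 20),
                 tolerance = 1e-9)
    j <- 3
    nz <- which(m[, j] > 0)[1:2]
    expect_equal(cpmValues(cm)[nz[1], j] / cpmValues(cm)[nz[2], j],
                 m[nz[1], j] / m[nz[2], j])
    # zero-total cells are a precondition violation pointing at QC
    bad <- makeCounts(cbind(m[, 1], 0L))
    expect_error(cpmNormalize(bad), "filterCells")
})

test_that("Fano selection: arithmetic, toy case, and constant genes", {
    # gene A: values 0/4 (mean 2, var ~4); gene B: 1/3 (mean 2, var ~1);
    # gene C constant
    m <- rbind(A = c(0L, 4L, 0L, 4L), B = c(1L, 3L, 1L, 3L),
               C = c(2L, 2L, 2L, 2L), D = c(4L, 0L, 4L, 0L))
    cm <- cpmNormalize(makeCounts(m, genes = rownames(m), mouse = "m1"))
    expect_identical(selectFeatures(cm, nFeatures = 2,
                                    majorityFraction = 1)[1:2] |> sort(),
                     c("A", "D"))
    # a constant gene has Fano 0 on the raw scale and is never selected
    expect_false("C" %in% selectFeatures(cm, nFeatures = 3,
                                         majorityFraction = 1))
})

test_that("Fano majority vote equals an independent double-loop oracle", {
    sim <- simulateCounts(miniSpec(seed = 12, nPerStratum = 80,
                                   nGenes = 200))
    cm <- cpmNormalize(sim$counts)
    nFeatures <- 40
    got <- selectFeatures(cm, nFeatures = nFeatures)
    # oracle: per-mouse Fano ranks, then majority, then (support, median
    # Fano, symbol) ordering -- written independently of the implementation
    cpm <- cpmValues(cm)
    mice <- unique(colData(cm)$mouse_id)
    fano <- sapply(mice, function(ms) {
        sub <- cpm[, colData(cm)$mouse_id == ms, drop = FALSE]
        apply(sub, 1, function(v) if (mean(v) == 0) 0 else var(v) / mean(v))
    })
    topSets <- apply(fano, 2, function(f)
        rownames(fano)[order(-f, rownames(fano))][seq_len(nFeatures)])
    support <- rowSums(sapply(seq_along(mice),
                              function(i) rownames(fano) %in% topSets[, i]))
    names(support) <- rownames(fano)
    med <- apply(fano, 1, median)
    qual <- names(support)[support / length(mice) >= 0.5]
    oracle <- head(qual[order(-support[qual], -med[qual], qual)], nFeatures)
    expect_identical(got, oracle)
    # invariance to cell order and to mouse relabeling
    perm <- sample(ncol(cm))
    expect_identical(selectFeatures(cm[, perm], nFeatures = nFeatures), got)
    rel <- cm
    colData(rel)$mouse_id <- chartr("12", "89", colData(rel)$mouse_id)
    expect_identical(selectFeatures(rel, nFeatures = nFeatures), got)
})

test_that("PCA embedding: pseudocount, rank-1 case, eigen oracle, centering", {
    # value 0 maps to log10(0.1) = -1 before centering
    expect_equal(log10(0 + 0.1), -1)
    # one direction of variance: PC1 explains ~everything
    set.seed(13)
    base <- rnbinom(30, mu = 50, size = 5) + 1L
    scale_ <- rep(c(1L, 4L), each = 10)
    m <- outer(base, scale_)
    storage.mode(m) <- "integer"
    cm <- cpmNormalize(makeCounts(m))
    # CPM removes pure scale, so build variance along one gene instead
    m2 <- matrix(rep(base, 20), 30, 20)
    m2[1, ] <- rep(c(5L, 400L), each = 10)
    storage.mode(m2) <- "integer"
    cm2 <- cpmNormalize(makeCounts(m2))
    e <- embedPCA(cm2, rownames(cm2), nPCs = 5)
    expect_gt(e@varExplained[1], 0.95)
    # scores are centered
    expect_true(all(abs(colMeans(embeddingCoords(e))) < 1e-8))
    # explained variance matches a dense eigendecomposition
    sim <- simulateCounts(miniSpec(seed = 14, nPerStratum = 25, nGenes = 200))
    cmx <- cpmNormalize(sim$counts)
    feats <- rownames(cmx)[1:60]
    emb <- embedPCA(cmx, feats, nPCs = 10)
    lx <- t(log10(cpmValues(cmx)[feats, ] + 0.1))
    ev <- eigen(cov(lx), symmetric = TRUE)$values
    expect_equal(emb@varExplained,
                 (ev / sum(ev))[1:10], tolerance = 1e-8)
    # parameter validation
    expect_error(embedPCA(cmx, feats, nPCs = 60), "nPCs")
    expect_error(embedPCA(cmx, c(feats, "nope")), "absent")
})

test_that("t-SNE is deterministic, 2-D, and separates distinct subtypes", {
    sim <- simulateCounts(miniSpec(seed = 15, nPerStratum = 60, nGenes = 150))
    cm <- cpmNormalize(sim$counts)
    e <- embedPCA(cm, selectFeatures(cm, 80), nPCs = 10)
    y1 <- embedTSNE(e, seed = 42)
    y2 <- embedTSNE(e, seed = 42)
    expect_identical(y1, y2)
    expect_identical(dim(y1), c(nrow(embeddingCoords(e)), 2L))
    tr <- sim$truth$cells
    sub <- tr$true_subtype[match(rownames(y1), tr$cell_id)]
    centd <- function(s) colMeans(y1[sub == s, , drop = FALSE])
    inter <- sqrt(sum((centd("TypeA") - centd("TypeB"))^2))
    intra <- mean(sqrt(rowSums(sweep(y1[sub == "TypeA", ], 2,
                                     centd("TypeA"))^2)))
    expect_gt(inter, intra)
})
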