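test_that("Leiden recovers well-separated point clouds deterministically", {
    set.seed(21)
    co <- rbind(matrix(rnorm(120 * 5), 120, 5),
                matrix(rnorm(80 * 5, mean = 30), 80, 5))
    rownames(co) <- sprintf("c%03d", 1:200)
    emb <- new("CellEmbedding", coords = co, featureGenes = character(),
               varExplained = rep(0.2, 5), params = list(),
               source = character())
    cl <- clusterLeiden(emb, nNeighbors = 10, resolution = 0.3, seed = 7)
    expect_equal(length(unique(cl)), 2L)
    # labels renumbered by decreasing size: the 120-cloud is cluster 1
    expect_true(all(cl[1:120] == 1L) && all(cl[121:200] == 2L))
    expect_identical(clusterLeiden(emb, nNeighbors = 10, resolution = 0.3, seed = 7), cl)
    expect_error(clusterLeiden(emb, nNeighbors = 300), "smaller")
    # permutation of cells changes nothing but the order of the labels
    perm <- sample(200)
    emb2 <- new("CellEmbedding", coords = co[perm, ],
                featureGenes = character(), varExplained = rep(0.2, 5),
                params = list(), source = character())
    cl2 <- clusterLeiden(emb2, nNeighbors = 10, resolution = 0.3, seed = 7)
    expect_identical(cl2[names(cl)], cl)
})

test_that("doublet flagging: coexpression rule and small-cluster rule", {
    mm <- markerMatrix(list(c("Adh1", "Wnt2"), c("Pdgfrb", "Cox4i2")))
    cm <- mm$cm
    # no cell coexpresses: nothing flagged
    expect_false(any(flagDoublets(cm, mm$labels, minClusterSize = 5)))
    # inject a cell expressing both Adh1 and Pdgfrb above threshold
    m <- as.matrix(counts(cm))
    m[c("Adh1", "Pdgfrb"), 1] <- 500L
    cm2 <- cpmNormalize(makeCounts(m, genes = rownames(m)))
    fl <- flagDoublets(cm2, mm$labels, minClusterSize = 5)
    expect_true(fl[[1]])
    expect_equal(sum(fl), 1L)
    # cells in clusters below minClusterSize are flagged wholesale
    lab <- mm$labels
    lab[1:3] <- 99L
    fl <- flagDoublets(cm, lab, minClusterSize = 5)
    expect_true(all(fl[1:3]))
    expect_false(any(fl[-(1:3)]))
})

test_that("marker rules assign subtypes per the Hhip/Pdgfra logic", {
    mm <- markerMatrix(list(
        c("Tgfbi", "Hhip"),                    # early ASM
        c("Tgfbi", "Hhip", "Pdgfra"),          # ASM/MyoF precursor
        c("Tgfbi", "Pdgfra", "Mki67"),         # proliferating MyoF
        c("Acta1", "Tubb3"),                   # emergent Acta1+ population
        c("Adh1", "Col13a1", "Wnt2")))         # alveolar fibroblast
    ann <- assignSubtypes(mm$cm, mm$labels)
    bycl <- ann$subtype[!duplicated(ann$cluster_id)][order(unique(ann$cluster_id))]
    expect_identical(bycl, c("Early ASM", "ASM/MyoF precursor",
                             "Proliferating myofibroblast", "HA-novel-1",
                             "Alveolar fibroblast"))
    expect_true(all(ann$proliferating[ann$cluster_id == 3]))
    expect_false(any(ann$proliferating[ann$cluster_id != 3]))
    expect_identical(unique(ann$group[ann$cluster_id == 4]), "novel")
    # doublet cells lose their subtype
    dbl <- stats::setNames(seq_len(nrow(ann)) == 1, ann$cell_id)
    ann2 <- assignSubtypes(mm$cm, mm$labels, doublets = dbl)
    expect_true(is.na(ann2$subtype[1]))
    expect_identical(ann2$group[1], "doublet")
    expect_error(assignSubtypes(mm$cm, mm$labels,
                                rules = defaultMarkerRules()[0, ]),
                 "empty rule")
})

test_that("subtype assignment is a pure function of cluster summaries", {
    mm <- markerMatrix(list(c("Tgfbi", "Hhip"), c("Adh1", "Col14a1")))
    ann <- assignSubtypes(mm$cm, mm$labels)
    # permute cells within clusters: per-cluster labels must not change
    perm <- unlist(lapply(split(seq_along(mm$labels), mm$labels), sample))
    cm2 <- mm$cm[, perm]
    ann2 <- assignSubtypes(cm2, mm$labels[perm])
    merged <- merge(ann, ann2, by = "cell_id")
    expect_true(all(merged$subtype.x == merged$subtype.y))
})

test_that("harmonized embedding co-locates same-subtype cells across sources", {
    q <- simulateCounts(miniSpec(seed = 31, nPerStratum = 80, nGenes = 250))
    a <- simulateCounts(miniSpec(seed = 32, nPerStratum = 80, nGenes = 250))
    joint <- harmonizeEmbed(q$counts, a$counts, k = 10, nFeatures = 120,
                            nPCs = 10)
    src <- embeddingSource(joint)
    expect_equal(sort(unique(src)), c("atlas", "query"))
    expect_equal(length(src), nrow(embeddingCoords(joint)))
    co <- embeddingCoords(joint)
    truthOf <- function(sim, prefix) {
        tr <- sim$truth$cells
        stats::setNames(tr$true_subtype, paste0(prefix, ":", tr$cell_id))
    }
    sub <- c(truthOf(q, "query"), truthOf(a, "atlas"))[rownames(co)]
    for (ty in c("TypeA", "TypeB", "TypeC")) {
        qi <- which(sub == ty & src == "query")
        ai <- which(sub == ty & src == "atlas")
        inter <- sqrt(sum((colMeans(co[qi, , drop = FALSE]) -
                           colMeans(co[ai, , drop = FALSE]))^2))
        intra <- mean(sqrt(rowSums(sweep(co[qi, , drop = FALSE], 2,
                                         colMeans(co[qi, , drop = FALSE]))^2)))
        expect_lt(inter, 1.5 * intra)
    }
    # k = 0 degenerates to plain joint PCA (no smoothing)
    j0 <- harmonizeEmbed(q$counts, a$counts, k = 0, nFeatures = 120,
                         nPCs = 10)
    expect_false(identical(embeddingCoords(j0), co))
    expect_equal(dim(embeddingCoords(j0)), dim(co))
    expect_error(harmonizeEmbed(q$counts[1:5, ], a$counts[6:10, ], k = 0),
                 "no genes")
})

test_that("ellipse reannotation equals explicit Mahalanobis computation", {
    set.seed(41)
    n <- 100
    co <- cbind(rnorm(n, sd = 2), rnorm(n), rnorm(n, sd = 0.5))
    co[1:50, 1] <- co[1:50, 1] + 1
    rownames(co) <- sprintf("c%03d", seq_len(n))
    joint <- new("CellEmbedding", coords = co, featureGenes = character(),
                 varExplained = c(0.5, 0.3, 0.2),
                 params = list(), source = rep(c("query", "atlas"), each = 50))
    focal <- rownames(co)[1:50]
    other <- rownames(co)[51:100]
    got <- ellipseReannotate(joint, focal, other, nDims = 2,
                             expansion = 1.2, quantile = 0.9)
    # oracle: explicit inverse-covariance quadratic form per point
    f <- co[focal, 1:2]
    mu <- colMeans(f)
    Sinv <- solve(cov(f))
    r2 <- (1.2 * sqrt(qchisq(0.9, 2)))^2
    oracle <- other[vapply(other, function(id) {
        d <- co[id, 1:2] - mu
        drop(t(d) %*% Sinv %*% d) <= r2
    }, logical(1))]
    expect_identical(got, oracle)
    # membership is monotone in expansion; infinite expansion catches all
    prev <- character()
    for (ex in c(1, 1.5, 2, 4, 1e6)) {
        cur <- ellipseReannotate(joint, focal, other, expansion = ex)
        expect_true(all(prev %in% cur))
        prev <- cur
    }
    expect_setequal(prev, other)
    # a point at the focal mean is always inside
    co2 <- rbind(co, center = c(mu, 0))
    joint2 <- new("CellEmbedding", coords = co2,
                  featureGenes = character(), varExplained = c(0.5, 0.3, 0.2),
                  params = list(), source = character())
    expect_identical(ellipseReannotate(joint2, focal, "center"), "center")
    expect_error(ellipseReannotate(joint, focal[1:2], other), "focal")
})
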