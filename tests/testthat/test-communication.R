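test_that("detection threshold is inclusive and respects absent genes", {
    toy <- toyPopulations(list(La = c(10, 0), Ra = c(0, 10),
                               Lb = c(2, 0), Rb = c(0, 2),
                               Lc = c(1, 0), Rc = c(0, 10)))
    db <- LRPairs(data.frame(pair_id = c("full", "boundary", "below", "ghost"),
                             ligand_gene = c("La", "Lb", "Lc", "La"),
                             receptor_gene = c("Ra", "Rb", "Rc", "Missing")))
    res <- detectInteractions(toy$cm, toy$ann, db, "TypeS", "TypeT",
                              "P7", "normoxia")
    expect_true(res$detected[res$pair_id == "full"])
    # exactly 20% expressing on both sides: "at least 20%" is inclusive
    expect_equal(res$frac_ligand[res$pair_id == "boundary"], 0.2)
    expect_true(res$detected[res$pair_id == "boundary"])
    expect_false(res$detected[res$pair_id == "below"])
    # a gene absent from the matrix counts as 0% expressing
    expect_equal(res$frac_receptor[res$pair_id == "ghost"], 0)
    expect_false(res$detected[res$pair_id == "ghost"])
    expect_error(detectInteractions(toy$cm, toy$ann, db, "Nobody", "TypeT",
                                    "P7", "normoxia"), "Nobody")
})

test_that("detected set equals a brute-force double loop over pairs/cells", {
    set.seed(72)
    pattern <- list()
    for (i in 1:30) {
        pattern[[paste0("L", i)]] <- c(sample(0:10, 1), 0)
        pattern[[paste0("R", i)]] <- c(0, sample(0:10, 1))
    }
    toy <- toyPopulations(pattern)
    db <- LRPairs(data.frame(pair_id = paste0("pr", 1:30),
                             ligand_gene = paste0("L", 1:30),
                             receptor_gene = paste0("R", 1:30)))
    res <- detectInteractions(toy$cm, toy$ann, db, "TypeS", "TypeT",
                              "P7", "normoxia")
    cpm <- cpmValues(toy$cm)
    srcCells <- toy$ann$cell_id[toy$ann$subtype == "TypeS"]
    tgtCells <- toy$ann$cell_id[toy$ann$subtype == "TypeT"]
    for (i in 1:30) {
        nL <- 0
        for (cc in srcCells) if (cpm[paste0("L", i), cc] > 0) nL <- nL + 1
        nR <- 0
        for (cc in tgtCells) if (cpm[paste0("R", i), cc] > 0) nR <- nR + 1
        expect_equal(res$detected[i],
                     nL / length(srcCells) >= 0.2 &&
                     nR / length(tgtCells) >= 0.2)
    }
    # detected count never increases as the threshold rises
    counts <- vapply(seq(0.05, 0.95, by = 0.05), function(th)
        sum(detectInteractions(toy$cm, toy$ann, db, "TypeS", "TypeT",
                               "P7", "normoxia",
                               threshold = th)$detected), numeric(1))
    expect_true(all(diff(counts) <= 0))
    # swapping (source,target) with (ligand,receptor) leaves detection
    dbSwap <- LRPairs(data.frame(pair_id = paste0("pr", 1:30),
                                 ligand_gene = paste0("R", 1:30),
                                 receptor_gene = paste0("L", 1:30)))
    resSwap <- detectInteractions(toy$cm, toy$ann, dbSwap, "TypeT", "TypeS",
                                  "P7", "normoxia")
    expect_identical(resSwap$detected, res$detected)
})

test_that("interaction strength is the abundance-weighted expression product", {
    # hand toy: ligand mean 100 CPM at source prop 0.2, receptor mean 50
    # CPM at target prop 0.1 gives 100*0.2 * 50*0.1 = 100
    ann <- data.frame(cell_id = sprintf("c%03d", 1:20), cluster_id = 1L,
                      group = "g",
                      subtype = rep(c("S", "T", "U"), c(4, 2, 14)),
                      proliferating = FALSE, doublet = FALSE,
                      timepoint = "P7", condition = "normoxia",
                      stringsAsFactors = FALSE)
    # counts chosen so each cell totals exactly 1e6 and CPM equals counts
    m <- matrix(0L, 3, 20,
                dimnames = list(c("Lig", "Rec", "Bulk"), ann$cell_id))
    m["Lig", 1:4] <- 100L
    m["Rec", 5:6] <- 50L
    m["Bulk", ] <- 1000000L - colSums(m[c("Lig", "Rec"), , drop = FALSE])
    cm <- cpmNormalize(makeCounts(m, genes = rownames(m),
                                  cells = ann$cell_id))
    got <- interactionStrength(cm, ann, "Lig", "Rec", "S", "T",
                               "P7", "normoxia")
    expect_equal(got, (100 * 0.2) * (50 * 0.1))
    # source-only abundance variant
    gotS <- interactionStrength(cm, ann, "Lig", "Rec", "S", "T",
                                "P7", "normoxia", abundanceMode = "source")
    expect_equal(gotS, (100 * 0.2) * 50)
    # zero expression on either side gives zero strength
    expect_equal(interactionStrength(cm, ann, "Lig", "Bulk", "S", "U",
                                     "P7", "normoxia") > 0, TRUE)
    expect_equal(interactionStrength(cm, ann, "Rec", "Rec", "S", "T",
                                     "P7", "normoxia"), 0)
})

test_that("strength scales quadratically when diluted by unrelated cells", {
    toy <- toyPopulations(list(La = c(10, 0), Ra = c(0, 10)), nOther = 5)
    s1 <- interactionStrength(toy$cm, toy$ann, "La", "Ra", "TypeS", "TypeT",
                              "P7", "normoxia")
    # add 25 unrelated cells with zero La/Ra: both proportions shrink by
    # the same factor, so strength shrinks by that factor squared
    toy2 <- toyPopulations(list(La = c(10, 0), Ra = c(0, 10)), nOther = 30)
    s2 <- interactionStrength(toy2$cm, toy2$ann, "La", "Ra", "TypeS",
                              "TypeT", "P7", "normoxia")
    f <- (10 / 50) / (10 / 25)
    expect_equal(s2 / s1, f^2, tolerance = 1e-6)
})

test_that("interaction counting groups detected records", {
    empty <- detectInteractions(
        toyPopulations(list(La = c(10, 0)))$cm,
        toyPopulations(list(La = c(10, 0)))$ann,
        LRPairs(data.frame(pair_id = character(), ligand_gene = character(),
                           receptor_gene = character())),
        "TypeS", "TypeT", "P7", "normoxia")
    expect_equal(nrow(countInteractions(empty)), 0L)
    toy <- toyPopulations(list(La = c(10, 0), Ra = c(0, 10),
                               Lb = c(9, 0), Rb = c(0, 9),
                               Lc = c(8, 0), Rc = c(0, 8)))
    db <- LRPairs(data.frame(pair_id = c("p1", "p2", "p3"),
                             ligand_gene = c("La", "Lb", "Lc"),
                             receptor_gene = c("Ra", "Rb", "Rc")))
    tab <- rbind(
        detectInteractions(toy$cm, toy$ann, db, "TypeS", "TypeT",
                           "P7", "normoxia"),
        detectInteractions(toy$cm, toy$ann, db, "TypeS", "TypeU",
                           "P7", "normoxia"))
    cnt <- countInteractions(tab)
    expect_equal(cnt$n_detected[cnt$target_type == "TypeT"], 3L)
    # oracle: filter-then-count
    expect_equal(cnt$n_detected,
                 as.integer(tapply(tab$detected, tab$target_type, sum)[
                     cnt$target_type]))
})
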