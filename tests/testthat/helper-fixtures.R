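# Fixtures are built in code; nothing is read from disk except files the
# tests themselves write to tempdir().

# Deterministic small count object with complete metadata.
makeCounts <- function(counts, timepoint = "P7", condition = "normoxia",
                       mouse = c("m1", "m2"), genes = NULL, cells = NULL) {
    counts <- as.matrix(counts)
    if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(counts)))
    if (is.null(cells)) cells <- sprintf("c%03d", seq_len(ncol(counts)))
    n <- ncol(counts)
    meta <- data.frame(
        mouse_id = rep_len(mouse, n),
        timepoint = rep_len(timepoint, n),
        condition = rep_len(condition, n),
        sex = rep_len(c("F", "M"), n),
        stringsAsFactors = FALSE)
    dimnames(counts) <- list(genes, cells)
    MesenchymeCounts(counts, meta)
}

# Three-subtype generator spec for fast recovery tests.
miniSpec <- function(seed = 1L, nPerStratum = 300L, nGenes = 300L,
                     doubletRate = 0, lowqRate = 0, ...) {
    subtypes <- list(
        subtypeSpec("TypeA", c("Adh1", "Wnt2")),
        subtypeSpec("TypeB", c("Tgfbi", "Hhip")),
        subtypeSpec("TypeC", c("Pdgfrb", "Cox4i2")))
    comp <- c(TypeA = 0.5, TypeB = 0.3, TypeC = 0.2)
    simSpec(subtypes,
            composition = list("P1|normoxia" = comp, "P7|normoxia" = comp),
            nCells = c("P1|normoxia" = nPerStratum,
                       "P7|normoxia" = nPerStratum),
            nGenes = nGenes, doubletRate = doubletRate, lowqRate = lowqRate,
            seed = seed, ...)
}

# Two-subtype spec with progression genes in the focal type, for the
# developmental-arrest analyses (arrest on/off via progressionInHyperoxia).
progSpec <- function(seed = 1L, progressionInHyperoxia = FALSE,
                     nPerStratum = 300L) {
    subtypes <- list(subtypeSpec("Focal", "Adh1"),
                     subtypeSpec("Other", "Tgfbi"))
    comp <- c(Focal = 0.6, Other = 0.4)
    strata <- c("P1|normoxia", "P7|normoxia", "P7|hyperoxia")
    simSpec(subtypes,
            composition = stats::setNames(rep(list(comp), 3), strata),
            nCells = stats::setNames(rep(nPerStratum, 3), strata),
            nGenes = 600L,
            progressionGenes = list(Focal = sprintf("Prog%02d", 1:12)),
            progressionInHyperoxia = progressionInHyperoxia, seed = seed)
}

# Ground-truth annotation table (bypasses clustering) for a simulation.
truthAnnotation <- function(sim) {
    cm <- sim$counts
    tr <- sim$truth$cells
    i <- match(colnames(cm), tr$cell_id)
    cd <- SummarizedExperiment::colData(cm)
    data.frame(cell_id = colnames(cm),
               cluster_id = as.integer(factor(tr$true_subtype[i])),
               group = "unused",
               subtype = tr$true_subtype[i],
               proliferating = FALSE,
               doublet = tr$is_doublet[i],
               timepoint = cd$timepoint,
               condition = cd$condition,
               stringsAsFactors = FALSE)
}

# Build a matrix whose clusters have prescribed marker expression: marker
# genes get high counts in their cluster and zero elsewhere, on top of a
# shared filler baseline.
markerMatrix <- function(clusterMarkers, nPerCluster = 20, nFiller = 100,
                         markerCount = 1000L, seed = 1) {
    set.seed(seed)
    genes <- unique(unlist(clusterMarkers))
    nc <- length(clusterMarkers) * nPerCluster
    m <- rbind(
        matrix(0L, length(genes), nc, dimnames = list(genes, NULL)),
        matrix(rnbinom(nFiller * nc, mu = 20, size = 5) + 1L, nFiller, nc,
               dimnames = list(sprintf("f%03d", seq_len(nFiller)), NULL)))
    lab <- rep(seq_along(clusterMarkers), each = nPerCluster)
    for (k in seq_along(clusterMarkers))
        m[clusterMarkers[[k]], lab == k] <- markerCount
    cm <- cpmNormalize(makeCounts(m, genes = rownames(m)))
    list(cm = cm, labels = stats::setNames(lab, colnames(cm)))
}

# Independent two-sample KS statistic: exhaustive ECDF evaluation at every
# pooled point (the brute-force oracle the package implementation is
# checked against).
bruteKS <- function(a, b) {
    pts <- sort(unique(c(a, b)))
    max(abs(vapply(pts, function(t) mean(a <= t) - mean(b <= t),
                   numeric(1))))
}

# Toy stratum: 10 source (TypeS) and 10 target (TypeT) cells plus 5
# bystanders (TypeU), with per-gene expressing-cell counts set explicitly.
toyPopulations <- function(exprPattern, nSrc = 10, nTgt = 10, nOther = 5) {
    genes <- names(exprPattern)
    n <- nSrc + nTgt + nOther
    # constant filler keeps per-cell totals (hence CPM) identical across
    # toys that differ only in bystander count
    filler <- matrix(30L, 50, n, dimnames = list(sprintf("f%03d", 1:50), NULL))
    m <- rbind(matrix(0L, length(genes), n, dimnames = list(genes, NULL)),
               filler)
    src <- seq_len(nSrc); tgt <- nSrc + seq_len(nTgt)
    for (g in genes) {
        m[g, src[seq_len(exprPattern[[g]][1])]] <- 200L
        m[g, tgt[seq_len(exprPattern[[g]][2])]] <- 200L
    }
    cm <- cpmNormalize(makeCounts(m, genes = rownames(m)))
    ann <- data.frame(cell_id = colnames(cm), cluster_id = 1L,
                      group = rep(c("mesench", "mesench", "other"),
                                  c(nSrc, nTgt, nOther)),
                      subtype = rep(c("TypeS", "TypeT", "TypeU"),
                                    c(nSrc, nTgt, nOther)),
                      proliferating = FALSE, doublet = FALSE,
                      timepoint = "P7", condition = "normoxia",
                      stringsAsFactors = FALSE)
    list(cm = cm, ann = ann)
}

# Embed two groups of expression values for one gene in a CPM-ready object:
# gene "target" carries the values; a constant filler gene absorbs the rest
# of the library so CPM of "target" is proportional to the input values.
twoGroupObject <- function(valsA, valsB) {
    v <- c(valsA, valsB)
    m <- rbind(target = as.integer(v), filler = as.integer(1e5 - v))
    cm <- makeCounts(m, genes = rownames(m))
    list(cm = cpmNormalize(cm),
         A = colnames(cm)[seq_along(valsA)],
         B = colnames(cm)[length(valsA) + seq_along(valsB)])
}
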