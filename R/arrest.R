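#' Cell-subtype composition of a stratum
#'
#' Proportions of each subtype among the non-doublet cells of one
#' (timepoint, condition) stratum. Subtypes absent from the stratum get
#' proportion 0, so profiles from different strata are directly comparable.
#'
#' @param ann annotation data.frame (from \code{\link{assignSubtypes}}, or
#'   any data.frame with \code{subtype}, \code{doublet}, \code{timepoint},
#'   \code{condition} columns)
#' @param timepoint,condition the stratum
#' @param subtypes the subtype universe (default: all non-doublet subtypes
#'   present anywhere in \code{ann})
#' @return list with \code{proportions} (named numeric summing to 1),
#'   \code{n} (cells used), \code{timepoint}, \code{condition}
#' @export
compositionProfile <- function(ann, timepoint, condition, subtypes = NULL) {
    if (is.null(subtypes))
        subtypes <- sort(unique(ann$subtype[!ann$doublet & !is.na(ann$subtype)]))
    use <- !ann$doublet & !is.na(ann$subtype) &
        stratumIndex(ann, timepoint, condition)
    if (!any(use))
        stop("no non-doublet cells in stratum (", timepoint, ", ",
             condition, ")")
    counts <- table(factor(ann$subtype[use], levels = subtypes))
    list(proportions = stats::setNames(as.numeric(counts) / sum(counts),
                                       subtypes),
         n = sum(use), timepoint = timepoint, condition = condition)
}

#' Total variation distance between two composition vectors
#'
#' Half the L1 distance between two probability vectors: the canonical
#' compositional distance, in [0, 1], zero iff equal. Named vectors are
#' aligned on the union of their names (absent entries count 0).
#'
#' @param p,q probability vectors (or \code{compositionProfile} results)
#' @return the distance, a number in [0, 1]
#' @export
totalVariation <- function(p, q) {
    if (is.list(p)) p <- p$proportions
    if (is.list(q)) q <- q$proportions
    if (!is.null(names(p)) && !is.null(names(q)) &&
        !identical(names(p), names(q))) {
        u <- union(names(p), names(q))
        p <- stats::setNames(p[u], u); p[is.na(p)] <- 0
        q <- stats::setNames(q[u], u); q[is.na(q)] <- 0
    }
    sum(abs(p - q)) / 2
}

compDistance <- function(p, q, distance) {
    if (distance == "tv") totalVariation(p, q)
    else sqrt(sum((p - q)^2))
}

#' Bootstrap test for compositional developmental arrest
#'
#' Asks whether a focal stratum's cell-subtype composition is closer to an
#' early reference than to a late one. Per bootstrap replicate, \code{n}
#' cells (the smallest stratum size, so every stratum is equally
#' represented) are resampled with replacement independently from each of
#' the three strata; the replicate records
#' \code{diff = d(focal, refLate) - d(focal, refEarly)} with \code{d} the
#' total variation distance by default. A positive difference means the
#' focal composition is closer to the early reference. The empirical P is
#' the fraction of replicates with \code{diff <= 0} (focal at least as
#' close to the late reference); ties count against the arrest hypothesis.
#'
#' @param ann annotation data.frame (see \code{\link{compositionProfile}})
#' @param focal,refEarly,refLate strata as \code{c(timepoint, condition)};
#'   defaults encode the hyperoxia-P7 vs P1/P7-normoxia comparison
#' @param B number of bootstrap replicates (default 1000)
#' @param seed integer seed
#' @param distance \code{"tv"} (total variation, default) or
#'   \code{"euclidean"}
#' @param subtypes optional subtype universe for the composition vectors
#' @return list with \code{diffs} (length B), \code{empirical_p}, \code{B},
#'   \code{n} (per-stratum resample size), \code{seed},
#'   \code{distance_name}
#' @export
bootstrapArrest <- function(ann, focal = c("P7", "hyperoxia"),
                            refEarly = c("P1", "normoxia"),
                            refLate = c("P7", "normoxia"),
                            B = 1000, seed = 1L,
                            distance = c("tv", "euclidean"),
                            subtypes = NULL) {
    distance <- match.arg(distance)
    if (B < 1) stop("B must be at least 1")
    if (is.null(subtypes))
        subtypes <- sort(unique(ann$subtype[!ann$doublet & !is.na(ann$subtype)]))
    pull <- function(stratum) {
        use <- !ann$doublet & !is.na(ann$subtype) &
            stratumIndex(ann, stratum[1], stratum[2])
        if (!any(use))
            stop("no non-doublet cells in stratum (", stratum[1], ", ",
                 stratum[2], ")")
        factor(ann$subtype[use], levels = subtypes)
    }
    sf <- pull(focal); se <- pull(refEarly); sl <- pull(refLate)
    n <- min(length(sf), length(se), length(sl))
    k <- length(subtypes)
    # each stratum gets its own seed stream (derived from the stratum key,
    # not from its role), so exchanging the two references reuses exactly
    # the same resamples and negates every replicate's difference
    resample <- function(fac, stratum) {
        sub <- (sum(utf8ToInt(paste(stratum, collapse = "|"))) * 131) %%
            1000003L
        withSeed((seed + sub) %% .Machine$integer.max,
                 matrix(sample(as.integer(fac), n * B, replace = TRUE),
                        nrow = B))
    }
    rf <- resample(sf, focal)
    re <- resample(se, refEarly)
    rl <- resample(sl, refLate)
    diffs <- vapply(seq_len(B), function(i) {
        pf <- tabulate(rf[i, ], k) / n
        pe <- tabulate(re[i, ], k) / n
        pl <- tabulate(rl[i, ], k) / n
        compDistance(pf, pl, distance) - compDistance(pf, pe, distance)
    }, numeric(1))
    list(diffs = diffs, empirical_p = mean(diffs <= 0), B = as.integer(B),
         n = n, seed = as.integer(seed), distance_name = distance)
}

#' Progression-gene arrest within a cell type
#'
#' Identifies the cell type's "progression genes" -- genes up-regulated at
#' P7 versus P1 in normoxia (signed KS > 0 and KS statistic at least
#' \code{ksMin}) -- and scores, for each, the hyperoxia effect as the
#' signed KS of hyperoxia-P7 versus normoxia-P7 expression. The arrest
#' fraction is the share of progression genes whose hyperoxia effect is
#' negative, i.e. whose developmental up-regulation hyperoxia suppressed.
#'
#' @param x a CPM-normalized \linkS4class{MesenchymeCounts}
#' @param ann annotation data.frame aligned with \code{x} (cell ids)
#' @param cellType subtype to interrogate; must be present in normoxia P1,
#'   normoxia P7 and hyperoxia P7
#' @param ksMin KS floor defining progression (default 0.3)
#' @param genes optional gene subset to scan (default all)
#' @return list with \code{cell_type}, \code{progression_genes},
#'   \code{table} (per progression gene: \code{normoxia_progress_ks},
#'   \code{hyperoxia_effect_ks}) and \code{arrest_fraction} (NA when no
#'   gene passes \code{ksMin})
#' @export
progressionArrest <- function(x, ann, cellType, ksMin = 0.3, genes = NULL) {
    stopifnot(identical(ann$cell_id, colnames(x)))
    pick <- function(timepoint, condition) {
        use <- !ann$doublet & !is.na(ann$subtype) &
            ann$subtype == cellType &
            stratumIndex(ann, timepoint, condition)
        if (sum(use) < 2)
            stop("cell type '", cellType, "' has fewer than 2 cells in ",
                 "stratum (", timepoint, ", ", condition, ")")
        ann$cell_id[use]
    }
    p1n <- pick("P1", "normoxia")
    p7n <- pick("P7", "normoxia")
    p7h <- pick("P7", "hyperoxia")
    de <- ksDE(x, p7n, p1n, genes = genes)
    prog <- de[de$signed_ks > 0 & de$ks_stat >= ksMin, , drop = FALSE]
    if (!nrow(prog))
        return(list(cell_type = cellType, progression_genes = character(),
                    table = data.frame(), arrest_fraction = NA_real_))
    eff <- ksDE(x, p7h, p7n, genes = prog$gene)
    tab <- data.frame(gene = prog$gene,
                      normoxia_progress_ks = prog$signed_ks,
                      hyperoxia_effect_ks = eff$signed_ks,
                      stringsAsFactors = FALSE, row.names = NULL)
    list(cell_type = cellType, progression_genes = prog$gene, table = tab,
         arrest_fraction = mean(tab$hyperoxia_effect_ks < 0))
}
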