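#' Default incompatible marker pairs for doublet detection
#'
#' Pairs of gene sets that no single mesenchymal subtype coexpresses: the
#' three broad group markers against each other (Adh1 fibroblasts, Tgfbi
#' ASM/MyoF, Pdgfrb mural), the Acta1 panel against all three groups, and
#' within-group pairs that separate subtypes (e.g. Wnt2 alveolar vs Col14a1
#' adventitial identity, Cox4i2 pericytes vs Tagln smooth muscle, Mki67
#' against markers of the non-proliferating subtypes). A cell coexpressing
#' both sides of any pair is an artifactual library from two cells.
#'
#' @return list of two-sided gene-set pairs (each a list with elements
#'   \code{a} and \code{b})
#' @seealso \code{\link{flagDoublets}}
#' @export
defaultIncompatiblePairs <- function() {
    pair <- function(a, b) list(a = a, b = b)
    list(
        pair("Adh1", "Tgfbi"),
        pair("Adh1", "Pdgfrb"),
        pair("Tgfbi", "Pdgfrb"),
        pair("Acta1", c("Adh1", "Tgfbi", "Pdgfrb")),
        pair("Wnt2", c("Col14a1", "Mest")),
        pair("Hsd11b1", c("Wnt2", "Mest", "Mki67")),
        pair("Mki67", c("Wnt2", "Mest", "Col14a1", "Hhip", "Acta2", "Tagln")),
        pair("Cox4i2", "Tagln"),
        pair("Acta2", "Pdgfra"))
}

#' Flag doublets by small clusters and incompatible marker coexpression
#'
#' A cell is flagged as a doublet if (a) its cluster has fewer than
#' \code{minClusterSize} cells, or (b) it expresses (CPM above
#' \code{cpmThreshold}) at least one gene from each side of any incompatible
#' marker pair.
#'
#' @param x a CPM-normalized \linkS4class{MesenchymeCounts}
#' @param clusters integer cluster labels named by cell id
#'   (from \code{\link{clusterLeiden}})
#' @param incompatiblePairs list of two-sided gene-set pairs
#'   (default \code{\link{defaultIncompatiblePairs}})
#' @param minClusterSize clusters smaller than this are discarded whole
#'   (default 10)
#' @param cpmThreshold per-marker expression threshold (default 100 CPM)
#' @return logical vector named by cell id; TRUE = doublet
#' @export
flagDoublets <- function(x, clusters,
                         incompatiblePairs = defaultIncompatiblePairs(),
                         minClusterSize = 10, cpmThreshold = 100) {
    cpm <- cpmAssay(x)
    ids <- colnames(x)
    if (is.null(names(clusters)) || !setequal(names(clusters), ids))
        stop("cluster labels must cover all cells")
    clusters <- clusters[ids]
    sizes <- table(clusters)
    flag <- as.vector(sizes[as.character(clusters)] < minClusterSize)
    for (p in incompatiblePairs) {
        a <- intersect(p$a, rownames(cpm))
        b <- intersect(p$b, rownames(cpm))
        if (!length(a) || !length(b)) next
        hasA <- colSums(cpm[a, , drop = FALSE] > cpmThreshold) > 0
        hasB <- colSums(cpm[b, , drop = FALSE] > cpmThreshold) > 0
        flag <- flag | (hasA & hasB)
    }
    stats::setNames(flag, ids)
}

#' Shipped marker-rule table for mesenchymal subtype annotation
#'
#' One row per subtype: the broad group, required-positive genes and
#' required-negative genes (semicolon-separated). Rules are ordered most
#' specific first (more required genes), so the first match wins
#' deterministically. The logic encodes the field's marker conventions:
#' Adh1 marks fibroblasts, Tgfbi marks the ASM/MyoF group, Pdgfrb marks
#' mural cells; within groups, Hhip+/Pdgfra- is (early) ASM, Hhip-/Pdgfra+
#' is myofibroblast and Hhip+/Pdgfra+ their precursor; Col13a1 vs Col14a1
#' split alveolar from adventitial fibroblasts (coexpressed in embryonic
#' precursors); Tagln/Acta2 with Pdgfrb identify vascular smooth muscle;
#' Mki67 marks proliferating variants.
#'
#' @return data.frame with columns \code{subtype}, \code{group},
#'   \code{positive}, \code{negative}
#' @seealso \code{\link{assignSubtypes}}, \code{\link{readMarkerRules}}
#' @export
defaultMarkerRules <- function() {
    rule <- function(subtype, group, positive, negative = "")
        data.frame(subtype = subtype, group = group, positive = positive,
                   negative = negative, stringsAsFactors = FALSE)
    rbind(
        rule("Fibroblast precursor", "fibroblast",
             "Adh1;Col13a1;Col14a1;Hsd11b1"),
        rule("ASM/MyoF precursor", "ASM/MyoF", "Tgfbi;Hhip;Pdgfra"),
        rule("Proliferating myofibroblast", "ASM/MyoF",
             "Tgfbi;Pdgfra;Mki67", "Hhip"),
        rule("Proliferating pericyte", "mural", "Pdgfrb;Cox4i2;Mki67"),
        rule("Proliferating fibroblast", "fibroblast",
             "Adh1;Col13a1;Mki67", "Col14a1"),
        rule("Early alveolar fibroblast", "fibroblast",
             "Adh1;Col13a1;Mest", "Col14a1;Mki67"),
        rule("Early adventitial fibroblast", "fibroblast",
             "Adh1;Col14a1;Mest", "Col13a1;Mki67"),
        rule("Alveolar fibroblast", "fibroblast",
             "Adh1;Col13a1;Wnt2", "Col14a1;Mest;Mki67"),
        rule("VSM", "mural", "Pdgfrb;Tagln;Acta2", "Mki67"),
        rule("ASM", "ASM/MyoF", "Tgfbi;Hhip;Acta2", "Pdgfra;Pdgfrb;Mki67"),
        rule("Adventitial fibroblast", "fibroblast",
             "Adh1;Col14a1", "Col13a1;Mest;Mki67"),
        rule("Pericyte", "mural", "Pdgfrb;Cox4i2", "Tagln;Mki67"),
        rule("Early ASM", "ASM/MyoF", "Tgfbi;Hhip", "Pdgfra;Acta2;Mki67"),
        rule("Myofibroblast", "ASM/MyoF", "Tgfbi;Pdgfra", "Hhip;Mki67"))
}

#' Read / write a marker-rule table
#'
#' Tab-delimited with columns \code{subtype}, \code{group}, \code{positive},
#' \code{negative} (gene symbols semicolon-separated).
#'
#' @param path path to the TSV file
#' @return \code{readMarkerRules}: a rules data.frame
#' @export
readMarkerRules <- function(path) {
    r <- utils::read.delim(path, stringsAsFactors = FALSE,
                           comment.char = "#", check.names = FALSE)
    need <- c("subtype", "group", "positive", "negative")
    missing_cols <- setdiff(need, colnames(r))
    if (length(missing_cols))
        stop("rule table lacks column(s): ",
             paste(missing_cols, collapse = ", "))
    r$negative[is.na(r$negative)] <- ""
    r[, need]
}

#' @rdname readMarkerRules
#' @param rules a rules data.frame
#' @return \code{writeMarkerRules}: invisibly, \code{path}
#' @export
writeMarkerRules <- function(rules, path) {
    utils::write.table(rules, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

splitGenes <- function(s) {
    if (is.na(s) || !nzchar(s)) character() else strsplit(s, ";")[[1]]
}

#' Assign subtypes to clusters by marker rules
#'
#' Per cluster, a gene is "positive" if its mean CPM exceeds
#' \code{meanCpmThreshold} and the fraction of cells expressing it above
#' \code{exprFloor} CPM exceeds \code{fracThreshold}. The floor matters at
#' Smart-seq2 depth, where nearly every gene has at least one read in most
#' cells: counting only clearly expressing cells keeps a handful of
#' contaminating cells from switching a negative marker positive at the
#' cluster level. The cluster receives the first
#' rule (in table order) whose required-positive genes are all positive and
#' required-negative genes all non-positive. Clusters matching no rule but
#' positive for Acta1 are labeled \code{"HA-novel-k"} (hyperoxia-associated
#' Acta1+ populations); remaining unmatched clusters are
#' \code{"unassigned"}. A cluster is flagged proliferating iff Mki67 is
#' positive. Doublet cells receive no subtype and group \code{"doublet"};
#' cluster summaries are computed without them.
#'
#' @param x a CPM-normalized \linkS4class{MesenchymeCounts}
#' @param clusters integer cluster labels named by cell id
#' @param rules rules data.frame (default \code{\link{defaultMarkerRules}});
#'   rule genes absent from the matrix are treated as never positive
#' @param doublets optional logical vector named by cell id
#'   (from \code{\link{flagDoublets}})
#' @param meanCpmThreshold,fracThreshold cluster-level positivity knobs
#'   (defaults 50 CPM and 0.25)
#' @param exprFloor per-cell CPM floor for the expressing fraction
#'   (default 50)
#' @param novelPanel marker panel for the emergent Acta1+ populations
#' @return data.frame (one row per cell): \code{cell_id},
#'   \code{cluster_id}, \code{group}, \code{subtype}, \code{proliferating},
#'   \code{doublet}, plus the cell's \code{timepoint} and \code{condition}
#' @export
assignSubtypes <- function(x, clusters, rules = defaultMarkerRules(),
                           doublets = NULL, meanCpmThreshold = 50,
                           fracThreshold = 0.25, exprFloor = 50,
                           novelPanel = c("Acta1", "Tubb3", "Lgals3", "Aqp3")) {
    if (!nrow(rules)) stop("empty rule table")
    cpm <- cpmAssay(x)
    ids <- colnames(x)
    if (is.null(names(clusters)) || !setequal(names(clusters), ids))
        stop("cluster labels must cover all cells")
    clusters <- clusters[ids]
    if (is.null(doublets)) doublets <- stats::setNames(rep(FALSE, length(ids)), ids)
    doublets <- doublets[ids]
    ruleGenes <- lapply(seq_len(nrow(rules)), function(i)
        list(pos = splitGenes(rules$positive[i]),
             neg = splitGenes(rules$negative[i])))
    clUnique <- sort(unique(clusters))
    subtype <- stats::setNames(rep("unassigned", length(clUnique)),
                               clUnique)
    group <- stats::setNames(rep("novel", length(clUnique)), clUnique)
    prolif <- stats::setNames(rep(FALSE, length(clUnique)), clUnique)
    novelK <- 0L
    for (cl in clUnique) {
        use <- clusters == cl & !doublets
        if (!any(use)) next
        sub <- cpm[, use, drop = FALSE]
        isPos <- function(g) {
            if (!g %in% rownames(sub)) return(FALSE)
            v <- sub[g, ]
            mean(v) > meanCpmThreshold && mean(v > exprFloor) > fracThreshold
        }
        prolif[[as.character(cl)]] <- isPos("Mki67")
        matched <- FALSE
        for (i in seq_along(ruleGenes)) {
            rg <- ruleGenes[[i]]
            if (all(vapply(rg$pos, isPos, logical(1))) &&
                !any(vapply(rg$neg, isPos, logical(1)))) {
                subtype[[as.character(cl)]] <- rules$subtype[i]
                group[[as.character(cl)]] <- rules$group[i]
                matched <- TRUE
                break
            }
        }
        if (!matched && isPos(novelPanel[1])) {
            novelK <- novelK + 1L
            subtype[[as.character(cl)]] <- paste0("HA-novel-", novelK)
            group[[as.character(cl)]] <- "novel"
        }
    }
    cd <- SummarizedExperiment::colData(x)
    out <- data.frame(
        cell_id = ids,
        cluster_id = as.integer(clusters),
        group = unname(group[as.character(clusters)]),
        subtype = unname(subtype[as.character(clusters)]),
        proliferating = unname(prolif[as.character(clusters)]),
        doublet = unname(doublets),
        timepoint = cd$timepoint,
        condition = cd$condition,
        stringsAsFactors = FALSE)
    out$subtype[out$doublet] <- NA_character_
    out$group[out$doublet] <- "doublet"
    out$proliferating[out$doublet] <- FALSE
    out
}

#' Fraction of cells annotated with their true subtype
#'
#' Scores an annotation against simulation ground truth over cells that are
#' true singlets (not doublets). An assigned \code{"HA-novel-k"} label
#' counts as correct for a true HA1/HA2 cell.
#'
#' @param ann annotation data.frame from \code{\link{assignSubtypes}}
#' @param truth the \code{truth$cells} data.frame from
#'   \code{\link{simulateCounts}}
#' @return fraction in [0, 1]
#' @export
annotationAccuracy <- function(ann, truth) {
    m <- merge(ann, truth, by = "cell_id")
    m <- m[!m$is_doublet, ]
    ok <- !is.na(m$subtype) &
        (m$subtype == m$true_subtype |
         (grepl("^HA-novel-", m$subtype) & m$true_subtype %in% c("HA1", "HA2")))
    mean(ok)
}
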