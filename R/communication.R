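resolvePopulation <- function(ann, type, timepoint, condition, label) {
    use <- !ann$doublet & !is.na(ann$subtype) &
        stratumIndex(ann, timepoint, condition) &
        (ann$subtype == type | ann$group == type)
    if (!any(use))
        stop(label, " population '", type, "' is empty in stratum (",
             timepoint, ", ", condition, ")")
    ann$cell_id[use]
}

#' Detect ligand-receptor interactions between two populations
#'
#' For every pair in the database, computes the fraction of source cells
#' expressing the ligand and of target cells expressing the receptor
#' (expression = CPM above \code{exprFloor}, default simple presence,
#' CPM > 0) within one (timepoint, condition) stratum. An interaction is
#' detected when both fractions reach \code{threshold} (at least 20\% of
#' cells expressing each gene, inclusive, by default). Genes absent from
#' the matrix count as 0\% expressing. Each record also carries the
#' interaction strength: the product of mean ligand CPM in the source,
#' source-type abundance in the stratum, mean receptor CPM in the target,
#' and target-type abundance (abundances over non-doublet stratum cells).
#' With \code{abundanceMode = "source"} only the source-side abundance
#' enters the product.
#'
#' @param x a CPM-normalized \linkS4class{MesenchymeCounts}
#' @param ann annotation data.frame aligned with \code{x}
#' @param db an \linkS4class{LRPairs} database
#' @param sourceType,targetType subtype or group names; ligands are scored
#'   in the source population, receptors in the target
#' @param timepoint,condition the stratum
#' @param threshold detection threshold on both expressing fractions
#'   (default 0.20, inclusive)
#' @param exprFloor CPM floor defining "expressing" (default 0 = presence)
#' @param abundanceMode \code{"both"} (default) or \code{"source"} for the
#'   strength product
#' @return data.frame, one row per pair: \code{pair_id},
#'   \code{ligand_gene}, \code{receptor_gene}, \code{source_type},
#'   \code{target_type}, \code{timepoint}, \code{condition},
#'   \code{frac_ligand}, \code{frac_receptor}, \code{detected},
#'   \code{strength}
#' @export
detectInteractions <- function(x, ann, db, sourceType, targetType,
                               timepoint, condition, threshold = 0.20,
                               exprFloor = 0,
                               abundanceMode = c("both", "source")) {
    abundanceMode <- match.arg(abundanceMode)
    stopifnot(methods::is(db, "LRPairs"), threshold > 0, threshold <= 1)
    stopifnot(identical(ann$cell_id, colnames(x)))
    cpm <- cpmAssay(x)
    src <- resolvePopulation(ann, sourceType, timepoint, condition, "source")
    tgt <- resolvePopulation(ann, targetType, timepoint, condition, "target")
    nStratum <- sum(!ann$doublet & !is.na(ann$subtype) &
                        stratumIndex(ann, timepoint, condition))
    propSrc <- length(src) / nStratum
    propTgt <- length(tgt) / nStratum
    p <- db@pairs
    if (!nrow(p))
        return(data.frame(pair_id = character(), ligand_gene = character(),
                          receptor_gene = character(),
                          source_type = character(),
                          target_type = character(),
                          timepoint = character(), condition = character(),
                          frac_ligand = numeric(), frac_receptor = numeric(),
                          detected = logical(), strength = numeric(),
                          stringsAsFactors = FALSE))
    fracOf <- function(gene, cells) {
        if (!gene %in% rownames(cpm)) return(0)
        mean(cpm[gene, cells] > exprFloor)
    }
    meanOf <- function(gene, cells) {
        if (!gene %in% rownames(cpm)) return(0)
        mean(cpm[gene, cells])
    }
    fracL <- vapply(p$ligand_gene, fracOf, numeric(1), cells = src)
    fracR <- vapply(p$receptor_gene, fracOf, numeric(1), cells = tgt)
    meanL <- vapply(p$ligand_gene, meanOf, numeric(1), cells = src)
    meanR <- vapply(p$receptor_gene, meanOf, numeric(1), cells = tgt)
    strength <- if (abundanceMode == "both")
        (meanL * propSrc) * (meanR * propTgt)
    else (meanL * propSrc) * meanR
    data.frame(pair_id = p$pair_id, ligand_gene = p$ligand_gene,
               receptor_gene = p$receptor_gene,
               source_type = sourceType, target_type = targetType,
               timepoint = timepoint, condition = condition,
               frac_ligand = unname(fracL), frac_receptor = unname(fracR),
               detected = unname(fracL >= threshold & fracR >= threshold),
               strength = unname(strength),
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Interaction strength of one ligand-receptor pair
#'
#' The product of cell-type abundance and gene expression level on each
#' side: mean ligand CPM in the source population times the source type's
#' share of the stratum, times the same product for the receptor in the
#' target population. See \code{\link{detectInteractions}}, which reports
#' this per pair.
#'
#' @inheritParams detectInteractions
#' @param ligand,receptor gene symbols
#' @return a single non-negative number
#' @export
interactionStrength <- function(x, ann, ligand, receptor, sourceType,
                                targetType, timepoint, condition,
                                abundanceMode = c("both", "source")) {
    db <- LRPairs(data.frame(pair_id = "pair", ligand_gene = ligand,
                             receptor_gene = receptor))
    detectInteractions(x, ann, db, sourceType, targetType, timepoint,
                       condition, abundanceMode = abundanceMode)$strength
}

#' Count detected interactions per group
#'
#' @param table an interaction table (rows from
#'   \code{\link{detectInteractions}}, possibly concatenated over strata
#'   and population pairs)
#' @param by grouping columns (default target type within stratum)
#' @return data.frame of the grouping columns plus \code{n_detected}
#' @export
countInteractions <- function(table,
                              by = c("target_type", "timepoint",
                                     "condition")) {
    if (!nrow(table)) {
        out <- table[, intersect(by, colnames(table)), drop = FALSE]
        out$n_detected <- integer()
        return(out)
    }
    missing_cols <- setdiff(by, colnames(table))
    if (length(missing_cols))
        stop("missing grouping column(s): ",
             paste(missing_cols, collapse = ", "))
    agg <- stats::aggregate(table$detected,
                            by = table[by], FUN = function(z) sum(z))
    names(agg)[ncol(agg)] <- "n_detected"
    agg$n_detected <- as.integer(agg$n_detected)
    agg[do.call(order, agg[by]), , drop = FALSE]
}
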