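#' SimSpec: specification for the synthetic lung-mesenchyme generator
#'
#' Describes a negative-binomial gene-by-cell count simulation with the
#' compositional, temporal and perturbation structure the analysis assumes:
#' subtypes with on/off marker-gene signatures, a (timepoint, condition)
#' composition map, log-normal per-cell sequencing depth with a
#' QC-filterable low-depth tail, additive doublets, and "progression" genes
#' whose mean rises from P1 to P7 in normoxia but not (by default) under
#' hyperoxia.
#'
#' @slot subtypes list of subtype specifications (see \code{\link{subtypeSpec}})
#' @slot composition named list, one probability vector over subtype names
#'   per \code{"timepoint|condition"} stratum (each sums to 1)
#' @slot nCells named integer vector of cells per stratum (same keys)
#' @slot nGenes total number of simulated genes
#' @slot nbDispersion negative-binomial shape (size) parameter; smaller
#'   means more overdispersed
#' @slot depthMean,depthSd mean and sd of per-cell total counts (log-normal)
#' @slot lowqDepthRange uniform range of total counts for simulated
#'   low-quality cells (kept below the 50,000-count QC threshold)
#' @slot markerOffFactor multiplier applied to a marker gene's baseline
#'   weight in subtypes that do not carry it (markers are near-binary)
#' @slot progressionGenes named list: subtype -> genes whose mean rises
#'   P1 -> P7/P21
#' @slot progressionMultiplier mean fold increase of progression genes
#' @slot progressionInHyperoxia if TRUE the progression also happens under
#'   hyperoxia (a "no arrest" control scenario)
#' @slot doubletRate,lowqRate fractions of simulated doublets / low-quality
#'   cells
#' @slot extraGenes gene symbols guaranteed to be in the simulated universe
#'   (e.g. ligand genes used by interaction analyses)
#' @slot seed integer seed; identical spec + seed gives identical output
#' @seealso \code{\link{simSpec}}, \code{\link{defaultLungSpec}},
#'   \code{\link{simulateCounts}}
#' @export
setClass("SimSpec", representation(
    subtypes = "list",
    composition = "list",
    nCells = "integer",
    nGenes = "integer",
    nbDispersion = "numeric",
    depthMean = "numeric",
    depthSd = "numeric",
    lowqDepthRange = "numeric",
    markerOffFactor = "numeric",
    progressionGenes = "list",
    progressionMultiplier = "numeric",
    progressionInHyperoxia = "logical",
    doubletRate = "numeric",
    lowqRate = "numeric",
    extraGenes = "character",
    seed = "integer"))

specSubtypeNames <- function(spec)
    vapply(spec@subtypes, `[[`, character(1), "name")

specMarkerUnion <- function(spec)
    unique(unlist(lapply(spec@subtypes, `[[`, "markers")))

specNamedGenes <- function(spec)
    unique(c(specMarkerUnion(spec), unlist(spec@progressionGenes),
             spec@extraGenes))

setValidity("SimSpec", function(object) {
    msg <- character()
    nm <- specSubtypeNames(object)
    if (anyDuplicated(nm))
        msg <- c(msg, "subtype names must be unique")
    for (s in object@subtypes) {
        if (!is.numeric(s$multiplier) || s$multiplier <= 1)
            msg <- c(msg, paste0("marker multiplier must be > 1 (", s$name, ")"))
    }
    if (!setequal(names(object@composition), names(object@nCells)))
        msg <- c(msg, "composition and nCells must cover the same strata")
    for (k in names(object@composition)) {
        p <- object@composition[[k]]
        if (length(setdiff(names(p), nm)))
            msg <- c(msg, paste0("composition for ", k,
                                 " names unknown subtypes"))
        if (abs(sum(p) - 1) > 1e-9)
            msg <- c(msg, paste0("composition for ", k, " must sum to 1"))
        if (any(p < 0))
            msg <- c(msg, paste0("composition for ", k, " has negative entries"))
    }
    if (object@doubletRate < 0 || object@doubletRate >= 0.5)
        msg <- c(msg, "doubletRate must be in [0, 0.5)")
    if (object@lowqRate < 0 || object@lowqRate >= 1)
        msg <- c(msg, "lowqRate must be in [0, 1)")
    if (object@nbDispersion <= 0)
        msg <- c(msg, "nbDispersion must be > 0")
    if (object@nGenes < length(specNamedGenes(object)))
        msg <- c(msg, paste0("nGenes (", object@nGenes,
                             ") is smaller than the set of named genes (",
                             length(specNamedGenes(object)), ")"))
    if (length(setdiff(names(object@progressionGenes), nm)))
        msg <- c(msg, "progressionGenes names unknown subtypes")
    if (length(msg)) msg else TRUE
})

#' Describe one simulated cell subtype
#'
#' @param name subtype name, unique within a spec
#' @param markers gene symbols highly expressed in this subtype
#' @param multiplier fold increase of marker expression over baseline (> 1)
#' @param proliferating if TRUE, Mki67 is added to the markers
#' @param baselineMean relative scale of this subtype's baseline expression
#' @return a list usable in the \code{subtypes} slot of a
#'   \linkS4class{SimSpec}
#' @export
subtypeSpec <- function(name, markers, multiplier = 8,
                        proliferating = FALSE, baselineMean = 1) {
    if (proliferating) markers <- union(markers, "Mki67")
    list(name = name, markers = markers, multiplier = multiplier,
         proliferating = proliferating, baselineMean = baselineMean)
}

#' Construct a simulation specification
#'
#' @param subtypes list of \code{\link{subtypeSpec}} entries
#' @param composition named list of per-stratum probability vectors over
#'   subtype names; keys are \code{"timepoint|condition"}
#' @param nCells named integer vector of cells per stratum (same keys)
#' @param nGenes number of simulated genes
#' @param nbDispersion negative-binomial size parameter
#' @param depthMean,depthSd per-cell total-count law (log-normal)
#' @param lowqDepthRange total-count range for low-quality cells
#' @param markerOffFactor baseline multiplier of a marker gene in subtypes
#'   not carrying it
#' @param progressionGenes named list subtype -> progression gene set
#' @param progressionMultiplier fold increase of progression genes at P7/P21
#' @param progressionInHyperoxia keep the progression under hyperoxia
#'   (no-arrest control; default FALSE, i.e. hyperoxia arrests)
#' @param doubletRate,lowqRate simulated artifact fractions
#' @param extraGenes extra gene symbols to include in the universe
#' @param seed integer seed
#' @return a validated \linkS4class{SimSpec}
#' @export
simSpec <- function(subtypes, composition, nCells,
                    nGenes = 2000L, nbDispersion = 2,
                    depthMean = 5e5, depthSd = 1.2e5,
                    lowqDepthRange = c(1e4, 3.5e4),
                    markerOffFactor = 0.005,
                    progressionGenes = list(),
                    progressionMultiplier = 3,
                    progressionInHyperoxia = FALSE,
                    doubletRate = 0, lowqRate = 0,
                    extraGenes = character(), seed = 1L) {
    nCells <- stats::setNames(as.integer(nCells), names(nCells))
    methods::new("SimSpec",
        subtypes = subtypes, composition = composition, nCells = nCells,
        nGenes = as.integer(nGenes), nbDispersion = nbDispersion,
        depthMean = depthMean, depthSd = depthSd,
        lowqDepthRange = lowqDepthRange,
        markerOffFactor = markerOffFactor,
        progressionGenes = progressionGenes,
        progressionMultiplier = progressionMultiplier,
        progressionInHyperoxia = progressionInHyperoxia,
        doubletRate = doubletRate, lowqRate = lowqRate,
        extraGenes = extraGenes, seed = as.integer(seed))
}

#' @describeIn simSpec compact display
#' @param object a \code{SimSpec}
#' @export
setMethod("show", "SimSpec", function(object) {
    cat("SimSpec:", length(object@subtypes), "subtypes,",
        object@nGenes, "genes,", sum(object@nCells), "cells over",
        length(object@nCells), "strata\n")
    invisible(NULL)
})

splitStratum <- function(key) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    if (length(parts) != 2)
        stop("stratum key must be 'timepoint|condition': ", key)
    parts
}

# Per-subtype expected expression profiles (columns sum to 1).
subtypeProfiles <- function(spec, baseWeights, progressed) {
    nm <- specSubtypeNames(spec)
    markerUnion <- specMarkerUnion(spec)
    W <- matrix(baseWeights, nrow = spec@nGenes, ncol = length(nm),
                dimnames = list(names(baseWeights), nm))
    off <- names(baseWeights) %in% markerUnion
    for (s in spec@subtypes) {
        w <- baseWeights * s$baselineMean
        w[off] <- w[off] * spec@markerOffFactor
        w[s$markers] <- baseWeights[s$markers] * s$baselineMean * s$multiplier
        if (progressed && s$name %in% names(spec@progressionGenes)) {
            pg <- spec@progressionGenes[[s$name]]
            w[pg] <- w[pg] * spec@progressionMultiplier
        }
        W[, s$name] <- w
    }
    sweep(W, 2, colSums(W), "/")
}

#' Simulate a count matrix with ground truth
#'
#' Draws cells stratum by stratum: the subtype follows the stratum's
#' composition vector, per-cell depth is log-normal (or uniform-low for
#' simulated low-quality cells), and counts are negative binomial around
#' the subtype's expected expression profile. Doublets are the sum of the
#' cell's own draw and an independent draw from a random same-stratum
#' profile. Progression genes are mean-shifted at P7/P21 in normoxia (and,
#' only if \code{progressionInHyperoxia}, under hyperoxia). Identical spec
#' and seed give identical output.
#'
#' @param spec a \linkS4class{SimSpec}
#' @return a list with elements \code{counts}
#'   (\linkS4class{MesenchymeCounts}) and \code{truth} (list of data.frames
#'   \code{cells} -- cell_id, true_subtype, is_doublet, is_lowq,
#'   doublet_partner -- and \code{genes} -- gene_id, marker_of,
#'   progression_of).
#' @examples
#' sim <- simulateCounts(defaultLungSpec(seed = 1, nCellsPerStratum = 50))
#' sim$counts
#' @export
simulateCounts <- function(spec) {
    methods::validObject(spec)
    withSeed(spec@seed, {
        nm <- specSubtypeNames(spec)
        named <- specNamedGenes(spec)
        nFill <- spec@nGenes - length(named)
        genes <- c(named, sprintf("Gene%04d", seq_len(nFill)))
        # baseline weights are a property of the gene universe (derived
        # seed), not of the simulation seed: two datasets simulated from
        # the same spec with different seeds share their biology and
        # differ by a mild per-gene batch perturbation plus sampling
        # noise, as replicate experiments do. Named genes (markers,
        # progression panels, ligands) are solidly expressed where on, as
        # in the study's dot plots; filler genes keep the long-tailed law.
        uSeed <- (sum(utf8ToInt(paste(genes, collapse = ""))) * 7L +
                      spec@nGenes) %% 1000003L
        b0 <- withSeed(uSeed, {
            x <- stats::rlnorm(spec@nGenes, 0, 1)
            x[seq_along(named)] <- stats::rlnorm(length(named), log(2), 0.5)
            x
        })
        batch <- stats::rlnorm(spec@nGenes, 0, 0.15)
        b <- stats::setNames(b0 * batch, genes)
        P0 <- subtypeProfiles(spec, b, progressed = FALSE)
        P1 <- subtypeProfiles(spec, b, progressed = TRUE)
        sdlog <- sqrt(log(1 + (spec@depthSd / spec@depthMean)^2))
        meanlog <- log(spec@depthMean) - sdlog^2 / 2

        blocks <- list()
        cellrows <- list()
        idx0 <- 0L
        for (k in names(spec@nCells)) {
            tpcond <- splitStratum(k)
            tp <- tpcond[1]; cond <- tpcond[2]
            n <- spec@nCells[[k]]
            if (n == 0L) next
            comp <- spec@composition[[k]]
            comp <- comp[comp > 0]
            sub <- sample(names(comp), n, replace = TRUE, prob = comp)
            cat_p <- c(lowq = spec@lowqRate, doublet = spec@doubletRate)
            cat <- sample(c("lowq", "doublet", "singlet"), n, replace = TRUE,
                          prob = c(cat_p, 1 - sum(cat_p)))
            depth <- stats::rlnorm(n, meanlog, sdlog)
            depth[cat == "lowq"] <- stats::runif(sum(cat == "lowq"),
                                                 spec@lowqDepthRange[1],
                                                 spec@lowqDepthRange[2])
            progressed <- tp %in% c("P7", "P21") &&
                (cond == "normoxia" || spec@progressionInHyperoxia)
            P <- if (progressed) P1 else P0
            MU <- P[, sub, drop = FALSE] %*% diag(depth, nrow = n)
            counts <- matrix(stats::rnbinom(length(MU), mu = as.vector(MU),
                                            size = spec@nbDispersion),
                             nrow = spec@nGenes)
            dbl <- which(cat == "doublet")
            partner <- rep(NA_character_, n)
            if (length(dbl)) {
                partner[dbl] <- sample(names(comp), length(dbl),
                                       replace = TRUE, prob = comp)
                pdepth <- stats::rlnorm(length(dbl), meanlog, sdlog)
                PMU <- P[, partner[dbl], drop = FALSE] %*%
                    diag(pdepth, nrow = length(dbl))
                counts[, dbl] <- counts[, dbl, drop = FALSE] +
                    matrix(stats::rnbinom(length(PMU), mu = as.vector(PMU),
                                          size = spec@nbDispersion),
                           nrow = spec@nGenes)
            }
            ids <- sprintf("c%06d", idx0 + seq_len(n))
            idx0 <- idx0 + n
            mouse <- paste0("m_", tp, "_", cond, "_",
                            sample(1:2, n, replace = TRUE))
            colnames(counts) <- ids
            rownames(counts) <- genes
            blocks[[k]] <- counts
            cellrows[[k]] <- data.frame(
                cell_id = ids, mouse_id = mouse, timepoint = tp,
                condition = cond,
                sex = ifelse(grepl("_1$", mouse), "F", "M"),
                true_subtype = sub, is_doublet = cat == "doublet",
                is_lowq = cat == "lowq", doublet_partner = partner,
                stringsAsFactors = FALSE)
        }
        counts <- do.call(cbind, blocks)
        cells <- do.call(rbind, cellrows)
        rownames(cells) <- NULL
        storage.mode(counts) <- "integer"
        cm <- MesenchymeCounts(
            counts, cells[, REQUIRED_CELL_META, drop = FALSE],
            cellIds = cells$cell_id)
        marker_of <- vapply(genes, function(g) paste(
            nm[vapply(spec@subtypes, function(s) g %in% s$markers, logical(1))],
            collapse = ";"), character(1))
        prog_of <- vapply(genes, function(g) paste(
            names(spec@progressionGenes)[vapply(spec@progressionGenes,
                                                function(p) g %in% p,
                                                logical(1))],
            collapse = ";"), character(1))
        truth <- list(
            cells = cells[, c("cell_id", "true_subtype", "is_doublet",
                              "is_lowq", "doublet_partner")],
            genes = data.frame(gene_id = genes, marker_of = marker_of,
                               progression_of = prog_of,
                               stringsAsFactors = FALSE, row.names = NULL))
        list(counts = cm, truth = truth)
    })
}

#' Default simulation spec emulating the perinatal lung mesenchyme study
#'
#' Fourteen mesenchymal subtypes with marker signatures matching the
#' shipped annotation rules (\code{\link{defaultMarkerRules}}): three broad
#' groups (Adh1+ fibroblasts, Tgfbi+ ASM/MyoF, Pdgfrb+ mural cells) split
#' into alveolar (Col13a1) vs adventitial (Col14a1) fibroblasts and their
#' early/precursor states, Hhip/Pdgfra-defined ASM vs myofibroblasts and
#' their coexpressing precursor, Mki67+ proliferating variants, pericytes
#' (Cox4i2/Notch3) and Tagln/Acta2+ vascular smooth muscle. Two additional
#' Acta1+ populations (HA1: Acta1/Tubb3; HA2: Acta1/Lgals3/Aqp3) exist only
#' in the hyperoxia arm. The hyperoxia-P7 composition equals the normoxia-P1
#' composition on the 14 normal subtypes (rescaled for the HA mass),
#' encoding compositional developmental arrest, and progression genes
#' (12 per progressing subtype) rise threefold from P1 to P7 in normoxia
#' only. Composition values are the package's own choices: the source
#' figures report them only graphically.
#'
#' @param seed integer seed stored in the spec
#' @param nCellsPerStratum cells per (timepoint, condition) stratum
#'   (five strata: E18.5/P1/P7/P21 normoxia and P7 hyperoxia)
#' @param nGenes number of simulated genes
#' @param doubletRate,lowqRate simulated artifact fractions
#' @return a validated \linkS4class{SimSpec}
#' @export
defaultLungSpec <- function(seed = 1L, nCellsPerStratum = 600L,
                            nGenes = 2000L, doubletRate = 0.05,
                            lowqRate = 0.05) {
    subtypes <- list(
        subtypeSpec("Fibroblast precursor",
                    c("Adh1", "Col13a1", "Col14a1", "Hsd11b1")),
        subtypeSpec("Alveolar fibroblast", c("Adh1", "Col13a1", "Wnt2")),
        subtypeSpec("Adventitial fibroblast", c("Adh1", "Col14a1")),
        subtypeSpec("Early alveolar fibroblast",
                    c("Adh1", "Col13a1", "Mest")),
        subtypeSpec("Early adventitial fibroblast",
                    c("Adh1", "Col14a1", "Mest")),
        subtypeSpec("Proliferating fibroblast", c("Adh1", "Col13a1"),
                    proliferating = TRUE),
        subtypeSpec("ASM/MyoF precursor",
                    c("Tgfbi", "Hhip", "Pdgfra", "Crh")),
        subtypeSpec("Early ASM", c("Tgfbi", "Hhip")),
        subtypeSpec("ASM", c("Tgfbi", "Hhip", "Acta2")),
        subtypeSpec("Myofibroblast", c("Tgfbi", "Pdgfra")),
        subtypeSpec("Proliferating myofibroblast", c("Tgfbi", "Pdgfra"),
                    proliferating = TRUE),
        subtypeSpec("Pericyte", c("Pdgfrb", "Cox4i2", "Notch3")),
        subtypeSpec("Proliferating pericyte",
                    c("Pdgfrb", "Cox4i2", "Notch3"), proliferating = TRUE),
        subtypeSpec("VSM", c("Pdgfrb", "Tagln", "Acta2")),
        subtypeSpec("HA1", c("Acta1", "Tubb3", "Actc1")),
        subtypeSpec("HA2", c("Acta1", "Lgals3", "Aqp3")))
    nm <- vapply(subtypes, `[[`, character(1), "name")
    comp <- function(...) {
        p <- c(...)
        full <- stats::setNames(numeric(length(nm)), nm)
        full[names(p)] <- p
        stopifnot(abs(sum(full) - 1) < 1e-9)
        full
    }
    e185 <- comp("Fibroblast precursor" = 0.42,
                 "Early alveolar fibroblast" = 0.08,
                 "Early adventitial fibroblast" = 0.05,
                 "Proliferating fibroblast" = 0.06,
                 "ASM/MyoF precursor" = 0.15, "Early ASM" = 0.04,
                 "Myofibroblast" = 0.05, "Proliferating myofibroblast" = 0.01,
                 "Pericyte" = 0.08, "Proliferating pericyte" = 0.01,
                 "VSM" = 0.05)
    p1 <- comp("Alveolar fibroblast" = 0.14, "Adventitial fibroblast" = 0.07,
               "Early alveolar fibroblast" = 0.20,
               "Early adventitial fibroblast" = 0.09,
               "Proliferating fibroblast" = 0.08, "Early ASM" = 0.10,
               "ASM" = 0.01, "Myofibroblast" = 0.10,
               "Proliferating myofibroblast" = 0.02, "Pericyte" = 0.10,
               "Proliferating pericyte" = 0.02, "VSM" = 0.07)
    p7 <- comp("Alveolar fibroblast" = 0.16, "Adventitial fibroblast" = 0.07,
               "Early alveolar fibroblast" = 0.04,
               "Early adventitial fibroblast" = 0.02,
               "Proliferating fibroblast" = 0.06, "Early ASM" = 0.12,
               "ASM" = 0.03, "Myofibroblast" = 0.15,
               "Proliferating myofibroblast" = 0.08, "Pericyte" = 0.12,
               "Proliferating pericyte" = 0.05, "VSM" = 0.10)
    p21 <- comp("Alveolar fibroblast" = 0.28, "Adventitial fibroblast" = 0.14,
                "Early ASM" = 0.02, "ASM" = 0.10, "Myofibroblast" = 0.08,
                "Pericyte" = 0.21, "Proliferating pericyte" = 0.01,
                "VSM" = 0.16)
    haMass <- 0.08
    hyper <- p1 * (1 - haMass)
    hyper["HA1"] <- 0.05
    hyper["HA2"] <- 0.03
    prog <- matrix(sprintf("Prog%02d", 1:48), ncol = 4)
    progressionGenes <- list(
        "Alveolar fibroblast" = prog[, 1],
        "Early ASM" = prog[, 2],
        "Myofibroblast" = prog[, 3],
        "Pericyte" = prog[, 4])
    lig <- c("Pdgfa", "Pdgfb", "Dll4", "Jag1", "Vegfa", "Angpt1", "Wnt5a",
             "Tgfb1", "Fgf10", "Cxcl12", "Kdr", "Tek", "Fzd1", "Tgfbr2",
             "Fgfr2", "Cxcr4")
    simSpec(
        subtypes = subtypes,
        composition = list("E18.5|normoxia" = e185, "P1|normoxia" = p1,
                           "P7|normoxia" = p7, "P21|normoxia" = p21,
                           "P7|hyperoxia" = hyper),
        nCells = stats::setNames(rep(as.integer(nCellsPerStratum), 5),
                                 c("E18.5|normoxia", "P1|normoxia",
                                   "P7|normoxia", "P21|normoxia",
                                   "P7|hyperoxia")),
        nGenes = nGenes, progressionGenes = progressionGenes,
        doubletRate = doubletRate, lowqRate = lowqRate,
        extraGenes = lig, seed = seed)
}
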