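#' Assemble a pipeline configuration
#'
#' Returns the full configuration list driving \code{\link{runPipeline}},
#' with every analysis default at its published value where one exists
#' (50,000 counts / 400 genes QC, 500 Fano features, pseudocount 0.1, 25
#' principal components, KS floor 0.3, 1000 bootstraps, 20\% expressing
#' threshold). Pass overrides as named arguments; nested lists are merged
#' field by field. A configuration can equivalently be read from YAML with
#' \code{\link{readPipelineConfig}}.
#'
#' @param ... overrides of the defaults, e.g.
#'   \code{simulate = list(nCellsPerStratum = 200)} or
#'   \code{input = list(matrix = ..., genes = ..., cells = ...)} to run on
#'   files instead of simulated data
#' @param seed global integer seed for every stochastic stage
#' @return a configuration list
#' @export
pipelineConfig <- function(..., seed = 1L) {
    config <- list(
        seed = as.integer(seed),
        simulate = list(nCellsPerStratum = 300L, nGenes = 1500L,
                        doubletRate = 0.05, lowqRate = 0.05),
        input = NULL,
        qc = list(minReads = 50000, minGenes = 400),
        features = list(nFeatures = 500, majorityFraction = 0.5),
        embedding = list(nPCs = 25, pseudocount = 0.1),
        clustering = list(nNeighbors = 15, resolution = 1.5),
        doublets = list(minClusterSize = 10, cpmThreshold = 100),
        annotation = list(meanCpmThreshold = 50, fracThreshold = 0.25,
                          rulesPath = NULL),
        de = list(timepoint = "P7", conditionA = "hyperoxia",
                  conditionB = "normoxia", ksMin = 0.3, topN = 50),
        arrest = list(B = 1000, distance = "tv", cellTypes = "Pericyte"),
        communication = list(lrPath = NULL, sourceType = "Pericyte",
                             targetTypes = c("fibroblast", "ASM/MyoF", "VSM"),
                             threshold = 0.2))
    dots <- list(...)
    for (nm in names(dots)) {
        if (is.list(dots[[nm]]) && is.list(config[[nm]])) {
            for (f in names(dots[[nm]])) config[[nm]][[f]] <- dots[[nm]][[f]]
        } else config[[nm]] <- dots[[nm]]
    }
    config
}

#' Read a pipeline configuration from YAML
#'
#' Fields present in the file override the package defaults
#' (\code{\link{pipelineConfig}}).
#'
#' @param path path to a YAML configuration file
#' @return a configuration list
#' @export
readPipelineConfig <- function(path) {
    y <- yaml::read_yaml(path)
    do.call(pipelineConfig, y)
}

#' Run the full analysis pipeline
#'
#' Executes QC, CPM normalization, feature selection, PCA embedding, Leiden
#' clustering, doublet flagging, subtype annotation, KS differential
#' expression, the compositional bootstrap arrest test, progression-gene
#' arrest scoring, and ligand-receptor interaction counting, writing every
#' intermediate table (with a provenance header carrying the configuration
#' hash, seed and stage), a log, and a machine-readable
#' \code{summary.json}. Re-running with an identical configuration
#' reproduces the summary byte for byte.
#'
#' @param config configuration list from \code{\link{pipelineConfig}} or
#'   \code{\link{readPipelineConfig}}
#' @param outDir output directory (created if needed)
#' @param quiet suppress progress messages
#' @return invisibly, a list with the \code{summary} (also written as
#'   JSON), the output \code{dir}, and the in-memory \code{annotation}
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = tempfile("run"),
                        quiet = FALSE) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    cfgPath <- file.path(outDir, "config.yaml")
    yaml::write_yaml(config, cfgPath)
    cfgHash <- unname(tools::md5sum(cfgPath))
    logPath <- file.path(outDir, "run.log")
    logCon <- file(logPath, open = "wt")
    on.exit(close(logCon))
    say <- function(...) {
        msg <- paste0(...)
        writeLines(msg, logCon)
        if (!quiet) message(msg)
    }
    prov <- function(stage) c(package = "scMesenchyme",
                              version = as.character(
                                  utils::packageVersion("scMesenchyme")),
                              config_hash = cfgHash,
                              seed = as.character(config$seed),
                              stage = stage)
    stage <- function(name, expr) {
        say("[", name, "] starting")
        tryCatch(expr, error = function(e)
            stop("pipeline stage '", name, "' failed: ",
                 conditionMessage(e), call. = FALSE))
    }
    summary <- list(config_hash = cfgHash, seed = config$seed)

    truth <- NULL
    cm <- stage("input", {
        if (!is.null(config$input)) {
            readCounts(config$input$matrix, config$input$genes,
                       config$input$cells)
        } else {
            sim <- simulateCounts(defaultLungSpec(
                seed = config$seed,
                nCellsPerStratum = config$simulate$nCellsPerStratum,
                nGenes = config$simulate$nGenes,
                doubletRate = config$simulate$doubletRate,
                lowqRate = config$simulate$lowqRate))
            truth <- sim$truth
            sim$counts
        }
    })
    say("input: ", nrow(cm), " genes x ", ncol(cm), " cells")
    summary$n_cells_input <- ncol(cm)

    cm <- stage("qc", {
        filt <- filterCells(cm, config$qc$minReads, config$qc$minGenes)
        say("qc: removed ", ncol(cm) - ncol(filt), " of ", ncol(cm),
            " cells (<", config$qc$minReads, " counts or <",
            config$qc$minGenes, " genes)")
        filt
    })
    summary$n_cells_qc <- ncol(cm)
    if (!is.null(truth)) {
        kept <- truth$cells$cell_id %in% colnames(cm)
        summary$n_lowq_truth <- sum(truth$cells$is_lowq)
        summary$n_removed_qc <- summary$n_cells_input - summary$n_cells_qc
    }

    cm <- stage("normalize", cpmNormalize(cm))
    features <- stage("features", selectFeatures(
        cm, config$features$nFeatures, config$features$majorityFraction))
    writeResultTable(data.frame(gene = features),
                     file.path(outDir, "features.tsv"), prov("features"))
    summary$n_features <- length(features)

    emb <- stage("embed", embedPCA(cm, features, config$embedding$nPCs,
                                   config$embedding$pseudocount))
    writeResultTable(
        data.frame(cell_id = rownames(emb@coords), emb@coords),
        file.path(outDir, "embedding.tsv"), prov("embed"))

    labels <- stage("cluster", clusterLeiden(
        emb, config$clustering$nNeighbors, config$clustering$resolution,
        seed = config$seed))
    summary$n_clusters <- length(unique(labels))
    say("cluster: ", summary$n_clusters, " clusters")

    ann <- stage("annotate", {
        dbl <- flagDoublets(cm, labels,
                            minClusterSize = config$doublets$minClusterSize,
                            cpmThreshold = config$doublets$cpmThreshold)
        rules <- if (is.null(config$annotation$rulesPath))
            defaultMarkerRules()
        else readMarkerRules(config$annotation$rulesPath)
        assignSubtypes(cm, labels, rules, doublets = dbl,
                       meanCpmThreshold = config$annotation$meanCpmThreshold,
                       fracThreshold = config$annotation$fracThreshold)
    })
    writeResultTable(ann, file.path(outDir, "annotation.tsv"),
                     prov("annotate"))
    summary$n_doublets_flagged <- sum(ann$doublet)
    summary$subtype_counts <- as.list(table(ann$subtype[!ann$doublet]))
    if (!is.null(truth))
        summary$annotation_accuracy <- annotationAccuracy(ann, truth$cells)

    stage("de", {
        a <- ann$cell_id[!ann$doublet &
                             ann$timepoint == config$de$timepoint &
                             ann$condition == config$de$conditionA]
        b <- ann$cell_id[!ann$doublet &
                             ann$timepoint == config$de$timepoint &
                             ann$condition == config$de$conditionB]
        if (length(a) >= 2 && length(b) >= 2) {
            de <- ksDE(cm, a, b)
            writeResultTable(de, file.path(outDir, "de.tsv"), prov("de"))
            top <- rankGenes(de, "by_fc_above_ks", ksMin = config$de$ksMin,
                             topN = config$de$topN)
            summary$de_top_genes <- top
            summary$de_n_significant <- sum(de$p_adj < 0.05)
        } else say("de: a comparison group has <2 cells; skipped")
        NULL
    })

    boot <- stage("arrest", bootstrapArrest(
        ann, B = config$arrest$B, seed = config$seed,
        distance = config$arrest$distance))
    writeResultTable(data.frame(replicate = seq_along(boot$diffs),
                                diff = boot$diffs),
                     file.path(outDir, "arrest_bootstrap.tsv"),
                     prov("arrest"))
    summary$arrest_empirical_p <- boot$empirical_p
    summary$arrest_distance <- boot$distance_name
    say("arrest: empirical P = ", boot$empirical_p)
    for (ct in config$arrest$cellTypes) {
        pa <- stage(paste0("progression:", ct),
                    progressionArrest(cm, ann, ct, ksMin = config$de$ksMin))
        summary$progression[[ct]] <- list(
            n_progression_genes = length(pa$progression_genes),
            arrest_fraction = pa$arrest_fraction)
    }

    stage("communication", {
        lrPath <- config$communication$lrPath %||%
            system.file("extdata", "lr_pairs_synthetic.tsv",
                        package = "scMesenchyme")
        db <- readLRPairs(lrPath)
        tabs <- list()
        for (cond in intersect(unique(ann$condition), CONDITION_LEVELS))
            for (tt in config$communication$targetTypes)
                tabs[[paste(cond, tt)]] <- detectInteractions(
                    cm, ann, db, config$communication$sourceType, tt,
                    timepoint = "P7", condition = cond,
                    threshold = config$communication$threshold)
        itab <- do.call(rbind, tabs)
        rownames(itab) <- NULL
        writeResultTable(itab, file.path(outDir, "interactions.tsv"),
                         prov("communication"))
        cnt <- countInteractions(itab)
        writeResultTable(cnt, file.path(outDir, "interaction_counts.tsv"),
                         prov("communication"))
        summary$interaction_counts <- stats::setNames(
            as.list(cnt$n_detected),
            paste(cnt$target_type, cnt$condition, sep = "|"))
        NULL
    })

    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    say("done: ", outDir)
    invisible(list(summary = summary, dir = outDir, annotation = ann))
}
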