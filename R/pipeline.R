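#' @include io.R
NULL

#' Default pipeline configuration
#'
#' Assembles the default end-to-end configuration: the packaged taxon
#' tables, the 16-sample study layout with its per-sample read depths, the
#' simulator settings, filtering thresholds (>= 2 samples, >= 100 reads),
#' clustering and assignment identity thresholds (98.7% default), the
#' sampling depth of 500 for alpha diversity, and the rarefaction depth
#' grid (150-5000).
#'
#' @param seed master seed.
#' @param ... named overrides of any configuration entry.
#' @return a named list.
#' @export
pipelineConfig <- function(seed = 1, ...) {
    layout <- studyDesigns()
    records <- TaxonSet(rbind(as.data.frame(mockCommunityTaxa("biofilm")),
                              as.data.frame(mockCommunityTaxa("meat"))))
    cfg <- list(
        records = records,
        designs = layout$designs,
        info = layout$info,
        sim = simulationConfig(
            nReads = stats::setNames(layout$info$n_reads, layout$info$sample),
            seed = seed, splitTaxa = "H6a"),
        minSamples = 2, minFrequency = 100,
        otuThreshold = 98.7, taxaThreshold = 98.7,
        samplingDepth = 500,
        rarefactionDepths = c(150, 500, 1000, 2000, 5000),
        rarefactionIter = 50,
        seed = seed,
        tree = NULL)
    dots <- list(...)
    cfg[names(dots)] <- dots
    cfg
}

.logLine <- function(con, fmt, ...) {
    line <- sprintf(fmt, ...)
    message(line)
    if (!is.null(con)) writeLines(line, con)
}

#' Run the benchmarking pipeline
#'
#' Chains the pipeline stages and writes TSV artifacts to `outDir`:
#' `simulate` emits the raw feature count table and the ground-truth
#' feature map; `process` filters, OTU-clusters (on a synthetic identity
#' matrix derived from the ground truth), assigns species at the identity
#' threshold, aggregates to species level and applies copy-number
#' normalization; `diversity` writes per-sample alpha diversity at the
#' sampling depth and rarefaction curves; `bias` writes the per-species
#' log2 fold changes, per-mode attribution and the G+C regression summary.
#' `all` runs every stage in order. A `run.log` records the seed and
#' parameters.
#'
#' @param stage one of `"simulate"`, `"process"`, `"diversity"`, `"bias"`,
#'   `"all"`.
#' @param config list from [pipelineConfig()].
#' @param outDir output directory (created if needed).
#' @return invisibly, a list of the in-memory stage results.
#' @export
runPipeline <- function(stage = c("all", "simulate", "process", "diversity",
                                  "bias"),
                        config = pipelineConfig(), outDir = tempfile()) {
    stage <- match.arg(stage)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    logCon <- file(file.path(outDir, "run.log"), "w")
    on.exit(close(logCon))
    .logLine(logCon, "mockbench pipeline | stage=%s seed=%d", stage,
             as.integer(config$seed))
    .logLine(logCon,
             "params | minSamples=%d minFrequency=%d otuId=%.1f taxaId=%.1f depth=%d",
             config$minSamples, config$minFrequency, config$otuThreshold,
             config$taxaThreshold, config$samplingDepth)
    res <- list()

    doSim <- stage %in% c("all", "simulate")
    doProc <- stage %in% c("all", "process")
    doDiv <- stage %in% c("all", "diversity")
    doBias <- stage %in% c("all", "bias")

    simPaths <- file.path(outDir, c("counts.tsv", "truth.tsv"))
    if (doSim) {
        sim <- simulateExperiment(config$designs, config$records, config$sim)
        writeFeatureTable(sim$table, simPaths[1])
        utils::write.table(as.data.frame(sim$truth), simPaths[2],
                           sep = "\t", quote = FALSE, row.names = FALSE)
        .logLine(logCon, "simulate | %d features x %d samples",
                 nrow(sim$table), ncol(sim$table))
        res$sim <- sim
    }

    speciesPath <- file.path(outDir, "species_raw.tsv")
    gcnPath <- file.path(outDir, "species_gcn.tsv")
    if (doProc) {
        if (is.null(res$sim)) {
            if (!all(file.exists(simPaths)))
                stop("process stage needs the simulate outputs in ", outDir)
            res$sim <- list(table = readFeatureTable(simPaths[1]),
                            truth = S4Vectors::DataFrame(
                                utils::read.delim(simPaths[2],
                                                  stringsAsFactors = FALSE)))
        }
        filt <- filterFeatures(res$sim$table, config$minSamples,
                               config$minFrequency)
        .logLine(logCon, "filter | dropped %d feature(s)",
                 length(S4Vectors::metadata(filt)$filtered_out))
        idm <- syntheticIdentityMatrix(res$sim$truth)
        clustered <- clusterFeatureTable(filt, idm, config$otuThreshold)
        .logLine(logCon, "cluster | %d feature(s) -> %d OTU(s) at %.1f%%",
                 nrow(filt), nrow(clustered), config$otuThreshold)
        truth <- res$sim$truth
        cand <- truth[match(rownames(clustered), truth$feature_id), ]
        map <- assignTaxonomy(cand, config$taxaThreshold)
        .logLine(logCon, "assign | %d unassigned at %.1f%% identity",
                 sum(map$assigned_taxon == "UNASSIGNED"),
                 config$taxaThreshold)
        species <- aggregateBySpecies(clustered, map)
        norm <- gcnNormalize(species, copyNumberLookup(config$records))
        writeFeatureTable(species, speciesPath)
        writeFeatureTable(norm, gcnPath)
        writeAssignmentMap(map, file.path(outDir, "assignments.tsv"))
        res$species <- species
        res$norm <- norm
    }

    .needSpecies <- function() {
        if (is.null(res$species)) {
            if (!file.exists(speciesPath))
                stop("this stage needs the process outputs in ", outDir)
            res$species <<- readFeatureTable(speciesPath)
            res$norm <<- readFeatureTable(gcnPath)
        }
    }

    if (doDiv) {
        .needSpecies()
        totals <- sampleTotals(res$species)
        if (all(totals < config$samplingDepth))
            stop("every sample total is below the sampling depth of ",
                 config$samplingDepth)
        tree <- config$tree
        if (is.null(tree))
            tree <- syntheticTree(setdiff(rownames(res$species),
                                          "UNASSIGNED"),
                                  seed = config$seed)
        keep <- setdiff(rownames(res$species), "UNASSIGNED")
        divTab <- res$species[keep, ]
        div <- alphaDiversity(divTab, tree = tree,
                              depth = config$samplingDepth,
                              seed = config$seed)
        utils::write.table(div, file.path(outDir, "diversity.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        rc <- rarefactionCurve(divTab, depths = config$rarefactionDepths,
                               nIter = config$rarefactionIter, tree = tree,
                               seed = config$seed)
        utils::write.table(rc, file.path(outDir, "rarefaction.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        .logLine(logCon, "diversity | %d sample(s) at depth %d",
                 nrow(div), config$samplingDepth)
        res$diversity <- div
        res$rarefaction <- rc
    }

    if (doBias) {
        .needSpecies()
        report <- biasReport(res$species, config$designs, config$records)
        perSp <- as.data.frame(biasPerSpecies(report))
        utils::write.table(perSp, file.path(outDir, "bias_per_species.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        attribution <- attributeFactors(perSp)
        utils::write.table(attribution,
                           file.path(outDir, "bias_by_mode.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        reg <- biasRegression(report)
        if (length(reg))
            .logLine(logCon,
                     "bias | GC regression slope=%.4f R2=%.3f p=%.4g (n=%d)",
                     reg$slope, reg$r_squared, reg$p_value, reg$n)
        .logLine(logCon, "bias | mode ranking: %s",
                 paste(attribution$mode, collapse = " < "))
        res$bias <- report
        res$attribution <- attribution
    }

    invisible(res)
}
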