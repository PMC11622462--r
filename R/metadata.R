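#' @include AllGenerics.R
NULL

#' Construct a TaxonSet from a data frame
#'
#' @param df data frame with columns `species`, `strain`, `phylum`,
#'   `copy_number`, `copy_number_rank`, `genome_size_mb`, `gc_mol_percent`,
#'   `identity_pct`.
#' @return a [TaxonSet].
#' @export
TaxonSet <- function(df) {
    out <- new("TaxonSet", S4Vectors::DataFrame(df))
    rownames(out) <- out$strain
    validObject(out)
    out
}

#' Load a taxon metadata table
#'
#' Reads a tab-separated table of per-species genomic attributes (16S rRNA
#' gene copy number and whether it is a species-level value or a genus-level
#' mean, genome size in Mb, 16S G+C content in mol%, percent identity to the
#' nearest database reference) into a [TaxonSet]. The packaged fixtures
#' `taxa_biofilm.tsv` (13 milking-machine biofilm isolates) and
#' `taxa_meat.tsv` (14 raw-meat isolates) can be loaded with
#' [mockCommunityTaxa()].
#'
#' @param path path to a TSV file.
#' @return a [TaxonSet] with one record per row.
#' @export
loadTaxonTable <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- tryCatch(
        utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character",
                          check.names = FALSE, strip.white = TRUE),
        error = function(e) stop("schema error: unreadable taxon table: ",
                                 path, " (", conditionMessage(e), ")"))
    if (nrow(df) == 0) stop("schema error: empty taxon table: ", path)
    missing <- setdiff(.TAXON_COLUMNS, colnames(df))
    if (length(missing))
        stop("schema error: missing column(s): ",
             paste(missing, collapse = ", "))
    for (col in c("copy_number", "genome_size_mb", "gc_mol_percent",
                  "identity_pct")) {
        val <- suppressWarnings(as.numeric(df[[col]]))
        bad <- which(is.na(val) & nzchar(df[[col]]))
        if (length(bad))
            stop(sprintf("parse error: non-numeric '%s' in row %d", col, bad[1]))
        if (anyNA(val))
            stop(sprintf("parse error: missing '%s' in row %d", col,
                         which(is.na(val))[1]))
        df[[col]] <- val
    }
    TaxonSet(df)
}

#' Packaged mock community taxon tables
#'
#' @param habitat `"biofilm"` (13 members) or `"meat"` (14 members).
#' @return a [TaxonSet].
#' @export
mockCommunityTaxa <- function(habitat = c("biofilm", "meat")) {
    habitat <- match.arg(habitat)
    loadTaxonTable(system.file("extdata",
                               sprintf("taxa_%s.tsv", habitat),
                               package = "mockbench", mustWork = TRUE))
}

#' Summarize taxon attributes
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of the
#' 16S copy number, genome size and 16S G+C content across a [TaxonSet],
#' with a display rounding to one decimal alongside the full-precision
#' values.
#'
#' @param records a [TaxonSet] with at least 2 rows.
#' @return data frame with columns `attribute`, `mean`, `sd`,
#'   `mean_display`, `sd_display`.
#' @export
summarizeMetadata <- function(records) {
    if (nrow(records) < 2)
        stop("at least 2 records are required (SD undefined otherwise)")
    attrs <- c(copy_number = "copy_number", genome_size_mb = "genome_size_mb",
               gc_mol_percent = "gc_mol_percent")
    means <- vapply(attrs, function(a) mean(records[[a]]), numeric(1))
    sds <- vapply(attrs, function(a) stats::sd(records[[a]]), numeric(1))
    data.frame(attribute = names(attrs), mean = unname(means),
               sd = unname(sds), mean_display = round(unname(means), 1),
               sd_display = round(unname(sds), 1), row.names = NULL)
}

#' Construct a mock community design
#'
#' @param name community label.
#' @param habitat `"biofilm"` or `"meat"`.
#' @param mode `"EPS"` (whole cells), `"PS"` (mixed DNA) or `"S"` (mixed
#'   PCR products).
#' @param members strain labels of the community members.
#' @param log10Count named numeric, measured log10 cfu/ml (EPS mode).
#'   Unnamed scalar is recycled to all members.
#' @param massFraction named numeric, relative DNA mass (PS mode); defaults
#'   to equal mass.
#' @param dilution named numeric, log10 dilution factors (default: none).
#' @param belowDetection members whose counts were below the detection limit.
#' @param countOverride named numeric, declared log10 counts for members that
#'   cannot be plated (e.g. swarming strains).
#' @param detectionLimit log10 cfu/ml detection limit (default 6.6).
#' @return a [MockDesign].
#' @export
mockDesign <- function(name, habitat, mode, members, log10Count = numeric(0),
                       massFraction = numeric(0), dilution = numeric(0),
                       belowDetection = character(0),
                       countOverride = numeric(0), detectionLimit = 6.6) {
    if (length(log10Count) == 1 && is.null(names(log10Count)))
        log10Count <- stats::setNames(rep(log10Count, length(members)), members)
    dil <- stats::setNames(rep(0, length(members)), members)
    dil[names(dilution)] <- dilution
    new("MockDesign", name = name, habitat = habitat, mode = mode,
        members = members, log10Count = log10Count,
        massFraction = massFraction, dilution = dil,
        belowDetection = belowDetection, countOverride = countOverride,
        detectionLimit = detectionLimit)
}

# Resolve the effective log10 count for each member of a whole-cell design:
# below-detection members take the detection limit, unmeasured members their
# declared override.
.resolveLog10 <- function(design, measured = NULL) {
    vapply(design@members, function(m) {
        if (!is.null(measured) && m %in% names(measured)) return(measured[[m]])
        if (m %in% design@belowDetection) return(design@detectionLimit)
        if (m %in% names(design@log10Count) &&
            !is.na(design@log10Count[[m]])) return(design@log10Count[[m]])
        if (m %in% names(design@countOverride))
            return(design@countOverride[[m]])
        stop("configuration error: no resolvable count for member '", m, "'")
    }, numeric(1))
}

#' Preset (expected) community composition
#'
#' Computes per-member expected relative abundances from cultivation counts.
#' For whole-cell (EPS) designs the weight of member i is
#' `10^(L_i + d_i)` where `L_i` is the measured log10 cfu/ml — substituted by
#' the detection limit (default 6.6) when the member is flagged below
#' detection, or by its declared override when unmeasurable — and `d_i` is
#' the log10 dilution factor. For DNA-mix (PS) and amplicon-mix (S) designs
#' members enter with equal base weight, modified only by dilution factors.
#'
#' @param design a [MockDesign].
#' @param measured optional named numeric of measured log10 cfu/ml values
#'   overriding the design's stored counts.
#' @return named numeric vector of relative abundances summing to 1.
#' @export
presetComposition <- function(design, measured = NULL) {
    stopifnot(is(design, "MockDesign"))
    if (design@mode == "EPS") {
        L <- .resolveLog10(design, measured)
    } else {
        L <- stats::setNames(rep(0, length(design@members)), design@members)
        if (length(design@massFraction))
            L[names(design@massFraction)] <- log10(design@massFraction)
    }
    lw <- L + design@dilution[design@members]
    # exponentiate around the maximum to avoid overflow on extreme log scales
    w <- 10^(lw - max(lw))
    stats::setNames(w / sum(w), design@members)
}

#' The 16-sample benchmarking study layout
#'
#' Builds the full sample grid of the benchmarking design: ten whole-cell
#' samples (M1-M10, mode EPS) covering two biofilm replicate communities,
#' one meat community, and 10^4-fold dilution (log4red) or dominance
#' (log4dom) of *Acinetobacter guillouiae* M9, each extracted with one of
#' two kits; four DNA-mixture samples (M11-M14, mode PS) including log4red/
#' log4dom variants; and two pooled-amplicon samples (M15-M16, mode S).
#' Default target read depths span the range such experiments yield
#' per sample (about 3.5e3 to 5.5e4).
#'
#' @return list with `designs` (named list of [MockDesign], one per sample
#'   M1..M16) and `info` (data frame: sample, community, habitat, mode, kit,
#'   variant, n_reads).
#' @export
studyDesigns <- function() {
    bio <- mockCommunityTaxa("biofilm")
    meat <- mockCommunityTaxa("meat")
    bioM <- bio$strain
    meatM <- meat$strain
    ag <- "M9"   # Acinetobacter guillouiae, biofilm
    othersB <- setdiff(bioM, ag)

    bd_A <- c("M57", "M293a")            # below detection in community A
    bd_B <- c("M57", "M293a", "M169")    # community B additionally C. shigense
    bd_C <- "H14a"                       # R. nasimurium, meat community
    ovr_C <- c(H1 = 8)                   # P. mirabilis: not platable, 8 log10

    mcA <- mockDesign("MC A", "biofilm", "EPS", bioM, log10Count = 8,
                      belowDetection = bd_A)
    mcB <- mockDesign("MC B", "biofilm", "EPS", bioM, log10Count = 8,
                      belowDetection = bd_B)
    mcC <- mockDesign("MC C", "meat", "EPS", meatM, log10Count = 8,
                      belowDetection = bd_C, countOverride = ovr_C)
    mcD <- mockDesign("MC D", "biofilm", "EPS", bioM, log10Count = 8,
                      belowDetection = bd_B,
                      dilution = stats::setNames(-4, ag))
    mcE <- mockDesign("MC E", "biofilm", "EPS", bioM, log10Count = 8,
                      belowDetection = bd_B,
                      dilution = stats::setNames(rep(-4, length(othersB)),
                                                 othersB))
    mcF <- mockDesign("MC F", "biofilm", "PS", bioM)
    mcG <- mockDesign("MC G", "meat", "PS", meatM)
    mcH <- mockDesign("MC H", "biofilm", "PS", bioM,
                      dilution = stats::setNames(-4, ag))
    mcI <- mockDesign("MC I", "biofilm", "PS", bioM,
                      dilution = stats::setNames(rep(-4, length(othersB)),
                                                 othersB))
    mcJ <- mockDesign("MC J", "biofilm", "S", bioM)
    mcK <- mockDesign("MC K", "meat", "S", meatM)

    info <- data.frame(
        sample = paste0("M", 1:16),
        community = c("MC A", "MC A", "MC B", "MC B", "MC C", "MC C", "MC D",
                      "MC E", "MC D", "MC E", "MC F", "MC G", "MC H", "MC I",
                      "MC J", "MC K"),
        habitat = c(rep("biofilm", 4), "meat", "meat", rep("biofilm", 4),
                    "biofilm", "meat", "biofilm", "biofilm", "biofilm",
                    "meat"),
        mode = c(rep("EPS", 10), rep("PS", 4), "S", "S"),
        kit = c("1", "2", "1", "2", "1", "2", "2", "2", "1", "1",
                rep(NA, 6)),
        variant = c(rep("equal", 6), "log4red", "log4dom", "log4red",
                    "log4dom", "equal", "equal", "log4red", "log4dom",
                    "equal", "equal"),
        n_reads = c(13972, 5281, 19415, 55397, 3481, 44686, 46564, 53685,
                    27648, 45294, 19100, 17146, 21918, 55135, 13400, 17316),
        stringsAsFactors = FALSE)

    designs <- list(mcA, mcA, mcB, mcB, mcC, mcC, mcD, mcE, mcD, mcE,
                    mcF, mcG, mcH, mcI, mcJ, mcK)
    names(designs) <- info$sample
    list(designs = designs, info = info)
}
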