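#' @include features.R
NULL

#' Build a copy-number lookup from taxon records
#'
#' Constructs the species -> copy number and genus -> mean copy number
#' lookup used by [gcnNormalize()]. Records whose copy number is a
#' species-level match become species-rank entries; records carrying a
#' genus-level mean become genus-rank entries keyed by the genus name.
#'
#' @param records a [TaxonSet].
#' @return data frame with columns `rank` (`"species"` or `"genus"`),
#'   `name`, `copy_number`.
#' @export
copyNumberLookup <- function(records) {
    isSpecies <- records$copy_number_rank == "species"
    sp <- data.frame(rank = "species", name = records$species[isSpecies],
                     copy_number = records$copy_number[isSpecies])
    gn <- data.frame(rank = "genus",
                     name = vapply(strsplit(records$species[!isSpecies], " "),
                                   `[`, character(1), 1),
                     copy_number = records$copy_number[!isSpecies])
    out <- unique(rbind(sp, gn))
    if (any(out$copy_number < 1)) stop("copy numbers must be >= 1")
    rownames(out) <- NULL
    out
}

# Resolve the copy-number divisor for one species label:
# species entry -> genus-mean entry -> 1. UNASSIGNED always divides by 1.
.resolveDivisor <- function(species, lookup) {
    if (species == "UNASSIGNED")
        return(list(divisor = 1, path = "unassigned"))
    hit <- lookup$copy_number[lookup$rank == "species" &
                              lookup$name == species]
    if (length(hit)) return(list(divisor = hit[1], path = "species"))
    genus <- strsplit(species, " ")[[1]][1]
    hit <- lookup$copy_number[lookup$rank == "genus" & lookup$name == genus]
    if (length(hit)) return(list(divisor = hit[1], path = "genus_mean"))
    list(divisor = 1, path = "default")
}

#' 16S gene copy-number normalization
#'
#' Divides each species row by its 16S rRNA gene copy number, resolving
#' species -> genus mean -> 1. Unassigned rows always divide by 1, which is
#' the documented pitfall: when every assigned species has copy number > 1,
#' the relative share of the unassigned row strictly increases after
#' normalization. The resolution path per species is logged in
#' `metadata(.)$gcn_resolution`.
#'
#' @param table a species-level [FeatureTable].
#' @param lookup copy-number lookup as returned by [copyNumberLookup()] or
#'   [readCopyNumberLookup()].
#' @return a [FeatureTable] with `normalization = "gcn"` and real-valued
#'   counts.
#' @export
gcnNormalize <- function(table, lookup) {
    stopifnot(is(table, "FeatureTable"))
    m <- featureCounts(table)
    if (any(m < 0)) stop("counts must be non-negative")
    res <- lapply(rownames(m), .resolveDivisor, lookup = lookup)
    divisor <- vapply(res, `[[`, numeric(1), "divisor")
    log <- S4Vectors::DataFrame(species = rownames(m), divisor = divisor,
                                path = vapply(res, `[[`, character(1), "path"))
    out <- featureTable(m / divisor,
                        rowData = SummarizedExperiment::rowData(table),
                        colData = SummarizedExperiment::colData(table),
                        normalization = "gcn")
    S4Vectors::metadata(out)$gcn_resolution <- log
    out
}

#' Genome-size normalization for DNA-mixture samples
#'
#' For samples assembled from equal DNA masses per isolate, the genome count
#' of species i is proportional to `1 / g_i` (genome size), so recovering
#' cell-equivalent abundances multiplies each row by `g_i`. With
#' `combineWithGcn = TRUE` the row is additionally divided by the species'
#' 16S copy number, combining both corrections.
#'
#' @param table a species-level [FeatureTable].
#' @param records a [TaxonSet] supplying genome sizes (and copy numbers).
#' @param combineWithGcn also divide by 16S copy number (default `FALSE`).
#' @return a [FeatureTable] with `normalization = "gcn_genome"` when
#'   combined, else `"gcn"`-style real-valued counts flagged
#'   `"gcn_genome"`.
#' @export
genomeSizeNormalize <- function(table, records, combineWithGcn = FALSE) {
    stopifnot(is(table, "FeatureTable"))
    m <- featureCounts(table)
    species <- rownames(m)
    factor <- vapply(species, function(s) {
        if (s == "UNASSIGNED") return(1)
        idx <- which(records$species == s)
        if (!length(idx))
            stop("missing genome size for species '", s, "'")
        g <- records$genome_size_mb[idx[1]]
        if (combineWithGcn) g / records$copy_number[idx[1]] else g
    }, numeric(1))
    featureTable(m * factor,
                 rowData = SummarizedExperiment::rowData(table),
                 colData = SummarizedExperiment::colData(table),
                 normalization = "gcn_genome")
}

#' Relative abundances of a FeatureTable
#'
#' @param table a [FeatureTable].
#' @return matrix of per-sample relative abundances (columns sum to 1).
#' @export
relativeAbundance <- function(table) {
    m <- featureCounts(table)
    sweep(m, 2, colSums(m), "/")
}
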