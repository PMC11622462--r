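#' @include bias.R
NULL

#' Write a FeatureTable as TSV
#'
#' Features as rows, samples as columns. The normalization state is carried
#' in a `# normalization:` comment line preceding the header.
#'
#' @param table a [FeatureTable].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeFeatureTable <- function(table, path) {
    stopifnot(is(table, "FeatureTable"))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# normalization: %s", normalization(table)), con)
    m <- featureCounts(table)
    df <- data.frame(feature_id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a FeatureTable from TSV
#'
#' @param path TSV written by [writeFeatureTable()] (or any feature-by-
#'   sample TSV with a `feature_id` first column).
#' @return a [FeatureTable].
#' @export
readFeatureTable <- function(path) {
    first <- readLines(path, n = 1)
    norm <- "raw"
    if (startsWith(first, "# normalization:"))
        norm <- trimws(sub("# normalization:", "", first, fixed = TRUE))
    df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                            check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    featureTable(m, normalization = norm)
}

#' Write / read an assignment map as TSV
#'
#' Columns: feature_id, identity_pct, candidate_taxon, assigned_taxon,
#' threshold.
#'
#' @param map an [AssignmentMap].
#' @param path file path.
#' @return `path` (write) or an [AssignmentMap] (read).
#' @export
writeAssignmentMap <- function(map, path) {
    stopifnot(is(map, "AssignmentMap"))
    df <- as.data.frame(map)
    df$threshold <- map@threshold
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeAssignmentMap
#' @export
readAssignmentMap <- function(path) {
    df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
    assignTaxonomy(df, thresholdPct = df$threshold[1])
}

#' Read a copy-number lookup TSV
#'
#' Columns: `rank` (species|genus), `name`, `copy_number`.
#'
#' @param path TSV file.
#' @return lookup data frame for [gcnNormalize()].
#' @export
readCopyNumberLookup <- function(path) {
    df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
    req <- c("rank", "name", "copy_number")
    missing <- setdiff(req, colnames(df))
    if (length(missing))
        stop("missing column(s): ", paste(missing, collapse = ", "))
    if (!all(df$rank %in% c("species", "genus")))
        stop("rank must be 'species' or 'genus'")
    if (any(df$copy_number < 1)) stop("copy numbers must be >= 1")
    df
}

#' Read a square identity matrix TSV
#'
#' Header row and first column carry feature ids.
#'
#' @param path TSV file.
#' @return numeric matrix with feature ids as dimnames.
#' @export
readIdentityMatrix <- function(path) {
    df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                            stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    storage.mode(m) <- "double"
    m
}

#' Read a mock design from a YAML file
#'
#' Expected keys: `name`, `habitat`, `mode`, `members` (list with `strain`
#' and optionally `log10_cfu`, `mass_fraction`, `below_detection`,
#' `count_override`), `dilution` (map strain -> log10 factor),
#' `detection_limit`.
#'
#' @param path YAML file.
#' @return a [MockDesign].
#' @export
readMockDesign <- function(path) {
    cfg <- yaml::read_yaml(path)
    members <- vapply(cfg$members, `[[`, character(1), "strain")
    getNum <- function(key) {
        v <- vapply(cfg$members, function(m)
            if (!is.null(m[[key]])) as.numeric(m[[key]]) else NA_real_,
            numeric(1))
        stats::setNames(v, members)[!is.na(v)]
    }
    below <- members[vapply(cfg$members, function(m)
        isTRUE(m$below_detection), logical(1))]
    dil <- if (!is.null(cfg$dilution)) unlist(cfg$dilution) else numeric(0)
    mockDesign(name = cfg$name, habitat = cfg$habitat, mode = cfg$mode,
               members = members,
               log10Count = getNum("log10_cfu"),
               massFraction = getNum("mass_fraction"),
               dilution = dil, belowDetection = below,
               countOverride = getNum("count_override"),
               detectionLimit = if (!is.null(cfg$detection_limit))
                   cfg$detection_limit else 6.6)
}

#' Synthetic pairwise identity matrix from ground-truth features
#'
#' Builds the identity matrix a clustering step needs when features come
#' from the simulator rather than from real sequences: length variants of
#' the same species are highly similar (`withinSpecies`), features of
#' different species fall well below any clustering threshold
#' (`betweenSpecies`).
#'
#' @param truth DataFrame from [simulateExperiment()] (`feature_id`,
#'   `candidate_taxon`).
#' @param withinSpecies identity between features of the same species
#'   (default 99.9).
#' @param betweenSpecies identity between features of different species
#'   (default 90).
#' @return square numeric matrix with feature ids as dimnames.
#' @export
syntheticIdentityMatrix <- function(truth, withinSpecies = 99.9,
                                    betweenSpecies = 90) {
    ids <- truth$feature_id
    sp <- truth$candidate_taxon
    same <- outer(sp, sp, "==")
    m <- ifelse(same, withinSpecies, betweenSpecies)
    diag(m) <- 100
    dimnames(m) <- list(ids, ids)
    m
}
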