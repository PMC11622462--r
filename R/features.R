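#' @include simulate.R
NULL

#' Abundance and prevalence filtering of features
#'
#' Retains features present (count > 0) in at least `minSamples` samples and
#' with a read frequency of at least `minFrequency`. The frequency clause is
#' applied to the total count across samples by default
#' (`frequencyMode = "total"`); `"per_sample"` instead requires at least
#' `minSamples` samples to each reach `minFrequency` reads.
#'
#' @param table a raw [FeatureTable].
#' @param minSamples minimum number of samples with nonzero counts
#'   (default 2).
#' @param minFrequency minimum read frequency (default 100).
#' @param frequencyMode `"total"` or `"per_sample"`.
#' @return the filtered [FeatureTable]; dropped feature ids are recorded in
#'   `metadata(.)$filtered_out`.
#' @export
filterFeatures <- function(table, minSamples = 2, minFrequency = 100,
                           frequencyMode = c("total", "per_sample")) {
    stopifnot(is(table, "FeatureTable"))
    frequencyMode <- match.arg(frequencyMode)
    if (minSamples > ncol(table))
        stop("minSamples (", minSamples, ") exceeds the number of samples (",
             ncol(table), ")")
    m <- featureCounts(table)
    prevalence <- rowSums(m > 0)
    keep <- if (frequencyMode == "total") {
        prevalence >= minSamples & rowSums(m) >= minFrequency
    } else {
        prevalence >= minSamples & rowSums(m >= minFrequency) >= minSamples
    }
    out <- table[keep, ]
    S4Vectors::metadata(out)$filtered_out <- rownames(table)[!keep]
    out
}

#' Greedy de novo OTU clustering at an identity threshold
#'
#' Features are processed in decreasing total-abundance order (ties broken
#' by feature id); each feature joins the first existing cluster centroid
#' with pairwise identity >= `thresholdPct`, otherwise it founds a new
#' cluster. This is the abundance-ordered greedy centroid scheme typical of
#' de novo OTU pickers.
#'
#' @param identity square numeric matrix of pairwise percent identities with
#'   feature ids as dimnames; must be symmetric with 100 on the diagonal.
#' @param abundance named numeric vector of total feature abundances (same
#'   features as `identity`).
#' @param thresholdPct identity threshold in percent (e.g. 98.7 or 99.5).
#' @return data frame with columns `feature_id`, `centroid`; attribute
#'   `cluster_abundance` holds summed abundances per centroid.
#' @export
otuCluster <- function(identity, abundance, thresholdPct) {
    identity <- as.matrix(identity)
    if (nrow(identity) != ncol(identity) ||
        !isTRUE(all.equal(identity, t(identity), tolerance = 1e-8)))
        stop("identity matrix must be square and symmetric")
    if (!all(abs(diag(identity) - 100) < 1e-8))
        stop("identity matrix must have 100 on the diagonal")
    ids <- rownames(identity)
    if (is.null(ids)) stop("identity matrix needs feature ids as dimnames")
    abundance <- abundance[ids]
    ord <- ids[order(-abundance, ids)]
    centroids <- character(0)
    assignment <- stats::setNames(character(length(ids)), ids)
    for (f in ord) {
        hit <- NA_character_
        for (ctr in centroids) {
            if (identity[f, ctr] >= thresholdPct) { hit <- ctr; break }
        }
        if (is.na(hit)) { centroids <- c(centroids, f); hit <- f }
        assignment[f] <- hit
    }
    out <- data.frame(feature_id = ids, centroid = unname(assignment[ids]),
                      stringsAsFactors = FALSE)
    attr(out, "cluster_abundance") <-
        tapply(abundance, assignment[ids], sum)[centroids]
    out
}

#' Cluster a FeatureTable into OTUs
#'
#' Applies [otuCluster()] to a raw [FeatureTable] and sums member counts
#' into their centroid rows.
#'
#' @param table a [FeatureTable].
#' @param identity pairwise identity matrix over the table's features.
#' @param thresholdPct identity threshold in percent.
#' @return a [FeatureTable] with one row per cluster centroid.
#' @export
clusterFeatureTable <- function(table, identity, thresholdPct) {
    stopifnot(is(table, "FeatureTable"))
    cl <- otuCluster(identity[rownames(table), rownames(table)],
                     rowSums(featureCounts(table)), thresholdPct)
    m <- featureCounts(table)
    agg <- rowsum(m, group = cl$centroid, reorder = FALSE)
    rd <- SummarizedExperiment::rowData(table)[rownames(agg), , drop = FALSE]
    featureTable(agg, rowData = rd,
                 colData = SummarizedExperiment::colData(table),
                 normalization = normalization(table))
}

#' Identity-threshold species assignment
#'
#' Single-best-hit (maxaccepts 1) assignment: a feature is assigned its
#' candidate species when its percent identity to that best hit reaches
#' `thresholdPct`, and remains `"UNASSIGNED"` otherwise. No lowest-common-
#' ancestor or genus fallback is applied.
#'
#' @param candidates a data frame or DataFrame with columns `feature_id`,
#'   `identity_pct`, `candidate_taxon` (e.g. the `truth` component of
#'   [simulateExperiment()]).
#' @param thresholdPct assignment threshold in percent (98.7 is the
#'   conventional species delineation cutoff; 97 is the permissive
#'   alternative).
#' @return an [AssignmentMap].
#' @export
assignTaxonomy <- function(candidates, thresholdPct = 98.7) {
    candidates <- as.data.frame(candidates)
    req <- c("feature_id", "identity_pct", "candidate_taxon")
    missing <- setdiff(req, colnames(candidates))
    if (length(missing))
        stop("missing column(s): ", paste(missing, collapse = ", "))
    if (any(candidates$identity_pct <= 0 | candidates$identity_pct > 100))
        stop("identity_pct must lie in (0, 100]")
    assigned <- ifelse(candidates$identity_pct >= thresholdPct,
                       candidates$candidate_taxon, "UNASSIGNED")
    out <- new("AssignmentMap",
               S4Vectors::DataFrame(feature_id = candidates$feature_id,
                                    identity_pct = candidates$identity_pct,
                                    candidate_taxon = candidates$candidate_taxon,
                                    assigned_taxon = assigned),
               threshold = thresholdPct)
    validObject(out)
    out
}

#' Aggregate a feature table to species level
#'
#' Sums rows sharing an assigned species into one row per species;
#' unassigned features sum into a single `"UNASSIGNED"` row. Column sums
#' are conserved exactly.
#'
#' @param table a [FeatureTable].
#' @param map an [AssignmentMap] covering every feature of `table`.
#' @return a species-level [FeatureTable].
#' @export
aggregateBySpecies <- function(table, map) {
    stopifnot(is(table, "FeatureTable"), is(map, "AssignmentMap"))
    idx <- match(rownames(table), map$feature_id)
    if (anyNA(idx))
        stop("feature(s) missing from assignment map: ",
             paste(rownames(table)[is.na(idx)], collapse = ", "))
    species <- map$assigned_taxon[idx]
    m <- featureCounts(table)
    agg <- rowsum(m, group = species, reorder = TRUE)
    featureTable(agg, colData = SummarizedExperiment::colData(table),
                 normalization = normalization(table))
}
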