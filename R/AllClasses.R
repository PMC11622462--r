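#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom S4Vectors DFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

.TAXON_COLUMNS <- c("species", "strain", "phylum", "copy_number",
                    "copy_number_rank", "genome_size_mb", "gc_mol_percent",
                    "identity_pct")

.PHYLA <- c("Bacillota", "Actinomycetota", "Pseudomonadota", "Bacteroidota")

#' Reference attributes of mock community members
#'
#' A `TaxonSet` is a data-frame-like container holding one row per community
#' member: species and strain labels, phylum, 16S rRNA gene copy number per
#' genome (and whether it is a species-level match or a genus-level mean),
#' genome size in Mb, mol% G+C of the 16S rRNA gene, and the percent identity
#' of the isolate's 16S sequence to its nearest database reference.
#'
#' @seealso [loadTaxonTable()], [summarizeMetadata()]
#' @export
setClass("TaxonSet", contains = "DFrame")

setValidity("TaxonSet", function(object) {
    msg <- character(0)
    missing <- setdiff(.TAXON_COLUMNS, colnames(object))
    if (length(missing))
        return(sprintf("missing column(s): %s", paste(missing, collapse = ", ")))
    if (any(duplicated(object$strain)))
        msg <- c(msg, "strain labels must be unique")
    if (!all(object$phylum %in% .PHYLA))
        msg <- c(msg, sprintf("phylum must be one of %s",
                              paste(.PHYLA, collapse = ", ")))
    if (!all(object$copy_number_rank %in% c("species", "genus_mean")))
        msg <- c(msg, "copy_number_rank must be 'species' or 'genus_mean'")
    if (any(object$copy_number < 1)) msg <- c(msg, "copy_number must be >= 1")
    if (any(object$genome_size_mb <= 0)) msg <- c(msg, "genome_size_mb must be > 0")
    if (any(object$gc_mol_percent <= 0 | object$gc_mol_percent >= 100))
        msg <- c(msg, "gc_mol_percent must lie in (0, 100)")
    if (any(object$identity_pct <= 0 | object$identity_pct > 100))
        msg <- c(msg, "identity_pct must lie in (0, 100]")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' A named mock community design
#'
#' A `MockDesign` describes one benchmarking sample: the community members
#' (referenced by strain label), their cultivation counts in log10 cfu/ml
#' (for whole-cell communities) or relative DNA mass fractions (for DNA
#' mixtures), per-member log10 dilution factors, and the processing mode:
#' `"EPS"` (extraction + PCR + sequencing of mixed whole cells), `"PS"`
#' (PCR + sequencing of mixed DNA extracts), or `"S"` (sequencing of
#' equalized, pooled PCR products).
#'
#' Members whose cultivation counts fell below the plating detection limit
#' are listed in `belowDetection` and are substituted by `detectionLimit`
#' (default 6.6 log10 cfu/ml) when the preset composition is computed.
#' Members that cannot be counted at all (e.g. swarming strains) carry an
#' explicit override in `countOverride`.
#'
#' @slot name community label, e.g. "MC A".
#' @slot habitat `"biofilm"` or `"meat"`.
#' @slot mode `"EPS"`, `"PS"` or `"S"`.
#' @slot members character vector of strain labels.
#' @slot log10Count named numeric, measured log10 cfu/ml per member (`NA`
#'   where unmeasured).
#' @slot massFraction named numeric, relative DNA mass per member (PS mode).
#' @slot dilution named numeric, log10 dilution factor per member (0 = none).
#' @slot belowDetection character, members below the detection limit.
#' @slot countOverride named numeric, declared defaults for unmeasurable
#'   members.
#' @slot detectionLimit numeric, log10 cfu/ml plating detection limit.
#' @export
setClass("MockDesign",
    representation(name = "character", habitat = "character",
                   mode = "character", members = "character",
                   log10Count = "numeric", massFraction = "numeric",
                   dilution = "numeric", belowDetection = "character",
                   countOverride = "numeric", detectionLimit = "numeric"))

setValidity("MockDesign", function(object) {
    msg <- character(0)
    if (length(object@members) == 0) msg <- c(msg, "members must be non-empty")
    if (any(duplicated(object@members))) msg <- c(msg, "duplicate members")
    if (!object@mode %in% c("EPS", "PS", "S"))
        msg <- c(msg, "mode must be 'EPS', 'PS' or 'S'")
    if (!object@habitat %in% c("biofilm", "meat"))
        msg <- c(msg, "habitat must be 'biofilm' or 'meat'")
    if (!all(is.finite(object@dilution)))
        msg <- c(msg, "dilution factors must be finite")
    if (!all(names(object@dilution) %in% object@members))
        msg <- c(msg, "dilution names must be members")
    if (!all(object@belowDetection %in% object@members))
        msg <- c(msg, "belowDetection entries must be members")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Simulator settings for the three-layer bias model
#'
#' Parameters of the forward simulation of a mock-community sequencing
#' experiment: target read depth, PCR cycle count, per-cycle amplification
#' efficiency at the community-mean G+C and its linear decrease per mol%
#' G+C above the mean, optional per-phylum or per-strain extraction
#' efficiencies, optional Dirichlet-multinomial overdispersion of the final
#' read draw, and the master seed.
#'
#' @slot nReads target read depth; a single value or a named per-sample vector.
#' @slot pcrCycles number of PCR cycles (default 23).
#' @slot baseEfficiency per-cycle amplification efficiency in (0, 1] at the
#'   community-mean 16S G+C content.
#' @slot gcSlope efficiency decrease per mol% G+C above the community mean
#'   (>= 0; 0 disables GC bias).
#' @slot extractionEfficiency named numeric in (0, 1], keyed by strain label
#'   or phylum; members without an entry lyse with efficiency 1.
#' @slot noiseDispersion Dirichlet-multinomial overdispersion (0 = pure
#'   multinomial).
#' @slot splitTaxa strain labels whose reads are split 50/50 into two
#'   features (emulating length variants of one species).
#' @slot seed master seed; per-sample sub-seeds are derived from it.
#' @export
setClass("SimulationConfig",
    representation(nReads = "numeric", pcrCycles = "integer",
                   baseEfficiency = "numeric", gcSlope = "numeric",
                   extractionEfficiency = "numeric",
                   noiseDispersion = "numeric", splitTaxa = "character",
                   seed = "integer"))

setValidity("SimulationConfig", function(object) {
    msg <- character(0)
    if (any(object@nReads <= 0)) msg <- c(msg, "nReads must be positive")
    if (object@pcrCycles < 1L) msg <- c(msg, "pcrCycles must be >= 1")
    if (object@baseEfficiency <= 0 || object@baseEfficiency > 1)
        msg <- c(msg, "baseEfficiency must lie in (0, 1]")
    if (object@gcSlope < 0) msg <- c(msg, "gcSlope must be >= 0")
    if (length(object@extractionEfficiency) &&
        (any(object@extractionEfficiency <= 0) ||
         any(object@extractionEfficiency > 1)))
        msg <- c(msg, "extraction efficiencies must lie in (0, 1]")
    if (object@noiseDispersion < 0) msg <- c(msg, "noiseDispersion must be >= 0")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Features-by-samples count table
#'
#' A `FeatureTable` is a [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' holding a single `counts` assay with features as rows and samples as
#' columns, plus a `normalization` state: `"raw"` (integer read counts),
#' `"gcn"` (divided by 16S gene copy number) or `"gcn_genome"` (additionally
#' corrected for genome size).
#'
#' @slot normalization one of `"raw"`, `"gcn"`, `"gcn_genome"`.
#' @seealso [featureTable()], [filterFeatures()], [gcnNormalize()]
#' @export
setClass("FeatureTable", contains = "SummarizedExperiment",
         representation(normalization = "character"),
         prototype(normalization = "raw"))

setValidity("FeatureTable", function(object) {
    msg <- character(0)
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        return("assay 'counts' is required")
    m <- SummarizedExperiment::assay(object, "counts")
    if (any(m < 0)) msg <- c(msg, "counts must be non-negative")
    if (!object@normalization %in% c("raw", "gcn", "gcn_genome"))
        msg <- c(msg, "normalization must be 'raw', 'gcn' or 'gcn_genome'")
    if (identical(object@normalization, "raw") && any(m != floor(m)))
        msg <- c(msg, "raw tables must contain integer counts")
    if (any(duplicated(rownames(object)))) msg <- c(msg, "duplicate feature ids")
    if (any(duplicated(colnames(object)))) msg <- c(msg, "duplicate sample ids")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Feature-to-species assignments at an identity threshold
#'
#' One row per feature: the percent identity of the feature sequence to its
#' single best database hit (maxaccepts-1 semantics), the candidate species
#' of that hit, and the resulting assignment — the candidate species when
#' identity >= threshold, otherwise `"UNASSIGNED"`.
#'
#' @slot threshold the identity threshold (%) used for assignment.
#' @export
setClass("AssignmentMap", contains = "DFrame",
         representation(threshold = "numeric"))

setValidity("AssignmentMap", function(object) {
    req <- c("feature_id", "identity_pct", "candidate_taxon", "assigned_taxon")
    missing <- setdiff(req, colnames(object))
    if (length(missing))
        return(sprintf("missing column(s): %s", paste(missing, collapse = ", ")))
    msg <- character(0)
    if (any(duplicated(object$feature_id))) msg <- c(msg, "duplicate feature ids")
    if (any(object$identity_pct <= 0 | object$identity_pct > 100))
        msg <- c(msg, "identity_pct must lie in (0, 100]")
    una <- object$assigned_taxon == "UNASSIGNED"
    below <- object$identity_pct < object@threshold
    if (!identical(unname(una), unname(below)))
        msg <- c(msg, "assigned_taxon must be UNASSIGNED iff identity < threshold")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Preset-versus-observed bias summary
#'
#' Collects, per sample and species, the preset (expected) and observed
#' relative abundances and their log2 fold change; per-sample mean absolute
#' log2 fold changes with not-detected counts; an ordinary least squares
#' regression of log2 fold change on 16S G+C content; and optional
#' Kruskal-Wallis group contrasts with Benjamini-Hochberg correction.
#'
#' @slot perSpecies DataFrame: sample, species, preset, observed, log2fc,
#'   detected.
#' @slot perSample DataFrame: sample, mode, mean_abs_log2fc, n_not_detected.
#' @slot regression list: slope, intercept, r_squared, p_value, n.
#' @slot groupTests DataFrame of pairwise contrasts (may be empty).
#' @export
setClass("BiasReport",
    representation(perSpecies = "DFrame", perSample = "DFrame",
                   regression = "list", groupTests = "DFrame"))
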