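#' @include metadata.R
NULL

#' Construct simulator settings
#'
#' @param nReads target read depth; a single value or a named per-sample
#'   vector (default 20000).
#' @param pcrCycles PCR cycle count (default 23, the amplification protocol
#'   of the benchmark).
#' @param baseEfficiency per-cycle amplification efficiency at the
#'   community-mean 16S G+C content (default 0.9).
#' @param gcSlope efficiency decrease per mol% G+C above the community mean
#'   (default 0.01; 0 disables GC-dependent PCR bias).
#' @param extractionEfficiency named numeric in (0, 1], keyed by strain or
#'   phylum (default: all 1).
#' @param noiseDispersion Dirichlet-multinomial overdispersion of the read
#'   draw (default 0 = pure multinomial).
#' @param splitTaxa strain labels whose reads are split into two length-
#'   variant features of the same species (default none).
#' @param seed master seed.
#' @return a [SimulationConfig].
#' @export
simulationConfig <- function(nReads = 20000, pcrCycles = 23L,
                             baseEfficiency = 0.9, gcSlope = 0.01,
                             extractionEfficiency = numeric(0),
                             noiseDispersion = 0,
                             splitTaxa = character(0), seed = 1L) {
    new("SimulationConfig", nReads = nReads,
        pcrCycles = as.integer(pcrCycles),
        baseEfficiency = baseEfficiency, gcSlope = gcSlope,
        extractionEfficiency = extractionEfficiency,
        noiseDispersion = noiseDispersion, splitTaxa = splitTaxa,
        seed = as.integer(seed))
}

.memberRecords <- function(design, records) {
    idx <- match(design@members, records$strain)
    if (anyNA(idx))
        stop("member(s) not found in taxon records: ",
             paste(design@members[is.na(idx)], collapse = ", "))
    records[idx, , drop = FALSE]
}

.extractionEff <- function(recs, config) {
    eff <- config@extractionEfficiency
    vapply(seq_len(nrow(recs)), function(i) {
        if (recs$strain[i] %in% names(eff)) return(eff[[recs$strain[i]]])
        if (recs$phylum[i] %in% names(eff)) return(eff[[recs$phylum[i]]])
        1
    }, numeric(1))
}

#' Template pool entering PCR (or sequencing)
#'
#' Computes the per-taxon proportions of 16S template molecules for a
#' design, by processing mode. Whole-cell (EPS) designs contribute
#' `10^(L_i + d_i) * eff_i * c_i` (cells x lysis efficiency x 16S copies per
#' genome); DNA mixtures (PS) contribute `m_i * c_i / g_i` (equal DNA mass
#' means genome counts proportional to 1/genome size, times copies);
#' equalized amplicon pools (S) are uniform.
#'
#' @param design a [MockDesign].
#' @param records a [TaxonSet] resolving every member.
#' @param config a [SimulationConfig].
#' @return named numeric proportions summing to 1.
#' @export
templatePool <- function(design, records, config = simulationConfig()) {
    recs <- .memberRecords(design, records)
    n <- length(design@members)
    dil <- design@dilution[design@members]
    if (design@mode == "EPS") {
        L <- .resolveLog10(design)
        lw <- (L + dil) * log(10) + log(.extractionEff(recs, config)) +
              log(recs$copy_number)
    } else if (design@mode == "PS") {
        m <- stats::setNames(rep(1, n), design@members)
        if (length(design@massFraction))
            m[names(design@massFraction)] <- design@massFraction
        lw <- log(m) + dil * log(10) + log(recs$copy_number) -
              log(recs$genome_size_mb)
    } else if (design@mode == "S") {
        lw <- rep(0, n)
    } else stop("unknown mode: ", design@mode)
    w <- exp(lw - max(lw))
    stats::setNames(w / sum(w), design@members)
}

#' Per-taxon PCR amplification efficiencies
#'
#' Linear G+C model: `e_i = clamp(base - slope * (GC_i - mean GC), 0, 1)`,
#' with the mean taken over the community members.
#'
#' @param recs member rows of a [TaxonSet].
#' @param config a [SimulationConfig].
#' @return numeric vector of per-cycle efficiencies in \[0, 1\].
#' @keywords internal
.pcrEfficiency <- function(recs, config) {
    gc <- recs$gc_mol_percent
    e <- config@baseEfficiency - config@gcSlope * (gc - mean(gc))
    pmin(pmax(e, 0), 1)
}

#' Exponential-phase PCR amplification
#'
#' Applies the growth law `amplicon_i proportional to template_i *
#' (1 + e_i)^C` over `C` cycles, where the per-cycle efficiency `e_i`
#' decreases linearly with the taxon's 16S G+C content above the community
#' mean. With `gcSlope = 0` all efficiencies are equal and the composition
#' is unchanged. Template saturation (plateau phase) is not modeled.
#'
#' @param template named proportion vector (sums to 1).
#' @param records a [TaxonSet] resolving every template entry (by strain).
#' @param config a [SimulationConfig].
#' @return named proportion vector after amplification.
#' @export
amplify <- function(template, records, config = simulationConfig()) {
    stopifnot(abs(sum(template) - 1) < 1e-8)
    idx <- match(names(template), records$strain)
    if (anyNA(idx))
        stop("template entries not found in taxon records: ",
             paste(names(template)[is.na(idx)], collapse = ", "))
    recs <- records[idx, , drop = FALSE]
    e <- .pcrEfficiency(recs, config)
    lw <- log(template) + config@pcrCycles * log1p(e)
    lw[template == 0] <- -Inf
    w <- exp(lw - max(lw))
    stats::setNames(w / sum(w), names(template))
}

#' Draw sequencing read counts
#'
#' Multinomial sampling of reads from a proportion vector (or
#' Dirichlet-multinomial when `noiseDispersion > 0`, with Dirichlet
#' concentrations `p_i / noiseDispersion`).
#'
#' @param proportions named proportion vector summing to 1.
#' @param config a [SimulationConfig].
#' @param nReads read depth; defaults to `config@nReads` (first element).
#' @param seed RNG seed; defaults to `config@seed`.
#' @return named integer vector of counts summing to `nReads`.
#' @export
sequenceSample <- function(proportions, config = simulationConfig(),
                           nReads = NULL, seed = NULL) {
    stopifnot(abs(sum(proportions) - 1) < 1e-8)
    if (is.null(nReads)) nReads <- config@nReads[1]
    if (nReads <= 0) stop("nReads must be positive")
    if (is.null(seed)) seed <- config@seed
    set.seed(seed)
    p <- proportions
    if (config@noiseDispersion > 0) {
        alpha <- p / config@noiseDispersion
        g <- stats::rgamma(length(p), shape = alpha, rate = 1)
        g[alpha == 0] <- 0
        p <- if (sum(g) > 0) g / sum(g) else p
    }
    counts <- as.vector(stats::rmultinom(1, size = round(nReads), prob = p))
    stats::setNames(counts, names(proportions))
}

.featureId <- function(species, strain)
    paste(gsub("[^A-Za-z0-9]+", "_", species), strain, sep = "_")

#' Construct a FeatureTable
#'
#' @param counts numeric matrix, features x samples, with dimnames.
#' @param rowData optional DataFrame of feature metadata.
#' @param colData optional DataFrame of sample metadata.
#' @param normalization `"raw"`, `"gcn"` or `"gcn_genome"`.
#' @return a [FeatureTable].
#' @export
featureTable <- function(counts, rowData = NULL, colData = NULL,
                         normalization = "raw") {
    counts <- as.matrix(counts)
    args <- list(assays = list(counts = counts))
    if (!is.null(rowData)) args$rowData <- rowData
    if (!is.null(colData)) args$colData <- colData
    se <- do.call(SummarizedExperiment::SummarizedExperiment, args)
    new("FeatureTable", se, normalization = normalization)
}

#' Forward-simulate a mock community sequencing experiment
#'
#' For each design, composes the three bias layers — template pooling by
#' processing mode, exponential PCR amplification with G+C-dependent
#' efficiency (skipped in mode S, where purified amplicons are pooled
#' after amplification of single cultures), and multinomial read sampling —
#' into a post-denoising feature count table. By default each taxon yields
#' one feature; strains listed in `config@splitTaxa` are split 50/50 into
#' two length-variant features of the same species.
#'
#' Per-sample sub-seeds are derived deterministically from the master seed
#' and the sample index, so a fixed configuration is fully reproducible.
#'
#' @param designs named list of [MockDesign] (names become sample ids).
#' @param records a [TaxonSet] resolving every member of every design.
#' @param config a [SimulationConfig]; `config@nReads` may be a named
#'   per-sample vector.
#' @return list with `table` (a raw [FeatureTable], features x samples,
#'   with true species/strain and identity-to-reference in `rowData`) and
#'   `truth` (DataFrame: feature_id, candidate_taxon, identity_pct, strain
#'   — the ground-truth input for [assignTaxonomy()]).
#' @export
simulateExperiment <- function(designs, records,
                               config = simulationConfig()) {
    if (is.null(names(designs)) || any(!nzchar(names(designs))))
        stop("designs must be a named list (names are sample ids)")
    sampleIds <- names(designs)
    perSample <- lapply(seq_along(designs), function(i) {
        d <- designs[[i]]
        p <- templatePool(d, records, config)
        if (d@mode != "S") p <- amplify(p, records, config)
        depth <- if (!is.null(names(config@nReads)) &&
                     sampleIds[i] %in% names(config@nReads))
            config@nReads[[sampleIds[i]]] else config@nReads[1]
        sequenceSample(p, config, nReads = depth,
                       seed = config@seed + i)
    })

    # assemble the union feature space across designs
    strains <- unique(unlist(lapply(designs, function(d) d@members)))
    idx <- match(strains, records$strain)
    recs <- records[idx, , drop = FALSE]
    rowMeta <- data.frame(strain = strains, species = recs$species,
                          identity_pct = recs$identity_pct,
                          stringsAsFactors = FALSE)
    rowMeta$feature_id <- .featureId(rowMeta$species, rowMeta$strain)

    # optional split features: one taxon's reads divided over two variants
    if (length(config@splitTaxa)) {
        extra <- rowMeta[rowMeta$strain %in% config@splitTaxa, , drop = FALSE]
        rowMeta$variant <- ifelse(rowMeta$strain %in% config@splitTaxa, 1L, NA)
        extra$variant <- 2L
        rowMeta$feature_id <- ifelse(is.na(rowMeta$variant),
            rowMeta$feature_id, paste0(rowMeta$feature_id, "_v1"))
        extra$feature_id <- paste0(extra$feature_id, "_v2")
        rowMeta <- rbind(rowMeta, extra)
    }

    counts <- matrix(0L, nrow = nrow(rowMeta), ncol = length(designs),
                     dimnames = list(rowMeta$feature_id, sampleIds))
    for (i in seq_along(designs)) {
        cnt <- perSample[[i]]
        for (s in names(cnt)) {
            rows <- which(rowMeta$strain == s)
            if (length(rows) == 1) {
                counts[rows, i] <- cnt[[s]]
            } else if (length(rows) == 2) {
                half <- cnt[[s]] %/% 2L
                counts[rows[1], i] <- cnt[[s]] - half
                counts[rows[2], i] <- half
            }
        }
    }

    truth <- S4Vectors::DataFrame(feature_id = rowMeta$feature_id,
                                  candidate_taxon = rowMeta$species,
                                  identity_pct = rowMeta$identity_pct,
                                  strain = rowMeta$strain)
    colMeta <- S4Vectors::DataFrame(
        sample_id = sampleIds,
        community = vapply(designs, function(d) d@name, character(1)),
        habitat = vapply(designs, function(d) d@habitat, character(1)),
        mode = vapply(designs, function(d) d@mode, character(1)))
    rowData <- S4Vectors::DataFrame(rowMeta[, c("strain", "species",
                                                "identity_pct")])
    rownames(rowData) <- rowMeta$feature_id
    list(table = featureTable(counts, rowData = rowData, colData = colMeta),
         truth = truth)
}
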