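#' @include diversity.R
NULL

#' Per-species log2 fold changes of observed versus preset abundance
#'
#' `log2fc_i = log2(observed_i / preset_i)`. Species present in the design
#' but without any observed reads are flagged not-detected (`detected =
#' FALSE`, `log2fc = NA`) rather than assigned an infinite value; a species
#' observed but absent from the design (preset 0) is an error.
#'
#' @param observed named numeric vector of observed relative abundances
#'   over the design's species (entries may sum to slightly less than 1
#'   when part of the sample is unassigned).
#' @param preset named numeric vector from [presetComposition()] (sums
#'   to 1), on the same species set.
#' @return data frame: species, preset, observed, log2fc, detected.
#' @export
log2FoldChanges <- function(observed, preset) {
    if (abs(sum(preset) - 1) > 1e-8)
        stop("preset abundances must sum to 1")
    if (!setequal(names(observed), names(preset)))
        stop("observed and preset must cover the same species set")
    observed <- observed[names(preset)]
    if (any(preset == 0 & observed > 0))
        stop("species not in design (preset 0, observed > 0): ",
             paste(names(preset)[preset == 0 & observed > 0], collapse = ", "))
    detected <- observed > 0
    log2fc <- ifelse(detected, log2(observed / preset), NA_real_)
    data.frame(species = names(preset), preset = unname(preset),
               observed = unname(observed), log2fc = unname(log2fc),
               detected = unname(detected), row.names = NULL)
}

#' Regression of abundance deviation on 16S G+C content
#'
#' Ordinary least squares of per-species log2 fold change (observed vs
#' preset) on the 16S rRNA gene G+C content, with a two-sided p-value for
#' the slope. A negative slope indicates preferred amplification of
#' low-G+C taxa. Not-detected species (non-finite log2fc) are excluded.
#'
#' @param fc data frame from [log2FoldChanges()] (or any frame with
#'   `species` and `log2fc` columns).
#' @param records a [TaxonSet] supplying `gc_mol_percent` per species.
#' @return list: slope, intercept, r_squared, p_value, n.
#' @export
gcDeviationRegression <- function(fc, records) {
    fc <- fc[is.finite(fc$log2fc), , drop = FALSE]
    gc <- records$gc_mol_percent[match(fc$species, records$species)]
    ok <- !is.na(gc)
    gc <- gc[ok]; y <- fc$log2fc[ok]
    if (length(y) < 3)
        stop("at least 3 species with finite log2fc are required")
    if (stats::sd(gc) == 0) stop("zero variance in G+C content")
    fit <- stats::lm(y ~ gc)
    sm <- summary(fit)
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = sm$r.squared,
         p_value = sm$coefficients[2, 4],
         n = length(y))
}

#' Pairwise Kruskal-Wallis tests with Benjamini-Hochberg correction
#'
#' Runs a rank-based two-group Kruskal-Wallis test (tie-corrected) for each
#' requested contrast and adjusts the p-values across the contrast family
#' by the Benjamini-Hochberg step-up procedure.
#'
#' @param groups named list of numeric vectors (each of length >= 2).
#' @param contrasts list of length-2 character vectors naming group pairs;
#'   defaults to all pairs.
#' @return data frame: group1, group2, statistic, p_value, p_adjusted.
#' @export
kruskalBH <- function(groups, contrasts = NULL) {
    lens <- lengths(groups)
    if (any(lens < 2))
        stop("group(s) with fewer than 2 values: ",
             paste(names(groups)[lens < 2], collapse = ", "))
    if (is.null(contrasts)) {
        nm <- names(groups)
        contrasts <- utils::combn(nm, 2, simplify = FALSE)
    }
    rows <- lapply(contrasts, function(ct) {
        x <- groups[[ct[1]]]; y <- groups[[ct[2]]]
        if (stats::sd(c(x, y)) == 0) {
            stat <- 0; p <- 1     # all observations tied: no separation
        } else {
            kt <- stats::kruskal.test(list(x, y))
            stat <- unname(kt$statistic); p <- kt$p.value
        }
        data.frame(group1 = ct[1], group2 = ct[2], statistic = stat,
                   p_value = p)
    })
    out <- do.call(rbind, rows)
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
    out
}

#' Rank processing modes by mean absolute log2 fold change
#'
#' Summarizes a per-sample/per-species bias table into the mean absolute
#' log2 fold change per processing mode (EPS, PS, S), excluding
#' not-detected entries (their count is reported), and the induced ranking
#' (1 = least biased).
#'
#' @param perSpecies data frame with columns `mode`, `log2fc`, `detected`
#'   (e.g. `biasPerSpecies(report)`).
#' @return data frame: mode, mean_abs_log2fc, n_species, n_not_detected,
#'   rank.
#' @export
attributeFactors <- function(perSpecies) {
    perSpecies <- as.data.frame(perSpecies)
    modes <- unique(perSpecies$mode)
    if (!length(modes)) stop("no processing modes present")
    rows <- lapply(modes, function(md) {
        sub <- perSpecies[perSpecies$mode == md, , drop = FALSE]
        det <- sub[sub$detected & is.finite(sub$log2fc), , drop = FALSE]
        if (!nrow(det)) stop("mode '", md, "' has no detected species")
        data.frame(mode = md, mean_abs_log2fc = mean(abs(det$log2fc)),
                   n_species = nrow(det),
                   n_not_detected = sum(!sub$detected))
    })
    out <- do.call(rbind, rows)
    out$rank <- rank(out$mean_abs_log2fc, ties.method = "min")
    out[order(out$rank), , drop = FALSE]
}

#' Build a preset-versus-observed bias report
#'
#' For every sample, compares the observed species-level relative
#' abundances with the preset composition of its design, collects log2
#' fold changes, per-sample mean absolute log2 fold changes, and an OLS
#' regression of log2 fold change on 16S G+C content over the samples
#' selected by `regressionModes`.
#'
#' @param table species-level [FeatureTable] (rows are species; an
#'   `"UNASSIGNED"` row, if present, is ignored for the comparison but
#'   still contributes to each sample's total).
#' @param designs named list of [MockDesign], one entry per table column.
#' @param records a [TaxonSet] mapping strains to species and G+C content.
#' @param regressionModes processing modes pooled for the G+C regression
#'   (default `"PS"`, the PCR-dominated samples).
#' @return a [BiasReport].
#' @export
biasReport <- function(table, designs, records, regressionModes = "PS") {
    stopifnot(is(table, "FeatureTable"))
    if (!all(colnames(table) %in% names(designs)))
        stop("missing design(s) for sample(s): ",
             paste(setdiff(colnames(table), names(designs)), collapse = ", "))
    rel <- relativeAbundance(table)
    perSpecies <- list()
    perSample <- list()
    for (s in colnames(table)) {
        d <- designs[[s]]
        preset <- presetComposition(d)
        sp <- records$species[match(names(preset), records$strain)]
        preset <- stats::setNames(unname(preset), sp)
        obs <- stats::setNames(rep(0, length(sp)), sp)
        hit <- intersect(sp, rownames(rel))
        obs[hit] <- rel[hit, s]
        fc <- log2FoldChanges(obs, preset)
        fc <- cbind(sample = s, mode = d@mode, fc)
        perSpecies[[s]] <- fc
        det <- fc[fc$detected, , drop = FALSE]
        perSample[[s]] <- data.frame(sample = s, mode = d@mode,
            mean_abs_log2fc = mean(abs(det$log2fc)),
            n_not_detected = sum(!fc$detected))
    }
    perSpecies <- do.call(rbind, perSpecies)
    rownames(perSpecies) <- NULL
    perSample <- do.call(rbind, perSample)
    rownames(perSample) <- NULL
    regSub <- perSpecies[perSpecies$mode %in% regressionModes &
                         is.finite(perSpecies$log2fc), , drop = FALSE]
    regression <- if (nrow(regSub) >= 3)
        gcDeviationRegression(regSub, records) else list()
    new("BiasReport", perSpecies = S4Vectors::DataFrame(perSpecies),
        perSample = S4Vectors::DataFrame(perSample),
        regression = regression,
        groupTests = S4Vectors::DataFrame(matrix(nrow = 0, ncol = 0)))
}
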