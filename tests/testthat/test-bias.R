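test_that("log2 fold changes follow the log-ratio definition", {
    preset <- c(a = 0.5, b = 0.25, c = 0.25)
    same <- log2FoldChanges(preset, preset)
    expect_equal(same$log2fc, c(0, 0, 0))

    fc <- log2FoldChanges(c(a = 0.25, b = 0.5, c = 0.25), preset)
    expect_equal(fc$log2fc, c(-1, 1, 0))

    dbl <- log2FoldChanges(c(a = 0.5, b = 0.5, c = 0), c(a = 0.25, b = 0.5,
                                                         c = 0.25))
    expect_equal(dbl$log2fc[1], 1)
    expect_false(dbl$detected[3])           # observed 0: flagged, not -Inf
    expect_true(is.na(dbl$log2fc[3]))

    expect_error(log2FoldChanges(c(a = 0.5, b = 0.5), c(a = 1, b = 0)),
                 "not in design")
    expect_error(log2FoldChanges(c(a = 1), c(a = 0.7, b = 0.3)),
                 "same species set")
    expect_error(log2FoldChanges(c(a = 1, b = 0), c(a = 0.9, b = 0.2)),
                 "sum to 1")
})

test_that("swapping observed and preset negates every finite fold change", {
    set.seed(41)
    for (i in 1:10) {
        n <- sample(4:10, 1)
        p <- prop.table(runif(n)); q <- prop.table(runif(n))
        names(p) <- names(q) <- paste0("t", seq_len(n))
        a <- log2FoldChanges(q, p)$log2fc
        b <- log2FoldChanges(p, q)$log2fc
        expect_equal(a, -b, tolerance = 1e-12)
    }
})

test_that("GC regression matches the closed-form OLS solution", {
    recs <- TaxonSet(data.frame(
        species = paste("Sp", 1:5), strain = paste0("x", 1:5),
        phylum = "Bacillota", copy_number = 4,
        copy_number_rank = "species", genome_size_mb = 3,
        gc_mol_percent = c(50, 52, 54, 56, 58), identity_pct = 99))
    y <- c(1.2, 0.4, 0.1, -0.6, -1.3)
    fc <- data.frame(species = paste("Sp", 1:5), log2fc = y)
    fit <- gcDeviationRegression(fc, recs)

    gc <- recs$gc_mol_percent
    slopeHat <- sum((gc - mean(gc)) * (y - mean(y))) / sum((gc - mean(gc))^2)
    expect_equal(fit$slope, slopeHat)
    expect_equal(fit$intercept, mean(y) - slopeHat * mean(gc))
    expect_equal(fit$r_squared, cor(gc, y)^2)
    expect_equal(fit$n, 5)

    # exact line: R^2 = 1 with a negative slope; constant response: slope 0
    lin <- data.frame(species = paste("Sp", 1:5), log2fc = 3 - 0.5 * gc)
    fitLin <- suppressWarnings(gcDeviationRegression(lin, recs))
    expect_equal(fitLin$r_squared, 1)
    expect_lt(fitLin$slope, 0)
    flat <- data.frame(species = paste("Sp", 1:5), log2fc = rep(0.7, 5))
    expect_equal(suppressWarnings(gcDeviationRegression(flat, recs))$slope, 0)

    expect_error(gcDeviationRegression(fc[1:2, ], recs), "at least 3")
    flatDf <- as.data.frame(recs); flatDf$gc_mol_percent <- 55
    expect_error(gcDeviationRegression(fc, TaxonSet(flatDf)), "zero variance")
})

test_that("pairwise Kruskal-Wallis with BH correction matches hand computation", {
    groups <- list(lo = c(1, 2, 3), hi = c(10, 11, 12), same = c(5, 5, 5),
                   same2 = c(5, 5, 5))
    out <- kruskalBH(groups, contrasts = list(c("lo", "hi"),
                                              c("same", "same2")))
    # tie-free two-group H for n = 3, 3 with complete separation
    expect_equal(out$statistic[1], 3.857, tolerance = 1e-3)
    expect_equal(out$statistic[1],
                 unname(kruskal.test(list(c(1, 2, 3),
                                          c(10, 11, 12)))$statistic))
    expect_equal(out$statistic[2], 0)
    expect_equal(out$p_value[2], 1)
    expect_true(all(out$p_adjusted >= out$p_value))
    expect_true(all(out$p_adjusted <= 1))
    expect_error(kruskalBH(list(a = 1, b = c(1, 2))), "fewer than 2")
})

test_that("BH adjustment follows the step-up definition", {
    # raw (0.01, 0.02, 0.03, 0.04) over 4 contrasts -> all adjusted to 0.04
    groups <- list(g1 = c(1, 2), g2 = c(3, 4))
    raw <- c(0.01, 0.02, 0.03, 0.04)
    expect_equal(p.adjust(raw, method = "BH"), rep(0.04, 4))
    # and adjusted p's stay ordered with raw p's on random families
    set.seed(13)
    for (i in 1:5) {
        p <- runif(6)
        adj <- p.adjust(p, method = "BH")
        expect_true(all(diff(adj[order(p)]) >= -1e-12))
    }
})

test_that("factor attribution ranks modes by mean absolute fold change", {
    perSp <- data.frame(
        mode = rep(c("EPS", "PS", "S"), each = 3),
        log2fc = c(1, -1, 0.5, 2, -2, 1, 0.1, -0.1, 0),
        detected = TRUE)
    out <- attributeFactors(perSp)
    expect_equal(out$mode, c("S", "EPS", "PS"))
    expect_equal(out$mean_abs_log2fc, c(0.2 / 3, 2.5 / 3, 5 / 3))
    expect_equal(out$rank, 1:3)

    tied <- data.frame(mode = c("EPS", "PS", "S"), log2fc = 0.3,
                       detected = TRUE)
    expect_equal(attributeFactors(tied)$rank, rep(1, 3))

    nd <- data.frame(mode = c("S", "S"), log2fc = c(0.5, NA),
                     detected = c(TRUE, FALSE))
    expect_equal(attributeFactors(nd)$n_not_detected, 1)
    expect_error(attributeFactors(data.frame(mode = "S", log2fc = NA,
                                             detected = FALSE)),
                 "no detected species")

    # single-species samples have composition forced to 1: zero bias
    single <- data.frame(mode = c("EPS", "PS", "S"), log2fc = 0,
                         detected = TRUE)
    expect_equal(attributeFactors(single)$mean_abs_log2fc, rep(0, 3))
})

test_that("simulation recovers the negative GC slope and the mode ranking", {
    layout <- studyDesigns()
    negSlope <- logical(20)
    sBelow <- logical(20)
    for (i in 1:20) {
        cfg <- simulationConfig(nReads = 8000, gcSlope = 0.01,
                                seed = 5000 + 37 * i)
        sim <- simulateExperiment(layout$designs, allTaxa, cfg)
        map <- assignTaxonomy(sim$truth, 97)   # permissive: every species kept
        species <- aggregateBySpecies(sim$table, map)
        rep <- biasReport(species, layout$designs, allTaxa,
                          regressionModes = "PS")
        negSlope[i] <- biasRegression(rep)$slope < 0
        att <- attributeFactors(as.data.frame(biasPerSpecies(rep)))
        mf <- setNames(att$mean_abs_log2fc, att$mode)
        sBelow[i] <- mf["S"] < mf["PS"] && mf["S"] < mf["EPS"]
    }
    expect_gte(sum(negSlope), 19)
    expect_gte(sum(sBelow), 19)
})

test_that("bias reports assemble per-sample comparisons against the preset", {
    layout <- studyDesigns()
    cfg <- simulationConfig(nReads = 10000, seed = 2L)
    sim <- simulateExperiment(layout$designs[c("M15", "M16")], allTaxa, cfg)
    map <- assignTaxonomy(sim$truth, 98.7)
    species <- aggregateBySpecies(sim$table, map)
    rep <- biasReport(species, layout$designs, allTaxa)
    ps <- as.data.frame(biasPerSpecies(rep))
    expect_setequal(unique(ps$sample), c("M15", "M16"))
    expect_equal(sum(ps$sample == "M15"), 13)
    expect_equal(sum(ps$sample == "M16"), 14)
    # A. pullicarnis is unassigned at 98.7% and therefore not detected
    ap <- ps[ps$sample == "M16" & ps$species == "Acinetobacter pullicarnis", ]
    expect_false(ap$detected)
    smp <- as.data.frame(biasPerSample(rep))
    expect_equal(smp$n_not_detected[smp$sample == "M16"], 1)
    # equalized amplicon pools track the uniform preset closely
    expect_lt(max(abs(ps$log2fc[ps$sample == "M15"])), 0.5)
})
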