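cfgNull <- simulationConfig(gcSlope = 0, seed = 7L)

test_that("template pools follow the mode-specific arithmetic", {
    # PS: equal mass, proportions follow c/g
    p <- templatePool(toyDesign("PS"), toyTaxa)
    expect_equal(unname(p), c(2 / 3, 1 / 3))   # (6/2.7) : (6/5.4)

    # EPS with uniform cells and efficiencies 1: proportional to copy number
    members <- bioTaxa$strain
    d <- mockDesign("eps", "biofilm", "EPS", members, log10Count = 8)
    p2 <- templatePool(d, bioTaxa, cfgNull)
    expect_equal(unname(p2),
                 bioTaxa$copy_number / sum(bioTaxa$copy_number),
                 tolerance = 1e-12)

    # S: uniform regardless of design details
    d3 <- mockDesign("s", "biofilm", "S", members, log10Count = 8,
                     dilution = setNames(-4, "M9"))
    expect_equal(unname(templatePool(d3, bioTaxa)), rep(1 / 13, 13))
})

test_that("template proportions sum to one across modes and designs", {
    for (mode in c("EPS", "PS", "S")) {
        d <- mockDesign("x", "meat", mode, meatTaxa$strain, log10Count = 8,
                        countOverride = c(H1 = 8),
                        dilution = setNames(-4, "R7a"))
        p <- templatePool(d, meatTaxa)
        expect_true(all(p >= 0))
        expect_equal(sum(p), 1, tolerance = 1e-12)
    }
})

test_that("extraction efficiencies resolve by strain then phylum", {
    d <- toyDesign("EPS")
    cfg <- simulationConfig(gcSlope = 0,
                            extractionEfficiency = c(Bacillota = 0.5))
    p <- templatePool(d, toyTaxa, cfg)
    # T1 (Bacillota) lysed at 0.5, T2 at 1; copy numbers equal
    expect_equal(unname(p), c(1 / 3, 2 / 3))
    cfgStrain <- simulationConfig(gcSlope = 0,
                                  extractionEfficiency = c(T1 = 0.5,
                                                           Bacillota = 1))
    expect_equal(unname(templatePool(d, toyTaxa, cfgStrain)), c(1 / 3, 2 / 3))
})

test_that("amplification reduces to the closed-form ratio law", {
    # gcSlope 0: composition unchanged
    p <- c(T1 = 0.3, T2 = 0.7)
    expect_equal(amplify(p, toyTaxa, cfgNull), p, tolerance = 1e-12)

    # two taxa with efficiencies 0.9 / 0.8 after 23 cycles: (1.9/1.8)^23
    # with base 0.85 and this slope the two efficiencies are exactly 0.9 / 0.8
    gcs <- toyTaxa$gc_mol_percent
    cfg <- simulationConfig(baseEfficiency = 0.85,
                            gcSlope = 0.1 / (gcs[2] - gcs[1]))
    out <- amplify(c(T1 = 0.5, T2 = 0.5), toyTaxa, cfg)
    expect_equal(unname(out[1] / out[2]), (1.9 / 1.8)^23, tolerance = 1e-10)

    # single-taxon community: proportion 1 regardless of parameters
    one <- TaxonSet(as.data.frame(toyTaxa)[1, ])
    expect_equal(unname(amplify(c(T1 = 1), one,
                                simulationConfig(gcSlope = 0.3))), 1)
})

test_that("read sampling is multinomial, seeded, and depth-conserving", {
    one <- TaxonSet(as.data.frame(toyTaxa)[1, ])
    expect_equal(unname(sequenceSample(c(T1 = 1), nReads = 5000, seed = 1)),
                 5000)
    expect_error(sequenceSample(c(T1 = 1), nReads = 0), "positive")

    p <- setNames(rep(1 / 13, 13), paste0("s", 1:13))
    a <- sequenceSample(p, nReads = 2000, seed = 99)
    b <- sequenceSample(p, nReads = 2000, seed = 99)
    expect_identical(a, b)
    expect_equal(sum(a), 2000)

    # 200 replicates: per-taxon mean within 3 binomial standard errors
    nReads <- 50000; reps <- 200
    acc <- vapply(seq_len(reps), function(i)
        sequenceSample(p, nReads = nReads, seed = 1000 + i), numeric(13))
    se <- sqrt(nReads * (1 / 13) * (12 / 13)) / sqrt(reps)
    expect_true(all(abs(rowMeans(acc) - nReads / 13) < 3 * se))
})

test_that("overdispersed sampling inflates variance but keeps the mean", {
    p <- c(a = 0.5, b = 0.5)
    cfgOd <- simulationConfig(noiseDispersion = 0.05)
    draws <- vapply(1:300, function(i)
        sequenceSample(p, cfgOd, nReads = 1000, seed = 2000 + i)[1],
        numeric(1))
    multinomVar <- 1000 * 0.25
    expect_gt(var(draws), 2 * multinomVar)
    expect_lt(abs(mean(draws) - 500), 5 * sqrt(var(draws) / 300))
})

test_that("the simulated experiment mirrors the 16-sample study layout", {
    layout <- studyDesigns()
    expect_equal(names(layout$designs), paste0("M", 1:16))
    expect_equal(layout$info$mode,
                 c(rep("EPS", 10), rep("PS", 4), "S", "S"))
    cfg <- simulationConfig(
        nReads = setNames(layout$info$n_reads, layout$info$sample),
        seed = 11L)
    sim <- simulateExperiment(layout$designs, allTaxa, cfg)
    expect_s4_class(sim$table, "FeatureTable")
    expect_equal(ncol(sim$table), 16)
    expect_equal(unname(sampleTotals(sim$table)), layout$info$n_reads)
    expect_true(all(range(sampleTotals(sim$table)) >= 3e3))
    expect_true(all(sim$truth$feature_id == rownames(sim$table)))
    expect_setequal(unique(SummarizedExperiment::colData(sim$table)$mode),
                    c("EPS", "PS", "S"))
})

test_that("split features divide one taxon's reads between two variants", {
    layout <- studyDesigns()
    cfg <- simulationConfig(nReads = 10000, seed = 3L, splitTaxa = "H6a")
    sim <- simulateExperiment(layout$designs["M16"], allTaxa, cfg)
    pa <- grep("Pantoea", rownames(sim$table), value = TRUE)
    expect_length(pa, 2)
    cnt <- featureCounts(sim$table)[pa, 1]
    expect_lte(abs(cnt[1] - cnt[2]), 1)
    expect_equal(sum(featureCounts(sim$table)[, 1]), 10000)
    expect_equal(unique(sim$truth$candidate_taxon[
        sim$truth$feature_id %in% pa]), "Pantoea agglomerans")
})

test_that("with all biases off the composition matches the preset", {
    # S-mode template is uniform and equals the uniform preset; EPS with
    # equal copy numbers behaves the same
    members <- paste0("s", 1:13)
    recs <- TaxonSet(data.frame(
        species = paste("Genus", members), strain = members,
        phylum = "Bacillota", copy_number = 4,
        copy_number_rank = "species", genome_size_mb = 3,
        gc_mol_percent = 53, identity_pct = 99.9))
    d <- mockDesign("null", "biofilm", "EPS", members, log10Count = 8)
    preset <- presetComposition(d)
    cfg <- simulationConfig(gcSlope = 0, nReads = 20000)
    reps <- 100
    acc <- vapply(seq_len(reps), function(i) {
        p <- amplify(templatePool(d, recs, cfg), recs, cfg)
        sequenceSample(p, cfg, seed = 500 + i) / 20000
    }, numeric(13))
    se <- apply(acc, 1, sd) / sqrt(reps)
    expect_true(all(abs(rowMeans(acc) - preset) < 3 * se + 1e-12))
})

test_that("a positive GC slope depresses high-GC taxa", {
    d <- mockDesign("gc", "meat", "EPS", meatTaxa$strain, log10Count = 8,
                    countOverride = c(H1 = 8))
    preset <- presetComposition(d)
    cfg0 <- simulationConfig(gcSlope = 0.02, nReads = 30000)
    negative <- vapply(1:20, function(i) {
        cfg <- simulationConfig(gcSlope = 0.02, nReads = 30000,
                                seed = 100 + i)
        p <- amplify(templatePool(d, meatTaxa, cfg), meatTaxa, cfg)
        cnt <- sequenceSample(p, cfg, seed = 100 + i)
        dev <- log2((cnt / sum(cnt) + 1e-9) / preset)
        cor(meatTaxa$gc_mol_percent, dev, method = "spearman") < 0
    }, logical(1))
    expect_true(all(negative))
})
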