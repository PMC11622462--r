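# mockbench

Benchmarking bias in full-length 16S rRNA gene amplicon sequencing of
defined bacterial mock communities.

## The problem

Amplicon sequencing of the 16S rRNA gene is the workhorse for profiling
food-associated microbiomes, but the relative abundances it reports are
distorted at every step: DNA extraction (lysis efficiency differs between
taxa), PCR amplification (per-cycle efficiency depends on the template's
G+C content), sequencing itself, and bioinformatic choices (identity
thresholds for species assignment, 16S gene copy-number normalization).
Mock communities — defined mixtures of known strains with known cultivation
counts — make these distortions measurable, because the *preset*
composition is known.

`mockbench` is for researchers who want to quantify and attribute such
bias. It implements:

- **Preset compositions** from cultivation counts:
  abundance_i = 10^(L_i + d_i) / Σ_j 10^(L_j + d_j), where L_i is the
  measured log10 cfu/ml (substituted by the plating detection limit of
  6.6 log10 when a member is below detection) and d_i a log10 dilution
  factor.
- A **mechanistic forward simulator** of the three bias layers for
  whole-cell (E/P/S), mixed-DNA (P/S) and pooled-amplicon (S) designs:
  template_i ∝ cells_i · lysis_i · c_i (copies per genome) or m_i·c_i/g_i
  (equal DNA mass), exponential PCR with amplicon_i ∝ template_i·(1+e_i)^C
  where e_i = clamp(e₀ − s·(GC_i − mean GC), 0, 1), and multinomial (or
  Dirichlet-multinomial) read sampling.
- The **evaluation stack**: prevalence/frequency feature filtering (≥ 2
  samples, ≥ 100 reads), greedy de novo OTU clustering at an identity
  threshold (98.7 / 99.5 %), single-best-hit species assignment at an
  identity cutoff (98.7 vs 97 %), 16S copy-number normalization with
  genus-mean fallback (and the unassigned-divides-by-one pitfall), genome-
  size normalization for DNA mixtures, alpha diversity (Shannon H in bits,
  Pielou J = H/log2(S), Faith PD, observed features) with rarefaction, and
  bias attribution via per-species log2(observed/preset) fold changes, an
  OLS regression of log2FC on 16S G+C content, and pairwise Kruskal-Wallis
  tests with Benjamini-Hochberg correction.

Two curated communities ship with the package: 13 milking-machine biofilm
isolates and 14 raw-meat isolates, with per-species 16S copy numbers,
genome sizes, 16S G+C content and identity to the nearest database
reference.

## Worked example

```r
library(mockbench)

taxa <- TaxonSet(rbind(as.data.frame(mockCommunityTaxa("biofilm")),
                       as.data.frame(mockCommunityTaxa("meat"))))
layout <- studyDesigns()                 # the 16-sample benchmarking grid
cfg <- simulationConfig(nReads = 10000, gcSlope = 0.01, seed = 1)

sim <- simulateExperiment(layout$designs, taxa, cfg)
sim$table
#> FeatureTable: 27 features x 16 samples [raw]

map     <- assignTaxonomy(sim$truth, 98.7)
species <- aggregateBySpecies(sim$table, map)
report  <- biasReport(species, layout$designs, taxa, regressionModes = "PS")
report
#> BiasReport: 212 sample/species rows, 16 samples
#>   GC regression: slope -0.1860, R^2 0.249, p 0.0003568 (n = 47)

attributeFactors(as.data.frame(biasPerSpecies(report)))
#>   mode mean_abs_log2fc n_species n_not_detected rank
#> 3    S      0.05359678        26              1    1
#> 1  EPS      0.62120553       108             24    2
#> 2   PS      0.62906459        47              6    3
```

Reading the output: the G+C regression slope is negative — low-G+C taxa
are preferentially amplified, inflating their observed abundance — and
pooled-amplicon samples (mode S, sequencing only) show an order of
magnitude less bias (mean |log2FC| ≈ 0.05) than samples that passed
through PCR (P/S and E/P/S, ≈ 0.6): PCR amplification is the dominant
bias source. The one not-detected species in mode S is the novel
*Acinetobacter* isolate (98.2 % identity), which stays unassigned at the
98.7 % threshold.

A thin command-line wrapper around the same pipeline lives at
`inst/scripts/run_pipeline.R`:

```sh
Rscript inst/scripts/run_pipeline.R --stage all --seed 1 --out results_dir
```

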