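---
title: "Modeling and attributing bias in mock community 16S amplicon sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and attributing bias in mock community 16S amplicon sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and model

`mockbench` treats a mock-community sequencing experiment as a chain of
three multiplicative distortions applied to a known cell composition,
followed by multinomial read sampling. The package covers defined
communities processed at three levels: mixed whole cells
(extraction + PCR + sequencing, "EPS"), mixed DNA extracts of single
cultures (PCR + sequencing, "PS"), and pooled, concentration-equalized PCR
products of single cultures (sequencing only, "S"). Comparing observed
against preset compositions across these modes attributes the overall bias
to its experimental layers.

### Preset composition

The preset relative abundance of member $i$ is
$$a_i = \frac{10^{L_i + d_i}}{\sum_j 10^{L_j + d_j}},$$
with $L_i$ the measured cultivation count in log10 cfu/ml and $d_i$ a
log10 dilution factor. Counts are carried in log10 units end to end and
exponentiated only here (shifted by the maximum exponent), so that
$10^{4}$-fold dominance/dilution designs cannot overflow and the result is
invariant to adding a constant to all log counts. Two substitution rules
reflect how such communities are actually assembled: members whose plate
counts fell below the detection limit enter at that limit (default
6.6 log10 cfu/ml), and members that cannot be plated at all (e.g. swarming
strains) carry an explicit per-member override rather than a hard-coded
special case, so other unplatable strains can reuse the mechanism.

### The three bias layers

**Template pooling.** EPS designs contribute
$t_i \propto 10^{L_i + d_i}\,\varepsilon_i\,c_i$ (cells × lysis efficiency
× 16S copies per genome); PS designs contribute
$t_i \propto m_i c_i / g_i$, because equal DNA mass per isolate means
genome counts proportional to $1/g_i$ (genome size in Mb); S designs are
uniform, because purified amplicons are equalized before pooling.
Extraction efficiencies $\varepsilon_i$ resolve by strain first, then
phylum, then default to 1 — the benchmark this package emulates found no
significant kit effect and quantified no per-taxon lysis efficiencies, so
guessing kit-specific values would add unsupported structure. The
parameter exists for users who have such measurements.

**PCR amplification.** Exponential growth over $C$ cycles with a linear
G+C-dependent per-cycle efficiency:
$$A_i \propto t_i\,(1 + e_i)^C, \qquad
  e_i = \mathrm{clamp}\!\left(e_0 - s\,(GC_i - \overline{GC}),\ 0,\ 1\right).$$
Only the *sign* of the G+C effect is empirically established (low-G+C
templates amplify preferentially, visible as a negative correlation
between G+C content and abundance deviation); the exponential-with-
efficiency form is the standard PCR kinetics choice and keeps the
per-cycle parameter interpretable. Defaults: $C = 23$ cycles (the
amplification protocol of the benchmark), $e_0 = 0.9$, and
$s = 0.01$ per mol% G+C. With the ~7.6 mol% G+C span of the packaged
communities, $s = 0.01$ yields per-species |log2FC| values of roughly
0.5–2 after 23 cycles, the magnitude range such benchmarks report.
Template saturation (plateau phase) is deliberately not modeled; 23
cycles are treated as exponential phase throughout, and this is a known
limitation for users simulating high-cycle protocols.

**Read sampling.** Multinomial by default, so null tests have exact
sampling distributions. Setting `noiseDispersion` $> 0$ switches to a
Dirichlet-multinomial with concentrations $p_i/\phi$, adding between-
replicate overdispersion without changing the mean. One master seed
drives everything; per-sample sub-seeds are derived from the sample index,
so a 16-sample experiment is reproducible column by column.

### What the simulator emulates — and what it does not

The simulator emits *post-denoising feature count tables*: one feature per
taxon, optionally splitting one species' reads 50/50 into two
length-variant features (mirroring the real phenomenon of one species
yielding two denoised sequence variants). It does not simulate sequences,
read errors, chimeras, or denoising itself; identity-to-reference values
are attributes of the taxa, not alignments. Consequently, passing tests
demonstrate that the *evaluation stack* (filtering, clustering,
assignment, normalization, diversity, attribution) behaves correctly on
data with the right structure and biases — they cannot validate denoising
pipelines or error models against real reads.

## The evaluation stack

- **Filtering** keeps features present in ≥ 2 samples with a total read
  frequency ≥ 100. Whether the published filter read "frequency" as total
  or per-sample is ambiguous; total matches the common prevalence-filter
  idiom and is the default, with `frequencyMode = "per_sample"` as the
  switchable alternative.
- **OTU clustering** is greedy, abundance-ordered centroid clustering on a
  pairwise identity matrix: features are processed in decreasing
  total-abundance order (ties broken lexicographically by feature id, so
  reruns are deterministic) and join the first centroid at or above the
  threshold. Thresholds of interest are 98.7 % (species delineation) and
  99.5 % (for communities with very similar members).
- **Species assignment** is single-best-hit (maxaccepts 1): assigned iff
  identity ≥ threshold, otherwise `UNASSIGNED`, with no genus/LCA
  fallback. This makes the threshold's effect sharp: a novel species at
  98.2 % identity is unassigned at 98.7 % and assigned at 97 %.
- **Copy-number normalization** divides each species row by its 16S copy
  number, resolving species → genus mean → 1, and always divides
  `UNASSIGNED` by 1. The resolution path is logged per row precisely so
  the resulting artifact — unassigned features become overrepresented
  whenever every assigned species has more than one 16S copy — is
  auditable rather than silent. Normalized counts stay real-valued;
  rarefaction floors them and reports the total lost to flooring, since
  the rounding rule of the published plugin chain is unstated.
- **Genome-size normalization** multiplies DNA-mixture rows by $g_i$
  (undoing the $1/g_i$ genome-count distortion of equal-mass pooling) and,
  combined with the copy-number correction, cancels the $c_i/g_i$ read
  bias exactly, restoring the equal-mass preset. This operational
  definition is chosen over matching a reported per-species direction of
  change that is not derivable from any printed formula.

## Diversity conventions

Shannon entropy is computed in bits — forced by the analytic maxima
$\log_2 13 = 3.70$ and $\log_2 14 = 3.81$ of uniform 13/14-member
communities. Pielou's $J = H/\log_2 S$ is defined as 0 when $S = 1$
(single observed feature). Faith PD sums the branch lengths of the
minimal subtree connecting the present tips *and the root*
(root-inclusive, the convention of phylogenetic core-metrics pipelines),
exposed as a flag; it is implemented as a root-path union over the tree's
edge table and cross-checked in the test suite against both a brute-force
edge-enumeration oracle and an independent implementation. Rarefaction is
uniform subsampling without replacement (multivariate hypergeometric), so
mean rarefied richness follows the closed form
$E[S] = \sum_i \left(1 - \binom{N - n_i}{d}\big/\binom{N}{d}\right)$,
which the tests verify. Alpha diversity defaults to a sampling depth of
500 with shallower samples dropped and warned about; rarefaction curves
default to depths 150–5000 with 50 iterations per depth.

## Bias attribution

Per-species bias is $\log_2(\text{observed}/\text{preset})$. Species with
zero observed reads are flagged not-detected and excluded from means and
regressions rather than pseudocounted — no pseudocount is implied by
rendering such species as capped arrows in typical figures; a pseudocount
mode can be layered on upstream by the user if desired. The G+C
regression is ordinary least squares of log2FC on mol% G+C with a
two-sided slope test; the response choice (log-ratio deviation) and the
samples pooled (default: the PCR-dominated P/S samples) are configuration,
not baked in. Group contrasts use pairwise two-group Kruskal-Wallis tests
(matching the pairwise-test convention rather than omnibus-then-posthoc)
with Benjamini-Hochberg correction across the contrast family.

## The packaged study layout

`studyDesigns()` reproduces a 16-sample benchmarking grid: M1–M10 are
whole-cell samples (two biofilm replicate communities, one meat community,
and variants with one member 10^4-fold diluted or dominant, split over two
extraction kits), M11–M14 are DNA mixtures including the dilution/
dominance variants, and M15–M16 are pooled amplicons. Default per-sample
read depths mirror the read frequencies such an experiment yields
(≈ 3.5×10³–5.5×10⁴). The packaged taxon tables store the curated
per-species attributes as printed, including one community-level summary
quirk: the biofilm copy-number mean recomputes to 4.7 from the stored
per-row values while the published summary prints 4.8 (most plausibly an
average over unrounded database values); the tables are not silently
"corrected", and `summarizeMetadata()` reports what the stored rows give.

```{r}
library(mockbench)
layout <- studyDesigns()
cfg <- simulationConfig(seed = 1,
                        nReads = setNames(layout$info$n_reads,
                                          layout$info$sample))
res <- runPipeline("all", pipelineConfig(seed = 1), outDir = "mockbench_out")
```

## Numerical and testing choices

Proportion vectors are normalized after a max-shift in log space;
probability sums are asserted to 1e-12. The simulator's property tests
run at read depths of 4 000–50 000 with 20–200 replicates, sizes at which
multinomial standard errors make the null recovery and sign-recovery
checks sharp while the full suite stays fast. The synthetic reference
phylogeny used by the pipeline's diversity stage (`syntheticTree()`) is a
seeded random tree — adequate for testing conventions and monotonicity,
but its branch lengths carry no biological meaning, so absolute Faith PD
values from simulated runs are not comparable to values from a real
phylogeny.

## Known limitations

- No plateau-phase PCR, primer-mismatch, or chimera modeling.
- Extraction efficiencies default to 1 for all taxa (no kit-specific
  values are assumed).
- Identity values are inputs, not alignments: the package neither aligns
  sequences nor queries reference databases.
- The G+C regression on simulated data recovers the sign and
  significance behavior of the real-data finding, not its exact
  R²/p values, which depend on the unpublished real abundance tables.
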