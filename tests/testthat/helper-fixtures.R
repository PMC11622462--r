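# Shared fixtures: packaged taxon tables and small hand-built communities.

bioTaxa <- mockCommunityTaxa("biofilm")
meatTaxa <- mockCommunityTaxa("meat")
allTaxa <- TaxonSet(rbind(as.data.frame(bioTaxa), as.data.frame(meatTaxa)))

# a tiny two-member community used across modules
toyTaxa <- TaxonSet(data.frame(
    species = c("Staphylococcus cohnii", "Serratia quinivorans"),
    strain = c("T1", "T2"),
    phylum = c("Bacillota", "Pseudomonadota"),
    copy_number = c(6, 6),
    copy_number_rank = c("species", "species"),
    genome_size_mb = c(2.7, 5.4),
    gc_mol_percent = c(51.3, 54.5),
    identity_pct = c(99.9, 99.5)))

toyDesign <- function(mode = "PS")
    mockDesign("toy", "biofilm", mode, members = c("T1", "T2"),
               log10Count = 8)

# species-level table helper: counts matrix from named vectors per sample
speciesTable <- function(..., normalization = "raw") {
    cols <- list(...)
    species <- unique(unlist(lapply(cols, names)))
    m <- sapply(cols, function(x) {
        v <- stats::setNames(numeric(length(species)), species)
        v[names(x)] <- x
        v
    })
    if (is.null(dim(m))) m <- matrix(m, ncol = length(cols),
                                     dimnames = list(species, names(cols)))
    featureTable(m, normalization = normalization)
}
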