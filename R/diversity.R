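#' @include normalize.R
NULL

#' Shannon entropy in bits
#'
#' `H = -sum(p_i * log2(p_i))` over nonzero proportions. Base 2 is the
#' convention throughout this package, so a uniform community of S species
#' has `H = log2(S)` (3.70 bits for 13 species, 3.81 for 14).
#'
#' @param counts non-negative numeric vector.
#' @return Shannon entropy in bits.
#' @export
shannonEntropy <- function(counts) {
    if (sum(counts) <= 0) stop("all-zero count vector")
    as.numeric(vegan::diversity(counts, index = "shannon", base = 2))
}

#' Pielou's evenness
#'
#' `J = H / log2(S)` with `S` the number of nonzero entries; 1 means a
#' completely uniform community, values near 0 mean dominance of a single
#' species. Defined as 0 when `S = 1` (the maximum entropy `log2(1)` is 0).
#'
#' @param counts non-negative numeric vector.
#' @return evenness in \[0, 1\].
#' @export
pielouEvenness <- function(counts) {
    if (sum(counts) <= 0) stop("all-zero count vector")
    s <- sum(counts > 0)
    if (s <= 1) return(0)
    shannonEntropy(counts) / log2(s)
}

#' Faith's phylogenetic diversity
#'
#' Sum of the branch lengths of the minimal subtree connecting the present
#' tips. With `includeRoot = TRUE` (the default, matching the convention of
#' phylogenetic core-metrics pipelines) the subtree is anchored at the tree
#' root, so a single present tip contributes its full root-to-tip path.
#'
#' @param present character vector of present tip labels (may be empty).
#' @param tree a rooted [ape::phylo] tree with branch lengths.
#' @param includeRoot anchor the spanning subtree at the root (default
#'   `TRUE`).
#' @return total branch length (0 for an empty set).
#' @export
faithPD <- function(present, tree, includeRoot = TRUE) {
    stopifnot(inherits(tree, "phylo"))
    if (length(present) == 0) return(0)
    tipIdx <- match(present, tree$tip.label)
    if (anyNA(tipIdx))
        stop("species not in tree: ",
             paste(present[is.na(tipIdx)], collapse = ", "))
    parent <- integer(max(tree$edge))
    edgeOf <- integer(max(tree$edge))
    parent[tree$edge[, 2]] <- tree$edge[, 1]
    edgeOf[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
    root <- ape::Ntip(tree) + 1L
    used <- logical(nrow(tree$edge))
    for (node in tipIdx) {
        while (node != root && !used[edgeOf[node]]) {
            used[edgeOf[node]] <- TRUE
            node <- parent[node]
        }
    }
    if (!includeRoot && length(tipIdx) >= 1) {
        # strip the edges between the MRCA of the set and the root
        mrca <- if (length(tipIdx) == 1) tipIdx else
            ape::getMRCA(tree, tipIdx)
        node <- mrca
        while (node != root) {
            used[edgeOf[node]] <- FALSE
            node <- parent[node]
        }
    }
    sum(tree$edge.length[used])
}

#' Rarefy a count vector to a fixed depth
#'
#' Uniform subsampling without replacement (multivariate hypergeometric):
#' `depth` reads are drawn from the pool of individual reads. Real-valued
#' (normalized) counts are floored to integers first; the total count lost
#' to flooring is attached as attribute `"floored"`.
#'
#' @param counts non-negative numeric vector.
#' @param depth target depth (positive integer, at most `sum(floor(counts))`).
#' @param seed RNG seed (optional).
#' @return integer vector summing to `depth`, same length and names as
#'   `counts`.
#' @export
rarefyCounts <- function(counts, depth, seed = NULL) {
    if (depth <= 0) stop("depth must be positive")
    floored <- sum(counts) - sum(floor(counts))
    counts <- floor(counts)
    if (sum(counts) < depth)
        stop("sample total (", sum(counts), ") below rarefaction depth (",
             depth, ")")
    if (!is.null(seed)) set.seed(seed)
    pool <- rep.int(seq_along(counts), counts)
    drawn <- pool[sample.int(length(pool), depth)]
    out <- tabulate(drawn, nbins = length(counts))
    names(out) <- names(counts)
    attr(out, "floored") <- floored
    out
}

#' Closed-form expected richness under rarefaction
#'
#' `E[S] = sum_i (1 - choose(N - n_i, d) / choose(N, d))` for a vector with
#' totals `n_i`, grand total `N`, and depth `d`.
#'
#' @param counts non-negative integer vector.
#' @param depth rarefaction depth.
#' @return expected number of features observed at that depth.
#' @export
expectedRichness <- function(counts, depth) {
    n <- sum(counts)
    sum(1 - exp(lchoose(n - counts, depth) - lchoose(n, depth)))
}

.metricFuns <- function(tree) list(
    observed = function(x) sum(x > 0),
    shannon = shannonEntropy,
    pielou = pielouEvenness,
    faith_pd = function(x) {
        if (is.null(tree)) return(NA_real_)
        faithPD(names(x)[x > 0], tree)
    })

#' Alpha diversity of every sample in a table
#'
#' Rarefies each sample to a common depth and computes observed features,
#' Shannon entropy (bits), Pielou evenness and (when a tree is supplied)
#' Faith PD. Samples whose total is below the depth are dropped with a
#' warning. With `rarefy = FALSE` metrics are computed on the full sample
#' instead.
#'
#' @param table a species-level [FeatureTable] (row names must match tree
#'   tips for Faith PD).
#' @param tree optional rooted [ape::phylo] tree.
#' @param depth sampling depth (default 500).
#' @param rarefy rarefy before computing metrics (default `TRUE`).
#' @param seed RNG seed for the rarefaction draws.
#' @return data frame: sample, sampling_depth, observed, shannon, pielou,
#'   faith_pd.
#' @export
alphaDiversity <- function(table, tree = NULL, depth = 500, rarefy = TRUE,
                           seed = 1) {
    stopifnot(is(table, "FeatureTable"))
    m <- featureCounts(table)
    totals <- colSums(floor(m))
    keep <- if (rarefy) totals >= depth else totals > 0
    if (rarefy && any(!keep))
        warning("dropping sample(s) below depth ", depth, ": ",
                paste(colnames(m)[!keep], collapse = ", "))
    if (!any(keep))
        stop("no sample reaches the sampling depth of ", depth)
    funs <- .metricFuns(tree)
    rows <- lapply(which(keep), function(j) {
        x <- m[, j]
        if (rarefy) x <- rarefyCounts(x, depth, seed = seed + j)
        data.frame(sample = colnames(m)[j],
                   sampling_depth = if (rarefy) depth else sum(x),
                   observed = funs$observed(x), shannon = funs$shannon(x),
                   pielou = funs$pielou(x), faith_pd = funs$faith_pd(x))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Rarefaction curves of alpha diversity metrics
#'
#' For each sample and each depth not exceeding the sample total, the mean
#' of each metric over `nIter` independent rarefactions.
#'
#' @param table a species-level [FeatureTable].
#' @param depths increasing depths (default spanning 150 to 5000).
#' @param nIter rarefaction iterations per depth (default 50).
#' @param metrics subset of `c("observed", "shannon", "pielou",
#'   "faith_pd")`.
#' @param tree optional rooted tree (needed for `faith_pd`).
#' @param seed RNG seed.
#' @return long data frame: sample, depth, metric, value (iteration mean).
#' @export
rarefactionCurve <- function(table, depths = c(150, 500, 1000, 2000, 5000),
                             nIter = 50,
                             metrics = c("observed", "shannon", "pielou",
                                         "faith_pd"),
                             tree = NULL, seed = 1) {
    stopifnot(is(table, "FeatureTable"))
    if (length(depths) == 0) stop("empty depth list")
    if (nIter < 1) stop("nIter must be >= 1")
    metrics <- match.arg(metrics, several.ok = TRUE)
    funs <- .metricFuns(tree)[metrics]
    m <- featureCounts(table)
    out <- list()
    for (j in seq_len(ncol(m))) {
        total <- sum(floor(m[, j]))
        for (d in depths[depths <= total]) {
            acc <- matrix(0, nrow = nIter, ncol = length(metrics),
                          dimnames = list(NULL, metrics))
            for (it in seq_len(nIter)) {
                x <- rarefyCounts(m[, j], d,
                                  seed = seed + 7919L * j + 104729L * it + d)
                acc[it, ] <- vapply(funs, function(f) f(x), numeric(1))
            }
            out[[length(out) + 1L]] <- data.frame(
                sample = colnames(m)[j], depth = d, metric = metrics,
                value = colMeans(acc), row.names = NULL)
        }
    }
    if (!length(out)) stop("no sample reaches any requested depth")
    do.call(rbind, out)
}

#' Synthetic reference phylogeny over a species set
#'
#' Generates a random rooted ultrametric-free tree with the given species as
#' tip labels, as a stand-in for a reference phylogeny when only diversity
#' conventions (not real branch lengths) are under test. The tree is purely
#' synthetic and seeded for reproducibility.
#'
#' @param species tip labels.
#' @param seed RNG seed.
#' @return a rooted [ape::phylo] object.
#' @export
syntheticTree <- function(species, seed = 1) {
    set.seed(seed)
    tree <- ape::rtree(length(species), tip.label = species, rooted = TRUE)
    tree
}
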