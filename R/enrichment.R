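#' Rank genes for preranked GSEA
#'
#' Sorts tested genes by Wald z descending (most upregulated first), with
#' deterministic lexicographic tie-breaking on gene id.
#'
#' @param de data.frame from [nbWaldTest()].
#' @param metric ranking metric column (default `"wald_z"`; the shrunken
#'   fold change is the alternative).
#' @return named numeric vector of scores, sorted decreasing.
#' @export
rankGenes <- function(de, metric = "wald_z") {
  ok <- is.finite(de[[metric]])
  s <- de[[metric]][ok]
  names(s) <- de$gene_id[ok]
  s[order(-s, names(s))]
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Classic GSEA running sum: walking down the ranking, set members (hits)
#' increment by `|score|^p / sum_hits |score|^p` and non-members decrement
#' by `1/(N - N_hits)`; the enrichment score is the signed extremum. The
#' leading edge contains the hits at or before the extremum (positive ES)
#' or at or after it (negative ES).
#'
#' @param ranked named numeric vector from [rankGenes()] (sorted
#'   decreasing).
#' @param set character vector of member genes.
#' @param p weighting exponent (default 1).
#' @return list with `es`, `leading_edge`, `n_hits`.
#' @export
enrichmentScore <- function(ranked, set, p = 1) {
  N <- length(ranked)
  hit <- names(ranked) %in% set
  nh <- sum(hit)
  if (nh == 0 || nh == N)
    stopf("gene set has no members (or all genes) in the ranked universe")
  w <- abs(ranked)^p
  inc <- numeric(N)
  inc[hit] <- w[hit] / sum(w[hit])
  inc[!hit] <- -1 / (N - nh)
  rs <- cumsum(inc)
  i_max <- which.max(rs); i_min <- which.min(rs)
  es <- if (rs[i_max] >= -rs[i_min]) rs[i_max] else rs[i_min]
  le <- if (es >= 0) names(ranked)[seq_len(i_max)][hit[seq_len(i_max)]]
        else names(ranked)[i_min:N][hit[i_min:N]]
  list(es = es, leading_edge = le, n_hits = nh)
}

## ES of many random sets of size s (gene-label permutation null)
.nullES <- function(ranked, s, n_perm, p = 1) {
  N <- length(ranked)
  w <- abs(ranked)^p
  vapply(seq_len(n_perm), function(b) {
    pos <- sort(sample.int(N, s))
    wh <- w[pos]
    hits <- cumsum(wh) / sum(wh)
    step <- 1 / (N - s)
    ## running sum just after each hit, and just before each hit
    after <- hits - (pos - seq_len(s)) * step
    before <- c(0, hits[-s]) - (pos - 1 - (seq_len(s) - 1)) * step
    mx <- max(after); mn <- min(before)
    if (mx >= -mn) mx else mn
  }, 0)
}

#' Preranked gene-set enrichment analysis
#'
#' For each gene set (size-filtered to the members present in the ranked
#' universe), computes the running-sum enrichment score, a gene-label
#' permutation null of `n_perm` random same-size sets, the normalized
#' enrichment score `nes = es / mean(|null es| of matching sign)`, a
#' sign-matched permutation p-value, and Benjamini-Hochberg FDR across
#' sets (significance at `fdr < 0.01`).
#'
#' @param ranked named numeric vector from [rankGenes()].
#' @param collection named list of gene sets (e.g. [readGMT()]).
#' @param n_perm permutations per set size (default 1000; < 100 warns).
#' @param min_size,max_size set-size filter on members in the universe.
#' @param p weighting exponent.
#' @param alpha FDR threshold (default 0.01).
#' @param seed integer seed.
#' @return data.frame: `set`, `size`, `es`, `nes`, `p`, `fdr`, `signif`,
#'   `leading_edge` (`;`-joined).
#' @export
gseaPreranked <- function(ranked, collection, n_perm = 1000,
                          min_size = 15, max_size = 500, p = 1,
                          alpha = 0.01, seed = 1) {
  if (!length(collection)) stopf("empty gene-set collection")
  if (n_perm < 100) warnf("n_perm < 100: unstable GSEA p-values")
  universe <- names(ranked)
  sizes <- vapply(collection, function(s) sum(universe %in% s), 0L)
  use <- sizes >= min_size & sizes <= max_size
  skipped <- names(collection)[sizes == 0]
  if (length(skipped))
    warnf("%d set(s) with no members in the universe skipped",
          length(skipped))
  collection <- collection[use]; sizes <- sizes[use]
  if (!length(collection))
    return(data.frame(set = character(), size = integer(), es = numeric(),
                      nes = numeric(), p = numeric(), fdr = numeric(),
                      signif = logical(), leading_edge = character(),
                      stringsAsFactors = FALSE))
  obs <- lapply(collection, function(s) enrichmentScore(ranked, s, p = p))
  es <- vapply(obs, `[[`, 0, "es")

  set.seed(seed)
  null_by_size <- lapply(sort(unique(sizes)), function(s)
    .nullES(ranked, s, n_perm, p = p))
  names(null_by_size) <- as.character(sort(unique(sizes)))

  nes <- pval <- rep(NA_real_, length(es))
  for (i in seq_along(es)) {
    nl <- null_by_size[[as.character(sizes[i])]]
    same <- if (es[i] >= 0) nl[nl >= 0] else nl[nl < 0]
    if (!length(same)) { nes[i] <- NA; pval[i] <- 1; next }
    nes[i] <- es[i] / mean(abs(same))
    pval[i] <- (1 + sum(abs(same) >= abs(es[i]))) / (length(same) + 1)
  }
  fdr <- stats::p.adjust(pval, method = "BH")
  data.frame(set = names(collection), size = sizes, es = es, nes = nes,
             p = pval, fdr = fdr, signif = fdr < alpha,
             leading_edge = vapply(obs, function(o)
               paste(o$leading_edge, collapse = ";"), ""),
             row.names = NULL, stringsAsFactors = FALSE)
}

.jaccard <- function(a, b) {
  length(intersect(a, b)) / length(union(a, b))
}

#' Collapse overlapping significant gene sets
#'
#' Greedy parent-set reduction: order sets by p ascending and keep a set
#' only when its Jaccard index with every already-kept set stays below
#' `threshold`; dropped sets are recorded under the kept set that
#' absorbed them.
#'
#' @param gsea data.frame from [gseaPreranked()] (typically significant
#'   rows).
#' @param collection the gene-set list.
#' @param threshold Jaccard collapse threshold (default 0.5).
#' @return `gsea` restricted to kept sets, with a `collapsed`
#'   column listing absorbed set names (`;`-joined).
#' @export
collapseGeneSets <- function(gsea, collection, threshold = 0.5) {
  if (!nrow(gsea)) return(cbind(gsea, collapsed = character(0)))
  ord <- order(gsea$p, gsea$set)
  gsea <- gsea[ord, , drop = FALSE]
  kept <- integer(0)
  absorbed <- list()
  for (i in seq_len(nrow(gsea))) {
    gi <- collection[[gsea$set[i]]]
    J <- vapply(kept, function(k) .jaccard(gi, collection[[gsea$set[k]]]), 0)
    if (length(kept) && any(J >= threshold)) {
      owner <- kept[which.max(J)]
      absorbed[[as.character(owner)]] <-
        c(absorbed[[as.character(owner)]], gsea$set[i])
    } else kept <- c(kept, i)
  }
  out <- gsea[kept, , drop = FALSE]
  out$collapsed <- vapply(kept, function(k)
    paste(absorbed[[as.character(k)]] %||% character(0), collapse = ";"), "")
  rownames(out) <- NULL
  out
}

#' Cluster significant gene sets by Jaccard similarity
#'
#' Builds a graph with an edge whenever the Jaccard index of two sets is
#' at least `threshold` and reports connected components; the
#' representative of a cluster is its lowest-p member.
#'
#' @param gsea data.frame of significant sets (needs `set`, `p`).
#' @param collection the gene-set list.
#' @param threshold Jaccard edge threshold (default 0.25).
#' @return data.frame: `set`, `cluster`, `representative`.
#' @export
clusterGeneSets <- function(gsea, collection, threshold = 0.25) {
  if (!nrow(gsea))
    return(data.frame(set = character(), cluster = integer(),
                      representative = character(), stringsAsFactors = FALSE))
  nm <- gsea$set
  k <- length(nm)
  adj <- matrix(0, k, k, dimnames = list(nm, nm))
  if (k > 1) for (i in seq_len(k - 1)) for (j in (i + 1):k)
    if (.jaccard(collection[[nm[i]]], collection[[nm[j]]]) >= threshold)
      adj[i, j] <- adj[j, i] <- 1
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  rep_of <- vapply(split(seq_len(k), comp), function(ix)
    nm[ix][which.min(gsea$p[ix])], "")
  data.frame(set = nm, cluster = unname(comp),
             representative = rep_of[as.character(comp)],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Hypergeometric overrepresentation test
#'
#' For each gene set, the upper-tail hypergeometric probability of
#' observing at least the seen overlap between the query genes (e.g.
#' DEGs) and the set, within the universe; Benjamini-Hochberg FDR across
#' sets.
#'
#' @param query character vector (e.g. significant gene ids).
#' @param universe character vector of all tested genes.
#' @param collection named list of gene sets.
#' @return data.frame: `set`, `overlap`, `size`, `expected`, `p`, `fdr`.
#' @export
overrepresentationTest <- function(query, universe, collection) {
  query <- intersect(query, universe)
  res <- lapply(names(collection), function(nm) {
    s <- intersect(collection[[nm]], universe)
    ov <- length(intersect(query, s))
    data.frame(set = nm, overlap = ov, size = length(s),
               expected = length(s) * length(query) / length(universe),
               p = stats::phyper(ov - 1, length(s),
                                 length(universe) - length(s),
                                 length(query), lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$fdr <- stats::p.adjust(res$p, method = "BH")
  res
}
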