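#' Pair significant DMRs with significant DEGs in cis
#'
#' A (DMR, gene) pair is formed whenever the DMR overlaps the gene span
#' extended by `window` bp on both sides (the "< 2000 bp upstream and
#' downstream" rule). One gene may pair with several DMRs.
#'
#' @param dmrs data.frame of significant DMRs (from [findDMRs()]).
#' @param degs data.frame of significant genes (rows of the
#'   [nbWaldTest()] result).
#' @param geneAnno gene annotation `GRanges`.
#' @param window flank in bp (default 2000).
#' @return data.frame `dmr_id`, `gene_id`, `category`.
#' @export
pairDmrsToDegs <- function(dmrs, degs, geneAnno, window = 2000) {
  empty <- data.frame(dmr_id = character(), gene_id = character(),
                      category = character(), stringsAsFactors = FALSE)
  if (!NROW(dmrs) || !NROW(degs)) return(empty)
  ann <- annotateRegionToGenes(dmrs, geneAnno, window = window)
  ann <- ann[ann$gene_id %in% degs$gene_id, , drop = FALSE]
  names(ann)[names(ann) == "region_id"] <- "dmr_id"
  rownames(ann) <- NULL
  ann
}

#' Per-sample median methylation of a DMR
#'
#' @param betas CpG x sample beta matrix.
#' @param probe_ids member probes of the region (character vector, or one
#'   `;`-joined string as stored in the DMR table).
#' @return named numeric vector, one median beta per sample.
#' @export
dmrMedianMethylation <- function(betas, probe_ids) {
  if (length(probe_ids) == 1 && grepl(";", probe_ids))
    probe_ids <- strsplit(probe_ids, ";", fixed = TRUE)[[1]]
  missing <- setdiff(probe_ids, rownames(betas))
  if (length(missing))
    stopf("probes missing from beta matrix: %s",
          paste(utils::head(missing, 5), collapse = ", "))
  apply(betas[probe_ids, , drop = FALSE], 2, stats::median)
}

## vectorized Pearson correlation of paired columns
.colPearson <- function(X, Y) {
  n <- nrow(X)
  mx <- colMeans(X); my <- colMeans(Y)
  sxy <- colSums(X * Y) - n * mx * my
  sxx <- colSums(X^2) - n * mx^2
  syy <- colSums(Y^2) - n * my^2
  sxy / sqrt(sxx * syy)
}

#' Methylation-expression association for one DMR-gene pair
#'
#' Pearson correlation of per-sample DMR median beta against log
#' expression; a 95% percentile confidence interval from paired bootstrap
#' resampling (degenerate zero-variance resamples are redrawn) and a
#' permutation p-value from shuffling the expression vector, with floor
#' `1 / (n_perm + 1)`.
#'
#' @param median_beta per-sample DMR median methylation.
#' @param expression per-sample log-scale expression, same order.
#' @param n_boot bootstrap resamples for the CI (default 100000).
#' @param n_perm expression permutations for the p-value (default 10000).
#' @param seed integer seed (bootstrap and permutation use independent
#'   substreams).
#' @param alpha significance threshold on the permutation p (default
#'   0.05).
#' @return one-row data.frame: `r`, `ci_low`, `ci_high`, `p`,
#'   `significant`, `direction`, `n`.
#' @export
eqtmTest <- function(median_beta, expression, n_boot = 100000,
                     n_perm = 10000, seed = 1, alpha = 0.05) {
  x <- as.numeric(median_beta); y <- as.numeric(expression)
  n <- length(x)
  if (n < 4) stopf("need at least 4 paired samples")
  if (length(y) != n) stopf("methylation and expression lengths differ")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(data.frame(r = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                      p = NA_real_, significant = FALSE,
                      direction = NA_real_, n = n))
  r_obs <- stats::cor(x, y)

  set.seed(childSeed(seed, 1))
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n, n_boot)
  rb <- .colPearson(matrix(x[idx], n), matrix(y[idx], n))
  bad <- !is.finite(rb)
  guard <- 0
  while (any(bad) && guard < 50) {
    k <- sum(bad)
    idx2 <- matrix(sample.int(n, n * k, replace = TRUE), n, k)
    rb[bad] <- .colPearson(matrix(x[idx2], n), matrix(y[idx2], n))
    bad <- !is.finite(rb)
    guard <- guard + 1
  }
  rb <- rb[is.finite(rb)]
  ci <- unname(stats::quantile(rb, c(0.025, 0.975)))

  set.seed(childSeed(seed, 2))
  pm <- vapply(seq_len(n_perm), function(i) sample.int(n), integer(n))
  rp <- .colPearson(matrix(x, n, n_perm), matrix(y[pm], n))
  p <- (1 + sum(abs(rp) >= abs(r_obs) - 1e-12)) / (n_perm + 1)

  data.frame(r = r_obs, ci_low = ci[1], ci_high = ci[2], p = p,
             significant = p < alpha, direction = sign(r_obs), n = n)
}

#' Run the integrative methylation-expression (eQTM) analysis
#'
#' Pairs significant DMRs with genes in cis, computes per-sample DMR
#' median methylation and log2 size-factor-normalized expression
#' (`log2(count / sf + 1)`), and applies [eqtmTest()] to every candidate
#' pair. With `scope = "deg-pairs"` (the DMR-DEG table of the study
#' design) only significant DEGs are candidate partners; with
#' `scope = "all-dmr-genes"` every tested gene in cis of a significant
#' DMR is considered.
#'
#' @param dmrs DMR table from [findDMRs()] (significant rows are used).
#' @param de DE table from [nbWaldTest()].
#' @param betas CpG x sample beta matrix.
#' @param counts gene x sample count matrix.
#' @param size_factors per-sample scalars (recomputed when `NULL`).
#' @param geneAnno gene annotation `GRanges`.
#' @param window cis window in bp (default 2000).
#' @param scope `"deg-pairs"` or `"all-dmr-genes"`.
#' @param n_boot,n_perm,seed,alpha passed to [eqtmTest()].
#' @return data.frame sorted by p, one row per tested pair: pairing
#'   columns plus the [eqtmTest()] columns, `p_adj` (BH across pairs) and
#'   `n_cpgs`. Attribute `n_distinct_cpgs` counts distinct CpGs across
#'   significant associations.
#' @export
runIntegration <- function(dmrs, de, betas, counts, size_factors = NULL,
                           geneAnno = NULL, window = 2000,
                           scope = c("deg-pairs", "all-dmr-genes"),
                           n_boot = 100000, n_perm = 10000, seed = 1,
                           alpha = 0.05) {
  scope <- match.arg(scope)
  empty <- data.frame(dmr_id = character(), gene_id = character(),
                      category = character(), r = numeric(),
                      ci_low = numeric(), ci_high = numeric(), p = numeric(),
                      p_adj = numeric(), significant = logical(),
                      direction = numeric(), n = integer(),
                      n_cpgs = integer(), stringsAsFactors = FALSE)
  attr(empty, "n_distinct_cpgs") <- 0L
  sig_dmrs <- dmrs[dmrs$signif %||% (dmrs$fdr < 0.01), , drop = FALSE]
  if (!NROW(sig_dmrs)) return(empty)
  partners <- if (scope == "deg-pairs")
    de[!is.na(de$fdr) & de$fdr < 0.05, , drop = FALSE]
  else de[!is.na(de$p), , drop = FALSE]
  pairs <- pairDmrsToDegs(sig_dmrs, partners, geneAnno, window = window)
  if (!nrow(pairs)) return(empty)

  if (is.null(size_factors)) size_factors <- medianRatioSizeFactors(counts)
  expr <- log2(sweep(counts, 2, size_factors[colnames(counts)], "/") + 1)

  res <- lapply(seq_len(nrow(pairs)), function(i) {
    dmr <- sig_dmrs[sig_dmrs$dmr_id == pairs$dmr_id[i], , drop = FALSE]
    med <- dmrMedianMethylation(betas, dmr$probe_ids[1])
    tst <- eqtmTest(med, expr[pairs$gene_id[i], names(med)],
                    n_boot = n_boot, n_perm = n_perm,
                    seed = childSeed(seed, i), alpha = alpha)
    cbind(pairs[i, , drop = FALSE], tst, n_cpgs = dmr$n_cpgs[1])
  })
  res <- do.call(rbind, res)
  res$p_adj <- NA_real_
  ok <- !is.na(res$p)
  res$p_adj[ok] <- stats::p.adjust(res$p[ok], method = "BH")
  res <- res[order(res$p), , drop = FALSE]
  rownames(res) <- NULL
  sig <- res[!is.na(res$p) & res$significant, , drop = FALSE]
  cp <- unique(unlist(strsplit(
    sig_dmrs$probe_ids[match(sig$dmr_id, sig_dmrs$dmr_id)], ";")))
  attr(res, "n_distinct_cpgs") <- length(cp)
  res
}
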