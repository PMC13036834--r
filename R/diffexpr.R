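#' Prefilter lowly expressed genes
#'
#' Keeps a gene when at least `min_samples` samples have at least
#' `min_count` counts (the "fewer than ten counts in four samples" rule).
#'
#' @param counts gene x sample integer matrix.
#' @param min_count,min_samples filter thresholds.
#' @return character vector of retained gene ids.
#' @export
prefilterGenes <- function(counts, min_count = 10, min_samples = 4) {
  keep <- rowSums(counts >= min_count) >= min_samples
  rownames(counts)[keep]
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization scalars: for each gene the geometric mean
#' across samples is computed (genes with any zero count are excluded from
#' the reference), and a sample's size factor is the median over genes of
#' count / geometric mean.
#'
#' @param counts gene x sample integer matrix.
#' @return named positive numeric vector, one per sample.
#' @export
medianRatioSizeFactors <- function(counts) {
  logc <- log(counts)
  ok <- rowSums(counts > 0) == ncol(counts)
  if (!any(ok))
    stopf(paste("no gene with nonzero counts in every sample;",
                "a pseudo-reference fallback is not implemented"))
  loggeo <- rowMeans(logc[ok, , drop = FALSE])
  sf <- apply(logc[ok, , drop = FALSE], 2,
              function(x) exp(stats::median(x - loggeo)))
  stats::setNames(sf, colnames(counts))
}

## single-gene NB IRLS fit with log link and offsets; expected information
.nbFit <- function(y, X, offset, alpha, max_iter = 50, tol = 1e-8) {
  beta <- qr.coef(qr(X), log(y + 0.5) - offset)
  beta[is.na(beta)] <- 0
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta) + offset
    mu <- pmin(exp(eta), 1e12)
    w <- mu / (1 + alpha * mu)
    z <- (eta - offset) + (y - mu) / mu
    fit <- tryCatch(stats::lm.wfit(X, z, w), error = function(e) NULL)
    if (is.null(fit) || anyNA(fit$coefficients)) return(NULL)
    new_beta <- fit$coefficients
    delta <- max(abs(new_beta - beta))
    beta <- new_beta
    if (!is.finite(delta)) return(NULL)
    if (delta < tol) break
  }
  eta <- drop(X %*% beta) + offset
  mu <- pmin(exp(eta), 1e12)
  w <- mu / (1 + alpha * mu)
  info <- crossprod(X * sqrt(w))
  cov <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(cov)) return(NULL)
  list(beta = beta, se = sqrt(diag(cov)), converged = it < max_iter || delta < tol)
}

## method-of-moments dispersion per gene, stratified by design cells
.momDispersion <- function(norm_counts, cells, xi) {
  lev <- levels(cells)
  num <- 0; den <- 0
  for (lv in lev) {
    idx <- which(cells == lv)
    if (length(idx) < 2) next
    m <- rowMeans(norm_counts[, idx, drop = FALSE])
    v <- apply(norm_counts[, idx, drop = FALSE], 1, stats::var)
    num <- num + (length(idx) - 1) * (v - m * xi)
    den <- den + (length(idx) - 1) * m^2
  }
  a <- num / den
  a[!is.finite(a)] <- NA
  pmin(pmax(a, 1e-8), 10)
}

## dispersion trend a0 + a1/mu by 30%-trimmed least squares
.dispersionTrend <- function(alpha_mom, base_mean, min_nonzero_mean = 3) {
  use <- which(is.finite(alpha_mom) & base_mean > min_nonzero_mean)
  if (length(use) < 10)
    return(c(a0 = stats::median(alpha_mom, na.rm = TRUE) %||% 0.1, a1 = 0))
  x <- 1 / base_mean[use]; y <- alpha_mom[use]
  fit <- stats::lm(y ~ x)
  r <- abs(stats::residuals(fit))
  keep <- r <= stats::quantile(r, 0.7)
  fit <- stats::lm(y[keep] ~ x[keep])
  a <- stats::coef(fit)
  c(a0 = max(a[[1]], 1e-8), a1 = max(a[[2]], 0))
}

#' Negative-binomial Wald differential expression test
#'
#' Per gene, fits a negative-binomial log-link GLM of counts on condition
#' (control as reference, so positive log2 fold changes are up in DS) plus
#' covariates, with log size factors as offsets, by iteratively reweighted
#' least squares. The gene dispersion is `max(trend(mu), MoM)` where the
#' trend `a0 + a1/mu` is fitted over genes by 30%-trimmed least squares
#' and MoM is a design-cell-stratified method-of-moments estimate. Wald
#' z = coefficient / SE from the expected information; two-sided normal p;
#' Benjamini-Hochberg FDR over tested genes.
#'
#' @param counts gene x sample integer matrix (already prefiltered).
#' @param samples sample sheet with `condition` (levels control, DS) and
#'   optionally `sex` used as covariate.
#' @param size_factors per-sample normalization scalars; computed with
#'   [medianRatioSizeFactors()] when `NULL`.
#' @param geneAnno optional `GRanges` to attach a `chrom` column.
#' @param dispersion optional fixed dispersion (bypasses estimation).
#' @param alpha significance threshold on FDR (stored in the `signif`
#'   column; default 0.05).
#' @return data.frame (one row per gene): `gene_id`, `base_mean`,
#'   `log2fc`, `shrunken_log2fc`, `se`, `wald_z`, `p`, `fdr`, `signif`,
#'   `chrom`.
#' @export
nbWaldTest <- function(counts, samples, size_factors = NULL, geneAnno = NULL,
                       dispersion = NULL, alpha = 0.05) {
  samples <- as.data.frame(samples)
  cond <- factor(samples$condition, levels = c("control", "DS"))
  if (any(table(cond) < 2)) stopf("need >= 2 samples per condition")
  covars <- data.frame(condition = cond)
  if (!is.null(samples$sex) && nlevels(droplevels(factor(samples$sex))) > 1)
    covars$sex <- droplevels(factor(samples$sex))
  X <- stats::model.matrix(~ ., covars)
  if (qr(X)$rank < ncol(X)) stopf("design is rank deficient")
  if (is.null(size_factors)) size_factors <- medianRatioSizeFactors(counts)
  sf <- size_factors[colnames(counts)]
  offset <- log(sf)
  nc <- sweep(counts, 2, sf, "/")
  base_mean <- rowMeans(nc)

  if (is.null(dispersion)) {
    cells <- interaction(covars, drop = TRUE)
    amom <- .momDispersion(nc, cells, xi = mean(1 / sf))
    tr <- .dispersionTrend(amom, base_mean)
    atrend <- tr["a0"] + tr["a1"] / pmax(base_mean, 1e-8)
    disp <- pmax(atrend, ifelse(is.na(amom), 0, amom))
  } else {
    disp <- rep_len(dispersion, nrow(counts))
  }

  ci <- which(colnames(X) == "conditionDS")
  n_g <- nrow(counts)
  est <- se <- rep(NA_real_, n_g)
  for (g in seq_len(n_g)) {
    f <- .nbFit(counts[g, ], X, offset, disp[g])
    if (is.null(f) || !f$converged) next
    est[g] <- f$beta[ci]; se[g] <- f$se[ci]
  }
  log2fc <- est / log(2)
  se2 <- se / log(2)
  wald_z <- est / se
  p <- 2 * stats::pnorm(-abs(wald_z))
  fdr <- rep(NA_real_, n_g)
  fdr[!is.na(p)] <- stats::p.adjust(p[!is.na(p)], method = "BH")
  res <- data.frame(gene_id = rownames(counts), base_mean = base_mean,
                    log2fc = log2fc, shrunken_log2fc = NA_real_,
                    se = se2, wald_z = wald_z, p = p, fdr = fdr,
                    signif = !is.na(fdr) & fdr < alpha,
                    dispersion = disp,
                    chrom = NA_character_,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(geneAnno))
    res$chrom <- as.character(GenomicRanges::seqnames(geneAnno))[
      match(res$gene_id, geneAnno$gene_id)]
  shrinkLogFC(res)
}

#' Empirical-Bayes shrinkage of log2 fold changes
#'
#' Ridge shrinkage under a normal prior N(0, tau^2) whose variance is
#' estimated by moment matching from the marginal distribution of
#' (log2fc, se): `tau^2 = var(log2fc) - mean(se^2)`, falling back to
#' `median(se^2)` when the estimate is not positive. The shrunken
#' estimate is `log2fc * tau^2 / (tau^2 + se^2)`, so |shrunken| <= |raw|
#' always.
#'
#' @param de data.frame from [nbWaldTest()] (needs `log2fc` and `se`).
#' @return the same data.frame with `shrunken_log2fc` filled in.
#' @export
shrinkLogFC <- function(de) {
  ok <- is.finite(de$log2fc) & is.finite(de$se)
  tau2 <- stats::var(de$log2fc[ok]) - mean(de$se[ok]^2)
  if (!is.finite(tau2) || tau2 <= 0) tau2 <- stats::median(de$se[ok]^2)
  de$shrunken_log2fc <- de$log2fc * tau2 / (tau2 + de$se^2)
  attr(de, "shrink_tau2") <- tau2
  de
}

#' Chromosome-level enrichment statistics for DEGs
#'
#' Three Pearson chi-squared tests over the tested genes: (a) chr21
#' enrichment, a 2x2 test of DEG status against chr21 membership (no
#' continuity correction); (b) uniformity, a goodness-of-fit test of
#' per-chromosome DEG counts against expectations proportional to
#' expressed genes per chromosome, excluding chr21; (c) direction
#' balance, a homogeneity test of up/down counts across chromosomes
#' excluding chr21. For (b) and (c), chromosomes with an expected count
#' below 5 are pooled into one class.
#'
#' @param de data.frame from [nbWaldTest()] with `chrom` filled in.
#' @param alpha FDR threshold defining DEGs (default 0.05).
#' @return list of three `htest`-like lists: `chr21`, `uniformity`,
#'   `direction`, each with `statistic`, `df`, `p`, plus the underlying
#'   `table`.
#' @export
chromosomeEnrichment <- function(de, alpha = 0.05) {
  de <- de[!is.na(de$p) & !is.na(de$chrom), , drop = FALSE]
  deg <- !is.na(de$fdr) & de$fdr < alpha
  mk <- function(stat, df, p, tab) list(statistic = unname(stat),
                                        df = unname(df), p = unname(p),
                                        table = tab)
  if (!any(deg)) {
    warnf("no significant genes; enrichment p-values set to 1")
    e <- mk(NA_real_, NA_real_, 1, NULL)
    return(list(chr21 = e, uniformity = e, direction = e))
  }
  is21 <- de$chrom == "chr21"
  tab21 <- table(factor(deg, c(TRUE, FALSE)), factor(is21, c(TRUE, FALSE)))
  ct <- suppressWarnings(stats::chisq.test(tab21, correct = FALSE))
  chr21 <- mk(ct$statistic, ct$parameter, ct$p.value, tab21)

  other <- de[!is21, , drop = FALSE]
  odeg <- deg[!is21]
  pool <- function(obs, exp_prop, n_events) {
    expd <- exp_prop * n_events
    small <- expd < 5
    if (sum(small) >= 2) {
      obs <- c(obs[!small], pooled = sum(obs[small]))
      exp_prop <- c(exp_prop[!small], pooled = sum(exp_prop[small]))
    }
    list(obs = obs, p = exp_prop)
  }
  if (any(odeg)) {
    chroms <- factor(other$chrom)
    n_chr <- table(chroms)
    deg_chr <- table(chroms[odeg])
    prop <- as.numeric(n_chr) / sum(n_chr)
    pl <- pool(as.numeric(deg_chr), prop, sum(odeg))
    if (length(pl$obs) >= 2) {
      gt <- suppressWarnings(stats::chisq.test(pl$obs, p = pl$p / sum(pl$p)))
      uniformity <- mk(gt$statistic, gt$parameter, gt$p.value,
                       stats::setNames(pl$obs, names(pl$p)))
    } else uniformity <- mk(NA_real_, NA_real_, 1, NULL)
  } else uniformity <- mk(NA_real_, NA_real_, 1, NULL)

  updown <- other[odeg, , drop = FALSE]
  if (nrow(updown) > 0 && length(unique(updown$chrom)) > 1 &&
      length(unique(updown$log2fc > 0)) > 1) {
    chroms <- factor(updown$chrom)
    tab <- table(ifelse(updown$log2fc > 0, "up", "down"), chroms)
    expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    small <- apply(expd, 2, min) < 5
    if (sum(small) >= 2) {
      tab <- cbind(tab[, !small, drop = FALSE], pooled = rowSums(tab[, small,
                                                                     drop = FALSE]))
    }
    if (ncol(tab) > 1) {
      ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      direction <- mk(ht$statistic, ht$parameter, ht$p.value, tab)
    } else direction <- mk(NA_real_, NA_real_, 1, tab)
  } else direction <- mk(NA_real_, NA_real_, 1, NULL)

  list(chr21 = chr21, uniformity = uniformity, direction = direction)
}
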