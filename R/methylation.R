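#' Filter methylation probes by annotation flags
#'
#' Drops any probe flagged allosomal, chr21, polymorphic (minor allele
#' frequency > 0.01) or cross-reactive.
#'
#' @param betas CpG x sample matrix.
#' @param cpgAnno `GRanges` CpG annotation covering all probes.
#' @return character vector of retained probe ids.
#' @export
filterProbes <- function(betas, cpgAnno) {
  idx <- match(rownames(betas), cpgAnno$probe_id)
  if (anyNA(idx))
    stopf("probes missing annotation: %s",
          paste(utils::head(rownames(betas)[is.na(idx)], 5), collapse = ", "))
  flagged <- cpgAnno$flag_allosomal[idx] | cpgAnno$flag_chr21[idx] |
    cpgAnno$flag_polymorphic[idx] | cpgAnno$flag_crossreactive[idx]
  rownames(betas)[!flagged]
}

#' Beta to M-value transform
#'
#' `M = log2(beta / (1 - beta))`, with beta clipped to
#' `[eps, 1 - eps]` first so boundary values stay finite.
#'
#' @param beta numeric vector/matrix in \[0,1\].
#' @param eps clipping bound (default 1e-6).
#' @return M-values of the same shape.
#' @export
betaToM <- function(beta, eps = 1e-6) {
  b <- pmin(pmax(beta, eps), 1 - eps)
  log2(b / (1 - b))
}

#' M-value to beta transform (inverse of [betaToM()])
#' @param m M-values.
#' @return beta values in (0,1).
#' @export
mToBeta <- function(m) {
  2^m / (1 + 2^m)
}

#' Residual-PCA surrogate variables
#'
#' Residualizes the M-value matrix on the known design (condition + sex),
#' then takes the first `n_sv` principal components of the residual
#' matrix over samples (classical SVD) as surrogate covariates for
#' unmodeled structure such as batch. Surrogates are unit-variance scaled
#' and orthogonal to the design columns by construction.
#'
#' @param M CpG x sample M-value matrix.
#' @param samples sample sheet with `condition` and `sex`.
#' @param n_sv number of surrogates (must be < residual degrees of
#'   freedom).
#' @return sample x n_sv matrix (columns `sv1`, ...).
#' @export
estimateSurrogates <- function(M, samples, n_sv = 1) {
  samples <- as.data.frame(samples)
  covars <- data.frame(condition = factor(samples$condition))
  if (!is.null(samples$sex) && nlevels(droplevels(factor(samples$sex))) > 1)
    covars$sex <- droplevels(factor(samples$sex))
  X <- stats::model.matrix(~ ., covars)
  r <- qr(X)$rank
  if (r < ncol(X)) stopf("design is rank deficient")
  if (n_sv >= ncol(M) - r)
    stopf("n_sv must be smaller than the residual degrees of freedom (%d)",
          ncol(M) - r)
  res <- stats::lm.fit(X, t(M))$residuals      # samples x CpGs
  sv <- svd(res, nu = n_sv, nv = 0)
  out <- sv$u[, seq_len(n_sv), drop = FALSE]
  out <- sweep(out, 2, apply(out, 2, stats::sd), "/")
  colnames(out) <- paste0("sv", seq_len(n_sv))
  rownames(out) <- colnames(M)
  out
}

## shared design builder: condition + sex + surrogates
.methDesign <- function(samples, surrogates = NULL) {
  samples <- as.data.frame(samples)
  cond <- factor(samples$condition, levels = c("control", "DS"))
  covars <- data.frame(condition = cond)
  if (!is.null(samples$sex) && nlevels(droplevels(factor(samples$sex))) > 1)
    covars$sex <- droplevels(factor(samples$sex))
  X <- stats::model.matrix(~ ., covars)
  if (!is.null(surrogates)) X <- cbind(X, as.matrix(surrogates))
  X
}

#' Differentially methylated positions (per-CpG linear model)
#'
#' Per CpG, ordinary least squares of M-values on condition plus sex and
#' optional surrogate covariates; t statistic on the condition
#' coefficient with residual degrees of freedom, two-sided p and
#' Benjamini-Hochberg FDR. The effect is also reported on the beta scale
#' (`delta_beta`, DS minus control group means).
#'
#' @param betas CpG x sample beta matrix (filtered).
#' @param samples sample sheet.
#' @param surrogates optional sample x k surrogate matrix from
#'   [estimateSurrogates()].
#' @param alpha FDR significance threshold (default 0.05).
#' @return data.frame: `probe_id`, `delta_beta`, `m_coefficient`,
#'   `t_stat`, `p`, `fdr`, `signif`.
#' @export
dmpTest <- function(betas, samples, surrogates = NULL, alpha = 0.05) {
  samples <- as.data.frame(samples)
  cond <- factor(samples$condition, levels = c("control", "DS"))
  if (any(table(cond) < 2)) stopf("need >= 2 samples per condition")
  X <- .methDesign(samples, surrogates)
  df <- ncol(betas) - ncol(X)
  if (df <= 0) stopf("zero residual degrees of freedom")
  M <- betaToM(betas)
  fit <- stats::lm.fit(X, t(M))
  ci <- which(colnames(X) == "conditionDS")
  coefs <- fit$coefficients[ci, ]
  rss <- colSums(fit$residuals^2)
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(XtXinv[ci, ci] * rss / df)
  t_stat <- coefs / se
  p <- 2 * stats::pt(-abs(t_stat), df)
  fdr <- stats::p.adjust(p, method = "BH")
  ds <- cond == "DS"
  delta_beta <- rowMeans(betas[, ds, drop = FALSE]) -
    rowMeans(betas[, !ds, drop = FALSE])
  data.frame(probe_id = rownames(betas), delta_beta = delta_beta,
             m_coefficient = coefs, t_stat = t_stat, p = p, fdr = fdr,
             signif = fdr < alpha, row.names = NULL, stringsAsFactors = FALSE)
}

## per-CpG condition coefficient on the beta scale, adjusting covariates
.betaScaleCoefs <- function(betas, X, ci) {
  fit <- stats::lm.fit(X, t(betas))
  fit$coefficients[ci, ]
}

## cluster CpGs: same chromosome, consecutive gaps <= maxgap
.clusterCpGs <- function(chrom, pos, maxgap) {
  newc <- c(TRUE, chrom[-1] != chrom[-length(chrom)] |
                  diff(pos) > maxgap)
  cumsum(newc)
}

## candidate regions from smoothed coefficients: maximal single-sign runs
## above cutoff with >= min_cpgs members; returns index ranges + areas
.findCandidates <- function(sm, cluster, cutoff, min_cpgs) {
  state <- ifelse(sm >= cutoff, 1L, ifelse(sm <= -cutoff, -1L, 0L))
  grp <- paste0(cluster, ":", state)
  r <- rle(grp)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  st <- state[starts]
  keep <- st != 0L & r$lengths >= min_cpgs
  data.frame(start_idx = starts[keep], end_idx = ends[keep],
             sign = st[keep],
             area = vapply(which(keep), function(i)
               sum(abs(sm[starts[i]:ends[i]])), 0))
}

## running mean, window 3, within clusters
.smoothWithin <- function(coefs, cluster) {
  sm <- coefs
  for (idx in split(seq_along(coefs), cluster)) {
    if (length(idx) < 2) next
    x <- coefs[idx]; L <- length(x)
    left <- c(NA, x[-L]); right <- c(x[-1], NA)
    m <- cbind(left, x, right)
    sm[idx] <- rowMeans(m, na.rm = TRUE)
  }
  sm
}

#' Bump-hunting differentially methylated regions
#'
#' Per CpG, the condition coefficient is computed on the beta scale by
#' least squares adjusting for sex and optional surrogates; coefficients
#' are smoothed within clusters (CpGs at most `maxgap` bp apart) by a
#' window-3 running mean; candidate regions are maximal runs of at least
#' `min_cpgs` consecutive CpGs whose smoothed coefficient exceeds
#' `cutoff` in absolute value with a single sign, scored by the area
#' (sum of |smoothed coefficient|). The null distribution pools candidate
#' areas from `n_perm` condition-label permutations (covariates stay with
#' their samples); `p = (1 + #(null areas >= area)) / (1 + #null areas)`,
#' then Benjamini-Hochberg FDR (significance at `fdr < 0.01`).
#'
#' @param betas CpG x sample beta matrix (filtered probes).
#' @param samples sample sheet (`condition`, `sex`).
#' @param cpgAnno `GRanges` CpG annotation (positions).
#' @param surrogates optional surrogate covariates.
#' @param cutoff beta-scale area cutoff per CpG (default 0.05).
#' @param min_cpgs minimum CpGs per region (default 3).
#' @param maxgap maximum intra-cluster gap in bp (default 500).
#' @param n_perm number of label permutations (default 100; < 10 warns).
#' @param alpha FDR significance threshold (default 0.01).
#' @param seed integer seed for the permutation stream.
#' @return data.frame: `dmr_id`, `chrom`, `start`, `end`, `n_cpgs`,
#'   `probe_ids` (`;`-joined, position-sorted), `delta_beta` (mean member
#'   delta beta), `area`, `p`, `fdr`, `signif`.
#' @export
findDMRs <- function(betas, samples, cpgAnno, surrogates = NULL,
                     cutoff = 0.05, min_cpgs = 3, maxgap = 500,
                     n_perm = 100, alpha = 0.01, seed = 1) {
  if (n_perm < 10) warnf("n_perm < 10: permutation p-values are unstable")
  samples <- as.data.frame(samples)
  cond <- factor(samples$condition, levels = c("control", "DS"))
  if (any(table(cond) < 2)) stopf("need >= 2 samples per condition")
  idx <- match(rownames(betas), cpgAnno$probe_id)
  if (anyNA(idx)) stopf("probes missing from annotation")
  chrom <- as.character(GenomicRanges::seqnames(cpgAnno))[idx]
  pos <- GenomicRanges::start(cpgAnno)[idx]
  ord <- order(chrom, pos, rownames(betas))
  betas <- betas[ord, , drop = FALSE]
  chrom <- chrom[ord]; pos <- pos[ord]
  cluster <- .clusterCpGs(chrom, pos, maxgap)

  X <- .methDesign(samples, surrogates)
  ci <- which(colnames(X) == "conditionDS")
  emptyRes <- data.frame(dmr_id = character(), chrom = character(),
                         start = integer(), end = integer(),
                         n_cpgs = integer(), probe_ids = character(),
                         delta_beta = numeric(), area = numeric(),
                         p = numeric(), fdr = numeric(), signif = logical(),
                         stringsAsFactors = FALSE)
  if (max(table(cluster)) < min_cpgs) return(emptyRes)

  candFor <- function(Xd) {
    coefs <- .betaScaleCoefs(betas, Xd, ci)
    sm <- .smoothWithin(coefs, cluster)
    .findCandidates(sm, cluster, cutoff, min_cpgs)
  }
  obs <- candFor(X)
  if (!nrow(obs)) return(emptyRes)

  set.seed(seed)
  null_areas <- numeric(0)
  Xp <- X
  ds_idx <- which(cond == "DS"); ct_idx <- which(cond == "control")
  n1 <- length(ds_idx); n0 <- length(ct_idx)
  ## balanced permutations (when group sizes allow): the permuted "DS"
  ## group draws half its members from each true condition, so genuine
  ## group effects cannot leak into the null area pool
  k_ds <- round(n1 * n1 / (n1 + n0))
  balanced <- k_ds >= 1 && k_ds < n1 && (n1 - k_ds) <= n0
  ## guard against draws nearly collinear with the covariates (sex,
  ## surrogates): such labelings would absorb genuine covariate structure
  ## into the permuted condition coefficient and corrupt the null pool
  Xc <- X[, -ci, drop = FALSE]
  qc_ <- qr(Xc)
  r_cond <- X[, ci] - qr.fitted(qc_, X[, ci])
  ## effect-transfer factor of a permuted labeling: the fraction of a true
  ## condition effect that its covariate-adjusted contrast would inherit.
  ## Plain balance is not enough once covariates are partialled out, so
  ## draws are restricted to near-zero transfer (and away from
  ## covariate collinearity, which would absorb covariate structure).
  gammaOf <- function(r_lab) {
    abs(sum(r_lab * r_cond)) / sum(r_lab^2)
  }
  drawLab <- function() {
    best <- NULL; best_g <- Inf
    for (try in 1:100) {
      lab <- numeric(n1 + n0)
      if (balanced) {
        lab[c(sample(ds_idx, k_ds), sample(ct_idx, n1 - k_ds))] <- 1
      } else {
        lab[sample(n1 + n0, n1)] <- 1
      }
      r_lab <- lab - qr.fitted(qc_, lab)
      v <- sum((lab - mean(lab))^2)
      r2 <- if (v == 0) 1 else 1 - sum(r_lab^2) / v
      if (r2 > 0.75) next
      g <- gammaOf(r_lab)
      if (g <= 0.25) return(lab)
      if (g < best_g) { best_g <- g; best <- lab }
    }
    best %||% lab
  }
  for (b in seq_len(n_perm)) {
    Xp[, ci] <- drawLab()
    null_areas <- c(null_areas, candFor(Xp)$area)
  }
  p <- vapply(obs$area, function(a)
    (1 + sum(null_areas >= a)) / (1 + length(null_areas)), 0)
  fdr <- stats::p.adjust(p, method = "BH")

  ds <- cond == "DS"
  db_all <- rowMeans(betas[, ds, drop = FALSE]) -
    rowMeans(betas[, !ds, drop = FALSE])
  rows <- lapply(seq_len(nrow(obs)), function(i) {
    ix <- obs$start_idx[i]:obs$end_idx[i]
    data.frame(chrom = chrom[ix[1]], start = min(pos[ix]),
               end = max(pos[ix]), n_cpgs = length(ix),
               probe_ids = paste(rownames(betas)[ix], collapse = ";"),
               delta_beta = mean(db_all[ix]), area = obs$area[i],
               p = p[i], fdr = fdr[i], stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[order(res$p, res$chrom, res$start), , drop = FALSE]
  res <- cbind(dmr_id = sprintf("DMR%03d", seq_len(nrow(res))), res,
               stringsAsFactors = FALSE)
  res$signif <- res$fdr < alpha
  rownames(res) <- NULL
  res
}
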