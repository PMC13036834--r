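#' Tissue-identity check from marker-gene expression
#'
#' Computes per-sample log2(CPM + 1) medians over thyroid and skeletal
#' muscle marker genes and flags samples whose muscle median reaches or
#' exceeds the thyroid median (ties flag: conservative exclusion). This is
#' the first quality-control step, run before robust PCA.
#'
#' @param counts gene x sample integer matrix.
#' @param geneAnno `GRanges` gene annotation with `symbol` metadata.
#' @param thyroid_markers,muscle_markers marker gene symbols; all must be
#'   present in the annotation.
#' @return data.frame with `sample_id`, `thyroid_log2cpm`,
#'   `muscle_log2cpm`, `contaminant_flag`.
#' @export
markerGeneCheck <- function(counts, geneAnno,
                            thyroid_markers = c("TPO", "TG", "TSHR", "SLC5A5"),
                            muscle_markers = c("MYH1", "MYOD1")) {
  if (!nrow(counts)) stopf("empty count matrix")
  sym <- geneAnno$symbol
  ids <- geneAnno$gene_id
  missing <- setdiff(c(thyroid_markers, muscle_markers), sym)
  if (length(missing))
    stopf("marker genes missing from annotation: %s",
          paste(missing, collapse = ", "))
  lcpm <- log2cpm(counts)
  rowsOf <- function(markers) {
    g <- ids[match(markers, sym)]
    g <- intersect(g, rownames(counts))
    if (!length(g)) stopf("marker genes absent from count matrix")
    lcpm[g, , drop = FALSE]
  }
  thy <- colMedians(rowsOf(thyroid_markers))
  mus <- colMedians(rowsOf(muscle_markers))
  data.frame(sample_id = colnames(counts), thyroid_log2cpm = thy,
             muscle_log2cpm = mus, contaminant_flag = mus >= thy,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Remove covariate effects by per-feature least squares
#'
#' Fits, for every feature, an ordinary least-squares model on the given
#' covariates (with intercept) and returns residuals plus the fitted
#' intercept, so the grand mean is preserved. Used to residualize
#' log2-transformed data before visualization and robust PCA, in the
#' spirit of limma's `removeBatchEffect`.
#'
#' @param m feature x sample matrix.
#' @param covariates data.frame (one row per sample) of covariates to
#'   remove; factors are expanded to a model matrix.
#' @return matrix of the same shape.
#' @export
residualize <- function(m, covariates) {
  X <- stats::model.matrix(~ ., data = as.data.frame(covariates))
  if (qr(X)$rank < ncol(X)) stopf("covariate design is rank deficient")
  fit <- stats::lm.fit(X, t(m))
  res <- t(fit$residuals)
  cf <- fit$coefficients
  intercept <- if (is.matrix(cf)) cf["(Intercept)", ] else cf["(Intercept)"]
  res + intercept
  }

#' Projection-pursuit robust PCA (grid algorithm)
#'
#' Finds successive unit loading directions maximizing a robust scale
#' (the MAD, consistency-scaled by 1.4826) of the projected samples, via
#' grid search in the planes spanned by the current direction and each
#' coordinate axis, halving the angular aperture each sweep; the data are
#' deflated between components. This is the projection-pursuit idea behind
#' the PCAgrid algorithm used for sample outlier detection in small
#' RNA-seq studies.
#'
#' The search runs in the SVD-reduced sample subspace (any direction
#' orthogonal to it has zero projections), which changes nothing about the
#' optimum but makes the grid search cheap when features vastly outnumber
#' samples.
#'
#' @param m feature x sample matrix (typically residualized log2 counts);
#'   each feature is median-centered internally.
#' @param k number of components (must not exceed `min(dim)`).
#' @param n_angles grid points per plane and sweep.
#' @param n_sweeps aperture-halving sweeps per component.
#' @return list with `loadings` (features x k, orthonormal), `scores`
#'   (samples x k), `scales` (robust scale per component, non-increasing),
#'   `center` (per-feature medians) and `od` (per-sample orthogonal
#'   distance to the k-dimensional model).
#' @export
pcaGrid <- function(m, k = 2, n_angles = 10, n_sweeps = 25) {
  n <- ncol(m); p <- nrow(m)
  if (n < 3) stopf("robust PCA needs at least 3 samples")
  if (k > min(n, p)) stopf("k exceeds matrix rank bound")
  ctr <- rowMedians(m)
  Y <- t(m - ctr)                       # samples x features
  if (all(abs(Y) < 1e-12)) stopf("zero-variance matrix")
  sv <- svd(Y)
  r <- sum(sv$d > max(sv$d) * 1e-10)
  if (k > r) stopf("k exceeds the rank of the centered data")
  Z <- sv$u[, seq_len(r), drop = FALSE] %*% diag(sv$d[seq_len(r)], r)
  V <- sv$v[, seq_len(r), drop = FALSE] # maps reduced coords -> features

  rscale <- function(x) 1.4826 * stats::mad(x, constant = 1)
  dirs <- matrix(0, r, k); scales <- numeric(k)
  Zd <- Z
  for (comp in seq_len(k)) {
    ax_sc <- apply(Zd, 2, rscale)
    a <- rep(0, r); a[which.max(ax_sc)] <- 1
    za <- Zd %*% a
    best <- rscale(za)
    aperture <- pi / 2
    for (sweep in seq_len(n_sweeps)) {
      theta <- seq(-aperture, aperture, length.out = n_angles)
      theta <- theta[theta != 0]
      for (j in seq_len(r)) {
        zj <- Zd[, j]
        for (t in theta) {
          ct <- cos(t); st <- sin(t)
          nrm <- sqrt(ct^2 + st^2 + 2 * ct * st * a[j])
          if (nrm < 1e-12) next
          sc <- rscale((ct * za + st * zj) / nrm)
          if (sc > best + 1e-12) {
            best <- sc
            a <- (ct * a + st * (seq_len(r) == j)) / nrm
            za <- Zd %*% a
          }
        }
      }
      aperture <- aperture / 2
    }
    ## orthogonalize against previous components (numerical safety)
    if (comp > 1) {
      prev <- dirs[, seq_len(comp - 1), drop = FALSE]
      a <- a - prev %*% crossprod(prev, a)
      a <- a / sqrt(sum(a^2))
      za <- Zd %*% a
    }
    dirs[, comp] <- a
    scales[comp] <- rscale(za)
    Zd <- Zd - (Zd %*% a) %*% t(a)      # deflate
  }
  ord <- order(scales, decreasing = TRUE)
  dirs <- dirs[, ord, drop = FALSE]; scales <- scales[ord]
  loadings <- V %*% dirs
  scores <- Z %*% dirs
  resid <- Z - scores %*% t(dirs)
  od <- sqrt(rowSums(resid^2))
  rownames(scores) <- colnames(m)
  rownames(loadings) <- rownames(m)
  list(loadings = loadings, scores = scores, scales = scales,
       center = ctr, od = od)
}

#' Flag outlying samples from robust PCA
#'
#' Computes the robust score distance per sample,
#' `sqrt(sum_j (score_ij / scale_j)^2)`, and flags samples exceeding
#' `sqrt(qchisq(quantile, k))`. When the `pca` object carries orthogonal
#' distances (`od`), the standard robust-PCA orthogonal-distance rule is
#' applied as well (cutoff from the chi-square-motivated scaled-normal
#' approximation on `od^(2/3)`), and a sample is an outlier if either
#' distance exceeds its cutoff.
#'
#' @param pca list from [pcaGrid()], or a score matrix.
#' @param scales robust scales (ignored when `pca` is a [pcaGrid()] list).
#' @param quantile chi-square quantile for the cutoff (default 0.975).
#' @return data.frame with `sample_id`, `score_distance`, `od`,
#'   `outlier_flag`.
#' @export
detectOutliers <- function(pca, scales = NULL, quantile = 0.975) {
  if (is.list(pca)) {
    scores <- pca$scores; scales <- pca$scales; od <- pca$od
  } else {
    scores <- pca; od <- NULL
  }
  scores <- as.matrix(scores)
  k <- ncol(scores)
  z <- sweep(scores, 2, scales, "/")
  z[, scales <= 0] <- 0
  sd_ <- sqrt(rowSums(z^2))
  cutoff <- sqrt(stats::qchisq(quantile, df = k))
  flag <- sd_ > cutoff
  od_flag <- rep(FALSE, nrow(scores))
  if (!is.null(od) && any(od > 1e-8)) {
    od23 <- od^(2 / 3)
    mu <- stats::median(od23); s <- stats::mad(od23)
    if (s > 0) {
      od_cut <- (mu + s * stats::qnorm(quantile))^(3 / 2)
      od_flag <- od > od_cut
    }
  }
  data.frame(sample_id = rownames(scores) %||% as.character(seq_len(nrow(scores))),
             score_distance = sd_, od = if (is.null(od)) NA_real_ else od,
             outlier_flag = flag | od_flag,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Euclidean sample-to-sample distances
#'
#' Pairwise Euclidean distances between sample columns, as used for the
#' sample-distance heatmap and average-linkage hierarchical clustering.
#'
#' @param m feature x sample matrix.
#' @return symmetric distance matrix with sample dimnames.
#' @export
sampleDistances <- function(m) {
  if (ncol(m) < 2) stopf("need at least 2 samples")
  d <- as.matrix(stats::dist(t(m)))
  dimnames(d) <- list(colnames(m), colnames(m))
  d
}

#' Two-step sample quality control
#'
#' Runs the marker-gene tissue-identity check, removes flagged samples,
#' then performs projection-pursuit robust PCA on sex-residualized
#' log2(CPM + 1) of prefiltered genes and flags statistically deviant
#' samples by robust distances.
#'
#' @param counts gene x sample integer matrix.
#' @param samples sample sheet (`sample_id`, `condition`, `sex`).
#' @param geneAnno gene annotation `GRanges`.
#' @param k robust components used for outlier calling.
#' @param quantile outlier cutoff quantile (default 0.99: with ~10
#'   samples a per-sample 0.975 rule would false-flag some sample in
#'   roughly one cohort in five).
#' @param prior prior count added to CPM before the log2 transform used
#'   for robust PCA (default 5, damping low-count variance).
#' @return list with `report` (per-sample QC table), `keep` (retained
#'   sample ids), `excluded` (ids with reasons), and the `pca` object.
#' @export
runSampleQC <- function(counts, samples, geneAnno, k = 2, quantile = 0.99,
                        prior = 5) {
  samples <- as.data.frame(samples)
  mk <- markerGeneCheck(counts, geneAnno)
  keep1 <- mk$sample_id[!mk$contaminant_flag]
  cnt <- counts[, keep1, drop = FALSE]
  smp <- samples[match(keep1, samples$sample_id), , drop = FALSE]
  kept_genes <- prefilterGenes(cnt)
  lm2 <- log2cpm(cnt[kept_genes, , drop = FALSE], prior = prior)
  res <- residualize(lm2, data.frame(sex = smp$sex))
  pca <- pcaGrid(res, k = k)
  out <- detectOutliers(pca, quantile = quantile)
  report <- merge(mk, out, by = "sample_id", all.x = TRUE, sort = FALSE)
  report <- report[match(mk$sample_id, report$sample_id), , drop = FALSE]
  report$excluded <- report$contaminant_flag |
    (!is.na(report$outlier_flag) & report$outlier_flag)
  report$reason <- ifelse(report$contaminant_flag, "contaminant",
                          ifelse(report$excluded, "outlier", ""))
  keep <- report$sample_id[!report$excluded]
  list(report = report,
       keep = keep,
       excluded = report[report$excluded, c("sample_id", "reason")],
       pca = pca)
}
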