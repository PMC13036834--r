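test_that("marker-gene check flags muscle-like and degenerate samples", {
  st <- defaultStudy()
  mk <- markerGeneCheck(studyCounts(st), geneAnnotation(st))
  tr <- truthLedger(st)$samples
  contam <- tr$sample_id[tr$role == "contaminant"]
  expect_setequal(mk$sample_id[mk$contaminant_flag], contam)

  ## clear thyroid profile is not flagged; all-zero sample ties and is flagged
  g <- geneAnnotation(st)
  thy <- g$gene_id[g$marker_class == "thyroid"]
  mus <- g$gene_id[g$marker_class == "muscle"]
  cnt <- studyCounts(st)[, 1:2]
  cnt[, 2] <- 0L
  cnt[thy, 1] <- 5000L; cnt[mus, 1] <- 1L
  mk2 <- markerGeneCheck(cnt, g)
  expect_false(mk2$contaminant_flag[1])
  expect_true(mk2$contaminant_flag[2])

  expect_error(markerGeneCheck(cnt, g, thyroid_markers = c("TPO", "NOPE")),
               "NOPE")
})

test_that("residualization removes modeled covariates and matches normal equations", {
  set.seed(11)
  m <- matrix(rnorm(30), 5, 6, dimnames = list(paste0("f", 1:5),
                                               paste0("s", 1:6)))
  sex <- factor(c("F", "M", "F", "M", "F", "M"))
  ## planted additive sex shift is removed exactly
  shifted <- m + matrix(rep(ifelse(sex == "M", 2, 0), each = 5), 5)
  r <- residualize(shifted, data.frame(sex = sex))
  gmF <- rowMeans(r[, sex == "F"]); gmM <- rowMeans(r[, sex == "M"])
  expect_equal(gmF, gmM, tolerance = 1e-12)

  ## direct normal-equations oracle, feature by feature
  x <- rnorm(6)
  r2 <- residualize(m, data.frame(x = x))
  X <- cbind(1, x)
  for (i in 1:5) {
    beta <- solve(t(X) %*% X, t(X) %*% m[i, ])
    expect_equal(unname(r2[i, ]), unname(m[i, ] - drop(X %*% beta) + beta[1]),
                 tolerance = 1e-10)
  }

  ## covariate orthogonal to every feature leaves the data unchanged
  m0 <- matrix(rep(c(1, -1, 1, -1), 2), 2, 4, byrow = TRUE)
  r3 <- residualize(m0, data.frame(z = c(1, 1, -1, -1)))
  expect_equal(r3, m0, tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(residualize(m, data.frame(a = rep(0, 6))), "rank")
})

test_that("grid projection pursuit recovers the dominant direction on clean data", {
  ## the sample MAD maximizer is a noisy estimator, so the agreement with
  ## classical PCA is asserted on the typical case over fixed seeds
  angs <- vapply(1:5, function(s) {
    set.seed(s)
    n <- 200
    scores <- cbind(rnorm(n, 0, 6), rnorm(n, 0, 0.5))
    rot <- qr.Q(qr(matrix(rnorm(25), 5)))[, 1:2]
    m <- t(scores %*% t(rot)) + rnorm(5 * n, 0, 0.02)  # features x samples
    p <- pcaGrid(m, k = 2)
    cl <- prcomp(t(m))$rotation[, 1]
    if (s == 1) {
      ## orthonormal loadings, non-increasing robust scales
      expect_equal(crossprod(p$loadings), diag(2), tolerance = 1e-8,
                   ignore_attr = TRUE)
      expect_true(all(diff(p$scales) <= 1e-8))
    }
    acos(min(abs(sum(p$loadings[, 1] * cl)), 1)) * 180 / pi
  }, 0)
  expect_lt(median(angs), 5)
})

test_that("full-rank projection reconstructs the median-centered data", {
  set.seed(22)
  m <- matrix(rnorm(40), 8, 5)
  p <- pcaGrid(m, k = 5)   # median-centered 5-sample data have rank 5
  ctr <- m - apply(m, 1, median)
  rec <- p$scores %*% t(p$loadings)
  expect_equal(rec, t(ctr), tolerance = 1e-6, ignore_attr = TRUE)
  expect_lt(max(p$od), 1e-6)
})

test_that("a gross outlier bends classical PCA but not the robust direction", {
  set.seed(23)
  n <- 40
  m <- rbind(x = rnorm(n, 0, 3), y = rnorm(n, 0, 0.5))
  clean_cl <- prcomp(t(m))$rotation[, 1]
  clean_rb <- pcaGrid(m, k = 1)$loadings[, 1]
  m_out <- cbind(m, c(0, 40))          # one gross outlier along y
  dirty_cl <- prcomp(t(m_out))$rotation[, 1]
  dirty_rb <- pcaGrid(m_out, k = 1)$loadings[, 1]
  ang <- function(a, b) acos(min(abs(sum(a * b)), 1)) * 180 / pi
  expect_lt(ang(clean_rb, dirty_rb), ang(clean_cl, dirty_cl))
  expect_lt(ang(clean_rb, dirty_rb), 15)
})

test_that("robust and classical subspaces agree on outlier-free Gaussian data", {
  angs <- vapply(1:5, function(s) {
    set.seed(100 + s)
    n <- 100
    lat <- cbind(rnorm(n, 0, 6), rnorm(n, 0, 1))
    rot <- qr.Q(qr(matrix(rnorm(64), 8)))[, 1:2]
    m <- t(lat %*% t(rot)) + rnorm(8 * n, 0, 0.1)
    p <- pcaGrid(m, k = 1)
    cl <- prcomp(t(m))$rotation[, 1]
    acos(min(abs(sum(p$loadings[, 1] * cl)), 1)) * 180 / pi
  }, 0)
  expect_lt(median(angs), 10)
})

test_that("score distances flag samples beyond the chi-square cutoff", {
  ## identical samples: no variation, no flags
  sc <- matrix(0, 4, 1)
  out <- detectOutliers(sc, scales = 0)
  expect_false(any(out$outlier_flag))
  expect_equal(out$score_distance, rep(0, 4))
  ## k = 1, one score at 10 robust scales: 10 > sqrt(5.024)
  out <- detectOutliers(matrix(c(0, 0, 0, 10), 4, 1), scales = 1)
  expect_equal(out$outlier_flag, c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(sqrt(qchisq(0.975, 1)), sqrt(5.023886), tolerance = 1e-5)
})

test_that("euclidean sample distances match a brute-force double loop", {
  m <- matrix(c(0, 0, 0, 3, 1, 1), 3, 2,
              dimnames = list(NULL, c("a", "b")))
  d <- sampleDistances(cbind(m, m[, 1, drop = FALSE]))
  expect_equal(d[1, 3], 0)
  m2 <- matrix(c(1, 1, 1, 1, 1, 4), 3, 2)   # one feature differs by 3
  expect_equal(sampleDistances(m2)[1, 2], 3)
  set.seed(25)
  m3 <- matrix(rnorm(20), 5, 4)
  d3 <- sampleDistances(m3)
  for (i in 1:4) for (j in 1:4)
    expect_equal(d3[i, j], sqrt(sum((m3[, i] - m3[, j])^2)), tolerance = 1e-12)
})

test_that("QC pipeline excludes exactly the planted problem samples", {
  st <- defaultStudy()
  qc <- defaultQC()
  tr <- truthLedger(st)$samples
  expect_setequal(qc$excluded$sample_id, tr$sample_id)
  expect_equal(sort(qc$excluded$reason[match(tr$sample_id,
                                             qc$excluded$sample_id)]),
               sort(tr$role))
  ## contaminants are excluded before robust PCA runs
  expect_true(all(is.na(
    qc$report$score_distance[qc$report$reason == "contaminant"])))
})
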