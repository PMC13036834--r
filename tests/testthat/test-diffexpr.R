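test_that("count prefilter keeps genes with >= 10 counts in >= 4 samples", {
  cnt <- rbind(
    kept    = c(12L, 11L, 10L, 10L, 0L, 0L, 0L, 0L, 0L),
    dropped = rep(9L, 9),
    zero    = rep(0L, 9))
  colnames(cnt) <- paste0("s", 1:9)
  expect_identical(prefilterGenes(cnt), "kept")
})

test_that("median-of-ratios size factors behave like the hand computation", {
  set.seed(41)
  base <- rpois(50, 100) + 1L
  cnt <- cbind(s1 = base, s2 = 2L * base)
  rownames(cnt) <- paste0("g", 1:50)
  sf <- medianRatioSizeFactors(cnt)
  ## geometric mean is base*sqrt(2): factors 1/sqrt(2) and sqrt(2)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)

  same <- cbind(s1 = base, s2 = base, s3 = base)
  expect_equal(unname(medianRatioSizeFactors(same)), rep(1, 3))

  ## scale equivariance: scaling one sample scales its factor
  cnt3 <- cbind(s1 = base, s2 = base + 7L, s3 = base * 3L)
  sf3 <- medianRatioSizeFactors(cnt3)
  cnt4 <- cnt3; cnt4[, 2] <- cnt4[, 2] * 5L
  sf4 <- medianRatioSizeFactors(cnt4)
  ## the reference geometric mean changes too; compare factor ratios
  expect_equal(sf4[2] / sf4[1], 5 * sf3[2] / sf3[1], tolerance = 1e-12)

  allzero <- cbind(s1 = c(0L, 5L), s2 = c(3L, 0L))
  rownames(allzero) <- c("a", "b")
  expect_error(medianRatioSizeFactors(allzero), "nonzero")
})

test_that("NB Wald estimate approaches the exact ratio as dispersion vanishes", {
  smp <- data.frame(sample_id = paste0("s", 1:8),
                    condition = rep(c("control", "DS"), each = 4),
                    sex = rep(c("F", "M"), 4))
  L <- 1.25
  cnt <- rbind(g1 = c(rep(400L, 4), rep(as.integer(400 * 2^L), 4)),
               g2 = rep(500L, 8))
  colnames(cnt) <- smp$sample_id
  de <- nbWaldTest(cnt, smp, size_factors = setNames(rep(1, 8), smp$sample_id),
                   dispersion = 1e-8)
  ## integer rounding of the counts moves the exact ratio slightly off L
  expect_equal(de$log2fc[1], log2(cnt[1, 5] / 400), tolerance = 1e-6)
  expect_equal(de$log2fc[1], L, tolerance = 1e-3)
  expect_equal(de$log2fc[2], 0, tolerance = 1e-6)
  ## with sex orthogonal to condition, the estimate equals the plain
  ## ratio of normalized group means in the zero-dispersion limit
  expect_equal(de$log2fc[1],
               log2(mean(cnt[1, 5:8]) / mean(cnt[1, 1:4])), tolerance = 1e-4)
})

test_that("planted log2 fold changes are recovered with small bias", {
  cfg <- simulationConfig(n_ds = 6, n_control = 6, nb_dispersion = 0.05,
                          n_contaminant_samples = 0, n_outlier_samples = 0,
                          seed = 55)
  st <- simulateStudy(cfg)
  smp <- as.data.frame(sampleSheet(st))
  cnt <- studyCounts(st)
  kept <- prefilterGenes(cnt)
  de <- nbWaldTest(cnt[kept, ], smp, geneAnno = geneAnnotation(st))
  tr <- truthLedger(st)$de_genes
  tr <- tr[tr$type == "planted" & tr$gene_id %in% de$gene_id, ]
  err <- de$log2fc[match(tr$gene_id, de$gene_id)] - tr$true_log2fc
  expect_lt(abs(mean(err)), 0.1)
})

test_that("shrinkage contracts estimates toward zero, never past the raw value", {
  set.seed(43)
  de <- data.frame(log2fc = rnorm(200, 0, 1),
                   se = abs(rnorm(200, 0.3, 0.1)))
  sh <- shrinkLogFC(de)
  expect_true(all(abs(sh$shrunken_log2fc) <= abs(sh$log2fc) + 1e-12))
  expect_true(all(sign(sh$shrunken_log2fc) == sign(sh$log2fc) |
                  sh$shrunken_log2fc == 0))
  ## zero standard error: no shrinkage for that gene
  de0 <- data.frame(log2fc = c(1, -2), se = c(0, 0.5))
  expect_equal(shrinkLogFC(de0)$shrunken_log2fc[1], 1)
  ## shrinkage factor equals tau^2 / (tau^2 + se^2) with the estimated
  ## (or fallen-back) prior variance; se >> tau drives estimates to ~0
  deT <- data.frame(log2fc = rnorm(100, 0, 0.01), se = rep(1, 100))
  shT <- shrinkLogFC(deT)
  tau2 <- attr(shT, "shrink_tau2")
  expect_equal(shT$shrunken_log2fc, deT$log2fc * tau2 / (tau2 + 1),
               tolerance = 1e-12)
  deS <- data.frame(log2fc = rnorm(100, 0, 0.005), se = rep(10, 100))
  expect_lte(max(abs(shrinkLogFC(deS)$shrunken_log2fc)),
             max(abs(deS$log2fc)) / 2)
})

test_that("BH adjustment equals the textbook step-up computation", {
  set.seed(44)
  for (rep in 1:10) {
    p <- runif(sample(5:40, 1))^sample(1:3, 1)
    expect_equal(p.adjust(p, "BH"), bruteBH(p), tolerance = 1e-12)
  }
})

test_that("chi-squared enrichment statistics match the direct formula", {
  de <- data.frame(gene_id = paste0("g", 1:1100),
                   log2fc = rep(c(1, -1), 550),
                   p = 0.5, fdr = 1, chrom = "chr1")
  ## 2x2 oracle: [[30,70],[100,900]] laid out as DEG x chr21
  de$chrom[1:130] <- c(rep("chr21", 30), rep("chr1", 100))
  de$fdr[1:130] <- 0
  de$chrom[131:200] <- "chr21"
  res <- chromosomeEnrichment(de)
  O <- matrix(c(30, 70, 100, 900), 2, byrow = TRUE)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  expect_equal(res$chr21$statistic, sum((O - E)^2 / E), tolerance = 1e-10)
  expect_equal(res$chr21$p,
               pchisq(sum((O - E)^2 / E), 1, lower.tail = FALSE),
               tolerance = 1e-12)

  ## no significant genes: p-values of 1 with a warning
  de$fdr <- 1
  expect_warning(res0 <- chromosomeEnrichment(de), "no significant")
  expect_equal(res0$chr21$p, 1)
})

test_that("uniformity p-values are calibrated for uniformly drawn DEGs", {
  set.seed(46)
  chroms <- paste0("chr", c(1:20, 22))
  ps <- replicate(300, {
    de <- data.frame(gene_id = paste0("g", 1:4200),
                     log2fc = rnorm(4200),
                     p = 0.5, fdr = 1,
                     chrom = rep(chroms, each = 200))
    de$fdr[sample(4200, 400)] <- 0
    chromosomeEnrichment(de)$uniformity$p
  })
  ## approximately uniform: no gross miscalibration in either tail
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.03)
  expect_lt(abs(mean(ps < 0.5) - 0.5), 0.15)
})
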