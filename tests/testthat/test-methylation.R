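test_that("probe filter drops every flagged probe and only those", {
  pos <- seq(100, by = 1000, length.out = 10)
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(pos, pos),
    probe_id = sprintf("cg%02d", 1:10),
    flag_allosomal = c(TRUE, rep(FALSE, 9)),
    flag_chr21 = c(FALSE, TRUE, rep(FALSE, 8)),
    flag_polymorphic = c(FALSE, FALSE, TRUE, rep(FALSE, 7)),
    flag_crossreactive = c(rep(FALSE, 3), TRUE, rep(FALSE, 6)))
  names(gr) <- gr$probe_id
  b <- matrix(0.5, 10, 2, dimnames = list(gr$probe_id, c("a", "b")))
  kept <- filterProbes(b, gr)
  expect_length(kept, 6)
  expect_false(any(sprintf("cg%02d", 1:4) %in% kept))
  expect_error(filterProbes(rbind(b, cgXX = c(0.5, 0.5)), gr), "cgXX")
})

test_that("beta/M transforms are exact and mutually inverse", {
  expect_equal(betaToM(0.5), 0)
  expect_equal(betaToM(0.8), 2)
  b <- seq(0.001, 0.999, length.out = 101)
  expect_equal(mToBeta(betaToM(b)), b, tolerance = 1e-12)
  ## boundary values are clipped, not infinite
  expect_true(all(is.finite(betaToM(c(0, 1)))))
})

test_that("residual-PCA surrogate recovers a planted orthogonal batch effect", {
  st <- defaultStudy()
  keep <- defaultQC()$keep
  bet <- studyBetas(st)[, keep]
  smp <- as.data.frame(sampleSheet(st))
  smp <- smp[match(keep, smp$sample_id), ]
  bet <- bet[filterProbes(bet, cpgAnnotation(st)), ]
  sv <- estimateSurrogates(betaToM(bet), smp, n_sv = 1)
  batch <- as.numeric(factor(truthLedger(st)$batch[keep]))
  expect_gt(abs(cor(sv[, 1], batch)), 0.9)
  ## orthogonal to the design columns by construction
  X <- model.matrix(~ condition + sex, smp)
  expect_lt(max(abs(crossprod(X, sv))), 1e-6)
  expect_error(estimateSurrogates(betaToM(bet), smp, n_sv = 9), "n_sv")
})

test_that("DMP linear model matches a hand-computed regression", {
  smp <- data.frame(sample_id = paste0("s", 1:6),
                    condition = rep(c("control", "DS"), each = 3),
                    sex = c("F", "M", "F", "M", "F", "M"))
  set.seed(51)
  b <- matrix(runif(4 * 6, 0.2, 0.8), 4, 6,
              dimnames = list(paste0("cg", 1:4), smp$sample_id))
  res <- dmpTest(b, smp)
  smp$condition <- factor(smp$condition, levels = c("control", "DS"))
  X <- model.matrix(~ condition + sex, smp)
  for (i in 1:4) {
    y <- betaToM(b[i, ])
    beta <- solve(t(X) %*% X, t(X) %*% y)
    r <- y - drop(X %*% beta)
    s2 <- sum(r^2) / (6 - 3)
    se <- sqrt(s2 * solve(t(X) %*% X)[2, 2])
    expect_equal(res$m_coefficient[i], beta[2], tolerance = 1e-10)
    expect_equal(res$t_stat[i], beta[2] / se, tolerance = 1e-10)
    expect_equal(res$p[i], 2 * pt(-abs(beta[2] / se), 3), tolerance = 1e-12)
  }
  expect_equal(res$delta_beta,
               unname(rowMeans(b[, 4:6]) - rowMeans(b[, 1:3])))
})

test_that("an exact group shift with no noise gives a vanishing DMP p", {
  smp <- data.frame(sample_id = paste0("s", 1:8),
                    condition = rep(c("control", "DS"), each = 4),
                    sex = rep(c("F", "M"), 4))
  b <- matrix(rep(c(0.3, 0.3, 0.3, 0.3, 0.5, 0.5, 0.5, 0.5), 2), 2,
              byrow = TRUE, dimnames = list(c("cg1", "cg2"), smp$sample_id))
  b[2, ] <- b[2, ] + rep(c(0, 0.001), 4)   # tiny sex wiggle avoids 0/0
  res <- dmpTest(b, smp)
  expect_lt(res$p[2], 1e-10)
  expect_equal(res$delta_beta, c(0.2, 0.2), tolerance = 1e-12)
})

test_that("DMP test holds its nominal false-positive rate", {
  cfg <- simulationConfig(dosage_factor = 1, n_planted_de = 0,
                          n_planted_dmrs = 0, n_cis_effects = 0,
                          n_cpgs = 2000,
                          n_contaminant_samples = 0, n_outlier_samples = 0,
                          seed = 57)
  st <- simulateStudy(cfg)
  smp <- as.data.frame(sampleSheet(st))
  bet <- studyBetas(st)[filterProbes(studyBetas(st), cpgAnnotation(st)), ]
  sv <- estimateSurrogates(betaToM(bet), smp)
  res <- dmpTest(bet, smp, sv)
  expect_lt(abs(mean(res$p < 0.05) - 0.05), 0.02)
})

test_that("candidate regions follow the area, run-length and sign rules", {
  sm <- c(0.08, 0.07, 0.06)
  cand <- trisomics:::.findCandidates(sm, rep(1, 3), cutoff = 0.05,
                                      min_cpgs = 3)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$area, 0.21)       # hand-summed |0.08|+|0.07|+|0.06|
  ## a sign flip inside the run breaks it
  cand <- trisomics:::.findCandidates(c(0.08, -0.07, 0.06), rep(1, 3),
                                      0.05, 3)
  expect_equal(nrow(cand), 0)
  ## runs never cross cluster boundaries
  cand <- trisomics:::.findCandidates(rep(0.1, 6), c(1, 1, 1, 2, 2, 2),
                                      0.05, 3)
  expect_equal(nrow(cand), 2)
  ## below-cutoff member interrupts the run
  cand <- trisomics:::.findCandidates(c(0.08, 0.03, 0.08, 0.08, 0.08),
                                      rep(1, 5), 0.05, 3)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$start_idx, 3)
})

test_that("detected DMRs respect positional and summary invariants", {
  st <- defaultStudy()
  m <- defaultMeth()
  dmrs <- m$dmrs
  expect_gt(nrow(dmrs), 0)
  anno <- cpgAnnotation(st)
  smp <- defaultDE()$samples
  ds <- smp$condition == "DS"
  for (i in seq_len(nrow(dmrs))) {
    pr <- strsplit(dmrs$probe_ids[i], ";")[[1]]
    pos <- GenomicRanges::start(anno)[match(pr, anno$probe_id)]
    expect_true(all(diff(pos) > 0))                    # sorted members
    expect_true(all(diff(pos) <= 500))                 # within maxgap
    expect_equal(dmrs$start[i], min(pos))
    expect_equal(dmrs$end[i], max(pos))
    expect_gte(dmrs$n_cpgs[i], 3)
    db <- rowMeans(m$betas[pr, ds, drop = FALSE]) -
      rowMeans(m$betas[pr, !ds, drop = FALSE])
    expect_equal(dmrs$delta_beta[i], mean(db), tolerance = 1e-12)
    expect_gte(dmrs$area[i], dmrs$n_cpgs[i] * 0.05)
  }
  expect_true(all(dmrs$p > 0))                         # +1/+1 keeps p > 0
})

test_that("planted DMRs are detected and null data yield none", {
  st <- defaultStudy()
  dmrs <- defaultMeth()$dmrs
  tr <- truthLedger(st)$dmrs
  hits <- vapply(seq_len(nrow(tr)), function(i)
    any(dmrs$signif & dmrs$chrom == tr$chrom[i] &
        dmrs$start <= tr$end[i] & dmrs$end >= tr$start[i]), TRUE)
  expect_gte(mean(hits), 0.8)
  ## sign of the recovered effect matches the planted direction
  for (i in which(hits)) {
    j <- which(dmrs$signif & dmrs$chrom == tr$chrom[i] &
               dmrs$start <= tr$end[i] & dmrs$end >= tr$start[i])[1]
    expect_equal(sign(dmrs$delta_beta[j]), sign(tr$true_delta_beta[i]))
  }

  cfg <- simulationConfig(dosage_factor = 1, n_planted_de = 0,
                          n_planted_dmrs = 0, n_cis_effects = 0,
                          n_contaminant_samples = 0, n_outlier_samples = 0,
                          seed = 58)
  stn <- simulateStudy(cfg)
  smp <- as.data.frame(sampleSheet(stn))
  bet <- studyBetas(stn)[filterProbes(studyBetas(stn), cpgAnnotation(stn)), ]
  svn <- estimateSurrogates(betaToM(bet), smp)
  null_dmrs <- findDMRs(bet, smp, cpgAnnotation(stn), svn, seed = 59)
  expect_equal(sum(null_dmrs$signif), 0)
})
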