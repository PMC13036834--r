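# shared fixtures, computed lazily and cached for the whole test run

.fixtures <- new.env(parent = emptyenv())

cachedFixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures))
    assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures)
}

defaultStudy <- function() cachedFixture("study", simulateStudy())

defaultQC <- function() cachedFixture("qc", {
  st <- defaultStudy()
  runSampleQC(studyCounts(st), sampleSheet(st), geneAnnotation(st))
})

# post-QC counts, samples and DE results for the default study
defaultDE <- function() cachedFixture("de", {
  st <- defaultStudy()
  keep <- defaultQC()$keep
  cnt <- studyCounts(st)[, keep]
  smp <- as.data.frame(sampleSheet(st))
  smp <- smp[match(keep, smp$sample_id), ]
  kept <- prefilterGenes(cnt)
  sf <- medianRatioSizeFactors(cnt[kept, ])
  list(counts = cnt[kept, ], samples = smp, sf = sf,
       de = nbWaldTest(cnt[kept, ], smp, sf, geneAnno = geneAnnotation(st)))
})

defaultMeth <- function() cachedFixture("meth", {
  st <- defaultStudy()
  keep <- defaultQC()$keep
  bet <- studyBetas(st)[, keep]
  smp <- defaultDE()$samples
  kp <- filterProbes(bet, cpgAnnotation(st))
  bet <- bet[kp, ]
  sv <- estimateSurrogates(betaToM(bet), smp)
  dmrs <- findDMRs(bet, smp, cpgAnnotation(st), sv, seed = 101)
  list(betas = bet, sv = sv, dmrs = dmrs)
})

defaultEqtm <- function() cachedFixture("eqtm", {
  st <- defaultStudy()
  d <- defaultDE(); m <- defaultMeth()
  runIntegration(m$dmrs, d$de, m$betas, d$counts, d$sf,
                 geneAnnotation(st), n_boot = 5000, n_perm = 5000, seed = 1)
})

# tiny gene annotation builder for interval tests
toyGenes <- function(chrom, start, end, strand = "+",
                     gene_id = sprintf("g%02d", seq_along(start))) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                               strand = strand, gene_id = gene_id,
                               symbol = gene_id,
                               marker_class = "none",
                               thyroid_related = FALSE)
  names(gr) <- gene_id
  gr
}

# brute-force BH step-up (textbook definition), oracle for p.adjust
bruteBH <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}
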